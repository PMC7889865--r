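# Contig-to-reference alignment. Two interchangeable backends produce the
# same edit-operation table: a built-in anchor-chain aligner (unique k-mer
# anchors, longest-increasing-subsequence chaining, affine-gap alignment of
# the inter-anchor segments) for toy genomes, and a PAF + cs-string parser
# for an external minimap2-style aligner.

# Edit-op tibble columns: op ("M", "X", "I", "D"), ref_pos (0-based genome),
# query_pos (0-based contig), len, ref_bases, alt_bases.

#' Align one contig to a reference window
#'
#' Finds k-mers unique in both the contig and the reference window, chains
#' them colinearly (longest increasing subsequence), and aligns the
#' segments between consecutive anchor runs with an affine-gap global
#' alignment. Contig sequence outside the outermost anchors is
#' soft-clipped. Intended for the near-reference contigs this pipeline
#' produces; it is not a general-purpose aligner.
#'
#' @param contig_seq Contig sequence.
#' @param ref_seq Full reference sequence.
#' @param window_start,window_end 0-based half-open reference window to
#'   align against.
#' @param anchor_k Anchor k-mer size (default 21).
#' @param max_seg Longest inter-anchor segment to align before giving up
#'   and emitting the region as a paired deletion/insertion (default
#'   20000 bp).
#' @return A one-row tibble: `ref_start`, `ref_end`, `query_start`,
#'   `query_end`, `mapq` (60), `ops` (list column of the edit-op tibble),
#'   or `NULL` when no anchor chain exists.
#' @export
align_contig <- function(contig_seq, ref_seq, window_start, window_end,
                         anchor_k = 21, max_seg = 20000) {
  win <- substring(ref_seq, window_start + 1L, window_end)
  qk <- seq_kmers(contig_seq, anchor_k)
  rk <- seq_kmers(win, anchor_k)
  q_once <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))
  r_once <- !(duplicated(rk) | duplicated(rk, fromLast = TRUE))
  m <- match(qk, rk)
  qpos <- which(q_once & !is.na(m) & r_once[m])
  if (length(qpos) == 0) return(NULL)
  rpos <- m[qpos]

  # collapse anchor runs: same diagonal AND anchor gaps <= k (overlapping
  # or adjacent k-mer windows guarantee the whole run span matches the
  # reference; a larger gap can hide a substitution and must become an
  # inter-run segment). Then chain runs by longest increasing subsequence
  # of their reference starts.
  diag <- rpos - qpos
  brk <- diff(diag) != 0 | diff(qpos) > anchor_k
  starts <- c(1L, which(brk) + 1L)
  ends <- c(starts[-1] - 1L, length(qpos))
  runs <- tibble(q0 = qpos[starts], q1 = qpos[ends],
                 r0 = rpos[starts], r1 = rpos[ends])
  runs <- runs[lis_indices(runs$r0), , drop = FALSE]
  # successive runs may overlap through breakpoint micro-homology (bases
  # shared by the matches on both sides of an indel): trim the head of the
  # next run to start past the previous one, and drop runs consumed whole
  keep <- rep(TRUE, nrow(runs))
  last_q <- -Inf; last_r <- -Inf
  for (i in seq_len(nrow(runs))) {
    trim <- max(0, last_q - runs$q0[i] + 1, last_r - runs$r0[i] + 1)
    if (runs$q0[i] + trim > runs$q1[i]) {
      keep[i] <- FALSE
      next
    }
    runs$q0[i] <- runs$q0[i] + trim
    runs$r0[i] <- runs$r0[i] + trim
    last_q <- runs$q1[i] + anchor_k - 1
    last_r <- runs$r1[i] + anchor_k - 1
  }
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(NULL)

  ops <- list()
  add_op <- function(op, ref_pos, query_pos, len, ref_bases = "",
                     alt_bases = "") {
    ops[[length(ops) + 1L]] <<- tibble(
      op = op, ref_pos = as.integer(ref_pos),
      query_pos = as.integer(query_pos), len = as.integer(len),
      ref_bases = ref_bases, alt_bases = alt_bases)
  }
  # 1-based run coordinates -> 0-based
  g_r <- function(r) window_start + r - 1L

  for (i in seq_len(nrow(runs))) {
    # match over this run (anchors overlap; run covers q0..q1+k-1)
    mlen <- runs$q1[i] + anchor_k - runs$q0[i]
    add_op("M", g_r(runs$r0[i]), runs$q0[i] - 1L, mlen)
    if (i < nrow(runs)) {
      qs <- runs$q1[i] + anchor_k       # 1-based first unaligned q
      qe <- runs$q0[i + 1] - 1L
      rs <- runs$r1[i] + anchor_k
      re <- runs$r0[i + 1] - 1L
      qseg <- if (qe >= qs) substring(contig_seq, qs, qe) else ""
      rseg <- if (re >= rs) substring(win, rs, re) else ""
      seg_ops <- align_segment(qseg, rseg, g_r(rs), qs - 1L, max_seg)
      ops <- c(ops, seg_ops)
    }
  }
  ops <- bind_rows(ops)
  tibble(
    ref_start = g_r(runs$r0[1]) ,
    ref_end = g_r(runs$r1[nrow(runs)]) + anchor_k,
    query_start = runs$q0[1] - 1L,
    query_end = runs$q1[nrow(runs)] + anchor_k - 1L,
    mapq = 60L,
    ops = list(ops)
  )
}

# Align an inter-anchor segment; returns list of edit-op tibbles.
# ref_pos0/query_pos0 are the 0-based coordinates of the segment starts.
align_segment <- function(qseg, rseg, ref_pos0, query_pos0, max_seg) {
  ql <- nchar(qseg); rl <- nchar(rseg)
  res <- list()
  add <- function(op, rp, qp, len, rb = "", ab = "") {
    res[[length(res) + 1L]] <<- tibble(op = op, ref_pos = as.integer(rp),
                                       query_pos = as.integer(qp),
                                       len = as.integer(len),
                                       ref_bases = rb, alt_bases = ab)
  }
  if (ql == 0 && rl == 0) return(res)
  if (ql == 0) { add("D", ref_pos0, query_pos0, rl, rb = rseg); return(res) }
  if (rl == 0) { add("I", ref_pos0, query_pos0, ql, ab = qseg); return(res) }
  if (ql > max_seg || rl > max_seg) {
    add("D", ref_pos0, query_pos0, rl, rb = rseg)
    add("I", ref_pos0 + rl, query_pos0, ql, ab = qseg)
    return(res)
  }
  if (ql == rl) {
    # equal-length segment: treat positionwise (substitution block)
    qa <- strsplit(qseg, "")[[1]]; ra <- strsplit(rseg, "")[[1]]
    r <- rle(qa == ra)
    off <- 0L
    for (t in seq_along(r$lengths)) {
      if (r$values[t]) {
        add("M", ref_pos0 + off, query_pos0 + off, r$lengths[t])
      } else {
        for (u in seq_len(r$lengths[t])) {
          add("X", ref_pos0 + off + u - 1L, query_pos0 + off + u - 1L, 1L,
              rb = ra[off + u], ab = qa[off + u])
        }
      }
      off <- off + r$lengths[t]
    }
    return(res)
  }
  pa <- Biostrings::pairwiseAlignment(
    qseg, rseg, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  rp <- ref_pos0; qp <- query_pos0
  i <- 1L; n <- length(qa)
  while (i <= n) {
    if (qa[i] != "-" && ra[i] != "-") {
      j <- i
      while (j <= n && qa[j] != "-" && ra[j] != "-") j <- j + 1L
      len <- j - i
      qs <- paste(qa[i:(j - 1L)], collapse = "")
      rs <- paste(ra[i:(j - 1L)], collapse = "")
      if (qs == rs) {
        add("M", rp, qp, len)
      } else {
        # compress match stretches; substitutions stay per-base so each
        # becomes one SNP candidate
        eq <- qa[i:(j - 1L)] == ra[i:(j - 1L)]
        r <- rle(eq)
        off <- 0L
        for (t in seq_along(r$lengths)) {
          if (r$values[t]) {
            add("M", rp + off, qp + off, r$lengths[t])
          } else {
            for (u in seq_len(r$lengths[t])) {
              add("X", rp + off + u - 1L, qp + off + u - 1L, 1L,
                  rb = ra[i + off + u - 2L + 1L], ab = qa[i + off + u - 2L + 1L])
            }
          }
          off <- off + r$lengths[t]
        }
      }
      rp <- rp + len; qp <- qp + len; i <- j
    } else if (qa[i] == "-") {
      j <- i
      while (j <= n && qa[j] == "-") j <- j + 1L
      add("D", rp, qp, j - i, rb = paste(ra[i:(j - 1L)], collapse = ""))
      rp <- rp + (j - i); i <- j
    } else {
      j <- i
      while (j <= n && ra[j] == "-") j <- j + 1L
      add("I", rp, qp, j - i, ab = paste(qa[i:(j - 1L)], collapse = ""))
      qp <- qp + (j - i); i <- j
    }
  }
  res
}

#' Align a set of named contigs to the reference
#'
#' Windows are derived from each contig's header (phase-block span padded
#' by `window_pad`).
#'
#' @param contigs Named character vector (names follow the contig header
#'   grammar; see [name_contigs()]).
#' @param ref_seq Reference sequence.
#' @param windows Optional tibble (`contig_id`, `start`, `end`) giving the
#'   reference window per contig (e.g. derived from chunk intervals). By
#'   default the window is the header's phase-block span padded by
#'   `window_pad`.
#' @param window_pad Window padding (default 100000, generous enough to
#'   cover molecule overhang past the phased span).
#' @param ... Passed to [align_contig()].
#' @return Tibble of class `contig_alignments`: one row per aligned
#'   contig with `contig_id`, `contig_len`, `haplotype`, `block_id`,
#'   alignment span columns and the `ops` list column.
#' @export
align_contigs <- function(contigs, ref_seq, windows = NULL,
                          window_pad = 100000, ...) {
  L <- nchar(ref_seq)
  rows <- imap(contigs, function(seq, header) {
    meta <- parse_contig_header(header)
    if (!is.null(windows) && header %in% windows$contig_id) {
      w <- windows[windows$contig_id == header, ]
      lo <- max(0, w$start[1]); hi <- min(L, w$end[1])
    } else {
      lo <- max(0, meta$ps_start - window_pad)
      hi <- min(L, meta$ps_end + window_pad)
    }
    aln <- align_contig(seq, ref_seq, as.integer(lo), as.integer(hi), ...)
    if (is.null(aln)) return(NULL)
    bind_cols(tibble(contig_id = header, contig_len = nchar(seq),
                     haplotype = meta$haplotype,
                     block_id = meta$ps_start), aln)
  })
  out <- bind_rows(compact(rows))
  class(out) <- c("contig_alignments", class(out))
  out
}

# ---- external aligner: PAF with cs difference strings ------------------

#' Parse PAF records with cs difference strings
#'
#' Reads the PAF produced by an external contig aligner run with a
#' cs-string option (e.g. `minimap2 -cx asm5 --cs`) into the same
#' edit-operation table the built-in aligner produces. The cs grammar
#' handled: `:N` (match run), `*ab` (substitution, ref base then query
#' base), `+seq` (insertion), `-seq` (deletion).
#'
#' @param lines Character vector of PAF lines (or a file path of length 1
#'   pointing to an existing file).
#' @return A `contig_alignments` tibble.
#' @export
read_paf_cs <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(lines)]
  rows <- map(lines, function(ln) {
    f <- str_split(ln, "\t")[[1]]
    if (length(f) < 12) abort("malformed PAF record (fewer than 12 fields)")
    if (f[5] == "-") return(NULL)  # reverse-strand hits not used
    cs <- f[startsWith(f, "cs:Z:")]
    if (length(cs) == 0) abort("PAF record lacks a cs:Z: tag")
    ops <- parse_cs_string(substring(cs[1], 6),
                           ref_pos0 = as.integer(f[8]),
                           query_pos0 = as.integer(f[3]))
    meta <- tryCatch(parse_contig_header(f[1]), error = function(e) NULL)
    tibble(contig_id = f[1], contig_len = as.integer(f[2]),
           haplotype = if (!is.null(meta)) meta$haplotype else NA_integer_,
           block_id = if (!is.null(meta)) meta$ps_start else NA_integer_,
           ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
           query_start = as.integer(f[3]), query_end = as.integer(f[4]),
           mapq = as.integer(f[12]), ops = list(ops))
  })
  out <- bind_rows(compact(rows))
  class(out) <- c("contig_alignments", class(out))
  out
}

parse_cs_string <- function(cs, ref_pos0, query_pos0) {
  toks <- str_match_all_cs(cs)
  rp <- ref_pos0; qp <- query_pos0
  ops <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    tag <- substring(t, 1, 1)
    body <- substring(t, 2)
    if (tag == ":") {
      len <- as.integer(body)
      ops[[i]] <- tibble(op = "M", ref_pos = rp, query_pos = qp, len = len,
                         ref_bases = "", alt_bases = "")
      rp <- rp + len; qp <- qp + len
    } else if (tag == "*") {
      ops[[i]] <- tibble(op = "X", ref_pos = rp, query_pos = qp, len = 1L,
                         ref_bases = toupper(substring(body, 1, 1)),
                         alt_bases = toupper(substring(body, 2, 2)))
      rp <- rp + 1L; qp <- qp + 1L
    } else if (tag == "+") {
      ops[[i]] <- tibble(op = "I", ref_pos = rp, query_pos = qp,
                         len = nchar(body), ref_bases = "",
                         alt_bases = toupper(body))
      qp <- qp + nchar(body)
    } else if (tag == "-") {
      ops[[i]] <- tibble(op = "D", ref_pos = rp, query_pos = qp,
                         len = nchar(body), ref_bases = toupper(body),
                         alt_bases = "")
      rp <- rp + nchar(body)
    } else {
      abort(sprintf("malformed cs string at token %d ('%s')", i, t))
    }
  }
  bind_rows(ops)
}

# tokenize a cs string into ":N", "*ab", "+seq", "-seq" pieces
str_match_all_cs <- function(cs) {
  m <- gregexpr("(:[0-9]+|\\*[a-zA-Z]{2}|\\+[a-zA-Z]+|-[a-zA-Z]+)", cs)[[1]]
  if (m[1] == -1) {
    if (nchar(cs) > 0) abort("malformed cs string at offset 1")
    return(character(0))
  }
  lens <- attr(m, "match.length")
  if (sum(lens) != nchar(cs)) {
    off <- cumsum(c(1, lens))
    gap <- which(off[-length(off)] != m)[1]
    abort(sprintf("malformed cs string at offset %d",
                  if (is.na(gap)) sum(lens) + 1L else m[gap]))
  }
  substring(cs, m, m + lens - 1L)
}

#' Align contigs with an external minimap2-style aligner
#'
#' Writes contigs and reference to FASTA, runs the external command with
#' assembly-to-reference presets and cs output, and parses the PAF.
#'
#' @param contigs Named character vector of contigs.
#' @param ref_seq Reference sequence.
#' @param ref_name Reference sequence name (default "chr1").
#' @param cmd Aligner executable (default `"minimap2"`).
#' @return A `contig_alignments` tibble.
#' @export
align_contigs_external <- function(contigs, ref_seq, ref_name = "chr1",
                                   cmd = "minimap2") {
  if (Sys.which(cmd) == "") {
    abort(sprintf("external aligner '%s' not found on PATH", cmd))
  }
  dir <- tempfile("aln")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  ref_fa <- file.path(dir, "ref.fasta")
  ctg_fa <- file.path(dir, "contigs.fasta")
  paf <- file.path(dir, "aln.paf")
  write_fasta(setNames(ref_seq, ref_name), ref_fa)
  write_fasta(contigs, ctg_fa)
  status <- system2(cmd, c("-cx", "asm5", "--cs", ref_fa, ctg_fa),
                    stdout = paf, stderr = FALSE)
  if (status != 0) abort(sprintf("%s failed (exit %d)", cmd, status))
  read_paf_cs(paf)
}
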