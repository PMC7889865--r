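# Local assembly: read partitioning per (block, haplotype, chunk), a
# pluggable per-chunk assembler (built-in de Bruijn backend or an external
# command), and contig naming per the header grammar
# "<n>_PS<start>:<end>_hp<k>[_merge<a>:<b>_hp<k>-...]".

#' Partition reads into per-chunk, per-haplotype sets
#'
#' A molecule assigned to a haplotype contributes its reads to chunks of
#' its own block and haplotype that its span overlaps; reads of UNASSIGNED
#' molecules go to both haplotypes of every chunk they overlap (diploid
#' coverage in het-poor regions requires it). Individual reads are kept if
#' they overlap the chunk interval extended by `pad`, so assembled
#' minicontigs reach past the partitioning point far enough to contain the
#' stitch anchor.
#'
#' @param chunks Chunk tibble from [cut_phase_blocks()].
#' @param alignments Alignment tibble (with `seq`).
#' @param molecules Molecule tibble (with `read_ids` list column).
#' @param assignments Molecule assignments from [assign_molecules()].
#' @param pad Chunk interval padding in bp (default 500).
#' @return Tibble `chunk_id`, `read_id`, `seq`.
#' @export
partition_reads <- function(chunks, alignments, molecules, assignments,
                            pad = 500) {
  mol <- left_join(
    molecules[c("molecule_id", "start", "end", "read_ids")],
    assignments[c("molecule_id", "block_id", "haplotype")],
    by = "molecule_id")
  ch_ir <- IRanges::IRanges(start = chunks$start + 1L - pad,
                            end = chunks$end + pad)
  mol_ir <- IRanges::IRanges(start = mol$start + 1L, end = mol$end)
  hits <- IRanges::findOverlaps(mol_ir, ch_ir)
  pairs <- tibble(
    mol_row = S4Vectors::queryHits(hits),
    chunk_row = S4Vectors::subjectHits(hits)
  )
  pairs$assigned <- !is.na(mol$haplotype[pairs$mol_row])
  keep <- !pairs$assigned |
    (mol$block_id[pairs$mol_row] == chunks$block_id[pairs$chunk_row] &
       mol$haplotype[pairs$mol_row] == chunks$haplotype[pairs$chunk_row])
  keep[is.na(keep)] <- FALSE
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(tibble(chunk_id = character(), read_id = character(),
                  seq = character()))
  }

  reads <- tibble(
    molecule_id = rep(mol$molecule_id, lengths(mol$read_ids)),
    read_id = unlist(mol$read_ids)
  ) %>%
    left_join(alignments[c("read_id", "start", "end", "seq")],
              by = "read_id")
  expanded <- tibble(
    molecule_id = mol$molecule_id[pairs$mol_row],
    chunk_id = chunks$chunk_id[pairs$chunk_row],
    c_start = chunks$start[pairs$chunk_row] - pad,
    c_end = chunks$end[pairs$chunk_row] + pad
  ) %>%
    inner_join(reads, by = "molecule_id", relationship = "many-to-many") %>%
    filter(.data$start < .data$c_end, .data$end > .data$c_start)
  expanded[c("chunk_id", "read_id", "seq")]
}

#' Assemble one chunk's reads into minicontigs
#'
#' The built-in `"toy"` backend is a greedy de Bruijn assembler: count
#' k-mers (k = 31), drop those below `min_count` (2), and emit maximal
#' unambiguous paths. The `"external"` backend shells out to a
#' user-configured assembler command that must read a FASTA of reads
#' (argument 1) and write contigs FASTA (argument 2).
#'
#' @param reads Character vector of read sequences (or tibble with `seq`).
#' @param backend `"toy"` or `"external"`.
#' @param k k-mer size for the toy backend (default 31).
#' @param min_count Minimum k-mer count (default 2).
#' @param purge_ratio At a graph fork, drop edges whose k-mer coverage is
#'   outweighed this many times by the strongest sibling edge (default 3).
#'   This resolves the allelic bubbles created by duplicating unassigned
#'   molecules' reads to both haplotypes; set to 0 to disable.
#' @param assembler_cmd Path of the external assembler (required for
#'   `backend = "external"`; configure via option
#'   `diploidlr.assembler_cmd`).
#' @param min_len Discard minicontigs shorter than this (default `k`).
#' @return Character vector of minicontig sequences.
#' @export
assemble_chunk <- function(reads, backend = c("toy", "external"), k = 31,
                           min_count = 2, purge_ratio = 3,
                           assembler_cmd = getOption("diploidlr.assembler_cmd"),
                           min_len = k) {
  backend <- match.arg(backend)
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 0) return(character(0))
  if (backend == "toy") {
    contigs <- .debruijn_assemble(reads, k = as.integer(k),
                                  min_count = as.integer(min_count),
                                  purge_ratio = purge_ratio)
  } else {
    if (is.null(assembler_cmd) || !nzchar(assembler_cmd) ||
        Sys.which(assembler_cmd) == "") {
      abort(paste0(
        "external assembler not found; set options(diploidlr.assembler_cmd=)",
        " to a runnable command or use backend = \"toy\""))
    }
    dir <- tempfile("asm")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    in_fa <- file.path(dir, "reads.fasta")
    out_fa <- file.path(dir, "contigs.fasta")
    write_fasta(setNames(reads, sprintf("read%06d", seq_along(reads))), in_fa)
    status <- system2(assembler_cmd, c(in_fa, out_fa))
    if (status != 0 || !file.exists(out_fa)) {
      abort(sprintf("external assembler failed (exit %d)", status))
    }
    contigs <- unname(read_fasta(out_fa))
  }
  contigs[nchar(contigs) >= min_len]
}

#' Assemble all chunks
#'
#' Runs [assemble_chunk()] per chunk and labels minicontigs with their
#' chunk lineage for stitching.
#'
#' @param chunk_reads Output of [partition_reads()].
#' @param chunks Chunk tibble.
#' @param ... Passed to [assemble_chunk()].
#' @return Minicontig tibble: `block_id`, `haplotype`, `chunk_start`,
#'   `chunk_end`, `seq`.
#' @export
assemble_chunks <- function(chunk_reads, chunks, ...) {
  split_reads <- split(chunk_reads$seq, chunk_reads$chunk_id)
  res <- imap(split_reads, function(seqs, cid) {
    ch <- chunks[chunks$chunk_id == cid, ]
    contigs <- assemble_chunk(seqs, ...)
    if (length(contigs) == 0) return(NULL)
    tibble(block_id = ch$block_id, haplotype = ch$haplotype,
           chunk_start = ch$start, chunk_end = ch$end, seq = contigs)
  })
  bind_rows(compact(res))
}

#' Format contig headers
#'
#' Headers follow
#' `"<n>_PS<start>:<end>_hp<k>"`, with a `"_merge"` suffix listing the
#' constituent chunk intervals (`"<a>:<b>_hp<k>"` joined by `"-"`) for
#' contigs concatenated from several chunks.
#'
#' @param contigs Contig tibble from [stitch_minicontigs()].
#' @param block_spans Tibble `block_id`, `start`, `end` giving each phase
#'   block's full span.
#' @return Named character vector of sequences (names are headers), ready
#'   for [write_fasta()].
#' @export
name_contigs <- function(contigs, block_spans) {
  sp <- block_spans[match(contigs$block_id, block_spans$block_id), ]
  base <- sprintf("%d_PS%d:%d_hp%d", seq_len(nrow(contigs)),
                  sp$start, sp$end, contigs$haplotype)
  merge_sfx <- map2_chr(contigs$chunks, contigs$haplotype, function(ch, hp) {
    if (length(ch) <= 1) return("")
    paste0("_merge", paste(map_chr(ch, function(iv)
      sprintf("%d:%d_hp%d", iv[1], iv[2], hp)), collapse = "-"))
  })
  setNames(contigs$seq, paste0(base, merge_sfx))
}

#' Parse a contig header
#'
#' @param header Header string (without `">"`).
#' @return One-row tibble: `contig_n`, `ps_start`, `ps_end`, `haplotype`,
#'   `chunks` (list of `c(start, end)` for merged contigs, `NULL`
#'   otherwise).
#' @export
parse_contig_header <- function(header) {
  m <- str_match(header,
                 "^(\\d+)_PS(\\d+):(\\d+)_hp([12])(?:_merge(.*))?$")
  if (is.na(m[1, 1])) abort(sprintf("unparseable contig header: %s", header))
  chunks <- NULL
  if (!is.na(m[1, 6])) {
    parts <- str_split(m[1, 6], "-")[[1]]
    pm <- str_match(parts, "^(\\d+):(\\d+)_hp[12]$")
    if (anyNA(pm[, 1])) abort(sprintf("bad merge suffix in: %s", header))
    chunks <- map(seq_len(nrow(pm)),
                  ~ c(as.integer(pm[.x, 2]), as.integer(pm[.x, 3])))
  }
  tibble(contig_n = as.integer(m[1, 2]), ps_start = as.integer(m[1, 3]),
         ps_end = as.integer(m[1, 4]), haplotype = as.integer(m[1, 5]),
         chunks = list(chunks))
}

#' Reformat a parsed header (round-trip of [parse_contig_header()])
#' @param parsed One-row tibble from [parse_contig_header()].
#' @return Header string.
#' @export
format_contig_header <- function(parsed) {
  base <- sprintf("%d_PS%d:%d_hp%d", parsed$contig_n, parsed$ps_start,
                  parsed$ps_end, parsed$haplotype)
  ch <- parsed$chunks[[1]]
  if (is.null(ch)) return(base)
  paste0(base, "_merge",
         paste(map_chr(ch, ~ sprintf("%d:%d_hp%d", .x[1], .x[2],
                                     parsed$haplotype)), collapse = "-"))
}
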