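# Contiguity: coverage/uniqueness profiles, high-confidence partitioning
# points, phase-block chunking, and minicontig stitching at shared
# partitioning points.

#' Per-base read and fragment coverage profiles
#'
#' `C[pos]` counts reads overlapping each position, `C_F[pos]` counts
#' molecules. Averages are taken over the covered region (positions with
#' non-zero coverage of the respective profile).
#'
#' @param alignments Alignment tibble (0-based half-open `start`/`end`).
#' @param molecules Molecule tibble.
#' @param chrom_length Chromosome length in bp.
#' @return Object of class `coverage_profile`: list with integer vectors
#'   `C`, `C_F` (length `chrom_length`) and scalars `C_avg`, `C_F_avg`.
#' @export
compute_profiles <- function(alignments, molecules, chrom_length) {
  cov_vec <- function(start, end) {
    if (length(start) == 0) return(integer(chrom_length))
    ir <- IRanges::IRanges(start = pmax(start + 1L, 1L),
                           end = pmin(end, chrom_length))
    as.integer(IRanges::coverage(ir, width = chrom_length))
  }
  C <- cov_vec(alignments$start, alignments$end)
  C_F <- cov_vec(molecules$start, molecules$end)
  structure(list(
    C = C, C_F = C_F,
    C_avg = if (any(C > 0)) mean(C[C > 0]) else 0,
    C_F_avg = if (any(C_F > 0)) mean(C_F[C_F > 0]) else 0,
    chrom_length = chrom_length
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d bp; C_avg %.1f, C_F_avg %.1f\n",
              x$chrom_length, x$C_avg, x$C_F_avg))
  invisible(x)
}

#' k-mer uniqueness track of a reference sequence
#'
#' A position is marked unique when its k-mer (k = 100 by default) occurs
#' exactly once among all k-mers of the sequence and its reverse
#' complement.
#'
#' @param ref_seq Reference sequence (character scalar).
#' @param k k-mer length (default 100).
#' @return Object of class `uniqueness_track`: list with logical vector
#'   `unique_at` over positions `0 .. L-k` (0-based) and `k`.
#' @export
compute_uniqueness <- function(ref_seq, k = 100) {
  L <- nchar(ref_seq)
  if (k > L) {
    return(structure(list(unique_at = logical(0), k = k),
                     class = "uniqueness_track"))
  }
  kf <- seq_kmers(ref_seq, k)
  kr <- seq_kmers(revcomp(ref_seq), k)
  all_k <- c(kf, kr)
  dup <- duplicated(all_k) | duplicated(all_k, fromLast = TRUE)
  structure(list(unique_at = !dup[seq_along(kf)], k = k),
            class = "uniqueness_track")
}

#' Read a uniqueness track from BED
#'
#' Accepts a precomputed mappability-style BED (0-based half-open
#' intervals of unique positions) as an alternative to
#' [compute_uniqueness()].
#'
#' @param path BED path.
#' @param chrom_length Chromosome length.
#' @param k k-mer size the track was built with (default 100).
#' @return A `uniqueness_track`.
#' @export
read_uniqueness_bed <- function(path, chrom_length, k = 100) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"))
  n <- chrom_length - k + 1L
  u <- logical(n)
  for (i in seq_len(nrow(bed))) {
    lo <- max(bed$start[i] + 1L, 1L)
    hi <- min(bed$end[i], n)
    if (lo <= hi) u[lo:hi] <- TRUE
  }
  structure(list(unique_at = u, k = k), class = "uniqueness_track")
}

#' Select high-confidence partitioning points
#'
#' A position qualifies when read coverage and fragment coverage both
#' exceed `factor` (default 0.8) times their covered-region averages and
#' the position's 100-mer is unique in the reference. Assemblies can be
#' cut and rejoined at such points with high confidence.
#'
#' @param profile A [compute_profiles()] result.
#' @param uniq A [compute_uniqueness()] result.
#' @param factor Coverage multiplier (default 0.8).
#' @return Sorted integer vector of 0-based positions.
#' @export
select_partitioning_points <- function(profile, uniq, factor = 0.8) {
  n <- length(uniq$unique_at)
  if (n == 0) return(integer(0))
  pos <- which(
    profile$C[seq_len(n)] > factor * profile$C_avg &
      profile$C_F[seq_len(n)] > factor * profile$C_F_avg &
      uniq$unique_at
  ) - 1L
  pos
}

#' Cut phase blocks into assembly chunks
#'
#' Blocks no longer than `block_threshold` (200 kb) become a single chunk
#' per haplotype. Longer blocks are cut at the qualifying partitioning
#' point nearest each ideal multiple of `chunk_len` (100 kb), searching
#' within `search_window` (+-20 kb); when no point qualifies near an ideal
#' cut, that boundary is skipped and the chunk simply runs longer. Chunks
#' tile each block exactly, neighbouring chunks sharing their cut point.
#'
#' @param blocks Tibble with `block_id`, `start`, `end` (the span to
#'   assemble; 0-based half-open).
#' @param points Sorted partitioning points from
#'   [select_partitioning_points()].
#' @param block_threshold,chunk_len,search_window Cutting parameters (bp).
#' @return Chunk tibble: `chunk_id`, `block_id`, `haplotype`, `start`,
#'   `end`, `first`, `last` (block-boundary flags).
#' @export
cut_phase_blocks <- function(blocks, points, block_threshold = 200000,
                             chunk_len = 100000, search_window = 20000) {
  if (is.unsorted(points)) abort("points must be sorted")
  one_block <- function(block_id, start, end) {
    len <- end - start
    bounds <- c(start, end)
    if (len > block_threshold) {
      ideals <- start + seq_len(floor(len / chunk_len)) * chunk_len
      ideals <- ideals[ideals < end - chunk_len / 2]
      cuts <- map_dbl(ideals, function(x) {
        cand <- points[points >= x - search_window & points <= x + search_window]
        if (length(cand) == 0) return(NA_real_)
        cand[which.min(abs(cand - x))]
      })
      cuts <- unique(cuts[!is.na(cuts)])
      bounds <- sort(unique(c(start, cuts, end)))
    }
    tibble(block_id = block_id,
           start = as.integer(bounds[-length(bounds)]),
           end = as.integer(bounds[-1]))
  }
  chunks <- pmap(blocks[c("block_id", "start", "end")], one_block) %>%
    bind_rows() %>%
    group_by(.data$block_id) %>%
    mutate(first = row_number() == 1L, last = row_number() == n()) %>%
    ungroup()
  chunks <- bind_rows(mutate(chunks, haplotype = 1L),
                      mutate(chunks, haplotype = 2L)) %>%
    arrange(.data$block_id, .data$haplotype, .data$start)
  chunks$chunk_id <- sprintf("chunk%05d", seq_len(nrow(chunks)))
  chunks[c("chunk_id", "block_id", "haplotype", "start", "end",
           "first", "last")]
}

#' Stitch minicontigs at shared partitioning points
#'
#' Neighbouring minicontigs of the same block and haplotype are spliced at
#' their shared partitioning point: the reference `anchor_k`-mer starting
#' at the point (unique in the reference by construction) is located near
#' the right end of the left minicontig and near the left end of the right
#' one; the stitched sequence is the left prefix up to the anchor followed
#' by the right minicontig from the anchor on. Concatenation proceeds
#' left-to-right, each stitched contig feeding the next splice. If the
#' anchor is absent or ambiguous on either side, no splice happens there
#' and both pieces are emitted.
#'
#' @param minicontigs Tibble `block_id`, `haplotype`, `chunk_start`,
#'   `chunk_end`, `seq` (one or more rows per chunk).
#' @param ref_seq Reference sequence.
#' @param anchor_k Anchor k-mer length (default 100, the uniqueness k).
#' @param search_margin How far from the minicontig end/start to search
#'   for the anchor (default 2000 bp).
#' @return Contig tibble: `block_id`, `haplotype`, `seq`, `chunks`
#'   (list column of constituent `c(start, end)` intervals), `n_chunks`.
#' @export
stitch_minicontigs <- function(minicontigs, ref_seq, anchor_k = 100,
                               search_margin = 2000) {
  find_once <- function(hay, needle) {
    hits <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (length(hits) == 1 && hits[1] > 0) hits[1] else NA_integer_
  }
  out <- list()
  grps <- minicontigs %>%
    arrange(.data$block_id, .data$haplotype, .data$chunk_start,
            desc(nchar(.data$seq)))
  for (g in split(grps, paste(grps$block_id, grps$haplotype))) {
    # one candidate minicontig per chunk: keep the longest
    g <- g %>%
      group_by(.data$chunk_start, .data$chunk_end) %>%
      mutate(rank = row_number()) %>%
      ungroup()
    extras <- g[g$rank > 1, , drop = FALSE]
    g <- g[g$rank == 1, , drop = FALSE]
    cur_seq <- g$seq[1]
    cur_chunks <- list(c(g$chunk_start[1], g$chunk_end[1]))
    emit <- function(seq, chunk_list) {
      out[[length(out) + 1L]] <<- tibble(
        block_id = g$block_id[1], haplotype = g$haplotype[1], seq = seq,
        chunks = list(chunk_list), n_chunks = length(chunk_list))
    }
    if (nrow(g) > 1) {
      for (i in 2:nrow(g)) {
        point <- g$chunk_start[i]
        spliced <- FALSE
        if (point == cur_chunks[[length(cur_chunks)]][2]) {
          anchor <- substring(ref_seq, point + 1L, point + anchor_k)
          lw <- min(nchar(cur_seq), search_margin + anchor_k)
          rw <- min(nchar(g$seq[i]), search_margin + anchor_k)
          left_tail <- substring(cur_seq, nchar(cur_seq) - lw + 1L)
          right_head <- substring(g$seq[i], 1L, rw)
          li <- find_once(left_tail, anchor)
          ri <- find_once(right_head, anchor)
          if (!is.na(li) && !is.na(ri)) {
            cut_left <- nchar(cur_seq) - lw + li - 1L
            cur_seq <- paste0(substring(cur_seq, 1L, cut_left),
                              substring(g$seq[i], ri))
            cur_chunks <- c(cur_chunks, list(c(g$chunk_start[i],
                                               g$chunk_end[i])))
            spliced <- TRUE
          }
        }
        if (!spliced) {
          emit(cur_seq, cur_chunks)
          cur_seq <- g$seq[i]
          cur_chunks <- list(c(g$chunk_start[i], g$chunk_end[i]))
        }
      }
    }
    emit(cur_seq, cur_chunks)
    # chunks that assembled into several minicontigs: extras stand alone
    for (j in seq_len(nrow(extras))) {
      out[[length(out) + 1L]] <- tibble(
        block_id = extras$block_id[j], haplotype = extras$haplotype[j],
        seq = extras$seq[j],
        chunks = list(list(c(extras$chunk_start[j], extras$chunk_end[j]))),
        n_chunks = 1L)
    }
  }
  bind_rows(out)
}
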