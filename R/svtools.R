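# SV post-analysis: cross-callset merging, Alu / tandem-repeat
# classification, ancestral-allele inference from outgroup flank
# alignments, and derived-allele segregation patterns.

#' Merge SV callsets across libraries or individuals
#'
#' Deletions are the same event when their reference intervals overlap
#' (>= 1 bp); insertions when their breakpoints are within `ins_tol`
#' (20 bp). Merging is a transitive closure (computed by 1-D chaining
#' per chromosome and type, which is exact for interval overlap and
#' breakpoint distance), so the result does not depend on callset order.
#'
#' @param callsets List of SV tibbles (`chrom`, `start`, `end`, `type`,
#'   `size`, optionally `genotype`, `sequence`).
#' @param ins_tol Insertion breakpoint tolerance (default 20 bp).
#' @return Merged tibble: one row per merged SV with representative
#'   coordinates (leftmost member), `n_callsets`, and logical presence
#'   columns `in_cs1`, `in_cs2`, ...
#' @export
merge_sv_callsets <- function(callsets, ins_tol = 20) {
  stopifnot(length(callsets) >= 1)
  all_sv <- bind_rows(imap(callsets, function(cs, i) {
    mutate(cs, callset = as.integer(i))
  })) %>%
    arrange(.data$chrom, .data$type, .data$start, .data$end)
  if (nrow(all_sv) == 0) return(all_sv)
  comp <- all_sv %>%
    group_by(.data$chrom, .data$type) %>%
    mutate(component = {
      if (.data$type[1] == "DEL") {
        prev_max <- lag(cummax(as.numeric(.data$end)), default = -Inf)
        cumsum(.data$start >= prev_max)   # half-open: touching != overlap
      } else {
        gap <- .data$start - lag(as.numeric(.data$start), default = -Inf)
        cumsum(gap > ins_tol)
      }
    }) %>%
    ungroup()
  merged <- comp %>%
    group_by(.data$chrom, .data$type, .data$component) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      size = .data$size[1],
      sequence = if ("sequence" %in% names(comp)) .data$sequence[1] else
        NA_character_,
      genotype = if ("genotype" %in% names(comp)) .data$genotype[1] else
        NA_character_,
      n_callsets = n_distinct(.data$callset),
      members = list(sort(unique(.data$callset))),
      .groups = "drop")
  for (i in seq_along(callsets)) {
    merged[[paste0("in_cs", i)]] <- map_lgl(merged$members, ~ i %in% .x)
  }
  select(merged, -"component", -"members") %>%
    arrange(.data$chrom, .data$start)
}

#' Global percent identity between two sequences
#'
#' Matches divided by alignment columns of an affine-gap global
#' alignment.
#'
#' @param a,b Sequences.
#' @return Identity in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 0.5)
  Biostrings::nmatch(pa) / nchar(as.character(Biostrings::alignedPattern(pa)))
}

#' Classify an SV sequence as an Alu element
#'
#' True when the SV is 250-350 bp and its sequence aligns to the AluY
#' consensus at >= `min_identity` global identity (both strands are
#' tried, so the call is symmetric under reverse complement).
#'
#' @param sv_seq SV sequence (insertion allele for INS, deleted bases for
#'   DEL).
#' @param consensus Alu consensus sequence; default is the bundled
#'   synthetic Alu-like consensus
#'   (`system.file("extdata", "alu_consensus_synthetic.fa")`), which
#'   stands in for a real AluY consensus FASTA that users should supply
#'   for real data.
#' @param min_identity Identity threshold (default 0.80).
#' @param size_range Eligible size window (default 250-350 bp).
#' @return Logical.
#' @export
classify_alu <- function(sv_seq, consensus = alu_consensus(),
                         min_identity = 0.80, size_range = c(250, 350)) {
  if (is.na(sv_seq) || !nzchar(sv_seq)) {
    abort("SV sequence is required for Alu classification")
  }
  n <- nchar(sv_seq)
  if (n < size_range[1] || n > size_range[2]) return(FALSE)
  id_f <- global_identity(sv_seq, consensus)
  if (id_f >= min_identity) return(TRUE)
  global_identity(revcomp(sv_seq), consensus) >= min_identity
}

#' Bundled synthetic Alu-like consensus
#'
#' A 311-bp synthetic stand-in for the AluY consensus (the package does
#' not ship the real Repbase sequence); adequate for testing the
#' classifier's identity logic. Supply a real consensus FASTA for real
#' data.
#'
#' @return Consensus sequence (character scalar).
#' @export
alu_consensus <- function() {
  path <- system.file("extdata", "alu_consensus_synthetic.fa",
                      package = "diploidlr")
  unname(read_fasta(path)[1])
}

# Naive tandem-repeat detector: TRUE when some period p <= max_period has
# a repeated stretch of >= 3 copies covering >= min_cover of the sequence.
detect_tandem_repeat <- function(seq, max_period = 6, min_copies = 3,
                                 min_cover = 0.5) {
  n <- nchar(seq)
  if (n == 0) return(FALSE)
  s <- strsplit(seq, "")[[1]]
  for (p in seq_len(min(max_period, n - 1))) {
    eq <- s[-seq_len(p)] == s[seq_len(n - p)]
    r <- rle(eq)
    best <- max(c(0, r$lengths[r$values]))
    stretch <- best + p
    if (stretch >= min_copies * p && stretch / n >= min_cover) return(TRUE)
  }
  FALSE
}

#' Classify an SV into Alu / Repeat / Other
#'
#' Alu classification wins; otherwise the SV is `Repeat` when a supplied
#' repeat annotation overlaps it (or, lacking an annotation, when the
#' built-in naive detector finds a short-period tandem repeat covering at
#' least half of the SV sequence); everything else is `Other`.
#'
#' @param sv One-row SV tibble (`chrom`, `start`, `end`, `size`,
#'   `sequence`).
#' @param repeat_annotation Optional BED-like tibble (`chrom`, `start`,
#'   `end`) of tandem-repeat intervals.
#' @param ... Passed to [classify_alu()].
#' @return `"Alu"`, `"Repeat"` or `"Other"`.
#' @export
classify_repeat <- function(sv, repeat_annotation = NULL, ...) {
  if (classify_alu(sv$sequence, ...)) return("Alu")
  if (!is.null(repeat_annotation)) {
    ra <- repeat_annotation[repeat_annotation$chrom == sv$chrom, ]
    if (nrow(ra) > 0 &&
        any(ra$start < sv$end & ra$end > sv$start)) {
      return("Repeat")
    }
    return("Other")
  }
  if (detect_tandem_repeat(sv$sequence)) "Repeat" else "Other"
}

#' Infer the ancestral state of an SV from outgroup flank alignments
#'
#' The 500-bp flanks of the SV are located on an outgroup (ape) genome;
#' `gap` is the distance between the left flank's end and the right
#' flank's start there. A deletion call whose flanks are adjacent on the
#' outgroup (gap <= 2 bp) means the reference carries extra sequence the
#' outgroup lacks: an insertion on the reference lineage (`Ins_Ref`, an
#' actual insertion). A deletion call with an outgroup gap close to the
#' SV size (within 0.9-1.1x, inclusive) means the outgroup carries the
#' sequence too: the individual deleted it (`Del_Tar`, actual deletion).
#' Insertion calls mirror this (`Ins_Tar` / `Del_Ref`). Anything else,
#' including flanks on different outgroup chromosomes, is unresolved.
#'
#' @param sv One-row SV tibble (`type`, `size`).
#' @param flank One-row flank-alignment tibble: `gap`, `same_chrom`
#'   (logical), optionally `strand`.
#' @param adjacency_tol Flank adjacency tolerance (default 2 bp).
#' @param size_window Relative gap window for the deletion case (default
#'   `c(0.9, 1.1)`, endpoints included).
#' @return Tibble `label`, `actual_type`.
#' @export
infer_ancestral <- function(sv, flank, adjacency_tol = 2,
                            size_window = c(0.9, 1.1)) {
  unresolved <- tibble(label = "unresolved", actual_type = "unresolved")
  if (is.null(flank) || !isTRUE(flank$same_chrom)) return(unresolved)
  gap <- flank$gap
  in_size <- gap >= size_window[1] * sv$size & gap <= size_window[2] * sv$size
  if (sv$type == "DEL") {
    if (gap <= adjacency_tol) {
      tibble(label = "Ins_Ref", actual_type = "actual_insertion")
    } else if (in_size) {
      tibble(label = "Del_Tar", actual_type = "actual_deletion")
    } else unresolved
  } else {
    if (gap <= adjacency_tol) {
      tibble(label = "Ins_Tar", actual_type = "actual_insertion")
    } else if (in_size) {
      tibble(label = "Del_Ref", actual_type = "actual_deletion")
    } else unresolved
  }
}

#' Combine ancestral inferences from two outgroups
#'
#' Resolved and agreeing labels win; a disagreement between outgroups is
#' unresolved.
#'
#' @param a,b Results of [infer_ancestral()] on the two outgroups.
#' @return Tibble `label`, `actual_type`.
#' @export
combine_ancestral <- function(a, b) {
  if (a$label == "unresolved") return(b)
  if (b$label == "unresolved") return(a)
  if (a$label == b$label) return(a)
  tibble(label = "unresolved", actual_type = "unresolved")
}

#' Enumerate derived-allele segregation patterns
#'
#' At an SV locus there are five sampled chromosomes: two per individual
#' plus the reference haplome. Each individual's genotype is a derived-
#' allele count (0, 1, 2) and the reference is ancestral or derived:
#' 3 x 3 x 2 = 18 raw combinations. The two all-identical configurations
#' cannot be observed as variants, leaving 16 patterns with one to four
#' derived alleles. The 12 patterns where the individuals' genotypes
#' differ form 6 equivalence pairs under swapping the individuals.
#'
#' @return Tibble: `genotype_A`, `genotype_B`, `ref_state`,
#'   `derived_total`, `observable`, `differing`, `pair_class` (id shared
#'   by the two members of an equivalence pair, `NA` for symmetric
#'   patterns).
#' @export
enumerate_segregation_patterns <- function() {
  grid <- tidyr::expand_grid(genotype_A = 0:2, genotype_B = 0:2,
                             ref_state = c("ancestral", "derived"))
  grid <- grid %>%
    mutate(
      derived_total = .data$genotype_A + .data$genotype_B +
        as.integer(.data$ref_state == "derived"),
      observable = !(.data$derived_total %in% c(0L, 5L)),
      differing = .data$genotype_A != .data$genotype_B
    )
  key <- with(grid, paste(pmin(genotype_A, genotype_B),
                          pmax(genotype_A, genotype_B), ref_state))
  diff_keys <- unique(key[grid$differing])
  grid$pair_class <- ifelse(grid$differing, match(key, diff_keys),
                            NA_integer_)
  grid
}

#' Classify an SV locus into its segregation pattern
#'
#' Translates the two individuals' alternate-allele genotypes into
#' derived-allele counts using the ancestral annotation: for `Ins_Tar` /
#' `Del_Tar` the alternate allele is derived, for `Ins_Ref` / `Del_Ref`
#' the reference allele is derived. Unresolved ancestry is excluded.
#'
#' @param gt_A,gt_B Alternate-allele counts (0, 1, 2) for the two
#'   individuals.
#' @param annotation An [infer_ancestral()] result.
#' @return One-row tibble: the pattern columns of
#'   [enumerate_segregation_patterns()] plus `actual_type` and
#'   `class12` (`actual_type`:`pair_class`, the 12-way classification for
#'   differing genotypes).
#' @export
classify_locus <- function(gt_A, gt_B, annotation) {
  if (annotation$actual_type == "unresolved") {
    abort("cannot classify a locus with unresolved ancestry")
  }
  ref_derived <- annotation$label %in% c("Ins_Ref", "Del_Ref")
  dA <- if (ref_derived) 2L - gt_A else gt_A
  dB <- if (ref_derived) 2L - gt_B else gt_B
  patterns <- enumerate_segregation_patterns()
  row <- patterns %>%
    filter(.data$genotype_A == dA, .data$genotype_B == dB,
           .data$ref_state == if (ref_derived) "derived" else "ancestral")
  if (!row$observable) {
    abort("locus is invariant across all five chromosomes")
  }
  row %>%
    mutate(actual_type = annotation$actual_type,
           class12 = if (.data$differing)
             paste0(annotation$actual_type, ":", .data$pair_class)
           else NA_character_)
}
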