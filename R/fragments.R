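# Long-fragment (molecule) reconstruction from barcode-sorted alignments,
# molecule-level het-SNP allele assignment, multi-library merging, and
# coverage statistics.

#' Reconstruct long molecules from barcoded alignments
#'
#' Groups reads sharing a barcode (per chromosome) into molecules, splitting
#' whenever the distance between the end of the previous read and the start
#' of the next exceeds `split_gap` (50 kb by default). Reads below the MAPQ
#' floor are excluded first.
#'
#' The input must already be sorted by (`barcode`, `chrom`, `start`);
#' unsorted input is an error rather than being silently re-sorted, so that
#' streaming callers notice broken pipelines.
#'
#' @param alignments Alignment tibble with at least `read_id`, `barcode`,
#'   `chrom`, `start`, `end`, `mapq` (0-based half-open coordinates).
#' @param split_gap Maximum within-molecule gap in bp; a gap strictly larger
#'   starts a new molecule. Default 50000.
#' @param min_mapq Reads with `mapq` below this are ignored. Default 20.
#' @return Molecule tibble: `molecule_id`, `barcode`, `chrom`, `start`,
#'   `end`, `n_reads`, `read_ids` (list column).
#' @examples
#' al <- tibble::tibble(
#'   read_id = c("a", "b"), barcode = "BX000001", chrom = "chr1",
#'   start = c(0L, 60100L), end = c(100L, 60200L), mapq = 60L)
#' reconstruct_fragments(al)  # gap > 50 kb: two molecules
#' @export
reconstruct_fragments <- function(alignments, split_gap = 50000,
                                  min_mapq = 20) {
  al <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  if (nrow(al) == 0) {
    return(tibble(molecule_id = character(), barcode = character(),
                  chrom = character(), start = integer(), end = integer(),
                  n_reads = integer(), read_ids = list()))
  }
  if (!identical(order(al$barcode, al$chrom, al$start,
                       method = "radix"),
                 seq_len(nrow(al)))) {
    abort("alignments must be sorted by (barcode, chrom, start)")
  }
  al <- al %>%
    group_by(.data$barcode, .data$chrom) %>%
    mutate(
      prev_max_end = lag(cummax(.data$end)),
      new_mol = is.na(.data$prev_max_end) |
        .data$start - .data$prev_max_end > split_gap,
      mol_idx = cumsum(.data$new_mol)
    ) %>%
    ungroup()
  mols <- al %>%
    group_by(.data$barcode, .data$chrom, .data$mol_idx) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_reads = n(), read_ids = list(.data$read_id),
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$barcode)
  mols$molecule_id <- sprintf("M%06d", seq_len(nrow(mols)))
  mols[c("molecule_id", "barcode", "chrom", "start", "end", "n_reads",
         "read_ids")]
}

#' Attach het-SNP allele calls to molecules
#'
#' Joins per-read allele observations onto their molecules and aggregates
#' one call per (molecule, het site). Sites where reads of the same
#' molecule disagree (both alleles observed) are dropped from that molecule
#' only: such internal conflicts are almost always sequencing error, and
#' the molecule's remaining sites stay usable. The call confidence is
#' `p_correct = 1 - 10^(-Q/10)` of the best supporting base, clamped to
#' `[0.51, 0.9999]`.
#'
#' @param molecules Molecule tibble from [reconstruct_fragments()].
#' @param allele_calls Per-read calls: `read_id`, `variant_id`, `allele`
#'   (0 = ref, 1 = alt), `qual` (phred).
#' @param variants Optional het-variant tibble; if given, calls are
#'   restricted to its `variant_id`s (e.g. after [prune_variants()]).
#' @return Tibble `molecule_id`, `variant_id`, `allele`, `p` with one row
#'   per retained (molecule, site) call.
#' @export
assign_alleles <- function(molecules, allele_calls, variants = NULL) {
  membership <- tibble(
    molecule_id = rep(molecules$molecule_id, lengths(molecules$read_ids)),
    read_id = unlist(molecules$read_ids) %||% character(0)
  )
  # each read belongs to exactly one molecule; a read can call several sites
  calls <- inner_join(membership, allele_calls, by = "read_id",
                      relationship = "one-to-many")
  if (!is.null(variants)) {
    calls <- calls[calls$variant_id %in% variants$variant_id, , drop = FALSE]
  }
  if (nrow(calls) == 0) {
    return(tibble(molecule_id = character(), variant_id = character(),
                  allele = integer(), p = numeric()))
  }
  calls %>%
    group_by(.data$molecule_id, .data$variant_id) %>%
    summarise(
      n_alleles = n_distinct(.data$allele),
      allele = .data$allele[which.max(.data$qual)],
      qual = max(.data$qual),
      .groups = "drop"
    ) %>%
    filter(.data$n_alleles == 1L) %>%
    mutate(p = phred_to_pcorrect(.data$qual)) %>%
    select("molecule_id", "variant_id", "allele", "p")
}

#' Merge molecules reconstructed from multiple libraries
#'
#' Linked-read libraries reuse the same barcode whitelist, so raw reads
#' from different libraries cannot be pooled; molecules can. After
#' per-library reconstruction, barcodes are no longer needed, and this
#' function simply re-keys molecule ids (and barcodes) with a library
#' prefix and concatenates.
#'
#' @param molecule_list List of molecule tibbles, one per library.
#' @param calls_list Optional list of matching call tibbles (per-read
#'   allele calls or [assign_alleles()] output), re-keyed the same way
#'   (molecule, barcode and read identifiers all get the library prefix,
#'   since read names also repeat across libraries).
#' @return A molecule tibble, or (if `calls_list` is given) a list with
#'   `molecules` and `calls`.
#' @export
merge_libraries <- function(molecule_list, calls_list = NULL) {
  rekey <- function(tb, i) {
    tb$molecule_id <- paste0("L", i, "_", tb$molecule_id)
    if ("barcode" %in% names(tb)) tb$barcode <- paste0("L", i, "_", tb$barcode)
    if ("read_ids" %in% names(tb)) {
      tb$read_ids <- lapply(tb$read_ids, function(r) paste0("L", i, "_", r))
    }
    tb
  }
  mols <- bind_rows(imap(molecule_list, rekey))
  if (is.null(calls_list)) return(mols)
  calls <- bind_rows(imap(calls_list, function(tb, i) {
    if ("molecule_id" %in% names(tb)) {
      tb$molecule_id <- paste0("L", i, "_", tb$molecule_id)
    }
    if ("read_id" %in% names(tb)) {
      tb$read_id <- paste0("L", i, "_", tb$read_id)
    }
    tb
  }))
  list(molecules = mols, calls = calls)
}

#' Raw, physical and within-fragment read coverage
#'
#' Computes `C_F` (physical/fragment coverage: total molecule length over
#' genome length), `C_R` (read coverage within molecules: total aligned
#' read bases over total molecule length) and `C` (raw read coverage);
#' `C = C_F * C_R` holds by construction.
#'
#' @param molecules Molecule tibble.
#' @param alignments Alignment tibble (read bases are `end - start`).
#' @param genome_length Reference length in bp.
#' @return A one-row tibble with `C`, `C_F`, `C_R`.
#' @export
coverage_stats <- function(molecules, alignments, genome_length) {
  if (genome_length <= 0) abort("genome_length must be positive")
  if (nrow(molecules) == 0 || nrow(alignments) == 0) {
    abort("coverage_stats needs non-empty molecules and alignments")
  }
  mol_bases <- sum(as.numeric(molecules$end - molecules$start))
  read_bases <- sum(as.numeric(alignments$end - alignments$start))
  tibble(C = read_bases / genome_length,
         C_F = mol_bases / genome_length,
         C_R = read_bases / mol_bases)
}
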