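# Molecule-to-block maximum-likelihood assignment, phasing evaluation, and
# the end-to-end haplotyping driver.

#' Assign molecules to phase blocks by maximum likelihood
#'
#' For a molecule `M` with per-site call confidences `p_i` and a candidate
#' haplotype `H`, the likelihood is
#' `L(M|H) = prod_i [theta(H_i, M_i) p_i + (1 - theta(H_i, M_i)) (1 - p_i)]`
#' with `theta = 1` when the alleles agree. Each molecule is assigned to
#' the block (and side) maximising `L(M|H) - L(M|H_c)` over the block's
#' complementary haplotype pair. Molecules with fewer than two het calls,
#' or with a likelihood margin below `tie_eps`, stay UNASSIGNED (their
#' reads later contribute to both haplotypes).
#'
#' @param calls Molecule-level calls from [assign_alleles()].
#' @param pb A `phase_blocks` object.
#' @param min_sites Minimum shared het sites (default 2).
#' @param tie_eps Margin below which the assignment is a tie (default 1e-12).
#' @return Tibble `molecule_id`, `block_id`, `haplotype`, `margin`,
#'   `n_sites`; `block_id`/`haplotype` are `NA` for UNASSIGNED molecules.
#' @export
assign_molecules <- function(calls, pb, min_sites = 2, tie_eps = 1e-12) {
  all_mols <- unique(calls$molecule_id)
  vcols <- intersect(c("variant_id", "cluster_id", "block_id", "hap1"),
                     names(pb$variants))
  scored <- inner_join(calls, pb$variants[vcols], by = "variant_id") %>%
    group_by(.data$molecule_id, .data$cluster_id, .data$block_id) %>%
    summarise(
      n_sites = n(),
      L1 = prod(ifelse(.data$hap1 == .data$allele, .data$p, 1 - .data$p)),
      L2 = prod(ifelse(.data$hap1 != .data$allele, .data$p, 1 - .data$p)),
      .groups = "drop") %>%
    filter(.data$n_sites >= min_sites) %>%
    mutate(margin = abs(.data$L1 - .data$L2)) %>%
    group_by(.data$molecule_id) %>%
    slice(which.max(.data$margin)) %>%
    ungroup() %>%
    mutate(haplotype = if_else(.data$L1 >= .data$L2, 1L, 2L)) %>%
    mutate(block_id = if_else(.data$margin < tie_eps,
                              NA_integer_, .data$block_id),
           haplotype = if_else(.data$margin < tie_eps,
                               NA_integer_, .data$haplotype))
  missing <- setdiff(all_mols, scored$molecule_id)
  bind_rows(
    scored[c("molecule_id", "block_id", "haplotype", "margin", "n_sites")],
    tibble(molecule_id = missing, block_id = NA_integer_,
           haplotype = NA_integer_, margin = NA_real_, n_sites = 0L)
  )
}

#' Evaluate phasing against a truth phase
#'
#' Compares each block's haplotype string with the truth
#' haplotype-of-origin of its variants, after choosing the per-block
#' orientation that minimises disagreement (haplotype labels within a
#' block are arbitrary). Disagreement runs of length 1 are mismatch errors
#' (an isolated, presumably mis-genotyped site: two back-to-back
#' switches); runs of two or more consecutive sites are long switch
#' errors. Blocks overlapping fewer than two truth variants are skipped.
#'
#' @param pb A `phase_blocks` object.
#' @param truth_phase Tibble `variant_id`, `hap` (1/2: haplotype carrying
#'   the alternate allele).
#' @return Object of class `phasing_eval`: list with `summary` (one-row
#'   tibble: `phased_count`, `mismatch_errors`, `long_switch_errors`,
#'   `block_n50`, `max_block`, `n_blocks`) and `per_block`.
#' @export
evaluate_phasing <- function(pb, truth_phase) {
  joined <- inner_join(pb$variants, truth_phase, by = "variant_id") %>%
    arrange(.data$cluster_id, .data$pos)
  per_block <- joined %>%
    group_by(.data$cluster_id, .data$block_id) %>%
    filter(n() >= 2) %>%
    summarise(err = list({
      pred <- .data$hap1
      truth1 <- as.integer(.data$hap == 1L)
      dis <- pred != truth1
      if (sum(dis) > sum(!dis)) dis <- !dis
      r <- rle(dis)
      c(mismatch = sum(r$values & r$lengths == 1L),
        long_switch = sum(r$values & r$lengths >= 2L),
        n = length(dis))
    }), .groups = "drop") %>%
    mutate(mismatch = map_int(.data$err, ~ as.integer(.x[["mismatch"]])),
           long_switch = map_int(.data$err, ~ as.integer(.x[["long_switch"]])),
           n_compared = map_int(.data$err, ~ as.integer(.x[["n"]]))) %>%
    select(-"err")
  spans <- pb$blocks$end - pb$blocks$start + 1L
  summary <- tibble(
    phased_count = nrow(pb$variants),
    mismatch_errors = sum(per_block$mismatch),
    long_switch_errors = sum(per_block$long_switch),
    block_n50 = as.integer(n50(spans)),
    max_block = if (length(spans) > 0) max(spans) else 0L,
    n_blocks = nrow(pb$blocks)
  )
  structure(list(summary = summary, per_block = per_block),
            class = "phasing_eval")
}

#' @export
print.phasing_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<phasing_eval> %d phased; %d mismatch, %d long-switch errors; block N50 %d bp\n",
    s$phased_count, s$mismatch_errors, s$long_switch_errors, s$block_n50))
  invisible(x)
}

#' @export
glance.phasing_eval <- function(x, ...) x$summary

#' Run the full haplotyping stage
#'
#' Prunes the read-based het callset, attaches allele calls to molecules,
#' decides pair parities, clusters molecules into paired haplotype
#' clusters, builds and extends phase blocks, and assigns every molecule
#' to a block by maximum likelihood.
#'
#' @param molecules Molecule tibble from [reconstruct_fragments()].
#' @param allele_calls Per-read allele calls.
#' @param het_variants Het-variant tibble (see [het_variant_table()]).
#' @param prune Pruning thresholds ([prune_config()]).
#' @param alpha Parity significance level (default 0.99).
#' @param merge_support Cluster-merge molecule support (default 3).
#' @param overlap_support Block-extension shared-variant support (default 5).
#' @return Object of class `phaseset`: list with `blocks`
#'   (`phase_blocks`), `assignments`, `variants` (pruned het variants),
#'   `calls` (molecule-level), `decisions` and the parameters used.
#' @export
phase_haplotypes <- function(molecules, allele_calls, het_variants,
                             prune = prune_config(), alpha = 0.99,
                             merge_support = 3, overlap_support = 5) {
  pruned <- prune_variants(het_variants, prune)
  calls <- assign_alleles(molecules, allele_calls, pruned)
  obs <- parity_observations(calls, pruned)
  decisions <- decide_parity(obs, alpha = alpha)
  cp <- recursive_cluster(calls, decisions, pruned,
                          merge_support = merge_support)
  pb <- build_phase_blocks(cp, pruned)
  pb <- extend_phase_blocks(pb, overlap_support = overlap_support)
  assignments <- assign_molecules(calls, pb)
  structure(list(blocks = pb, assignments = assignments, variants = pruned,
                 calls = calls, decisions = decisions,
                 params = list(alpha = alpha, merge_support = merge_support,
                               overlap_support = overlap_support)),
            class = "phaseset")
}

#' @export
print.phaseset <- function(x, ...) {
  cat(sprintf("<phaseset> %d blocks; %d/%d molecules assigned\n",
              nrow(x$blocks$blocks),
              sum(!is.na(x$assignments$haplotype)),
              nrow(x$assignments)))
  invisible(x)
}

#' @export
tidy.phaseset <- function(x, ...) x$blocks$variants

#' @export
glance.phaseset <- function(x, ...) {
  spans <- x$blocks$blocks$end - x$blocks$blocks$start + 1L
  tibble(n_blocks = nrow(x$blocks$blocks),
         phased_variants = nrow(x$blocks$variants),
         assigned_molecules = sum(!is.na(x$assignments$haplotype)),
         block_n50 = as.integer(n50(spans)),
         max_block = if (length(spans)) max(spans) else 0L)
}

#' Write phased het SNPs as VCF
#'
#' @param phaseset A [phase_haplotypes()] result.
#' @param path Output path.
#' @param ref_lengths Optional named contig lengths.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(phaseset, path, ref_lengths = NULL) {
  v <- inner_join(phaseset$blocks$variants,
                  phaseset$variants[c("variant_id", "ref", "alt", "qual")],
                  by = "variant_id") %>%
    arrange(.data$chrom, .data$pos)
  write_vcf(tibble(chrom = v$chrom, pos = v$pos, id = v$variant_id,
                   ref = v$ref, alt = v$alt, qual = v$qual,
                   gt = paste0(v$hap1, "|", v$hap2), ps = v$block_id),
            path, ref_lengths = ref_lengths)
  invisible(path)
}
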