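# Haplotyping: variant pruning, Bayesian even/odd parity decisions per
# het-SNP pair, recursive clustering of molecules into paired haplotype
# clusters, phase-block construction/extension, maximum-likelihood molecule
# assignment, and phasing evaluation against truth.

#' Pruning thresholds for read-based het variants
#'
#' @param min_alt_fraction Minimum alternate allele fraction
#'   (`alt/(alt+ref)`); default 0.25.
#' @param coverage_low_pct,coverage_high_pct Two-tailed per-variant depth
#'   band. In the default percentile mode these are percentiles (10th-90th)
#'   of the observed depth distribution; with `percentile = FALSE` they are
#'   multipliers of the mean depth (`0.10 * avg` to `0.90 * avg`).
#' @param min_qual Minimum variant quality (phred); default 13.
#' @param percentile Use the percentile interpretation of the depth band
#'   (default) or the literal mean-multiplier band.
#' @return A `prune_config` list.
#' @export
prune_config <- function(min_alt_fraction = 0.25, coverage_low_pct = 10,
                         coverage_high_pct = 90, min_qual = 13,
                         percentile = TRUE) {
  stopifnot(min_alt_fraction >= 0, min_alt_fraction <= 1,
            coverage_low_pct < coverage_high_pct)
  structure(list(min_alt_fraction = min_alt_fraction,
                 coverage_low_pct = coverage_low_pct,
                 coverage_high_pct = coverage_high_pct,
                 min_qual = min_qual, percentile = percentile),
            class = "prune_config")
}

#' Prune unreliable het variants before haplotyping
#'
#' Keeps variants with alternate-allele fraction >= 0.25, quality >= 13,
#' and per-variant depth inside a two-tailed band (10th-90th depth
#' percentile by default). All comparisons are boundary-inclusive.
#'
#' @param variants Het-variant tibble with `depth`, `alt_fraction`, `qual`.
#' @param cfg A [prune_config()].
#' @return The filtered variant tibble.
#' @export
prune_variants <- function(variants, cfg = prune_config()) {
  if (nrow(variants) == 0) return(variants)
  if (cfg$percentile) {
    band <- quantile(variants$depth,
                     c(cfg$coverage_low_pct, cfg$coverage_high_pct) / 100,
                     names = FALSE)
  } else {
    avg <- mean(variants$depth)
    band <- c(cfg$coverage_low_pct, cfg$coverage_high_pct) / 100 * avg
  }
  variants %>%
    filter(.data$alt_fraction >= cfg$min_alt_fraction,
           .data$qual >= cfg$min_qual,
           .data$depth >= band[1], .data$depth <= band[2])
}

#' Summarise read-based het-SNP evidence into a variant table
#'
#' Convenience constructor for the het-variant table consumed by
#' [prune_variants()]: depth and alternate fraction are tallied from
#' per-read allele calls, positions and alleles come from a VCF-shaped
#' truth or callset tibble.
#'
#' @param allele_calls Per-read calls (`read_id`, `variant_id`, `allele`,
#'   `qual`).
#' @param vcf VCF-shaped tibble with `id`, `chrom`, `pos`, `ref`, `alt`
#'   (only het SNP records are used).
#' @param qual Variant quality to assign when the callset does not carry
#'   one (default 60).
#' @return Het-variant tibble: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `depth`, `alt_fraction`.
#' @export
het_variant_table <- function(allele_calls, vcf, qual = 60) {
  het <- vcf[nchar(vcf$ref) == 1 & nchar(vcf$alt) == 1 &
               grepl("^(0[/|]1|1[/|]0)$", vcf$gt), , drop = FALSE]
  depth <- allele_calls %>%
    count(.data$variant_id, name = "depth")
  altn <- allele_calls %>%
    group_by(.data$variant_id) %>%
    summarise(alt_n = sum(.data$allele == 1L), .groups = "drop")
  tibble(variant_id = het$id, chrom = het$chrom, pos = het$pos,
         ref = het$ref, alt = het$alt,
         qual = if ("qual" %in% names(het)) {
           q <- suppressWarnings(as.numeric(het$qual))
           ifelse(is.na(q), qual, q)
         } else qual) %>%
    left_join(depth, by = "variant_id") %>%
    left_join(altn, by = "variant_id") %>%
    mutate(depth = replace_na(.data$depth, 0L),
           alt_n = replace_na(.data$alt_n, 0L),
           alt_fraction = ifelse(.data$depth > 0,
                                 .data$alt_n / .data$depth, 0)) %>%
    select(-"alt_n")
}

# ---- parity model ------------------------------------------------------

#' Posterior probability that a het-SNP pair has even parity
#'
#' For two neighbouring het sites, molecules carry two-site keys `00/11`
#' (even parity) or `01/10` (odd). With per-variant correctness
#' probabilities `p1`, `p2`, a molecule shows the correct parity with
#' `p_c = p1*p2 + (1-p1)*(1-p2)` (either both calls right or both wrong).
#' Out of `N` molecules covering the pair, `k` show even keys. The
#' normalised two-hypothesis posterior (prior 0.5 each) is
#' `p_c^k (1-p_c)^(N-k) / (p_c^k (1-p_c)^(N-k) + (1-p_c)^k p_c^(N-k))`;
#' binomial coefficients cancel. Parity is called EVEN when the posterior
#' exceeds `alpha`, ODD when its complement does, else UNDETERMINED.
#'
#' With `literal = TRUE` the unnormalised textbook-Bayes form with a flat
#' `P(A) = choose(N, k)/2^N` denominator and `P(B) = 1` is returned
#' instead; it is not a probability (it can exceed 1) and is provided for
#' comparison only.
#'
#' @param n_even,n_odd Molecule counts by key parity (`k` and `N - k`);
#'   vectors are accepted.
#' @param p1,p2 Per-variant probabilities the allele call matches truth,
#'   in (0.5, 1).
#' @param alpha Significance level for the decision (default 0.99).
#' @param literal Return the textbook-Bayes unnormalised quantity instead of the normalised posterior.
#' @return Tibble with `posterior_even` and `decision`
#'   (`"EVEN"`/`"ODD"`/`"UNDETERMINED"`).
#' @examples
#' parity_posterior(5, 0, p1 = 0.99, p2 = 0.99)  # EVEN
#' parity_posterior(3, 2, p1 = 0.99, p2 = 0.99)  # 0.9802, UNDETERMINED
#' @export
parity_posterior <- function(n_even, n_odd, p1, p2, alpha = 0.99,
                             literal = FALSE) {
  stopifnot(all(p1 > 0.5 & p1 < 1), all(p2 > 0.5 & p2 < 1))
  k <- n_even
  N <- n_even + n_odd
  p_c <- p1 * p2 + (1 - p1) * (1 - p2)
  if (literal) {
    post <- choose(N, k) * p_c^k * (1 - p_c)^(N - k) / (choose(N, k) / 2^N)
  } else {
    post <- stats::plogis((2 * k - N) * (log(p_c) - log1p(-p_c)))
  }
  decision <- dplyr::case_when(
    N == 0 ~ "UNDETERMINED",
    post > alpha ~ "EVEN",
    (1 - post) > alpha ~ "ODD",
    TRUE ~ "UNDETERMINED"
  )
  tibble(posterior_even = post, decision = decision)
}

#' Tabulate two-site keys for neighbouring het-variant pairs
#'
#' For every molecule with at least two het allele calls, records each
#' neighbouring (by position, among the sites that molecule covers) pair of
#' variants and the molecule's two-site key, then tallies keys per pair.
#'
#' @param calls Molecule-level calls from [assign_alleles()].
#' @param variants Variant tibble with `variant_id`, `pos` (pruned set).
#' @return Tibble per pair: `v1`, `v2`, `n00`, `n01`, `n10`, `n11`, `N`,
#'   `k` (even count), plus per-pair `p1`, `p2` (per-variant mean call
#'   confidence, floored at 0.95).
#' @export
parity_observations <- function(calls, variants) {
  calls <- calls[calls$variant_id %in% variants$variant_id, , drop = FALSE]
  calls <- left_join(calls,
                     variants[c("variant_id", "pos")], by = "variant_id") %>%
    arrange(.data$molecule_id, .data$pos)
  paired <- calls %>%
    group_by(.data$molecule_id) %>%
    mutate(v2 = lead(.data$variant_id), a2 = lead(.data$allele)) %>%
    ungroup() %>%
    filter(!is.na(.data$v2))
  if (nrow(paired) == 0) {
    return(tibble(v1 = character(), v2 = character(), n00 = integer(),
                  n01 = integer(), n10 = integer(), n11 = integer(),
                  N = integer(), k = integer(), p1 = numeric(),
                  p2 = numeric()))
  }
  var_p <- calls %>%
    group_by(.data$variant_id) %>%
    summarise(p_var = pmax(mean(.data$p), 0.95), .groups = "drop")
  obs <- paired %>%
    mutate(key = paste0(.data$allele, .data$a2)) %>%
    count(v1 = .data$variant_id, v2 = .data$v2, .data$key) %>%
    pivot_wider(names_from = "key", values_from = "n", values_fill = 0L,
                names_prefix = "n")
  for (col in c("n00", "n01", "n10", "n11")) {
    if (!col %in% names(obs)) obs[[col]] <- 0L
  }
  obs %>%
    mutate(N = .data$n00 + .data$n01 + .data$n10 + .data$n11,
           k = .data$n00 + .data$n11) %>%
    left_join(rename(var_p, p1 = "p_var"), by = c(v1 = "variant_id")) %>%
    left_join(rename(var_p, p2 = "p_var"), by = c(v2 = "variant_id"))
}

# ---- union-find with orientation parity --------------------------------

uf_new <- function(n) {
  uf <- new.env(parent = emptyenv())
  uf$parent <- seq_len(n)
  uf$rank <- integer(n)
  uf$flip <- integer(n)  # orientation of node relative to its parent
  uf
}

# root and parity of x relative to its root, with path compression
uf_find <- function(uf, x) {
  path <- integer(0)
  while (uf$parent[x] != x) {
    path <- c(path, x)
    x <- uf$parent[x]
  }
  p <- 0L
  if (length(path) > 0) {
    acc <- 0L
    for (i in rev(seq_along(path))) {
      acc <- (acc + uf$flip[path[i]]) %% 2L
      uf$parent[path[i]] <- x
      uf$flip[path[i]] <- acc
    }
    p <- uf$flip[path[1]]
  }
  c(x, p)
}

# merge the sets of a and b such that parity(a) xor parity(b) == flip
uf_union <- function(uf, a, b, flip) {
  fa <- uf_find(uf, a)
  fb <- uf_find(uf, b)
  ra <- fa[1]; rb <- fb[1]
  if (ra == rb) return(invisible(FALSE))
  rel <- (fa[2] + fb[2] + flip) %% 2L
  if (uf$rank[ra] < uf$rank[rb]) {
    uf$parent[ra] <- rb; uf$flip[ra] <- rel
  } else {
    uf$parent[rb] <- ra; uf$flip[rb] <- rel
    if (uf$rank[ra] == uf$rank[rb]) uf$rank[ra] <- uf$rank[ra] + 1L
  }
  invisible(TRUE)
}

uf_groups <- function(uf) {
  n <- length(uf$parent)
  root <- integer(n); par <- integer(n)
  for (i in seq_len(n)) {
    f <- uf_find(uf, i)
    root[i] <- f[1]; par[i] <- f[2]
  }
  tibble(node = seq_len(n), root = root, parity = par)
}
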