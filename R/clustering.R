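# Recursive clustering of molecules into paired haplotype clusters, and
# phase-block construction, extension and molecule assignment.

# Two-site keys: for each molecule, neighbouring covered het sites and the
# molecule's key at that pair.
molecule_pair_keys <- function(calls, variants) {
  calls <- calls[calls$variant_id %in% variants$variant_id, , drop = FALSE]
  calls <- left_join(calls, variants[c("variant_id", "pos")],
                     by = "variant_id") %>%
    arrange(.data$molecule_id, .data$pos)
  calls %>%
    group_by(.data$molecule_id) %>%
    mutate(v2 = lead(.data$variant_id), a2 = lead(.data$allele)) %>%
    ungroup() %>%
    filter(!is.na(.data$v2)) %>%
    transmute(.data$molecule_id, v1 = .data$variant_id, v2 = .data$v2,
              a1 = .data$allele, a2 = .data$a2,
              key = paste0(.data$allele, .data$a2))
}

#' Decide even/odd parity for all observed het-SNP pairs
#'
#' Applies [parity_posterior()] to every neighbouring pair tabulated by
#' [parity_observations()].
#'
#' @param obs Output of [parity_observations()].
#' @param alpha Significance level (default 0.99).
#' @param literal Use the textbook-literal unnormalised score (see [parity_posterior()]).
#' @return `obs` with `posterior_even` and `decision` columns added.
#' @export
decide_parity <- function(obs, alpha = 0.99, literal = FALSE) {
  if (nrow(obs) == 0) {
    return(mutate(obs, posterior_even = numeric(0), decision = character(0)))
  }
  res <- parity_posterior(obs$k, obs$N - obs$k, obs$p1, obs$p2,
                          alpha = alpha, literal = literal)
  bind_cols(obs, res)
}

#' Recursively cluster molecules into paired haplotype clusters
#'
#' Each parity-determined het-SNP pair seeds a pair of complementary
#' clusters (molecules keyed `00`/`11` for even parity, `01`/`10` for odd;
#' molecules whose key has the rejected parity are excluded as sequencing
#' error for that pair only). Cluster pairs are then merged recursively:
#' two pairs merge when the number of distinct molecules supporting the
#' same haplotype in both reaches `merge_support` (3 by default) while the
#' opposite orientation stays below it. Complementary clusters merge in
#' lockstep, clusters are re-sorted by genomic position each round, and
#' merging repeats to a fixed point.
#'
#' @param calls Molecule-level calls from [assign_alleles()].
#' @param decisions Output of [decide_parity()].
#' @param variants Variant tibble with `variant_id`, `pos`.
#' @param merge_support Minimum shared-molecule support to merge (default 3).
#' @return An object of class `cluster_pairs`: list with `membership`
#'   (`cluster_id`, `molecule_id`, `side` 0/1), `haplotype` (per-cluster
#'   per-variant majority allele on side A with `n_for`/`n_against` vote
#'   counts) and `clusters` (summary tibble).
#' @export
recursive_cluster <- function(calls, decisions, variants, merge_support = 3) {
  keys <- molecule_pair_keys(calls, variants)
  seeds <- decisions %>%
    filter(.data$decision != "UNDETERMINED") %>%
    mutate(seed_id = row_number())
  empty <- structure(list(
    membership = tibble(cluster_id = integer(), molecule_id = character(),
                        side = integer()),
    haplotype = tibble(cluster_id = integer(), variant_id = character(),
                       allele_A = integer(), n_for = integer(),
                       n_against = integer()),
    clusters = tibble(cluster_id = integer(), start = numeric(),
                      end = numeric(), n_variants = integer(),
                      n_molecules = integer())), class = "cluster_pairs")
  if (nrow(seeds) == 0) return(empty)

  membership <- keys %>%
    inner_join(seeds[c("v1", "v2", "decision", "seed_id")],
               by = c("v1", "v2")) %>%
    mutate(side = dplyr::case_when(
      .data$decision == "EVEN" & .data$key == "00" ~ 0L,
      .data$decision == "EVEN" & .data$key == "11" ~ 1L,
      .data$decision == "ODD" & .data$key == "01" ~ 0L,
      .data$decision == "ODD" & .data$key == "10" ~ 1L,
      TRUE ~ NA_integer_
    )) %>%
    filter(!is.na(.data$side)) %>%
    distinct(cluster_id = .data$seed_id, .data$molecule_id, .data$side)

  vpos <- setNames(variants$pos, variants$variant_id)
  cluster_vars <- seeds %>%
    transmute(cluster_id = .data$seed_id, v1 = .data$v1, v2 = .data$v2)

  repeat {
    # candidate pairs: clusters sharing at least one molecule
    self <- inner_join(membership, membership, by = "molecule_id",
                       relationship = "many-to-many")
    # membership is distinct per (cluster, molecule), so plain counts give
    # the number of distinct shared molecules per orientation
    cand <- self %>%
      filter(.data$cluster_id.x < .data$cluster_id.y) %>%
      count(c1 = .data$cluster_id.x, c2 = .data$cluster_id.y,
            agree = .data$side.x == .data$side.y) %>%
      pivot_wider(names_from = "agree", values_from = "n",
                  values_fill = 0L, names_prefix = "a")
    for (cl in c("aTRUE", "aFALSE")) {
      if (!cl %in% names(cand)) cand[[cl]] <- 0L
    }
    cand <- cand %>%
      rename(same = "aTRUE", flip = "aFALSE") %>%
      mutate(smax = pmax(.data$same, .data$flip),
             smin = pmin(.data$same, .data$flip)) %>%
      filter(.data$smax >= merge_support, .data$smin < merge_support)
    if (nrow(cand) == 0) break

    ids <- sort(unique(membership$cluster_id))
    idx <- setNames(seq_along(ids), ids)
    uf <- uf_new(length(ids))
    merged_any <- FALSE
    for (i in seq_len(nrow(cand))) {
      a <- idx[[as.character(cand$c1[i])]]
      b <- idx[[as.character(cand$c2[i])]]
      fl <- as.integer(cand$flip[i] > cand$same[i])
      if (uf_union(uf, a, b, fl)) merged_any <- TRUE
    }
    if (!merged_any) break
    grp <- uf_groups(uf)
    relab <- tibble(cluster_id = ids, root = grp$root, parity = grp$parity)

    membership <- membership %>%
      left_join(relab, by = "cluster_id") %>%
      mutate(side = (.data$side + .data$parity) %% 2L) %>%
      group_by(cluster_id = .data$root, .data$molecule_id) %>%
      summarise(n0 = sum(.data$side == 0L), n1 = sum(.data$side == 1L),
                .groups = "drop") %>%
      filter(.data$n0 != .data$n1) %>%
      transmute(.data$cluster_id, .data$molecule_id,
                side = as.integer(.data$n1 > .data$n0))
    cluster_vars <- cluster_vars %>%
      left_join(relab, by = "cluster_id") %>%
      transmute(cluster_id = .data$root, .data$v1, .data$v2)

    # re-sort clusters by genomic position for the next round
    order_tbl <- cluster_vars %>%
      group_by(.data$cluster_id) %>%
      summarise(minpos = min(vpos[.data$v1], vpos[.data$v2]),
                .groups = "drop") %>%
      arrange(.data$minpos) %>%
      mutate(new_id = row_number())
    membership <- membership %>%
      left_join(order_tbl[c("cluster_id", "new_id")], by = "cluster_id") %>%
      transmute(cluster_id = .data$new_id, .data$molecule_id, .data$side)
    cluster_vars <- cluster_vars %>%
      left_join(order_tbl[c("cluster_id", "new_id")], by = "cluster_id") %>%
      transmute(cluster_id = .data$new_id, .data$v1, .data$v2)
  }

  haplotype <- cluster_haplotype_votes(membership, calls)
  clusters <- haplotype %>%
    left_join(variants[c("variant_id", "pos")], by = "variant_id") %>%
    group_by(.data$cluster_id) %>%
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_variants = n(), .groups = "drop") %>%
    left_join(count(membership, .data$cluster_id, name = "n_molecules"),
              by = "cluster_id")
  structure(list(membership = membership, haplotype = haplotype,
                 clusters = clusters),
            class = "cluster_pairs")
}

# Majority-vote haplotype per cluster side A, with vote counts.
cluster_haplotype_votes <- function(membership, calls) {
  if (nrow(membership) == 0) {
    return(tibble(cluster_id = integer(), variant_id = character(),
                  allele_A = integer(), n_for = integer(),
                  n_against = integer()))
  }
  inner_join(membership, calls, by = "molecule_id",
             relationship = "many-to-many") %>%
    mutate(implied_A = (.data$allele + .data$side) %% 2L) %>%
    group_by(.data$cluster_id, .data$variant_id) %>%
    summarise(n1 = sum(.data$implied_A == 1L), n0 = sum(.data$implied_A == 0L),
              .groups = "drop") %>%
    transmute(.data$cluster_id, .data$variant_id,
              allele_A = as.integer(.data$n1 >= .data$n0),
              n_for = pmax(.data$n1, .data$n0),
              n_against = pmin(.data$n1, .data$n0))
}

#' Build phase blocks from converged cluster pairs
#'
#' A variant is phased into a block only when every assigned molecule
#' covering it agrees (per haplotype); variants with any contradicting
#' molecule are excluded from further steps. Clusters retaining fewer than
#' two unanimous variants do not form blocks.
#'
#' @param cluster_pairs A [recursive_cluster()] result.
#' @param variants Variant tibble with `variant_id`, `pos` (1-based),
#'   `chrom`.
#' @return An object of class `phase_blocks`: list with `blocks`
#'   (`block_id` = leftmost phased variant position, span, sizes),
#'   `variants` (`block_id`, `variant_id`, `pos`, `hap1`, `hap2`,
#'   `n_support`) and `molecules` (`block_id`, `molecule_id`, `haplotype`).
#' @export
build_phase_blocks <- function(cluster_pairs, variants) {
  hap <- cluster_pairs$haplotype %>%
    filter(.data$n_against == 0L, .data$n_for >= 1L) %>%
    left_join(variants[c("variant_id", "pos", "chrom")], by = "variant_id")
  keep <- hap %>% count(.data$cluster_id) %>% filter(.data$n >= 2)
  hap <- hap[hap$cluster_id %in% keep$cluster_id, , drop = FALSE]
  blocks_from_parts(hap, cluster_pairs$membership, id_col = "cluster_id")
}

# Shared assembler of a phase_blocks object from per-cluster variant and
# membership tables. `cluster_id` stays the unique internal key (distinct
# overlapping clusters can share a leftmost variant position before
# extension); `block_id` is the positional PS label.
blocks_from_parts <- function(hap, membership, id_col) {
  if (nrow(hap) == 0) {
    return(structure(list(
      blocks = tibble(cluster_id = integer(), block_id = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), n_variants = integer(),
                      n_molecules = integer()),
      variants = tibble(cluster_id = integer(), block_id = integer(),
                        variant_id = character(), chrom = character(),
                        pos = integer(), hap1 = integer(), hap2 = integer(),
                        n_support = integer()),
      molecules = tibble(cluster_id = integer(), block_id = integer(),
                         molecule_id = character(), haplotype = integer())),
      class = "phase_blocks"))
  }
  if (id_col != "cluster_id") hap$cluster_id <- hap[[id_col]]
  ids <- hap %>%
    group_by(.data$cluster_id) %>%
    summarise(block_id = as.integer(min(.data$pos)), .groups = "drop")
  vars <- hap %>%
    left_join(ids, by = "cluster_id") %>%
    transmute(.data$cluster_id, .data$block_id, .data$variant_id,
              .data$chrom, .data$pos,
              hap1 = .data$allele_A, hap2 = 1L - .data$allele_A,
              n_support = .data$n_for) %>%
    arrange(.data$block_id, .data$cluster_id, .data$pos)
  if (id_col != "cluster_id" && id_col %in% names(membership)) {
    membership$cluster_id <- membership[[id_col]]
  }
  mols <- membership %>%
    inner_join(ids, by = "cluster_id") %>%
    transmute(.data$cluster_id, .data$block_id, .data$molecule_id,
              haplotype = .data$side + 1L)
  blocks <- vars %>%
    group_by(.data$cluster_id, .data$block_id, .data$chrom) %>%
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_variants = n(), .groups = "drop") %>%
    left_join(count(mols, .data$cluster_id, name = "n_molecules"),
              by = "cluster_id") %>%
    mutate(n_molecules = replace_na(.data$n_molecules, 0L)) %>%
    arrange(.data$block_id, .data$cluster_id)
  structure(list(blocks = blocks, variants = vars, molecules = mols),
            class = "phase_blocks")
}

#' Extend phase blocks by merging on shared variants
#'
#' Two blocks merge when they share at least `overlap_support` variants
#' (5 by default) whose relative orientation is consistent across all
#' shared sites, so the chance of a spurious merge from per-site error `p`
#' is at most `p^5`. Merging is transitive (union-find) and repeats to a
#' fixed point; afterwards any variant still phased in more than one block
#' is kept only in the block with stronger support, making final blocks
#' non-overlapping in variant membership.
#'
#' @param pb A [build_phase_blocks()] result.
#' @param overlap_support Minimum consistent shared variants (default 5).
#' @return A `phase_blocks` object.
#' @export
extend_phase_blocks <- function(pb, overlap_support = 5) {
  vars <- pb$variants
  if (nrow(vars) == 0) return(pb)
  shared <- inner_join(vars, vars, by = "variant_id",
                       relationship = "many-to-many") %>%
    filter(.data$cluster_id.x < .data$cluster_id.y) %>%
    group_by(c1 = .data$cluster_id.x, c2 = .data$cluster_id.y) %>%
    summarise(n_same = sum(.data$hap1.x == .data$hap1.y),
              n_flip = sum(.data$hap1.x != .data$hap1.y),
              .groups = "drop") %>%
    filter(pmax(.data$n_same, .data$n_flip) >= overlap_support,
           pmin(.data$n_same, .data$n_flip) == 0L)

  ids <- sort(unique(vars$cluster_id))
  if (nrow(shared) > 0) {
    idx <- setNames(seq_along(ids), ids)
    uf <- uf_new(length(ids))
    for (i in seq_len(nrow(shared))) {
      uf_union(uf, idx[[as.character(shared$c1[i])]],
               idx[[as.character(shared$c2[i])]],
               as.integer(shared$n_flip[i] > 0))
    }
    grp <- uf_groups(uf)
    relab <- tibble(cluster_id = ids, root = grp$root, parity = grp$parity)
    vars <- vars %>%
      left_join(relab, by = "cluster_id") %>%
      mutate(hap1 = (.data$hap1 + .data$parity) %% 2L,
             hap2 = 1L - .data$hap1)
    mols <- pb$molecules %>%
      left_join(relab, by = "cluster_id") %>%
      mutate(haplotype = (.data$haplotype - 1L + .data$parity) %% 2L + 1L) %>%
      transmute(cluster_id = .data$root, .data$molecule_id,
                side = .data$haplotype - 1L) %>%
      group_by(.data$cluster_id, .data$molecule_id) %>%
      summarise(n0 = sum(.data$side == 0L), n1 = sum(.data$side == 1L),
                .groups = "drop") %>%
      filter(.data$n0 != .data$n1) %>%
      transmute(.data$cluster_id, .data$molecule_id,
                side = as.integer(.data$n1 > .data$n0))
    vars <- vars %>%
      transmute(cluster_id = .data$root, .data$variant_id, .data$chrom,
                .data$pos, allele_A = .data$hap1, n_for = .data$n_support)
  } else {
    mols <- pb$molecules %>%
      transmute(.data$cluster_id, .data$molecule_id,
                side = .data$haplotype - 1L)
    vars <- vars %>%
      transmute(.data$cluster_id, .data$variant_id, .data$chrom,
                .data$pos, allele_A = .data$hap1, n_for = .data$n_support)
  }

  # a variant phased in several blocks is kept only in its strongest copy
  vars <- vars %>%
    group_by(.data$cluster_id, .data$variant_id) %>%
    slice(which.max(.data$n_for)) %>%
    ungroup() %>%
    group_by(.data$variant_id) %>%
    slice(which.max(.data$n_for)) %>%
    ungroup()
  out <- blocks_from_parts(vars, mols, id_col = "cluster_id")
  # drop clusters reduced below two phased variants by the dedup
  keep <- out$blocks$cluster_id[out$blocks$n_variants >= 2]
  structure(list(blocks = out$blocks[out$blocks$cluster_id %in% keep, ],
                 variants = out$variants[out$variants$cluster_id %in% keep, ],
                 molecules = out$molecules[out$molecules$cluster_id %in% keep, ]),
            class = "phase_blocks")
}

#' @export
print.cluster_pairs <- function(x, ...) {
  cat(sprintf("<cluster_pairs> %d cluster pairs, %d molecule assignments\n",
              nrow(x$clusters), nrow(x$membership)))
  invisible(x)
}

#' @export
print.phase_blocks <- function(x, ...) {
  cat(sprintf("<phase_blocks> %d blocks, %d phased variants, N50 span %d bp\n",
              nrow(x$blocks), nrow(x$variants),
              as.integer(n50(x$blocks$end - x$blocks$start + 1))))
  invisible(x)
}
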