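# Variant pruning, the parity model, recursive clustering, phase-block
# construction/extension, molecule assignment and phasing evaluation.

test_that("pruning applies the alt-fraction, quality and depth-band rules inclusively", {
  v <- tibble::tibble(
    variant_id = sprintf("v%d", 1:23),
    pos = 1:23 * 100L,
    depth = c(50L, 50L, 50L, rep(c(30L, 40L, 50L, 60L, 70L), 4)),
    alt_fraction = c(0.20, 0.25, 0.5, rep(0.5, 20)),
    qual = c(30, 13, 12, rep(30, 20)))
  kept <- prune_variants(v, prune_config())
  expect_false("v1" %in% kept$variant_id)  # alt fraction 0.20 < 0.25
  expect_true("v2" %in% kept$variant_id)   # 0.25 and qual 13: boundaries kept
  expect_false("v3" %in% kept$variant_id)  # qual 12 < 13
  # depth band: percentile mode keeps the bulk
  band <- quantile(v$depth, c(.1, .9))
  expect_true(all(kept$depth >= band[1] & kept$depth <= band[2]))
  expect_equal(nrow(prune_variants(v[0, ], prune_config())), 0)
})

test_that("literal mean-multiplier depth band is available and differs", {
  v <- tibble::tibble(variant_id = sprintf("v%d", 1:5), pos = 1:5,
                      depth = c(30L, 40L, 50L, 60L, 70L),
                      alt_fraction = 0.5, qual = 30)
  lit <- prune_variants(v, prune_config(percentile = FALSE))
  # 0.1*50=5, 0.9*50=45: only depths 30 and 40 pass
  expect_setequal(lit$variant_id, c("v1", "v2"))
})

test_that("parity posterior matches the stated worked examples", {
  r1 <- parity_posterior(5, 0, 0.99, 0.99)
  expect_equal(r1$decision, "EVEN")
  expect_lt(abs((1 - r1$posterior_even) - 3.4e-9), 1e-9)
  r2 <- parity_posterior(3, 2, 0.99, 0.99)
  expect_equal(r2$posterior_even, 0.9802, tolerance = 1e-10)
  expect_equal(r2$decision, "UNDETERMINED")
  r3 <- parity_posterior(4, 4, 0.95, 0.95)
  expect_equal(r3$posterior_even, 0.5)
  expect_equal(r3$decision, "UNDETERMINED")
  expect_equal(parity_posterior(0, 0, 0.9, 0.9)$decision, "UNDETERMINED")
})

test_that("the normalised posterior lies in [0,1] everywhere; the literal formula does not", {
  for (p in c(0.9, 0.95, 0.99)) {
    for (N in 1:10) {
      for (k in 0:N) {
        r <- parity_posterior(k, N - k, p, p)
        expect_gte(r$posterior_even, 0)
        expect_lte(r$posterior_even, 1)
      }
    }
  }
  lit <- parity_posterior(10, 0, 0.99, 0.99, literal = TRUE)
  expect_gt(lit$posterior_even, 1)
})

# Hand-built clustering instance: 8 het SNPs, two haplotypes, molecules
# covering neighbouring pairs.
mk_cluster_input <- function(n_mol = 30, n_var = 8, span = 3, seed = 1,
                             p = 0.999) {
  set.seed(seed)
  vars <- tibble::tibble(variant_id = sprintf("v%02d", 1:n_var),
                         pos = (1:n_var) * 1000L, chrom = "chr1")
  hap1 <- sample(0:1, n_var, replace = TRUE)
  calls <- purrr::map_dfr(1:n_mol, function(m) {
    s <- sample.int(n_var - span + 1L, 1)
    side <- sample(1:2, 1)
    tibble::tibble(molecule_id = sprintf("M%03d", m),
                   variant_id = vars$variant_id[s:(s + span - 1L)],
                   allele = if (side == 1) hap1[s:(s + span - 1L)] else
                     1L - hap1[s:(s + span - 1L)],
                   p = p)
  })
  list(vars = vars, hap1 = hap1, calls = calls)
}

test_that("cluster pairs merge at 3 shared supporting molecules but not at 2", {
  # two determined pairs (v1,v2) and (v2,v3); shared molecules span all three
  vars <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                         pos = c(100L, 200L, 300L), chrom = "chr1")
  mk_calls <- function(n_shared) {
    spanning <- purrr::map_dfr(seq_len(n_shared), function(m)
      tibble::tibble(molecule_id = sprintf("S%d", m),
                     variant_id = c("v1", "v2", "v3"),
                     allele = c(0L, 1L, 0L), p = 0.999))
    extra <- dplyr::bind_rows(
      tibble::tibble(molecule_id = "E1", variant_id = c("v1", "v2"),
                     allele = c(1L, 0L), p = 0.999),
      tibble::tibble(molecule_id = "E2", variant_id = c("v2", "v3"),
                     allele = c(0L, 1L), p = 0.999))
    dplyr::bind_rows(spanning, extra)
  }
  for (n_shared in c(2L, 3L)) {
    calls <- mk_calls(n_shared)
    obs <- parity_observations(calls, vars)
    dec <- decide_parity(obs)
    cp <- recursive_cluster(calls, dec, vars, merge_support = 3)
    if (n_shared == 3L) {
      expect_equal(nrow(cp$clusters), 1)
    } else {
      expect_equal(nrow(cp$clusters), 2)
    }
  }
})

test_that("clustering reaches the same fixed point as an exhaustive any-order oracle", {
  inp <- mk_cluster_input(n_mol = 30, seed = 11)
  obs <- parity_observations(inp$calls, inp$vars)
  dec <- decide_parity(obs)
  cp <- recursive_cluster(inp$calls, dec, inp$vars)

  # oracle: seed clusters per determined pair; merge any qualifying pair
  # (random order) until stable; compare final molecule partitions
  oracle_partition <- function(order_seed) {
    set.seed(order_seed)
    keys <- diploidlr:::molecule_pair_keys(inp$calls, inp$vars)
    seeds <- dec[dec$decision != "UNDETERMINED", ]
    clusters <- purrr::map(seq_len(nrow(seeds)), function(i) {
      k <- keys[keys$v1 == seeds$v1[i] & keys$v2 == seeds$v2[i], ]
      good <- if (seeds$decision[i] == "EVEN") c("00", "11") else c("01", "10")
      k <- k[k$key %in% good, ]
      list(A = k$molecule_id[k$key == good[1]],
           B = k$molecule_id[k$key == good[2]])
    })
    alive <- rep(TRUE, length(clusters))
    repeat {
      merged <- FALSE
      idx <- sample(seq_along(clusters))
      for (i in idx) for (j in idx) {
        if (i >= j || !alive[i] || !alive[j]) next
        a <- clusters[[i]]; b <- clusters[[j]]
        same <- length(intersect(a$A, b$A)) + length(intersect(a$B, b$B))
        flip <- length(intersect(a$A, b$B)) + length(intersect(a$B, b$A))
        if (max(same, flip) >= 3 && min(same, flip) < 3) {
          if (flip > same) b <- list(A = b$B, B = b$A)
          clusters[[i]] <- list(A = union(a$A, b$A), B = union(a$B, b$B))
          alive[j] <- FALSE
          merged <- TRUE
        }
      }
      if (!merged) break
    }
    clusters <- clusters[alive]
    part <- purrr::map_chr(clusters, function(cl)
      paste(sort(c(paste0(sort(cl$A), collapse = ","),
                   paste0(sort(cl$B), collapse = ","))), collapse = "|"))
    sort(part)
  }
  p1 <- oracle_partition(1)
  p2 <- oracle_partition(99)
  expect_identical(p1, p2)  # order independence of the oracle itself
  got <- cp$membership %>%
    dplyr::group_by(cluster_id) %>%
    dplyr::summarise(key = paste(sort(c(
      paste0(sort(molecule_id[side == 0]), collapse = ","),
      paste0(sort(molecule_id[side == 1]), collapse = ","))),
      collapse = "|")) %>%
    dplyr::pull(key) %>% sort()
  expect_identical(got, p1)
})

test_that("phase blocks keep unanimous variants and exclude contradicted ones", {
  vars <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                         pos = c(100L, 200L, 300L), chrom = "chr1")
  calls <- dplyr::bind_rows(
    purrr::map_dfr(1:4, function(m)
      tibble::tibble(molecule_id = sprintf("M%d", m),
                     variant_id = c("v1", "v2", "v3"),
                     allele = c(0L, 1L, 0L), p = 0.999)),
    # one molecule contradicting v3 only
    tibble::tibble(molecule_id = "M9", variant_id = c("v1", "v2", "v3"),
                   allele = c(0L, 1L, 1L), p = 0.999))
  obs <- parity_observations(calls, vars)
  cp <- recursive_cluster(calls, decide_parity(obs), vars)
  pb <- build_phase_blocks(cp, vars)
  expect_true(all(c("v1", "v2") %in% pb$variants$variant_id))
  expect_false("v3" %in% pb$variants$variant_id)
  expect_equal(pb$blocks$block_id, 100L)  # leftmost phased position
  # complementarity
  expect_true(all(pb$variants$hap1 + pb$variants$hap2 == 1L))
})

test_that("block extension needs 5 consistent shared variants and is transitive", {
  mk_pb <- function(blocks) {
    vars <- dplyr::bind_rows(purrr::imap(blocks, function(b, i) {
      tibble::tibble(cluster_id = as.integer(i), variant_id = b$ids,
                     chrom = "chr1", pos = b$pos, allele_A = b$hap1,
                     n_for = 5L)
    }))
    mols <- tibble::tibble(cluster_id = integer(), molecule_id = character(),
                           side = integer())
    diploidlr:::blocks_from_parts(vars, mols, "cluster_id")
  }
  ids <- sprintf("v%02d", 1:18)
  hap <- rep(c(0L, 1L), length.out = 18)
  # A and B share v06..v10 (5, consistently flipped); B and C share only 4
  # (v12..v15), and C keeps three variants of its own
  pbA <- list(ids = ids[1:10], pos = (1:10) * 100L, hap1 = hap[1:10])
  pbB <- list(ids = ids[6:15], pos = (6:15) * 100L, hap1 = 1L - hap[6:15])
  pbC <- list(ids = ids[12:18], pos = (12:18) * 100L, hap1 = hap[12:18])
  pb <- mk_pb(list(pbA, pbB, pbC))
  ext <- extend_phase_blocks(pb, overlap_support = 5)
  expect_equal(nrow(ext$blocks), 2)  # A+B merged; C (4 shared) apart
  # after dedup, no variant is phased in two blocks
  expect_false(any(duplicated(ext$variants$variant_id)))

  # a block whose variants are all phased in a bigger block disappears
  pbCsub <- list(ids = ids[12:15], pos = (12:15) * 100L, hap1 = hap[12:15])
  ext_sub <- extend_phase_blocks(mk_pb(list(pbA, pbB, pbCsub)),
                                 overlap_support = 5)
  expect_equal(nrow(ext_sub$blocks), 1)

  # chain A-B, B-C with 5 shared each merges all three (union-find closure)
  pbC5 <- list(ids = ids[11:15], pos = (11:15) * 100L, hap1 = hap[11:15])
  pbB10 <- list(ids = ids[6:15], pos = (6:15) * 100L, hap1 = 1L - hap[6:15])
  ext2 <- extend_phase_blocks(mk_pb(list(pbA, pbB10, pbC5)),
                              overlap_support = 5)
  expect_equal(nrow(ext2$blocks), 1)
  # merged haplotypes are orientation-consistent with block A
  merged <- ext2$variants
  expect_equal(merged$hap1[match(ids[1:10], merged$variant_id)], hap[1:10])
})

test_that("molecule assignment follows the likelihood with its tie and minimum-site rules", {
  vars <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                         pos = c(100L, 200L, 300L), chrom = "chr1")
  hap <- tibble::tibble(cluster_id = 1L, variant_id = vars$variant_id,
                        allele_A = c(1L, 1L, 1L), n_for = 3L)
  pb <- diploidlr:::blocks_from_parts(
    dplyr::left_join(hap, vars[c("variant_id", "pos", "chrom")],
                     by = "variant_id"),
    tibble::tibble(cluster_id = integer(), molecule_id = character(),
                   side = integer()),
    "cluster_id")
  calls <- tibble::tibble(molecule_id = "M1",
                          variant_id = c("v1", "v2", "v3"),
                          allele = c(1L, 1L, 1L), p = 0.99)
  a <- assign_molecules(calls, pb)
  expect_equal(a$haplotype, 1L)
  expect_equal(a$margin, 0.99^3 - 0.01^3, tolerance = 1e-12)
  expect_equal(0.99^3, 0.970299)

  one_call <- calls[1, ]
  a1 <- assign_molecules(one_call, pb)
  expect_true(is.na(a1$haplotype))

  # perfectly ambiguous molecule: equal evidence for both sides is a tie
  calls_tie <- tibble::tibble(molecule_id = "M2",
                              variant_id = c("v1", "v2"),
                              allele = c(1L, 0L), p = c(0.99, 0.99))
  a2 <- assign_molecules(calls_tie, pb)
  expect_true(is.na(a2$haplotype))
})

test_that("phasing evaluation distinguishes mismatch and long switch errors", {
  mk_eval <- function(pred) {
    vars <- tibble::tibble(cluster_id = 1L,
                           variant_id = sprintf("v%d", seq_along(pred)),
                           chrom = "chr1", pos = seq_along(pred) * 100L,
                           allele_A = pred, n_for = 3L)
    pb <- diploidlr:::blocks_from_parts(
      vars, tibble::tibble(cluster_id = integer(),
                           molecule_id = character(), side = integer()),
      "cluster_id")
    truth <- tibble::tibble(variant_id = vars$variant_id,
                            hap = rep(2L, length(pred)))  # truth all "0"
    glance(evaluate_phasing(pb, truth))
  }
  r1 <- mk_eval(c(0L, 1L, 0L, 0L))
  expect_equal(c(r1$mismatch_errors, r1$long_switch_errors), c(1L, 0L))
  r2 <- mk_eval(c(0L, 0L, 1L, 1L))
  expect_equal(c(r2$mismatch_errors, r2$long_switch_errors), c(0L, 1L))
  r3 <- mk_eval(c(0L, 0L, 0L, 0L))
  expect_equal(c(r3$mismatch_errors, r3$long_switch_errors), c(0L, 0L))
})

test_that("injected isolated flips are counted at the expected rate", {
  set.seed(202)
  n <- 400; r <- 0.02
  reps <- purrr::map_int(1:5, function(i) {
    flips <- rbinom(n, 1, r) == 1
    mk_pred <- as.integer(flips)  # truth all zeros
    vars <- tibble::tibble(cluster_id = 1L,
                           variant_id = sprintf("v%03d", 1:n),
                           chrom = "chr1", pos = (1:n) * 50L,
                           allele_A = mk_pred, n_for = 3L)
    pb <- diploidlr:::blocks_from_parts(
      vars, tibble::tibble(cluster_id = integer(),
                           molecule_id = character(), side = integer()),
      "cluster_id")
    truth <- tibble::tibble(variant_id = vars$variant_id, hap = 2L)
    glance(evaluate_phasing(pb, truth))$mismatch_errors
  })
  expected <- (n - 2) * r * (1 - r)^2 + 2 * r * (1 - r)
  expect_lt(abs(mean(reps) - expected), 3 * sqrt(expected / 5))
})

test_that("error-free simulation phases with zero switch and mismatch errors", {
  fx <- small_phaseset(error = 0)
  pe <- evaluate_phasing(fx$phaseset$blocks, truth_phase_of(fx$truth))
  expect_equal(pe$summary$mismatch_errors, 0L)
  expect_equal(pe$summary$long_switch_errors, 0L)
  expect_gt(pe$summary$phased_count, 100)
  v <- fx$phaseset$blocks$variants
  expect_true(all(v$hap1 + v$hap2 == 1L))
})

test_that("raising support thresholds never increases merging", {
  fx <- small_phaseset(error = 0)
  mols <- fx$molecules; calls <- fx$phaseset$calls
  pruned <- fx$phaseset$variants
  obs <- parity_observations(calls, pruned)
  dec <- decide_parity(obs)
  n_prev <- 0L
  for (ms in c(3, 5, 8)) {
    cp <- recursive_cluster(calls, dec, pruned, merge_support = ms)
    expect_gte(nrow(cp$clusters), n_prev)
    n_prev <- nrow(cp$clusters)
  }
})
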