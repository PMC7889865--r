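# SV merging, Alu/repeat classification, ancestral inference and
# segregation patterns.

test_that("SV callset merging follows the overlap and 20 bp rules", {
  cs1 <- tibble::tibble(chrom = "chr1", start = c(100L, 1000L),
                        end = c(300L, 1000L), type = c("DEL", "INS"),
                        size = c(200L, 80L))
  cs2 <- tibble::tibble(chrom = "chr1", start = c(250L, 1019L),
                        end = c(500L, 1019L), type = c("DEL", "INS"),
                        size = c(250L, 80L))
  m <- merge_sv_callsets(list(cs1, cs2))
  expect_equal(nrow(m), 2)  # DELs overlap; INS 19 bp apart merge
  expect_true(all(m$n_callsets == 2))

  cs3 <- tibble::tibble(chrom = "chr1", start = 1021L, end = 1021L,
                        type = "INS", size = 80L)
  m2 <- merge_sv_callsets(list(cs1, cs3))
  expect_equal(nrow(m2), 3)  # 21 bp apart: distinct insertions
  expect_equal(sum(m2$in_cs1), 2)
  expect_equal(sum(m2$in_cs2), 1)
})

test_that("merging is independent of callset order (closure oracle)", {
  set.seed(55)
  mk_cs <- function(n) {
    start <- sample.int(5000L, n)
    type <- sample(c("DEL", "INS"), n, replace = TRUE)
    size <- sample(50:300, n, replace = TRUE)
    tibble::tibble(chrom = "chr1", start = start,
                   end = ifelse(type == "DEL", start + size, start),
                   type = type, size = size)
  }
  css <- list(mk_cs(20), mk_cs(20), mk_cs(20))
  m_fwd <- merge_sv_callsets(css)
  m_rev <- merge_sv_callsets(rev(css))
  expect_equal(nrow(m_fwd), nrow(m_rev))
  expect_equal(m_fwd[c("chrom", "start", "end", "type")],
               m_rev[c("chrom", "start", "end", "type")])

  # exhaustive pairwise closure oracle on the pooled records
  pool <- dplyr::bind_rows(css)
  n <- nrow(pool)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (pool$type[i] != pool$type[j]) next
      same <- if (pool$type[i] == "DEL") {
        pool$start[i] < pool$end[j] && pool$start[j] < pool$end[i]
      } else {
        abs(pool$start[i] - pool$start[j]) <= 20
      }
      if (same && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(nrow(m_fwd), length(unique(comp)))
})

test_that("Alu classification needs the size window and 80% identity on either strand", {
  consensus <- alu_consensus()
  expect_equal(nchar(consensus), 311L)

  mutate_seq <- function(s, rate, seed) {
    set.seed(seed)
    v <- strsplit(s, "")[[1]]
    idx <- which(runif(length(v)) < rate)
    v[idx] <- vapply(v[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "x")
    paste(v, collapse = "")
  }
  near <- mutate_seq(consensus, 0.10, 1)
  expect_true(classify_alu(near))
  # reverse complement of a matching sequence still classifies
  expect_true(classify_alu(diploidlr:::revcomp(near)))

  far <- mutate_seq(consensus, 0.45, 2)
  expect_false(classify_alu(far))
  expect_false(classify_alu(random_seq(300, seed = 3)))
  expect_false(classify_alu(random_seq(400, seed = 4)))  # outside 250-350
  expect_false(classify_alu(substring(consensus, 1, 200)))  # too short
  expect_error(classify_alu(NA_character_), "sequence")
})

test_that("repeat classification: Alu wins, tandem repeats detected, random is Other", {
  alu_sv <- tibble::tibble(chrom = "chr1", start = 0L, end = 311L,
                           size = 311L, sequence = alu_consensus())
  annot <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(classify_repeat(alu_sv, repeat_annotation = annot), "Alu")

  cag <- tibble::tibble(chrom = "chr1", start = 0L, end = 0L, size = 90L,
                        sequence = strrep("CAG", 30))
  expect_equal(classify_repeat(cag), "Repeat")

  rnd <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5000L,
                        size = 200L, sequence = random_seq(200, seed = 6))
  expect_equal(classify_repeat(rnd), "Other")
  # with an annotation overlapping it, annotation wins over the detector
  expect_equal(classify_repeat(rnd, repeat_annotation = annot), "Other")
  expect_equal(classify_repeat(
    rnd, repeat_annotation = tibble::tibble(chrom = "chr1", start = 4900L,
                                            end = 5100L)), "Repeat")
})

test_that("ancestral inference reproduces the four-label table", {
  fl <- function(gap, same = TRUE) tibble::tibble(gap = gap, same_chrom = same)
  del300 <- tibble::tibble(type = "DEL", size = 300L)
  ins300 <- tibble::tibble(type = "INS", size = 300L)
  cases <- list(
    list(del300, fl(1),   "Ins_Ref", "actual_insertion"),
    list(del300, fl(310), "Del_Tar", "actual_deletion"),
    list(ins300, fl(2),   "Ins_Tar", "actual_insertion"),
    list(ins300, fl(295), "Del_Ref", "actual_deletion"),
    list(del300, fl(150), "unresolved", "unresolved"),
    list(del300, fl(270, same = FALSE), "unresolved", "unresolved"))
  for (cs in cases) {
    got <- infer_ancestral(cs[[1]], cs[[2]])
    expect_equal(got$label, cs[[3]])
    expect_equal(got$actual_type, cs[[4]])
  }
  # the 0.9-1.1 size window is inclusive at both endpoints
  expect_equal(infer_ancestral(del300, fl(270))$label, "Del_Tar")
  expect_equal(infer_ancestral(del300, fl(330))$label, "Del_Tar")
  expect_equal(infer_ancestral(del300, fl(331))$label, "unresolved")

  # outgroup disagreement is unresolved
  a <- infer_ancestral(del300, fl(1))
  b <- infer_ancestral(del300, fl(310))
  expect_equal(combine_ancestral(a, b)$label, "unresolved")
  expect_equal(combine_ancestral(a, infer_ancestral(del300, fl(150)))$label,
               "Ins_Ref")
})

test_that("segregation pattern counts are 18 raw, 16 observable, 12 differing in 6 pairs", {
  pat <- enumerate_segregation_patterns()
  expect_equal(nrow(pat), 18)
  expect_equal(sum(pat$observable), 16)
  expect_equal(sum(pat$differing), 12)
  expect_equal(dplyr::n_distinct(pat$pair_class[pat$differing]), 6)
  obs <- pat[pat$observable, ]
  expect_true(all(obs$derived_total >= 1 & obs$derived_total <= 4))
  expect_equal(pat$derived_total,
               pat$genotype_A + pat$genotype_B +
                 as.integer(pat$ref_state == "derived"))
})

test_that("locus classification covers all 16 observable patterns exactly once", {
  seen <- character(0)
  for (label in c("Ins_Tar", "Ins_Ref")) {
    ann <- tibble::tibble(label = label,
                          actual_type = "actual_insertion")
    for (a in 0:2) for (b in 0:2) {
      res <- tryCatch(classify_locus(a, b, ann), error = function(e) NULL)
      if (is.null(res)) next  # the invariant all-identical configuration
      seen <- c(seen, paste(res$genotype_A, res$genotype_B, res$ref_state))
    }
  }
  expect_equal(length(seen), 16)
  expect_false(any(duplicated(seen)))

  # the worked example: A het, B ancestral-hom, reference derived
  ex <- classify_locus(1L, 2L, tibble::tibble(label = "Ins_Ref",
                                              actual_type = "actual_insertion"))
  expect_equal(ex$genotype_A, 1L)   # one derived allele in A
  expect_equal(ex$genotype_B, 0L)   # B carries no derived allele
  expect_equal(ex$ref_state, "derived")
  expect_equal(ex$derived_total, 2L)
  expect_match(ex$class12, "actual_insertion:")

  expect_error(classify_locus(1L, 1L,
                              tibble::tibble(label = "unresolved",
                                             actual_type = "unresolved")),
               "unresolved")
})

test_that("low-frequency derived alleles make singleton loci the most common class", {
  set.seed(77)
  n <- 300
  freq <- 0.15
  counts <- table(replicate(n, {
    chroms <- rbinom(5, 1, freq)  # 4 individual chromosomes + reference
    dt <- sum(chroms)
    if (dt %in% c(0, 5)) NA else min(dt, 4)
  }))
  expect_gt(counts[["1"]], sum(counts[names(counts) %in% c("2", "3", "4")]))
})
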