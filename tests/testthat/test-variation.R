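# Contig alignment, candidate extraction, zygosity inference, SNP-set
# merging, phasing of final variants and VCF round-trips.

test_that("the built-in aligner recovers a single planted substitution", {
  ref <- random_seq(3000, seed = 41)
  contig <- ref
  substr(contig, 1500, 1500) <- if (substring(ref, 1500, 1500) == "G") "T" else "G"
  aln <- align_contig(contig, ref, 0L, 3000L)
  ops <- aln$ops[[1]]
  x <- ops[ops$op == "X", ]
  expect_equal(nrow(x), 1)
  expect_equal(x$ref_pos, 1499L)  # 0-based
  expect_equal(x$alt_bases, substring(contig, 1500, 1500))
})

test_that("the built-in aligner recovers planted indels with exact breakpoints", {
  ref <- random_seq(4000, seed = 42)
  ins_seq <- random_seq(120)
  contig <- paste0(substring(ref, 1, 1200), ins_seq,
                   substring(ref, 1201, 2500), substring(ref, 2581, 4000))
  aln <- align_contig(contig, ref, 0L, 4000L)
  ops <- aln$ops[[1]]
  expect_equal(ops$len[ops$op == "I"], 120L)
  expect_equal(ops$ref_pos[ops$op == "I"], 1200L)
  expect_equal(ops$len[ops$op == "D"], 80L)
  # breakpoint micro-homology may shift the raw op; after left-alignment
  # the call is identical to the left-aligned planted deletion
  d <- ops[ops$op == "D", ]
  norm <- diploidlr:::normalize_indel(ref, d$ref_pos - 1L, d$ref_bases, "")
  planted <- diploidlr:::normalize_indel(ref, 2499L,
                                         substring(ref, 2501, 2580), "")
  expect_identical(norm, planted)
})

test_that("candidate extraction enforces the contig-length and MAPQ filters", {
  ref <- random_seq(2000, seed = 43)
  ops <- tibble::tibble(op = "X", ref_pos = 100L, query_pos = 100L,
                        len = 1L, ref_bases = "A", alt_bases = "G")
  alns <- tibble::tibble(
    contig_id = c("a", "b", "c"), contig_len = c(900L, 5000L, 5000L),
    haplotype = 1L, block_id = 1L, ref_start = 0L, ref_end = 1500L,
    query_start = 0L, query_end = 1500L, mapq = c(60L, 19L, 60L),
    ops = list(ops, ops, ops))
  out <- extract_variants(alns, ref)
  expect_equal(out$contig_id, "c")  # 900 bp contig and MAPQ 19 dropped
  expect_equal(out$pos, 101L)
  expect_equal(out$type, "SNP")
})

test_that("indel candidates are VCF-anchored and left-aligned", {
  # ref ...ACACAC...: a 2 bp deletion inside the repeat must shift left
  ref <- paste0(random_seq(50, seed = 44), "TACACACACG", random_seq(50))
  # deletion of "CA" at offset 56-57 (1-based in repeat) is equivalent to
  # deleting "AC" right after the anchor T at position 51
  norm <- diploidlr:::normalize_indel(ref, 55L, "CA", "")
  expect_equal(norm$pos, 50L)
  expect_equal(substring(norm$ref, 1, 1), "T")
  expect_equal(nchar(norm$ref), 3L)
})

test_that("SNP zygosity follows the two-haplotype rules", {
  cov <- tibble::tibble(haplotype = c(1L, 2L), start = 0L, end = 10000L)
  base <- tibble::tibble(block_id = 1L, contig_id = "x", chrom = "chr1",
                         type = "SNP", size = 1L)
  both <- dplyr::bind_rows(
    dplyr::mutate(base, haplotype = 1L, pos = 100L, ref = "A", alt = "G"),
    dplyr::mutate(base, haplotype = 2L, pos = 100L, ref = "A", alt = "G"))
  expect_equal(infer_snp_zygosity(both, cov)$genotype, "hom")

  one <- dplyr::mutate(base, haplotype = 1L, pos = 100L, ref = "A", alt = "G")
  het <- infer_snp_zygosity(one, cov)
  expect_equal(het$genotype, "het")
  expect_equal(het$carrier_hp, 1L)
  expect_false(het$low_conf)

  cov1 <- cov[cov$haplotype == 1L, ]
  het2 <- infer_snp_zygosity(one, cov1)
  expect_true(het2$low_conf)  # other haplotype does not cover the site

  multi <- dplyr::bind_rows(
    dplyr::mutate(base, haplotype = 1L, pos = 100L, ref = "A", alt = "G"),
    dplyr::mutate(base, haplotype = 2L, pos = 100L, ref = "A", alt = "T"))
  m <- infer_snp_zygosity(multi, cov)
  expect_equal(nrow(m), 2)
  expect_true(all(m$genotype == "het"))
  expect_true(all(m$multiallelic))
})

test_that("indel/SV zygosity matches deletions by overlap and insertions within 20 bp", {
  cov <- tibble::tibble(haplotype = c(1L, 2L), start = 0L, end = 100000L)
  mk <- function(hp, pos, type, size, ref = "N", alt = "N") {
    tibble::tibble(haplotype = hp, block_id = 1L, contig_id = "x",
                   chrom = "chr1", pos = pos, ref = ref, alt = alt,
                   type = type, size = size)
  }
  dels <- dplyr::bind_rows(mk(1L, 100L, "DEL", 200L),
                           mk(2L, 250L, "DEL", 250L))
  d <- infer_indel_sv_zygosity(dels, cov)
  expect_true(all(d$genotype == "het") || any(d$genotype == "hom"))
  # intervals [100,300) and [250,500) overlap -> same deletion; alleles
  # differ -> compound, split into two het records
  expect_equal(nrow(d), 2)
  expect_setequal(d$carrier_hp, c(1L, 2L))

  same_del <- dplyr::bind_rows(mk(1L, 100L, "DEL", 200L, "NNN", "N"),
                               mk(2L, 100L, "DEL", 200L, "NNN", "N"))
  expect_equal(infer_indel_sv_zygosity(same_del, cov)$genotype, "hom")

  ins15 <- dplyr::bind_rows(mk(1L, 1000L, "INS", 300L, "N", "NNN"),
                            mk(2L, 1015L, "INS", 300L, "N", "NNN"))
  i15 <- infer_indel_sv_zygosity(ins15, cov)
  expect_equal(nrow(i15), 2)  # matched but alleles differ -> compound split
  ins15b <- dplyr::bind_rows(mk(1L, 1000L, "INS", 300L, "N", "NNN"),
                             mk(2L, 1000L, "INS", 300L, "N", "NNN"))
  expect_equal(infer_indel_sv_zygosity(ins15b, cov)$genotype, "hom")

  ins25 <- dplyr::bind_rows(mk(1L, 1000L, "INS", 300L, "N", "NNN"),
                            mk(2L, 1025L, "INS", 300L, "N", "NNN"))
  i25 <- infer_indel_sv_zygosity(ins25, cov)
  expect_equal(nrow(i25), 2)
  expect_true(all(i25$genotype == "het"))
})

test_that("SNP merging takes the union, records sources and prefers read-based genotypes", {
  asm <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                        ref = c("A", "C"), alt = c("G", "T"),
                        type = "SNP", size = 1L,
                        genotype = c("het", "hom"),
                        carrier_hp = c(1L, NA), block_id = 1L,
                        low_conf = FALSE, multiallelic = FALSE)
  rb <- tibble::tibble(chrom = "chr1", pos = c(200L, 300L),
                       ref = c("C", "G"), alt = c("T", "A"),
                       gt = c("0/1", "1/1"))
  m <- merge_snp_calls(asm, rb)
  expect_equal(nrow(m), 3)
  expect_equal(m$source[m$pos == 100], "assembly")
  expect_equal(m$source[m$pos == 200], "both")
  expect_equal(m$source[m$pos == 300], "read_based")
  # conflict at 200: assembly hom vs read het -> read-based wins
  expect_equal(m$genotype[m$pos == 200], "het")
  expect_true(m$gt_conflict[m$pos == 200])

  bad <- rb; bad$ref[1] <- "T"
  expect_error(merge_snp_calls(asm, bad), "mismatch")
})

test_that("final variants are phased by majority vote with a tie rule", {
  scafvars <- tibble::tibble(
    cluster_id = 1L, variant_id = sprintf("s%d", 1:10), chrom = "chr1",
    pos = (1:10) * 100L, allele_A = rep(c(1L, 0L), 5), n_for = 5L)
  pb <- diploidlr:::blocks_from_parts(
    scafvars, tibble::tibble(cluster_id = integer(),
                             molecule_id = character(), side = integer()),
    "cluster_id")
  scaffold <- tibble::tibble(variant_id = sprintf("s%d", 1:10),
                             ref = "A", alt = "G")
  # assembly SNPs at the scaffold sites, all carried by contig hp2, plus one SV
  fv <- tibble::tibble(
    chrom = "chr1", pos = c((1:10) * 100L, 5000L),
    ref = "A", alt = c(rep("G", 10), "AGGG"),
    type = c(rep("SNP", 10), "INS"), size = c(rep(1L, 10), 3L),
    genotype = "het",
    carrier_hp = c(ifelse(rep(c(1L, 0L), 5) == 1L, 2L, 1L), 2L),
    block_id = 100L, low_conf = FALSE, multiallelic = FALSE)
  out <- phase_variants(fv, pb, scaffold)
  # scaffold sites inherit the scaffold phase directly
  expect_equal(out$gt[1], "1|0")
  expect_equal(out$ps[1], 100L)
  # the SV is phased by the (unanimous) orientation vote: contig hp2 is
  # scaffold hap1, so the hp2-carried insertion goes to haplotype 1
  expect_equal(out$gt[11], "1|0")
  expect_equal(out$ps[11], 100L)

  # a tied vote leaves non-scaffold variants unphased
  fv_tie <- fv
  # all sites carried by hp1: alternating scaffold sides make the vote 5 vs 5
  fv_tie$carrier_hp <- c(rep(1L, 10), 2L)
  out_tie <- phase_variants(fv_tie, pb, scaffold)
  expect_equal(out_tie$gt[11], "0/1")
  expect_true(is.na(out_tie$ps[11]))
})

test_that("hom variants carry 1/1 without phase order", {
  pb <- diploidlr:::blocks_from_parts(
    tibble::tibble(cluster_id = integer(), variant_id = character(),
                   chrom = character(), pos = integer(),
                   allele_A = integer(), n_for = integer()),
    tibble::tibble(cluster_id = integer(), molecule_id = character(),
                   side = integer()), "cluster_id")
  fv <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                       type = "SNP", size = 1L, genotype = "hom",
                       carrier_hp = NA_integer_, block_id = NA_integer_,
                       low_conf = FALSE, multiallelic = FALSE)
  out <- phase_variants(fv, pb, tibble::tibble(variant_id = character(),
                                               ref = character(),
                                               alt = character()))
  expect_equal(out$gt, "1/1")
  expect_true(is.na(out$ps))
})

test_that("the final VCF round-trips through the package reader and vcfR", {
  fv <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 250L, 400L),
    ref = c("A", "C", "GTT"), alt = c("G", "CAA", "G"),
    type = c("SNP", "INS", "DEL"), size = c(1L, 2L, 2L),
    genotype = c("het", "het", "hom"),
    gt = c("1|0", "0/1", "1/1"), ps = c(100L, NA, NA),
    source = c("both", "assembly", "assembly"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "out.vcf")
  write_final_vcf(fv, path, ref_lengths = c(chr1 = 1000L))
  back <- read_vcf(path)
  expect_equal(back$pos, fv$pos)
  expect_equal(back$ref, fv$ref)
  expect_equal(back$alt, fv$alt)
  expect_equal(back$gt, fv$gt)
  expect_equal(back$ps, fv$ps)

  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), 3)
  expect_equal(as.integer(v@fix[, "POS"]), fv$pos)
  gt <- vcfR::extract.gt(v, element = "GT")
  expect_equal(unname(gt[, 1]), fv$gt)

  expect_error(write_vcf(tibble::tibble(chrom = "chr1", pos = c(5L, 2L),
                                        id = ".", ref = "A", alt = "G",
                                        qual = 60, gt = "0/1"),
                         file.path(dir, "bad.vcf")), "sorted")
})

test_that("malformed cs strings and PAF records are rejected with position info", {
  expect_error(diploidlr:::parse_cs_string("xx", 0L, 0L), "malformed")
  good <- paste0("ctg\t100\t0\t100\t+\tchr1\t1000\t0\t100\t100\t100\t60\t",
                 "cs:Z::50*ac:20+gg:28")
  alns <- read_paf_cs(good)
  ops <- alns$ops[[1]]
  expect_equal(ops$op, c("M", "X", "M", "I", "M"))
  expect_equal(ops$ref_pos[2], 50L)
  expect_equal(ops$alt_bases[4], "GG")
  expect_error(read_paf_cs("a\tb\tc"), "malformed PAF")
  expect_error(read_paf_cs(sub("cs:Z:", "xx:Z:", good)), "cs:Z")
})

test_that("minimap2 PAF output parses into the same op table shape", {
  skip_if(Sys.which("minimap2") == "", "minimap2 not on PATH")
  ref <- random_seq(20000, seed = 77)
  contig <- paste0(substring(ref, 1, 9000), substring(ref, 9051, 20000))
  names(contig) <- "5_PS0:20000_hp1"
  alns <- align_contigs_external(c("5_PS0:20000_hp1" = unname(contig)), ref)
  expect_equal(nrow(alns), 1)
  dels <- alns$ops[[1]][alns$ops[[1]]$op == "D", ]
  expect_equal(dels$len, 50L)
  # the external aligner may shift the event by a repeated base
  expect_lte(abs(dels$ref_pos - 9000L), 5L)
})
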