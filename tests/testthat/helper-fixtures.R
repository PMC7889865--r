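# Shared fixtures, memoised so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small diploid simulation: 200 kb, one molecule per barcode (the genome is
# too short to hold barcode pairs 200 kb apart), error-free by default.
small_cfg <- function(error = 0, seed = 42, ...) {
  sim_config(genome_length = 2e5, molecule_mean_length = 2e4,
             n_barcodes = 500, molecules_per_barcode = 1,
             base_error_rate = error, seed = seed,
             sv_spec = tibble::tibble(type = c("DEL", "INS"),
                                      size = c(120L, 90L),
                                      zygosity = c("het", "het")),
             ...)
}

small_sim <- function(error = 0, seed = 42) {
  memo(sprintf("sim_%g_%d", error, seed), {
    cfg <- small_cfg(error, seed)
    truth <- simulate_truth(cfg)
    sim <- simulate_reads(truth, cfg)
    list(cfg = cfg, truth = truth, sim = sim)
  })
}

# Molecules + molecule-level calls for the small simulation.
small_phase_input <- function(error = 0, seed = 42) {
  memo(sprintf("phasein_%g_%d", error, seed), {
    fx <- small_sim(error, seed)
    al <- dplyr::arrange(fx$sim$alignments, barcode, chrom, start)
    molecules <- reconstruct_fragments(al)
    hets <- het_variant_table(fx$sim$allele_calls, fx$sim$truth_vcf)
    c(fx, list(alignments = al, molecules = molecules, hets = hets))
  })
}

small_phaseset <- function(error = 0, seed = 42) {
  memo(sprintf("phaseset_%g_%d", error, seed), {
    fx <- small_phase_input(error, seed)
    c(fx, list(phaseset = phase_haplotypes(fx$molecules,
                                           fx$sim$allele_calls, fx$hets)))
  })
}

truth_phase_of <- function(truth) {
  v <- truth$variants
  v <- v[v$zygosity == "het" & v$type == "SNP", ]
  tibble::tibble(variant_id = v$variant_id, hap = v$hap)
}

# The acceptance-scale run: 1 Mb, error-free, default library design,
# full pipeline with the built-in assembler.
acceptance_run <- function(seed = 101) {
  memo(sprintf("e2e_%d", seed), {
    cfg <- sim_config(base_error_rate = 0, seed = seed)
    truth <- simulate_truth(cfg)
    sim <- simulate_reads(truth, cfg)
    s1 <- run_step1(sim$alignments, sim$allele_calls, sim$truth_vcf,
                    truth$ref_seq)
    s2 <- run_step2(s1, truth$ref_seq)
    vc <- run_varcall_and_phase(s2, s1, truth$ref_seq, sim$truth_vcf)
    list(cfg = cfg, truth = truth, sim = sim, s1 = s1, s2 = s2, vc = vc)
  })
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Error-free reads tiling seq at roughly `depth` coverage. The boundary
# reads appear twice so terminal k-mers clear the assembler's minimum
# count.
tiling_reads <- function(seq, read_len = 100, depth = 30, seed = 1) {
  set.seed(seed)
  n <- ceiling(depth * nchar(seq) / read_len)
  starts <- c(rep(c(1L, nchar(seq) - read_len + 1L), 2),
              sample.int(nchar(seq) - read_len + 1L, n, replace = TRUE))
  substring(seq, starts, starts + read_len - 1L)
}
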