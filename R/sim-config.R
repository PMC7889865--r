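#' Configuration for the synthetic linked-read simulator
#'
#' Defines a diploid genome simulation: planted variation (het/hom SNPs,
#' small indels, structural variants), long-molecule sampling, and barcoded
#' short-read generation. Defaults emulate a desk-scale version of a typical
#' linked-read library: long fragments with an exponential length
#' distribution (mean 50 kb), high physical coverage (`C_F` around 200x),
#' sparse within-molecule read coverage (`C_R` = 0.3x), so raw read coverage
#' `C = C_F * C_R` is about 60x.
#'
#' @param genome_length Reference length in bp. Must be at least
#'   `10 * molecule_mean_length`.
#' @param het_snp_rate,hom_snp_rate Per-bp rates of heterozygous and
#'   homozygous SNPs.
#' @param indel_rate Per-bp rate of small indels (half insertions, half
#'   deletions); sizes drawn from `indel_size_weights`.
#' @param indel_size_weights Unnormalised weights over indel sizes
#'   `1..length(indel_size_weights)`. The default decays geometrically with a
#'   mild 2-bp periodicity (even sizes upweighted), matching the size spectra
#'   seen in real human indel callsets.
#' @param sv_spec Tibble of requested structural variants with columns
#'   `type` (`"INS"`/`"DEL"`), `size` (bp, >= 50) and `zygosity`
#'   (`"het"`/`"hom"`), and optionally `pos` (0-based placement). `NULL`
#'   plants a small default set spanning the Alu-typical size range.
#' @param molecule_mean_length Mean of the exponential molecule-length
#'   distribution (bp), truncated to `[1 kb, 5 * mean]`.
#' @param n_barcodes,molecules_per_barcode Number of barcodes and molecules
#'   per barcode; together with `molecule_mean_length` these set the physical
#'   coverage `C_F`.
#' @param barcode_min_spacing Minimum distance (bp) between molecules sharing
#'   a barcode. The default 200 kb keeps the 50 kb molecule split rule
#'   unambiguous; lower it to stress-test molecule reconstruction.
#' @param read_length Read length in bp (paired reads of this length).
#' @param read_pairs_per_kb_of_molecule Read-pair density along each
#'   molecule; sets `C_R = 2 * read_length * density / 1000`.
#' @param insert_size_mean,insert_size_sd Insert size distribution of read
#'   pairs.
#' @param base_error_rate Per-base substitution error probability. Error
#'   bases are emitted with quality Q10, correct bases with Q30.
#' @param seed Integer seed; a fixed seed makes all simulator output
#'   byte-identical across runs.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 5e5, seed = 7)
#' cfg$het_snp_rate
#' @export
sim_config <- function(genome_length = 1e6,
                       het_snp_rate = 1e-3,
                       hom_snp_rate = 5e-4,
                       indel_rate = 1e-4,
                       indel_size_weights = default_indel_size_weights(),
                       sv_spec = default_sv_spec(),
                       molecule_mean_length = 5e4,
                       n_barcodes = 2000,
                       molecules_per_barcode = 2,
                       barcode_min_spacing = 2e5,
                       read_length = 100,
                       read_pairs_per_kb_of_molecule = 1.5,
                       insert_size_mean = 350,
                       insert_size_sd = 35,
                       base_error_rate = 1e-3,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    het_snp_rate = het_snp_rate,
    hom_snp_rate = hom_snp_rate,
    indel_rate = indel_rate,
    indel_size_weights = indel_size_weights,
    sv_spec = sv_spec,
    molecule_mean_length = molecule_mean_length,
    n_barcodes = as.integer(n_barcodes),
    molecules_per_barcode = as.integer(molecules_per_barcode),
    barcode_min_spacing = barcode_min_spacing,
    read_length = as.integer(read_length),
    read_pairs_per_kb_of_molecule = read_pairs_per_kb_of_molecule,
    insert_size_mean = insert_size_mean,
    insert_size_sd = insert_size_sd,
    base_error_rate = base_error_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_indel_size_weights <- function(max_size = 10, decay = 0.65,
                                       even_boost = 1.5) {
  sizes <- seq_len(max_size)
  w <- decay^(sizes - 1)
  w[sizes %% 2 == 0] <- w[sizes %% 2 == 0] * even_boost
  w
}

default_sv_spec <- function() {
  tibble::tibble(
    type = c("DEL", "INS", "DEL", "INS", "DEL", "INS"),
    size = c(330L, 330L, 80L, 60L, 150L, 500L),
    zygosity = c("het", "het", "hom", "het", "het", "hom")
  )
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$het_snp_rate, cfg$hom_snp_rate, cfg$indel_rate,
             cfg$base_error_rate)
  if (any(rates < 0 | rates >= 1)) {
    abort("all rates must lie in [0, 1)")
  }
  if (cfg$genome_length < 10 * cfg$molecule_mean_length) {
    abort("genome_length must be >= 10 * molecule_mean_length")
  }
  if (!is.null(cfg$sv_spec)) {
    stopifnot(all(cfg$sv_spec$type %in% c("INS", "DEL")),
              all(cfg$sv_spec$size >= 50),
              all(cfg$sv_spec$zygosity %in% c("het", "hom")))
  }
  if (cfg$read_length < 20) abort("read_length must be >= 20")
  if (cfg$molecules_per_barcode > 1 && cfg$barcode_min_spacing >= 5e4 &&
      cfg$genome_length / cfg$molecules_per_barcode <
        cfg$barcode_min_spacing + 5 * cfg$molecule_mean_length) {
    abort(paste0(
      "genome too short to keep molecules sharing a barcode ",
      "barcode_min_spacing apart; lower molecules_per_barcode to 1 or ",
      "reduce barcode_min_spacing below 50 kb (stress mode)"))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cf <- x$n_barcodes * x$molecules_per_barcode * x$molecule_mean_length /
    x$genome_length
  cr <- 2 * x$read_length * x$read_pairs_per_kb_of_molecule / 1000
  cat("<sim_config>\n",
      sprintf("  genome %d bp | het SNP %.2g/bp | error %.2g\n",
              x$genome_length, x$het_snp_rate, x$base_error_rate),
      sprintf("  molecules: mean %.0f bp, %d barcodes x %d | C_F ~ %.0fx, C_R ~ %.2fx, C ~ %.0fx\n",
              x$molecule_mean_length, x$n_barcodes, x$molecules_per_barcode,
              cf, cr, cf * cr),
      sep = "")
  invisible(x)
}
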