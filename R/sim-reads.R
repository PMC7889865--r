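# Barcoded read-pair simulation from truth molecules, with truth-placed
# alignments and per-read het-SNP allele calls.

#' Simulate barcoded linked reads from a diploid truth
#'
#' Draws read pairs along each truth molecule at the configured density,
#' extracts their sequences from the molecule's haplome (with substitution
#' errors at `base_error_rate`), and emits truth-placed alignment records:
#' the mapping step is bypassed, every read is placed at its known reference
#' position with MAPQ 60 and its molecule's barcode. Per-read allele calls
#' at heterozygous SNP sites are derived directly from the read sequence
#' (quality Q30, or Q10 where the base is an error).
#'
#' @param truth A [simulate_truth()] result.
#' @param cfg The same [sim_config()] used for the truth.
#' @return An object of class `linked_reads`: list with `alignments`
#'   (tibble: `read_id`, `barcode`, `chrom`, 0-based half-open `start`/`end`,
#'   `mapq`, `seq`, plus truth columns `molecule_id`, `hap`, `hstart`,
#'   `hend`), `allele_calls` (tibble: `read_id`, `variant_id`, `allele`,
#'   `qual`), `errors` (tibble of planted error offsets), `truth_vcf`
#'   (tibble form of the truth callset) and `cfg`.
#' @examples
#' cfg <- sim_config(genome_length = 5e5, n_barcodes = 400, seed = 11)
#' truth <- simulate_truth(cfg)
#' sim <- simulate_reads(truth, cfg)
#' nrow(sim$alignments)
#' @export
simulate_reads <- function(truth, cfg) {
  stopifnot(inherits(truth, "diploid_truth"))
  set.seed(cfg$seed + 1L)
  rl <- cfg$read_length
  mol <- truth$molecules

  n_pairs <- rpois(nrow(mol), cfg$read_pairs_per_kb_of_molecule *
                     mol$length / 1000)
  pair_mol <- rep(seq_len(nrow(mol)), n_pairs)
  n_pair <- length(pair_mol)
  ins <- as.integer(round(rnorm(n_pair, cfg$insert_size_mean,
                                cfg$insert_size_sd)))
  ins <- pmax(2L * rl, pmin(ins, mol$length[pair_mol]))
  ps <- mol$hstart[pair_mol] +
    as.integer(floor(runif(n_pair) * (mol$length[pair_mol] - ins + 1L)))

  reads <- tibble(
    pair_id = rep(seq_len(n_pair), each = 2L),
    mate = rep(1:2, n_pair),
    mol_row = rep(pair_mol, each = 2L)
  )
  reads$hstart <- ifelse(reads$mate == 1L, ps[reads$pair_id],
                         ps[reads$pair_id] + ins[reads$pair_id] - rl)
  reads$hstart <- as.integer(reads$hstart)
  reads$hend <- reads$hstart + rl
  reads$hap <- mol$hap[reads$mol_row]
  reads$read_id <- sprintf("rd%08d/%d", reads$pair_id, reads$mate)

  # sequences from the haplome of origin
  seqs <- character(nrow(reads))
  for (h in 1:2) {
    idx <- reads$hap == h
    seqs[idx] <- substring(truth$hap_seq[h], reads$hstart[idx] + 1L,
                           reads$hend[idx])
  }

  # substitution errors
  errors <- tibble(read_row = integer(0), offset = integer(0))
  if (cfg$base_error_rate > 0 && nrow(reads) > 0) {
    n_err <- rbinom(nrow(reads), rl, cfg$base_error_rate)
    with_err <- which(n_err > 0)
    if (length(with_err) > 0) {
      offs <- lapply(n_err[with_err], function(k) sample.int(rl, k))
      errors <- tibble(read_row = rep(with_err, lengths(offs)),
                       offset = unlist(offs))
      for (j in seq_along(with_err)) {
        i <- with_err[j]
        s <- strsplit(seqs[i], "")[[1]]
        for (o in offs[[j]]) {
          s[o] <- sample(setdiff(DNA_BASES, s[o]), 1)
        }
        seqs[i] <- paste(s, collapse = "")
      }
    }
  }
  reads$seq <- seqs

  # reference placement (anchored through the coordinate map)
  rstart <- integer(nrow(reads))
  for (h in 1:2) {
    idx <- reads$hap == h
    rstart[idx] <- map_hap_to_ref_anchor(truth$maps[[h]], reads$hstart[idx])
  }
  reads$start <- rstart
  reads$end <- rstart + rl

  alignments <- tibble(
    read_id = reads$read_id,
    barcode = mol$barcode[reads$mol_row],
    chrom = mol$chrom[reads$mol_row],
    start = reads$start,
    end = reads$end,
    mapq = 60L,
    seq = reads$seq,
    molecule_id = mol$molecule_id[reads$mol_row],
    hap = reads$hap,
    hstart = reads$hstart,
    hend = reads$hend
  )

  allele_calls <- call_het_sites(truth, reads)
  errors$read_id <- alignments$read_id[errors$read_row]

  structure(
    list(alignments = alignments,
         allele_calls = allele_calls,
         errors = errors[c("read_id", "offset")],
         truth_vcf = truth_vcf_table(truth),
         cfg = cfg),
    class = "linked_reads"
  )
}

# Per-read allele calls at het SNP sites, from the simulated sequences.
call_het_sites <- function(truth, reads) {
  v <- truth$variants
  het <- v[v$type == "SNP" & v$zygosity == "het", , drop = FALSE]
  out <- list()
  for (h in 1:2) {
    if (nrow(het) == 0) break
    hpos <- map_ref_to_hap(truth$maps[[h]], het$pos)
    ridx <- which(reads$hap == h)
    if (length(ridx) == 0) next
    ord <- ridx[order(reads$hstart[ridx])]
    starts <- reads$hstart[ord]
    rl <- reads$hend[ord][1] - starts[1]
    hi <- findInterval(hpos, starts)
    lo <- findInterval(hpos - rl, starts) + 1L
    n_cov <- pmax(hi - lo + 1L, 0L)
    site_rep <- rep(seq_len(nrow(het)), n_cov)
    read_sel <- unlist(lapply(seq_len(nrow(het)), function(i) {
      if (n_cov[i] <= 0) integer(0) else seq(lo[i], hi[i])
    }))
    if (length(site_rep) == 0) next
    rrows <- ord[read_sel]
    offset <- hpos[site_rep] - reads$hstart[rrows] + 1L
    obs <- substring(reads$seq[rrows], offset, offset)
    true_base <- ifelse(het$hap[site_rep] == h, het$alt[site_rep],
                        het$ref[site_rep])
    allele <- dplyr::case_when(
      obs == het$ref[site_rep] ~ 0L,
      obs == het$alt[site_rep] ~ 1L,
      TRUE ~ NA_integer_
    )
    qual <- ifelse(obs == true_base, 30L, 10L)
    out[[h]] <- tibble(
      read_id = reads$read_id[rrows],
      variant_id = het$variant_id[site_rep],
      allele = allele,
      qual = qual
    )
  }
  calls <- bind_rows(out)
  calls[!is.na(calls$allele), , drop = FALSE]
}

# Truth callset as a VCF-shaped tibble (1-based positions, phased GT).
truth_vcf_table <- function(truth) {
  v <- truth$variants
  gt <- dplyr::case_when(
    v$zygosity == "hom" ~ "1|1",
    v$hap == 1L ~ "1|0",
    TRUE ~ "0|1"
  )
  tibble(
    chrom = v$chrom,
    pos = v$pos + 1L,
    id = v$variant_id,
    ref = v$ref,
    alt = v$alt,
    qual = 60,
    gt = gt,
    ps = ifelse(v$zygosity == "het", 1L, NA_integer_),
    type = v$type,
    size = v$size,
    zygosity = v$zygosity
  )
}

#' @export
print.linked_reads <- function(x, ...) {
  cat("<linked_reads>\n",
      sprintf("  %d reads, %d barcodes, %d het-site allele calls\n",
              nrow(x$alignments), dplyr::n_distinct(x$alignments$barcode),
              nrow(x$allele_calls)),
      sep = "")
  invisible(x)
}
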