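# Diploid truth generation: planted variants, haplome construction,
# ref<->haplotype coordinate maps, molecule sampling.

#' Simulate a diploid truth genome
#'
#' Generates a random reference sequence, plants heterozygous/homozygous
#' SNPs, small indels and the requested structural variants (rejecting
#' overlapping requests), assigns each het variant to one haplotype, builds
#' both haplome sequences, and samples barcoded long molecules from the two
#' haplotypes.
#'
#' Variant footprints never overlap (on either haplotype), so applying the
#' per-haplotype variant lists to the reference reconstructs each haplome
#' exactly.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `diploid_truth`: a list with `ref_seq`,
#'   `hap_seq` (length-2 character), `variants` (tibble; 0-based anchored
#'   `pos`, `ref`, `alt`, `type`, `size`, `zygosity`, `hap` where 0 = both
#'   haplotypes), `molecules` (truth molecule table with haplotype of origin
#'   and both haplotype- and reference-coordinate spans), and the two
#'   coordinate maps.
#' @examples
#' truth <- simulate_truth(sim_config(genome_length = 5e5, seed = 3))
#' dplyr::count(truth$variants, type, zygosity)
#' @export
simulate_truth <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  L <- cfg$genome_length
  ref <- random_dna(L)

  variants <- plant_variants(ref, cfg)
  hap1 <- apply_variants(ref, variants, hap = 1L)
  hap2 <- apply_variants(ref, variants, hap = 2L)

  molecules <- sample_molecules(cfg, hap1, hap2)

  structure(
    list(
      ref_seq = ref,
      hap_seq = c(hap1$seq, hap2$seq),
      variants = variants,
      maps = list(hap1$map, hap2$map),
      molecules = molecules,
      cfg = cfg
    ),
    class = "diploid_truth"
  )
}

# ---- variant planting --------------------------------------------------

plant_variants <- function(ref, cfg) {
  L <- nchar(ref)
  edge <- 2000L  # keep variants away from genome ends

  svs <- cfg$sv_spec
  if (is.null(svs)) {
    svs <- tibble(type = character(), size = integer(),
                  zygosity = character())
  }
  n_sv <- nrow(svs)

  # footprint length on the reference (anchored representation)
  sv_foot <- ifelse(svs$type == "DEL", svs$size + 1L, 1L)

  # place requested SVs first, evenly spread with jitter
  if (n_sv > 0) {
    if (!"pos" %in% names(svs)) {
      slots <- round(seq(edge, L - edge, length.out = n_sv + 2))[-c(1, n_sv + 2)]
      svs$pos <- as.integer(slots + sample(-500:500, n_sv, replace = TRUE))
    }
    sv_iv <- cbind(svs$pos, svs$pos + sv_foot - 1L)
    o <- order(sv_iv[, 1])
    if (n_sv > 1 && any(sv_iv[o, 1][-1] <= sv_iv[o, 2][-n_sv])) {
      bad <- which(sv_iv[o, 1][-1] <= sv_iv[o, 2][-n_sv])
      abort(sprintf(
        "requested SVs overlap on the reference (e.g. SV %d and %d); adjust sv_spec positions/sizes",
        o[bad[1]], o[bad[1] + 1]))
    }
  }

  n_het <- rpois(1, L * cfg$het_snp_rate)
  n_hom <- rpois(1, L * cfg$hom_snp_rate)
  n_ind <- rpois(1, L * cfg$indel_rate)

  snp_pos <- sample.int(L - 2L * edge, n_het + n_hom) + edge - 1L
  ind_pos <- sample.int(L - 2L * edge, n_ind) + edge - 1L
  ind_size <- if (n_ind > 0) {
    sample(seq_along(cfg$indel_size_weights), n_ind, replace = TRUE,
           prob = cfg$indel_size_weights)
  } else integer(0)
  ind_type <- sample(c("INS", "DEL"), n_ind, replace = TRUE)

  ref_base <- function(p) substring(ref, p + 1L, p + 1L)

  rand <- bind_rows(
    tibble(pos = snp_pos, type = "SNP", size = 1L,
           zygosity = rep(c("het", "hom"), c(n_het, n_hom))),
    if (n_ind > 0) tibble(pos = ind_pos, type = ind_type,
                          size = as.integer(ind_size),
                          zygosity = sample(c("het", "hom"), n_ind,
                                            replace = TRUE, prob = c(2, 1)))
  )
  rand$foot <- ifelse(rand$type == "DEL", rand$size + 1L, 1L)

  # drop random candidates touching a requested-SV footprint (+1 bp spacer)
  if (n_sv > 0) {
    sv_lo <- svs$pos - 1L
    sv_hi <- svs$pos + sv_foot
    hit <- map_lgl(seq_len(nrow(rand)), function(i) {
      any(rand$pos[i] <= sv_hi & rand$pos[i] + rand$foot[i] - 1L >= sv_lo)
    })
    rand <- rand[!hit, , drop = FALSE]
  }

  # greedy non-overlap filter among the random candidates
  rand <- rand[order(rand$pos), , drop = FALSE]
  keep <- logical(nrow(rand))
  last_end <- -2L
  for (i in seq_len(nrow(rand))) {
    if (rand$pos[i] > last_end + 1L) {
      keep[i] <- TRUE
      last_end <- rand$pos[i] + rand$foot[i] - 1L
    }
  }
  rand <- rand[keep, , drop = FALSE]

  cand <- bind_rows(
    if (n_sv > 0) tibble(pos = as.integer(svs$pos), type = svs$type,
                         size = as.integer(svs$size), zygosity = svs$zygosity,
                         foot = sv_foot),
    rand
  )
  cand <- cand[order(cand$pos), , drop = FALSE]

  # build ref/alt strings
  n <- nrow(cand)
  refs <- character(n); alts <- character(n)
  for (i in seq_len(n)) {
    p <- cand$pos[i]
    if (cand$type[i] == "SNP") {
      refs[i] <- ref_base(p)
      alts[i] <- sample(setdiff(DNA_BASES, refs[i]), 1)
    } else if (cand$type[i] == "INS") {
      refs[i] <- ref_base(p)
      alts[i] <- paste0(refs[i], random_dna(cand$size[i]))
    } else { # DEL
      refs[i] <- substring(ref, p + 1L, p + 1L + cand$size[i])
      alts[i] <- ref_base(p)
    }
  }

  hap <- ifelse(cand$zygosity == "hom", 0L,
                sample(1:2, n, replace = TRUE))

  tibble(
    variant_id = sprintf("var%06d", seq_len(n)),
    chrom = "chr1",
    pos = cand$pos,
    ref = refs,
    alt = alts,
    type = cand$type,
    size = cand$size,
    zygosity = cand$zygosity,
    hap = hap
  )
}

# ---- haplome construction and coordinate maps --------------------------

# Apply the variants carried by haplotype `hap` (hap 0 = both) to `ref`.
# Returns the haplotype sequence plus a coordinate map of identity segments
# (ref_start, hap_start, len; 0-based). SNPs substitute in place and do not
# break the map; indels do.
apply_variants <- function(ref, variants, hap) {
  v <- variants[variants$hap %in% c(0L, hap), , drop = FALSE]
  v <- v[order(v$pos), , drop = FALSE]
  L <- nchar(ref)

  indels <- v[v$type != "SNP", , drop = FALSE]
  pieces <- character(0)
  seg_ref <- integer(0); seg_hap <- integer(0); seg_len <- integer(0)
  ref_cursor <- 0L; hap_cursor <- 0L
  for (i in seq_len(nrow(indels))) {
    p <- indels$pos[i]
    # identity segment up to and including the anchor base
    len <- p + 1L - ref_cursor
    pieces <- c(pieces, substring(ref, ref_cursor + 1L, p + 1L))
    seg_ref <- c(seg_ref, ref_cursor); seg_hap <- c(seg_hap, hap_cursor)
    seg_len <- c(seg_len, len)
    hap_cursor <- hap_cursor + len
    if (indels$type[i] == "INS") {
      ins <- substring(indels$alt[i], 2L)
      pieces <- c(pieces, ins)
      hap_cursor <- hap_cursor + nchar(ins)
      ref_cursor <- p + 1L
    } else { # DEL: skip deleted bases
      ref_cursor <- p + 1L + indels$size[i]
    }
  }
  if (ref_cursor < L) {
    pieces <- c(pieces, substring(ref, ref_cursor + 1L, L))
    seg_ref <- c(seg_ref, ref_cursor); seg_hap <- c(seg_hap, hap_cursor)
    seg_len <- c(seg_len, L - ref_cursor)
  }
  seq <- paste(pieces, collapse = "")
  map <- tibble(ref_start = seg_ref, hap_start = seg_hap, len = seg_len)

  # substitute SNPs in place (byte-level for speed)
  snps <- v[v$type == "SNP", , drop = FALSE]
  if (nrow(snps) > 0) {
    hp <- map_ref_to_hap(map, snps$pos)
    raw <- charToRaw(seq)
    raw[hp + 1L] <- charToRaw(paste(snps$alt, collapse = ""))
    seq <- rawToChar(raw)
  }
  list(seq = seq, map = map)
}

# Map 0-based reference positions to haplotype positions (NA if deleted).
map_ref_to_hap <- function(map, pos) {
  i <- findInterval(pos, map$ref_start)
  ok <- i >= 1 & pos < map$ref_start[pmax(i, 1)] + map$len[pmax(i, 1)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- map$hap_start[i[ok]] + (pos[ok] - map$ref_start[i[ok]])
  out
}

# Map 0-based haplotype positions back to reference positions. Positions
# inside an insertion map to NA.
map_hap_to_ref <- function(map, pos) {
  i <- findInterval(pos, map$hap_start)
  ok <- i >= 1 & pos < map$hap_start[pmax(i, 1)] + map$len[pmax(i, 1)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- map$ref_start[i[ok]] + (pos[ok] - map$hap_start[i[ok]])
  out
}

# Nearest mapped reference position at or left of a haplotype position.
map_hap_to_ref_anchor <- function(map, pos) {
  i <- pmax(findInterval(pos, map$hap_start), 1L)
  within <- pmin(pos - map$hap_start[i], map$len[i] - 1L)
  map$ref_start[i] + pmax(within, 0L)
}

# ---- molecule sampling -------------------------------------------------

sample_molecules <- function(cfg, hap1, hap2) {
  n_mol <- cfg$n_barcodes * cfg$molecules_per_barcode
  mean_len <- cfg$molecule_mean_length
  lens <- rexp(n_mol, 1 / mean_len)
  # truncate to [1 kb, 5 * mean]; resample out-of-range draws
  bad <- which(lens < 1000 | lens > 5 * mean_len)
  while (length(bad) > 0) {
    lens[bad] <- rexp(length(bad), 1 / mean_len)
    bad <- bad[lens[bad] < 1000 | lens[bad] > 5 * mean_len]
  }
  lens <- as.integer(round(lens))
  hap <- sample(1:2, n_mol, replace = TRUE)
  hap_len <- c(nchar(hap1$seq), nchar(hap2$seq))
  # molecules may overhang the sequence ends and are clamped, so per-base
  # physical coverage stays flat right up to the ends (as in an interior
  # window of a real chromosome) instead of ramping from zero
  start0 <- as.integer(floor(runif(n_mol) * (hap_len[hap] + lens))) - lens
  start <- pmax(0L, start0)
  end <- pmin(hap_len[hap], start0 + lens)
  lens <- end - start

  maps <- list(hap1$map, hap2$map)
  ref_start <- integer(n_mol); ref_end <- integer(n_mol)
  for (h in 1:2) {
    idx <- hap == h
    ref_start[idx] <- map_hap_to_ref_anchor(maps[[h]], start[idx])
    ref_end[idx] <- map_hap_to_ref_anchor(maps[[h]], end[idx] - 1L) + 1L
  }
  ord <- order(ref_start)
  barcode_idx <- integer(n_mol)
  if (cfg$barcode_min_spacing < 5e4) {
    # stress mode (spacing request below the molecule split threshold):
    # same-barcode molecules placed as close as the layout allows, to
    # exercise molecule mis-splitting
    barcode_idx[ord] <- (seq_len(n_mol) - 1L) %/% cfg$molecules_per_barcode + 1L
  } else {
    # stride through position-sorted molecules: same-barcode molecules end
    # up ~genome_length/molecules_per_barcode apart
    barcode_idx[ord] <- (seq_len(n_mol) - 1L) %% cfg$n_barcodes + 1L
  }

  tibble(
    molecule_id = sprintf("mol%06d", seq_len(n_mol)),
    barcode = sprintf("BX%06d", barcode_idx),
    chrom = "chr1",
    hap = hap,
    hstart = start,
    hend = end,
    start = ref_start,
    end = ref_end,
    length = lens
  )
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat("<diploid_truth>\n",
      sprintf("  reference %d bp; haplomes %d / %d bp\n", nchar(x$ref_seq),
              nchar(x$hap_seq[1]), nchar(x$hap_seq[2])),
      sprintf("  %d variants (%d het, %d hom); %d molecules\n",
              nrow(x$variants), sum(x$variants$zygosity == "het"),
              sum(x$variants$zygosity == "hom"), nrow(x$molecules)),
      sep = "")
  invisible(x)
}
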