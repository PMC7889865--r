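# Variation module: variant candidates from contig alignments, zygosity
# inference across the two haploid callsets, merging with the read-based
# SNP set, phasing against the phase-block scaffold, and final VCF output.

#' Extract variant candidates from contig alignments
#'
#' Contigs of 1 kb or less and alignments below MAPQ 20 are filtered out;
#' every remaining edit operation of at least 1 bp becomes a candidate.
#' Indels are VCF-anchored (position of the base before the event,
#' 1-based) and left-aligned against the reference so equivalent calls
#' from the two haplotypes are comparable.
#'
#' @param alns A `contig_alignments` tibble ([align_contigs()] or
#'   [read_paf_cs()]).
#' @param ref_seq Reference sequence (for indel anchors and
#'   normalisation).
#' @param min_contig_len Minimum contig length (default 1000; applies to
#'   the contig, not the alignment block).
#' @param min_mapq Minimum mapping quality (default 20).
#' @return Candidate tibble: `haplotype`, `block_id`, `contig_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `type` (`SNP`/`INS`/`DEL`),
#'   `size`.
#' @export
extract_variants <- function(alns, ref_seq, min_contig_len = 1000,
                             min_mapq = 20, chrom = "chr1") {
  alns <- alns[alns$contig_len > min_contig_len & alns$mapq >= min_mapq, ,
               drop = FALSE]
  if (nrow(alns) == 0) {
    return(tibble(haplotype = integer(), block_id = integer(),
                  contig_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  type = character(), size = integer()))
  }
  rows <- map(seq_len(nrow(alns)), function(i) {
    ops <- alns$ops[[i]]
    ops <- ops[ops$op != "M", , drop = FALSE]
    if (nrow(ops) == 0) return(NULL)
    cand <- map(seq_len(nrow(ops)), function(j) {
      o <- ops[j, ]
      if (o$op == "X") {
        tibble(pos = o$ref_pos + 1L, ref = o$ref_bases, alt = o$alt_bases,
               type = "SNP", size = 1L)
      } else if (o$op == "I") {
        # insertion sits between ref_pos-1 and ref_pos (0-based)
        norm <- normalize_indel(ref_seq, o$ref_pos - 1L, "", o$alt_bases)
        tibble(pos = norm$pos + 1L, ref = norm$ref, alt = norm$alt,
               type = "INS", size = o$len)
      } else { # D
        norm <- normalize_indel(ref_seq, o$ref_pos - 1L, o$ref_bases, "")
        tibble(pos = norm$pos + 1L, ref = norm$ref, alt = norm$alt,
               type = "DEL", size = o$len)
      }
    })
    bind_cols(tibble(haplotype = alns$haplotype[i],
                     block_id = alns$block_id[i],
                     contig_id = alns$contig_id[i]),
              bind_rows(cand))
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0) {
    return(tibble(haplotype = integer(), block_id = integer(),
                  contig_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  type = character(), size = integer()))
  }
  out$chrom <- chrom
  distinct(out[c("haplotype", "block_id", "contig_id", "chrom", "pos",
                 "ref", "alt", "type", "size")])
}

# Left-align an indel. anchor0 is the 0-based position of the base before
# the inserted/deleted bases; `del`/`ins` is the deleted/inserted sequence
# (one of them empty). Returns VCF-style pos (0-based anchor), ref, alt.
normalize_indel <- function(ref_seq, anchor0, del, ins) {
  moving <- if (nchar(del) > 0) del else ins
  while (anchor0 > 0) {
    last <- substring(moving, nchar(moving), nchar(moving))
    anchor_base <- substring(ref_seq, anchor0 + 1L, anchor0 + 1L)
    if (last != anchor_base) break
    moving <- paste0(anchor_base, substring(moving, 1, nchar(moving) - 1L))
    anchor0 <- anchor0 - 1L
  }
  anchor_base <- substring(ref_seq, anchor0 + 1L, anchor0 + 1L)
  if (nchar(del) > 0) {
    list(pos = anchor0, ref = paste0(anchor_base, moving), alt = anchor_base)
  } else {
    list(pos = anchor0, ref = anchor_base, alt = paste0(anchor_base, moving))
  }
}

# Reference intervals covered by each haplotype's passing contigs.
haplotype_coverage <- function(alns, min_contig_len = 1000, min_mapq = 20) {
  alns <- alns[alns$contig_len > min_contig_len & alns$mapq >= min_mapq, ,
               drop = FALSE]
  alns %>%
    transmute(haplotype = .data$haplotype, start = .data$ref_start,
              end = .data$ref_end)
}

covered_at <- function(coverage, hap, pos) {
  cov <- coverage[coverage$haplotype == hap, , drop = FALSE]
  out <- logical(length(pos))
  if (nrow(cov) == 0) return(out)
  for (i in seq_len(nrow(cov))) {
    out <- out | (pos > cov$start[i] & pos <= cov$end[i])
  }
  out
}

#' Infer SNP zygosity across the two haploid callsets
#'
#' A SNP seen with the same alternate allele on both haplotypes is
#' homozygous; seen on one haplotype while the other haplotype's contig
#' covers the site with the reference allele, heterozygous; if the other
#' haplotype does not cover the site, heterozygous with a low-confidence
#' flag. Two different alternate alleles at one site yield two
#' heterozygous records flagged multiallelic.
#'
#' @param cands Candidates from [extract_variants()] (SNPs used).
#' @param coverage Per-haplotype covered intervals
#'   ([haplotype_coverage()]).
#' @return Final-variant tibble: `chrom`, `pos`, `ref`, `alt`, `type`,
#'   `size`, `genotype` (`het`/`hom`), `carrier_hp`, `block_id`,
#'   `low_conf`, `multiallelic`.
#' @export
infer_snp_zygosity <- function(cands, coverage) {
  snps <- cands[cands$type == "SNP", , drop = FALSE]
  if (nrow(snps) == 0) {
    return(empty_final_variants())
  }
  snps %>%
    group_by(.data$chrom, .data$pos) %>%
    group_modify(function(d, key) {
      h1 <- d[d$haplotype == 1L, ]; h2 <- d[d$haplotype == 2L, ]
      alts <- unique(d$alt)
      if (nrow(h1) > 0 && nrow(h2) > 0 && length(alts) == 1) {
        tibble(ref = d$ref[1], alt = alts, type = "SNP", size = 1L,
               genotype = "hom", carrier_hp = NA_integer_,
               block_id = d$block_id[1], low_conf = FALSE,
               multiallelic = FALSE)
      } else if (length(alts) > 1) {
        d %>% transmute(ref = .data$ref, alt = .data$alt, type = "SNP",
                        size = 1L, genotype = "het",
                        carrier_hp = .data$haplotype,
                        block_id = .data$block_id, low_conf = FALSE,
                        multiallelic = TRUE)
      } else {
        carrier <- d$haplotype[1]
        other_cov <- covered_at(coverage, 3L - carrier, key$pos)
        tibble(ref = d$ref[1], alt = alts, type = "SNP", size = 1L,
               genotype = "het", carrier_hp = carrier,
               block_id = d$block_id[1], low_conf = !other_cov,
               multiallelic = FALSE)
      }
    }) %>%
    ungroup()
}

empty_final_variants <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), type = character(), size = integer(),
         genotype = character(), carrier_hp = integer(),
         block_id = integer(), low_conf = logical(),
         multiallelic = logical())
}

#' Infer indel and SV zygosity across haplotypes
#'
#' Two deletions from opposite haplotypes are the same event when their
#' reference intervals overlap by at least 1 bp; two insertions when
#' their breakpoints are within `ins_tol` (20 bp). Matched events are
#' homozygous (the haplotype-1 allele is reported); unmatched events are
#' heterozygous, with a low-confidence flag when the other haplotype's
#' contigs do not cover the site. Compound events (a deletion matching an
#' insertion is impossible; but two same-type events with different
#' alleles) are split into two heterozygous records.
#'
#' @param cands Candidates from [extract_variants()] (INS/DEL used).
#' @param coverage Per-haplotype covered intervals.
#' @param ins_tol Insertion breakpoint tolerance in bp (default 20).
#' @return Final-variant tibble (see [infer_snp_zygosity()]).
#' @export
infer_indel_sv_zygosity <- function(cands, coverage, ins_tol = 20) {
  ind <- cands[cands$type %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(ind) == 0) return(empty_final_variants())
  h1 <- ind[ind$haplotype == 1L, , drop = FALSE]
  h2 <- ind[ind$haplotype == 2L, , drop = FALSE]
  used2 <- logical(nrow(h2))
  out <- list()
  emit <- function(row, genotype, carrier, low_conf = FALSE) {
    out[[length(out) + 1L]] <<- tibble(
      chrom = row$chrom, pos = row$pos, ref = row$ref, alt = row$alt,
      type = row$type, size = row$size, genotype = genotype,
      carrier_hp = carrier, block_id = row$block_id, low_conf = low_conf,
      multiallelic = FALSE)
  }
  match_idx <- function(row) {
    if (nrow(h2) == 0) return(integer(0))
    same_type <- h2$type == row$type & !used2
    if (row$type == "DEL") {
      # interval overlap on the reference (deleted bases span)
      s1 <- row$pos; e1 <- row$pos + row$size
      which(same_type & h2$pos < e1 & (h2$pos + h2$size) > s1)
    } else {
      which(same_type & abs(h2$pos - row$pos) <= ins_tol)
    }
  }
  for (i in seq_len(nrow(h1))) {
    r <- h1[i, ]
    m <- match_idx(r)
    if (length(m) > 0) {
      m <- m[1]
      used2[m] <- TRUE
      identical_allele <- h2$pos[m] == r$pos & h2$ref[m] == r$ref &
        h2$alt[m] == r$alt
      if (identical_allele) {
        emit(r, "hom", NA_integer_)
      } else {
        # compound event: two heterozygous records
        emit(r, "het", 1L)
        emit(h2[m, ], "het", 2L)
      }
    } else {
      emit(r, "het", 1L, low_conf = !covered_at(coverage, 2L, r$pos))
    }
  }
  for (m in which(!used2)) {
    r <- h2[m, ]
    emit(r, "het", 2L, low_conf = !covered_at(coverage, 1L, r$pos))
  }
  bind_rows(out) %>% arrange(.data$chrom, .data$pos)
}

#' Merge assembly SNPs with a read-based SNP callset
#'
#' Takes the union of sites. Sites present in both keep the read-based
#' genotype when the two disagree (the mapping-based genotype is the more
#' reliable of the two), with the assembly call retained as an
#' annotation. A reference-allele contradiction at a shared site is an
#' error.
#'
#' @param assembly_snps Final-variant tibble of SNPs (from
#'   [infer_snp_zygosity()]).
#' @param read_vcf Read-based callset tibble (`chrom`, `pos`, `ref`,
#'   `alt`, `gt`).
#' @return Final-variant tibble with a `source` column
#'   (`assembly`/`read_based`/`both`) and `gt_conflict` flag.
#' @export
merge_snp_calls <- function(assembly_snps, read_vcf) {
  rb <- read_vcf[nchar(read_vcf$ref) == 1 & nchar(read_vcf$alt) == 1, ,
                 drop = FALSE]
  rb$genotype <- ifelse(grepl("^(1[/|]1)$", rb$gt), "hom", "het")
  key_a <- paste(assembly_snps$chrom, assembly_snps$pos)
  key_r <- paste(rb$chrom, rb$pos)
  shared <- intersect(key_a, key_r)
  clash <- assembly_snps[key_a %in% shared, ]
  rmatch <- rb[match(paste(clash$chrom, clash$pos), key_r), ]
  if (any(clash$ref != rmatch$ref)) {
    abort("reference allele mismatch between assembly and read-based calls")
  }
  both <- clash %>%
    mutate(gt_conflict = .data$genotype != rmatch$genotype |
             .data$alt != rmatch$alt,
           assembly_genotype = .data$genotype,
           genotype = rmatch$genotype,
           alt = rmatch$alt,
           source = "both")
  only_a <- assembly_snps[!key_a %in% shared, ] %>%
    mutate(gt_conflict = FALSE, assembly_genotype = .data$genotype,
           source = "assembly")
  only_r <- rb[!key_r %in% key_a, ] %>%
    transmute(chrom = .data$chrom, pos = .data$pos, ref = .data$ref,
              alt = .data$alt, type = "SNP", size = 1L,
              genotype = .data$genotype, carrier_hp = NA_integer_,
              block_id = NA_integer_, low_conf = FALSE,
              multiallelic = FALSE, gt_conflict = FALSE,
              assembly_genotype = NA_character_, source = "read_based")
  bind_rows(both, only_a, only_r) %>% arrange(.data$chrom, .data$pos)
}

#' Phase final variants against the phase-block scaffold
#'
#' For every (phase block, contig haplotype) the orientation relative to
#' the scaffold is decided by majority vote over assembly SNPs that match
#' scaffold-phased SNPs; all het variants carried by that haplotype are
#' then oriented accordingly with `PS` set to the block id. Het variants
#' with no informative match (or a tied vote) stay unphased. Read-based
#' het SNPs that are themselves scaffold variants inherit the scaffold
#' phase.
#'
#' @param final_variants Output of the zygosity/merge steps.
#' @param pb A `phase_blocks` object (the scaffold).
#' @param scaffold_variants Het-variant tibble with `variant_id`, `pos`
#'   (to translate scaffold variant ids to positions).
#' @return `final_variants` with `gt` (e.g. `"1|0"`, `"0/1"`, `"1/1"`)
#'   and `ps` columns.
#' @export
phase_variants <- function(final_variants, pb, scaffold_variants) {
  scaf <- pb$variants %>%
    left_join(scaffold_variants[c("variant_id", "ref", "alt")],
              by = "variant_id")
  fv <- final_variants

  # orientation votes: assembly het SNPs matching scaffold phased SNPs
  votes <- fv %>%
    filter(.data$genotype == "het", .data$type == "SNP",
           !is.na(.data$carrier_hp), !is.na(.data$block_id)) %>%
    inner_join(scaf[c("chrom", "pos", "alt", "hap1", "block_id")],
               by = c("chrom", "pos", "alt"),
               suffix = c("", ".scaf")) %>%
    mutate(scaffold_carrier = if_else(.data$hap1 == 1L, 1L, 2L),
           orient = if_else(.data$carrier_hp == 1L, .data$scaffold_carrier,
                            3L - .data$scaffold_carrier)) %>%
    count(block_id = .data$block_id.scaf, .data$orient)
  orientation <- votes %>%
    pivot_wider(names_from = "orient", values_from = "n",
                values_fill = 0L, names_prefix = "o")
  for (cl in c("o1", "o2")) {
    if (!cl %in% names(orientation)) orientation[[cl]] <- 0L
  }
  orientation <- orientation %>%
    mutate(orient = dplyr::case_when(.data$o1 > .data$o2 ~ 1L,
                                     .data$o2 > .data$o1 ~ 2L,
                                     TRUE ~ NA_integer_)) %>%
    select("block_id", "orient")

  scaf_key <- paste(scaf$chrom, scaf$pos, scaf$alt)
  fv <- fv %>%
    left_join(orientation, by = "block_id")
  n <- nrow(fv)
  gt <- character(n); ps <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (fv$genotype[i] == "hom") {
      gt[i] <- "1/1"
      next
    }
    key <- paste(fv$chrom[i], fv$pos[i], fv$alt[i])
    s <- match(key, scaf_key)
    if (!is.na(s)) {
      # scaffold-phased site: inherit scaffold phase directly
      gt[i] <- paste0(scaf$hap1[s], "|", scaf$hap2[s])
      ps[i] <- scaf$block_id[s]
    } else if (!is.na(fv$carrier_hp[i]) && !is.na(fv$orient[i])) {
      scaf_hap <- if (fv$carrier_hp[i] == 1L) fv$orient[i] else
        3L - fv$orient[i]
      gt[i] <- if (scaf_hap == 1L) "1|0" else "0|1"
      ps[i] <- fv$block_id[i]
    } else {
      gt[i] <- "0/1"
    }
  }
  fv$gt <- gt
  fv$ps <- ps
  select(fv, -"orient")
}

#' Write final variants as a phased VCF
#'
#' @param final_variants Phased final-variant tibble
#'   ([phase_variants()]).
#' @param path Output path.
#' @param ref_lengths Optional named contig lengths.
#' @return `path`, invisibly.
#' @export
write_final_vcf <- function(final_variants, path, ref_lengths = NULL) {
  fv <- final_variants %>% arrange(.data$chrom, .data$pos)
  info <- ifelse(fv$size >= 50 & fv$type != "SNP",
                 sprintf("SVTYPE=%s;SVLEN=%d;SRC=%s", fv$type,
                         ifelse(fv$type == "DEL", -fv$size, fv$size),
                         fv$source %||% "assembly"),
                 sprintf("SRC=%s", if (!is.null(fv$source)) fv$source
                         else "assembly"))
  write_vcf(tibble(chrom = fv$chrom, pos = fv$pos,
                   id = sprintf("v%06d", seq_len(nrow(fv))),
                   ref = fv$ref, alt = fv$alt, qual = 60,
                   gt = fv$gt, ps = fv$ps, info = info),
            path, ref_lengths = ref_lengths)
}
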