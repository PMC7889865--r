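# Pipeline orchestration: stage drivers mirroring the step structure
# (haplotyping + partitioning; local assembly + stitching; variant calling
# + phasing), a central default configuration, and truth-based evaluation.

#' Pipeline configuration with published defaults
#'
#' Every default is the method's stated operating point: 50 kb molecule
#' split gap; pruning at alt fraction 0.25, quality 13, 10-90 depth
#' percentiles; parity significance 0.99; cluster merge support 3; block
#' extension overlap 5; 200 kb block threshold and 100 kb chunks cut at
#' partitioning points (coverage factor 0.8, 100-mer uniqueness); contigs
#' over 1 kb at MAPQ >= 20 for variant calling; 20 bp insertion matching
#' tolerance; 50 bp SV size floor.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    split_gap = 50000,
    min_mapq_reads = 20,
    min_alt_fraction = 0.25,
    coverage_low_pct = 10,
    coverage_high_pct = 90,
    min_qual = 13,
    alpha = 0.99,
    merge_support = 3,
    overlap_support = 5,
    block_threshold = 200000,
    chunk_len = 100000,
    search_window = 20000,
    pp_factor = 0.8,
    k_uniq = 100,
    chunk_pad = 500,
    assembler_k = 31,
    min_kmer_count = 2,
    stitch_anchor_k = 100,
    stitch_search_margin = 2000,
    min_contig_len = 1000,
    min_mapq_contig = 20,
    ins_tol = 20,
    sv_min_size = 50,
    align_anchor_k = 21,
    window_pad = 5000
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(sprintf("unknown run_config fields: %s", paste(bad, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Haplotyping + partitioning stage
#'
#' Reconstructs molecules, phases het SNPs into blocks, computes coverage
#' and uniqueness profiles, selects partitioning points and cuts blocks
#' into assembly chunks. Each block's assembly span is the union of its
#' assigned molecules (clamped to the chromosome), so assembly reaches
#' past the outermost phased SNPs.
#'
#' @param alignments Alignment tibble (see [read_sam()] /
#'   [simulate_reads()]).
#' @param allele_calls Per-read het-site allele calls.
#' @param read_vcf Read-based callset tibble (het SNPs are the phasing
#'   input).
#' @param ref_seq Reference sequence.
#' @param cfg A [run_config()].
#' @param out_dir Optional directory for artifacts (phased VCF, block
#'   summary, molecule table, manifest).
#' @return Object of class `step1_result`: `molecules`, `phaseset`,
#'   `profile`, `points`, `chunks`, `block_spans`, `coverage`.
#' @export
run_step1 <- function(alignments, allele_calls, read_vcf, ref_seq,
                      cfg = run_config(), out_dir = NULL) {
  L <- nchar(ref_seq)
  al <- alignments %>% arrange(.data$barcode, .data$chrom, .data$start)
  molecules <- reconstruct_fragments(al, split_gap = cfg$split_gap,
                                     min_mapq = cfg$min_mapq_reads)
  hets <- het_variant_table(allele_calls, read_vcf)
  phaseset <- phase_haplotypes(
    molecules, allele_calls, hets,
    prune = prune_config(cfg$min_alt_fraction, cfg$coverage_low_pct,
                         cfg$coverage_high_pct, cfg$min_qual),
    alpha = cfg$alpha, merge_support = cfg$merge_support,
    overlap_support = cfg$overlap_support)

  profile <- compute_profiles(al, molecules, L)
  uniq <- compute_uniqueness(ref_seq, k = cfg$k_uniq)
  points <- select_partitioning_points(profile, uniq, factor = cfg$pp_factor)

  block_spans <- phaseset$blocks$molecules %>%
    inner_join(phaseset$assignments[c("molecule_id", "block_id")],
               by = c("molecule_id", "block_id")) %>%
    inner_join(molecules[c("molecule_id", "start", "end")],
               by = "molecule_id") %>%
    group_by(.data$block_id) %>%
    summarise(start = max(0L, min(.data$start)),
              end = min(L, max(.data$end)), .groups = "drop")
  # blocks with no assigned molecules fall back to their variant span
  missing <- anti_join(phaseset$blocks$blocks, block_spans, by = "block_id")
  if (nrow(missing) > 0) {
    block_spans <- bind_rows(
      block_spans,
      transmute(missing, .data$block_id, start = .data$start - 1L,
                end = .data$end)) %>%
      arrange(.data$block_id)
  }
  chunks <- cut_phase_blocks(block_spans, points,
                             block_threshold = cfg$block_threshold,
                             chunk_len = cfg$chunk_len,
                             search_window = cfg$search_window)
  coverage <- coverage_stats(molecules, al, L)

  res <- structure(
    list(molecules = molecules, phaseset = phaseset, profile = profile,
         points = points, chunks = chunks, block_spans = block_spans,
         coverage = coverage, alignments = al, cfg = cfg,
         genome_length = L),
    class = "step1_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phased_vcf(phaseset, file.path(out_dir, "phased_snps.vcf"),
                     ref_lengths = c(chr1 = L))
    write_molecule_table(molecules[c("molecule_id", "barcode", "chrom",
                                     "start", "end", "n_reads")],
                         file.path(out_dir, "molecules.tsv"))
    readr::write_tsv(phaseset$blocks$blocks,
                     file.path(out_dir, "phase_blocks.tsv"))
    readr::write_tsv(chunks, file.path(out_dir, "chunks.tsv"))
    write_manifest(out_dir, "step1", list(
      n_molecules = nrow(molecules),
      n_blocks = nrow(phaseset$blocks$blocks),
      n_phased_variants = nrow(phaseset$blocks$variants),
      n_chunks = nrow(chunks),
      n_partitioning_points = length(points),
      coverage = as.list(round(coverage, 6))))
  }
  res
}

#' Local assembly + stitching stage
#'
#' Partitions reads per (block, haplotype, chunk), assembles each chunk
#' with the configured backend, stitches minicontigs at shared
#' partitioning points and names the contigs.
#'
#' @param step1 A [run_step1()] result.
#' @param ref_seq Reference sequence (stitch anchors).
#' @param backend Assembler backend ([assemble_chunk()]).
#' @param out_dir Optional artifact directory (contig FASTA + manifest).
#' @return Object of class `step2_result`: `contigs` (tibble with
#'   lineage), `fasta` (named character vector), `chunk_reads` counts.
#' @export
run_step2 <- function(step1, ref_seq, backend = "toy", out_dir = NULL) {
  cfg <- step1$cfg
  chunk_reads <- partition_reads(step1$chunks, step1$alignments,
                                 step1$molecules,
                                 step1$phaseset$assignments,
                                 pad = cfg$chunk_pad)
  minis <- assemble_chunks(chunk_reads, step1$chunks, backend = backend,
                           k = cfg$assembler_k,
                           min_count = cfg$min_kmer_count)
  contigs <- stitch_minicontigs(minis, ref_seq,
                                anchor_k = cfg$stitch_anchor_k,
                                search_margin = cfg$stitch_search_margin)
  fasta <- name_contigs(contigs, step1$block_spans)
  contigs$contig_id <- names(fasta)
  res <- structure(
    list(contigs = contigs, fasta = fasta,
         n_chunk_reads = nrow(chunk_reads)),
    class = "step2_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(fasta, file.path(out_dir, "contigs.fasta"))
    for (hp in 1:2) {
      sel <- contigs$haplotype == hp
      if (any(sel)) {
        write_fasta(fasta[sel],
                    file.path(out_dir, sprintf("contigs_chr1_hp%d.fasta", hp)))
      }
    }
    write_manifest(out_dir, "step2", list(
      n_contigs = length(fasta),
      total_bp = sum(nchar(fasta)),
      contig_n50 = as.integer(n50(nchar(fasta)))))
  }
  res
}

#' Variant calling + phasing stage
#'
#' Aligns contigs to the reference, extracts SNP/indel/SV candidates per
#' haplotype, infers zygosity across the two haploid callsets, merges
#' with the read-based SNP set, phases everything against the phase-block
#' scaffold and (optionally) writes the final VCF.
#'
#' @param step2 A [run_step2()] result.
#' @param step1 The matching [run_step1()] result.
#' @param ref_seq Reference sequence.
#' @param read_vcf Read-based SNP callset tibble.
#' @param out_dir Optional artifact directory (final VCF + manifest).
#' @return Object of class `variant_calls`: tibble `calls` plus
#'   `alignments` and summary counts.
#' @export
run_varcall_and_phase <- function(step2, step1, ref_seq, read_vcf,
                                  out_dir = NULL) {
  cfg <- step1$cfg
  windows <- tibble(
    contig_id = step2$contigs$contig_id,
    start = map_dbl(step2$contigs$chunks, ~ min(map_dbl(.x, 1))) -
      cfg$window_pad,
    end = map_dbl(step2$contigs$chunks, ~ max(map_dbl(.x, 2))) +
      cfg$window_pad)
  alns <- align_contigs(step2$fasta, ref_seq, windows = windows,
                        anchor_k = cfg$align_anchor_k)
  cands <- extract_variants(alns, ref_seq,
                            min_contig_len = cfg$min_contig_len,
                            min_mapq = cfg$min_mapq_contig)
  coverage <- haplotype_coverage(alns, cfg$min_contig_len,
                                 cfg$min_mapq_contig)
  snps <- infer_snp_zygosity(cands, coverage)
  indels <- infer_indel_sv_zygosity(cands, coverage, ins_tol = cfg$ins_tol)
  merged <- merge_snp_calls(snps, read_vcf)
  final <- bind_rows(merged,
                     mutate(indels, gt_conflict = FALSE,
                            assembly_genotype = .data$genotype,
                            source = "assembly")) %>%
    arrange(.data$chrom, .data$pos)
  final <- phase_variants(final, step1$phaseset$blocks,
                          step1$phaseset$variants)
  counts <- final %>%
    mutate(class = dplyr::case_when(
      .data$type == "SNP" ~ "SNP",
      .data$size >= cfg$sv_min_size ~ "SV",
      TRUE ~ "indel")) %>%
    count(.data$class, .data$genotype, phased = grepl("\\|", .data$gt))
  res <- structure(list(calls = final, alignments = alns, counts = counts),
                   class = "variant_calls")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_final_vcf(final, file.path(out_dir, "variants_phased.vcf"),
                    ref_lengths = c(chr1 = nchar(ref_seq)))
    write_manifest(out_dir, "varcall", list(
      n_calls = nrow(final),
      by_class = split(counts$n, paste(counts$class, counts$genotype,
                                       ifelse(counts$phased, "phased",
                                              "unphased")))))
  }
  res
}

write_manifest <- function(out_dir, stage, fields) {
  jsonlite::write_json(c(list(stage = stage), fields),
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("<variant_calls> %d calls\n", nrow(x$calls)))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.variant_calls <- function(x, ...) x$calls

#' @export
glance.variant_calls <- function(x, ...) {
  tibble(n_calls = nrow(x$calls),
         n_het = sum(x$calls$genotype == "het"),
         n_hom = sum(x$calls$genotype == "hom"),
         n_phased = sum(grepl("\\|", x$calls$gt)),
         n_sv = sum(x$calls$type != "SNP" & x$calls$size >= 50))
}

# ---- truth-based evaluation -------------------------------------------

#' Diploid and genome fraction of an assembly
#'
#' Genome fraction: share of the genome covered by at least one aligned
#' contig. Diploid fraction: share of the genome covered by exactly one
#' contig from each haplotype.
#'
#' @param alns A `contig_alignments` tibble.
#' @param genome_length Genome length.
#' @return One-row tibble: `genome_fraction`, `diploid_fraction`,
#'   `diploid_fraction_of_covered`.
#' @export
evaluate_assembly <- function(alns, genome_length) {
  cov <- function(hp) {
    a <- alns[alns$haplotype == hp, ]
    if (nrow(a) == 0) return(integer(genome_length))
    as.integer(IRanges::coverage(
      IRanges::IRanges(start = a$ref_start + 1L, end = a$ref_end),
      width = genome_length))
  }
  c1 <- cov(1); c2 <- cov(2)
  covered <- c1 + c2 > 0
  diploid <- c1 == 1L & c2 == 1L
  tibble(genome_fraction = mean(covered),
         diploid_fraction = mean(diploid),
         diploid_fraction_of_covered = sum(diploid) / max(sum(covered), 1))
}

#' Compare final calls with a truth callset
#'
#' SNPs and small indels match on exact (pos, ref, alt) after
#' normalisation; SVs (>= `sv_min_size`) match like the merging rules
#' (deletions by interval overlap, insertions by breakpoint within
#' `ins_tol`). Genotype concordance is tallied over true positives.
#'
#' @param calls Final-variant tibble (with `gt`, `genotype`).
#' @param truth_vcf Truth tibble ([simulate_reads()]'s `truth_vcf`).
#' @param regions Optional tibble (`start`, `end`, 1-based inclusive) to
#'   restrict both sets (e.g. chunk interiors).
#' @param ref_seq Optional reference sequence; when given, indels on both
#'   sides are left-aligned before matching, so representation differences
#'   do not count as errors.
#' @param sv_min_size SV size threshold (default 50).
#' @param ins_tol Insertion matching tolerance (default 20).
#' @return Tibble per class (`SNP`, `indel`, `SV`): `tp`, `fn`, `fp`,
#'   `gt_mismatch`, `precision`, `recall`, `f1`.
#' @export
evaluate_variants <- function(calls, truth_vcf, regions = NULL,
                              ref_seq = NULL, sv_min_size = 50,
                              ins_tol = 20) {
  if (!is.null(ref_seq)) {
    normalize_tbl <- function(tb) {
      idx <- which(nchar(tb$ref) != nchar(tb$alt))
      for (i in idx) {
        if (nchar(tb$ref[i]) > nchar(tb$alt[i])) {
          norm <- normalize_indel(ref_seq, tb$pos[i] - 1L,
                                  substring(tb$ref[i], 2), "")
        } else {
          norm <- normalize_indel(ref_seq, tb$pos[i] - 1L, "",
                                  substring(tb$alt[i], 2))
        }
        tb$pos[i] <- norm$pos + 1L
        tb$ref[i] <- norm$ref
        tb$alt[i] <- norm$alt
      }
      tb
    }
    calls <- normalize_tbl(calls)
    truth_vcf <- normalize_tbl(truth_vcf)
  }
  in_regions <- function(pos) {
    if (is.null(regions)) return(rep(TRUE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(regions))) {
      out <- out | (pos >= regions$start[i] & pos <= regions$end[i])
    }
    out
  }
  truth <- truth_vcf %>%
    mutate(type = dplyr::case_when(
      nchar(.data$ref) == 1 & nchar(.data$alt) == 1 ~ "SNP",
      nchar(.data$alt) > nchar(.data$ref) ~ "INS",
      TRUE ~ "DEL"),
      size = pmax(nchar(.data$ref), nchar(.data$alt)) - 1L,
      size = ifelse(.data$type == "SNP", 1L, .data$size),
      class = dplyr::case_when(.data$type == "SNP" ~ "SNP",
                               .data$size >= sv_min_size ~ "SV",
                               TRUE ~ "indel"),
      genotype = ifelse(.data$gt %in% c("1|1", "1/1"), "hom", "het")) %>%
    filter(in_regions(.data$pos))
  calls <- calls %>%
    mutate(class = dplyr::case_when(.data$type == "SNP" ~ "SNP",
                                    .data$size >= sv_min_size ~ "SV",
                                    TRUE ~ "indel")) %>%
    filter(in_regions(.data$pos))

  score_class <- function(cl) {
    tr <- truth[truth$class == cl, ]
    ca <- calls[calls$class == cl, ]
    if (cl %in% c("SNP", "indel")) {
      key_t <- paste(tr$chrom, tr$pos, tr$ref, tr$alt)
      key_c <- paste(ca$chrom, ca$pos, ca$ref, ca$alt)
      tp_idx <- match(key_t, key_c)
      tp <- sum(!is.na(tp_idx))
      gt_mm <- sum(tr$genotype[!is.na(tp_idx)] !=
                     ca$genotype[tp_idx[!is.na(tp_idx)]])
      fp <- sum(!key_c %in% key_t)
    } else {
      matched_c <- logical(nrow(ca))
      tp <- 0L; gt_mm <- 0L
      for (i in seq_len(nrow(tr))) {
        if (tr$type[i] == "DEL") {
          hit <- which(!matched_c & ca$type == "DEL" &
                         ca$pos < tr$pos + tr$size &
                         ca$pos + ca$size > tr$pos)
        } else {
          hit <- which(!matched_c & ca$type == "INS" &
                         abs(ca$pos - tr$pos) <= ins_tol)
        }
        if (length(hit) > 0) {
          matched_c[hit[1]] <- TRUE
          tp <- tp + 1L
          if (ca$genotype[hit[1]] != tr$genotype[i]) gt_mm <- gt_mm + 1L
        }
      }
      fp <- sum(!matched_c)
    }
    fn <- nrow(tr) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    tibble(class = cl, tp = tp, fn = fn, fp = fp, gt_mismatch = gt_mm,
           precision = prec, recall = rec, f1 = f1)
  }
  bind_rows(map(c("SNP", "indel", "SV"), score_class))
}

#' Interior regions of assembly chunks
#'
#' Variants near chunk boundaries can be split across chunks; this
#' returns each chunk shrunk by `margin` on both sides, for
#' boundary-free evaluation.
#'
#' @param chunks Chunk tibble.
#' @param margin Shrink margin in bp (default 1000).
#' @return Tibble `start`, `end` (1-based inclusive).
#' @export
chunk_interiors <- function(chunks, margin = 1000) {
  chunks %>%
    filter(.data$haplotype == 1L) %>%
    transmute(start = .data$start + margin + 1L,
              end = .data$end - margin) %>%
    filter(.data$end > .data$start) %>%
    distinct()
}
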