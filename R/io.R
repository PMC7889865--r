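# Plain-text interchange: FASTA/FASTQ/SAM/VCF/TSV writers and readers.
# All coordinates are 0-based half-open in memory and 1-based in SAM/VCF.

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write simulated reads to FASTQ
#'
#' The barcode travels both in the read comment and as a `BX:Z:` tag so a
#' barcode-aware mapper can pick it up. Base qualities are Q30, except
#' planted error positions which get Q10.
#'
#' @param sim A [simulate_reads()] result.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  al <- sim$alignments
  rl <- nchar(al$seq[1])
  quals <- rep(strrep("?", rl), nrow(al))  # '?' = Q33+30
  if (nrow(sim$errors) > 0) {
    err <- sim$errors
    idx <- match(err$read_id, al$read_id)
    for (j in seq_len(nrow(err))) {
      substr(quals[idx[j]], err$offset[j], err$offset[j]) <- "+"  # Q10
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", al$read_id, " BX:Z:", al$barcode, "\n", al$seq,
                    "\n+\n", quals), con)
  invisible(path)
}

#' Write alignment records as SAM
#'
#' Emits a minimal sorted SAM with `BX:Z:` barcode tags and MAPQ as given
#' (simulated truth placements use MAPQ 60 and an all-match CIGAR).
#'
#' @param alignments Alignment tibble (`read_id`, `barcode`, `chrom`,
#'   `start`, `end`, `mapq`, `seq`).
#' @param path Output SAM path.
#' @param ref_lengths Named integer vector of reference lengths for the
#'   `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, ref_lengths) {
  al <- alignments[order(alignments$chrom, alignments$start), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                       as.integer(ref_lengths))), con)
  rl <- nchar(al$seq)
  writeLines(sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tBX:Z:%s",
                     al$read_id, al$chrom, al$start + 1L, al$mapq, rl,
                     al$seq, strrep("?", rl[1]), al$barcode), con)
  invisible(path)
}

#' Read a SAM file into an alignment tibble
#'
#' Parses the tab-separated SAM records (header lines skipped), taking the
#' barcode from the `BX:Z:` tag, with a fallback to a `_BX:<barcode>`
#' suffix on the read name. Records without a barcode are dropped with a
#' warning.
#'
#' @param path SAM path.
#' @return Tibble with `read_id`, `barcode`, `chrom`, 0-based half-open
#'   `start`/`end`, `mapq`, `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), barcode = character(),
                  chrom = character(), start = integer(), end = integer(),
                  mapq = integer(), seq = character()))
  }
  parts <- str_split(lines, "\t")
  bx <- map_chr(parts, function(f) {
    tag <- f[startsWith(f, "BX:Z:")]
    if (length(tag) > 0) return(substring(tag[1], 6))
    m <- str_match(f[1], "_BX:([^\\s_]+)")[, 2]
    if (!is.na(m)) m else NA_character_
  })
  if (anyNA(bx)) {
    warn(sprintf("%d SAM records without a barcode dropped", sum(is.na(bx))))
  }
  ok <- !is.na(bx)
  parts <- parts[ok]
  tibble(
    read_id = map_chr(parts, 1),
    barcode = bx[ok],
    chrom = map_chr(parts, 3),
    start = as.integer(map_chr(parts, 4)) - 1L,
    end = as.integer(map_chr(parts, 4)) - 1L + nchar(map_chr(parts, 10)),
    mapq = as.integer(map_chr(parts, 5)),
    seq = map_chr(parts, 10)
  )
}

#' Write a VCF-shaped tibble as VCF v4.2
#'
#' Records with a `ps` value are written phased (`GT` containing `|`, plus
#' a `PS` FORMAT field); others use their `gt` string as-is.
#'
#' @param vcf Tibble with `chrom`, `pos` (1-based), `id`, `ref`, `alt`,
#'   `qual`, `gt` and optionally `ps`, `info`.
#' @param path Output path.
#' @param sample Sample name for the single genotype column.
#' @param ref_lengths Optional named lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, sample = "SAMPLE", ref_lengths = NULL) {
  if (nrow(vcf) > 0 &&
      !identical(order(vcf$chrom, vcf$pos), seq_len(nrow(vcf)))) {
    abort("variants must be sorted by chrom, pos before writing")
  }
  v <- vcf
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set (block start)">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=SRC,Number=1,Type=String,Description="Call source">',
    if (!is.null(ref_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(ref_lengths),
              as.integer(ref_lengths)),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  ps <- if ("ps" %in% names(v)) v$ps else rep(NA_integer_, nrow(v))
  info <- if ("info" %in% names(v)) v$info else rep(".", nrow(v))
  info[is.na(info) | info == ""] <- "."
  fmt <- ifelse(is.na(ps), "GT", "GT:PS")
  gtcol <- ifelse(is.na(ps), v$gt, paste0(v$gt, ":", ps))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(v) > 0) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\t%s\t%s\t%s",
                       v$chrom, v$pos, v$id, v$ref, v$alt,
                       format(v$qual, trim = TRUE), info, fmt, gtcol), con)
  }
  invisible(path)
}

#' Read a single-sample VCF into a tibble
#'
#' Minimal VCF v4.x reader for the package's own interchange: returns one
#' row per record with the `GT` and (if present) `PS` fields split out.
#'
#' @param path VCF path.
#' @return Tibble with `chrom`, `pos`, `id`, `ref`, `alt`, `qual`, `info`,
#'   `gt`, `ps`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = character(),
                  info = character(), gt = character(), ps = integer()))
  }
  f <- str_split(lines, "\t")
  fmt <- str_split(map_chr(f, 9), ":")
  smp <- str_split(map_chr(f, 10), ":")
  get_field <- function(key) {
    map2_chr(fmt, smp, function(k, s) {
      i <- match(key, k)
      if (is.na(i)) NA_character_ else s[i]
    })
  }
  tibble(
    chrom = map_chr(f, 1),
    pos = as.integer(map_chr(f, 2)),
    id = map_chr(f, 3),
    ref = map_chr(f, 4),
    alt = map_chr(f, 5),
    qual = map_chr(f, 6),
    info = map_chr(f, 8),
    gt = get_field("GT"),
    ps = suppressWarnings(as.integer(get_field("PS")))
  )
}

#' Write a molecule table as TSV
#' @param molecules Molecule tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(molecules, path) {
  readr::write_tsv(molecules, path)
  invisible(path)
}
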