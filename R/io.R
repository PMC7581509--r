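#' Write a single-sample variant table as minimal VCF 4.2
#'
#' Emits one record per variant with `DP`, `AF` and `GENE` INFO fields and a
#' single sample column with `GT:AD:DP`. The table must contain exactly one
#' sample.
#'
#' @param variants Variant data.frame (see [simulate_sample()] for columns).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  sample_id <- unique(variants$sample_id)
  if (length(sample_id) != 1) {
    stop("write_variants_vcf() expects exactly one sample; got ",
         length(sample_id))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.6g;GENE=%s\tGT:AD:DP\t0/1:%d,%d:%d",
    v$chrom, as.integer(v$pos), v$ref, v$alt, v$total_reads, v$vaf, v$gene,
    v$total_reads - v$alt_reads, v$alt_reads, v$total_reads)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a variant VCF into the package's variant table
#'
#' Parses a VCF with \pkg{vcfR}. Alt/total read counts are taken from the
#' sample `AD` field when present, otherwise from the `DP` and `AF` INFO
#' fields; a `GENE` INFO field populates the `gene` column.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param sample_id Sample name; defaults to the VCF's single sample column.
#' @return Variant data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `alt_reads`, `total_reads`, `vaf`, `gene`.
#' @export
read_variants_vcf <- function(path, sample_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  n <- nrow(fix)
  if (is.null(sample_id)) {
    sample_id <- colnames(vcf@gt)[2]
  }
  gene <- tryCatch(vcfR::extract.info(vcf, "GENE"),
                   error = function(e) rep(NA_character_, n))
  ad <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    parts <- strsplit(ad[, 1], ",")
    ref_n <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    alt_n <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    total <- ref_n + alt_n
  } else {
    total <- as.integer(vcfR::extract.info(vcf, "DP"))
    alt_n <- as.integer(round(as.numeric(vcfR::extract.info(vcf, "AF")) * total))
  }
  data.frame(
    sample_id = sample_id, chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    alt_reads = alt_n, total_reads = total, vaf = alt_n / total, gene = gene
  )
}

#' Write / read a SEG-like segment table
#'
#' Tab-separated columns `sample`, `chrom`, `start`, `end`, `log2`,
#' `n_markers`, the common exchange format for copy-number segments.
#'
#' @param segments Segment data.frame.
#' @param path File path.
#' @return `write_seg()` the path invisibly; `read_seg()` a segment
#'   data.frame with the package's column names.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start, end = segments$end,
                    log2 = segments$log2_ratio,
                    n_markers = if (!is.null(segments$n_markers))
                      segments$n_markers else NA_integer_)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(sample_id = as.character(x$sample), chrom = x$chrom,
             start = x$start, end = x$end, log2_ratio = x$log2,
             integer_cn = NA_integer_, n_markers = x$n_markers)
}

#' Write a transcript as FASTA plus an exon table
#'
#' The CDS goes to a FASTA file (via \pkg{Biostrings}) and the coding exon
#' intervals to a tab-separated table (`exon`, `chrom`, `start`, `end`,
#' `strand`; 1-based inclusive).
#'
#' @param transcript A [transcript_model()].
#' @param fasta_path,exons_path Output paths.
#' @return The fasta path, invisibly.
#' @export
write_transcript <- function(transcript, fasta_path, exons_path) {
  seqs <- Biostrings::DNAStringSet(transcript$cds_sequence)
  names(seqs) <- transcript$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  ex <- transcript$exons
  out <- data.frame(exon = seq_len(nrow(ex)),
                    chrom = if (!is.null(ex$chrom)) ex$chrom else
                      transcript$chrom,
                    start = ex$start, end = ex$end,
                    strand = transcript$strand)
  write.table(out, exons_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a transcript from FASTA plus an exon table
#'
#' @param fasta_path FASTA file with a single CDS record.
#' @param exons_path Exon table written by [write_transcript()].
#' @return A [transcript_model()].
#' @export
read_transcript <- function(fasta_path, exons_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1) stop("expected a single CDS record in ", fasta_path)
  ex <- read.table(exons_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  transcript_model(as.character(seqs[[1]]), ex,
                   strand = unique(ex$strand),
                   chrom = if (!is.null(ex$chrom)) ex$chrom[1] else NA_character_,
                   id = names(seqs)[1])
}

#' Write a simulated cohort to a directory
#'
#' Writes `variants.tsv`, `segments.seg` and `labels.tsv` (plus one VCF per
#' sample under `vcf/` when `per_sample_vcf = TRUE`).
#'
#' @param sim A cohort from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @param per_sample_vcf Also write per-sample VCFs.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir, per_sample_vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(sim$variants, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_seg(sim$segments, file.path(dir, "segments.seg"))
  write.table(sim$labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (per_sample_vcf && nrow(sim$variants)) {
    vdir <- file.path(dir, "vcf")
    dir.create(vdir, showWarnings = FALSE)
    for (s in unique(sim$variants$sample_id)) {
      write_variants_vcf(sim$variants[sim$variants$sample_id == s, ],
                         file.path(vdir, paste0(s, ".vcf")))
    }
  }
  invisible(dir)
}
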