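#' Two-hit status of a single sample at a target gene
#'
#' Integrates small variants and copy-number segments at a tumor-suppressor
#' gene into one of four mutually exclusive statuses:
#' \describe{
#'   \item{`snv_plus_loh`}{at least one SNV/indel in the gene together with a
#'     called monoallelic loss (copy number 1) of the second allele;}
#'   \item{`biallelic_deletion`}{copy number 0 over the gene and no SNV/indel
#'     (if an SNV co-occurs with copy number 0 -- an anomaly, since the SNV
#'     would have no allele to sit on -- the copy state dominates and a
#'     warning note is attached);}
#'   \item{`single_hit`}{an SNV/indel without copy loss, or a monoallelic
#'     loss without an SNV/indel;}
#'   \item{`none`}{no hit at the gene.}
#' }
#'
#' An intratumoral-heterogeneity flag is raised when either
#' \enumerate{
#'   \item a gene-overlapping deletion's log2 ratio falls \emph{between} the
#'     monoallelic band and the biallelic ceiling -- too negative for a clonal
#'     single-copy loss, not negative enough for a clonal biallelic loss, the
#'     signature of a subclonal second deletion; or
#'   \item an SNV is present whose VAF (the purity a somatic clonal
#'     interpretation would require) lies more than `vaf_margin` below the
#'     assumed cohort purity, indicating the mutation is confined to a
#'     subclone.
#' }
#' When condition 1 coincides with an SNV in the gene, the intermediate
#' segment is interpreted as a clonal monoallelic loss plus a subclonal
#' second event and contributes copy number 1, so the sample is classified
#' `snv_plus_loh` with the flag set.
#'
#' The default biallelic ceiling is purity-aware:
#' `expected_log2(0, purity) + 0.25`, i.e. slightly above the log2 ratio a
#' clonal biallelic deletion produces at that purity (about -2.07 at purity
#' 0.8). Ratios at or below the ceiling are treated as biallelic; panel
#' callers often report much lower values (down to the ratio floor, -9.97)
#' for homozygous deletions.
#'
#' @param variants Data.frame of small variants (columns `sample_id`, `gene`,
#'   `vaf`, optionally `hgvs_c`, `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`). May be `NULL` or empty.
#' @param segments Data.frame of copy-number segments (columns `sample_id`,
#'   `chrom`, `start`, `end`, `log2_ratio`, optional `integer_cn`). May be
#'   `NULL` or empty.
#' @param gene Target gene interval from [gene_interval()]; variants are
#'   matched by gene symbol when a `gene` column is present, otherwise by
#'   genomic position.
#' @param purity Assumed tumor purity (default 0.8).
#' @param mono_band Log2 interval treated as clonal monoallelic loss
#'   (default `c(-1.5, -0.3)`).
#' @param biallelic_max Log2 ceiling for clonal biallelic loss; `NULL`
#'   (default) uses `expected_log2(0, purity) + 0.25`.
#' @param vaf_margin Heterogeneity margin on `purity - vaf` (default 0.3).
#' @param ploidy Normal copy number (default 2).
#' @return One-row data.frame: `sample_id`, `status`, `hit1`, `hit2`,
#'   `n_snv`, `cn_at_gene`, `heterogeneity_flag`, `notes`.
#' @examples
#' gene <- gene_interval("FH", "chr1", 241660903, 241683061)
#' segs <- data.frame(sample_id = "S05", chrom = "chr1",
#'                    start = 241661127, end = 241677014,
#'                    log2_ratio = -1.87)
#' vars <- data.frame(sample_id = "S05", gene = "FH", vaf = 0.443)
#' classify_sample(vars, segs, gene)  # snv_plus_loh, heterogeneity flagged
#' @export
classify_sample <- function(variants, segments, gene, purity = 0.8,
                            mono_band = c(-1.5, -0.3), biallelic_max = NULL,
                            vaf_margin = 0.3, ploidy = 2) {
  check_purity(purity)
  if (is.null(biallelic_max)) {
    biallelic_max <- expected_log2(0, purity, ploidy) + 0.25
  }
  sample_id <- unique(c(
    if (!is.null(variants) && nrow(variants)) variants$sample_id,
    if (!is.null(segments) && nrow(segments)) segments$sample_id))
  if (length(sample_id) > 1) {
    stop("classify_sample() expects a single sample; got: ",
         paste(sample_id, collapse = ", "))
  }
  if (length(sample_id) == 0) sample_id <- NA_character_

  tv <- target_variants(variants, gene)
  gs <- if (!is.null(segments) && nrow(segments)) {
    segments[overlaps_interval(segments, gene), , drop = FALSE]
  } else {
    NULL
  }

  notes <- character(0)
  het <- FALSE
  n_snv <- if (is.null(tv)) 0L else nrow(tv)

  cn_at_gene <- NA_integer_
  if (!is.null(gs) && nrow(gs)) {
    cn <- segment_cn(gs, purity, ploidy)
    between <- gs$log2_ratio > biallelic_max & gs$log2_ratio < mono_band[1]
    if (any(between)) {
      het <- TRUE
      notes <- c(notes, sprintf(
        "log2 %s between monoallelic band and biallelic ceiling (%.2f)",
        paste(sprintf("%.2f", gs$log2_ratio[between]), collapse = ", "),
        biallelic_max))
      if (n_snv >= 1) {
        # intermediate ratio + SNV: clonal monoallelic loss with a subclonal
        # second event; the formulaic CN (often 0) is overridden
        cn[between] <- 1L
      }
    }
    cn_at_gene <- min(cn)
  }

  if (n_snv >= 1) {
    lagging <- purity - tv$vaf > vaf_margin
    if (any(lagging)) {
      het <- TRUE
      notes <- c(notes, sprintf(
        "SNV VAF %s implies somatic clonal purity far below assumed %.2f",
        paste(sprintf("%.3f", tv$vaf[lagging]), collapse = ", "), purity))
    }
    if (n_snv >= 2) {
      notes <- c(notes, sprintf("%d SNVs/indels in target gene", n_snv))
    }
  }

  snv_desc <- if (n_snv >= 1) describe_variant(tv[1, , drop = FALSE]) else NA_character_
  del_desc <- function(rows) {
    paste(sprintf("CN-loss %s:%d-%d (log2 %.2f)", rows$chrom,
                  round(rows$start), round(rows$end), rows$log2_ratio),
          collapse = "; ")
  }

  if (is.na(cn_at_gene) && n_snv == 0) {
    status <- "none"; hit1 <- NA_character_; hit2 <- NA_character_
  } else if (!is.na(cn_at_gene) && cn_at_gene == 0) {
    status <- "biallelic_deletion"
    loss_rows <- gs[segment_cn(gs, purity, ploidy) < ploidy, , drop = FALSE]
    hit1 <- del_desc(loss_rows[1, , drop = FALSE])
    hit2 <- if (nrow(loss_rows) > 1) del_desc(loss_rows[-1, , drop = FALSE]) else
      "same deletion, both alleles"
    if (n_snv >= 1) {
      notes <- c(notes,
                 "anomaly: SNV co-occurs with copy number 0; copy state dominates")
    }
  } else if (n_snv >= 1 && !is.na(cn_at_gene) && cn_at_gene == 1) {
    status <- "snv_plus_loh"
    hit1 <- snv_desc
    hit2 <- del_desc(gs[which.min(segment_cn(gs, purity, ploidy)), , drop = FALSE])
  } else if (n_snv >= 1) {
    status <- "single_hit"; hit1 <- snv_desc; hit2 <- NA_character_
  } else if (!is.na(cn_at_gene) && cn_at_gene < ploidy) {
    status <- "single_hit"
    hit1 <- del_desc(gs[which.min(segment_cn(gs, purity, ploidy)), , drop = FALSE])
    hit2 <- NA_character_
  } else {
    status <- "none"; hit1 <- NA_character_; hit2 <- NA_character_
  }

  data.frame(
    sample_id = sample_id, status = status, hit1 = hit1, hit2 = hit2,
    n_snv = n_snv, cn_at_gene = cn_at_gene, heterogeneity_flag = het,
    notes = if (length(notes)) paste(notes, collapse = "; ") else ""
  )
}

#' Two-hit classification of a whole cohort
#'
#' Applies [classify_sample()] to every sample present in the variant or
#' segment tables.
#'
#' @inheritParams classify_sample
#' @param ... Further arguments passed to [classify_sample()].
#' @return Data.frame of per-sample calls (one row each).
#' @export
classify_cohort <- function(variants, segments, gene, purity = 0.8, ...) {
  samples <- sort(unique(c(
    if (!is.null(variants) && nrow(variants)) variants$sample_id,
    if (!is.null(segments) && nrow(segments)) segments$sample_id)))
  if (!length(samples)) stop("no samples in input")
  do.call(rbind, lapply(samples, function(s) {
    classify_sample(
      variants = if (!is.null(variants) && nrow(variants))
        variants[variants$sample_id == s, , drop = FALSE] else NULL,
      segments = if (!is.null(segments) && nrow(segments))
        segments[segments$sample_id == s, , drop = FALSE] else NULL,
      gene = gene, purity = purity, ...)
  }))
}

#' Summarize two-hit calls over a cohort
#'
#' @param calls Data.frame of calls from [classify_cohort()].
#' @return A list with `n` (samples), `counts` (data.frame `status`, `count`,
#'   `fraction`; fractions sum to 1), `fraction_with_snv` (share of samples
#'   with at least one target-gene SNV/indel) and `n_heterogeneity_flagged`.
#' @export
summarize_twohit_cohort <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) stop("no calls to summarize")
  lev <- c("snv_plus_loh", "biallelic_deletion", "single_hit", "none")
  counts <- table(factor(calls$status, levels = lev))
  list(
    n = nrow(calls),
    counts = data.frame(status = lev, count = as.integer(counts),
                        fraction = as.numeric(counts) / nrow(calls)),
    fraction_with_snv = mean(calls$n_snv >= 1),
    n_heterogeneity_flagged = sum(calls$heterogeneity_flag)
  )
}

#' Write a cohort two-hit summary as JSON
#'
#' @param summary A summary from [summarize_twohit_cohort()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_twohit_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

## ---- internal ------------------------------------------------------------

# variants hitting the target gene: by symbol when available, else position
target_variants <- function(variants, gene) {
  if (is.null(variants) || nrow(variants) == 0) return(NULL)
  if (!is.null(variants$gene) && any(!is.na(variants$gene))) {
    hit <- !is.na(variants$gene) & variants$gene == gene$symbol
  } else {
    hit <- !is.na(variants$pos) & variants$chrom == gene$chrom &
      variants$pos >= gene$start & variants$pos <= gene$end
  }
  out <- variants[hit, , drop = FALSE]
  if (nrow(out) == 0) NULL else out
}

describe_variant <- function(v) {
  col <- function(name) {
    x <- v[[name]]
    if (is.null(x) || is.na(x)) NA_character_ else as.character(x)
  }
  label <- col("hgvs_c")
  if (is.na(label)) {
    label <- sprintf("%s:%s", col("chrom"), col("pos"))
  }
  cons <- col("consequence")
  cons <- if (is.na(cons)) "" else paste0(cons, " ")
  sprintf("%s%s (VAF %.3f)", cons, label, v$vaf)
}
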