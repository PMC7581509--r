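#' Expected log2 copy ratio for an integer copy number
#'
#' Generative model behind purity-corrected copy-number calling: a specimen
#' that is a mixture of tumor cells (fraction `purity`, carrying `cn` copies)
#' and normal cells (carrying `ploidy` copies) has copy ratio
#' `(purity * cn + (1 - purity) * ploidy) / ploidy`. The ratio is floored at
#' `ratio_floor` before taking log2 so that complete biallelic losses in a
#' pure specimen yield a finite value; the default floor of 1e-3 corresponds
#' to a log2 of about -9.97, the value panel CNV callers report for
#' homozygous deletions.
#'
#' @param cn Integer copy number(s), >= 0.
#' @param purity Tumor purity in `(0, 1]`.
#' @param ploidy Normal-cell copy number at the locus (default 2).
#' @param ratio_floor Lower bound on the copy ratio before log2 (default 1e-3).
#' @return Numeric vector of log2 copy ratios.
#' @examples
#' expected_log2(2, 0.8)   # 0: copy-neutral
#' expected_log2(1, 0.8)   # log2(0.6) ~ -0.737: monoallelic loss
#' expected_log2(0, 1.0)   # floored at log2(0.001) ~ -9.97
#' @export
expected_log2 <- function(cn, purity, ploidy = 2, ratio_floor = 1e-3) {
  stopifnot(is.numeric(cn), all(cn >= 0), all(cn == round(cn)))
  check_purity(purity)
  if (any(ploidy < 1)) stop("`ploidy` must be >= 1")
  ratio <- (purity * cn + (1 - purity) * ploidy) / ploidy
  log2(pmax(ratio_floor, ratio))
}

#' Convert log2 copy ratios to purity-corrected integer copy numbers
#'
#' Inverts [expected_log2()]: the continuous tumor copy number implied by an
#' observed log2 ratio at a given purity is
#' `ploidy * (2^log2_ratio - (1 - purity)) / purity`, which is rounded
#' half-away-from-zero and truncated at zero.
#'
#' @param log2_ratio Observed log2 copy ratio(s).
#' @param purity Tumor purity in `(0, 1]`; default 0.8, the standard setting
#'   for macro-dissected tumor specimens with >80% tumor cellularity.
#' @param ploidy Normal-cell copy number (default 2).
#' @return Integer vector of copy numbers (>= 0).
#' @examples
#' log2_to_cn(-0.85, purity = 0.8)  # 1 (monoallelic loss)
#' log2_to_cn(-9.97, purity = 0.8)  # 0 (biallelic loss)
#' @export
log2_to_cn <- function(log2_ratio, purity = 0.8, ploidy = 2) {
  stopifnot(is.numeric(log2_ratio))
  check_purity(purity)
  if (any(ploidy < 1)) stop("`ploidy` must be >= 1")
  cn_cont <- ploidy * (2^log2_ratio - (1 - purity)) / purity
  as.integer(pmax(0, round_half_away(cn_cont)))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Segment size in kilobases
#'
#' Size of a copy-number segment, `(end - start) / 1000`, reported to 0.1 kb.
#' Coordinates are 1-based inclusive in the HGVS-style `chr:g.start_end`
#' convention.
#'
#' @param segments A data.frame of segments with columns `start` and `end`,
#'   or a numeric vector of start coordinates (then `end` must be given).
#' @param end Numeric vector of end coordinates when `segments` is numeric.
#' @return Numeric vector of sizes in kb, rounded to one decimal.
#' @examples
#' segment_size_kb(241661127, 241677014)  # 15.9
#' @export
segment_size_kb <- function(segments, end = NULL) {
  if (is.data.frame(segments)) {
    start <- segments$start
    end <- segments$end
  } else {
    start <- segments
  }
  stopifnot(is.numeric(start), is.numeric(end), length(start) == length(end))
  if (any(end <= start)) stop("segment `end` must be greater than `start`")
  round((end - start) / 1000, 1)
}

#' Summarize copy-number losses over a gene
#'
#' Restricts a segment table to segments overlapping a gene interval, derives
#' integer copy numbers where missing (via [log2_to_cn()] at the stated
#' purity), and summarizes the loss segments: count, size extremes and median
#' (in kb, to 0.1 kb), plus the per-sample minimum copy number over the gene.
#'
#' @param segments Data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `log2_ratio` and optionally `integer_cn`.
#' @param gene A one-row data.frame from [gene_interval()].
#' @param purity Tumor purity used when integer copy numbers are absent.
#' @param ploidy Normal copy number (default 2); a loss is `cn < ploidy`.
#' @return A list with `n_loss_segments`, `size_min_kb`, `size_max_kb`,
#'   `size_median_kb`, `sizes_kb` (per loss segment) and `per_sample_cn`
#'   (data.frame `sample_id`, `cn`). Empty input yields zero counts and `NA`
#'   sizes.
#' @export
summarize_losses <- function(segments, gene, purity = 0.8, ploidy = 2) {
  empty <- list(n_loss_segments = 0L, size_min_kb = NA_real_,
                size_max_kb = NA_real_, size_median_kb = NA_real_,
                sizes_kb = numeric(0),
                per_sample_cn = data.frame(sample_id = character(0),
                                           cn = integer(0)))
  if (is.null(segments) || nrow(segments) == 0) return(empty)
  ov <- segments[overlaps_interval(segments, gene), , drop = FALSE]
  if (nrow(ov) == 0) return(empty)
  cn <- segment_cn(ov, purity, ploidy)
  loss <- ov[cn < ploidy, , drop = FALSE]
  sizes <- if (nrow(loss)) (loss$end - loss$start) / 1000 else numeric(0)
  per_sample <- aggregate(list(cn = cn), by = list(sample_id = ov$sample_id),
                          FUN = min)
  list(
    n_loss_segments = nrow(loss),
    size_min_kb = if (length(sizes)) round(min(sizes), 1) else NA_real_,
    size_max_kb = if (length(sizes)) round(max(sizes), 1) else NA_real_,
    size_median_kb = if (length(sizes)) round(median(sizes), 1) else NA_real_,
    sizes_kb = round(sizes, 1),
    per_sample_cn = per_sample[order(per_sample$sample_id), , drop = FALSE]
  )
}

#' Gene-level recurrence test of copy-number losses or gains
#'
#' For each gene, counts case and control samples carrying at least one
#' overlapping segment with purity-corrected copy number below (`loss`) or
#' above (`gain`) the normal ploidy, and tests case enrichment with a
#' one-sided Fisher exact test on the 2x2 table (affected vs not, case vs
#' control), adjusted across genes (Bonferroni by default).
#'
#' @param case_segments,control_segments Segment data.frames (see
#'   [summarize_losses()]); each must contain at least one sample.
#' @param genes Data.frame of gene intervals with columns `symbol`, `chrom`,
#'   `start`, `end`.
#' @param direction `"loss"` or `"gain"`.
#' @param purity,ploidy Passed to [log2_to_cn()] when `integer_cn` is absent.
#' @param p_adjust_method Multiple-testing correction (default
#'   `"bonferroni"`); any method accepted by [stats::p.adjust()].
#' @return Data.frame with one row per gene: counts, `p_value`, `p_adjusted`.
#' @export
recurrence_test <- function(case_segments, control_segments, genes,
                            direction = c("loss", "gain"), purity = 0.8,
                            ploidy = 2, p_adjust_method = "bonferroni") {
  direction <- match.arg(direction)
  if (is.null(genes) || nrow(genes) == 0) stop("`genes` must be non-empty")
  if (!nrow(case_segments) || !nrow(control_segments)) {
    stop("both cohorts must contain at least one segment table row")
  }
  case_samples <- unique(case_segments$sample_id)
  control_samples <- unique(control_segments$sample_id)

  affected_samples <- function(segs, gene) {
    ov <- segs[overlaps_interval(segs, gene), , drop = FALSE]
    if (!nrow(ov)) return(character(0))
    cn <- segment_cn(ov, purity, ploidy)
    hit <- if (direction == "loss") cn < ploidy else cn > ploidy
    unique(ov$sample_id[hit])
  }

  res <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, , drop = FALSE]
    a_case <- length(affected_samples(case_segments, gene))
    a_ctrl <- length(affected_samples(control_segments, gene))
    tab <- matrix(c(a_case, length(case_samples) - a_case,
                    a_ctrl, length(control_samples) - a_ctrl),
                  nrow = 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(symbol = gene$symbol, case_affected = a_case,
               case_total = length(case_samples), control_affected = a_ctrl,
               control_total = length(control_samples), p_value = p)
  }))
  res$p_adjusted <- pmin(1, p.adjust(res$p_value, method = p_adjust_method))
  res
}

#' Construct a gene interval
#'
#' @param symbol Gene symbol.
#' @param chrom Chromosome name (e.g. `"chr1"`).
#' @param start,end 1-based inclusive coordinates, `end > start`.
#' @return One-row data.frame with columns `symbol`, `chrom`, `start`, `end`.
#' @examples
#' gene_interval("FH", "chr1", 241660903, 241683061)
#' @export
gene_interval <- function(symbol, chrom, start, end) {
  stopifnot(end > start)
  data.frame(symbol = symbol, chrom = chrom, start = start, end = end)
}

#' Parse HGVS-style copy-number strings
#'
#' Parses strings of the form `"chr1:g.241661127_241677014x1"` (a multiplication
#' sign is also accepted) into a segment table with the called integer copy
#' number.
#'
#' @param x Character vector of copy-number strings.
#' @return Data.frame with columns `chrom`, `start`, `end`, `integer_cn`.
#' @export
parse_cn_hgvs <- function(x) {
  pat <- "^([^:]+):g\\.([0-9]+)_([0-9]+)[x×]([0-9]+)$"
  ok <- grepl(pat, x)
  if (!all(ok)) stop("cannot parse copy-number string(s): ",
                     paste(x[!ok], collapse = ", "))
  data.frame(
    chrom = sub(pat, "\\1", x),
    start = as.numeric(sub(pat, "\\2", x)),
    end = as.numeric(sub(pat, "\\3", x)),
    integer_cn = as.integer(sub(pat, "\\4", x))
  )
}

## ---- internal helpers ----------------------------------------------------

# integer CN per segment row: stored value if present, else purity-corrected
segment_cn <- function(segments, purity, ploidy) {
  cn <- log2_to_cn(segments$log2_ratio, purity = purity, ploidy = ploidy)
  if (!is.null(segments$integer_cn)) {
    keep <- !is.na(segments$integer_cn)
    cn[keep] <- as.integer(segments$integer_cn[keep])
  }
  cn
}

# logical: which segment rows overlap the (single) gene interval
overlaps_interval <- function(segments, gene) {
  stopifnot(nrow(gene) == 1L)
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start, segments$end))
  gene_gr <- GenomicRanges::GRanges(
    gene$chrom, IRanges::IRanges(gene$start, gene$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, gene_gr)
  out <- logical(nrow(segments))
  out[S4Vectors::queryHits(hits)] <- TRUE
  out
}
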