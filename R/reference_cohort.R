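#' Reference cohort: 13 FH-deficient uterine leiomyomas
#'
#' The published per-sample variant and copy-number calls of a targeted-panel
#' study of 13 FH-deficient uterine leiomyomas (hg19, transcript
#' NM_000143.3), bundled as a worked example and test fixture. Eight samples
#' carry a single FH SNV/indel (with read counts and the printed allele
#' fractions), all carry at least one FH copy-number loss, and sample S05
#' shows the intratumoral-heterogeneity signature (depressed VAF of 0.443
#' together with an intermediate log2 ratio of -1.87). Sample S04
#' additionally carries two somatic TP53 variants whose VAFs anchor the
#' cohort purity estimate, and S07 a germline XPC variant.
#'
#' The `vaf` column reproduces the printed allele fractions, which can differ
#' from `alt_reads / total_reads` in the last printed digit.
#'
#' @return A list with elements
#'   \describe{
#'     \item{`variants`}{data.frame of SNVs/indels: `sample_id`, `gene`,
#'       `hgvs_c`, `consequence`, `alt_reads`, `total_reads`, `vaf`,
#'       `chrom`, `pos`, `likely_origin`.}
#'     \item{`segments`}{data.frame of FH copy-number segments: `sample_id`,
#'       `chrom`, `start`, `end`, `log2_ratio`, `printed_cn`.}
#'     \item{`gene`}{the FH gene interval (hg19).}
#'     \item{`purity`}{the assumed cohort tumor purity, 0.8.}
#'   }
#' @examples
#' cohort <- fh_ul_cohort()
#' median(cohort$variants$vaf[cohort$variants$gene == "FH"])  # 0.766
#' @export
fh_ul_cohort <- function() {
  variants <- data.frame(
    sample_id = c("S01", "S02", "S03", "S05", "S06", "S07", "S09", "S10",
                  "S04", "S04", "S07"),
    gene = c(rep("FH", 8), "TP53", "TP53", "XPC"),
    hgvs_c = c("c.944T>C", "c.587A>C", "c.379-2A>G", "c.587A>T", "c.457delG",
               "c.824G>C", "c.1236G>A", "c.817G>A",
               "c.782+1G>T", "c.309C>A", "c.1001C>A"),
    hgvs_p = c("p.(Leu315Pro)", "p.(His196Pro)", "p.0?", "p.(His196Leu)",
               "p.(Val153*)", "p.(Gly275Ala)", "p.[(Met412Ile);0?]",
               "p.(Ala273Thr)", "p.0?", "p.(Tyr103*)", "p.(Pro334His)"),
    consequence = c("missense", "missense", "splice", "missense", "frameshift",
                    "missense", "missense", "missense",
                    "splice", "nonsense", "missense"),
    alt_reads = c(137, 108, 110, 74, 153, 10, 104, 93, NA, NA, NA),
    total_reads = c(178, 140, 141, 167, 193, 19, 136, 154, NA, NA, NA),
    vaf = c(0.767, 0.771, 0.780, 0.443, 0.793, 0.526, 0.765, 0.604,
            0.408, 0.370, 0.560),
    chrom = c(rep("chr1", 8), "chr17", "chr17", "chr3"),
    pos = NA_integer_,
    likely_origin = c(rep("somatic", 10), "germline")
  )
  cn_strings <- c(
    S01 = "chr1:g.208278362_244894272x1",
    S02 = "chr1:g.221246882_247101663x1",
    S03 = "chr1:g.237286185_242686882x1",
    S04 = "chr1:g.237694880_243690241x0",
    S05 = "chr1:g.241661127_241677014x1",
    S06 = "chr1:g.206682236_249240121x1",
    S07 = "chr1:g.206482721_249240121x1",
    S09 = "chr1:g.208078846_249240121x1",
    S10 = "chr1:g.237490532_241884194x1",
    S11 = "chr1:g.240082627_242686882x0",
    S12 = "chr1:g.241661127_241677014x0",
    S12.2 = "chr1:g.241680481_243088226x0",
    S14 = "chr1:g.241266127_244292257x0",
    S16 = "chr1:g.238701877_242084866x0"
  )
  segments <- cbind(
    data.frame(sample_id = sub("\\..*$", "", names(cn_strings))),
    parse_cn_hgvs(unname(cn_strings))
  )
  names(segments)[names(segments) == "integer_cn"] <- "printed_cn"
  segments$log2_ratio <- c(-0.77, -0.85, -1.26, -9.97, -1.87, -1.02, -0.87,
                           -1.08, -0.9, -5.88, -9.97, -5.35, -5.31, -9.97)
  list(
    variants = variants,
    segments = segments,
    gene = gene_interval("FH", "chr1", 241660903, 241683061),
    purity = 0.8
  )
}
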