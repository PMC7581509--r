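#' Composition of a curated pathogenic variant set
#'
#' Restricts a population-variant table to (likely) pathogenic records (ACMG
#' classes 4 and 5) and tabulates the variant categories, with percentages
#' rounded to 0.1.
#'
#' @param records Data.frame with columns `acmg_class` (integer 1-5) and
#'   `category` (one of `truncating`, `splice`, `missense`,
#'   `inframe_indel`).
#' @param acmg_classes Classes counted as pathogenic (default `c(4, 5)`).
#' @return Data.frame `category`, `count`, `percent`.
#' @export
summarize_pathogenic_set <- function(records, acmg_classes = c(4, 5)) {
  lev <- c("truncating", "splice", "missense", "inframe_indel")
  path <- records[records$acmg_class %in% acmg_classes, , drop = FALSE]
  counts <- table(factor(path$category, levels = lev))
  total <- sum(counts)
  data.frame(
    category = lev,
    count = as.integer(counts),
    percent = if (total > 0) round(100 * as.integer(counts) / total, 1)
    else rep(0, length(lev))
  )
}

#' Population carrier frequency of pathogenic variants
#'
#' Aggregates per-variant allele counts into the expected fraction of
#' individuals carrying at least one pathogenic allele. In the rare-variant
#' approximation every pathogenic allele marks one carrier, so the default
#' estimator is
#' \deqn{CF = \sum_i AC_i / (AN_i / 2)}
#' where `AC_i`/`AN_i` are the allele count and allele number of variant `i`
#' and `AN_i / 2` the number of genotyped individuals. With
#' `count_hom_once = TRUE` homozygous individuals (who carry two alleles)
#' are counted once, i.e. `AC_i - hom_count_i` effective carrier alleles.
#' Records with `AN = 0` are skipped with a warning.
#'
#' @param records Data.frame with columns `allele_count`, `allele_number`,
#'   optionally `hom_count` and `acmg_class`.
#' @param acmg_classes Classes included (default `c(4, 5)`); set `NULL` to
#'   include all records.
#' @param count_hom_once Count homozygotes as a single carrier.
#' @return Carrier frequency as a fraction of individuals.
#' @examples
#' carrier_frequency(data.frame(allele_count = 2, allele_number = 10000,
#'                              hom_count = 0, acmg_class = 5))  # 4e-04
#' @export
carrier_frequency <- function(records, acmg_classes = c(4, 5),
                              count_hom_once = FALSE) {
  if (!is.null(acmg_classes) && !is.null(records$acmg_class)) {
    records <- records[records$acmg_class %in% acmg_classes, , drop = FALSE]
  }
  if (nrow(records) == 0) return(0)
  bad <- records$allele_number == 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with allele_number = 0 skipped")
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) return(0)
  hom <- if (!is.null(records$hom_count)) records$hom_count else 0
  ac <- if (count_hom_once) records$allele_count - hom else records$allele_count
  sum(ac / (records$allele_number / 2))
}

#' Expected population prevalence of a tumor subtype
#'
#' Product of the prevalence of the tumor entity and the proportion of the
#' subtype among them, e.g. lifetime uterine-leiomyoma prevalence times the
#' FH-deficient share.
#'
#' @param prev_ul Prevalence of the tumor entity, in `[0, 1]`.
#' @param prop_fhd_ul Proportion of the subtype among those tumors, `[0, 1]`.
#' @return Expected subtype prevalence (fraction).
#' @examples
#' expected_prevalence(0.70, 0.016)  # 0.0112, about 1.1%
#' @export
expected_prevalence <- function(prev_ul, prop_fhd_ul) {
  stopifnot(prev_ul >= 0, prev_ul <= 1, prop_fhd_ul >= 0, prop_fhd_ul <= 1)
  prev_ul * prop_fhd_ul
}

#' Expected germline-carrier fraction among subtype cases
#'
#' Under independence of carrier status and tumor occurrence, the fraction of
#' cases expected to carry a germline variant is the population carrier
#' frequency divided by the subtype prevalence. Values above 1 indicate the
#' independence assumption is violated and are flagged with a warning.
#'
#' @param carrier_freq Population carrier frequency (fraction).
#' @param prev_fhd_ul Subtype prevalence (fraction, > 0), e.g. from
#'   [expected_prevalence()].
#' @return Expected carrier fraction among cases.
#' @examples
#' germline_fraction_among_cases(1 / 3247, 0.7 * 0.016)  # about 2.7%
#' germline_fraction_among_cases(1 / 2563, 0.7 * 0.004)  # about 13.9%
#' @export
germline_fraction_among_cases <- function(carrier_freq, prev_fhd_ul) {
  stopifnot(prev_fhd_ul > 0, carrier_freq >= 0)
  out <- carrier_freq / prev_fhd_ul
  if (any(out > 1)) {
    warning("carrier fraction exceeds 1; independence assumption violated")
  }
  out
}

#' Fold enrichment of germline carriers in a screened series
#'
#' Ratio of the carrier rate observed in a screening series (`k` carriers of
#' `n` screened) to the population carrier frequency.
#'
#' @param k Number of carriers identified.
#' @param n Number of individuals screened (> 0).
#' @param carrier_freq Population carrier frequency (> 0).
#' @return Fold enrichment.
#' @examples
#' screening_enrichment(5, 2060, 1 / 2563)  # about 6.2
#' screening_enrichment(5, 2060, 1 / 3247)  # about 7.9
#' @export
screening_enrichment <- function(k, n, carrier_freq) {
  stopifnot(n > 0, carrier_freq > 0, k >= 0)
  (k / n) / carrier_freq
}

#' Probability of observing no carriers in a series
#'
#' Binomial probability `(1 - f)^n` of finding zero carriers among `n`
#' independent cases when each is a carrier with probability `f`.
#'
#' @param f Per-case carrier probability, `[0, 1]`.
#' @param n Number of cases.
#' @return Probability in `[0, 1]`.
#' @examples
#' prob_no_carriers(0.139, 13)  # about 0.143
#' @export
prob_no_carriers <- function(f, n) {
  stopifnot(f >= 0, f <= 1, n >= 0)
  (1 - f)^n
}

#' Upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, computed by exact summation of the
#' binomial mass function.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p Success probability, `[0, 1]`.
#' @return Tail probability.
#' @examples
#' binomial_tail(6, 8, 0.407)  # probability of >= 6 of 8 at baseline 40.7%
#' @export
binomial_tail <- function(k, n, p) {
  stopifnot(k >= 0, k <= n, p >= 0, p <= 1)
  if (k == 0) return(1)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}
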