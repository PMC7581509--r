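#' Expected variant allele fraction under loss of heterozygosity
#'
#' Predicts the variant allele fraction (VAF) observed in a tumor specimen for
#' a heterozygous point mutation whose second allele is lost somatically, as a
#' function of tumor purity. The model is
#' \deqn{AF = TP + (1 - TP) \cdot z}
#' where `TP` is the tumor purity (fraction of tumor cells in the specimen)
#' and `z` is the initial zygosity of the variant in normal cells: 0 for a
#' somatic variant (absent from normal cells) and 0.5 for a germline
#' heterozygous variant. Tumor cells are assumed to carry the variant on the
#' single remaining allele after the copy-number loss.
#'
#' This formula deliberately ignores the change of total allele count in
#' tumor cells (one allele after LOH, not two). A copy-number-aware
#' alternative, `AF_somatic = TP / (2 - TP)` and
#' `AF_germline = 1 / (2 - TP)`, is available via `cn_aware = TRUE` in
#' [classify_origin()] and [required_purity()].
#'
#' @param purity Tumor purity in `(0, 1]`. Vectorised.
#' @param zygosity Initial zygosity in normal cells: `0` (somatic) or
#'   `0.5` (germline heterozygous). Vectorised.
#' @return Numeric vector of expected VAFs, each in `[purity, 1]`.
#' @examples
#' expected_vaf(0.8, 0)    # somatic variant, pure LOH: 0.80
#' expected_vaf(0.8, 0.5)  # germline heterozygous variant: 0.90
#' @export
expected_vaf <- function(purity, zygosity = 0) {
  check_purity(purity)
  check_zygosity(zygosity)
  purity + (1 - purity) * zygosity
}

#' Tumor purity required to explain an observed VAF
#'
#' Algebraic inverse of [expected_vaf()]: the tumor purity that a germline
#' (`zygosity = 0.5`) or somatic (`zygosity = 0`) hypothesis would require to
#' produce the observed allele fraction, assuming LOH of the second allele.
#' Values outside `(0, 1]` are reported as-is and flagged infeasible rather
#' than clamped: an infeasible required purity is evidence against that
#' hypothesis.
#'
#' @param observed_vaf Observed variant allele fraction(s) in `[0, 1]`.
#' @param zygosity `0` (somatic hypothesis) or `0.5` (germline hypothesis).
#' @param cn_aware If `TRUE`, invert the copy-number-aware model instead
#'   (`TP = 2 vaf / (1 + vaf)` for somatic, `TP = 2 - 1/vaf` for germline).
#' @return A data.frame with columns `required_purity` and `feasible`
#'   (`TRUE` when the required purity lies in `(0, 1]`).
#' @examples
#' required_purity(0.75, zygosity = 0.5)   # 0.50
#' required_purity(0.443, zygosity = 0.5)  # -0.114, infeasible
#' @export
required_purity <- function(observed_vaf, zygosity = 0, cn_aware = FALSE) {
  stopifnot(is.numeric(observed_vaf), all(observed_vaf >= 0 & observed_vaf <= 1))
  check_zygosity(zygosity)
  n <- max(length(observed_vaf), length(zygosity))
  v <- rep_len(observed_vaf, n)
  z <- rep_len(zygosity, n)
  if (cn_aware) {
    tp <- ifelse(z == 0.5, 2 - 1 / v, 2 * v / (1 + v))
  } else {
    tp <- ifelse(z == 0.5, 2 * v - 1, v)
  }
  data.frame(required_purity = tp, feasible = tp > 0 & tp <= 1)
}

#' Estimate tumor purity from somatic heterozygous variant VAFs
#'
#' In a copy-neutral region, a clonal somatic heterozygous variant has
#' expected VAF `TP / 2`, so tumor purity is estimated as twice the observed
#' VAF per variant. VAFs above 0.5 imply purity above 1 and are flagged (they
#' indicate LOH, subclonal copy gain, or noise rather than a simple
#' heterozygous state).
#'
#' @param vafs Numeric vector of observed VAFs of somatic heterozygous
#'   variants, nominally in `(0, 0.5]`.
#' @return A list with `per_variant` (2 * vaf for each variant), `mean`
#'   (arithmetic mean of the per-variant estimates) and `flagged` (logical,
#'   `TRUE` where vaf > 0.5).
#' @examples
#' purity_from_somatic_het(c(0.408, 0.370))  # estimates 0.816, 0.740
#' @export
purity_from_somatic_het <- function(vafs) {
  if (length(vafs) == 0) stop("`vafs` must contain at least one VAF")
  stopifnot(is.numeric(vafs), all(vafs > 0 & vafs <= 1))
  est <- 2 * vafs
  list(per_variant = est, mean = mean(est), flagged = vafs > 0.5)
}

#' Classify variant origin (germline vs somatic) from VAF and purity
#'
#' Compares an observed VAF with the expectations of the somatic
#' (`expected_vaf(purity, 0)`) and germline-heterozygous
#' (`expected_vaf(purity, 0.5)`) hypotheses, both assuming somatic loss of the
#' second allele, and favours the hypothesis with the smaller absolute
#' residual. When the two residuals differ by less than `tolerance` the call
#' is `"ambiguous"`. Required purities under both hypotheses are reported so
#' that infeasible hypotheses (required purity outside `(0, 1]`) are visible.
#'
#' @param vaf Observed VAF(s) in `[0, 1]`. Vectorised.
#' @param purity Assumed tumor purity in `(0, 1]` (scalar or one per vaf).
#' @param tolerance Ambiguity band on the residual difference; default 0.05.
#' @param cn_aware If `TRUE`, use the copy-number-aware expectations
#'   `TP/(2-TP)` (somatic) and `1/(2-TP)` (germline).
#' @return A data.frame with one row per VAF: `vaf`, `purity_assumed`,
#'   `expected_somatic`, `expected_germline`, `favored_origin`
#'   (`"somatic"`, `"germline"` or `"ambiguous"`), `required_purity_somatic`,
#'   `somatic_feasible`, `required_purity_germline`, `germline_feasible`.
#' @examples
#' classify_origin(0.766, purity = 0.8)  # somatic
#' classify_origin(0.9, purity = 0.8)    # germline
#' @export
classify_origin <- function(vaf, purity = 0.8, tolerance = 0.05,
                            cn_aware = FALSE) {
  stopifnot(is.numeric(vaf), all(vaf >= 0 & vaf <= 1))
  check_purity(purity)
  stopifnot(length(purity) == 1L || length(purity) == length(vaf))
  stopifnot(is.numeric(tolerance), tolerance >= 0)
  if (cn_aware) {
    exp_s <- purity / (2 - purity)
    exp_g <- 1 / (2 - purity)
  } else {
    exp_s <- expected_vaf(purity, 0)
    exp_g <- expected_vaf(purity, 0.5)
  }
  r_s <- abs(vaf - exp_s)
  r_g <- abs(vaf - exp_g)
  favored <- ifelse(abs(r_s - r_g) < tolerance, "ambiguous",
                    ifelse(r_s < r_g, "somatic",
                           ifelse(r_g < r_s, "germline", "ambiguous")))
  rp_s <- required_purity(vaf, zygosity = 0, cn_aware = cn_aware)
  rp_g <- required_purity(vaf, zygosity = 0.5, cn_aware = cn_aware)
  data.frame(
    vaf = vaf,
    purity_assumed = rep_len(purity, length(vaf)),
    expected_somatic = rep_len(exp_s, length(vaf)),
    expected_germline = rep_len(exp_g, length(vaf)),
    favored_origin = favored,
    required_purity_somatic = rp_s$required_purity,
    somatic_feasible = rp_s$feasible,
    required_purity_germline = rp_g$required_purity,
    germline_feasible = rp_g$feasible
  )
}

## ---- internal argument checks -------------------------------------------

check_purity <- function(purity) {
  if (!is.numeric(purity) || any(!is.finite(purity)) ||
      any(purity <= 0 | purity > 1)) {
    stop("tumor purity must lie in (0, 1]")
  }
  invisible(purity)
}

check_zygosity <- function(zygosity) {
  if (!is.numeric(zygosity) || !all(zygosity %in% c(0, 0.5))) {
    stop("`zygosity` must be 0 (somatic) or 0.5 (germline heterozygous)")
  }
  invisible(zygosity)
}
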