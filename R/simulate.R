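#' Configuration for a synthetic tumor cohort
#'
#' Collects the generative parameters of the synthetic cohort: sample count,
#' tumor-purity range, mean sequencing depth, the mixture of two-hit
#' mechanisms at the target gene, and the log2-ratio noise. Defaults mirror a
#' 13-sample FH-deficient leiomyoma cohort: purities centred on 0.8
#' (macro-dissected specimens with >80% tumor cellularity), depths around
#' 150x, and mechanism weights 7/13 SNV+LOH, 5/13 biallelic deletion and
#' 1/13 heterogeneous.
#'
#' @param n_samples Number of samples (>= 0).
#' @param purity_range Length-2 interval in `(0, 1]`; per-sample purity is
#'   drawn uniformly from it.
#' @param depth_mean Mean read depth per variant (>= 1); realized depth is
#'   Poisson with a floor of 10 reads (the standard coverage filter).
#' @param mechanism_weights Named probabilities over `snv_plus_loh`,
#'   `biallelic_deletion`, `heterogeneous`, `germline_plus_loh`; must sum
#'   to 1.
#' @param log2_noise_sd Gaussian noise SD on segment log2 ratios.
#' @param gene Target gene interval (default: FH, hg19).
#' @param seed Integer seed used by [simulate_cohort()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 13,
                       purity_range = c(0.7, 0.9),
                       depth_mean = 150,
                       mechanism_weights = c(snv_plus_loh = 7 / 13,
                                             biallelic_deletion = 5 / 13,
                                             heterogeneous = 1 / 13,
                                             germline_plus_loh = 0),
                       log2_noise_sd = 0.15,
                       gene = gene_interval("FH", "chr1", 241660903, 241683061),
                       seed = 1L) {
  stopifnot(n_samples >= 0, n_samples == round(n_samples))
  stopifnot(length(purity_range) == 2, purity_range[1] <= purity_range[2])
  check_purity(purity_range)
  if (depth_mean < 1) stop("`depth_mean` must be >= 1")
  mech <- c("snv_plus_loh", "biallelic_deletion", "heterogeneous",
            "germline_plus_loh")
  if (!all(mech %in% names(mechanism_weights))) {
    stop("`mechanism_weights` must name all of: ", paste(mech, collapse = ", "))
  }
  mechanism_weights <- mechanism_weights[mech]
  if (any(mechanism_weights < 0) ||
      abs(sum(mechanism_weights) - 1) > 1e-9) {
    stop("`mechanism_weights` must be non-negative and sum to 1")
  }
  stopifnot(log2_noise_sd >= 0)
  structure(list(
    n_samples = as.integer(n_samples), purity_range = purity_range,
    depth_mean = depth_mean, mechanism_weights = mechanism_weights,
    log2_noise_sd = log2_noise_sd, gene = gene, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate one tumor sample
#'
#' Draws the variant calls and copy-number segments of a single sample from
#' the generative model, given its ground-truth label. Read counts at the
#' target variant are `Binomial(depth, TP + (1 - TP) * z)` with `z = 0`
#' (somatic) or `z = 0.5` (germline), assuming LOH of the second allele;
#' segment log2 ratios are `expected_log2(cn, TP)` plus Gaussian noise.
#' Heterogeneous samples mix two equal subclones -- one carrying the SNV plus
#' a monoallelic loss, one carrying an independent deletion of the other
#' allele -- which depresses the variant VAF to about `TP / 2` and places the
#' deletion log2 between the monoallelic and biallelic expectations. Each
#' sample also receives copy-neutral background segments and, with
#' probability 0.3, a passenger somatic heterozygous variant in another gene
#' (usable for purity estimation).
#'
#' Uses the current RNG state; seed via [simulate_cohort()] or `set.seed()`.
#'
#' @param config A [sim_config()].
#' @param label A one-row label: list or data.frame with `sample_id`,
#'   `mechanism`, `true_purity`.
#' @return A list with data.frames `variants` and `segments`.
#' @export
simulate_sample <- function(config, label) {
  stopifnot(inherits(config, "sim_config"))
  mech <- label$mechanism
  tp <- label$true_purity
  check_purity(tp)
  if (!mech %in% names(config$mechanism_weights)) {
    stop("unknown mechanism: ", mech)
  }
  gene <- config$gene
  id <- label$sample_id
  noise <- function() if (config$log2_noise_sd > 0)
    rnorm(1, 0, config$log2_noise_sd) else 0
  draw_depth <- function() max(10L, rpois(1, config$depth_mean))

  variants <- empty_variants()
  segments <- empty_segments()

  make_target_variant <- function(p_vaf, origin) {
    depth <- draw_depth()
    alt <- rbinom(1, depth, p_vaf)
    cons <- sample(c("missense", "frameshift", "splice"), 1,
                   prob = c(0.75, 0.125, 0.125))
    data.frame(sample_id = id, chrom = gene$chrom,
               pos = round(runif(1, gene$start, gene$end)),
               ref = sample(c("A", "C", "G", "T"), 1), alt = "N",
               alt_reads = alt, total_reads = depth, vaf = alt / depth,
               gene = gene$symbol, hgvs_c = NA_character_,
               consequence = cons, origin = origin)
  }
  make_target_segment <- function(log2_val, cn_true) {
    size <- round(10^runif(1, log10(15e3), log10(4.3e7)))
    width <- gene$end - gene$start
    start <- if (size >= width) {
      gene$start - round(runif(1) * (size - width))
    } else {
      gene$start + round(runif(1) * (width - size))
    }
    start <- max(1, start)
    end <- min(start + size, 249250621)  # chr1 length, hg19
    data.frame(sample_id = id, chrom = gene$chrom, start = start, end = end,
               log2_ratio = log2_val, integer_cn = NA_integer_,
               n_markers = max(3L, round((end - start) / 5e4)),
               true_cn = cn_true)
  }

  if (mech == "snv_plus_loh" || mech == "germline_plus_loh") {
    z <- if (mech == "germline_plus_loh") 0.5 else 0
    origin <- if (z == 0) "somatic" else "germline"
    variants <- rbind(variants, make_target_variant(expected_vaf(tp, z), origin))
    segments <- rbind(segments,
                      make_target_segment(expected_log2(1, tp) + noise(), 1L))
  } else if (mech == "biallelic_deletion") {
    segments <- rbind(segments,
                      make_target_segment(expected_log2(0, tp) + noise(), 0L))
  } else if (mech == "heterogeneous") {
    # two equal subclones: SNV+LOH (cn 1) and an independent deletion (cn 0)
    variants <- rbind(variants, make_target_variant(tp / 2, "somatic"))
    mix_ratio <- (tp / 2 * 1 + (1 - tp) * 2) / 2
    segments <- rbind(segments,
                      make_target_segment(log2(pmax(1e-3, mix_ratio)) + noise(), 1L))
  }

  # copy-neutral background segments on other chromosomes
  for (bg in list(c("chr2", 1e6, 5e7), c("chr13", 4.8e7, 5.0e7))) {
    segments <- rbind(segments, data.frame(
      sample_id = id, chrom = bg[1], start = as.numeric(bg[2]),
      end = as.numeric(bg[3]), log2_ratio = expected_log2(2, tp) + noise(),
      integer_cn = NA_integer_, n_markers = 50L, true_cn = 2L))
  }

  # passenger somatic heterozygous variant in a copy-neutral gene
  if (runif(1) < 0.3) {
    depth <- draw_depth()
    alt <- rbinom(1, depth, tp / 2)
    variants <- rbind(variants, data.frame(
      sample_id = id, chrom = "chr17", pos = round(runif(1, 7571720, 7590868)),
      ref = sample(c("A", "C", "G", "T"), 1), alt = "N", alt_reads = alt,
      total_reads = depth, vaf = alt / depth, gene = "TP53",
      hgvs_c = NA_character_, consequence = "missense", origin = "somatic"))
  }

  variants <- filter_variants(variants)
  list(variants = variants, segments = segments)
}

#' Simulate a labelled tumor cohort
#'
#' Generates `n_samples` tumors with per-sample ground truth: a mechanism of
#' biallelic target-gene inactivation, a tumor purity drawn uniformly from
#' `purity_range`, and the variant/segment tables implied by the generative
#' model (see [simulate_sample()]). With `assign = "quota"` (default) the
#' mechanism counts are fixed deterministically by largest-remainder
#' apportionment of the weights, so cohort composition is exactly
#' reproducible; `assign = "multinomial"` samples the mechanisms instead.
#'
#' @param config A [sim_config()].
#' @param assign `"quota"` or `"multinomial"`.
#' @return A list with data.frames `variants`, `segments` and `labels`
#'   (`sample_id`, `mechanism`, `true_purity`, `true_cn_at_gene`,
#'   `variant_origin`).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 4, seed = 7))
#' sim$labels
#' @export
simulate_cohort <- function(config, assign = c("quota", "multinomial")) {
  stopifnot(inherits(config, "sim_config"))
  assign <- match.arg(assign)
  set.seed(config$seed)
  n <- config$n_samples
  if (n == 0) {
    return(list(variants = empty_variants(), segments = empty_segments(),
                labels = empty_labels()))
  }
  w <- config$mechanism_weights
  mechanisms <- if (assign == "quota") {
    rep(names(w), quota_counts(w, n))
  } else {
    names(w)[sample.int(length(w), n, replace = TRUE, prob = w)]
  }
  labels <- data.frame(
    sample_id = sprintf("SIM%03d", seq_len(n)),
    mechanism = mechanisms,
    true_purity = runif(n, config$purity_range[1], config$purity_range[2]),
    true_cn_at_gene = ifelse(mechanisms == "biallelic_deletion", 0L, 1L),
    variant_origin = c(snv_plus_loh = "somatic",
                       biallelic_deletion = "none",
                       heterogeneous = "somatic",
                       germline_plus_loh = "germline")[mechanisms]
  )
  sims <- lapply(seq_len(n), function(i) {
    simulate_sample(config, labels[i, , drop = FALSE])
  })
  list(variants = do.call(rbind, c(list(empty_variants()),
                                   lapply(sims, `[[`, "variants"))),
       segments = do.call(rbind, c(list(empty_segments()),
                                   lapply(sims, `[[`, "segments"))),
       labels = labels)
}

#' Apply the standard read-support filters to a variant table
#'
#' Keeps variants with coverage of at least `min_depth` reads and an allele
#' fraction of at least `min_vaf` -- the filters under which panel variant
#' calls are considered reliable.
#'
#' @param variants Variant data.frame with `total_reads` and `vaf`.
#' @param min_depth Minimum coverage (default 10).
#' @param min_vaf Minimum allele fraction (default 0.10).
#' @return The filtered data.frame.
#' @export
filter_variants <- function(variants, min_depth = 10, min_vaf = 0.10) {
  if (is.null(variants) || nrow(variants) == 0) return(variants)
  variants[variants$total_reads >= min_depth & variants$vaf >= min_vaf, ,
           drop = FALSE]
}

#' Simulate a population variant table with known carrier frequency
#'
#' Stand-in for a population allele-frequency database annotated with a
#' curated pathogenic set. A share of the variants is (likely) pathogenic
#' (ACMG class 4/5); their per-variant allele frequencies are chosen to sum
#' to half the target carrier frequency (one carrier per allele), and allele
#' counts are drawn binomially at `allele_number = 2 * cohort_size`, so the
#' summed estimator of [carrier_frequency()] recovers `true_carrier_freq` in
#' expectation. Benign records (classes 1-3) carry arbitrary low frequencies
#' and must not contribute. Categories are assigned with probabilities
#' matching the composition of curated pathogenic sets (46.4% truncating,
#' 12.9% splice, 37.1% missense, 3.6% in-frame indel).
#'
#' @param n_variants Total number of variant records.
#' @param true_carrier_freq Target carrier frequency in `[0, 0.01]`.
#' @param cohort_size Number of genotyped individuals (>= 1).
#' @param seed Integer seed.
#' @param prop_pathogenic Share of records that are class 4/5 (default 0.6).
#' @return Data.frame: `chrom`, `pos`, `ref`, `alt`, `allele_count`,
#'   `allele_number`, `hom_count`, `acmg_class`, `category`.
#' @export
simulate_population_table <- function(n_variants, true_carrier_freq,
                                      cohort_size, seed = 1L,
                                      prop_pathogenic = 0.6) {
  if (cohort_size < 1) stop("`cohort_size` must be >= 1")
  stopifnot(n_variants >= 1, true_carrier_freq >= 0, true_carrier_freq <= 0.01)
  set.seed(seed)
  an <- 2 * cohort_size
  n_path <- max(1L, round(prop_pathogenic * n_variants))
  acmg <- c(sample(4:5, n_path, replace = TRUE),
            sample(1:3, n_variants - n_path, replace = TRUE))
  # per-variant allele frequencies: pathogenic ones sum to CF / 2
  share <- runif(n_path)
  f <- numeric(n_variants)
  f[seq_len(n_path)] <- true_carrier_freq / 2 * share / sum(share)
  if (n_variants > n_path) {
    f[(n_path + 1):n_variants] <- runif(n_variants - n_path, 0, 0.005)
  }
  ac <- rbinom(n_variants, an, f)
  hom <- rbinom(n_variants, ac %/% 2, f)  # rare-variant regime: almost all 0
  data.frame(
    chrom = "chr1",
    pos = sort(sample.int(22e6, n_variants)) + 241660000,
    ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
    alt = "N",
    allele_count = ac, allele_number = an, hom_count = hom,
    acmg_class = acmg,
    category = sample(c("truncating", "splice", "missense", "inframe_indel"),
                      n_variants, replace = TRUE,
                      prob = c(0.464, 0.129, 0.371, 0.036))
  )
}

#' Toy transcript, structure and domain fixtures
#'
#' Builds a small, fully consistent fixture set for testing the saturation
#' and clustering modules: a three-exon coding transcript (60 nt CDS with
#' start and stop codons and no internal stop), an ideal-helix C-alpha trace
#' over the 19-residue protein with a designated spatially tight residue
#' triple, and a toy domain map.
#'
#' @param seed Integer seed for the random internal codons.
#' @return A list with `transcript` (a [transcript_model()]), `structure`
#'   (a [structure_model()]), `domains` (data.frame `name`, `start`, `end`)
#'   and `tight_triple` (three consecutive residue numbers).
#' @export
make_toy_fixtures <- function(seed = 1L) {
  set.seed(seed)
  codons <- names(Biostrings::GENETIC_CODE)
  internal <- sample(codons[Biostrings::GENETIC_CODE != "*" &
                              codons != "ATG"], 18, replace = TRUE)
  cds <- paste0("ATG", paste(internal, collapse = ""), "TAA")
  # coding exon portions: 19 + 23 + 18 nt = 60 nt, introns of 100 nt
  widths <- c(19, 23, 18)
  starts <- cumsum(c(1001, head(widths, -1) + 100))
  exons <- data.frame(chrom = "chrT", start = starts,
                      end = starts + widths - 1)
  transcript <- transcript_model(cds, exons, strand = "+", chrom = "chrT",
                                 id = "TOY1")
  n_res <- nchar(transcript$protein_sequence)
  helix <- ideal_helix_structure(n_residues = n_res)
  helix$residues$aa <- strsplit(transcript$protein_sequence, "")[[1]]
  list(
    transcript = transcript,
    structure = helix,
    domains = data.frame(name = c("TransPep", "Lyase", "FumC-C"),
                         start = c(1, 5, 15), end = c(4, 14, n_res)),
    tight_triple = c(5L, 6L, 7L)
  )
}

## ---- internal ------------------------------------------------------------

# deterministic largest-remainder apportionment of weights into n counts
quota_counts <- function(w, n) {
  raw <- w * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

empty_variants <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = numeric(0), ref = character(0), alt = character(0),
             alt_reads = integer(0), total_reads = integer(0),
             vaf = numeric(0), gene = character(0), hgvs_c = character(0),
             consequence = character(0), origin = character(0))
}

empty_segments <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), log2_ratio = numeric(0),
             integer_cn = integer(0), n_markers = integer(0),
             true_cn = integer(0))
}

empty_labels <- function() {
  data.frame(sample_id = character(0), mechanism = character(0),
             true_purity = numeric(0), true_cn_at_gene = integer(0),
             variant_origin = character(0))
}
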