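test_that("simulation config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(purity_range = c(0, 0.8)), "purity")
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(mechanism_weights = c(snv_plus_loh = 0.6,
                                                biallelic_deletion = 0.6,
                                                heterogeneous = 0,
                                                germline_plus_loh = 0)),
               "sum to 1")
})

test_that("noiseless samples follow the generative model exactly", {
  cfg <- sim_config(log2_noise_sd = 0, depth_mean = 100000)
  set.seed(1)
  bi <- simulate_sample(cfg, list(sample_id = "B", mechanism = "biallelic_deletion",
                                  true_purity = 0.8))
  target <- bi$segments[bi$segments$chrom == cfg$gene$chrom, ]
  expect_equal(target$log2_ratio, log2(0.2), tolerance = 1e-12)
  expect_equal(sum(bi$variants$gene == cfg$gene$symbol), 0L)

  som <- simulate_sample(cfg, list(sample_id = "S", mechanism = "snv_plus_loh",
                                   true_purity = 0.8))
  tv <- som$variants[som$variants$gene == cfg$gene$symbol, ]
  # depth ~ 1e5: binomial VAF within 5 sd of the model expectation 0.8
  expect_lt(abs(tv$vaf - 0.8), 5 * sqrt(0.8 * 0.2 / tv$total_reads))

  ger <- simulate_sample(cfg, list(sample_id = "G",
                                   mechanism = "germline_plus_loh",
                                   true_purity = 0.8))
  gv <- ger$variants[ger$variants$gene == cfg$gene$symbol, ]
  expect_lt(abs(gv$vaf - 0.9), 5 * sqrt(0.9 * 0.1 / gv$total_reads))
  expect_equal(gv$origin, "germline")

  expect_error(simulate_sample(cfg, list(sample_id = "X", mechanism = "snv_plus_loh",
                                         true_purity = 1.2)),
               "purity")
})

test_that("quota assignment pins cohort composition exactly", {
  cfg <- sim_config(n_samples = 13,
                    mechanism_weights = c(snv_plus_loh = 8 / 13,
                                          biallelic_deletion = 5 / 13,
                                          heterogeneous = 0,
                                          germline_plus_loh = 0),
                    seed = 21)
  sim <- simulate_cohort(cfg, assign = "quota")
  expect_equal(sum(sim$labels$mechanism == "snv_plus_loh"), 8L)
  expect_equal(sum(sim$labels$mechanism == "biallelic_deletion"), 5L)
  # exactly the 8 SNV+LOH samples carry a target-gene SNV
  with_snv <- unique(sim$variants$sample_id[sim$variants$gene == "FH"])
  expect_setequal(with_snv,
                  sim$labels$sample_id[sim$labels$mechanism == "snv_plus_loh"])
})

test_that("seeded cohorts are bit-reproducible and n = 0 is empty", {
  cfg <- sim_config(n_samples = 10, seed = 77)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  empty <- simulate_cohort(sim_config(n_samples = 0))
  expect_equal(nrow(empty$variants), 0L)
  expect_equal(nrow(empty$segments), 0L)
  expect_equal(nrow(empty$labels), 0L)
})

test_that("simulated somatic VAFs are unbiased at purity 0.8", {
  cfg <- sim_config(n_samples = 0, log2_noise_sd = 0, depth_mean = 150)
  set.seed(123)
  vafs <- replicate(1000, {
    s <- simulate_sample(cfg, list(sample_id = "S",
                                   mechanism = "snv_plus_loh",
                                   true_purity = 0.8))
    s$variants$vaf[s$variants$gene == "FH"]
  })
  se <- sd(vafs) / sqrt(length(vafs))
  expect_lt(abs(mean(vafs) - 0.8), 3 * se)
})

test_that("read depths respect the Poisson model with a floor of 10", {
  cfg <- sim_config(depth_mean = 12, log2_noise_sd = 0)
  set.seed(2)
  depths <- replicate(300, {
    s <- simulate_sample(cfg, list(sample_id = "S",
                                   mechanism = "snv_plus_loh",
                                   true_purity = 0.9))
    s$variants$total_reads[s$variants$gene == "FH"]
  })
  expect_true(all(depths >= 10))
  expect_lt(abs(mean(depths) - mean(pmax(10, rpois(1e5, 12)))), 1)
})

test_that("population tables recover the target carrier frequency", {
  tab <- simulate_population_table(30, 1 / 3000, 60000, seed = 4)
  expect_true(all(tab$allele_count <= tab$allele_number))
  expect_true(all(2 * tab$hom_count <= tab$allele_count))
  est <- carrier_frequency(tab)
  se <- sqrt(2 * (1 / 3000) / 120000)  # binomial SE of the summed estimator
  expect_lt(abs(est - 1 / 3000), 3 * se)
  # unbiasedness: mean over 100 seeds within 3 SE of the mean
  ests <- vapply(1:100, function(s) {
    carrier_frequency(simulate_population_table(30, 1 / 3000, 60000, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1 / 3000), 3 * se / sqrt(100))
  # zero carrier frequency: no pathogenic alleles at all
  zero <- simulate_population_table(20, 0, 10000, seed = 1)
  expect_equal(sum(zero$allele_count[zero$acmg_class >= 4]), 0L)
  expect_error(simulate_population_table(10, 1e-3, 0), "cohort_size")
})

test_that("toy fixtures are internally consistent", {
  fx <- make_toy_fixtures(seed = 1)
  t <- fx$transcript
  expect_gte(nrow(t$exons), 3L)
  expect_equal(nchar(t$cds_sequence) %% 3, 0L)
  expect_equal(substr(t$cds_sequence, 1, 3), "ATG")
  expect_false(grepl("\\*", t$protein_sequence))
  expect_equal(nchar(t$protein_sequence), nrow(fx$structure$residues))
  # designated triple is tighter than the average random triple
  null_stats <- exhaustive_cluster_stats(fx$structure, 3)
  expect_lt(cluster_statistic(fx$tight_triple, fx$structure),
            mean(null_stats))
  expect_identical(make_toy_fixtures(seed = 5)$transcript$cds_sequence,
                   make_toy_fixtures(seed = 5)$transcript$cds_sequence)
})

test_that("the full chain recovers ground truth at high depth without noise", {
  cfg <- sim_config(n_samples = 30, purity_range = c(0.75, 0.85),
                    depth_mean = 20000, log2_noise_sd = 0,
                    mechanism_weights = c(snv_plus_loh = 0.5,
                                          biallelic_deletion = 0.3,
                                          heterogeneous = 0,
                                          germline_plus_loh = 0.2),
                    seed = 31)
  sim <- simulate_cohort(cfg)
  calls <- classify_cohort(sim$variants, sim$segments, cfg$gene, purity = 0.8)
  merged <- merge(calls, sim$labels, by = "sample_id")
  # mechanism recovery (germline_plus_loh presents as snv_plus_loh mechanically)
  mech_as_status <- ifelse(merged$mechanism == "germline_plus_loh",
                           "snv_plus_loh", merged$mechanism)
  expect_equal(merged$status, mech_as_status)
  # origin recovery from the VAFs at the per-sample true purity
  tv <- merge(sim$variants[sim$variants$gene == "FH", ], sim$labels,
              by = "sample_id")
  oc <- vapply(seq_len(nrow(tv)), function(i) {
    classify_origin(tv$vaf[i], purity = tv$true_purity[i])$favored_origin
  }, character(1))
  expect_equal(oc, tv$variant_origin)
})
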