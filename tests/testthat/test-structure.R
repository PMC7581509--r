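test_that("helix fixture has the designed C-alpha geometry", {
  helix <- ideal_helix_structure(20)
  xyz <- as.matrix(helix$residues[, c("x", "y", "z")])
  spacing <- sqrt(rowSums((xyz[-1, ] - xyz[-20, ])^2))
  expect_true(all(abs(spacing - 3.8) < 0.01))
})

test_that("cluster statistic is the mean pairwise distance", {
  two <- structure_model(data.frame(chain = "A", resno = 1:2, aa = "A",
                                    x = c(0, 3.8), y = 0, z = 0))
  expect_equal(cluster_statistic(1:2, two), 3.8)
  three <- structure_model(data.frame(chain = "A", resno = 1:3, aa = "A",
                                      x = c(0, 3.8, 7.6), y = 0, z = 0))
  expect_equal(cluster_statistic(1:3, three), mean(c(3.8, 3.8, 7.6)))
  expect_error(cluster_statistic(c(1, 1, 2), three), "duplicated")
  expect_error(cluster_statistic(c(1, 99), three), "not in structure")
})

test_that("cluster statistic is invariant under rigid motion", {
  helix <- ideal_helix_structure(20)
  obs <- cluster_statistic(c(5, 6, 7), helix)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- helix
  xyz <- as.matrix(moved$residues[, c("x", "y", "z")]) %*% rot
  moved$residues$x <- xyz[, 1] + 100
  moved$residues$y <- xyz[, 2] - 42
  moved$residues$z <- xyz[, 3] + 7
  expect_equal(cluster_statistic(c(5, 6, 7), moved), obs, tolerance = 1e-9)
})

test_that("bootstrap p matches exhaustive enumeration on the toy helix", {
  helix <- ideal_helix_structure(20)
  null_stats <- exhaustive_cluster_stats(helix, 3)  # all C(20,3) = 1140 triples
  expect_equal(length(null_stats), choose(20, 3))
  obs <- cluster_statistic(c(5, 6, 7), helix)
  p_exact <- mean(null_stats <= obs + 1e-9)
  res <- bootstrap_pvalue(c(5, 6, 7), helix, n_bootstrap = 10000, seed = 42)
  mc_tol <- 2 * sqrt(p_exact * (1 - p_exact) / res$n_bootstrap) +
    1 / (res$n_bootstrap + 1)  # Monte-Carlo error + add-one bias
  expect_lt(abs(res$p_empirical - p_exact), mc_tol)
})

test_that("bootstrap p is reproducible, add-one corrected, and monotone", {
  helix <- ideal_helix_structure(20)
  a <- bootstrap_pvalue(c(5, 6, 7), helix, n_bootstrap = 500, seed = 7)
  b <- bootstrap_pvalue(c(5, 6, 7), helix, n_bootstrap = 500, seed = 7)
  expect_identical(a$p_empirical, b$p_empirical)
  expect_gt(a$p_empirical, 0)
  # the whole structure resamples itself: p must be exactly 1
  whole <- bootstrap_pvalue(1:20, helix, n_bootstrap = 200, seed = 1)
  expect_equal(whole$p_empirical, 1.0)
  # tighter sets get smaller p than spread sets
  tight <- bootstrap_pvalue(c(5, 6, 7), helix, n_bootstrap = 2000, seed = 3)
  spread <- bootstrap_pvalue(c(2, 10, 18), helix, n_bootstrap = 2000, seed = 3)
  expect_lt(tight$p_empirical, spread$p_empirical)
  expect_error(bootstrap_pvalue(1:25, helix, n_bootstrap = 200),
               "not in structure")
})

test_that("empirical p is uniform under the null", {
  helix <- ideal_helix_structure(20)
  set.seed(9)
  ps <- replicate(200, {
    bootstrap_pvalue(sample(1:20, 3), helix, n_bootstrap = 199)$p_empirical
  })
  ks_d <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  # 1% Kolmogorov-Smirnov critical value plus the p-grid discreteness
  expect_lt(ks_d, 1.628 / sqrt(200) + 1 / 200)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("colocalization separates near from far residue sets", {
  helix <- ideal_helix_structure(20)
  near <- colocalization_test(c(10, 11), c(9, 12), helix,
                              n_bootstrap = 10000, seed = 1)
  expect_lt(near$p_empirical, 0.05)
  far <- colocalization_test(c(10, 11), c(1, 20), helix,
                             n_bootstrap = 10000, seed = 1)
  expect_gt(far$p_empirical, 0.5)
  # B = everything but A resamples itself: p = 1
  all_b <- colocalization_test(c(10, 11), setdiff(1:20, c(10, 11)), helix,
                               n_bootstrap = 200, seed = 2)
  expect_equal(all_b$p_empirical, 1.0)
  expect_error(colocalization_test(c(1, 2), c(2, 3), helix, 200), "disjoint")
})

test_that("PDB round trip preserves the C-alpha trace", {
  helix <- toy$structure
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  write_structure_pdb(helix, path)
  back <- read_structure_pdb(path)
  expect_equal(back$residues$resno, helix$residues$resno)
  expect_equal(back$residues$aa, helix$residues$aa)
  expect_equal(back$residues$x, helix$residues$x, tolerance = 1e-3)
  expect_equal(back$residues$z, helix$residues$z, tolerance = 1e-3)
  expect_equal(cluster_statistic(toy$tight_triple, back),
               cluster_statistic(toy$tight_triple, helix), tolerance = 1e-3)
})

test_that("structure model rejects malformed input", {
  expect_error(structure_model(data.frame(chain = "A", resno = c(1, 1),
                                          aa = "A", x = 0, y = 0, z = 0)),
               "duplicated")
  expect_error(structure_model(data.frame(chain = "A", resno = 1:2, aa = "A",
                                          x = c(0, Inf), y = 0, z = 0)),
               "finite")
})
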