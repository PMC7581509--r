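# shared fixtures, built in code at test time

toy <- make_toy_fixtures(seed = 1)

# exhaustive null distribution of the clustering statistic on a structure:
# mean pairwise CA distance of every k-subset (independent oracle)
exhaustive_cluster_stats <- function(s, k) {
  D <- as.matrix(dist(as.matrix(s$residues[, c("x", "y", "z")])))
  apply(combn(nrow(s$residues), k), 2, function(idx) {
    sum(D[idx, idx]) / (k * (k - 1))
  })
}
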