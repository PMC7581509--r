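#' Build a protein structure model from C-alpha coordinates
#'
#' A minimal residue-level representation of a protein structure: one
#' C-alpha coordinate per residue. Used for spatial clustering of mutated
#' residues.
#'
#' @param residues Data.frame with columns `chain`, `resno`, `aa` (one-letter
#'   code) and `x`, `y`, `z` (Angstrom). `(chain, resno)` pairs must be
#'   unique and coordinates finite.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(residues) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "resno", "aa", "x", "y", "z") %in% names(residues)))
  key <- paste(residues$chain, residues$resno)
  if (anyDuplicated(key)) stop("duplicated (chain, resno) in structure")
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure")
  }
  residues <- residues[order(residues$chain, residues$resno), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(residues = residues), class = "structure_model")
}

#' @method print structure_model
#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d chain(s)\n",
              nrow(x$residues), length(unique(x$residues$chain))))
  invisible(x)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Parses ATOM records with \pkg{bio3d}, keeps C-alpha atoms (first
#' alternate location per residue) and optionally filters to one chain.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier(s) to keep.
#' @return A [structure_model()].
#' @export
read_structure_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no C-alpha atoms found in ", path)
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno)), , drop = FALSE]
  structure_model(data.frame(
    chain = atoms$chain, resno = atoms$resno,
    aa = bio3d::aa321(atoms$resid),
    x = atoms$x, y = atoms$y, z = atoms$z
  ))
}

#' Write a structure model as PDB ATOM records
#'
#' Emits one C-alpha ATOM record per residue in fixed-width PDB format.
#'
#' @param s A [structure_model()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  r <- s$residues
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(r)), bio3d::aa123(r$aa), r$chain, r$resno, r$x, r$y, r$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Mean pairwise C-alpha distance of a residue set
#'
#' The spatial-clustering statistic: the mean Euclidean distance between all
#' pairs of C-alpha atoms of the given residues. Smaller values indicate
#' tighter spatial clustering.
#'
#' @param residues Residue identifiers: integer residue numbers (when the
#'   structure has a single chain, or numbers are unambiguous) or strings
#'   `"chain:resno"`. Duplicates are an error.
#' @param s A [structure_model()].
#' @return Mean pairwise distance in Angstrom.
#' @export
cluster_statistic <- function(residues, s) {
  idx <- resolve_residues(residues, s)
  if (length(idx) < 2) stop("need at least two residues")
  coords <- as.matrix(s$residues[idx, c("x", "y", "z")])
  mean(dist(coords))
}

#' Empirical bootstrap p-value for spatial clustering
#'
#' Compares the observed mean pairwise C-alpha distance of a residue set with
#' a null distribution obtained by resampling the same number of
#' \emph{distinct} residues uniformly from the whole structure. The p-value
#' uses the add-one correction
#' `p = (1 + #\{boot <= observed\}) / (n_bootstrap + 1)` and therefore never
#' returns 0.
#'
#' @param residues Observed residue identifiers (see [cluster_statistic()]).
#' @param s A [structure_model()].
#' @param n_bootstrap Number of bootstrap replicates (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `cluster_result`: a list with
#'   `observed_statistic`, `n_bootstrap`, `p_empirical`, `seed`,
#'   `residues_used`.
#' @export
bootstrap_pvalue <- function(residues, s, n_bootstrap = 1000, seed = NULL) {
  stopifnot(n_bootstrap >= 100)
  if (!is.null(seed)) set.seed(seed)
  idx <- resolve_residues(residues, s)
  k <- length(idx)
  n <- nrow(s$residues)
  if (k < 2) stop("need at least two residues")
  if (k > n) stop("more residues requested than present in the structure")
  D <- structure_distmat(s)
  obs <- subset_mean_dist(D, idx)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    subset_mean_dist(D, sample.int(n, k))
  }, numeric(1))
  p <- (1 + sum(boot <= obs + 1e-9)) / (n_bootstrap + 1)
  structure(list(observed_statistic = obs, n_bootstrap = n_bootstrap,
                 p_empirical = p, seed = seed,
                 residues_used = s$residues$resno[idx]),
            class = "cluster_result")
}

#' Colocalization of one residue set with another
#'
#' Tests whether set B lies unusually close to a fixed set A: the statistic
#' is the mean, over residues in B, of the minimum C-alpha distance to any
#' residue of A. The null resamples B (same size, distinct residues) from
#' the structure excluding A, keeping A fixed; the add-one empirical p-value
#' is reported.
#'
#' @param set_a,set_b Disjoint, non-empty residue identifier vectors.
#' @param s A [structure_model()].
#' @param n_bootstrap Number of replicates (>= 100).
#' @param seed Optional integer seed.
#' @return A `cluster_result` (see [bootstrap_pvalue()]).
#' @export
colocalization_test <- function(set_a, set_b, s, n_bootstrap = 1000,
                                seed = NULL) {
  stopifnot(n_bootstrap >= 100)
  if (!is.null(seed)) set.seed(seed)
  ia <- resolve_residues(set_a, s)
  ib <- resolve_residues(set_b, s)
  if (!length(ia) || !length(ib)) stop("both residue sets must be non-empty")
  if (length(intersect(ia, ib))) stop("residue sets must be disjoint")
  D <- structure_distmat(s)
  stat <- function(bidx) mean(apply(D[bidx, ia, drop = FALSE], 1, min))
  obs <- stat(ib)
  pool <- setdiff(seq_len(nrow(s$residues)), ia)
  if (length(ib) > length(pool)) stop("set B larger than structure minus A")
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    stat(sample(pool, length(ib)))
  }, numeric(1))
  p <- (1 + sum(boot <= obs + 1e-9)) / (n_bootstrap + 1)
  structure(list(observed_statistic = obs, n_bootstrap = n_bootstrap,
                 p_empirical = p, seed = seed,
                 residues_used = s$residues$resno[ib]),
            class = "cluster_result")
}

#' @method print cluster_result
#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> statistic = %.3f A, p = %.4g (%d bootstrap replicates)\n",
    x$observed_statistic, x$p_empirical, x$n_bootstrap))
  invisible(x)
}

#' Ideal alpha-helix C-alpha trace
#'
#' Generates an idealized alpha-helical C-alpha trace (rise 1.5 A and 100
#' degrees of rotation per residue); the helix radius is chosen so that
#' consecutive C-alpha atoms are exactly `ca_spacing` apart. Useful as a toy
#' structure with known geometry for clustering tests.
#'
#' @param n_residues Number of residues.
#' @param rise Rise per residue in Angstrom.
#' @param turn_deg Rotation per residue in degrees.
#' @param ca_spacing Consecutive C-alpha distance in Angstrom.
#' @param chain Chain identifier.
#' @return A [structure_model()] with residues numbered 1..n.
#' @export
ideal_helix_structure <- function(n_residues = 20, rise = 1.5,
                                  turn_deg = 100, ca_spacing = 3.8,
                                  chain = "A") {
  stopifnot(n_residues >= 2, ca_spacing > rise)
  theta <- turn_deg * pi / 180
  radius <- sqrt(ca_spacing^2 - rise^2) / (2 * sin(theta / 2))
  i <- seq_len(n_residues) - 1
  structure_model(data.frame(
    chain = chain, resno = seq_len(n_residues), aa = "A",
    x = radius * cos(i * theta), y = radius * sin(i * theta), z = i * rise
  ))
}

## ---- internal ------------------------------------------------------------

# map residue identifiers to row indices of s$residues
resolve_residues <- function(residues, s) {
  r <- s$residues
  if (anyDuplicated(residues)) stop("duplicated residue identifiers")
  if (is.character(residues) && any(grepl(":", residues))) {
    key <- paste(r$chain, r$resno, sep = ":")
    idx <- match(residues, key)
  } else {
    residues <- as.integer(residues)
    if (anyDuplicated(r$resno)) {
      stop("residue numbers are ambiguous across chains; use \"chain:resno\"")
    }
    idx <- match(residues, r$resno)
  }
  if (anyNA(idx)) {
    stop("residue(s) not in structure: ",
         paste(residues[is.na(idx)], collapse = ", "))
  }
  idx
}

# full pairwise distance matrix, cached on the structure's environment
structure_distmat <- function(s) {
  as.matrix(dist(as.matrix(s$residues[, c("x", "y", "z")])))
}

subset_mean_dist <- function(D, idx) {
  k <- length(idx)
  sum(D[idx, idx]) / (k * (k - 1))
}
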