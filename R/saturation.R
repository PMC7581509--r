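#' Build a coding transcript model
#'
#' Couples a coding sequence (CDS) with the exon structure that carries it.
#' The exon table gives the genomic intervals of the \emph{coding} portions of
#' each exon (1-based, inclusive); their widths must sum to the CDS length.
#' For minus-strand transcripts the CDS walks the exons in descending genomic
#' order. The CDS must start with ATG, end with a stop codon, have length
#' divisible by 3, and contain no internal stop codon; it is translated with
#' the standard nuclear code.
#'
#' @param cds_sequence Character scalar, the coding sequence (A/C/G/T).
#' @param exons Data.frame with columns `start`, `end` (genomic, 1-based
#'   inclusive); optional `chrom`.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name (optional, for export).
#' @param id Transcript identifier.
#' @return An object of class `transcript_model`: a list with `id`, `strand`,
#'   `chrom`, `exons` (sorted by genomic start), `cds_sequence`,
#'   `protein_sequence` (without the terminal stop), `exon_widths` (in CDS
#'   walk order) and `exon_boundary_cds_positions` (data.frame
#'   `last_base`/`first_base` CDS coordinates of the internal junctions).
#' @export
transcript_model <- function(cds_sequence, exons, strand = c("+", "-"),
                             chrom = NA_character_, id = "transcript") {
  strand <- match.arg(strand)
  cds_sequence <- toupper(cds_sequence)
  if (!grepl("^[ACGT]+$", cds_sequence)) stop("CDS must contain only A/C/G/T")
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds_sequence, 1, 3) != "ATG") stop("CDS must start with ATG")
  aa <- translate_cds(cds_sequence)
  if (substr(aa, nchar(aa), nchar(aa)) != "*") {
    stop("CDS must end with a stop codon")
  }
  if (grepl("\\*", substr(aa, 1, nchar(aa) - 1))) {
    stop("CDS contains an internal stop codon")
  }
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (any(exons$end < exons$start)) stop("exon end must be >= start")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must not overlap")
  }
  widths <- exons$end - exons$start + 1
  if (sum(widths) != n) {
    stop("sum of exon widths (", sum(widths), ") must equal CDS length (", n, ")")
  }
  walk_widths <- if (strand == "+") widths else rev(widths)
  cw <- cumsum(walk_widths)
  k <- length(walk_widths)
  boundaries <- if (k > 1) {
    data.frame(last_base = cw[-k], first_base = cw[-k] + 1)
  } else {
    data.frame(last_base = integer(0), first_base = integer(0))
  }
  structure(list(
    id = id, strand = strand, chrom = chrom, exons = exons,
    cds_sequence = cds_sequence,
    protein_sequence = substr(aa, 1, nchar(aa) - 1),
    exon_widths = walk_widths,
    exon_boundary_cds_positions = boundaries
  ), class = "transcript_model")
}

#' @method print transcript_model
#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s strand): %d exons, CDS %d nt, protein %d aa\n",
              x$id, x$strand, nrow(x$exons), nchar(x$cds_sequence),
              nchar(x$protein_sequence)))
  invisible(x)
}

#' Enumerate every coding SNV reachable by a single base exchange
#'
#' Saturation single-nucleotide mutagenesis of a transcript: for each CDS
#' position, all three alternative bases are generated and classified by the
#' resulting codon substitution (standard nuclear code). Any substitution in
#' the start codon is `start_lost` regardless of the encoded amino acid.
#' Substitutions in the stop codon are `stop_lost` when they abolish the stop
#' and `synonymous` when they exchange one stop codon for another. Positions
#' at internal exon junctions are flagged: the exact terminal coding base as
#' `last_base`/`first_base` and the adjacent `splice_flank - 1` bases as
#' `near_terminal` (a base exchange there can disrupt the splice consensus
#' even when the codon consequence looks benign, e.g. a "missense" at the
#' last base of an exon).
#'
#' @param transcript A [transcript_model()].
#' @param splice_flank Number of coding bases at each internal exon end
#'   considered splice-relevant (default 3).
#' @return Data.frame with `3 * nchar(cds)` rows: `cds_pos`, `ref_base`,
#'   `alt_base`, `codon_index`, `protein_pos`, `aa_ref`, `aa_alt`,
#'   `consequence` (one of `synonymous`, `missense`, `nonsense`,
#'   `stop_lost`, `start_lost`), `exon_terminal_flag` (`none`, `first_base`,
#'   `last_base`, `near_terminal`), `hgvs_c`, `hgvs_p`.
#' @examples
#' t <- transcript_model("ATGAAATAA",
#'                       data.frame(start = c(1, 101, 201),
#'                                  end = c(3, 103, 203)))
#' nrow(enumerate_coding_snvs(t))  # 27
#' @export
enumerate_coding_snvs <- function(transcript, splice_flank = 3) {
  stopifnot(inherits(transcript, "transcript_model"))
  cds <- strsplit(transcript$cds_sequence, "")[[1]]
  n <- length(cds)
  bases <- c("A", "C", "G", "T")

  cds_pos <- rep(seq_len(n), each = 3)
  ref <- cds[cds_pos]
  alt <- unlist(lapply(cds, function(b) setdiff(bases, b)), use.names = FALSE)

  codon_index <- (cds_pos - 1) %/% 3 + 1
  codon_offset <- (cds_pos - 1) %% 3 + 1
  codon_start <- (codon_index - 1) * 3
  ref_codon <- paste0(cds[codon_start + 1], cds[codon_start + 2],
                      cds[codon_start + 3])
  alt_codon <- ref_codon
  substr(alt_codon, codon_offset, codon_offset) <- alt

  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])

  consequence <- ifelse(codon_index == 1, "start_lost",
                 ifelse(aa_ref == "*" & aa_alt == "*", "synonymous",
                 ifelse(aa_ref == "*", "stop_lost",
                 ifelse(aa_alt == "*", "nonsense",
                 ifelse(aa_ref == aa_alt, "synonymous", "missense")))))

  b <- transcript$exon_boundary_cds_positions
  flag <- rep("none", length(cds_pos))
  if (nrow(b)) {
    near <- rep(FALSE, length(cds_pos))
    for (i in seq_len(nrow(b))) {
      near <- near |
        (cds_pos > b$last_base[i] - splice_flank & cds_pos < b$last_base[i]) |
        (cds_pos > b$first_base[i] & cds_pos < b$first_base[i] + splice_flank)
    }
    flag[near] <- "near_terminal"
    flag[cds_pos %in% b$last_base] <- "last_base"
    flag[cds_pos %in% b$first_base] <- "first_base"
  }

  data.frame(
    cds_pos = cds_pos, ref_base = ref, alt_base = alt,
    codon_index = codon_index, protein_pos = ceiling(cds_pos / 3),
    aa_ref = aa_ref, aa_alt = aa_alt, consequence = consequence,
    exon_terminal_flag = flag,
    hgvs_c = sprintf("c.%d%s>%s", cds_pos, ref, alt),
    hgvs_p = hgvs_p_string(ceiling(cds_pos / 3), aa_ref, aa_alt, consequence)
  )
}

#' Annotate coding SNVs with their protein domain
#'
#' Labels each variant with the domain containing its protein position, or
#' `"inter-domain"` when no domain covers it. Domain residue ranges are
#' configuration supplied by the user, not package constants.
#'
#' @param snvs Data.frame with a `protein_pos` column (e.g. from
#'   [enumerate_coding_snvs()]); note the enumeration includes the stop
#'   codon at `protein_length + 1`, which should be dropped before mapping.
#' @param domains Data.frame with columns `name`, `start`, `end` (residue
#'   coordinates, non-overlapping). May have zero rows.
#' @param protein_length Protein length in residues; positions beyond it are
#'   an error.
#' @return `snvs` with an added `domain` column.
#' @export
annotate_domains <- function(snvs, domains, protein_length) {
  check_domains(domains, protein_length)
  if (any(snvs$protein_pos > protein_length | snvs$protein_pos < 1)) {
    stop("protein_pos beyond protein length")
  }
  domain <- rep("inter-domain", nrow(snvs))
  for (i in seq_len(nrow(domains))) {
    hit <- snvs$protein_pos >= domains$start[i] &
      snvs$protein_pos <= domains$end[i]
    domain[hit] <- domains$name[i]
  }
  snvs$domain <- domain
  snvs
}

#' Test enrichment of observed residues in a protein domain
#'
#' One-sided Fisher exact (hypergeometric) test of whether observed mutated
#' residues fall inside a domain more often than expected for residues drawn
#' uniformly from the protein. The 2x2 table crosses observed vs all other
#' residues with in-domain vs outside.
#'
#' @param observed_residues Integer vector of mutated residue positions
#'   (duplicates are collapsed).
#' @param domain Name of the domain to test.
#' @param domains Domain table (see [annotate_domains()]).
#' @param protein_length Protein length in residues.
#' @return A list with `p_value`, `odds_ratio`, `n_in_domain`, `n_observed`,
#'   `domain_length` and `table` (the 2x2 matrix).
#' @export
domain_enrichment_test <- function(observed_residues, domain, domains,
                                   protein_length) {
  check_domains(domains, protein_length)
  row <- domains[domains$name == domain, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown domain: ", domain)
  m <- row$end - row$start + 1
  if (m < 1) stop("zero-length domain")
  res <- unique(observed_residues)
  if (any(res < 1 | res > protein_length)) {
    stop("observed residues beyond protein length")
  }
  k <- length(res)
  x_in <- sum(res >= row$start & res <= row$end)
  if (k == 0) {
    return(list(p_value = 1, odds_ratio = NA_real_, n_in_domain = 0L,
                n_observed = 0L, domain_length = m, table = NULL))
  }
  tab <- matrix(c(x_in, m - x_in,
                  k - x_in, (protein_length - m) - (k - x_in)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_domain", "outside"),
                                c("observed", "other")))
  ft <- fisher.test(tab, alternative = "greater")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       n_in_domain = x_in, n_observed = k, domain_length = m, table = tab)
}

#' Windowed mean score profile along a protein
#'
#' Aggregates per-variant scores (e.g. computational pathogenicity scores for
#' all possible missense variants) into a per-residue profile: scores at the
#' same residue are averaged, residues without any score contribute 0, and a
#' centered moving-average window (truncated at the protein ends) smooths the
#' result.
#'
#' @param scores Data.frame with columns `protein_pos` and `score`.
#' @param window Odd window width in residues (>= 1).
#' @param protein_length Length of the profile; defaults to the largest
#'   scored position.
#' @return Data.frame `protein_pos`, `score` with `protein_length` rows
#'   (zero rows for empty input).
#' @export
windowed_score_profile <- function(scores, window = 1, protein_length = NULL) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (is.null(scores) || nrow(scores) == 0) {
    return(data.frame(protein_pos = integer(0), score = numeric(0)))
  }
  if (is.null(protein_length)) protein_length <- max(scores$protein_pos)
  base <- numeric(protein_length)
  agg <- tapply(scores$score, scores$protein_pos, mean)
  base[as.integer(names(agg))] <- agg
  h <- (window - 1) / 2
  prof <- vapply(seq_len(protein_length), function(i) {
    mean(base[max(1, i - h):min(protein_length, i + h)])
  }, numeric(1))
  data.frame(protein_pos = seq_len(protein_length), score = prof)
}

## ---- internal ------------------------------------------------------------

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

check_domains <- function(domains, protein_length) {
  stopifnot(is.data.frame(domains),
            all(c("name", "start", "end") %in% names(domains)) ||
              nrow(domains) == 0)
  if (nrow(domains) == 0) return(invisible(domains))
  if (any(domains$start < 1 | domains$end > protein_length |
          domains$end < domains$start)) {
    stop("domains must lie within the protein and have end >= start")
  }
  d <- domains[order(domains$start), , drop = FALSE]
  if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
    stop("domains must not overlap")
  }
  invisible(domains)
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

hgvs_p_string <- function(protein_pos, aa_ref, aa_alt, consequence) {
  ref3 <- unname(AA3[aa_ref])
  alt3 <- unname(AA3[aa_alt])
  out <- sprintf("p.(%s%d%s)", ref3, protein_pos, alt3)
  out[consequence == "synonymous"] <-
    sprintf("p.(%s%d=)", ref3, protein_pos)[consequence == "synonymous"]
  out[consequence == "start_lost"] <- "p.(Met1?)"
  out
}
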