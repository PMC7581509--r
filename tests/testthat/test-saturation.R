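test_that("transcript model validates its coding sequence", {
  ex3 <- data.frame(start = c(1, 101, 201), end = c(3, 103, 203))
  expect_s3_class(transcript_model("ATGAAATAA", ex3), "transcript_model")
  expect_error(transcript_model("ATGAAATA", data.frame(start = 1, end = 8)),
               "divisible")
  expect_error(transcript_model("ATGTAAAAATAA",
                                data.frame(start = 1, end = 12)),
               "internal stop")
  expect_error(transcript_model("ATGAAAAAA", data.frame(start = 1, end = 9)),
               "stop codon")
  expect_error(transcript_model("ATGAAATAA", data.frame(start = 1, end = 6)),
               "exon widths")
})

test_that("saturation enumeration yields 3 variants per base, partitioned", {
  t <- transcript_model("ATGAAATAA",
                        data.frame(start = c(1, 101, 201),
                                   end = c(3, 103, 203)))
  snvs <- enumerate_coding_snvs(t)
  expect_equal(nrow(snvs), 27L)
  expect_equal(sum(table(snvs$consequence)), 27L)
  # c.4A>G: AAA -> GAA, Lys2Glu
  hit <- snvs[snvs$hgvs_c == "c.4A>G", ]
  expect_equal(hit$consequence, "missense")
  expect_equal(hit$protein_pos, 2L)
  expect_equal(hit$aa_ref, "K")
  expect_equal(hit$aa_alt, "E")
  expect_equal(hit$hgvs_p, "p.(Lys2Glu)")
  # all 9 start-codon substitutions are start_lost
  expect_equal(sum(snvs$consequence == "start_lost"), 9L)
  # TAA -> TGA/TAG remain synonymous stops; other stop edits are stop_lost
  stop_rows <- snvs[snvs$codon_index == 3, ]
  expect_equal(sum(stop_rows$consequence == "synonymous"), 2L)
  expect_equal(sum(stop_rows$consequence == "stop_lost"), 7L)
})

test_that("exon-terminal coding bases are flagged for splice relevance", {
  snvs <- enumerate_coding_snvs(toy$transcript)
  b <- toy$transcript$exon_boundary_cds_positions
  expect_equal(unique(snvs$cds_pos[snvs$exon_terminal_flag == "last_base"]),
               b$last_base)
  expect_equal(unique(snvs$cds_pos[snvs$exon_terminal_flag == "first_base"]),
               b$first_base)
  near <- unique(snvs$cds_pos[snvs$exon_terminal_flag == "near_terminal"])
  expect_setequal(near, c(b$last_base - 1, b$last_base - 2,
                          b$first_base + 1, b$first_base + 2))
  # a "missense" at the last coding base of an exon is still flagged:
  # the consequence and the splice flag are independent annotations
  expect_true(all(c("last_base", "first_base") %in%
                    snvs$exon_terminal_flag[snvs$consequence == "missense" |
                                              snvs$consequence == "synonymous"]))
})

test_that("enumeration counts 3 per CDS base on a long random transcript", {
  set.seed(42)
  codons <- names(Biostrings::GENETIC_CODE)
  ok <- codons[Biostrings::GENETIC_CODE != "*" & codons != "ATG"]
  cds <- paste0("ATG", paste(sample(ok, 500, replace = TRUE), collapse = ""),
                "TAA")
  t <- transcript_model(cds, data.frame(start = 1, end = nchar(cds)))
  snvs <- enumerate_coding_snvs(t)
  expect_equal(nrow(snvs), 3L * nchar(cds))
  # codon-table sanity: about a quarter of substitutions are synonymous
  syn_frac <- mean(snvs$consequence == "synonymous")
  expect_gt(syn_frac, 0.20)
  expect_lt(syn_frac, 0.30)
})

test_that("reverse-strand transcripts give the same protein-level result", {
  cds <- toy$transcript$cds_sequence
  fwd <- toy$transcript
  # on the minus strand the first coding exon is the genomically last one,
  # so the exon widths must be listed in reverse genomic order
  w <- rev(fwd$exon_widths)
  starts <- cumsum(c(5001, head(w, -1) + 100))
  rev_t <- transcript_model(cds, data.frame(start = starts,
                                            end = starts + w - 1),
                            strand = "-")
  expect_equal(rev_t$protein_sequence, fwd$protein_sequence)
  expect_equal(rev_t$exon_boundary_cds_positions,
               fwd$exon_boundary_cds_positions)
  expect_equal(enumerate_coding_snvs(rev_t), enumerate_coding_snvs(fwd))
})

test_that("domain annotation maps residues and defaults to inter-domain", {
  snvs <- enumerate_coding_snvs(toy$transcript)
  n_res <- nchar(toy$transcript$protein_sequence)
  # drop the stop codon (protein_pos = n_res + 1) before domain mapping
  snvs <- snvs[snvs$protein_pos <= n_res, ]
  ann <- annotate_domains(snvs, toy$domains, n_res)
  expect_equal(unique(ann$domain[ann$protein_pos == 6]), "Lyase")
  expect_equal(unique(ann$domain[ann$protein_pos == n_res]), "FumC-C")
  none <- annotate_domains(snvs, toy$domains[0, ], n_res)
  expect_true(all(none$domain == "inter-domain"))
  bad <- snvs
  bad$protein_pos[1] <- n_res + 5
  expect_error(annotate_domains(bad, toy$domains, n_res), "beyond")
})

test_that("domain enrichment matches the hypergeometric oracle", {
  domains <- data.frame(name = "D", start = 101, end = 150)
  res <- domain_enrichment_test(c(110, 120, 130, 140, 150), "D", domains, 500)
  # all 5 of 5 in a 50-residue domain of 500: choose(50,5)/choose(500,5)
  expect_equal(res$p_value, choose(50, 5) / choose(500, 5), tolerance = 1e-9)
  whole <- data.frame(name = "W", start = 1, end = 500)
  expect_equal(domain_enrichment_test(c(3, 77, 431), "W", whole, 500)$p_value, 1)
  expect_equal(domain_enrichment_test(integer(0), "D", domains, 500)$p_value, 1)
  expect_error(domain_enrichment_test(1, "X", domains, 500), "unknown")
})

test_that("windowed score profiles average correctly", {
  const <- data.frame(protein_pos = 1:30, score = 7)
  prof <- windowed_score_profile(const, window = 5)
  expect_equal(prof$score, rep(7, 30))
  spike <- data.frame(protein_pos = 10, score = 9)
  prof3 <- windowed_score_profile(spike, window = 3, protein_length = 20)
  expect_equal(prof3$score[9:11], rep(3, 3))
  expect_equal(prof3$score[c(8, 12)], c(0, 0))
  w1 <- windowed_score_profile(spike, window = 1, protein_length = 20)
  expect_equal(w1$score[10], 9)
  expect_equal(nrow(windowed_score_profile(spike[0, ], window = 3)), 0L)
  expect_error(windowed_score_profile(spike, window = 2), "window")
})
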