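---
title: "Reconstructing biallelic FH inactivation from tumor-only panel data"
author: "fhtwohit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing biallelic FH inactivation from tumor-only panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhtwohit)
```

## The problem

FH-deficient uterine leiomyomas (ULs) lose fumarate hydratase through
biallelic inactivation of the *FH* tumor suppressor -- Knudson's two-hit
model. When only tumor tissue is available (no matched normal), three
questions must be answered from the sequencing data alone:

1. Is an observed *FH* point mutation **germline or somatic**?
2. Does the copy-number signal indicate **monoallelic or biallelic loss**?
3. Do the two observations combine into a coherent **two-hit call** per
   sample?

`fhtwohit` implements the analytic chain for these questions, together with
downstream characterization tools (saturation mutagenesis with domain
mapping, spatial clustering of mutated residues on the protein structure,
and carrier-frequency epidemiology) and a ground-truth simulator that
generates cohorts with exactly the statistical structure the chain assumes.

## The purity/VAF model

A specimen is a mixture of tumor cells (fraction $TP$, the tumor purity) and
normal cells. For a heterozygous point mutation whose second allele is lost
somatically in the tumor cells, the expected variant allele fraction is

$$AF = TP + (1 - TP)\, z,$$

where $z$ is the variant's initial zygosity in normal cells: $z = 0$ for a
somatic variant, $z = 0.5$ for a germline heterozygous one. At $TP = 0.8$
the two hypotheses predict $AF = 0.80$ (somatic) versus $0.90$ (germline).
`classify_origin()` favours the hypothesis with the smaller residual and
abstains (`"ambiguous"`) when the residuals differ by less than a tolerance
(default 0.05, half the spread of purity-consistent VAFs in the bundled
reference cohort). `required_purity()` inverts the model: a germline
explanation of a VAF of 0.443 would require $TP = 2 \times 0.443 - 1 =
-0.114$, which is impossible and is reported as infeasible rather than
clamped.

This formula deliberately ignores that tumor cells retain only one allele
after LOH (the denominator stays $2$). We implement it exactly as commonly
used, because its simplicity is part of its appeal for desk verification; a
copy-number-aware variant ($AF_{som} = TP/(2-TP)$, $AF_{germ} = 1/(2-TP)$)
is available behind the `cn_aware` flag, default off. The gap between
hypotheses is larger under the aware model, so the default is the
conservative choice for origin classification.

Tumor purity itself is anchored on clonal somatic heterozygous passengers in
copy-neutral regions: `purity_from_somatic_het()` doubles their VAF (a TP53
VAF of 0.408 implies $TP \approx 0.816$).

## Copy-number interpretation

The generative model for an interval carrying $n$ tumor copies is

$$\log_2 R = \log_2\!\left(\frac{TP \cdot n + (1 - TP)\cdot 2}{2}\right),$$

floored at a copy ratio of $10^{-3}$ ($\log_2 \approx -9.97$), the value
panel CNV callers print for homozygous deletions; the bundled reference
cohort shows three independent biallelic segments at exactly $-9.97$,
consistent with that floor. `log2_to_cn()` inverts this, rounding
half-away-from-zero (none of the reference values sits at a rounding
boundary, so the tie rule is unambiguous there) and truncating at 0.
Segment sizes use `end - start` (not `+1`), which reproduces the printed
kilobase sizes of the reference segments exactly (15.9 kb, 1407.7 kb,
42,757.4 kb); coordinates are 1-based inclusive as in HGVS-style
`chr1:g.start_end` notation.

Gene-level recurrence of losses/gains against a control cohort
(`recurrence_test()`) uses a one-sided Fisher exact test per gene with
Bonferroni adjustment -- the most conservative standard correction, chosen
because the procedure behind published "corrected for multiple testing"
statements is rarely specified; the method is configurable.

## Two-hit calling and the heterogeneity flag

`classify_sample()` integrates both inputs at the target gene. Log2 ratios
near the monoallelic expectation ($\log_2 0.6 \approx -0.74$ at $TP = 0.8$;
band $[-1.5, -0.3]$ by default, bracketing the monoallelic range $-0.77$ to
$-1.26$ observed in the reference cohort) are clonal single-copy losses;
ratios at or below a *purity-aware biallelic ceiling* are clonal biallelic
losses. The ceiling is `expected_log2(0, purity) + 0.25` ($\approx -2.07$ at
purity 0.8) rather than a fixed constant: a clonal biallelic deletion at
purity 0.8 produces $\log_2 0.2 \approx -2.32$ under the generative model,
so any fixed cutoff below that (e.g. $-2.5$) would misroute noiseless
clonal biallelic losses into the "intermediate" zone. The 0.25 margin is
about 1.7 noise standard deviations at the default noise level.

Ratios *between* the bands are the signature of subclonal structure: too
negative for one clonal loss, not negative enough for two. The reference
sample S05 ($\log_2 = -1.87$, VAF 0.443 at assumed purity 0.8) sits exactly
there. The heterogeneity flag is raised when (a) a gene-overlapping deletion
falls between the bands, or (b) an SNV's VAF -- which equals the purity a
clonal somatic interpretation requires -- lies more than `vaf_margin`
(default 0.3) below the assumed purity. When (a) coincides with an SNV, the
segment is interpreted as a clonal monoallelic loss plus a subclonal second
event and contributes copy number 1, so such samples are classified
`snv_plus_loh` with the flag set rather than mislabelled biallelic. The
margin 0.3 separates the subclonal signature (equal-subclone mixtures have
$VAF \approx TP/2$, a deficit of $\ge 0.35$ at $TP \ge 0.7$) from ordinary
binomial scatter of clonal VAFs.

When an SNV co-occurs with copy number 0 -- an anomaly, as the SNV would
have no allele to reside on -- the copy state dominates and a warning note
is attached instead of hiding the conflict.

## Saturation mutagenesis and domain mapping

`enumerate_coding_snvs()` generates all $3 \times |CDS|$ single-base
exchanges and classifies each by codon substitution (standard nuclear
code). Start-codon substitutions are always `start_lost`. The enumeration
keeps exon structure: the exact first/last coding base of each internal
exon junction is flagged (`first_base`/`last_base`) and the adjacent two
bases as `near_terminal` (flank of 3, configurable). This captures the
practically important case of an apparent missense variant at the last
coding base of an exon that in fact disrupts the splice donor consensus --
without re-implementing splice predictors, which are inputs here, not
outputs. Whether such exon-terminal substitutions should be counted as
missense or excluded is left to the caller; both annotations are reported
independently.

Domain residue ranges are user configuration, not package constants, since
published domain tracks rarely print exact coordinates.
`domain_enrichment_test()` is a one-sided Fisher/hypergeometric test of
observed mutated residues against uniform placement.
`windowed_score_profile()` reduces per-variant scores to a per-residue
moving average (residues without scores contribute 0; window truncated at
the ends) -- a deliberately transparent substitute for fitted score curves.

## Spatial clustering on the structure

The clustering statistic is the **mean pairwise C-alpha distance** of the
mutated residues. Published analyses of this kind often delegate to web
tools whose internal statistic is not printed; we substitute a statistic
that is exhaustively verifiable (on a 20-residue toy helix the complete
null -- all $\binom{20}{3} = 1140$ triples -- is enumerated in the tests and
the bootstrap must agree within Monte-Carlo error). Consequently, published
cluster p-values from those tools (e.g. 0.0411 for the three-residue
fumarase cluster) are treated as qualitative context, not as numeric
targets.

The null resamples the same number of distinct residues uniformly from the
structure; the p-value uses the add-one correction
$p = (1 + \#\{T_b \le T_{obs}\})/(B + 1)$, so it is never 0 and is uniform
on the achievable grid under the null. Ties are compared with an absolute
slack of $10^{-9}$ angstrom so that geometrically identical resamples count
as ties regardless of floating-point noise. `colocalization_test()` asks a
different question -- is set B unusually close to a fixed set A -- with the
statistic $\mathrm{mean}_{b \in B} \min_{a \in A} d(a, b)$ and a null that
resamples B from the structure minus A. Residue numbering offsets between
transcript and crystal conventions are the caller's responsibility; residue
identifiers may be given as `"chain:resno"` when numbers repeat across
chains.

## Carrier-frequency epidemiology

The estimator treats every pathogenic allele (ACMG class 4/5) as one
carrier: $CF = \sum_i AC_i/(AN_i/2)$, with an option to count homozygotes
once. The summation rule behind published carrier frequencies is typically
unstated and database-snapshot dependent, so published values (1/2,563 to
1/3,247 for *FH*) are used as plug-in inputs to the downstream arithmetic,
never as test oracles. The chain
`expected_prevalence()` $\to$ `germline_fraction_among_cases()` $\to$
`prob_no_carriers()` / `screening_enrichment()` is exact desk arithmetic;
the independence assumption between carrier status and tumor occurrence is
asserted in the documentation and violations (ratio > 1) are flagged.
`binomial_tail()` is the exact binomial sum; note that published binomial
p-values of this kind are sensitive to the chosen baseline proportion
(37.1% vs 40.7% for the missense share changes $P(X \ge 6 \mid n = 8)$ from
0.034 to 0.054), which is why the function takes the baseline explicitly.

## What the simulator emulates -- and what it does not

`simulate_cohort()` draws, per sample: a mechanism (SNV+LOH, biallelic
deletion, heterogeneous, or germline+LOH), a purity uniform on
`purity_range`, binomial read counts at the model-implied VAF with
Poisson-distributed depth floored at 10 reads (the standard coverage
filter), and segment log2 ratios from the mixture model plus Gaussian noise.
Defaults are fixed at the study conditions the package is built around:
13 samples, mechanism weights 7/13 : 5/13 : 1/13 : 0, purity 0.7--0.9
(centred on the 0.8 purity that doubled passenger VAFs support), depth 150.
The log2 noise SD of 0.15 is chosen so that the simulated monoallelic band
brackets the observed monoallelic range ($-0.77$ to $-1.26$ around the
expectation $-0.74$) -- no published noise magnitude exists to calibrate
against. The heterogeneous mechanism is the minimal two-subclone model
(equal subclones, one with SNV+LOH, one with an independent deletion) that
reproduces the depressed-VAF/intermediate-log2 signature; real subclone
fractions are of course not constrained to 0.5. Mechanisms can be assigned
by deterministic largest-remainder quota (so tests can pin cohort
composition exactly) or multinomially.

The simulator does **not** model read-level errors, FFPE artifacts, mapping
bias, GC waves, or segmentation uncertainty -- segments are emitted directly
rather than re-segmented from bins. Passing recovery tests therefore
demonstrates the *logic* of the chain under its own assumptions, not
robustness to upstream artifacts of real panel data.

`simulate_population_table()` splits half the target carrier frequency
(alleles per haplotype) across the pathogenic records and draws allele
counts binomially, so `carrier_frequency()` recovers the truth in
expectation; class 1--3 records with arbitrary low frequencies verify that
only class 4/5 contributes.

## Numerical choices and test design

* Copy-ratio floor $10^{-3}$; integer-CN rounding half-away-from-zero;
  sizes to 0.1 kb. The reference cohort's recomputed median deletion size
  (4,897.2 kb) differs from the printed 4,897.1 kb in the last digit
  (truncation vs rounding in the source); the tests assert agreement within
  0.2 kb.
* Origin-classification accuracy is measured over *confident* (non-abstaining)
  calls: the ambiguity band is a deliberate reject option, and counting
  abstentions as errors would conflate calibration with accuracy.
* Bootstrap comparisons allow $2 \times$ Monte-Carlo standard error plus the
  $1/(B+1)$ add-one bias; the null-uniformity check uses the 1%
  Kolmogorov--Smirnov critical value plus the p-grid spacing.
* Problem sizes in the test-suite: 500-sample cohorts at depth 100 for
  origin recovery, 1,000 replicates for VAF unbiasedness, $B = 10^4$
  bootstrap replicates against the exhaustive 1,140-triple null, 200 null
  draws at $B = 199$ for uniformity, and 100 seeds for carrier-frequency
  unbiasedness. These sizes put each Monte-Carlo bound well below the
  assertion tolerance while keeping the default suite fast.

## Worked example

```{r example}
co <- fh_ul_cohort()
calls <- classify_cohort(co$variants, co$segments, co$gene, purity = co$purity)
calls[, c("sample_id", "status", "cn_at_gene", "heterogeneity_flag")]
summarize_twohit_cohort(calls)$fraction_with_snv
```

## Known limitations

* Tumor-only origin classification is inherently probabilistic; at high
  purity the germline and somatic expectations converge and abstention
  rates rise. The package reports required purities so users can apply the
  complementary feasibility argument.
* The two-hit decision table assumes a single target gene interval and does
  not phase hits; hit order is not reconstructed.
* Multi-chain structures: inter-subunit distances are included whenever
  residues from several chains are supplied; whether that is appropriate
  for a tetramer is a scientific choice left to the caller.
* ACMG classification, splice/missense predictor scores, and population
  database curation are inputs, not computations.
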