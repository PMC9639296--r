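---
title: "Methods and design of polyeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of polyeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyeqtl implements the downstream statistics of a population-scale eQTL
study in an allotetraploid crop whose genome splits into An and Cn
subgenomes. This vignette explains each model, its assumptions, the
parameters that matter, what the synthetic-study generator does and does
not emulate, and the choices made where the design was genuinely open.

## Coordinate contract

Everything in memory is 0-based half-open (`[start, end)`), the BED
convention; conversion to 1-based inclusive happens only when reading or
writing VCF and GFF3. One consequence worth spelling out: a lead SNP whose
0-based position equals an interval's `end` is *outside* that interval,
while `end - 1` (the 1-based `end` base) is inside. Strand is used only to
place the TSS (`start` for `+`, `end - 1` for `-`); all window arithmetic
is symmetric distance in bp.

## Association scan and clumping

The scan is per-gene ordinary least squares of `log2(TPM + 1)` on additive
dosage (heterozygotes coded 1). We report the marginal squared Pearson
correlation as the explained variance `r2` and the two-sided slope t-test
P, floored at 1e-300 so P stays in (0, 1]. A kinship mixed model is *not*
fitted: the generator plants no population structure, so OLS answers the
same association question at desk scale; for structured user data a
covariate matrix (e.g. genotype PCs) can be supplied, in which case
expression is residualized on it before the scan. Assumptions: additive
allelic effects, approximately Gaussian residuals on the log scale,
independent accessions.

Parameters (defaults in `pipeline_params()`):

* `maf_min = 0.05` — MAF filter, strict `>` (a SNP exactly at 0.05 is
  dropped).
* `threshold = 1e-6` — genome-wide significance on P. This is the
  conventional effective-test-count-corrected level; no effective-test
  computation is performed here, the threshold is simply a parameter.
* `r2_min = 0.2` — LD clumping, strict `>`. Clumping is greedy: smallest-P
  SNP leads, absorbs all significant SNPs in LD with *the lead*, repeat.
  Every significant SNP lands in exactly one eQTL. P ties are broken by
  larger `r2`, then lower coordinate — determinism, nothing more.
* `local_window = 5e5` bp — an eQTL is local iff its lead is on the gene's
  chromosome within `[start - 500 kb, end + 500 kb]`, *boundary inclusive*
  ("within" read inclusively; 500 kb approximates the distance at which LD
  decays to r² ≈ 0.1 in rapeseed-like populations).
* `expr_floor = 0` — genes whose 95th percentile of `log2(TPM+1)` does not
  exceed the floor are excluded as low-expressed. The literature leaves the
  exact cutoff on that percentile ambiguous, so it is an explicit parameter
  rather than a guess; the default only removes near-silent genes.

Two eQTLs of one gene match across developmental stages when their leads
are within 100 kb (`match_window`) or in LD r² > 0.2; unmatched records are
stage-specific.

## Distant-eQTL hotspots

Distant leads are counted in 1-Mb windows stepped every 100 kb (trailing
partial windows included). *Counting unit:* one count per distant eQTL
record — if thirty genes are regulated from the same locus, that window
counts 30. Counting distinct SNP positions instead would collapse exactly
the biology a hotspot is (many genes, one locus) to 1.

The null preserves only the number of distant leads and places them
uniformly over the concatenated genome; each of `n_perm = 1000`
permutations records the genome-wide *maximum* window count. The call
threshold is the smallest integer whose null exceedance fraction is below
`alpha = 0.01`, and each window's empirical P is its own null exceedance
fraction. Because the null is the maximum, this is family-wise calibrated
by construction; the acceptance suite verifies a type-I fraction near 0.01
over 200 null genomes. A per-chromosome-count-preserving placement is
available behind `per_chromosome = TRUE`.

Called windows that overlap or abut (`merge_gap = 0`; the 100-kb stepping
makes neighbours overlap anyway) are unioned. Hotspots are called per stage
and compared afterwards (`overlap` requires reciprocal containment ≥ 0.9 of
both intervals, anything less is `partial`, none is `special`); calling
jointly across stages would hide stage specificity, which is one of the
quantities of interest. TWAS-gene enrichment per hotspot is a one-sided
hypergeometric upper tail over the eGene universe with BH across hotspots;
the method is not fixed by precedent, so an equal-size permutation
alternative (`method = "permutation"`) is provided as a cross-check.

## Expression piggybacking

"Adjacent" means consecutive gene ordinals on the same chromosome, strand
ignored. The adjacency census counts local-eGene pairs at each intervening
gene count k; the permutation test redraws equally many genes uniformly
without replacement 1000 times and compares adjacent-pair (k = 0) counts.
Pair classes: I (both local), II (one), III (neither), plus IV — a random
sample of non-adjacent both-local pairs, by default of class-I size so the
correlation CDFs are comparable. The random baseline samples genome-wide
uniformly (not chromosome-matched). For chromatin strata, a gene with
several local eQTLs is represented by its minimum-P lead; strata are
`both_open` / `one_open` / `both_closed` by OCR membership, compared with
Welch t-tests (the unequal-variance form, since stratum variances have no
reason to agree).

## Homoeolog regulation and feedback

Pairs come from reciprocal best hit on the similarity table; score ties are
broken lexicographically, and a tie at the best hit that breaks reciprocity
yields no pair (strict "best"). RBH output is a matching and is invariant
to row/column permutation.

Gene X regulates its homoeolog Y iff X's TSS lies within ±150 kb
(inclusive) of any distant lead of Y on X's chromosome. The lead ± 150 kb —
rather than the whole clumped interval — is used because the window is the
only quantified part of the rule. Distant leads from either stage count by
default (stable regulation; a per-stage mode exists). Exactly one direction
makes an aHGP; none or both is symmetric.

Expression propensity is the mean over accessions of
`log2(TPM_An + 1) − log2(TPM_Cn + 1)` (positive = An-biased), tested with a
paired two-sided t-test per pair and BH across pairs (`padj < 0.05` =
imbalanced). Degenerate pairs: zero-variance difference with zero mean ⇒
P = 1; zero variance with non-zero mean ⇒ P floored (overwhelming
evidence). Feedback analysis groups pairs as `BG` (all), `Local` (aHGPs
whose *regulating* gene carries a local eQTL — the directionality the
biology implies; a flag conditions on the regulated gene instead for
sensitivity analysis) and `NoLocal`, comparing cross-homoeolog Pearson
correlations by two-sample KS. TF enrichment among feedback pairs is a
permutation test drawing equal-sized gene sets uniformly.

## Open-chromatin enrichment

Peak sets are merged with gap 0 (book-ended intervals fuse). The
permutation test keeps OCRs fixed and reshuffles lead positions uniformly
*per chromosome*, preserving per-chromosome lead counts — peaks have length
structure that naive shuffling distorts, and chromosome-count preservation
guards against chromosome-size confounding. An optional mode also
reshuffles OCR starts preserving lengths. The empirical P is
`(1 + #{null ≥ obs}) / (n_perm + 1)` (never exactly zero) and the reported
95% band is the 2.5/97.5 percentile of null counts (a band on counts, not
on a ratio). Explained-variance comparison of in- vs out-of-OCR eQTLs is a
two-sample KS on lead r², with the one-sided direction (in-OCR larger)
reported alongside the two-sided P.

## TWAS

Per-gene OLS of the trait on `log2(TPM + 1)` with BH control; significant
means `q ≤ 0.05`. Under a permuted trait the family-wise error of BH at the
global null is ≈ the FDR level, so roughly one run in twenty shows a stray
discovery — the calibration test's expectation, not a defect.

## Boosted-tree TF ranking

Per target gene, an XGBoost regressor of the target's `log2(TPM+1)` on all
TF `log2(TPM+1)` features (the target excluded from its own features when
it is a TF), with 1000 trees, depth 3, learning rate 1e-4, `reg_alpha = 0`,
`reg_lambda = 1`, single-threaded and deterministic. Importance is total
gain — the conventional regulatory-strength proxy in boosted-tree GRN
methods; features never used in a split score 0. The very low learning rate
fits tiny functions, but gain ordering is what matters here, and tests
verify that a conventional rate (0.05) agrees on the top TF for
strong-signal data. There is deliberately no train/test split: the
procedure is feature selection, not prediction benchmarking. Per target the
top 3 non-zero-gain TFs are extracted (ties lexicographic); aggregation
counts both top-k occurrences and rank-1-only occurrences — the field is
ambiguous about which defines the final order, so both are reported, with
top-k counts ranking first and rank-1 counts breaking ties. TFs whose gene
body lies inside the hotspot interval are flagged; the best-ranked flagged
TF is the headline candidate.

## The synthetic-study generator

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script; they were chosen once, for realism and
desk-scale power, and are not tuned per test:

* 300 accessions; 2 chromosome pairs (A01/C01, A02/C02) of 12 Mb; 100 genes
  per chromosome, positionally matched across subgenomes so RBH has a known
  truth; ~10% of homoeolog pairs flagged TF (both copies together).
* 300 SNPs per chromosome in 150-kb LD blocks: block founders are binomial
  draws at a MAF sampled in [0.1, 0.5]; block members are founder copies
  with 5% per-accession mutation, giving intra-block r² ≈ 0.9 and
  inter-block r² ≈ 0 — exactly the structure the 0.2 clumping rule needs,
  and nothing more. Realized MAFs are kept in range by redrawing.
* Expression is simulated directly on the `log2(TPM+1)` scale
  (`TPM = 2^y − 1`, clamped at 0) so planted betas are exactly linear on
  the analysis scale. Per-gene baselines are N(4, 1); the two homoeologs of
  a pair share their baseline, making unplanted pairs a true propensity
  null. Residual noise sd 0.5.
* Plantings: 20 standalone local eQTLs and 25 adjacent co-expressed pairs
  (both genes local, sharing a latent factor of sd 0.8, plus 0.5 when their
  causal SNPs share chromatin state) — |beta| = 1, random sign; one hotspot
  whose TF regulator is driven by its nearest-to-TSS SNP and propagates its
  expression deviation into 30 targets on other chromosomes with
  coefficient 0.8; 15 feedback homoeolog pairs (regulated copy =
  −0.8 × regulating copy's deviation, which yields both the distant
  association and the negative cross-correlation); 15 directly regulated
  pairs whose regulating gene carries *no* local eQTL (the SNP near its TSS
  acts on the partner only) — the NoLocal contrast group; 15 An-shifted
  pairs (+1 on the log2 scale) for the propensity sign; causal SNPs fall in
  OCRs with odds 5 × the 10% genomic fraction, and in-OCR local betas are
  boosted 1.5×; the trait is the sum of five hotspot-target expressions
  plus N(0, 1) noise; 30% of the standalone/adjacent local effects exist at
  stage 1 only, stage 2 reusing the remaining effects with fresh noise.
* Determinism: `simulate_study()` seeds the RNG once from `cfg$seed`;
  identical configs are byte-identical.

What the generator does **not** emulate: population structure and kinship
(so passing tests say nothing about confounding control), realistic LD
decay or recombination, allele-frequency spectra from demography,
heavy-tailed or zero-inflated expression, batch and environment effects,
multi-allelic variation, and ATAC coverage (peaks only). Recovery results
here demonstrate correctness of the machinery under its own assumptions,
not performance on real populations.

## Problem sizes and runtime

Module tests run a reduced configuration (120 accessions, 4-Mb
chromosomes, 40 genes and 120 SNPs per chromosome); recovery and
calibration checks use the demo configuration above. Null calibrations use
200 runs at 200 permutations; recovery uses 1000 permutations. These sizes
were picked so the whole suite runs in a few minutes on one CPU while every
planted effect is comfortably detectable at the demo scale — at the reduced
scale some adjacent-pair local eQTLs drop below the 1e-6 threshold because
the shared factor inflates residual variance, which is expected power
behavior, not an error.

## Known limitations

* OLS association will be miscalibrated under strong population structure;
  supply covariates or pre-residualized expression for structured data.
* The hotspot null ignores SNP density variation along the genome; regions
  dense in testable SNPs can be slightly anticonservative on real data.
* Regulation direction uses lead ± 150 kb, not the clumped interval; very
  long LD blocks can misplace the regulating gene.
* Gain importance from a single boosted model has no uncertainty attached;
  the ranking is a prioritization, not a significance statement.
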