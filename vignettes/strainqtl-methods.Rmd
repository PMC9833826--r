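---
title: "Methods: mixed-model pQTL mapping and systems-genetics integration in strainqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model pQTL mapping and systems-genetics integration in strainqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strainqtl implements the statistical core of a systems-genetics study of
protein abundance in a renewable inbred strain panel (a hybrid mouse
diversity panel design): each of ~75 inbred strains contributes 2–4
replicate animals, a quantitative proteome (log2 ratio-to-reference values,
with each protein quantified in a subset of mice), dense biallelic
genotypes, and a set of strain-level physiological or molecular traits.
This vignette documents the models, the choices that were genuinely open,
and what the synthetic test surface does and does not establish.

## The association model

For one feature (protein or trait) `y` measured at strain level and one SNP
with dosage vector `x` (alternate-allele count, {0,1,2}), the model is

    y = 1*mu + x*beta + u + e,
    var(u) = sigma_u^2 * K,   var(e) = sigma_e^2 * I,

where `K` is the identity-by-state (IBS) kinship matrix estimated from all
SNPs: `K[i,j]` is the mean over pairwise-complete SNPs of
`1 - |g_i - g_j| / 2`. The polygenic term `u` absorbs confounding from
genetic relatedness — in an inbred panel, strains are related in blocks, and
without `u` every heritable feature shows inflated association statistics
panel-wide.

Fitting follows the standard eigendecomposition strategy: with
`K = U S U'`, rotating the model by `U'` makes the covariance diagonal,
`sigma_u^2 * (S + delta)` with `delta = sigma_e^2 / sigma_u^2`. On the
no-SNP null model, `delta` is profiled by restricted maximum likelihood
(REML) over a grid of 100 log-spaced values in `[1e-5, 1e5]` followed by
bounded refinement (`optimize` on log10 delta); `sigma_u^2` has a closed
form at each `delta`. The null `delta` is then reused for every SNP of that
feature's scan — the "null-reuse" approximation of the fast mixed-model
literature — so each SNP costs a weighted 2x2 generalized least-squares
solve. Exact per-SNP re-estimation of `delta` is available behind
`assoc_scan(..., exact_delta = TRUE)` as a reference mode; on panels of
this size the two are indistinguishable in practice, and the fast path is
what the test suite's dense-solve oracle certifies.

The test of `beta = 0` is the standard F-test with 1 and `n - 2` degrees of
freedom, `F = (beta/se)^2`. Replicates are collapsed to strain means before
mapping, so `n` counts strains, not animals: genotype varies only at strain
level, and treating animals as units would pseudo-replicate the genetic
signal.

Numerical edge handling: kinship eigenvalues below `1e-8` trigger a
`+1e-6` diagonal regularization (with a warning); the regularized matrix is
the effective kinship everywhere downstream, so the dense-solve oracle in
the tests reproduces it exactly. p-values that underflow to 0 are reported
as the smallest positive double. Monomorphic SNPs and SNPs below the MAF
floor (default 0.05 among the strains actually used) are skipped with a
message; strains missing a genotype at a SNP are dropped pairwise for that
SNP, without imputation.

## Significance and cis/trans classification

Per feature, q-values are computed from the p-value distribution by the
step-up procedure; `"storey"` (default) additionally estimates the null
proportion `pi0 = min(1, mean(p > 0.5) / 0.5)`, `"bh"` fixes `pi0 = 1`.
Overall significance is `q < 0.1`.

A **cis** call requires the SNP within ±10 Mb of the feature's gene
(distance to the nearer gene boundary, 0 inside the gene), a window-local
adjusted p below `1e-4`, and `q < 0.1`; "local adjustment" is the q-value
computed over the SNPs inside the window only. A **trans** call requires
the SNP beyond the window or on another chromosome, a genome-wide adjusted
p below `5e-8`, and `q < 0.1`. The local/global adjustment scopes are a
declared interpretation: "local" is read as FDR adjustment restricted to
the window, the natural counterpart of "global" adjustment over all tested
SNPs. Each feature reports at most one lead cis SNP and one lead trans SNP
(minimal p, ties broken by genomic position, which makes classification
invariant to SNP input order).

Trans **hotspots** — loci regulating unusually many distant proteins,
visible as vertical streaks on a Manhattan plot — are operationalized by
tiling the genome in 4 Mb bins, counting distinct trans-regulated features
per bin via their lead SNPs, and flagging bins whose Poisson upper-tail
p-value (rate = genome-wide mean count per bin) survives BH adjustment at
`1e-3`. Bin width and the Poisson rule are artifact choices; the original
identification was visual.

## Correlation statistics and OPLS

Protein–protein and protein–trait associations use the biweight
midcorrelation (bicor): deviations from the median are downweighted by
`(1 - u^2)^2` with `u = d / (9 * mad)` (unscaled MAD), zeroing observations
more than 9 MADs out. This keeps single outlier mice from manufacturing or
destroying correlations. A zero-MAD vector falls back to Pearson with a
message. p-values use the Student t transform with `n - 2` degrees of
freedom and BH adjustment across all pairs. The shortlist filter keeps
pairs with `r <= -0.3` or `r >= 0.6` and `p < 0.05` — asymmetric on
purpose, mirroring the practice of admitting moderate negative and strong
positive protein–trait associations.

Before correlation and OPLS, samples are quantile normalized (rank-average
reference distribution; ties share the mean of their rank slots) and
replicates averaged per strain on the log2 scale. Mapping uses plain strain
means without quantile normalization.

The OPLS model of one trait on the strain-level proteome uses one
predictive and one orthogonal component: the PLS weight `w ∝ X'y` is
computed, the orthogonal component's loading is the part of the X-loading
orthogonal to `w`, `X` is deflated, and the predictive component is fitted
on the deflated matrix. By construction the predictive and orthogonal
scores are exactly orthogonal. Columns are centred and unit-variance scaled
by default (the common default of this workflow; the original scaling
choice is unstated, so scaling is exposed as a flag), `y` is centred, and
the predictive score is oriented so `cor(t_p, y) >= 0`. `Q2` uses
leave-one-strain-out cross-validation with per-fold re-centring. Missing
data are handled by complete-case column dropping, never imputation, which
would manufacture signal in a supervised model.

Reproducibility metrics: coefficients of variation are computed on
delogged linear ratios (`2^value`), because the CV of log-ratios centred at
0 is ill-defined; intra-strain CV uses strains with ≥2 replicates and
reports the median across strains per protein. Genetic repeatability `R`
is the one-way random-effects ANOVA intraclass correlation with the
unbalanced-design effective group size `n0`; negative between-strain
components are clipped to 0. Differential (screen/knockdown style) tests
are classical Student t-tests — pooled-variance two-sample, or paired on
within-pair differences — with BH adjustment across features; Welch's
correction is deliberately not used because the emulated workflow names
Student's test throughout.

## Three-step integration

For a candidate protein and a trait, prioritization requires:

1. **Shared genetics** — a non-empty exact intersection between the
   protein's cis-qualifying SNP set and the trait's significant
   (`q < 0.1`) SNP set. The lead shared SNP minimizes the larger of the two
   p-values. Exact id intersection is the strictest faithful reading; an
   LD-window slack (`window_bp`) is exposed because the original matching
   granularity is unstated.
2. **Phenotypic association** — the bicor filter above.
3. **Allelic contrast** — at the lead shared SNP, strains split by
   homozygous genotype (heterozygotes excluded, ≥3 strains per group) must
   differ in both protein abundance and trait by pooled-variance t-tests at
   `p < 0.05`, with the sign of the allelic effect product concordant with
   the correlation sign. Concordance is toggleable
   (`require_concordance`), since the original procedure does not state it;
   it is on by default because a discordant triple is mechanistically
   incoherent. The rule is invariant to jointly recoding the alleles
   (0↔2 flips both t signs).

Verdicts are `prioritized` (all three), `none`, or `partial` with the
passing-step pattern; records sort by lead shared-SNP strength.

## The synthetic panel generator

`simulate_panel()` emulates the study's data structure so every stage has a
fully seeded, no-download test surface:

* **Genotypes** — homozygous dosages {0,2} (inbred strains), LD blocks of
  4 Mb in which every SNP copies a per-strain founder allele with
  probability `sqrt(ld_rho)` (`ld_rho = 0.9` default, giving realistic
  block correlation; 1 reproduces identical SNPs, 0 independence), block
  allele frequencies uniform in `[0.15, 0.85]`. Default genome: 5
  chromosomes × 120 Mb, 1,000 SNPs, 320 genes of 20 kb.
* **Proteome** — 300 proteins; per protein
  `y = sum(x*beta) + u + e` at strain level with
  `u ~ MVN(0, 0.15 * K)` and `e ~ N(0, 0.10)` (heritability 0.6 on the
  log2 scale, total SD 0.5 — typical of strain-level log2 ratios). The
  generative `u` uses the realized IBS kinship of the simulated panel, so
  mapping with estimated `K` is exactly well-specified and calibration
  tests are sharp. 10% of proteins get a planted cis SNP within ±10 Mb of
  their gene, variance explained uniform in 0.2–0.6. One trans hotspot SNP
  regulates 30 proteins whose genes are trans to it, variance explained
  0.45–0.60: under the genome-wide trans threshold (q-adjusted p < 5e-8
  over a 1,000-SNP scan) a 75-strain panel with 70–100% per-protein
  coverage only has power for effects of roughly 45% variance explained
  and above, and the phenomenon being emulated — hotspot "streaks"
  conspicuous on a Manhattan plot — is by definition above threshold, so
  the generator plants effects in the detectable regime. Effect sizes are parameterized
  as variance-explained fractions and converted to `beta` via the realized
  dosage variance, which keeps them portable across panels. One subtlety:
  because the polygenic draw is correlated across strains, its strain-level
  sample variance is shrunk relative to `sigma_u^2` by roughly
  `1 - mean(K)`; the conversion targets this realized noise variance, so a
  nominal 50%-variance-explained effect really shows an `r^2` near 0.5 on
  the strain means.
* **Replicates and missingness** — 2–4 replicates per strain with i.i.d.
  Gaussian log2 noise (`replicate_sd = 0.13`, matching a ~9% linear-scale
  intra-strain CV); per protein, a random 70–100% of strains are retained
  and the rest dropped wholesale, mirroring panels where each protein is
  quantified in a subset of mice. The coverage floor for mapping defaults
  to the conventional 50-of-73 fraction rescaled to the panel.
* **Traits** — each trait is a weighted sum of strain-mean protein
  abundances plus Gaussian noise with SD half the signal SD. With
  `causal_chain = TRUE` (default) the first trait takes its unit-weight
  driver from the strongest planted cis protein, completing a
  SNP → protein → trait chain recorded in the truth ledger. Contributions
  missing for a strain are omitted from the sum; because values are
  centred log2 ratios this behaves as extra noise rather than bias.

The truth ledger records every planted cis pair, hotspot target, trait
weight, and per-protein realized heritability, so recovery, false-call and
ranking rates are computable exactly.

What the generator does **not** emulate: TMT batch effects and other
structured technical covariance, pedigree/coalescent allele-frequency
structure, dominance or epistasis, non-Gaussian trait distributions, and
correlated missingness (missingness is random by strain, not
abundance-dependent). Passing tests therefore certify the statistical
machinery under a well-specified model, not robustness to those real-data
pathologies.

## Problem sizes used in the tests

The acceptance suite exercises: 50 random small instances (≤30 strains,
≤50 SNPs) for oracle equivalence; ~2,700 null feature-SNP tests for
calibration plus an 80-strain two-subpopulation panel for the inflation
contrast; 20 seeds of the default 75-strain / 300-protein / 1,000-SNP
panel for cis recovery and heritability (plus 20-seed grids at generative
heritability 0.2/0.5/0.8); and 20 seeded end-to-end pipeline runs for the
causal-chain ranking. The acceptance script repeats the same computations
at moderately reduced seed counts. These sizes were chosen so the whole
surface re-runs comfortably on a laptop while keeping Monte-Carlo noise
well inside the asserted margins.

## Known limitations

* The null-reuse approximation slightly mis-estimates `delta` under very
  strong single-SNP effects; the exact mode exists but is not the default.
* q-values within a 1,000-SNP synthetic scan are coarser than in a real
  ~200k-SNP panel; threshold behaviour (e.g. how many planted effects
  clear `5e-8` after adjustment) scales with SNP count.
* Storey's `pi0` at `lambda = 0.5` is a declared default; the emulated
  workflow's exact q-value variant is ambiguous in its description.
* OPLS is fitted with exactly one predictive and one orthogonal component;
  no component-number selection is attempted.
* The integration verdict is rule-based, not a formal mediation or
  Mendelian-randomization analysis; "causal" means "consistent with the
  planted causal pattern", nothing stronger.
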