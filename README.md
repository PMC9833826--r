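# strainqtl

Systems genetics of protein abundance in renewable inbred strain panels.

## The problem

In a hybrid mouse diversity panel (HMDP) style study, each of ~75 inbred
strains contributes replicate animals with a quantified skeletal-muscle
proteome (log2 ratio-to-reference, each protein measured in a subset of
mice), dense biallelic genotypes, and strain-level physiological traits.
The analysis questions are: which genetic variants regulate the abundance
of which proteins (protein quantitative trait loci, pQTLs), locally (cis)
or at a distance (trans, including "hotspot" loci regulating many
proteins); which proteins track which traits; and which proteins sit on a
plausible causal path from variant to trait.

strainqtl implements that computation end to end for analysts working in R:

* **Kinship + mixed model** — identity-by-state kinship `K` and the REML
  linear mixed model `y = 1μ + xβ + u + e` with `var(u) = σu²K`,
  `var(e) = σe²I`, fitted by eigendecomposition with the variance ratio
  `δ = σe²/σu²` profiled on the null model and reused across SNPs; the
  standard F-test of `β = 0` with 1 and n−2 df; Storey/BH q-values.
* **Classification** — cis calls (±10 Mb of the gene, window-local adjusted
  p < 1e-4, q < 0.1), trans calls (beyond the window, genome-wide adjusted
  p < 5e-8, q < 0.1), intragenic/consequence annotation, and Poisson-test
  hotspot bins.
* **Correlation & OPLS** — quantile normalization, strain aggregation,
  biweight midcorrelation with the (r ≤ −0.3 or r ≥ 0.6, p < 0.05)
  shortlist filter, correlation networks, intra/inter-strain CV,
  repeatability (intraclass correlation), Student t screens with BH FDR,
  and a 1 predictive + 1 orthogonal component OPLS model of a trait on the
  proteome.
* **Three-step integration** — shared significant SNPs, correlation filter,
  and allelic-contrast t-tests with direction concordance, yielding a
  prioritized / partial / none verdict per (protein, trait).
* **Synthetic panel generator** — a fully seeded simulator of the whole
  data structure (LD blocks, planted cis effects, a trans hotspot,
  polygenic covariance through the realized kinship, protein-driven traits,
  strain-wise missingness) with a truth ledger, so every stage is testable
  without the original data.

Results are tibbles throughout and compose with dplyr; fitted objects have
`tidy()` / `glance()` methods and ggplot2 `plot_*()` helpers.

## Worked example

```r
library(strainqtl)

res <- run_pipeline(sim_config(seed = 11))
res$counts
#> # A tibble: 1 × 6
#>   n_proteins_mapped n_cis n_trans n_hotspot_bins n_selected_pairs n_prioritized
#>               <int> <int>   <int>          <int>            <int>         <int>
#> 1               300    23      16              1               43             1
```

On this seed, all 300 simulated proteins pass the coverage floor and are
mapped; 23 of the 30 planted cis effects are recovered as cis-pQTL
proteins, 16 proteins get a trans call, and the one planted 30-target
hotspot is flagged as exactly one enriched 4 Mb bin. 43 protein–trait
pairs pass the correlation shortlist. The integration step prioritizes a
single protein for the causally constructed trait — the planted driver:

```r
head(res$integration[res$integration$trait_id == "trait_01",
                     c("protein_id", "n_shared_snps", "r", "verdict")], 3)
#>   protein_id n_shared_snps      r     verdict
#> 1  prot_0185             6  0.849 prioritized
#> 2  prot_0042             0  0.383        none
#> 3  prot_0114             0 -0.361     partial
```

`prot_0185` is the protein whose planted cis SNP drives trait_01 in the
truth ledger (`res$truth$trait_weights`): it shares 6 significant SNPs with
the trait scan, correlates at bicor r = 0.85, and both allelic-contrast
t-tests pass with concordant direction. The OPLS view of the same trait:

```r
glance(res$opls[["trait_01"]])
#> # A tibble: 1 × 6
#>       n n_proteins   r2y    q2 r2x_pred r2x_ortho
#>   <int>      <int> <dbl> <dbl>    <dbl>     <dbl>
#> 1    50         12 0.837 0.702   0.0896     0.132
```

(Only the 12 proteins with complete strain coverage enter the model on
this seed; `plot_loadings(export_loadings(...))` draws the p1/o1 loading
plot with the correlation filter highlighted.)

Individual stages are exported too: `read_genotypes()` / `read_abundance()`
/ `read_traits()` / `read_genes()` for TSV/VCF/BED/GFF3 input,
`ibs_kinship()`, `fit_null()`, `assoc_scan()`, `map_qtl()`,
`classify_qtl()`, `detect_hotspots()`, `strain_aggregate()`, `bicor()`,
`correlate_features()`, `network_edges()`, `cv_report()`,
`repeatability()`, `differential()`, `fit_opls()`, `integrate_qtl()`.

See `vignettes/strainqtl-methods.Rmd` for the models, defaults and design
decisions.

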