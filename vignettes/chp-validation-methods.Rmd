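---
title: "Validating candidate SNPs for cold-heat pattern traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating candidate SNPs for cold-heat pattern traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chpvalid)
```

## The problem

Cold-heat pattern (C-HP) is a diagnostic framework of Traditional Korean
Medicine that classifies constitutional thermal sensitivity into a cold
pattern (CP) and a heat pattern (HP), scored with a 15-item questionnaire
(8 CP items, 7 HP items). The phenotype is heritable, but direct GWAS at
the cohort sizes typically available (tens of patients) is hopeless. The
pragmatic alternative implemented here is *candidate validation*: take
SNPs already reported for physiologically adjacent traits — cold/heat
response traits and thyroid-hormone traits (thyroid hormone drives
thermogenesis) — and test those few hundred markers against the CP and HP
scores of a small, deeply phenotyped cohort.

`chpvalid` implements that validation pipeline end to end, plus the
synthetic-data generators needed to exercise it without access to any
cohort: genotype and phenotype simulation, catalog filtering,
covariate-adjusted association with permutation significance, LD pruning
and clumping, genotype PCA, gene-set over-representation, pathway
similarity networks and control-trait comparison.

## The association model

For each reported SNP $j$ with dosage $g_{ij} \in \{0,1,2\}$ the score of
sample $i$ is modelled as

$$y_i = \beta_0 + \beta_a\,\mathrm{age}_i + \beta_s\,\mathrm{sex}_i +
  \sum_{c=1}^{5}\gamma_c\,\mathrm{PC}_{ic} + \beta_g\, g_{ij} +
  \varepsilon_i,$$

fitted by ordinary least squares. Age, sex and five genotype principal
components absorb demographic and ancestry confounding. The PCs are
computed from the variance-standardized genetic relationship matrix
$GRM = XX^\top/m$ over an LD-pruned marker set, the standard construction
for ancestry adjustment.

At $n \approx 90$ the asymptotic $t$ p value of $\beta_g$ is not
trustworthy, so significance is assessed by **Freedman-Lane residual
permutation**: fit the reduced model $y \sim Z$ (covariates only), form
$y^\ast = \hat y + \pi(\hat\varepsilon)$ for each of $B$ permutations
$\pi$, refit the full model on $y^\ast$, and compare the observed $|t|$ of
the genotype term with the permuted ones:

$$p = \frac{1 + \#\{|t^\ast_b| \ge |t_{\mathrm{obs}}|\}}{B + 1}.$$

The protocol names only "residual permutation"; Freedman-Lane is adopted
as the standard covariate-respecting scheme, with $|t|$ as the
(asymptotically pivotal) exchangeable statistic. The add-one convention
keeps $p \ge 1/(B+1)$, so a permutation p can never be exactly zero.
Internally the per-permutation refit is carried out with exact projection
algebra (the permuted residuals are projected off the covariate space
once per SNP); the test suite verifies that this is numerically identical
to literally refitting `lm` for every permutation.

Other analysis rules, all deliberate:

* **Missing genotypes** trigger per-SNP complete-case analysis, not mean
  imputation — at $n = 90$ imputation bias would be material. MAF is
  computed on the analyzed samples.
* **No multiple-testing correction** across SNPs, mirroring the original
  protocol; `run_pipeline()` emits a warning so nobody mistakes the
  candidate count for a family-wise-controlled discovery count.
* Significance is the **strict** inequality `permutation_p < alpha`
  (default `alpha = 0.05`).
* The effect allele is the VCF alternate allele. The packaged candidate
  tables transcribe the printed `maf` column verbatim even where the
  printed value plainly tracks the effect-allele rather than the
  minor-allele frequency; reinterpreting published numbers is not this
  package's job.

## LD handling

Pairwise LD is the squared Pearson correlation of dosages over
pairwise-complete samples (composite, unphased $r^2$) — appropriate
because the genotypes are unphased; no haplotype estimation is attempted.

**Pruning** (for PCA) uses 50 kb windows advanced by 5 markers with an
$r^2$ threshold of 0.2. Within a window, while any kept pair violates the
threshold, the member with the lower MAF is removed (equal MAF: the larger
position goes). Passes repeat until a pass removes nothing; this fixed
point simultaneously guarantees the post-condition (no violating pair
under the same window definition, checkable with `prune_violations()`)
and idempotence (pruning the output is a no-op).

**Clumping** (for independent signals) is greedy and p-value ordered with
`p2 = 1`, `r2 = 0.2`, `kb = 250`: the best unassigned SNP becomes an
index, and every unassigned SNP on the same chromosome within 250 kb and
with $r^2 \ge 0.2$ *against the index* (no transitive chaining) joins its
clump. Ties on p are broken by smaller position, then id, so the result
is deterministic. Clumping is ordered by the permutation p by default
(`p_col` switches to the asymptotic p); the source protocol does not say
which it used. The stated order of operations is ambiguous about whether
clumping preceded the significance filter; the default clumps the
significant set, and `clump_before_filter = TRUE` gives the other order.

## PCA

`genotype_pca()` standardizes each variant to
$(g - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$ (missing entries contribute 0
after centering, i.e. mean imputation in the standardized scale) and
takes the eigendecomposition of $XX^\top/m$ through the SVD of $X$ — the
same eigenpairs at lower cost when $m < n$, with zero eigenvalues implied
beyond the rank so the trace identity is preserved. Monomorphic variants
cannot be scaled and are dropped. Each component's sign is fixed so its
largest-magnitude sample loading is positive, making coordinates stable
across runs and platforms.

## Enrichment and the combined score

Genes mapped to the significant, clumped SNPs (one gene per SNP via a
static annotation table — the original analysis used a live
variant-to-gene service, which is out of scope here) are tested for
over-representation in each gene-set term with the **upper-tail
hypergeometric** p value $P(X \ge \text{overlap})$ — one-sided by
construction, since depletion is not of interest. The odds ratio comes
from the 2x2 table with a Haldane 0.5 correction when a cell is zero.
The default background is the union of all library genes (an explicit
background can be supplied); query genes outside the background are
excluded from the test rather than silently inflating the list size.

The published analysis ranked terms by a service-side "combined score"
whose exact calibration is not recomputable locally. `chpvalid` defines a
documented reconstruction: for each term, the expected rank and rank sd
are estimated from `R` random gene lists of the query's size, and

$$z = \frac{\mathbb{E}[\mathrm{rank}] - \mathrm{rank}_{\mathrm{obs}}}{\mathrm{sd}(\mathrm{rank})},
\qquad c = -\ln(p)\, z,$$

with $z := 0$ when the rank sd is 0. The score ranks terms the same way
in spirit, but its absolute values are **not** comparable with published
combined scores, and the package does not claim to reproduce them.

Top pathways are the `k = 5` smallest p values (ties: larger combined
score, then term name). The pathway similarity network joins two pathways
when the Jaccard coefficient of their gene sets reaches 0.3; the edge set
is canonically ordered and therefore invariant to pathway input order.
Control traits (e.g. body height, hair color, myopia records in the
catalog) run through the identical machinery, and
`control_comparison()` tabulates tested/significant counts, the
significant-SNP ratio, top pathways and network density side by side.

## What the synthetic generators emulate

The study cohort is private, so every stage is exercised on synthetic
data whose defaults mirror the study conditions:

* `simulate_genotypes()` — Gaussian-copula genotypes: block-AR(1) latent
  correlation (default blocks of 10, $\rho = 0.8$, 5 kb spacing)
  thresholded at Hardy-Weinberg quantiles for a target allele frequency.
  This gives controllable, geometrically decaying $r^2$ inside blocks —
  enough to exercise pruning and clumping — but no recombination-map
  realism, no mutation model, and exact HWE by construction.
* `simulate_structured_genotypes()` — Balding-Nichols model:
  per-population allele frequencies drawn from a Beta distribution around
  an ancestral frequency with divergence `fst`, genotypes binomial. The
  default panel mirrors the five continental reference groups
  (EUR 533, EAS 539, AMR 373, SAS 544, AFR 719). The achieved divergence
  is verified with the Hudson estimator (`hudson_fst()`).
* `simulate_phenotypes()` — linear scores with planted per-allele SNP
  effects plus age (Normal(50, 10) truncated to [19, 80]), sex
  (Bernoulli(0.5)) and Gaussian noise. The questionnaire's item structure
  is not simulated; scores are continuous and the association machinery
  is scale-agnostic. Defaults (`intercept = 20`, `age_effect = 0.05`,
  `sex_effect = 1`, `noise_sd = 6`) put planted effects of 2-4 score
  units at standard errors near 1 at $n = 90$, the regime of the
  replication tables; age/sex distributions are not stated in the source
  protocol, so these conventional choices are configurable.
* `simulate_catalog()` and `simulate_gene_sets()` — catalog rows with
  configurable fractions of X-chromosome and duplicate records (so the
  filters have work to do), and synthetic gene-set libraries with an
  optionally planted enriched term.

All generators are bit-reproducible given `(seed, parameters)`, and the
pipeline derives per-stage, per-SNP seeds from one master seed, so any
stage can be rerun in isolation.

Passing tests on these generators show that the *statistics* behave as
designed — calibrated type-I error under covariate confounding, power
against planted effects, correct LD thinning, recoverable population
structure. They cannot show robustness to genotyping error, imputation
artefacts, questionnaire measurement structure, or real LD topology;
conclusions about real cohorts still require real data.

## Numerical and degenerate-input choices

* OLS uses the QR decomposition; rank deficiency and $n \le k$ are hard
  errors, and the test suite pins the QR path to an explicit
  normal-equations oracle at 1e-8.
* Monomorphic genotypes are an error in `residual_permutation()` and
  `ld_r2()` (`"no_variation"`), a logged skip in `run_association()`, and
  a dropped column in `standardize_genotypes()` — the right response
  differs by context.
* `run_association()` canonicalizes sample order internally, so jointly
  reordering genotype and phenotype rows cannot change any result,
  including the permutation stream.
* Strict numeric parsing everywhere: malformed numbers in catalogs,
  phenotypes or fixtures raise errors instead of becoming `NA`.
* Multi-allelic VCF records are rejected by default (`split_multiallelic`
  opts into per-allele splitting); the candidate SNP panel is biallelic.
* The gene symbol `"NA"` in the packaged tables is a literal printed
  symbol and is preserved as such by the annotation parser.

## Problem sizes in the test suite

The suite exercises the study scale directly: calibration uses 500 null
SNPs at $n = 90$ with $B = 1000$ permutations; power and full-pipeline
properties use 10 seeded replicates at the same scale; large-sample
recovery uses $n = 2000$; the population-structure check uses the full
2708-sample five-population panel with 500 variants. `B = 10000` (the
protocol default) is reserved for real analyses; at desk scale
$B = 1000$ already gives a p-value grid of 1/1001, fine enough for every
property tested.

## Known limitations

* Kinship/mixed-model correction is out of scope; the PCs handle
  population-level structure only.
* One gene per SNP: multi-gene mappings and distance-based annotation are
  not supported.
* The combined score is a reconstruction (see above), and published
  enrichment scores depend on an external library version, so they are
  not reproduced numerically.
* No genome build handling: positions are taken as given; all inputs must
  share a build.
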