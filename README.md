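# chpvalid

Candidate-SNP validation and pathway analysis for cold-heat pattern
(C-HP) traits.

C-HP is a diagnostic framework of Traditional Korean Medicine that
classifies constitutional thermal sensitivity into a cold pattern (CP)
and a heat pattern (HP), each scored by questionnaire. Direct GWAS of
these scores is out of reach at typical cohort sizes, so the practical
route is validation: take SNPs already reported for adjacent traits
(cold/heat response, thyroid hormones — thyroid hormone drives
thermogenesis) and test those few hundred markers against the CP/HP
scores of a small cohort. `chpvalid` implements that pipeline for
researchers working at exactly this small-cohort scale:

* catalog filtering (X-chromosome, duplicate and ungenotyped records);
* per-SNP linear regression `score ~ age + sex + 5 PCs + dosage` with
  **Freedman-Lane residual-permutation** significance,
  `p = (1 + #{|t*| >= |t_obs|}) / (B + 1)`, the appropriate small-sample
  test when covariates must be respected under the null;
* LD pruning (50 kb / 5 markers / r² 0.2) feeding a
  variance-standardized GRM PCA, and greedy p-ordered LD clumping
  (p2 = 1, r² 0.2, 250 kb) for independent signals;
* SNP-to-gene mapping, hypergeometric over-representation with a
  Monte-Carlo combined score `c = -ln(p)·z`, top-5 pathway selection and
  a Jaccard (≥ 0.3) pathway-similarity network;
* control-trait comparison (same machinery, e.g. height/hair
  color/myopia records) to check specificity;
* synthetic-data generators (block-LD genotypes, Balding-Nichols
  structured panels, planted phenotype effects, catalogs, gene-set
  libraries) so the whole pipeline runs and is testable with no external
  data.

The published HP and CP candidate tables (20 and 19 SNPs) ship as
plain-text fixtures: `load_candidate_fixture("HP")` /
`load_candidate_fixture("CP")`, with their SNP-to-gene annotation at
`candidate_annotation_path()`.

See the vignette (`vignettes/chp-validation-methods.Rmd`) for the model,
the design decisions and what the synthetic tests do and do not show.

## Worked example

A fully synthetic study at the cohort's scale — 90 samples, 550 reported
SNPs in LD blocks, three planted CP effects of ±3 score units:

```r
library(chpvalid)
td <- tempfile(); dir.create(td)

gm <- simulate_genotypes(90, 550, seed = 42)
planted <- setNames(c(3, -3, 3), gm$variants$id[c(60, 260, 460)])
ph  <- simulate_phenotypes(gm, pheno_model_spec(causal_cp = planted), seed = 43)
cat <- simulate_catalog(gm, c("cold_heat", "thyroid"), seed = 44)
gs  <- simulate_gene_sets(40, c(5, 25), 600, seed = 45, snp_ids = gm$variants$id)

write_vcf(gm, file.path(td, "geno.vcf"))
write_phenotypes(ph, file.path(td, "pheno.tsv"))
write_catalog(cat, file.path(td, "catalog.tsv"))
write_annotation(gs$annotation, file.path(td, "annotation.tsv"))
write_gmt(gs$library, file.path(td, "library.gmt"))

cfg <- pipeline_config(
  vcf = file.path(td, "geno.vcf"), phenotypes = file.path(td, "pheno.tsv"),
  catalog = file.path(td, "catalog.tsv"),
  annotation = file.path(td, "annotation.tsv"),
  gmt = file.path(td, "library.gmt"),
  out_dir = file.path(td, "run"), seed = 7, score = "CP", B = 1000)
run_pipeline(cfg)

read.delim(file.path(td, "run", "candidates_CP.tsv"))[,
  c("snp", "gene", "maf", "beta", "se", "permutation_p")]
```

```
        snp      gene        maf      beta       se permutation_p
1  sim00055 GENE00284 0.06666667  5.169917 2.443015   0.038961039
2  sim00056 GENE00247 0.43333333  3.199547 1.425076   0.028971029
3  sim00059 GENE00194 0.17222222  3.527227 1.522365   0.019980020
...
8  sim00260 GENE00547 0.33333333 -2.908713 1.105023   0.006993007
...
18 sim00460 GENE00142 0.41666667  3.992549 1.194444   0.000999001
...
20 sim00519 GENE00581 0.18888889 -3.790819 1.461661   0.008991009
```

The manifest records the selection funnel
(`catalog 606 -> selected 550 -> tested 550 -> significant 20 ->
clumps 20`). The planted loci surface among the candidates — `sim00260`
and `sim00460` directly, the third through its LD block
(`sim00059`/`sim00056` sit next to the planted `sim00060`) — alongside
the ~5% of null SNPs expected at `alpha = 0.05` without multiple-testing
correction (the pipeline warns about exactly that). Each candidate row
mirrors the published table layout: effect allele, MAF among analyzed
samples, per-allele beta and SE in score units, and the permutation p.

`render_report(file.path(td, "run"))` writes a markdown summary;
`genotype_pca()`, `enrich()`, `similarity_network()` and
`control_comparison()` are usable directly as building blocks.

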