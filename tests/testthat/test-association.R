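make_catalog_rows <- function(snp, chrom, pos, p, category = "thyroid") {
  data.frame(snp = snp, chrom = chrom, pos = pos,
             trait = "Thyroid-stimulating hormone", category = category,
             effect_allele = "G", reported_beta = NA_real_, reported_p = p,
             stringsAsFactors = FALSE)
}

test_that("catalog selection removes X, collapses duplicates, drops ungenotyped", {
  gm <- gm_from_dosages(matrix(c(0, 1, 2, 1, 0, 1, 2, 2), nrow = 4))
  cat <- rbind(
    make_catalog_rows("v001", "1", 1e6, 1e-8),
    make_catalog_rows("vX", "X", 5e5, 1e-12),
    make_catalog_rows("v002", "1", 1e6 + 10000, 1e-5),
    make_catalog_rows("v002", "1", 1e6 + 10000, 1e-10),
    make_catalog_rows("missing", "2", 2e6, 1e-9))
  sel <- select_reported_snps(cat, gm)
  expect_equal(sort(sel$retained$snp), c("v001", "v002"))
  # the duplicate with the smaller reported p survives
  expect_equal(sel$retained$reported_p[sel$retained$snp == "v002"], 1e-10)
  expect_equal(sel$log$reason[sel$log$snp == "vX"], "chrX")
  expect_equal(sel$log$reason[sel$log$snp == "missing"], "not_genotyped")
  expect_true("duplicate" %in% sel$log$reason)
})

test_that("allele frequency and MAF follow the non-missing denominator", {
  expect_equal(compute_maf(c(0, 1, 2, 1, 0)), list(alt_freq = 0.4, maf = 0.4))
  expect_equal(compute_maf(c(2, 2, 2)), list(alt_freq = 1.0, maf = 0.0))
  expect_equal(compute_maf(c(0, NA, 2))$alt_freq, 0.5)
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("OLS matches exact fits and the normal-equations oracle", {
  fit <- fit_linear(c(1, 2, 3), cbind(1, x = c(0, 1, 2)))
  expect_equal(unname(fit$coefficients), c(1, 1))
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)

  x <- c(-3, 0.5, 2, 10)
  fit2 <- fit_linear(x, cbind(1, x = x))
  expect_equal(fit2$coefficients[["x"]], 1)

  set.seed(77)
  for (rep in 1:5) {
    X <- cbind(1, matrix(rnorm(30 * 3), 30))
    y <- rnorm(30)
    fit <- fit_linear(y, X)
    oracle <- ols_normal_equations(y, X)
    expect_equal(unname(fit$coefficients), unname(oracle$beta),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-8)
    # residuals orthogonal to every design column
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8 * 30)
  }
  expect_error(fit_linear(rnorm(5), cbind(1, c(1, 1, 1, 1, 1))),
               "rank-deficient")
  expect_error(fit_linear(rnorm(3), cbind(1, rnorm(3), rnorm(3))), "n <=")
})

test_that("residual permutation follows the add-one rule and matches a literal refit", {
  set.seed(5)
  n <- 50
  Z <- cbind(1, age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  g <- rbinom(n, 2, 0.4)
  # overwhelming effect: observed |t| beats every permutation
  y <- drop(Z %*% c(10, 0.05, 1)) + 5 * g + rnorm(n, 0, 0.5)
  rp <- residual_permutation(y, Z, g, permutation_spec(B = 99, seed = 2))
  expect_equal(rp$p, 1 / 100)

  # dual route: literal per-permutation lm refit
  y2 <- drop(Z %*% c(10, 0.05, 1)) + 0.4 * g + rnorm(n)
  rp2 <- residual_permutation(y2, Z, g, permutation_spec(B = 199, seed = 3))
  red <- lm.fit(Z, y2)
  set.seed(3)
  idx <- vapply(1:199, function(i) sample.int(n), integer(n))
  t_ref <- vapply(1:199, function(b) {
    ys <- red$fitted.values + red$residuals[idx[, b]]
    abs(coef(summary(lm(ys ~ Z[, -1] + g)))["g", "t value"])
  }, 0)
  expect_equal(rp2$p, (1 + sum(t_ref >= rp2$t_obs)) / 200, tolerance = 1e-12)

  expect_error(residual_permutation(y, Z, rep(1, n)), "no_variation")
  expect_error(permutation_spec(B = 0), "B must be")
})

test_that("permutation p is deterministic given the seed", {
  set.seed(8)
  n <- 40
  Z <- cbind(1, rnorm(n))
  g <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  a <- residual_permutation(y, Z, g, permutation_spec(500, seed = 10))
  b <- residual_permutation(y, Z, g, permutation_spec(500, seed = 10))
  expect_identical(a, b)
})

test_that("association scan is invariant to joint sample reordering and logs skips", {
  gm <- simulate_genotypes(60, 30, seed = 14)
  gm$dosages[1:5, 3] <- NA  # exercise per-SNP complete-case analysis
  mono <- gm$variants$id[8]
  gm$dosages[, 8] <- 1  # heterozygous everywhere: no variation
  ph <- simulate_phenotypes(gm, pheno_model_spec(noise_sd = 4), seed = 15)
  pca <- genotype_pca(gm, k = 5)
  out <- run_association(gm, ph, "CP", n_pcs = 5,
                         spec = permutation_spec(100, seed = 1), pca = pca)
  expect_equal(out$skipped$snp, mono)
  expect_equal(out$skipped$reason, "no_variation")
  expect_equal(out$results$n_analyzed[out$results$snp == gm$variants$id[3]],
               55)

  # joint permutation of rows leaves every statistic unchanged
  perm <- sample(seq_along(gm$samples))
  gm2 <- genotype_matrix(gm$samples[perm], gm$variants,
                         gm$dosages[perm, , drop = FALSE])
  ph2 <- ph[rev(seq_len(nrow(ph))), ]
  out2 <- run_association(gm2, ph2, "CP", n_pcs = 5,
                          spec = permutation_spec(100, seed = 1), pca = pca)
  expect_equal(out, out2)
})

test_that("nuisance PCs barely move effect estimates on unstructured data", {
  gm <- simulate_genotypes(2000, 300, ld = ld_block_spec(rho = 0), seed = 18)
  id <- gm$variants$id[10]
  ph <- simulate_phenotypes(gm, pheno_model_spec(
    causal_cp = setNames(2, id), noise_sd = 3), seed = 19)
  pca <- genotype_pca(gm, k = 5)
  spec <- permutation_spec(B = 5, seed = 4)
  with_pcs <- run_association(gm, ph, "CP", n_pcs = 5, spec = spec,
                              pca = pca)$results
  without <- run_association(gm, ph, "CP", n_pcs = 0, spec = spec)$results
  # estimated PCs are never exactly orthogonal to a tested SNP, so betas
  # shift by a finite-sample amount; it must stay well below the typical SE
  shift <- abs(with_pcs$beta - without$beta)
  expect_lt(mean(shift), 0.25 * median(without$se))
  expect_lt(max(shift), 1.5 * median(without$se))
  # and the planted effect is recovered on both routes
  expect_lt(abs(with_pcs$beta[with_pcs$snp == id] - 2),
            3 * with_pcs$se[with_pcs$snp == id])
  expect_lt(abs(without$beta[without$snp == id] - 2),
            3 * without$se[without$snp == id])
})

test_that("significance filter is strict and ratios are sum-consistent", {
  res <- data.frame(snp = c("a", "b", "c"),
                    permutation_p = c(0.049, 0.050, 0.2))
  kept <- filter_significant(res)
  expect_equal(kept$snp, "a")
  expect_equal(nrow(filter_significant(res[0, ])), 0)

  by_cat <- list(
    thyroid = data.frame(permutation_p = c(0.01, 0.2, 0.3, 0.04)),
    cold_heat = data.frame(permutation_p = c(0.6, 0.7)))
  tab <- significant_ratio(by_cat)
  expect_equal(tab$ratio[tab$category == "thyroid"], 0.5)
  expect_equal(tab$ratio[tab$category == "cold_heat"], 0)
  comb <- tab[tab$category == "combined", ]
  expect_equal(comb$ratio, sum(tab$n_significant[1:2]) / sum(tab$n_tested[1:2]))
  expect_error(significant_ratio(list(x = data.frame())), "empty category")
})

test_that("planted SNPs outrank null SNPs through the full association scan", {
  planted_better <- 0
  for (r in 1:10) {
    gm <- simulate_genotypes(90, 500, ld = ld_block_spec(10, 0.8, 5000),
                             seed = 9000 + r)
    ids <- gm$variants$id[c(50, 150, 250, 350, 450)]
    ph <- simulate_phenotypes(gm, pheno_model_spec(
      causal_cp = setNames(c(3, -3, 3, -3, 3), ids)), seed = 9100 + r)
    pca <- genotype_pca(gm, k = 5, prune_first = prune_spec())
    out <- run_association(gm, ph, "CP", n_pcs = 5,
                           spec = permutation_spec(1000, seed = 9200 + r),
                           pca = pca)$results
    med_planted <- median(out$permutation_p[out$snp %in% ids])
    med_null <- median(out$permutation_p[!out$snp %in% ids])
    if (med_planted < med_null) planted_better <- planted_better + 1
  }
  expect_equal(planted_better, 10)
})

test_that("asymptotic and permutation p agree on unstructured null data", {
  gm <- simulate_genotypes(2000, 120, ld = ld_block_spec(rho = 0), seed = 25)
  ph <- simulate_phenotypes(gm, pheno_model_spec(noise_sd = 4), seed = 26)
  out <- run_association(gm, ph, "HP", n_pcs = 0,
                         spec = permutation_spec(200, seed = 5))$results
  rho <- cor(out$p_asymptotic, out$permutation_p, method = "spearman")
  expect_gt(rho, 0.95)
})
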