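test_that("dosage r2 is 1 for identical or flipped variants and ~0 for independent ones", {
  set.seed(1)
  g <- rbinom(200, 2, 0.4)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)  # allele-flip invariance
  g1 <- rbinom(5000, 2, 0.3)
  g2 <- rbinom(5000, 2, 0.3)
  expect_lt(ld_r2(g1, g2), 0.01)
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1))
  expect_error(ld_r2(g, rep(2, 200)), "no_variation")
})

test_that("pruning keeps one of a duplicated pair and leaves uncorrelated sets alone", {
  set.seed(2)
  g <- rbinom(100, 2, 0.4)
  dup <- gm_from_dosages(cbind(g, g), pos = c(1e6, 1e6 + 1000))
  kept <- ld_prune(dup, prune_spec())
  expect_length(kept, 1)

  ind <- gm_from_dosages(
    sapply(1:10, function(i) rbinom(300, 2, 0.4)), spacing = 4000)
  expect_length(ld_prune(ind, prune_spec()), 10)

  unsorted <- gm_from_dosages(cbind(g, g), pos = c(2e6, 1e6))
  expect_error(ld_prune(unsorted), "not position-sorted")
})

test_that("pruning removes the lower-MAF member of a violating pair", {
  set.seed(3)
  common <- rbinom(400, 2, 0.45)
  # rarer variant carrying most of the same signal
  rare <- ifelse(common == 2, 1, 0)
  gm <- gm_from_dosages(cbind(common, rare), pos = c(1e6, 1e6 + 1000))
  stopifnot(ld_r2(common, rare) >= 0.2)
  kept <- ld_prune(gm)
  expect_equal(kept, "v001")  # the common variant survives
})

test_that("pruning satisfies its post-condition and is idempotent on random instances", {
  for (seed in 1:4) {
    gm <- simulate_genotypes(150, 50, ld = ld_block_spec(8, 0.85, 6000),
                             seed = seed)
    kept <- ld_prune(gm)
    expect_lt(length(kept), 50)  # strong within-block LD forces removals
    expect_equal(nrow(prune_violations(gm, kept)), 0)
    expect_identical(ld_prune(subset_variants(gm, kept)), kept)  # idempotent
  }
})

test_that("clumping respects the p-ordering, distance and r2 gates", {
  set.seed(4)
  g <- rbinom(200, 2, 0.4)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 2 - x[i]; x }
  # three correlated SNPs within 250 kb
  gm <- gm_from_dosages(cbind(g, flip(g, 10), flip(g, 15)),
                        pos = c(1e6, 1.1e6, 1.2e6))
  res <- data.frame(snp = c("v001", "v002", "v003"),
                    permutation_p = c(1e-8, 1e-4, 0.03))
  cl <- ld_clump(res, gm, clump_spec())
  expect_length(cl, 1)
  expect_equal(cl[[1]]$index, "v001")
  expect_setequal(cl[[1]]$members$snp, c("v001", "v002", "v003"))
  expect_equal(min(cl[[1]]$members$p), cl[[1]]$members$p[1])

  # identical variants 300 kb apart: the distance gate separates them
  far <- gm_from_dosages(cbind(g, g), pos = c(1e6, 1.3e6 + 1))
  cl2 <- ld_clump(data.frame(snp = c("v001", "v002"),
                             permutation_p = c(1e-4, 1e-3)), far)
  expect_length(cl2, 2)

  # uncorrelated neighbours: the r2 gate separates them
  g2 <- rbinom(200, 2, 0.4)
  stopifnot(ld_r2(g, g2) < 0.1)
  near <- gm_from_dosages(cbind(g, g2), pos = c(1e6, 1.01e6))
  cl3 <- ld_clump(data.frame(snp = c("v001", "v002"),
                             permutation_p = c(1e-4, 1e-3)), near)
  expect_length(cl3, 2)
})

test_that("clumping equals the brute-force transcription on random small instances", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(3:12, 1)
    gm <- simulate_genotypes(80, m, ld = ld_block_spec(4, 0.8, 50000),
                             seed = seed + 100)
    res <- data.frame(snp = gm$variants$id,
                      permutation_p = round(runif(m), 3),
                      stringsAsFactors = FALSE)
    fast <- ld_clump(res, gm, clump_spec())
    slow <- clump_bruteforce(res, gm)
    expect_equal(length(fast), length(slow))
    for (k in seq_along(fast)) {
      expect_equal(fast[[k]]$index, slow[[k]]$index)
      expect_equal(sort(fast[[k]]$members$snp), slow[[k]]$members)
    }
  }
})

test_that("standardization centers, scales and drops monomorphic variants", {
  gm <- gm_from_dosages(cbind(c(0, 1, 2, 1), c(1, 1, 1, 1), c(0, 0, 0, 0)))
  std <- standardize_genotypes(gm)
  # alt frequency 0.5: (g - 1)/sqrt(0.5)
  expect_equal(unname(std$X[, "v001"]),
               c(-1, 0, 1, 0) / sqrt(0.5), tolerance = 1e-12)
  expect_equal(std$dropped, "v003")  # monomorphic at 0
  expect_true("v002" %in% std$kept)  # constant hets scale to zeros, kept
  expect_lt(max(abs(colMeans(std$X))), 1e-10)
})

test_that("PCA satisfies spectral identities and separates structured populations", {
  gm <- simulate_genotypes(200, 500, ld = ld_block_spec(rho = 0), seed = 31)
  pc <- genotype_pca(gm, k = 5)
  expect_equal(sum(pc$eigenvalues), pc$grm_trace, tolerance = 1e-6)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_true(all(pc$eigenvalues > -1e-8))
  # standardized GRM diagonal is ~1 on average
  expect_gt(pc$grm_trace / 200, 0.8)
  expect_lt(pc$grm_trace / 200, 1.2)
  gram <- crossprod(pc$coordinates)
  expect_lt(max(abs(gram - diag(5))), 1e-6)
  expect_error(genotype_pca(gm, k = 200), "k must be smaller")

  pan <- simulate_structured_genotypes(
    population_spec(c("A", "B"), c(150, 150), fst = 0.25), m = 500, seed = 32)
  pc2 <- genotype_pca(pan$gm, k = 2)
  x <- pc2$coordinates[, 1]
  within_sd <- sqrt(mean(c(var(x[pan$labels == "A"]),
                           var(x[pan$labels == "B"]))))
  gap <- abs(mean(x[pan$labels == "A"]) - mean(x[pan$labels == "B"])) /
    within_sd
  expect_gt(gap, 2)
})

test_that("PCA after pruning uses only the surviving variants", {
  gm <- simulate_genotypes(100, 60, ld = ld_block_spec(6, 0.95, 2000),
                           seed = 33)
  kept <- ld_prune(gm)
  pc <- genotype_pca(gm, k = 3, prune_first = prune_spec())
  expect_setequal(pc$variants_used, kept)
  expect_lt(pc$n_variants, 60)
})
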