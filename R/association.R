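#' Filter catalog records against the genotyped panel
#'
#' Applies the reported-SNP selection rules: X-chromosome records are
#' removed, duplicate rsIDs are collapsed to the record with the smallest
#' reported p (ties broken by file order), and records absent from the
#' genotype panel are dropped.
#'
#' @param catalog Catalog data frame ([read_catalog()] schema).
#' @param gm A [genotype_matrix()] defining which SNPs are genotyped.
#' @return List with `retained` (filtered catalog) and `log` (data frame of
#'   excluded records with machine-readable `reason` codes:
#'   `chrX`, `duplicate`, `not_genotyped`).
#' @export
select_reported_snps <- function(catalog, gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  log <- data.frame(snp = character(), reason = character(),
                    stringsAsFactors = FALSE)
  drop_log <- function(snps, reason) {
    rbind(log, data.frame(snp = snps,
                          reason = rep(reason, length(snps)),
                          stringsAsFactors = FALSE))
  }
  keep <- catalog
  on_x <- keep$chrom == "X"
  log <- drop_log(keep$snp[on_x], "chrX")
  keep <- keep[!on_x, , drop = FALSE]

  if (nrow(keep) > 0) {
    # collapse duplicates: smallest reported p wins, ties go to file order;
    # a missing p loses to any stated p
    pval <- ifelse(is.na(keep$reported_p), Inf, keep$reported_p)
    best <- tapply(seq_len(nrow(keep)), keep$snp, function(ix) {
      ix[which.min(pval[ix])]
    })
    dup_rows <- setdiff(seq_len(nrow(keep)), unlist(best))
    log <- drop_log(keep$snp[dup_rows], "duplicate")
    keep <- keep[sort(unlist(best)), , drop = FALSE]
  }

  absent <- !keep$snp %in% gm$variants$id
  log <- drop_log(keep$snp[absent], "not_genotyped")
  keep <- keep[!absent, , drop = FALSE]
  rownames(keep) <- NULL
  list(retained = keep, log = log)
}

#' Allele frequency and MAF of a dosage vector
#'
#' @param dosage Numeric vector of dosages in `{0, 1, 2, NA}`.
#' @return List with `alt_freq` (alternate-allele frequency over non-missing
#'   entries) and `maf` (`min(f, 1 - f)`).
#' @export
compute_maf <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (length(d) == 0) stop("all genotypes missing")
  f <- sum(d) / (2 * length(d))
  list(alt_freq = f, maf = min(f, 1 - f))
}

#' Ordinary least squares fit with classical inference
#'
#' QR-based least squares with standard errors from
#' \eqn{\hat\sigma^2 (X'X)^{-1}}, \eqn{\hat\sigma^2 = RSS/(n-k)}, t
#' statistics and two-sided p values from the t distribution with `n - k`
#' degrees of freedom.
#'
#' @param y Response vector.
#' @param X Design matrix (must include the intercept column explicitly;
#'   full rank, `n > k`).
#' @return Object of class `ols_fit`: list with `coefficients`, `se`, `t`,
#'   `p`, `residuals`, `fitted`, `df`, `sigma2`.
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (n != nrow(X)) stop("length(y) != nrow(X)")
  if (n <= k) stop("n <= number of design columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  qrX <- qr(X)
  if (qrX$rank < k) stop("rank-deficient design")
  beta <- qr.coef(qrX, y)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - k
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- stats::setNames(sqrt(sigma2 * diag(XtXinv)), colnames(X))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(coefficients = beta, se = se, t = tval, p = pval,
                 residuals = res, fitted = fitted, df = df,
                 sigma2 = sigma2),
            class = "ols_fit")
}

#' Permutation test specification
#'
#' @param B Number of permutations (default 10000, matching the analysis
#'   protocol).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permutation_spec`. The test statistic is fixed
#'   to the absolute t of the genotype term.
#' @export
permutation_spec <- function(B = 10000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  structure(list(B = as.integer(B), seed = as.integer(seed)),
            class = "permutation_spec")
}

#' Freedman-Lane residual permutation p value
#'
#' Fits the reduced model `y ~ Z`, then for each of `B` permutations forms
#' `y* = fitted + permuted residuals`, refits the full model `y* ~ Z + g`,
#' and records the absolute t statistic of `g`. The p value is
#' `(1 + #(|t*| >= |t_obs|)) / (B + 1)`, so it is never exactly zero and is
#' bounded below by `1/(B+1)`. The per-permutation refit is carried out with
#' exact projection algebra (the permuted response is projected off the
#' covariate space once), which is algebraically identical to refitting the
#' full model for every permutation.
#'
#' @param y Response vector.
#' @param Z Covariate matrix including the intercept column.
#' @param g Genotype dosage vector (must vary across samples).
#' @param spec A [permutation_spec()].
#' @return List with `p` (permutation p), `t_obs`, `beta`, `se` (full-model
#'   genotype coefficient and SE) and `B`.
#' @export
residual_permutation <- function(y, Z, g, spec = permutation_spec()) {
  stopifnot(inherits(spec, "permutation_spec"))
  Z <- as.matrix(Z)
  n <- length(y)
  if (stats::var(g) == 0) stop("no_variation: genotype is monomorphic")
  full <- fit_linear(y, cbind(Z, g = g))
  kf <- ncol(Z) + 1L
  t_obs <- abs(full$t[["g"]])

  qz <- qr(Z)
  Q <- qr.Q(qz)
  e <- qr.resid(qz, y)          # reduced-model residuals
  gp <- qr.resid(qz, g)         # genotype projected off covariates
  s_g <- sum(gp^2)
  df <- n - kf

  t_perm <- with_seed(spec$seed, {
    idx <- vapply(seq_len(spec$B), function(i) sample.int(n),
                  integer(n))
    E <- matrix(e[idx], nrow = n)           # n x B permuted residuals
    A <- drop(crossprod(gp, E))             # genotype score per permutation
    # residual sum of squares of y* ~ Z is ||M_Z E||^2 column-wise
    rss_z <- colSums(E^2) - colSums(crossprod(Q, E)^2)
    rss_full <- pmax(rss_z - A^2 / s_g, 0)
    abs(A / s_g) / sqrt(rss_full / df / s_g)
  })
  p <- (1 + sum(t_perm >= t_obs)) / (spec$B + 1)
  list(p = p, t_obs = t_obs, beta = full$coefficients[["g"]],
       se = full$se[["g"]], B = spec$B)
}

#' Per-SNP covariate-adjusted association scan
#'
#' For every variant of `gm`, fits
#' `score ~ intercept + age + sex + PCs + dosage` on the samples with a
#' non-missing genotype at that SNP (per-SNP complete-case analysis) and
#' computes both the asymptotic and the Freedman-Lane permutation p value
#' of the dosage term. SNPs that cannot be tested (monomorphic among
#' analyzed samples, too few samples) are recorded in the skip log rather
#' than silently dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param pheno Phenotype data frame ([read_phenotypes()] schema) covering
#'   all samples of `gm`.
#' @param score `"CP"` or `"HP"`: which questionnaire score is the response.
#' @param n_pcs Number of genotype principal components included as
#'   covariates (default 5). `pca` must be supplied when `n_pcs > 0`.
#' @param spec A [permutation_spec()]; per-SNP permutation seeds are derived
#'   deterministically from `spec$seed` and the variant id.
#' @param pca Optional [genotype_pca()] result providing the PC covariates.
#' @return List with `results` (data frame: snp, a1, a2, n_analyzed,
#'   alt_freq, maf, beta, se, t, p_asymptotic, permutation_p) and `skipped`
#'   (data frame of snp/reason).
#' @export
run_association <- function(gm, pheno, score = c("CP", "HP"), n_pcs = 5,
                            spec = permutation_spec(), pca = NULL) {
  score <- match.arg(score)
  stopifnot(inherits(gm, "genotype_matrix"))
  # canonical sample order: results (including the permutation stream) are
  # then invariant to jointly reordering genotype and phenotype rows
  ord <- order(gm$samples)
  samples <- gm$samples[ord]
  dosages <- gm$dosages[ord, , drop = FALSE]
  idx <- match(samples, pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table does not cover all samples")
  pheno <- pheno[idx, , drop = FALSE]
  y_all <- if (score == "CP") pheno$cp_score else pheno$hp_score

  covars <- cbind(intercept = 1, age = pheno$age, sex = pheno$sex)
  if (n_pcs > 0) {
    if (is.null(pca)) stop("pca result required when n_pcs > 0")
    coords <- pca$coordinates
    if (ncol(coords) < n_pcs) stop("pca has fewer components than n_pcs")
    cidx <- if (!is.null(rownames(coords))) match(samples, rownames(coords))
            else NULL
    if (is.null(cidx) || anyNA(cidx)) {
      stop("pca coordinates do not cover the genotype samples")
    }
    covars <- cbind(covars, coords[cidx, seq_len(n_pcs), drop = FALSE])
  }

  m <- nrow(gm$variants)
  rows <- vector("list", m)
  skipped <- list()
  for (j in seq_len(m)) {
    id <- gm$variants$id[j]
    d <- dosages[, j]
    ok <- !is.na(d)
    n_an <- sum(ok)
    if (n_an <= ncol(covars) + 1) {
      skipped[[length(skipped) + 1]] <- data.frame(
        snp = id, reason = "too_few_samples", stringsAsFactors = FALSE)
      next
    }
    g <- d[ok]
    if (stats::var(g) == 0) {
      skipped[[length(skipped) + 1]] <- data.frame(
        snp = id, reason = "no_variation", stringsAsFactors = FALSE)
      next
    }
    fr <- compute_maf(g)
    snp_spec <- permutation_spec(spec$B, derive_seed(spec$seed, id))
    perm <- residual_permutation(y_all[ok], covars[ok, , drop = FALSE],
                                 g, snp_spec)
    fit <- fit_linear(y_all[ok], cbind(covars[ok, , drop = FALSE], g = g))
    rows[[j]] <- data.frame(
      snp = id, a1 = gm$variants$alt[j], a2 = gm$variants$ref[j],
      n_analyzed = n_an, alt_freq = fr$alt_freq, maf = fr$maf,
      beta = fit$coefficients[["g"]], se = fit$se[["g"]],
      t = fit$t[["g"]], p_asymptotic = fit$p[["g"]],
      permutation_p = perm$p, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(results)) {
    results <- data.frame(snp = character(), a1 = character(),
                          a2 = character(), n_analyzed = integer(),
                          alt_freq = numeric(), maf = numeric(),
                          beta = numeric(), se = numeric(), t = numeric(),
                          p_asymptotic = numeric(),
                          permutation_p = numeric(),
                          stringsAsFactors = FALSE)
  }
  rownames(results) <- NULL
  skipped <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(snp = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(results = results, skipped = skipped)
}

#' Retain SNPs significant under the permutation test
#'
#' Strict inequality: a SNP is retained iff `permutation_p < alpha`.
#' No multiple-testing correction is applied, matching the validation
#' protocol; candidate counts should be read accordingly.
#'
#' @param results Association results data frame (with `permutation_p`).
#' @param alpha Significance level (default 0.05).
#' @return The significant subset of `results`.
#' @export
filter_significant <- function(results, alpha = 0.05) {
  out <- results[results$permutation_p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significant-SNP ratio per category
#'
#' The specificity statistic used to compare case and control traits: the
#' fraction of tested SNPs that pass the permutation filter, per category,
#' plus the combined ratio over all listed categories.
#'
#' @param results_by_category Named list of association results data frames
#'   (one per category, each with >= 1 tested SNP).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with `category`, `n_tested`, `n_significant`, `ratio`;
#'   the final row (`category == "combined"`) aggregates all categories.
#' @export
significant_ratio <- function(results_by_category, alpha = 0.05) {
  stopifnot(is.list(results_by_category),
            length(results_by_category) >= 1)
  rows <- lapply(names(results_by_category), function(ct) {
    res <- results_by_category[[ct]]
    if (nrow(res) == 0) stop("empty category: ", ct)
    data.frame(category = ct, n_tested = nrow(res),
               n_significant = nrow(filter_significant(res, alpha)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(category = "combined",
                               n_tested = sum(out$n_tested),
                               n_significant = sum(out$n_significant),
                               stringsAsFactors = FALSE))
  out$ratio <- out$n_significant / out$n_tested
  out
}
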