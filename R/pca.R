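#' Variance-standardize a genotype matrix
#'
#' Per variant `j` with alternate-allele frequency `p` (over non-missing
#' samples), dosages are transformed to `(g - 2p) / sqrt(2p(1-p))`;
#' missing entries become 0 after centering (i.e. they are imputed at the
#' variant mean, which contributes nothing to covariances). Monomorphic
#' variants (`p` 0 or 1, or all-missing) cannot be scaled and are dropped.
#'
#' @param gm A [genotype_matrix()].
#' @return List with `X` (n x m' standardized matrix, columns named by
#'   variant id), `kept` and `dropped` variant ids.
#' @export
standardize_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- nrow(gm$variants)
  freqs <- vapply(seq_len(m), function(j) {
    d <- gm$dosages[, j]
    if (all(is.na(d))) NA_real_ else sum(d, na.rm = TRUE) / (2 * sum(!is.na(d)))
  }, 0)
  keep <- !is.na(freqs) & freqs > 0 & freqs < 1
  X <- gm$dosages[, keep, drop = FALSE]
  p <- freqs[keep]
  X <- sweep(X, 2, 2 * p)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  colnames(X) <- gm$variants$id[keep]
  list(X = X, kept = gm$variants$id[keep],
       dropped = gm$variants$id[!keep])
}

#' Principal component analysis of a genotype matrix
#'
#' Eigendecomposition of the variance-standardized genetic relationship
#' matrix `GRM = X X' / m` (computed through the SVD of `X`, which gives
#' the same eigenpairs). Optionally the variant set is LD-pruned first, as
#' in the validation protocol, so the components reflect genome-wide
#' structure rather than single LD blocks. Each component's sign is fixed
#' so that its largest-magnitude sample loading is positive.
#'
#' @param gm A [genotype_matrix()].
#' @param k Number of components to return (`k < n`).
#' @param prune_first Optional [prune_spec()]; when supplied, [ld_prune()]
#'   is applied and the surviving variants feed the GRM.
#' @param scale_by_eigenvalue If `TRUE`, coordinates are eigenvectors scaled
#'   by the square root of their eigenvalue; default returns unit-norm
#'   eigenvector coordinates.
#' @return Object of class `genotype_pca`: list with `eigenvalues`
#'   (all `n`, descending; zeros padded beyond the rank), `coordinates`
#'   (n x k matrix, columns `PC1..PCk`), `variants_used`, `n_variants`,
#'   `grm_trace`.
#' @export
genotype_pca <- function(gm, k = 5, prune_first = NULL,
                         scale_by_eigenvalue = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$samples)
  if (k >= n) stop("k must be smaller than the sample count")
  use <- gm
  if (!is.null(prune_first)) {
    kept <- ld_prune(gm, prune_first)
    if (length(kept) == 0) stop("no variants survive pruning")
    use <- subset_variants(gm, kept)
  }
  std <- standardize_genotypes(use)
  if (ncol(std$X) == 0) stop("no polymorphic variants available for PCA")
  m <- ncol(std$X)
  sv <- svd(std$X, nu = min(n, m), nv = 0)
  ev <- numeric(n)
  ev[seq_along(sv$d)] <- sv$d^2 / m
  U <- sv$u[, seq_len(k), drop = FALSE]
  if (scale_by_eigenvalue) {
    U <- sweep(U, 2, sqrt(pmax(ev[seq_len(k)], 0)), "*")
  }
  for (j in seq_len(k)) {
    top <- which.max(abs(U[, j]))
    if (U[top, j] < 0) U[, j] <- -U[, j]
  }
  dimnames(U) <- list(gm$samples, paste0("PC", seq_len(k)))
  structure(list(eigenvalues = ev, coordinates = U,
                 variants_used = std$kept, n_variants = m,
                 grm_trace = sum(std$X^2) / m),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples, %d variants, %d components\n",
              nrow(x$coordinates), x$n_variants, ncol(x$coordinates)))
  pv <- x$eigenvalues[seq_len(ncol(x$coordinates))] / sum(x$eigenvalues)
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * pv), collapse = " "), "\n")
  invisible(x)
}
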