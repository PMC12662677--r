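# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage / per-item seed derived from a master seed.
# Kept strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483563) + 1L
}

# Strict numeric parser: refuses silent coercion of malformed fields.
parse_numeric <- function(x, what = "value", allow_missing = FALSE) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  missing_in <- is.na(x) | x == ""
  bad <- is.na(out) & !missing_in
  if (any(bad)) {
    stop(sprintf("malformed numeric %s: '%s'", what, x[which(bad)[1]]))
  }
  if (!allow_missing && any(missing_in)) {
    stop(sprintf("missing numeric %s", what))
  }
  out
}

#' Hudson's Fst estimator for two populations
#'
#' Ratio-of-averages Hudson estimator over biallelic variants:
#' numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)},
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, where \eqn{p_i} are sample
#' alt-allele frequencies and \eqn{n_i} allele counts. Used to verify that
#' simulated structured panels achieve their target divergence.
#'
#' @param gm A [genotype_matrix()].
#' @param labels Population label per sample (exactly two distinct values).
#' @return Single numeric Fst estimate (averaged over variants).
#' @export
hudson_fst <- function(gm, labels) {
  stopifnot(inherits(gm, "genotype_matrix"))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(gm$samples))
  lv <- unique(labels)
  if (length(lv) != 2) stop("hudson_fst needs exactly two populations")
  g1 <- gm$dosages[labels == lv[1], , drop = FALSE]
  g2 <- gm$dosages[labels == lv[2], , drop = FALSE]
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(g1))
  n2 <- 2 * colSums(!is.na(g2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
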