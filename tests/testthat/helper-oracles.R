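# Independent oracles and small builders used across test files.

# OLS through explicit normal equations (independent of the package's QR path).
ols_normal_equations <- function(y, X) {
  X <- as.matrix(X)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  list(beta = drop(beta), se = se)
}

# Literal greedy clumping written as a direct transcription of the rule:
# full r2 matrix, explicit ordering, no candidate pre-filtering.
clump_bruteforce <- function(results, gm, p2 = 1, r2 = 0.2, kb = 250,
                             p_col = "permutation_p") {
  n <- nrow(results)
  idx <- match(results$snp, gm$variants$id)
  p <- results[[p_col]]
  pos <- gm$variants$pos[idx]
  chrom <- gm$variants$chrom[idx]
  R2 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        a <- gm$dosages[, idx[i]]; b <- gm$dosages[, idx[j]]
        ok <- !is.na(a) & !is.na(b)
        R2[i, j] <- if (sum(ok) >= 2 && var(a[ok]) > 0 && var(b[ok]) > 0)
          cor(a[ok], b[ok])^2 else 0
      }
    }
  }
  ord <- order(p, pos, results$snp)
  assigned <- rep(FALSE, n)
  clumps <- list()
  for (o in ord) {
    if (assigned[o]) next
    assigned[o] <- TRUE
    members <- o
    for (cc in ord) {
      if (assigned[cc]) next
      if (p[cc] <= p2 && chrom[cc] == chrom[o] &&
          abs(pos[cc] - pos[o]) <= kb * 1000 && R2[cc, o] >= r2) {
        assigned[cc] <- TRUE
        members <- c(members, cc)
      }
    }
    clumps[[length(clumps) + 1]] <- list(index = results$snp[o],
                                         members = sort(results$snp[members]))
  }
  clumps
}

# Exhaustive hypergeometric tail: enumerate every possible draw of
# `list_size` genes from the background and count draws whose overlap with
# the term is at least the observed one.
hyper_tail_enumerate <- function(n_overlap, term_size, list_size, bg_size) {
  draws <- combn(bg_size, list_size)
  # term occupies the first `term_size` background slots wlog
  hits <- colSums(draws <= term_size)
  mean(hits >= n_overlap)
}

# Convex-polygon intersection test (exact, for hull disjointness checks).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 && min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) ||
    on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

point_in_convex_hull <- function(pt, hull) {
  n <- nrow(hull)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (hull[j, 1] - hull[i, 1]) * (pt[2] - hull[i, 2]) -
      (hull[j, 2] - hull[i, 2]) * (pt[1] - hull[i, 1])
    if (cr != 0) {
      if (sgn == 0) sgn <- sign(cr)
      else if (sign(cr) != sgn) return(FALSE)
    }
  }
  TRUE
}

hulls_disjoint <- function(xy_a, xy_b) {
  ha <- xy_a[chull(xy_a), , drop = FALSE]
  hb <- xy_b[chull(xy_b), , drop = FALSE]
  for (i in seq_len(nrow(xy_a))) {
    if (point_in_convex_hull(xy_a[i, ], hb)) return(FALSE)
  }
  for (i in seq_len(nrow(xy_b))) {
    if (point_in_convex_hull(xy_b[i, ], ha)) return(FALSE)
  }
  na <- nrow(ha); nb <- nrow(hb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_intersect(ha[i, ], ha[if (i == na) 1 else i + 1, ],
                             hb[j, ], hb[if (j == nb) 1 else j + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Small hand-rolled VCF text builder for parser tests.
write_vcf_text <- function(path, samples, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# Genotype matrix built directly from a dosage matrix (variants 10 kb apart).
gm_from_dosages <- function(dos, chrom = "1", spacing = 10000,
                            pos = NULL) {
  m <- ncol(dos)
  variants <- data.frame(
    id = sprintf("v%03d", seq_len(m)), chrom = chrom,
    pos = if (is.null(pos)) as.integer(1e6 + (seq_len(m) - 1) * spacing)
          else as.integer(pos),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(sprintf("s%03d", seq_len(nrow(dos))), variants, dos)
}
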