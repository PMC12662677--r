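#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' Composite (unphased) r-squared: the squared Pearson correlation of the
#' two dosage vectors over pairwise-complete samples. Invariant to allele
#' flips (`g -> 2 - g`) and symmetric in its arguments.
#'
#' @param g1,g2 Dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("no_variation: monomorphic input")
  }
  stats::cor(a, b)^2
}

# r2 that treats monomorphic/degenerate pairs as unlinked (internal).
ld_r2_safe <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(0)
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) return(0)
  stats::cor(g1[ok], g2[ok])^2
}

#' LD pruning specification
#'
#' @param window_kb Window width in kilobases (markers within this distance
#'   of the window-start marker form a window).
#' @param step_markers Markers by which consecutive windows advance.
#' @param r2_threshold Pairs at or above this r-squared are thinned.
#' @return Object of class `prune_spec`. Defaults are 50 kb / 5 markers /
#'   0.2, the parameters of the validation protocol.
#' @export
prune_spec <- function(window_kb = 50, step_markers = 5, r2_threshold = 0.2) {
  stopifnot(window_kb > 0, step_markers > 0, r2_threshold > 0)
  structure(list(window_kb = window_kb,
                 step_markers = as.integer(step_markers),
                 r2_threshold = r2_threshold),
            class = "prune_spec")
}

#' Window-based LD pruning
#'
#' Sliding windows of `window_kb` advance by `step_markers` along each
#' chromosome (variants must be position-sorted within chromosomes). Inside
#' a window, while any kept pair has r-squared at or above the threshold,
#' the pair member with the lower MAF is removed (equal MAF: the larger
#' position goes). Passes repeat until one removes nothing, so the output
#' satisfies the no-violating-pair post-condition and pruning its own
#' output changes nothing.
#'
#' @param gm A [genotype_matrix()].
#' @param spec A [prune_spec()].
#' @return Character vector of surviving variant ids (original order).
#' @export
ld_prune <- function(gm, spec = prune_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "prune_spec"))
  v <- gm$variants
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    if (is.unsorted(p)) stop("variants not position-sorted on chromosome ", ch)
  }
  maf <- apply(gm$dosages, 2, function(d) {
    if (all(is.na(d))) 0 else compute_maf(d)$maf
  })
  kept <- rep(TRUE, nrow(v))
  window_bp <- spec$window_kb * 1000

  repeat {
    removed_any <- FALSE
    for (ch in unique(v$chrom)) {
      chrom_idx <- which(v$chrom == ch & kept)
      if (length(chrom_idx) < 2) next
      starts <- chrom_idx[seq(1, length(chrom_idx), by = spec$step_markers)]
      for (s in starts) {
        if (!kept[s]) next
        repeat {
          win <- which(kept & v$chrom == ch &
                         v$pos >= v$pos[s] & v$pos <= v$pos[s] + window_bp)
          if (length(win) < 2) break
          viol <- NULL
          for (a in seq_len(length(win) - 1)) {
            for (b in (a + 1):length(win)) {
              i <- win[a]; j <- win[b]
              if (ld_r2_safe(gm$dosages[, i], gm$dosages[, j]) >=
                  spec$r2_threshold) {
                viol <- c(i, j)
                break
              }
            }
            if (!is.null(viol)) break
          }
          if (is.null(viol)) break
          i <- viol[1]; j <- viol[2]
          drop <- if (maf[i] < maf[j]) i
                  else if (maf[j] < maf[i]) j
                  else if (v$pos[i] >= v$pos[j]) i else j
          kept[drop] <- FALSE
          removed_any <- TRUE
        }
      }
    }
    if (!removed_any) break
  }
  v$id[kept]
}

#' Scan a variant set for pruning violations
#'
#' Applies the same window definition as [ld_prune()] (windows start every
#' `step_markers` surviving markers and span `window_kb`) to an arbitrary
#' kept set and reports every co-resident pair with r-squared at or above
#' the threshold. [ld_prune()] output yields zero violations.
#'
#' @param gm A [genotype_matrix()].
#' @param kept Character vector of variant ids to scan.
#' @param spec A [prune_spec()].
#' @return Data frame with columns `a`, `b`, `r2` (one row per violating
#'   pair; zero rows when the set is clean).
#' @export
prune_violations <- function(gm, kept, spec = prune_spec()) {
  sub <- subset_variants(gm, kept)
  v <- sub$variants
  window_bp <- spec$window_kb * 1000
  out <- data.frame(a = character(), b = character(), r2 = numeric(),
                    stringsAsFactors = FALSE)
  for (ch in unique(v$chrom)) {
    chrom_idx <- which(v$chrom == ch)
    if (length(chrom_idx) < 2) next
    starts <- chrom_idx[seq(1, length(chrom_idx), by = spec$step_markers)]
    for (s in starts) {
      win <- chrom_idx[v$pos[chrom_idx] >= v$pos[s] &
                         v$pos[chrom_idx] <= v$pos[s] + window_bp]
      if (length(win) < 2) next
      for (a in seq_len(length(win) - 1)) {
        for (b in (a + 1):length(win)) {
          r2 <- ld_r2_safe(sub$dosages[, win[a]], sub$dosages[, win[b]])
          if (r2 >= spec$r2_threshold) {
            out <- rbind(out, data.frame(a = v$id[win[a]], b = v$id[win[b]],
                                         r2 = r2, stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  unique(out)
}

#' LD clumping specification
#'
#' @param p2 Membership p-value ceiling (default 1).
#' @param r2 Minimum r-squared with the index SNP (default 0.2).
#' @param kb Maximum distance from the index SNP in kilobases (default 250).
#' @return Object of class `clump_spec`. Defaults mirror the protocol's
#'   `--clump-p2 1 --clump-r2 0.2 --clump-kb 250`.
#' @export
clump_spec <- function(p2 = 1, r2 = 0.2, kb = 250) {
  stopifnot(p2 > 0, p2 <= 1, r2 > 0, r2 <= 1, kb > 0)
  structure(list(p2 = p2, r2 = r2, kb = kb), class = "clump_spec")
}

#' Greedy p-value-ordered LD clumping
#'
#' Association results are sorted by p ascending (ties: smaller position,
#' then lexicographic id). Repeatedly, the best unassigned SNP becomes an
#' index; every unassigned SNP with `p <= p2`, on the same chromosome,
#' within `kb` kilobases of the index (inclusive) and with
#' `r2(snp, index) >= r2` joins its clump. Membership is assessed against
#' the index only (no transitive chaining). The retained independent set is
#' the index SNPs.
#'
#' @param results Association results data frame (column `snp` plus the
#'   p-value column).
#' @param gm A [genotype_matrix()] containing every result SNP.
#' @param spec A [clump_spec()].
#' @param p_col Which p value orders the clumping: `"permutation_p"`
#'   (default) or `"p_asymptotic"`.
#' @return List of clumps, each a list with `index` (snp id) and `members`
#'   (data frame: snp, p, r2 with the index; the index is its own first
#'   member with r2 = 1).
#' @export
ld_clump <- function(results, gm, spec = clump_spec(),
                     p_col = c("permutation_p", "p_asymptotic")) {
  p_col <- match.arg(p_col)
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "clump_spec"))
  if (nrow(results) == 0) return(list())
  idx <- match(results$snp, gm$variants$id)
  if (anyNA(idx)) {
    stop("result SNP(s) missing from genotype matrix: ",
         paste(utils::head(results$snp[is.na(idx)], 5), collapse = ", "))
  }
  p <- results[[p_col]]
  pos <- gm$variants$pos[idx]
  chrom <- gm$variants$chrom[idx]
  ord <- order(p, pos, results$snp)
  assigned <- rep(FALSE, nrow(results))
  clumps <- list()
  for (o in ord) {
    if (assigned[o]) next
    assigned[o] <- TRUE
    member_rows <- o
    member_r2 <- 1
    cand <- which(!assigned & p <= spec$p2 & chrom == chrom[o] &
                    abs(pos - pos[o]) <= spec$kb * 1000)
    for (cc in cand) {
      r2 <- ld_r2_safe(gm$dosages[, idx[cc]], gm$dosages[, idx[o]])
      if (r2 >= spec$r2) {
        assigned[cc] <- TRUE
        member_rows <- c(member_rows, cc)
        member_r2 <- c(member_r2, r2)
      }
    }
    clumps[[length(clumps) + 1]] <- list(
      index = results$snp[o],
      members = data.frame(snp = results$snp[member_rows],
                           p = p[member_rows], r2 = member_r2,
                           stringsAsFactors = FALSE))
  }
  clumps
}

#' Index SNPs of a clump list
#'
#' @param clumps Output of [ld_clump()].
#' @return Character vector of index snp ids.
#' @export
clump_index_snps <- function(clumps) {
  vapply(clumps, `[[`, "", "index")
}
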