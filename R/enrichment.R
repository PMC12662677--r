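#' Map SNP ids to gene symbols through an annotation table
#'
#' One gene per SNP; the returned gene list is de-duplicated in order of
#' first appearance. SNPs absent from the annotation are reported with a
#' warning, never silently dropped.
#'
#' @param snp_ids Character vector of SNP ids.
#' @param annotation Data frame with `snp` and `gene` columns
#'   ([read_annotation()]).
#' @return Character vector of gene symbols.
#' @export
map_snps_to_genes <- function(snp_ids, annotation) {
  snp_ids <- unique(as.character(snp_ids))
  if (length(snp_ids) == 0) return(character())
  hit <- match(snp_ids, annotation$snp)
  if (anyNA(hit)) {
    warning("unmapped SNP id(s): ",
            paste(utils::head(snp_ids[is.na(hit)], 10), collapse = ", "))
  }
  unique(annotation$gene[hit[!is.na(hit)]])
}

#' Hypergeometric over-representation test
#'
#' Upper-tail p value `P(X >= overlap)` for the overlap between a gene list
#' and a term under hypergeometric sampling from the background
#' (enrichment is one-sided by construction). The odds ratio comes from the
#' 2x2 membership table, with a Haldane 0.5 correction when any cell is 0.
#'
#' @param genes Query gene list (non-empty; must lie within `background`).
#' @param term_genes Term gene set (must lie within `background`).
#' @param background Background gene universe.
#' @return List with `p`, `odds_ratio`, `overlap` (the overlapping genes),
#'   `n_overlap`, `list_size`, `term_size`, `background_size`.
#' @export
ora_test <- function(genes, term_genes, background) {
  genes <- unique(as.character(genes))
  term_genes <- unique(as.character(term_genes))
  background <- unique(as.character(background))
  if (length(genes) == 0) stop("empty gene list")
  if (length(setdiff(genes, background)) > 0) {
    stop("gene list not contained in background")
  }
  if (length(setdiff(term_genes, background)) > 0) {
    stop("term not contained in background")
  }
  overlap <- intersect(genes, term_genes)
  a <- length(overlap)
  N <- length(background); K <- length(term_genes); n <- length(genes)
  p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  b <- n - a; cc <- K - a; d <- N - K - b
  if (min(a, b, cc, d) == 0) {
    a2 <- a + 0.5; b2 <- b + 0.5; c2 <- cc + 0.5; d2 <- d + 0.5
  } else {
    a2 <- a; b2 <- b; c2 <- cc; d2 <- d
  }
  list(p = p, odds_ratio = (a2 * d2) / (b2 * c2), overlap = overlap,
       n_overlap = a, list_size = n, term_size = K, background_size = N)
}

# Vectorized hypergeometric p for all terms of a membership matrix.
# M: terms x background logical membership; idx: background indices drawn.
ora_p_all <- function(M, idx, N) {
  K <- rowSums(M)
  a <- rowSums(M[, idx, drop = FALSE])
  stats::phyper(a - 1, K, N - K, length(idx), lower.tail = FALSE)
}

#' Over-representation analysis with Monte-Carlo combined scores
#'
#' Tests every term of the library against the gene list with the
#' hypergeometric tail, then calibrates a rank-deviation z score by ranking
#' each term's p value against `R` random gene lists of the same size drawn
#' from the background: `z = (expected rank - observed rank) / sd(rank)`
#' (a term whose rank sd is 0 gets `z = 0`), and the combined score is
#' `c = -ln(p) * z`. The combined score is a reconstruction of the familiar
#' enrichment ranking statistic; its absolute scale depends on `R` and the
#' library and is not comparable across libraries.
#'
#' @param genes Query gene list.
#' @param lib A [gene_set_library()].
#' @param background Optional explicit background; default is the library's
#'   background (or the union of its terms).
#' @param R Random lists used for rank calibration (>= 1).
#' @param seed Integer seed for the calibration draws.
#' @return Data frame with one row per term: `term`, `n_overlap`,
#'   `list_size`, `term_size`, `background_size`, `overlap_genes`
#'   (semicolon-collapsed), `p`, `odds_ratio`, `z`, `combined`, sorted by
#'   p ascending.
#' @export
enrich <- function(genes, lib, background = NULL, R = 1000, seed = 1) {
  stopifnot(inherits(lib, "gene_set_library"))
  if (R < 1) stop("R must be >= 1")
  if (length(lib$terms) == 0) {
    return(data.frame(term = character(), n_overlap = integer(),
                      list_size = integer(), term_size = integer(),
                      background_size = integer(),
                      overlap_genes = character(), p = numeric(),
                      odds_ratio = numeric(), z = numeric(),
                      combined = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(background)) background <- library_background(lib)
  background <- unique(as.character(background))
  genes <- unique(as.character(genes))
  genes <- intersect(genes, background)  # genes outside the universe cannot inform
  if (length(genes) == 0) stop("no query genes in background")

  res <- lapply(names(lib$terms), function(tn) {
    r <- ora_test(genes, lib$terms[[tn]], background)
    data.frame(term = tn, n_overlap = r$n_overlap, list_size = r$list_size,
               term_size = r$term_size, background_size = r$background_size,
               overlap_genes = paste(sort(r$overlap), collapse = ";"),
               p = r$p, odds_ratio = r$odds_ratio,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  # Monte-Carlo rank calibration
  M <- do.call(rbind, lapply(lib$terms, function(g) background %in% g))
  N <- length(background)
  obs_rank <- rank(res$p, ties.method = "average")
  ranks <- with_seed(seed, {
    out <- matrix(0, nrow = R, ncol = nrow(res))
    for (r in seq_len(R)) {
      idx <- sample.int(N, length(genes))
      out[r, ] <- rank(ora_p_all(M, idx, N), ties.method = "average")
    }
    out
  })
  mu <- colMeans(ranks)
  sdv <- apply(ranks, 2, stats::sd)
  z <- ifelse(sdv == 0, 0, (mu - obs_rank) / sdv)
  res$z <- z
  res$combined <- -log(res$p) * z
  res <- res[order(res$p, -res$combined, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select the top enriched pathways
#'
#' Ascending p value; ties prefer the larger combined score, then the term
#' name. At most `k` rows are returned.
#'
#' @param results Enrichment data frame ([enrich()]).
#' @param k Number of pathways to keep (default 5).
#' @return The top rows of `results`.
#' @export
top_pathways <- function(results, k = 5) {
  if (nrow(results) == 0) return(results)
  ord <- order(results$p, -results$combined, results$term)
  out <- results[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard coefficient of two gene sets
#'
#' @param a,b Character vectors (at least one non-empty).
#' @return `|a intersect b| / |a union b|`, in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) stop("both sets empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Pathway similarity network from shared genes
#'
#' One node per pathway; an undirected edge joins two pathways whenever the
#' Jaccard coefficient of their gene sets is at or above the threshold.
#' The edge set does not depend on the order the pathways are given in.
#'
#' @param pathways Named list of gene sets (pathway name -> genes).
#' @param threshold Minimum Jaccard coefficient for an edge (default 0.3).
#' @return Object of class `pathway_network`: list with `nodes`, `edges`
#'   (data frame `a`, `b`, `jaccard`, with `a < b` lexicographically and
#'   rows sorted), `threshold`, `density` (edges over possible pairs; 0 for
#'   fewer than 2 nodes) and `components` (membership vector).
#' @export
similarity_network <- function(pathways, threshold = 0.3) {
  stopifnot(is.list(pathways))
  if (length(pathways) > 0 && is.null(names(pathways))) {
    stop("pathways must be named")
  }
  nodes <- names(pathways)
  edges <- data.frame(a = character(), b = character(), jaccard = numeric(),
                      stringsAsFactors = FALSE)
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        J <- jaccard(pathways[[i]], pathways[[j]])
        if (J >= threshold) {
          ab <- sort(c(nodes[i], nodes[j]))
          edges <- rbind(edges, data.frame(a = ab[1], b = ab[2], jaccard = J,
                                           stringsAsFactors = FALSE))
        }
      }
    }
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  # connected components by label propagation over the edge list
  comp <- stats::setNames(seq_along(nodes), nodes)
  if (nrow(edges) > 0) {
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        ca <- comp[[edges$a[e]]]; cb <- comp[[edges$b[e]]]
        if (ca != cb) {
          comp[comp == max(ca, cb)] <- min(ca, cb)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  comp <- stats::setNames(match(comp, sort(unique(comp))), nodes)
  density <- if (length(nodes) < 2) 0 else
    nrow(edges) / choose(length(nodes), 2)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 density = density, components = comp),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("pathway_network: %d nodes, %d edges (J >= %g), density %.3f, %d component(s)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$density,
              length(unique(x$components))))
  invisible(x)
}

# Per-trait summary row shared by control_comparison.
trait_summary_row <- function(trait, assoc, enrichment = NULL,
                              network = NULL, alpha = 0.05, k = 5) {
  sig <- filter_significant(assoc, alpha)
  top <- if (is.null(enrichment) || nrow(enrichment) == 0) character() else
    top_pathways(enrichment, k)$term
  data.frame(trait = trait, n_tested = nrow(assoc),
             n_significant = nrow(sig),
             ratio = if (nrow(assoc) > 0) nrow(sig) / nrow(assoc) else NA_real_,
             top_pathways = paste(top, collapse = ";"),
             network_density = if (is.null(network)) NA_real_ else
               network$density,
             stringsAsFactors = FALSE)
}

#' Case versus control-trait specificity comparison
#'
#' Summarizes the case trait and each control trait with the same pipeline
#' settings side by side: tested and significant SNP counts, the
#' significant-SNP ratio, the top enriched pathways and the similarity
#' network density.
#'
#' @param case List with elements `trait` (label), `assoc` (association
#'   results data frame) and optionally `enrichment` ([enrich()] output)
#'   and `network` ([similarity_network()] output).
#' @param controls List of such lists, one per control trait.
#' @param alpha Significance level (default 0.05).
#' @param k Pathways listed per trait (default 5).
#' @return Data frame with the case row first, one row per control after.
#' @export
control_comparison <- function(case, controls = list(), alpha = 0.05, k = 5) {
  rows <- list(trait_summary_row(case$trait, case$assoc, case$enrichment,
                                 case$network, alpha, k))
  for (ctl in controls) {
    rows[[length(rows) + 1]] <- trait_summary_row(
      ctl$trait, ctl$assoc, ctl$enrichment, ctl$network, alpha, k)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
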