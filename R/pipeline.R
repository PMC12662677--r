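#' Pipeline configuration
#'
#' Collects every input path and tuning parameter of the end-to-end
#' validation pipeline. Defaults mirror the analysis protocol: 10,000
#' permutations, alpha 0.05, pruning 50 kb / 5 markers / r2 0.2, clumping
#' p2 1 / r2 0.2 / 250 kb, 5 covariate PCs, top-5 pathways, Jaccard
#' threshold 0.3.
#'
#' @param vcf,phenotypes,catalog,annotation,gmt Input file paths (VCF,
#'   phenotype TSV, catalog TSV, SNP-to-gene TSV, GMT).
#' @param out_dir Output run directory (created if absent).
#' @param seed Master seed; per-stage seeds are derived from it
#'   deterministically, so each stage is independently reproducible.
#' @param score `"CP"`, `"HP"` or `"both"`.
#' @param B Permutation count.
#' @param alpha Significance level.
#' @param n_pcs Covariate principal components.
#' @param prune,clump [prune_spec()] and [clump_spec()].
#' @param top_k Pathways kept per score.
#' @param jaccard_threshold Network edge threshold.
#' @param enrich_R Monte-Carlo draws for the combined-score calibration.
#' @param clump_before_filter The protocol's stated order (the default,
#'   `FALSE`) clumps the permutation-significant SNPs; set `TRUE` to clump
#'   all tested SNPs first and then apply the significance filter to the
#'   index SNPs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, phenotypes, catalog, annotation, gmt,
                            out_dir, seed, score = c("both", "CP", "HP"),
                            B = 10000, alpha = 0.05, n_pcs = 5,
                            prune = prune_spec(), clump = clump_spec(),
                            top_k = 5, jaccard_threshold = 0.3,
                            enrich_R = 1000, clump_before_filter = FALSE) {
  score <- match.arg(score)
  if (missing(seed)) stop("config error: seed is required")
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha outside (0, 1)")
  for (p in c(vcf, phenotypes, catalog, annotation, gmt)) {
    if (!file.exists(p)) stop("config error: input path does not exist: ", p)
  }
  structure(list(vcf = vcf, phenotypes = phenotypes, catalog = catalog,
                 annotation = annotation, gmt = gmt, out_dir = out_dir,
                 seed = as.integer(seed), score = score, B = as.integer(B),
                 alpha = alpha, n_pcs = as.integer(n_pcs), prune = prune,
                 clump = clump, top_k = as.integer(top_k),
                 jaccard_threshold = jaccard_threshold,
                 enrich_R = as.integer(enrich_R),
                 clump_before_filter = clump_before_filter),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the end-to-end candidate-SNP validation pipeline
#'
#' Stages: catalog filtering -> LD-pruned covariate PCA -> per-SNP
#' covariate-adjusted association with residual-permutation significance
#' (per selected score) -> significance filter -> LD clumping ->
#' SNP-to-gene mapping -> over-representation with combined scores ->
#' top-pathway selection -> Jaccard similarity network -> control-trait
#' comparison (when the catalog carries `control` records). All outputs are
#' TSV files plus a JSON manifest (parameters, seed, versions, per-stage
#' record counts) in the run directory; runs with the same config and seed
#' are byte-identical. No multiple-testing correction is applied across
#' SNPs (a warning is emitted, mirroring the protocol).
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gm <- stage("read_vcf", read_vcf(config$vcf))
  pheno <- stage("read_phenotypes", read_phenotypes(config$phenotypes))
  catalog <- stage("read_catalog", read_catalog(config$catalog))
  annotation <- stage("read_annotation", read_annotation(config$annotation))
  lib <- stage("read_gmt", read_gmt(config$gmt))

  sel <- stage("select_reported_snps", select_reported_snps(catalog, gm))
  write_tsv(sel$log, file.path(config$out_dir, "exclusions.tsv"))
  if (nrow(sel$retained) == 0) stop("pipeline stage 'select_reported_snps' failed: no records retained")
  gm_sel <- subset_variants(gm, sel$retained$snp)

  pca <- stage("pca", genotype_pca(gm_sel, k = max(config$n_pcs, 2),
                                   prune_first = config$prune))
  pca_tab <- data.frame(sample_id = rownames(pca$coordinates),
                        pca$coordinates, stringsAsFactors = FALSE)
  write_tsv(pca_tab, file.path(config$out_dir, "pca.tsv"))

  warning("no multiple-testing correction is applied across SNPs; ",
          "permutation p values are per-SNP", call. = FALSE)

  is_control <- sel$retained$category == "control"
  case_cat <- sel$retained[!is_control, , drop = FALSE]
  counts <- list(catalog = nrow(catalog), selected = nrow(sel$retained),
                 case_selected = nrow(case_cat))
  scores <- if (config$score == "both") c("CP", "HP") else config$score

  analyze_group <- function(label, snp_ids, score) {
    gm_g <- subset_variants(gm_sel, snp_ids)
    spec <- permutation_spec(config$B,
                             derive_seed(config$seed,
                                         paste0("assoc_", score, "_", label)))
    assoc <- stage(paste0("association_", label),
                   run_association(gm_g, pheno, score,
                                   n_pcs = config$n_pcs, spec = spec,
                                   pca = pca))
    res <- assoc$results
    if (config$clump_before_filter) {
      clumps <- if (nrow(res) > 0)
        ld_clump(res, gm_g, config$clump) else list()
      res <- res[res$snp %in% clump_index_snps(clumps), , drop = FALSE]
      sig <- filter_significant(res, config$alpha)
    } else {
      sig <- filter_significant(res, config$alpha)
      clumps <- if (nrow(sig) > 0)
        ld_clump(sig, gm_g, config$clump) else list()
      sig <- sig[sig$snp %in% clump_index_snps(clumps), , drop = FALSE]
    }
    genes <- map_snps_to_genes(sig$snp, annotation)
    enr <- NULL
    net <- NULL
    if (length(genes) > 0) {
      bg <- union(library_background(lib), genes)
      enr <- stage(paste0("enrich_", label),
                   enrich(genes, lib, background = bg, R = config$enrich_R,
                          seed = derive_seed(config$seed,
                                             paste0("enrich_", score, "_",
                                                    label))))
      enr_sig <- enr[enr$p < config$alpha, , drop = FALSE]
      top <- top_pathways(enr_sig, config$top_k)
      sets <- lapply(top$term, function(tn) lib$terms[[tn]])
      names(sets) <- top$term
      net <- similarity_network(sets, config$jaccard_threshold)
    }
    list(assoc = assoc, results = assoc$results, significant = sig,
         clumps = clumps, genes = genes, enrichment = enr, network = net)
  }

  manifest_counts <- counts
  for (score in scores) {
    case <- analyze_group("case", case_cat$snp, score)
    pre <- sel$retained[match(case$significant$snp, sel$retained$snp), ]
    cand <- data.frame(
      snp = case$significant$snp, chrom = pre$chrom, pos = pre$pos,
      reported_trait = pre$trait, category = pre$category,
      gene = map_per_snp(case$significant$snp, annotation),
      a1 = case$significant$a1, a2 = case$significant$a2,
      maf = case$significant$maf, beta = case$significant$beta,
      se = case$significant$se,
      permutation_p = case$significant$permutation_p,
      pattern = score, stringsAsFactors = FALSE)
    write_tsv(case$results,
              file.path(config$out_dir, paste0("assoc_", score, ".tsv")))
    write_tsv(cand,
              file.path(config$out_dir, paste0("candidates_", score, ".tsv")))
    if (!is.null(case$enrichment)) {
      write_tsv(case$enrichment,
                file.path(config$out_dir, paste0("enrichment_", score, ".tsv")))
    }
    if (!is.null(case$network)) {
      write_tsv(case$network$edges,
                file.path(config$out_dir, paste0("network_", score, ".tsv")))
    }
    manifest_counts[[paste0("tested_", score)]] <- nrow(case$results)
    manifest_counts[[paste0("significant_", score)]] <- nrow(case$significant)
    manifest_counts[[paste0("clumps_", score)]] <- length(case$clumps)

    if (any(is_control)) {
      ctl_rows <- sel$retained[is_control, , drop = FALSE]
      controls <- lapply(unique(ctl_rows$trait), function(tr) {
        grp <- analyze_group(paste0("control_", gsub("\\W+", "_", tr)),
                             ctl_rows$snp[ctl_rows$trait == tr], score)
        list(trait = tr, assoc = grp$results, enrichment = grp$enrichment,
             network = grp$network)
      })
      cmp <- control_comparison(
        list(trait = "case", assoc = case$results,
             enrichment = case$enrichment, network = case$network),
        controls, alpha = config$alpha, k = config$top_k)
      write_tsv(cmp, file.path(config$out_dir,
                               paste0("control_comparison_", score, ".tsv")))
    }
  }

  manifest <- list(
    package = "chpvalid",
    version = as.character(utils::packageVersion("chpvalid")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(score = config$score, B = config$B,
                      alpha = config$alpha, n_pcs = config$n_pcs,
                      prune = unclass(config$prune),
                      clump = unclass(config$clump),
                      top_k = config$top_k,
                      jaccard_threshold = config$jaccard_threshold,
                      enrich_R = config$enrich_R,
                      clump_before_filter = config$clump_before_filter),
    counts = manifest_counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

# One gene per SNP, preserving SNP order (NA for unmapped).
map_per_snp <- function(snp_ids, annotation) {
  annotation$gene[match(snp_ids, annotation$snp)]
}

#' Count candidate rows passing the permutation filter
#'
#' @param rows Candidate table ([load_candidate_fixture()] schema or the
#'   pipeline's `candidates_*.tsv`).
#' @param pattern `"HP"` or `"CP"`.
#' @param category Optional category restriction (`"thyroid"`,
#'   `"cold_heat"` or `"control"`).
#' @param alpha Significance level (default 0.05); rows count only when
#'   `permutation_p < alpha` (strict).
#' @return Integer count.
#' @export
count_candidates <- function(rows, pattern, category = NULL, alpha = 0.05) {
  if (!pattern %in% c("HP", "CP")) stop("unknown pattern: ", pattern)
  keep <- rows$pattern == pattern & rows$permutation_p < alpha
  if (!is.null(category)) {
    if (!category %in% catalog_categories()) {
      stop("unknown category: ", category)
    }
    keep <- keep & rows$category == category
  }
  sum(keep)
}

#' Render a human-readable run report
#'
#' Reads a completed run directory and writes `report.md`: candidate tables
#' per pattern, top pathways, network statistics and the PCA coordinate
#' file reference. Re-rendering an unchanged run directory reproduces the
#' same report.
#'
#' @param run_dir Run directory produced by [run_pipeline()].
#' @return Character vector of report lines, invisibly; the report is also
#'   written to `<run_dir>/report.md`.
#' @export
render_report <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("incomplete run directory: no manifest")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  lines <- c("# Candidate SNP validation report", "",
             sprintf("- package: %s %s", mf$package, mf$version),
             sprintf("- seed: %d", mf$seed),
             sprintf("- permutations: %d, alpha: %g",
                     mf$parameters$B, mf$parameters$alpha), "")
  for (score in c("CP", "HP")) {
    lines <- c(lines, sprintf("## %s (%s pattern)", score,
                              if (score == "CP") "cold" else "heat"), "")
    cand_path <- file.path(run_dir, paste0("candidates_", score, ".tsv"))
    if (!file.exists(cand_path)) {
      lines <- c(lines, "not run", "")
      next
    }
    cand <- utils::read.delim(cand_path, stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("%d candidate SNP(s):", nrow(cand)))
    if (nrow(cand) > 0) {
      lines <- c(lines, "", "| snp | gene | maf | beta | se | permutation p |",
                 "|---|---|---|---|---|---|",
                 sprintf("| %s | %s | %.3f | %.3f | %.3f | %.3g |",
                         cand$snp, cand$gene, cand$maf, cand$beta, cand$se,
                         cand$permutation_p))
    }
    enr_path <- file.path(run_dir, paste0("enrichment_", score, ".tsv"))
    lines <- c(lines, "", sprintf("### Top pathways (%s)", score), "")
    if (file.exists(enr_path)) {
      enr <- utils::read.delim(enr_path, stringsAsFactors = FALSE)
      top <- utils::head(enr, 5)
      lines <- c(lines,
                 sprintf("- %s (p = %.3g, combined = %.1f)",
                         top$term, top$p, top$combined))
    } else {
      lines <- c(lines, "not run")
    }
    net_path <- file.path(run_dir, paste0("network_", score, ".tsv"))
    if (file.exists(net_path)) {
      net <- utils::read.delim(net_path, stringsAsFactors = FALSE)
      lines <- c(lines, "",
                 sprintf("Similarity network: %d edge(s).", nrow(net)))
    }
    lines <- c(lines, "")
  }
  if (file.exists(file.path(run_dir, "pca.tsv"))) {
    lines <- c(lines, "PCA coordinates: pca.tsv", "")
  }
  writeLines(lines, file.path(run_dir, "report.md"))
  invisible(lines)
}
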