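#' Genotype matrix container
#'
#' A `genotype_matrix` holds a samples x variants alt-allele dosage matrix
#' (entries 0, 1, 2 or `NA` for missing) together with per-variant metadata.
#' It is the substrate of the association, LD and PCA stages.
#'
#' @param samples Character vector of sample ids (unique, non-empty).
#' @param variants Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#'   Positions are 1-based as in VCF; chromosome labels are autosomes
#'   `"1"`..`"22"` plus `"X"` (recognized only so it can be excluded upstream).
#' @param dosages Numeric matrix, `length(samples)` rows by `nrow(variants)`
#'   columns, entries in `{0, 1, 2, NA}`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `variants` and `dosages` (dimnames set to sample and
#'   variant ids).
#' @export
genotype_matrix <- function(samples, variants, dosages) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(variants))
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("variants is missing column(s): ", paste(miss, collapse = ", "))
  }
  variants <- variants[, req]
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants)) {
    stop("dosage matrix dimensions do not match sample/variant counts")
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (any(!is.na(variants$pos) & variants$pos < 1L)) stop("positions must be >= 1")
  if (any(variants$id == "")) stop("empty variant id")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(samples, variants$id)
  rownames(variants) <- NULL
  structure(list(samples = samples, variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat(sprintf("  missing genotypes: %d (%.2f%%)\n",
                          nm, 100 * nm / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variant id
#'
#' @param gm A `genotype_matrix`.
#' @param ids Variant ids to keep, in the requested order.
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_variants <- function(gm, ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- match(ids, gm$variants$id)
  if (anyNA(idx)) {
    stop("unknown variant id(s): ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  genotype_matrix(gm$samples, gm$variants[idx, , drop = FALSE],
                  gm$dosages[, idx, drop = FALSE])
}

#' Extract one variant's dosage vector
#'
#' @param gm A `genotype_matrix`.
#' @param id Variant id.
#' @return Named numeric vector of dosages (one per sample).
#' @export
dosage_of <- function(gm, id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(id, gm$variants$id)
  if (is.na(j)) stop("unknown variant id: ", id)
  gm$dosages[, j]
}

# Recognized chromosome labels: autosomes and X (X only so that catalog
# filtering can exclude it explicitly).
recognized_chroms <- function() c(as.character(1:22), "X")
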