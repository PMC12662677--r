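#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) and converts diploid GT calls to
#' alt-allele dosages: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`.
#' Phased separators (`|`) are accepted and treated as unphased.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param split_multiallelic Multi-allelic records are rejected by default;
#'   set `TRUE` to split them into one biallelic record per alternate allele
#'   (ids suffixed `_alt<k>`, dosage counting that allele only).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, split_multiallelic = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  if (anyDuplicated(fix$ID[!is.na(fix$ID)])) {
    stop("duplicate variant id in VCF: ",
         fix$ID[duplicated(fix$ID)][1])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(v@gt)[-1]

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (!multi[i]) {
      rows[[i]] <- data.frame(row = i, alt_idx = 1L,
                              id = fix$ID[i], alt = fix$ALT[i],
                              stringsAsFactors = FALSE)
    } else if (!split_multiallelic) {
      stop("multi-allelic record at ", fix$CHROM[i], ":", fix$POS[i],
           " (", fix$ID[i], "); set split_multiallelic = TRUE to split")
    } else {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      rows[[i]] <- data.frame(row = i, alt_idx = seq_along(alts),
                              id = paste0(fix$ID[i], "_alt", seq_along(alts)),
                              alt = alts, stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  if (anyDuplicated(plan$id)) {
    stop("duplicate variant id in VCF: ",
         plan$id[duplicated(plan$id)][1])
  }

  dos <- matrix(NA_real_, nrow = length(samples), ncol = nrow(plan),
                dimnames = list(samples, plan$id))
  for (k in seq_len(nrow(plan))) {
    calls <- gt[plan$row[k], ]
    dos[, k] <- gt_to_dosage(calls, alt_idx = plan$alt_idx[k],
                             where = paste0(fix$CHROM[plan$row[k]], ":",
                                            fix$POS[plan$row[k]]))
  }
  variants <- data.frame(id = plan$id,
                         chrom = fix$CHROM[plan$row],
                         pos = as.integer(fix$POS[plan$row]),
                         ref = fix$REF[plan$row],
                         alt = plan$alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(samples, variants, dos)
}

# Convert one variant's GT strings to dosages of alternate allele `alt_idx`.
gt_to_dosage <- function(calls, alt_idx = 1L, where = "?") {
  out <- rep(NA_real_, length(calls))
  for (s in seq_along(calls)) {
    g <- calls[s]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) next
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2) {
      stop("non-diploid GT '", g, "' at ", where)
    }
    if (any(al == ".")) next  # half-missing treated as missing
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai)) stop("malformed GT '", g, "' at ", where)
    out[s] <- sum(ai == alt_idx)
  }
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal GT-only VCF: unphased `/` separator, missing genotypes as
#' `./.`. Dosage 0 becomes `0/0`, 1 becomes `0/1`, 2 becomes `1/1`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write VCF to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$variants))) {
    d <- gm$dosages[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1])
    writeLines(paste(c(gm$variants$chrom[j], gm$variants$pos[j],
                       gm$variants$id[j], gm$variants$ref[j],
                       gm$variants$alt[j], ".", ".", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with header columns `sample_id`, `cp_score`, `hp_score`,
#' `age`, `sex` (sex coded 0/1). All covariates must be present and finite.
#'
#' @param path Path to a TSV file.
#' @return Data frame with one row per sample.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("sample_id", "cp_score", "hp_score", "age", "sex")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("phenotype table missing column(s): ",
                             paste(miss, collapse = ", "))
  out <- data.frame(sample_id = tab$sample_id,
                    cp_score = parse_numeric(tab$cp_score, "cp_score"),
                    hp_score = parse_numeric(tab$hp_score, "hp_score"),
                    age = parse_numeric(tab$age, "age"),
                    sex = parse_numeric(tab$sex, "sex"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample id in phenotypes")
  if (!all(is.finite(out$cp_score)) || !all(is.finite(out$hp_score))) {
    stop("non-finite phenotype score")
  }
  if (!all(out$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  out
}

#' @rdname read_phenotypes
#' @param pheno Phenotype data frame as returned by [read_phenotypes()].
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

catalog_categories <- function() c("cold_heat", "thyroid", "control")

#' Read a GWAS-catalog-style reported-SNP table
#'
#' TSV with columns `snp`, `chrom`, `pos`, `trait`, `category`,
#' `effect_allele`, `reported_beta` (may be empty), `reported_p`.
#' Categories come from the controlled vocabulary `cold_heat`, `thyroid`,
#' `control`; malformed numerics and unknown categories are errors, never
#' silently coerced.
#'
#' @param path Path to a TSV file.
#' @return Data frame of catalog records (0 rows for an empty file).
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  req <- c("snp", "chrom", "pos", "trait", "category", "effect_allele",
           "reported_beta", "reported_p")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("catalog missing column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    return(data.frame(snp = character(), chrom = character(),
                      pos = integer(), trait = character(),
                      category = character(), effect_allele = character(),
                      reported_beta = numeric(), reported_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  bad <- !tab$category %in% catalog_categories()
  if (any(bad)) stop("unknown catalog category: '", tab$category[bad][1], "'")
  p <- parse_numeric(tab$reported_p, "reported_p", allow_missing = TRUE)
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("reported_p outside (0, 1]")
  data.frame(snp = tab$snp, chrom = tab$chrom,
             pos = as.integer(parse_numeric(tab$pos, "pos")),
             trait = tab$trait, category = tab$category,
             effect_allele = tab$effect_allele,
             reported_beta = parse_numeric(tab$reported_beta, "reported_beta",
                                           allow_missing = TRUE),
             reported_p = p, stringsAsFactors = FALSE)
}

#' @rdname read_catalog
#' @param catalog Catalog data frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Gene-set library container
#'
#' @param terms Named list: term name -> character vector of gene symbols
#'   (each non-empty; duplicates within a term are removed).
#' @param descriptions Optional named character vector of term descriptions.
#' @param background Optional character vector of background genes; when
#'   supplied, every term must be a subset of it. When absent, the union of
#'   all term genes acts as the default background.
#' @return Object of class `gene_set_library`.
#' @export
gene_set_library <- function(terms, descriptions = NULL, background = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) > 0 && is.null(names(terms))) stop("terms must be named")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(vapply(terms, length, 1L) == 0)) stop("empty gene set")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  }
  if (!is.null(background)) {
    background <- unique(as.character(background))
    out <- setdiff(unique(unlist(terms)), background)
    if (length(out) > 0) {
      stop("term gene(s) outside supplied background: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  structure(list(terms = terms,
                 descriptions = descriptions[names(terms)],
                 background = background),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library: %d terms, background %s\n",
              length(x$terms),
              if (is.null(x$background)) "implicit (union of terms)"
              else length(x$background)))
  invisible(x)
}

# Effective background of a library.
library_background <- function(lib) {
  if (!is.null(lib$background)) lib$background else unique(unlist(lib$terms))
}

#' Read / write GMT gene-set files
#'
#' GMT lines are `term TAB description TAB gene1 TAB gene2 ...`; duplicate
#' genes within a line are de-duplicated, the description survives a
#' round-trip.
#'
#' @param path Path to a GMT file.
#' @return [gene_set_library()] for `read_gmt`; `path` invisibly for
#'   `write_gmt`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gene_set_library(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  }
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(terms))) stop("duplicate term name in GMT")
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), names(terms))
  gene_set_library(terms, desc)
}

#' @rdname read_gmt
#' @param lib A [gene_set_library()].
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "gene_set_library"))
  lines <- vapply(names(lib$terms), function(tn) {
    paste(c(tn, lib$descriptions[[tn]], lib$terms[[tn]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP-to-gene annotation table
#'
#' TSV with columns `snp` and `gene` (one gene per SNP); `#` lines are
#' comments. Gene symbols are kept verbatim (the literal string `"NA"` is a
#' valid printed symbol, not a missing value).
#'
#' @param path Path to a TSV file.
#' @return Data frame with `snp` and `gene` columns.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character", na.strings = NULL)
  if (!all(c("snp", "gene") %in% names(tab))) {
    stop("annotation must have 'snp' and 'gene' columns")
  }
  tab[, c("snp", "gene")]
}

#' @rdname read_annotation
#' @param annotation Annotation data frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("snp", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged candidate-SNP tables
#'
#' Returns the published heat-pattern (HP) or cold-pattern (CP) candidate
#' SNP table shipped with the package, transcribed verbatim: per SNP the
#' reported trait and mapped gene, the originally reported effect and p
#' value, and the in-house replication (alleles, MAF as printed, beta, SE,
#' permutation p). The `maf` column reproduces the printed values, which for
#' some rows track the effect-allele rather than the minor-allele frequency;
#' they are not reinterpreted.
#'
#' @param pattern `"HP"` (heat) or `"CP"` (cold).
#' @return Data frame of candidate rows with a `pattern` column appended.
#' @export
load_candidate_fixture <- function(pattern = c("HP", "CP")) {
  pattern <- match.arg(pattern)
  fn <- if (pattern == "HP") "table1_hp_candidates.tsv" else "table2_cp_candidates.tsv"
  path <- system.file("extdata", fn, package = "chpvalid", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  out <- data.frame(
    snp = tab$snp, chrom = tab$chrom,
    pos = as.integer(parse_numeric(tab$pos, "pos")),
    reported_trait = tab$reported_trait, gene = tab$gene,
    category = tab$category,
    gwas_beta = parse_numeric(tab$gwas_beta, "gwas_beta", allow_missing = TRUE),
    gwas_a1 = ifelse(tab$gwas_a1 == "", NA_character_, tab$gwas_a1),
    gwas_p = parse_numeric(tab$gwas_p, "gwas_p"),
    a2 = tab$a2, a1 = tab$a1,
    maf = parse_numeric(tab$maf, "maf"),
    beta = parse_numeric(tab$beta, "beta"),
    se = parse_numeric(tab$se, "se"),
    permutation_p = parse_numeric(tab$permutation_p, "permutation_p"),
    pattern = pattern, stringsAsFactors = FALSE)
  stopifnot(all(out$category %in% c("thyroid", "cold_heat")),
            all(out$permutation_p > 0 & out$permutation_p < 1))
  out
}

#' Path to the packaged SNP-to-gene annotation for the candidate tables
#'
#' @return File path of the packaged annotation TSV.
#' @export
candidate_annotation_path <- function() {
  system.file("extdata", "snp_gene_annotation.tsv", package = "chpvalid",
              mustWork = TRUE)
}
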