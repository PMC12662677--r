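#' LD block specification
#'
#' Parameters of the Gaussian-copula block-LD genotype generator: variants
#' are grouped into blocks of `block_size` adjacent markers whose latent
#' Gaussians follow an AR(1) process with coefficient `rho`, independent
#' across blocks, so squared dosage correlation decays geometrically with
#' marker distance inside a block.
#'
#' @param block_size Markers per block (>= 1).
#' @param rho Adjacent latent correlation, in `[0, 1)`.
#' @param spacing_bp Base-pair distance between adjacent markers (>= 1).
#' @return Object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(block_size = 10, rho = 0.8, spacing_bp = 5000) {
  stopifnot(block_size >= 1, spacing_bp >= 1)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(list(block_size = as.integer(block_size), rho = rho,
                 spacing_bp = as.integer(spacing_bp)),
            class = "ld_block_spec")
}

#' Simulate genotypes with block LD
#'
#' Draws per-variant latent standard Gaussians with AR(1) correlation `rho`
#' within blocks (independent across blocks), then thresholds each latent
#' value at the Hardy-Weinberg genotype quantiles for that variant's target
#' alternate-allele frequency, drawn uniformly from `maf_range`. Positions
#' are laid out every `spacing_bp` base pairs on a single chromosome.
#'
#' @param n Number of samples (>= 2).
#' @param m Number of variants (>= 1).
#' @param maf_range Range for the target alternate-allele frequency.
#' @param ld An [ld_block_spec()].
#' @param seed Integer seed; the output is bit-reproducible given
#'   `(seed, parameters)`.
#' @param chrom Chromosome label for all variants.
#' @param start_pos Position of the first variant.
#' @return A [genotype_matrix()] with variant ids `sim00001`, ...
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld = ld_block_spec(), seed = 1,
                               chrom = "1", start_pos = 1e6) {
  stopifnot(n >= 2, m >= 1, inherits(ld, "ld_block_spec"))
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair inside (0, 1)")
  }
  with_seed(seed, {
    freqs <- stats::runif(m, maf_range[1], maf_range[2])
    dos <- matrix(0, n, m)
    j <- 1L
    while (j <= m) {
      bs <- min(ld$block_size, m - j + 1L)
      z <- matrix(0, n, bs)
      z[, 1] <- stats::rnorm(n)
      if (bs > 1) {
        for (b in 2:bs) {
          z[, b] <- ld$rho * z[, b - 1] +
            sqrt(1 - ld$rho^2) * stats::rnorm(n)
        }
      }
      for (b in seq_len(bs)) {
        p <- freqs[j + b - 1L]
        # HWE genotype quantiles for alt frequency p
        q0 <- stats::qnorm((1 - p)^2)
        q1 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
        dos[, j + b - 1L] <- ifelse(z[, b] < q0, 0, ifelse(z[, b] < q1, 1, 2))
      }
      j <- j + bs
    }
    variants <- data.frame(
      id = sprintf("sim%05d", seq_len(m)), chrom = chrom,
      pos = as.integer(start_pos + (seq_len(m) - 1) * ld$spacing_bp),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    genotype_matrix(sprintf("S%04d", seq_len(n)), variants, dos)
  })
}

#' Population panel specification
#'
#' @param labels Population labels. Defaults mirror the five continental
#'   reference groups.
#' @param sizes Samples per population (each >= 2). Defaults mirror the
#'   reference panel sizes (EUR 533, EAS 539, AMR 373, SAS 544, AFR 719).
#' @param fst Balding-Nichols divergence parameter, in `(0, 1)`.
#' @param maf_range Range of the ancestral allele frequency.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(labels = c("EUR", "EAS", "AMR", "SAS", "AFR"),
                            sizes = c(533, 539, 373, 544, 719),
                            fst = 0.1, maf_range = c(0.1, 0.9)) {
  stopifnot(length(labels) == length(sizes), all(sizes >= 2))
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  structure(list(labels = as.character(labels), sizes = as.integer(sizes),
                 fst = fst, maf_range = maf_range),
            class = "population_spec")
}

#' Simulate a structured multi-population panel (Balding-Nichols model)
#'
#' For each variant an ancestral frequency `p` is drawn uniformly from the
#' spec's range; each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` and genotypes are `Binomial(2, p_pop)`.
#'
#' @param spec A [population_spec()].
#' @param m Number of variants.
#' @param seed Integer seed (bit-reproducible output).
#' @param spacing_bp Base-pair spacing between adjacent variants.
#' @return List with elements `gm` (a [genotype_matrix()]) and `labels`
#'   (population label per sample).
#' @export
simulate_structured_genotypes <- function(spec, m, seed = 1,
                                          spacing_bp = 10000) {
  stopifnot(inherits(spec, "population_spec"), m >= 1)
  with_seed(seed, {
    n <- sum(spec$sizes)
    labels <- rep(spec$labels, spec$sizes)
    f <- spec$fst
    p_anc <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    dos <- matrix(0, n, m)
    for (k in seq_along(spec$labels)) {
      rows <- which(labels == spec$labels[k])
      p_pop <- stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      # guard against numerically degenerate Beta draws
      p_pop <- pmin(pmax(p_pop, 0), 1)
      dos[rows, ] <- matrix(stats::rbinom(length(rows) * m, 2,
                                          rep(p_pop, each = length(rows))),
                            nrow = length(rows))
    }
    variants <- data.frame(
      id = sprintf("pop%05d", seq_len(m)), chrom = "1",
      pos = as.integer(1e6 + (seq_len(m) - 1) * spacing_bp),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    gm <- genotype_matrix(sprintf("P%04d", seq_len(n)), variants, dos)
    list(gm = gm, labels = labels)
  })
}

#' Phenotype model specification
#'
#' Linear model generating questionnaire-style scores:
#' `score = intercept + sum(effect * dosage) + age_effect*age +
#' sex_effect*sex + Normal(0, noise_sd)`. Default effect and noise scales
#' are chosen so that at the study scale (n = 90) per-allele effects of
#' about |2-4| score units carry standard errors near 1, matching the
#' replication tables.
#'
#' @param causal_cp,causal_hp Named numeric vectors of per-alt-allele effects
#'   (score units) for the cold- and heat-pattern scores; names are variant
#'   ids of the genotype matrix.
#' @param age_effect,sex_effect,intercept Covariate effects (score units).
#' @param noise_sd Residual standard deviation (> 0).
#' @param clip Optional length-2 numeric giving score bounds (e.g. the
#'   questionnaire's attainable range); `NULL` (default) leaves scores
#'   unclipped.
#' @return Object of class `pheno_model_spec`.
#' @export
pheno_model_spec <- function(causal_cp = numeric(), causal_hp = numeric(),
                             age_effect = 0.05, sex_effect = 1,
                             intercept = 20, noise_sd = 6, clip = NULL) {
  stopifnot(noise_sd > 0)
  structure(list(causal_cp = causal_cp, causal_hp = causal_hp,
                 age_effect = age_effect, sex_effect = sex_effect,
                 intercept = intercept, noise_sd = noise_sd, clip = clip),
            class = "pheno_model_spec")
}

#' Simulate phenotypes from planted SNP effects
#'
#' Ages are Normal(50, 10) truncated to [19, 80]; sex is Bernoulli(0.5).
#' Missing dosages at causal SNPs contribute through the variant's mean
#' dosage so every sample receives a score.
#'
#' @param gm A [genotype_matrix()].
#' @param spec A [pheno_model_spec()].
#' @param seed Integer seed.
#' @return Phenotype data frame (`sample_id`, `cp_score`, `hp_score`,
#'   `age`, `sex`).
#' @export
simulate_phenotypes <- function(gm, spec = pheno_model_spec(), seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(spec, "pheno_model_spec"))
  for (ids in list(names(spec$causal_cp), names(spec$causal_hp))) {
    unknown <- setdiff(ids, gm$variants$id)
    if (length(unknown) > 0) {
      stop("unknown causal snp id(s): ", paste(unknown, collapse = ", "))
    }
  }
  with_seed(seed, {
    n <- length(gm$samples)
    age <- stats::rnorm(n, 50, 10)
    while (any(bad <- age < 19 | age > 80)) {
      age[bad] <- stats::rnorm(sum(bad), 50, 10)
    }
    sex <- stats::rbinom(n, 1, 0.5)
    genetic <- function(causal) {
      g <- rep(0, n)
      for (id in names(causal)) {
        d <- dosage_of(gm, id)
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        g <- g + causal[[id]] * d
      }
      g
    }
    base <- spec$intercept + spec$age_effect * age + spec$sex_effect * sex
    cp <- base + genetic(spec$causal_cp) + stats::rnorm(n, 0, spec$noise_sd)
    hp <- base + genetic(spec$causal_hp) + stats::rnorm(n, 0, spec$noise_sd)
    if (!is.null(spec$clip)) {
      cp <- pmin(pmax(cp, spec$clip[1]), spec$clip[2])
      hp <- pmin(pmax(hp, spec$clip[1]), spec$clip[2])
    }
    data.frame(sample_id = gm$samples, cp_score = cp, hp_score = hp,
               age = age, sex = sex, stringsAsFactors = FALSE)
  })
}

# Trait vocabularies used by the catalog generator.
trait_pool <- function(category) {
  switch(category,
    cold_heat = c("Response to cold", "Cold-induced vasodilation",
                  "Cold sensitivity", "Cold-inducible RNA-binding protein"),
    thyroid = c("Thyroid-stimulating hormone", "Thyroxine",
                "Triiodothyronine"),
    control = c("Body height", "Hair color", "Myopia"),
    stop("unknown category: ", category))
}

#' Simulate a reported-SNP catalog over a genotype panel
#'
#' Assigns each variant a trait and category, then injects a configurable
#' fraction of X-chromosome records and duplicate rsID rows so the catalog
#' filters have something to remove.
#'
#' @param gm A [genotype_matrix()] whose variants seed the catalog.
#' @param categories Categories to draw from (subset of `cold_heat`,
#'   `thyroid`, `control`).
#' @param seed Integer seed.
#' @param chrx_fraction Fraction of extra records placed on chromosome X.
#' @param duplicate_fraction Fraction of variants duplicated with a second,
#'   weaker reported p.
#' @return Catalog data frame in the [read_catalog()] schema.
#' @export
simulate_catalog <- function(gm, categories = c("cold_heat", "thyroid"),
                             seed = 1, chrx_fraction = 0.05,
                             duplicate_fraction = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"), length(categories) >= 1,
            all(categories %in% catalog_categories()))
  with_seed(seed, {
    m <- nrow(gm$variants)
    category <- sample(categories, m, replace = TRUE)
    trait <- vapply(category, function(ct) sample(trait_pool(ct), 1), "")
    base <- data.frame(
      snp = gm$variants$id, chrom = gm$variants$chrom,
      pos = gm$variants$pos, trait = trait, category = category,
      effect_allele = gm$variants$alt,
      reported_beta = round(stats::rnorm(m, 0, 0.1), 4),
      reported_p = 10^(-stats::runif(m, 6, 60)),
      stringsAsFactors = FALSE)
    n_dup <- round(duplicate_fraction * m)
    if (n_dup > 0) {
      pick <- sample(m, n_dup)
      dup <- base[pick, , drop = FALSE]
      dup$reported_p <- pmin(1, dup$reported_p * 10^stats::runif(n_dup, 1, 4))
      base <- rbind(base, dup)
    }
    n_x <- round(chrx_fraction * m)
    if (n_x > 0) {
      xrec <- data.frame(
        snp = sprintf("simX%04d", seq_len(n_x)), chrom = "X",
        pos = as.integer(1e6 + seq_len(n_x) * 1000),
        trait = sample(trait_pool(categories[1]), n_x, replace = TRUE),
        category = categories[1], effect_allele = "G",
        reported_beta = round(stats::rnorm(n_x, 0, 0.1), 4),
        reported_p = 10^(-stats::runif(n_x, 6, 60)),
        stringsAsFactors = FALSE)
      base <- rbind(base, xrec)
    }
    rownames(base) <- NULL
    base
  })
}

#' Simulate a gene-set library and SNP-to-gene annotation
#'
#' Generates `n_terms` gene sets of sizes drawn from `size_range` over a
#' synthetic background of `background_size` symbols. Optionally plants one
#' enriched term: the first term is forced to contain
#' `ceiling(planted_overlap * length(planted_genes))` of the designated
#' genes. When `snp_ids` is given, an annotation table mapping each SNP to
#' one gene is produced, with the planted genes assigned to the first SNPs.
#'
#' @param n_terms Number of terms (0 gives an empty library).
#' @param size_range Inclusive range of term sizes; max must not exceed
#'   `background_size`.
#' @param background_size Number of background gene symbols.
#' @param planted_genes Optional character vector of genes to enrich for.
#' @param planted_overlap Fraction of `planted_genes` forced into the first
#'   term, in `[0, 1]`.
#' @param seed Integer seed.
#' @param snp_ids Optional SNP ids for the annotation table.
#' @return List with `library` (a [gene_set_library()]) and `annotation`
#'   (data frame or `NULL`).
#' @export
simulate_gene_sets <- function(n_terms = 50, size_range = c(5, 50),
                               background_size = 1000,
                               planted_genes = NULL, planted_overlap = 0,
                               seed = 1, snp_ids = NULL) {
  stopifnot(size_range[1] >= 1, size_range[1] <= size_range[2])
  if (size_range[2] > background_size) {
    stop("size_range max exceeds background_size")
  }
  if (planted_overlap < 0 || planted_overlap > 1) {
    stop("planted_overlap must be in [0, 1]")
  }
  with_seed(seed, {
    background <- sprintf("GENE%05d", seq_len(background_size))
    if (!is.null(planted_genes)) {
      planted_genes <- as.character(planted_genes)
      if (length(planted_genes) > background_size) {
        stop("impossible overlap request: more planted genes than background")
      }
      # planted genes occupy the head of the background
      background[seq_along(planted_genes)] <- planted_genes
    }
    terms <- list()
    if (n_terms > 0) {
      sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                      replace = TRUE)
      terms <- lapply(sizes, function(s) sample(background, s))
      names(terms) <- sprintf("TERM_%03d", seq_len(n_terms))
      if (!is.null(planted_genes) && planted_overlap > 0) {
        k <- ceiling(planted_overlap * length(planted_genes))
        s <- max(sizes[1], k)
        filler <- sample(setdiff(background, planted_genes), s - k)
        terms[[1]] <- c(planted_genes[seq_len(k)], filler)
        names(terms)[1] <- "TERM_planted"
      }
    }
    lib <- gene_set_library(terms, background = background)
    annotation <- NULL
    if (!is.null(snp_ids)) {
      genes <- character(length(snp_ids))
      np <- min(length(planted_genes), length(snp_ids))
      if (np > 0) genes[seq_len(np)] <- planted_genes[seq_len(np)]
      if (length(snp_ids) > np) {
        genes[(np + 1):length(snp_ids)] <-
          sample(background, length(snp_ids) - np)
      }
      annotation <- data.frame(snp = snp_ids, gene = genes,
                               stringsAsFactors = FALSE)
    }
    list(library = lib, annotation = annotation)
  })
}
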