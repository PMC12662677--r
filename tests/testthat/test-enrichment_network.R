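test_that("SNP-to-gene mapping de-duplicates and warns on unmapped ids", {
  ann <- data.frame(snp = c("rs1", "rs2", "rs3"),
                    gene = c("GENEA", "GENEB", "GENEA"),
                    stringsAsFactors = FALSE)
  expect_equal(map_snps_to_genes(c("rs1", "rs3", "rs1"), ann),
               c("GENEA"))
  expect_equal(map_snps_to_genes(c("rs2", "rs1"), ann), c("GENEB", "GENEA"))
  expect_warning(got <- map_snps_to_genes(c("rs1", "rs9"), ann), "unmapped")
  expect_equal(got, "GENEA")
  expect_length(map_snps_to_genes(character(), ann), 0)

  # packaged annotation reproduces the printed heat-pattern gene column
  hp <- load_candidate_fixture("HP")
  genes <- map_snps_to_genes(hp$snp, read_annotation(candidate_annotation_path()))
  expect_length(genes, 20)
  expect_true(all(c("CAPZB", "CDKN2C", "HES1", "VEGFA", "CCBE1") %in% genes))
  expect_setequal(genes, unique(hp$gene))
})

test_that("hypergeometric tail matches exhaustive enumeration on small universes", {
  bg <- sprintf("g%02d", 1:20)
  term <- bg[1:5]
  r <- ora_test(bg[1:5], term, bg)
  expect_equal(r$p, 1 / choose(20, 5))   # full 5-of-5 overlap

  r0 <- ora_test(bg[6:10], term, bg)
  expect_equal(r0$p, 1)                  # overlap 0: whole distribution

  # enumeration oracle over random instances with background <= 25
  set.seed(12)
  for (rep in 1:8) {
    N <- sample(10:25, 1)
    bg <- sprintf("g%02d", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:min(8, N - 1), 1)
    term <- sample(bg, K)
    genes <- sample(bg, n)
    got <- ora_test(genes, term, bg)
    want <- hyper_tail_enumerate(got$n_overlap, K, n, N)
    expect_equal(got$p, want, tolerance = 1e-10)
  }

  # fixed sizes, growing overlap: strictly decreasing p
  bg <- sprintf("g%02d", 1:22)
  term <- bg[1:6]
  ps <- sapply(0:4, function(k) {
    ora_test(c(bg[seq_len(k)], bg[7:(11 - k)]), term, bg)$p
  })
  expect_true(all(diff(ps) < 0))

  expect_error(ora_test(character(), term, bg), "empty gene list")
  expect_error(ora_test("outsider", term, bg), "not contained")
})

test_that("combined score vanishes at p = 1 and crowns a planted term", {
  bg <- sprintf("g%03d", 1:60)
  lib <- gene_set_library(list(hit = bg[1:6], miss = bg[31:40]),
                          background = bg)
  er <- enrich(bg[1:6], lib, R = 200, seed = 1)
  expect_equal(er$combined[er$term == "miss"], 0)  # -ln(1) * z = 0
  expect_gt(er$combined[er$term == "hit"], 0)

  wins <- 0
  for (s in 1:10) {
    sim <- simulate_gene_sets(n_terms = 25, size_range = c(8, 8),
                              background_size = 300,
                              planted_genes = sprintf("PL%02d", 1:8),
                              planted_overlap = 1, seed = s)
    er <- enrich(sprintf("PL%02d", 1:8), sim$library, R = 300, seed = s + 50)
    if (er$term[which.max(er$combined)] == "TERM_planted") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("top-pathway selection orders by p with combined-score tie-break", {
  res <- data.frame(term = sprintf("t%d", 1:7),
                    p = c(0.01, 0.002, 0.002, 0.5, 0.03, 0.2, 0.04),
                    combined = c(5, 2, 9, 1, 3, 2, 4),
                    stringsAsFactors = FALSE)
  top <- top_pathways(res, k = 5)
  expect_equal(nrow(top), 5)
  expect_equal(top$term[1:2], c("t3", "t2"))  # tie at p=0.002 -> larger c first
  expect_equal(nrow(top_pathways(res, k = 50)), 7)
})

test_that("Jaccard coefficient and thresholded similarity network", {
  # the two heat-pattern vascular sets share HES1 and VEGFA
  expect_equal(jaccard(c("HES1", "VEGFA"), c("CCBE1", "HES1", "VEGFA")), 2 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A"), c("B")), 0)
  expect_error(jaccard(character(), character()), "both sets empty")

  sets <- list(vsmc = c("HES1", "VEGFA"),
               bvm = c("CCBE1", "HES1", "VEGFA"),
               far = c("PPARGC1A", "BOK"))
  net <- similarity_network(sets, threshold = 0.3)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$a, "bvm")
  expect_equal(net$edges$b, "vsmc")
  expect_equal(net$edges$jaccard, 2 / 3)
  expect_equal(net$density, 1 / 3)
  expect_equal(length(unique(net$components)), 2)

  # threshold 1 links only identical gene sets
  net1 <- similarity_network(list(a = c("X", "Y"), b = c("X", "Y"),
                                  c = c("X")), threshold = 1)
  expect_equal(nrow(net1$edges), 1)
  expect_setequal(c(net1$edges$a, net1$edges$b), c("a", "b"))

  empty <- similarity_network(list())
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$density, 0)

  # edge set invariant to pathway input order
  net_rev <- similarity_network(rev(sets), threshold = 0.3)
  expect_identical(net$edges, net_rev$edges)
})

test_that("under a random library few terms reach nominal significance", {
  set.seed(44)
  sim <- simulate_gene_sets(n_terms = 60, size_range = c(10, 40),
                            background_size = 800, seed = 90)
  frac <- replicate(5, {
    genes <- sample(sim$library$background, 20)
    er <- enrich(genes, sim$library, R = 50, seed = sample.int(1e6, 1))
    mean(er$p < 0.05)
  })
  expect_lte(mean(frac), 0.08)
})

test_that("control comparison is deterministic and separates planted signal", {
  assoc <- data.frame(snp = c("a", "b", "c"),
                      permutation_p = c(0.01, 0.3, 0.04))
  case <- list(trait = "case", assoc = assoc)
  out <- control_comparison(case, list(case))
  expect_equal(out[1, -1], out[2, -1], ignore_attr = TRUE)
  expect_equal(out$ratio[1], 2 / 3)

  none <- list(trait = "ctl",
               assoc = data.frame(snp = "x", permutation_p = 0.9))
  out2 <- control_comparison(case, list(none))
  expect_equal(out2$ratio[2], 0)
  expect_equal(out2$top_pathways[2], "")

  # planted enrichment in the case trait: denser case network than control
  core <- sprintf("CORE%d", 1:6)
  bg <- c(core, sprintf("g%03d", 1:300))
  denser <- 0
  for (s in 1:10) {
    set.seed(s)
    planted_sets <- lapply(1:5, function(i)
      c(core, sample(setdiff(bg, core), 2)))
    names(planted_sets) <- sprintf("planted_%d", 1:5)
    noise_sets <- lapply(1:10, function(i) sample(setdiff(bg, core), 10))
    names(noise_sets) <- sprintf("noise_%d", 1:10)
    lib <- gene_set_library(c(planted_sets, noise_sets), background = bg)
    er_case <- enrich(core, lib, R = 100, seed = s)
    er_ctl <- enrich(sample(setdiff(bg, core), 6), lib, R = 100, seed = s + 20)
    net_of <- function(er) {
      top <- top_pathways(er, 5)
      similarity_network(setNames(lib$terms[top$term], top$term), 0.3)
    }
    if (net_of(er_case)$density >= net_of(er_ctl)$density) denser <- denser + 1
  }
  expect_gte(denser, 8)
})
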