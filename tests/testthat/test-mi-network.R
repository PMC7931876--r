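test_that("mutual information matches hand-computed and degenerate cases", {
  expect_equal(mutual_information(rep(1, 10), rbinom(10, 1, 0.5)), 0)
  x <- rep(c(1, 0), 50)
  expect_equal(mutual_information(x, x), log(2))
  # 2x2 counts [[30,10],[10,30]], n = 80
  x <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  expect_equal(mutual_information(x, y), 0.130812, tolerance = 1e-6)
  expect_equal(mutual_information(x, y, unit = "bits"),
               mutual_information(x, y) / log(2))
  expect_error(mutual_information(c(1, 0), c(1, 0, 1)), "length")
  expect_error(mutual_information(c(1, NA), c(1, 0)), "missing")
})

test_that("plug-in MI agrees with the entropy-decomposition oracle", {
  set.seed(77)
  for (i in 1:300) {
    ct <- random_2x2()
    v <- counts_to_vectors(ct["n11"], ct["n1x"], ct["n1y"], ct["n"])
    mi <- mutual_information(v$x, v$y)
    expect_lt(abs(mi - oracle_mi_entropy(ct["n11"], ct["n1x"], ct["n1y"], ct["n"])),
              1e-12)
    expect_identical(mi, mutual_information(v$y, v$x))  # symmetry, exact
    hx <- oracle_mi_entropy(ct["n1x"], ct["n1x"], ct["n1x"], ct["n"])
    hy <- oracle_mi_entropy(ct["n1y"], ct["n1y"], ct["n1y"], ct["n"])
    expect_lte(mi, min(hx, hy) + 1e-12)
  }
})

test_that("flip noise on one variable strictly degrades expected MI", {
  set.seed(123)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  qs <- c(0, 0.1, 0.2, 0.3, 0.45)
  mis <- vapply(qs, function(q) {
    mean(replicate(5, {
      flip <- rbinom(n, 1, q)
      mutual_information(x, (x + flip) %% 2)
    }))
  }, numeric(1))
  expect_true(all(diff(mis) < 0))  # monotone decreasing over the q grid
})

test_that("permutation p-values behave at the degenerate extremes", {
  cst <- rep(1, 100)
  y <- rbinom(100, 1, 0.5)
  expect_equal(permutation_pvalue(cst, y, B = 99, seed = 1)$p_value, 1)
  x <- rep(c(1, 0), 100)
  res <- permutation_pvalue(x, x, B = 999, seed = 2)
  expect_equal(res$p_value, 1 / 1000)
  expect_true(all(res$null < res$observed - 1e-12))
  expect_error(permutation_pvalue(x, x, B = 0), "B")
})

test_that("permutation p-values are reproducible given a seed", {
  set.seed(9)
  x <- rbinom(200, 1, 0.4); y <- rbinom(200, 1, 0.3)
  a <- permutation_pvalue(x, y, B = 200, seed = 11)
  b <- permutation_pvalue(x, y, B = 200, seed = 11)
  expect_identical(a, b)
})

test_that("shared patient counts and sex prevalence are direct counts", {
  expect_equal(shared_patient_count(c(1, 1, 0), c(1, 0, 1)), 1)
  expect_equal(shared_patient_count(rep(1, 7), rep(1, 7)), 7)
  expect_equal(shared_patient_count(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(sex_prevalence(c(1, 1), c(1, 1)), 1)
  expect_equal(sex_prevalence(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)
  expect_equal(sex_prevalence(c(1, 0, 1, 1), c("M", "F", "F", "M")), 2 / 3)
  expect_warning(res <- sex_prevalence(c(0, 0), c(1, 0)), "undefined")
  expect_true(is.na(res))
})

test_that("vacuous filters keep the complete graph; impossible ones empty it", {
  spec <- small_block_spec(seed = 15, n = 600, n_noise = 5)
  gc <- generate_cohort(spec)
  cm <- apply_curation(gc$table, curation_config())
  sc <- logistic_zscores(cm$x, cm$y, paste0("blockA_", 1:3), alpha = 1)
  net <- build_network(cm, sc, B = 99, alpha = 1, correction = "none",
                       min_patients = 0, seed = 3)
  expect_equal(nrow(net$edges), 3)  # complete graph on 3 nodes
  expect_warning(
    empty <- build_network(cm, sc, B = 99, alpha = 1, correction = "none",
                           min_patients = net$n_cases + 1, seed = 3),
    "no edges")
  expect_equal(nrow(empty$edges), 0)
})

test_that("raising min_patients or lowering alpha never adds edges", {
  spec <- small_block_spec(seed = 25, n = 800, n_noise = 5)
  cm <- apply_curation(generate_cohort(spec)$table, curation_config())
  sc <- logistic_zscores(cm$x, cm$y, c(paste0("blockA_", 1:4), paste0("blockB_", 1:4)),
                         alpha = 1)
  loose <- build_network(cm, sc, B = 199, alpha = 0.3, min_patients = 5, seed = 4)
  key <- function(e) paste(e$from, e$to)
  for (mp in c(15, 40)) {
    tight <- suppressWarnings(
      build_network(cm, sc, B = 199, alpha = 0.3, min_patients = mp, seed = 4))
    expect_true(all(key(tight$edges) %in% key(loose$edges)))
  }
  stricter <- suppressWarnings(
    build_network(cm, sc, B = 199, alpha = 0.01, min_patients = 5, seed = 4))
  expect_true(all(key(stricter$edges) %in% key(loose$edges)))
})

test_that("within-block edges dominate the planted-block network", {
  # outcome independent of the blocks: the case subset is then a random
  # subsample and between-block pairs are exactly null
  ok <- vapply(1:3, function(s) {
    spec <- cohort_spec(1400,
      list(cohort_block("blockA", 8, 8, 0.3), cohort_block("blockB", 8, 8, 0.3)),
      n_noise_features = 20, outcome_intercept = 0, seed = s)
    gc <- generate_cohort(spec)
    cm <- apply_curation(gc$table, curation_config())
    nodes <- names(gc$truth$block_membership)
    sc <- logistic_zscores(cm$x, cm$y, nodes, alpha = 1)
    net <- build_network(cm, sc, B = 999, alpha = 0.05, min_patients = 15, seed = s)
    bm <- gc$truth$block_membership
    all(bm[net$edges$from] == bm[net$edges$to])
  }, logical(1))
  expect_gte(sum(ok), 2)
})

test_that("network export round-trips through GraphML and CSV", {
  spec <- small_block_spec(seed = 19, n = 700, n_noise = 5)
  cm <- apply_curation(generate_cohort(spec)$table, curation_config())
  sc <- logistic_zscores(cm$x, cm$y, paste0("blockA_", 1:4), alpha = 1)
  net <- build_network(cm, sc, B = 99, alpha = 1, correction = "none",
                       min_patients = 0, seed = 5)
  dir <- withr::local_tempdir()
  gp <- file.path(dir, "net.graphml")
  write_graphml(net, gp)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "name"), net$nodes$variable)
  write_network_csv(net, file.path(dir, "n.csv"), file.path(dir, "e.csv"))
  expect_equal(nrow(read.csv(file.path(dir, "e.csv"))), nrow(net$edges))
})
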