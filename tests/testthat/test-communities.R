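test_that("modularity matches closed-form values", {
  tri2 <- fx_two_triangles()
  nodes <- letters[1:6]
  one <- setNames(rep(1, 6), nodes)
  expect_equal(modularity(tri2, one, weighted = FALSE), 0)
  blocks <- setNames(c(1, 1, 1, 2, 2, 2), nodes)
  expect_equal(modularity(tri2, blocks, weighted = FALSE), 0.5)
  ring <- fx_ring(letters[1:6])
  singletons <- setNames(1:6, letters[1:6])
  expect_equal(modularity(ring, singletons, weighted = FALSE), -1 / 6)
  expect_error(modularity(edges_df(character(), character()), one), "edgeless")
  expect_error(modularity(tri2, setNames(rep(1, 5), nodes[1:5])), "cover")
})

test_that("modularity agrees with igraph on a random weighted graph", {
  set.seed(8)
  g <- igraph::sample_gnp(12, 0.4)
  igraph::V(g)$name <- paste0("n", 1:12)
  e <- igraph::as_data_frame(g, what = "edges")
  e$weight <- runif(nrow(e), 0.5, 2)
  memb <- setNames(sample(1:3, 12, replace = TRUE), paste0("n", 1:12))
  gi <- igraph::graph_from_data_frame(e, directed = FALSE)
  expect_equal(modularity(e, memb, weighted = TRUE),
               igraph::modularity(gi, memb[igraph::V(gi)$name],
                                  weights = igraph::E(gi)$weight),
               tolerance = 1e-12)
})

test_that("fast-greedy recovers separable fixtures at the brute-force optimum", {
  for (fx in list(fx_clique_bridge(), fx_triangle_ring(), fx_two_triangles())) {
    fg <- fast_greedy(fx, weighted = FALSE)
    bf <- brute_force_best_partition(fx, weighted = FALSE)
    expect_equal(fg$q_best, bf$q, tolerance = 1e-12)
    # identical partition up to label renaming
    expect_equal(length(unique(fg$membership)), length(unique(bf$membership)))
    expect_true(all(table(fg$membership[names(bf$membership)], bf$membership)
                    %in% c(0, table(bf$membership))))
  }
  cb <- fast_greedy(fx_clique_bridge(), weighted = FALSE)
  expect_equal(unname(split(names(cb$membership), cb$membership)[["1"]]),
               c("a", "b", "c", "d"))
  tr <- fast_greedy(fx_triangle_ring(), weighted = FALSE)
  expect_equal(length(unique(tr$membership)), 3)
})

test_that("fast-greedy never beats the exhaustive oracle on small graphs", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- letters[1:n]
    e <- igraph::as_data_frame(g, what = "edges")
    fg <- fast_greedy(e, weighted = FALSE, nodes = letters[1:n])
    bf <- brute_force_best_partition(e, weighted = FALSE, nodes = letters[1:n])
    expect_lte(fg$q_best, bf$q + 1e-12)
  }
})

test_that("complete graphs collapse to a single community at Q = 0", {
  fg <- fast_greedy(fx_complete(letters[1:5]), weighted = FALSE)
  expect_equal(fg$q_best, 0, tolerance = 1e-12)
  expect_equal(length(unique(fg$membership)), 1)
  bf <- brute_force_best_partition(fx_complete(letters[1:5]), weighted = FALSE)
  expect_equal(bf$q, 0, tolerance = 1e-12)
})

test_that("the dendrogram trace is internally consistent", {
  fg <- fast_greedy(fx_clique_bridge(), weighted = FALSE)
  expect_equal(nrow(fg$merges), 8 - 1)  # connected graph: n - 1 merges
  expect_equal(fg$merges$q_after, fg$q0 + cumsum(fg$merges$dq), tolerance = 1e-9)
  expect_gte(fg$q_best, max(fg$merges$q_after))
  expect_gte(fg$q_best, fg$q0)
})

test_that("node relabeling permutes the partition without changing it", {
  fx <- fx_triangle_ring()
  ren <- setNames(paste0("z", 9:1), letters[1:9])
  fx2 <- data.frame(from = ren[fx$from], to = ren[fx$to])
  a <- fast_greedy(fx, weighted = FALSE)
  b <- fast_greedy(fx2, weighted = FALSE)
  ma <- a$membership
  mb <- setNames(b$membership[ren[names(ma)]], names(ma))
  tab <- table(ma, mb)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("weighted and unweighted detection agree under equal weights", {
  fx <- fx_clique_bridge()
  fx$weight <- rep(2.5, nrow(fx))
  a <- fast_greedy(fx, weighted = TRUE)
  b <- fast_greedy(fx, weighted = FALSE)
  expect_equal(a$membership, b$membership)
  expect_equal(a$q_best, b$q_best, tolerance = 1e-12)
})

test_that("fast-greedy matches igraph's implementation on fixtures", {
  for (fx in list(fx_clique_bridge(), fx_triangle_ring())) {
    g <- igraph::graph_from_data_frame(fx, directed = FALSE)
    ig <- igraph::cluster_fast_greedy(g)
    fg <- fast_greedy(fx, weighted = FALSE)
    expect_equal(fg$q_best,
                 max(igraph::modularity(g, igraph::cut_at(ig, 1))
                     , igraph::modularity(ig)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate graphs are handled explicitly", {
  expect_error(brute_force_best_partition(edges_df(character(), character()),
                                          nodes = c("a", "b")), "edgeless")
  expect_error(brute_force_best_partition(fx_complete(letters[1:11])), "refusing")
  two <- edges_df("a", "b")
  bf <- brute_force_best_partition(two)
  expect_equal(bf$q, 0)
  expect_equal(length(unique(bf$membership)), 1)
  expect_warning(fg <- fast_greedy(edges_df(character(), character()),
                                   nodes = c("a", "b")), "edgeless")
  expect_equal(nrow(fg$merges), 0)
  lone <- fast_greedy(edges_df(character(), character()), nodes = "a")
  expect_equal(length(lone$membership), 1)
})

test_that("disconnected components are merged within themselves", {
  fx <- rbind(fx_two_triangles(), edges_df(c("x"), c("y")))
  fg <- fast_greedy(fx, weighted = FALSE)
  expect_equal(nrow(fg$merges), 8 - 3)  # n - number of components
  memb <- fg$membership
  expect_equal(length(unique(memb[c("a", "b", "c")])), 1)
  expect_equal(length(unique(memb[c("x", "y")])), 1)
  expect_false(memb["a"] == memb["x"])
})
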