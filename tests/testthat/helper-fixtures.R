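# Shared fixtures and independent oracles used across the suite.

# --- graph fixtures (edge data frames) ------------------------------

edges_df <- function(from, to) data.frame(from = from, to = to,
                                          stringsAsFactors = FALSE)

# two disjoint triangles {a,b,c} and {d,e,f}
fx_two_triangles <- function() edges_df(
  c("a", "a", "b", "d", "d", "e"),
  c("b", "c", "c", "e", "f", "f"))

# two 4-cliques joined by one bridge edge d-e
fx_clique_bridge <- function() edges_df(
  c("a", "a", "a", "b", "b", "c", "e", "e", "e", "f", "f", "g", "d"),
  c("b", "c", "d", "c", "d", "d", "f", "g", "h", "g", "h", "h", "e"))

# ring of 3 triangles, adjacent triangles linked by one edge
fx_triangle_ring <- function() edges_df(
  c("a", "a", "b", "d", "d", "e", "g", "g", "h", "c", "f", "i"),
  c("b", "c", "c", "e", "f", "f", "h", "i", "i", "d", "g", "a"))

fx_complete <- function(nodes) {
  p <- utils::combn(nodes, 2)
  edges_df(p[1, ], p[2, ])
}

fx_ring <- function(nodes) edges_df(nodes, nodes[c(2:length(nodes), 1)])

# --- independent oracles --------------------------------------------

# MI via the entropy decomposition H(X) + H(Y) - H(X,Y) (plug-in), a
# different route than the direct sum used by the implementation.
oracle_mi_entropy <- function(n11, n1x, n1y, n) {
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  joint <- c(n11, n1x - n11, n1y - n11, n - n1x - n1y + n11) / n
  h(c(n1x, n - n1x) / n) + h(c(n1y, n - n1y) / n) - h(joint)
}

# random valid 2x2 contingency table, as counts (n11, n1x, n1y, n)
random_2x2 <- function() {
  n <- sample(4:200, 1)
  n1x <- sample(0:n, 1)
  n1y <- sample(0:n, 1)
  lo <- max(0, n1x + n1y - n)
  hi <- min(n1x, n1y)
  n11 <- if (lo == hi) lo else sample(lo:hi, 1)
  c(n11 = n11, n1x = n1x, n1y = n1y, n = n)
}

# expand a 2x2 count table into a pair of binary vectors
counts_to_vectors <- function(n11, n1x, n1y, n) {
  x <- c(rep(1, n1x), rep(0, n - n1x))
  y <- c(rep(1, n11), rep(0, n1x - n11),
         rep(1, n1y - n11), rep(0, n - n1x - (n1y - n11)))
  list(x = x, y = y)
}

# --- cohort fixtures ------------------------------------------------

small_block_spec <- function(seed = 1, n = 1200, or = 8, prev = 0.3,
                             n_noise = 50) {
  cohort_spec(n,
    list(cohort_block("blockA", 8, or, prev),
         cohort_block("blockB", 8, or, prev)),
    n_noise_features = n_noise,
    outcome_coefficients = c(blockA_1 = 0.4, blockA_2 = 0.4,
                             blockB_1 = 0.4, blockB_2 = 0.4),
    outcome_intercept = -0.8, seed = seed)
}

# tiny hand-built cohort table
toy_cohort <- function() {
  data <- data.frame(
    dx1 = c(1L, 0L, 1L, 0L, 1L, 0L),
    dx2 = c(NA, NA, NA, NA, 1L, 0L),   # 4/6 missing
    age = c(45L, 17L, 30L, 52L, 61L, 38L),
    sex = c(1L, 0L, 1L, 0L, 1L, 0L),
    outcome = c(1L, 0L, "T1D", 0L, 1L, 0L),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    variable = names(data),
    kind = c("dichotomous", "dichotomous", "discrete", "dichotomous", "dichotomous"),
    role = c("diagnosis", "diagnosis", "demographic", "demographic", "outcome"),
    stringsAsFactors = FALSE)
  structure(list(data = data, meta = meta), class = "cohort_table")
}
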