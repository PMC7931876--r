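# Mutual-information network over the case subpopulation. Edges carry
# the plug-in MI of two binary variables, a Monte-Carlo permutation
# p-value, a multiplicity-adjusted p-value and the count of patients
# positive for both variables; nodes carry the logistic Wald z and the
# male fraction among node-positive patients.

.check_binary_pair <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (length(x) < 1) stop("empty vectors")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) stop("vectors must be binary 0/1")
}

# MI (nats) of a 2x2 joint given the 1/1 cell and the margins.
# Zero-probability cells contribute 0; tiny negative rounding is
# clipped to 0.
.mi_counts <- function(n11, n1x, n1y, n) {
  cells <- c(n11, n1x - n11, n1y - n11, n - n1x - n1y + n11)
  px <- c(n1x, n1x, n - n1x, n - n1x) / n
  py <- c(n1y, n - n1y, n1y, n - n1y) / n
  p <- cells / n
  pos <- p > 0
  val <- sum(p[pos] * log(p[pos] / (px[pos] * py[pos])))
  if (val < 0 && val > -1e-12) val <- 0
  val
}

#' Mutual information of two binary vectors
#'
#' Plug-in estimate from the empirical 2x2 joint distribution,
#' `sum p(x,y) log[ p(x,y) / (p(x) p(y)) ]`, in nats by default. Zero
#' for (empirically) independent variables; equals the marginal entropy
#' when the two vectors coincide.
#'
#' @param x,y Binary 0/1 vectors of equal length, no missing values.
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return Nonnegative MI estimate.
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1))  # ln 2
#' @export
mutual_information <- function(x, y, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  .check_binary_pair(x, y)
  v <- .mi_counts(sum(x * y), sum(x), sum(y), length(x))
  if (unit == "bits") v / log(2) else v
}

#' Monte-Carlo permutation p-value for mutual information
#'
#' Permutes `y` uniformly `B` times (implemented by resampling the
#' positions of its ones, which induces the same distribution over
#' permuted binary vectors), recomputes the MI, and reports the add-one
#' estimator `p = (1 + #[MI_perm >= MI_obs - 1e-12]) / (B + 1)`, so `p`
#' always lies in `[1/(B+1), 1]` and ties count conservatively.
#'
#' @param x,y Binary 0/1 vectors of equal length.
#' @param B Number of permutations (>= 1).
#' @param seed Optional seed for the permutation stream.
#' @return List with `p_value`, `observed` MI (nats) and the `null`
#'   vector of permuted MI values.
#' @export
permutation_pvalue <- function(x, y, B, seed = NULL) {
  if (!is.numeric(B) || length(B) != 1 || B < 1) stop("B must be >= 1")
  B <- as.integer(B)
  .check_binary_pair(x, y)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x); n1x <- sum(x); n1y <- sum(y)
  obs <- .mi_counts(sum(x * y), n1x, n1y, n)
  # under permutation only the 1/1 cell varies; precompute its MI values
  lo <- max(0L, n1x + n1y - n); hi <- min(n1x, n1y)
  mi_tab <- vapply(lo:hi, .mi_counts, numeric(1), n1x = n1x, n1y = n1y, n = n)
  null <- numeric(B)
  if (n1y == 0L || n1y == n) {
    null[] <- mi_tab[1L]
  } else {
    for (b in seq_len(B)) {
      n11 <- sum(x[sample.int(n, n1y)])
      null[b] <- mi_tab[n11 - lo + 1L]
    }
  }
  p <- (1 + sum(null >= obs - 1e-12)) / (B + 1)
  list(p_value = p, observed = obs, null = null)
}

#' Patients positive for both variables
#'
#' @param x,y Binary 0/1 vectors of equal length.
#' @return Count of records with `x == 1` and `y == 1`.
#' @export
shared_patient_count <- function(x, y) {
  .check_binary_pair(x, y)
  sum(x == 1 & y == 1)
}

#' Male fraction among node-positive patients
#'
#' @param x Binary 0/1 variable vector.
#' @param sex Sex vector, same length; male is coded 1, `"M"` or
#'   `"male"`.
#' @return Fraction of males among records with `x == 1`, or `NA` (with
#'   a warning) when no record is positive.
#' @export
sex_prevalence <- function(x, sex) {
  if (length(x) != length(sex)) stop("length mismatch between x and sex")
  pos <- x == 1
  if (!any(pos)) {
    warning("no positive records: sex prevalence undefined")
    return(NA_real_)
  }
  male <- sex == 1 | sex %in% c("M", "male", "Male")
  mean(male[pos])
}

#' Build the mutual-information network over the case subpopulation
#'
#' Restricts the curated matrix to outcome-positive records, computes
#' for every pair of significant nodes the MI, a Monte-Carlo permutation
#' p-value and the shared-patient count, adjusts the p-values for
#' multiplicity, and retains the edges passing both filters:
#' `p_adjusted < alpha` and `shared_patients >= min_patients`.
#'
#' @param curated A `curated_matrix`.
#' @param scores A `node_scores` data frame; rows with
#'   `significant == TRUE` become the network nodes (>= 2 required).
#' @param B Permutations per edge (default 999).
#' @param alpha Significance level for the adjusted edge p-values.
#' @param correction Multiple-testing correction across the edge tests:
#'   `"BH"` (Benjamini-Hochberg, default), `"bonferroni"` or `"none"`.
#' @param min_patients Minimum shared-patient count for a retained edge
#'   (default 15).
#' @param seed Optional seed making the permutation stream reproducible.
#' @param cases_only Restrict to outcome-positive records (default TRUE);
#'   set FALSE for an all-records network.
#' @return An `mi_network`: `$nodes` (variable, z, size = |z|,
#'   sex_prevalence), `$edges` (retained), `$tests` (all pairs, with
#'   `retained` flag), `$params`, `$n_cases`.
#' @export
build_network <- function(curated, scores, B = 999, alpha = 0.05,
                          correction = c("BH", "bonferroni", "none"),
                          min_patients = 15, seed = NULL, cases_only = TRUE) {
  correction <- match.arg(correction)
  stopifnot(inherits(curated, "curated_matrix"))
  vars <- intersect(scores$variable[scores$significant %in% TRUE],
                    colnames(curated$x))
  if (length(vars) < 2) stop("need at least 2 significant nodes, got ", length(vars))
  keep <- if (cases_only) curated$y == 1 else rep(TRUE, length(curated$y))
  if (!any(keep)) stop("case subpopulation is empty")
  xm <- curated$x[keep, vars, drop = FALSE]
  n_cases <- nrow(xm)

  if (!is.null(seed)) set.seed(seed)
  pairs <- combn(vars, 2)
  np <- ncol(pairs)
  mi <- pperm <- numeric(np); shared <- integer(np)
  for (k in seq_len(np)) {
    xa <- xm[, pairs[1, k]]; xb <- xm[, pairs[2, k]]
    pk <- permutation_pvalue(xa, xb, B)
    mi[k] <- pk$observed
    pperm[k] <- pk$p_value
    shared[k] <- sum(xa == 1 & xb == 1)
  }
  correction_method <- c(BH = "BH", bonferroni = "bonferroni", none = "none")[correction]
  padj <- p.adjust(pperm, method = correction_method)
  tests <- data.frame(from = pairs[1, ], to = pairs[2, ], mi = mi,
                      p_perm = pperm, p_adjusted = padj,
                      shared_patients = shared,
                      retained = padj < alpha & shared >= min_patients,
                      stringsAsFactors = FALSE)
  edges <- tests[tests$retained, setdiff(names(tests), "retained"), drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0) warning("no edges retained: empty network")

  zmap <- setNames(scores$z, scores$variable)
  sexprev <- rep(NA_real_, length(vars))
  if ("sex" %in% colnames(curated$x)) {
    sexvec <- curated$x[keep, "sex"]
    sexprev <- vapply(vars, function(v) {
      if (!any(xm[, v] == 1)) NA_real_ else mean(sexvec[xm[, v] == 1] == 1)
    }, numeric(1))
  }
  nodes <- data.frame(variable = vars, z = unname(zmap[vars]),
                      size = abs(unname(zmap[vars])),
                      sex_prevalence = unname(sexprev), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, tests = tests,
                 params = list(B = B, alpha = alpha, correction = correction,
                               min_patients = min_patients,
                               cases_only = cases_only, seed = seed),
                 n_cases = n_cases),
            class = "mi_network")
}

#' Convert an MI network to an igraph object
#'
#' Node attributes: z, size, sex_prevalence; edge attributes: mi (the
#' edge weight), p_perm, p_adjusted, shared_patients.
#'
#' @param network An `mi_network`.
#' @return An undirected igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mi_network"))
  e <- network$edges
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = network$nodes)
  if (nrow(e)) igraph::E(g)$weight <- e$mi
  g
}

#' Write an MI network as GraphML
#'
#' @param network An `mi_network`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write an MI network as flat node and edge CSVs
#'
#' @param network An `mi_network`.
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  .write_csv(network$nodes, nodes_path)
  .write_csv(network$edges, edges_path)
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' @export
print.mi_network <- function(x, ...) {
  cat("mi_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(of %d pairs tested), %d case records\n", nrow(x$tests), x$n_cases))
  cat(sprintf("  filters: adjusted p < %g (%s), shared patients >= %d\n",
              x$params$alpha, x$params$correction, x$params$min_patients))
  invisible(x)
}
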