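# Community detection: Newman modularity, agglomerative fast-greedy
# maximisation (deterministic lexicographic tie-breaking, full
# dendrogram, cut at the modularity maximum) and an exhaustive
# set-partition oracle for small graphs.

# Canonical internal graph form: node-name vector plus an edge data
# frame (from, to, weight). Accepts an mi_network (weights = MI) or a
# plain edge data frame with optional `weight`/`mi` column and optional
# explicit `nodes`.
.as_graph <- function(network, weighted = TRUE, nodes = NULL) {
  if (inherits(network, "mi_network")) {
    e <- network$edges
    w <- if (weighted && nrow(e)) e$mi else rep(1, nrow(e))
    return(list(nodes = network$nodes$variable,
                edges = data.frame(from = e$from, to = e$to, weight = w,
                                   stringsAsFactors = FALSE)))
  }
  if (is.data.frame(network)) {
    stopifnot(all(c("from", "to") %in% names(network)))
    wcol <- intersect(c("weight", "mi"), names(network))
    w <- if (weighted && length(wcol)) network[[wcol[1]]] else rep(1, nrow(network))
    from <- as.character(network$from); to <- as.character(network$to)
    if (any(from == to)) stop("self-loops are not allowed")
    if (is.null(nodes)) nodes <- unique(c(from, to))
    return(list(nodes = nodes,
                edges = data.frame(from = from, to = to, weight = w,
                                   stringsAsFactors = FALSE)))
  }
  stop("unsupported network representation: ", paste(class(network), collapse = "/"))
}

#' Newman modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e_cc` is the fraction of (weighted)
#' edge mass inside community `c` and `a_c` the fraction of (weighted)
#' degree attached to `c`. The all-in-one partition always scores 0.
#'
#' @param network An `mi_network` or an edge data frame with columns
#'   `from`, `to` and optionally `weight`/`mi`.
#' @param partition Named vector mapping every node to a community id.
#' @param weighted Use edge weights (default) or plain edge counts.
#' @return Modularity in `[-0.5, 1)`.
#' @examples
#' tri2 <- data.frame(from = c("a","a","b","d","d","e"),
#'                    to   = c("b","c","c","e","f","f"))
#' modularity(tri2, c(a=1, b=1, c=1, d=2, e=2, f=2))  # 0.5
#' @export
modularity <- function(network, partition, weighted = TRUE) {
  g <- .as_graph(network, weighted)
  if (nrow(g$edges) == 0) stop("edgeless network: modularity undefined")
  if (is.null(names(partition)) || !setequal(names(partition), g$nodes) ||
      anyDuplicated(names(partition)))
    stop("partition must cover all nodes exactly once")
  memb <- partition[g$nodes]
  m <- sum(g$edges$weight)
  same <- memb[g$edges$from] == memb[g$edges$to]
  e_in <- sum(g$edges$weight[same]) / m
  deg <- setNames(numeric(length(g$nodes)), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    deg[g$edges$from[i]] <- deg[g$edges$from[i]] + g$edges$weight[i]
    deg[g$edges$to[i]] <- deg[g$edges$to[i]] + g$edges$weight[i]
  }
  a <- tapply(deg, memb[names(deg)], sum) / (2 * m)
  e_in - sum(a^2)
}

#' Fast-greedy modularity communities
#'
#' Agglomerative (Clauset-Newman-Moore style) maximisation: start from
#' singleton communities and repeatedly merge the connected pair with
#' the largest modularity gain, breaking exact ties by the
#' lexicographically smallest community-id pair so runs are fully
#' deterministic. The whole merge sequence is recorded; the returned
#' partition is the cut with maximal modularity. Disconnected graphs are
#' handled naturally (only connected pairs ever merge) with a single
#' global cut.
#'
#' @param network An `mi_network` or edge data frame (see [modularity()]).
#' @param weighted Use edge weights (default TRUE).
#' @param nodes Optional explicit node-name vector (to include isolated
#'   nodes when passing an edge data frame).
#' @return An `fg_dendrogram`: `$merges` (step, comm_a, comm_b, dq,
#'   q_after), `$q0` (singleton-partition modularity), `$best_cut`
#'   (number of merges applied at the optimum), `$membership` (named,
#'   communities renumbered 1..k), `$q_best`.
#' @export
fast_greedy <- function(network, weighted = TRUE, nodes = NULL) {
  g <- .as_graph(network, weighted, nodes)
  n <- length(g$nodes)
  empty_merges <- data.frame(step = integer(), comm_a = integer(),
                             comm_b = integer(), dq = numeric(),
                             q_after = numeric())
  if (n < 2 || nrow(g$edges) == 0) {
    if (nrow(g$edges) == 0 && n >= 2)
      warning("edgeless network: trivial singleton dendrogram")
    memb <- setNames(seq_len(n), g$nodes)
    return(structure(list(merges = empty_merges, q0 = NA_real_, best_cut = 0L,
                          membership = memb, q_best = NA_real_,
                          n_nodes = n, node_names = g$nodes),
                     class = "fg_dendrogram"))
  }
  m <- sum(g$edges$weight)
  fi <- match(g$edges$from, g$nodes); ti <- match(g$edges$to, g$nodes)
  # EM[i,j]: fraction of edge-end mass between communities i and j
  EM <- matrix(0, n, n)
  for (k in seq_len(nrow(g$edges))) {
    w <- g$edges$weight[k] / (2 * m)
    EM[fi[k], ti[k]] <- EM[fi[k], ti[k]] + w
    EM[ti[k], fi[k]] <- EM[ti[k], fi[k]] + w
  }
  a <- rowSums(EM)
  active <- rep(TRUE, n)
  q <- q0 <- -sum(a^2)  # singleton partition: no internal edges
  merges <- vector("list", n - 1)
  merge_pairs <- matrix(0L, n - 1, 2)
  step <- 0L
  repeat {
    cand <- which(EM > 0 & upper.tri(EM), arr.ind = TRUE)
    if (nrow(cand) == 0) break
    dq <- 2 * (EM[cand] - a[cand[, 1]] * a[cand[, 2]])
    best <- max(dq)
    tied <- which(dq >= best - 1e-12)
    # lexicographically smallest (i, j) among ties
    ord <- order(cand[tied, 1], cand[tied, 2])
    pick <- tied[ord[1]]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    EM[i, ] <- EM[i, ] + EM[j, ]
    EM[, i] <- EM[, i] + EM[, j]
    EM[j, ] <- 0; EM[, j] <- 0
    a[i] <- a[i] + a[j]
    active[j] <- FALSE
    q <- q + dq[pick]
    step <- step + 1L
    merges[[step]] <- c(dq = dq[pick], q_after = q)
    merge_pairs[step, ] <- c(i, j)
  }
  if (step == 0L) {
    merges_df <- empty_merges
  } else {
    vals <- do.call(rbind, merges[seq_len(step)])
    merges_df <- data.frame(step = seq_len(step),
                            comm_a = merge_pairs[seq_len(step), 1],
                            comm_b = merge_pairs[seq_len(step), 2],
                            dq = vals[, "dq"], q_after = vals[, "q_after"])
  }
  trace <- c(q0, merges_df$q_after)
  best_cut <- which.max(trace) - 1L
  memb <- seq_len(n)
  if (best_cut > 0) {
    for (s in seq_len(best_cut)) {
      i <- merges_df$comm_a[s]; j <- merges_df$comm_b[s]
      memb[memb == j] <- i
    }
  }
  memb <- setNames(match(memb, unique(memb)), g$nodes)
  structure(list(merges = merges_df, q0 = q0, best_cut = best_cut,
                 membership = memb, q_best = trace[best_cut + 1L],
                 n_nodes = n, node_names = g$nodes),
            class = "fg_dendrogram")
}

#' @export
print.fg_dendrogram <- function(x, ...) {
  k <- length(unique(x$membership))
  cat("fast-greedy dendrogram:", x$n_nodes, "nodes,", nrow(x$merges),
      "merges; best cut after", x$best_cut, "merges ->", k,
      sprintf("communities (Q = %.4f)\n", x$q_best))
  invisible(x)
}

# Enumerate set partitions as restricted growth strings, applying `fun`
# to each membership vector.
.for_each_partition <- function(n, fun) {
  memb <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) { fun(memb); return(invisible()) }
    for (g in seq_len(kmax + 1L)) {
      memb[i] <<- g
      recurse(i + 1L, max(kmax, g))
    }
  }
  recurse(1L, 0L)
}

#' Exhaustive best-modularity partition (small-graph oracle)
#'
#' Enumerates every set partition of the nodes (Bell-number many) and
#' returns the global modularity maximum. Intended as an independent
#' correctness oracle for [fast_greedy()] on graphs of at most
#' `max_nodes` nodes.
#'
#' @param network An `mi_network` or edge data frame.
#' @param max_nodes Refuse graphs larger than this (default 10).
#' @param weighted Use edge weights (default TRUE).
#' @param nodes Optional explicit node-name vector.
#' @return List with `membership` (named, renumbered) and `q`.
#' @export
brute_force_best_partition <- function(network, max_nodes = 10,
                                       weighted = TRUE, nodes = NULL) {
  g <- .as_graph(network, weighted, nodes)
  n <- length(g$nodes)
  if (n > max_nodes)
    stop("refusing exhaustive search over ", n, " nodes (max_nodes = ", max_nodes, ")")
  if (nrow(g$edges) == 0) stop("edgeless network: modularity undefined")
  m <- sum(g$edges$weight)
  fi <- match(g$edges$from, g$nodes); ti <- match(g$edges$to, g$nodes)
  w <- g$edges$weight
  deg <- numeric(n)
  for (k in seq_along(w)) {
    deg[fi[k]] <- deg[fi[k]] + w[k]
    deg[ti[k]] <- deg[ti[k]] + w[k]
  }
  best_q <- -Inf; best_memb <- NULL
  .for_each_partition(n, function(memb) {
    e_in <- sum(w[memb[fi] == memb[ti]]) / m
    a <- tapply(deg, memb, sum) / (2 * m)
    q <- e_in - sum(a^2)
    if (q > best_q + 1e-15) {
      best_q <<- q
      best_memb <<- memb
    }
  })
  list(membership = setNames(match(best_memb, unique(best_memb)), g$nodes),
       q = best_q)
}

#' Per-community summary of a detected partition
#'
#' @param dendro An `fg_dendrogram`.
#' @param network The network it was computed from.
#' @return Data frame: community, size, internal_edges, top node by |z|
#'   where node scores are available.
#' @export
community_summary <- function(dendro, network) {
  memb <- dendro$membership
  g <- .as_graph(network, weighted = FALSE)
  z <- if (inherits(network, "mi_network"))
    setNames(network$nodes$z, network$nodes$variable) else NULL
  do.call(rbind, lapply(sort(unique(memb)), function(cid) {
    members <- names(memb)[memb == cid]
    internal <- sum(g$edges$from %in% members & g$edges$to %in% members)
    top <- if (!is.null(z)) members[which.max(abs(z[members]))] else members[1]
    data.frame(community = cid, size = length(members),
               internal_edges = internal, top_node = top,
               stringsAsFactors = FALSE)
  }))
}
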