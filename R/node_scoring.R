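# Node scoring: one multivariable logistic regression over the selected
# variables jointly; each variable's Wald z (coefficient over asymptotic
# standard error) sizes its node, and a two-sided p-value cutoff decides
# which variables enter the network.

#' Wald z-scores from a joint logistic regression
#'
#' Fits a single logistic regression of the outcome on all selected
#' variables (iteratively reweighted least squares, relative convergence
#' tolerance 1e-10, at most 100 iterations). Constant columns are
#' dropped with a warning. Variables showing the signature of perfect
#' separation or aliasing (diverging coefficient or exploding standard
#' error) are flagged and their scores reported as missing -- no silent
#' regularisation is applied.
#'
#' @param x Feature matrix (columns named).
#' @param y Binary outcome.
#' @param selected Variables to score (default: all columns of `x`).
#' @param alpha Two-sided significance level for the `significant` flag
#'   (default 0.05).
#' @return A `node_scores` data frame: variable, beta, se, z, p,
#'   significant.
#' @export
logistic_zscores <- function(x, y, selected = colnames(x), alpha = 0.05) {
  if (length(selected) == 0) stop("'selected' is empty")
  missing_vars <- setdiff(selected, colnames(x))
  if (length(missing_vars))
    stop("selected variable(s) absent from matrix: ", paste(missing_vars, collapse = ", "))
  xx <- as.matrix(x[, selected, drop = FALSE])
  const <- apply(xx, 2, function(col) length(unique(col)) < 2)
  if (any(const)) {
    warning("dropping constant column(s): ", paste(selected[const], collapse = ", "))
    xx <- xx[, !const, drop = FALSE]
    selected <- selected[!const]
    if (!length(selected)) stop("all selected columns are constant")
  }
  safe <- make.names(selected, unique = TRUE)
  df <- as.data.frame(xx)
  names(df) <- safe
  df$.outcome <- y
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.outcome ~ ., data = df, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- se <- rep(NA_real_, length(selected))
  names(beta) <- names(se) <- safe
  ok <- intersect(safe, rownames(sm))
  beta[ok] <- sm[ok, "Estimate"]
  se[ok] <- sm[ok, "Std. Error"]
  aliased <- !(safe %in% rownames(sm))
  separated <- !aliased & ((abs(beta) > 15 & se > 10) | se > 50 |
                             (sep_warn & abs(beta) > 15))
  separated[is.na(separated)] <- FALSE
  if (any(aliased))
    warning("aliased (collinear) column(s), scores unavailable: ",
            paste(selected[aliased], collapse = ", "))
  if (any(separated))
    warning("perfect separation suspected, scores unavailable for: ",
            paste(selected[separated], collapse = ", "))
  bad <- aliased | separated
  beta[bad] <- NA_real_; se[bad] <- NA_real_
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(variable = selected, beta = unname(beta), se = unname(se),
                    z = unname(z), p = unname(p),
                    significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("node_scores", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "converged") <- fit$converged
  if (!fit$converged) warning("logistic fit did not converge in 100 iterations")
  out
}

#' Filter node scores to the significant subset
#'
#' @param scores A `node_scores` data frame from [logistic_zscores()].
#' @param alpha Two-sided p-value cutoff (default 0.05).
#' @return Character vector of significant variable names (possibly
#'   empty); variables with missing scores are never kept.
#' @export
filter_significant <- function(scores, alpha = 0.05) {
  if (nrow(scores) == 0) return(character())
  scores$variable[!is.na(scores$p) & scores$p < alpha]
}
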