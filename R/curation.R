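# Curation: the configurable filter/transform stage turning a raw cohort
# into a complete binary analysis matrix. Drop order is fixed and every
# drop is written to a ledger with its reason, so record/variable counts
# are conserved and auditable.

#' Curation configuration
#'
#' @param exclude_variables Variables dropped outright (duplicated or
#'   redundant columns, blood-pressure style near-copies, ...).
#' @param max_missing_fraction Variables whose missing fraction (after
#'   record-level drops) exceeds this are excluded. The default 0.5
#'   mirrors excluding a smoking-style variable missing in more than
#'   half the records.
#' @param min_age Records with age less than or equal to this are dropped
#'   (adult cohort: default 18).
#' @param exclude_outcome_labels Outcome labels whose records are dropped
#'   before anything else (e.g. a type 1 diabetes flag in a type 2 study).
#' @param bmi_breaks Strictly increasing BMI thresholds splitting the
#'   positive axis into underweight / normal / overweight / obese.
#' @param dichotomize_rules Named list: variable -> vector of levels
#'   mapped to 1 (all other observed levels map to 0).
#' @return A `curation_config` list.
#' @export
curation_config <- function(exclude_variables = character(),
                            max_missing_fraction = 0.5,
                            min_age = 18,
                            exclude_outcome_labels = character(),
                            bmi_breaks = c(18.5, 25, 30),
                            dichotomize_rules = list()) {
  if (!is.numeric(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction > 1)
    stop("invalid config field 'max_missing_fraction': must be in [0,1]")
  if (length(bmi_breaks) != 3L || is.unsorted(bmi_breaks, strictly = TRUE))
    stop("invalid config field 'bmi_breaks': need 3 strictly increasing thresholds")
  structure(list(exclude_variables = exclude_variables,
                 max_missing_fraction = max_missing_fraction,
                 min_age = min_age,
                 exclude_outcome_labels = exclude_outcome_labels,
                 bmi_breaks = bmi_breaks,
                 dichotomize_rules = dichotomize_rules),
            class = "curation_config")
}

.bmi_levels <- c("underweight", "normal", "overweight", "obese")

#' Categorise BMI into the four standard weight ranges
#'
#' Intervals are half-open `[low, high)` with the top category
#' `[30, Inf)`, so every positive BMI falls in exactly one category;
#' non-positive or missing values yield `NA`.
#'
#' @param bmi Numeric vector of BMI values.
#' @param breaks The three thresholds (default 18.5, 25, 30).
#' @return Factor with levels underweight, normal, overweight, obese.
#' @examples
#' categorize_bmi(c(17, 27, 18.5, 31))
#' @export
categorize_bmi <- function(bmi, breaks = c(18.5, 25, 30)) {
  stopifnot(length(breaks) == 3L, !is.unsorted(breaks, strictly = TRUE))
  bmi <- as.numeric(bmi)
  bmi[!is.na(bmi) & bmi <= 0] <- NA
  cut(bmi, breaks = c(0, breaks, Inf), labels = .bmi_levels, right = FALSE)
}

# 4 indicator columns (integer 0/1, NA rows preserved)
.bmi_indicators <- function(bmi, breaks = c(18.5, 25, 30)) {
  cat <- categorize_bmi(bmi, breaks)
  out <- sapply(.bmi_levels, function(l) as.integer(cat == l))
  colnames(out) <- paste0("bmi_", .bmi_levels)
  out
}

#' Dichotomise a discrete column
#'
#' @param column Vector of observed levels (missing values pass through).
#' @param positive Levels mapped to 1; everything else maps to 0.
#' @param domain Optional declared domain of levels; observed levels
#'   outside it raise an error naming the level.
#' @return Integer 0/1 vector with `NA` preserved.
#' @examples
#' dichotomize(c(0, 2, 1, 0), positive = c(1, 2))
#' @export
dichotomize <- function(column, positive, domain = NULL) {
  if (!is.null(domain)) {
    bad <- setdiff(unique(column[!is.na(column)]), domain)
    if (length(bad))
      stop("level(s) outside declared domain: ", paste(bad, collapse = ", "))
  }
  out <- as.integer(column %in% positive)
  out[is.na(column)] <- NA_integer_
  out
}

#' Apply curation to a cohort table
#'
#' Drops, in order: records carrying an excluded outcome label; records
#' with age <= `min_age`; explicitly excluded variables; variables whose
#' missing fraction (computed after the record drops) exceeds
#' `max_missing_fraction`. Then applies the declared dichotomisation
#' rules, expands a continuous `bmi` column into four category
#' indicators, and finally drops the remaining records with any missing
#' value in a retained column (complete-case analysis). Every drop is
#' recorded in the ledger with its reason.
#'
#' @param table A `cohort_table`, or an already-curated `curated_matrix`
#'   (in which case the operation is idempotent).
#' @param config A [curation_config()].
#' @return A `curated_matrix`: `$x` integer 0/1 feature matrix (includes
#'   sex and the BMI indicators), `$y` binary outcome vector, `$age`
#'   retained ages, `$ledger` data frame of drops (kind, id, reason),
#'   `$meta` metadata of retained features.
#' @export
apply_curation <- function(table, config = curation_config()) {
  UseMethod("apply_curation")
}

#' @export
apply_curation.curated_matrix <- function(table, config = curation_config()) {
  apply_curation.cohort_table(as_cohort_table(table), config)
}

#' @export
apply_curation.cohort_table <- function(table, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  d <- table$data
  meta <- table$meta
  out_var <- meta$variable[meta$role == "outcome"]
  if (length(out_var) != 1L || !(out_var %in% names(d)))
    stop("outcome column absent from cohort table")
  ledger <- data.frame(kind = character(), id = character(),
                       reason = character(), stringsAsFactors = FALSE)
  rec_id <- seq_len(nrow(d))

  drop_records <- function(keep, reason) {
    if (any(!keep)) {
      ledger <<- rbind(ledger, data.frame(
        kind = "record", id = as.character(rec_id[!keep]),
        reason = reason, stringsAsFactors = FALSE))
      d <<- d[keep, , drop = FALSE]
      rec_id <<- rec_id[keep]
    }
  }
  drop_variables <- function(vars, reason) {
    vars <- intersect(vars, names(d))
    if (length(vars)) {
      ledger <<- rbind(ledger, data.frame(
        kind = "variable", id = vars, reason = reason, stringsAsFactors = FALSE))
      d <<- d[, setdiff(names(d), vars), drop = FALSE]
      meta <<- meta[!(meta$variable %in% vars), , drop = FALSE]
    }
  }

  # 1. excluded outcome labels (e.g. type 1 diabetes records)
  if (length(config$exclude_outcome_labels))
    drop_records(!(d[[out_var]] %in% config$exclude_outcome_labels),
                 "excluded_outcome_label")
  if (!all(d[[out_var]] %in% c(0, 1)))
    stop("outcome is not binary after label exclusion; labels seen: ",
         paste(utils::head(unique(d[[out_var]])), collapse = ", "))

  # 2. adult-age filter
  if ("age" %in% names(d))
    drop_records(is.na(d$age) | d$age > config$min_age, "age_filter")

  # 3. explicit variable exclusions
  drop_variables(setdiff(config$exclude_variables, out_var), "excluded_variable")

  # 4. missingness-based variable exclusions (fractions after record drops)
  feat <- setdiff(names(d), out_var)
  mf <- vapply(d[feat], function(col) mean(is.na(col)), numeric(1))
  drop_variables(feat[mf > config$max_missing_fraction], "missingness")

  # 5. transforms: declared dichotomisations, then BMI expansion
  for (v in names(config$dichotomize_rules)) {
    if (!(v %in% names(d))) next
    d[[v]] <- dichotomize(d[[v]], config$dichotomize_rules[[v]])
    meta$kind[meta$variable == v] <- "dichotomous"
  }
  if ("bmi" %in% names(d) && meta$kind[meta$variable == "bmi"] == "continuous") {
    ind <- .bmi_indicators(d$bmi, config$bmi_breaks)
    pos <- match("bmi", names(d))
    after <- if (pos < length(d)) d[seq(pos + 1L, length(d))] else NULL
    d <- cbind(d[seq_len(pos - 1L)], as.data.frame(ind), after)
    meta <- rbind(meta[meta$variable != "bmi", , drop = FALSE],
                  data.frame(variable = colnames(ind), kind = "dichotomous",
                             role = "demographic", stringsAsFactors = FALSE))
  }

  # 6. complete-case record drop over retained columns
  keep_cols <- setdiff(names(d), out_var)
  drop_records(complete.cases(d[keep_cols]), "incomplete_record")

  feat_meta <- meta[meta$variable %in% names(d) & meta$role != "outcome" &
                      meta$kind == "dichotomous", , drop = FALSE]
  feat_meta <- feat_meta[order(match(feat_meta$variable, names(d))), , drop = FALSE]
  x <- as.matrix(d[feat_meta$variable])
  storage.mode(x) <- "integer"
  if (length(x) && !all(x %in% c(0L, 1L)))
    stop("internal error: non-binary value in curated feature matrix")
  rownames(x) <- NULL
  structure(list(x = x, y = as.integer(d[[out_var]]),
                 age = if ("age" %in% names(d)) d$age else NULL,
                 ledger = ledger, meta = feat_meta,
                 record_id = rec_id),
            class = "curated_matrix")
}

#' Rebuild a cohort table from a curated matrix
#'
#' Useful for re-running curation (idempotence) or writing curated data
#' back out in the cohort CSV format.
#'
#' @param x A `curated_matrix`.
#' @return A `cohort_table`.
#' @export
as_cohort_table <- function(x) {
  stopifnot(inherits(x, "curated_matrix"))
  d <- as.data.frame(x$x)
  meta <- x$meta
  if (!is.null(x$age)) {
    d$age <- x$age
    meta <- rbind(meta, data.frame(variable = "age", kind = "discrete",
                                   role = "demographic", stringsAsFactors = FALSE))
  }
  d$outcome <- x$y
  meta <- rbind(meta, data.frame(variable = "outcome", kind = "dichotomous",
                                 role = "outcome", stringsAsFactors = FALSE))
  structure(list(data = d, meta = meta), class = "cohort_table")
}

#' @export
print.curated_matrix <- function(x, ...) {
  cat("curated_matrix:", nrow(x$x), "records x", ncol(x$x), "binary features",
      if (!is.null(x$age)) "(+ age)", "\n")
  cat("  outcome prevalence:", round(mean(x$y), 4), "\n")
  if (nrow(x$ledger)) {
    tab <- table(x$ledger$kind, x$ledger$reason)
    cat("  drops:\n"); print(tab)
  }
  invisible(x)
}
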