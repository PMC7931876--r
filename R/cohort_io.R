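# Cohort CSV round-trip. Data travel as a plain CSV (missing cells
# empty); the variable kind/role metadata travels in a companion
# `<stem>.meta.csv` so that a cohort file pair is self-describing.

.meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.csv")

#' Write a cohort table to CSV (plus metadata sidecar)
#'
#' @param table A `cohort_table` (see [generate_cohort()]).
#' @param path Output CSV path; the variable metadata is written next to
#'   it as `<stem>.meta.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_cohort <- function(table, path) {
  if (!inherits(table, "cohort_table")) stop("'table' must be a cohort_table")
  write.csv(table$data, path, row.names = FALSE, na = "")
  mp <- .meta_path(path)
  write.csv(table$meta, mp, row.names = FALSE)
  invisible(c(data = path, meta = mp))
}

#' Read a cohort table written by [write_cohort()]
#'
#' Validates the file against its metadata: dichotomous columns may only
#' contain 0, 1 or empty cells; a violation is reported with the
#' offending file line.
#'
#' @param path CSV path; `<stem>.meta.csv` must exist beside it.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty cohort file (line 1): ", path)
  mp <- .meta_path(path)
  if (!file.exists(mp)) stop("metadata file not found: ", mp)
  data <- read.csv(path, na.strings = "", check.names = FALSE)
  if (nrow(data) == 0) stop("parse error: cohort file has a header but no records (line 2): ", path)
  meta <- read.csv(mp, stringsAsFactors = FALSE)
  need <- c("variable", "kind", "role")
  if (!all(need %in% names(meta))) stop("parse error in ", mp, ": columns must include ", paste(need, collapse = ", "))
  missing_vars <- setdiff(meta$variable, names(data))
  if (length(missing_vars))
    stop("parse error: variables in metadata absent from data (line 1): ",
         paste(missing_vars, collapse = ", "))
  for (v in meta$variable[meta$kind == "dichotomous"]) {
    col <- data[[v]]
    bad <- which(!is.na(col) & !(col %in% c(0, 1)))
    if (length(bad))
      stop("parse error: non-binary value '", col[bad[1]], "' in dichotomous column '",
           v, "' (line ", bad[1] + 1L, ")")
    data[[v]] <- as.integer(col)
  }
  for (v in meta$variable[meta$kind == "discrete"]) data[[v]] <- as.integer(data[[v]])
  structure(list(data = data, meta = meta), class = "cohort_table")
}
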