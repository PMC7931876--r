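# End-to-end orchestration: simulate/load -> curate -> select -> score
# -> network -> communities, with one master seed deterministically
# deriving per-stage seeds and every artifact written as plain CSV /
# GraphML plus a JSON manifest of stages, parameters, seeds and file
# hashes. Rerunning an identical configuration reproduces byte-identical
# outputs.

# Deterministic CSV writer: doubles rounded to 6 significant digits and
# rendered through as.character for byte-stable output.
.write_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- as.character(signif(df[[j]], 6))
    if (is.logical(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive a per-stage seed from the master seed
#'
#' Stage-name salted so adding a stage never perturbs the seeds of
#' earlier ones; always a positive 32-bit integer.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer(((as.numeric(master) %% 1000003) * 2039 + h * 17) %% 2147483647L) + 1L
}

#' Pipeline run configuration
#'
#' Exactly one input source must be given: a [cohort_spec()] to
#' simulate, or the path of a cohort CSV written by [write_cohort()].
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort_spec Optional [cohort_spec()] (its seed is re-derived
#'   from the master seed so the run is fully seed-determined).
#' @param input_path Optional cohort CSV path.
#' @param curation A [curation_config()].
#' @param plan A [split_plan()] (its seed is likewise re-derived).
#' @param methods Selection arms to run: `"rf"`, `"lasso"` or both.
#' @param num_trees Trees per random forest.
#' @param alpha Significance level for node scores and edge filtering.
#' @param B Permutations per edge test.
#' @param correction Edge-wise multiple-testing correction.
#' @param min_patients Minimum shared-patient count per retained edge.
#' @param weighted Use MI weights in community detection.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, cohort_spec = NULL, input_path = NULL,
                       curation = curation_config(), plan = split_plan(),
                       methods = c("rf", "lasso"), num_trees = 500,
                       alpha = 0.05, B = 999, correction = "BH",
                       min_patients = 15, weighted = TRUE, seed = 1L) {
  if (is.null(cohort_spec) == is.null(input_path))
    stop("exactly one input source required: 'cohort_spec' or 'input_path'")
  if (!is.null(cohort_spec) && !inherits(cohort_spec, "cohort_spec"))
    stop("'cohort_spec' must be a cohort_spec object")
  stopifnot(inherits(curation, "curation_config"), inherits(plan, "split_plan"))
  methods <- match.arg(methods, c("rf", "lasso"), several.ok = TRUE)
  structure(list(out_dir = out_dir, cohort_spec = cohort_spec,
                 input_path = input_path, curation = curation, plan = plan,
                 methods = methods, num_trees = num_trees, alpha = alpha,
                 B = B, correction = correction, min_patients = min_patients,
                 weighted = weighted, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate/load, curate, select (one or both arms), score,
#' network and communities, writing every artifact under the configured
#' output directory together with a `manifest.json` (stage list,
#' parameters, per-stage seeds, md5 of every output). A stage failure
#' aborts with the stage name; artifacts already written are kept and a
#' `FAILED` marker names the failing stage.
#'
#' @param config A [run_config()].
#' @return A `run_report`: `$out_dir`, `$arms` (per-arm selection,
#'   scores, network, communities), `$curated`, `$paths`,
#'   `$manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  paths <- character()
  stages <- list()
  current_stage <- NA_character_

  run_stage <- function(name, fun) {
    current_stage <<- name
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage: ", name, "\nerror: ", conditionMessage(e)),
                 failed_marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  add_output <- function(stage, ...) {
    new <- c(...)
    paths <<- c(paths, new)
    stages[[stage]]$outputs <<- c(stages[[stage]]$outputs, unname(new))
  }

  # -- simulate / load ------------------------------------------------
  stages$simulate <- list(seed = stage_seed(config$seed, "simulate"))
  cohort <- run_stage("simulate", function() {
    if (!is.null(config$cohort_spec)) {
      spec <- config$cohort_spec
      spec$seed <- stages$simulate$seed
      gc <- generate_cohort(spec)
      write_cohort(gc$table, file.path(out, "cohort.csv"))
      gc$table
    } else {
      read_cohort(config$input_path)
    }
  })
  add_output("simulate", file.path(out, "cohort.csv"),
             .meta_path(file.path(out, "cohort.csv")))
  if (is.null(config$cohort_spec)) {
    file.copy(config$input_path, file.path(out, "cohort.csv"), overwrite = TRUE)
    file.copy(.meta_path(config$input_path), .meta_path(file.path(out, "cohort.csv")),
              overwrite = TRUE)
  }

  # -- curate ---------------------------------------------------------
  stages$curate <- list(seed = NA)
  curated <- run_stage("curate", function() {
    cm <- apply_curation(cohort, config$curation)
    .write_csv(cbind(as.data.frame(cm$x),
                     if (!is.null(cm$age)) data.frame(age = cm$age),
                     data.frame(outcome = cm$y)),
               file.path(out, "curated.csv"))
    .write_csv(cm$ledger, file.path(out, "curation_ledger.csv"))
    cm
  })
  add_output("curate", file.path(out, "curated.csv"),
             file.path(out, "curation_ledger.csv"))

  # -- select ---------------------------------------------------------
  sel_seed <- stage_seed(config$seed, "select")
  stages$select <- list(seed = sel_seed)
  plan <- config$plan
  plan$seed <- sel_seed
  arms <- run_stage("select", function() {
    res <- run_selection(curated, plan, methods = config$methods,
                         num_trees = config$num_trees)
    for (arm in names(res)) {
      if (!is.null(res[[arm]]$importances))
        .write_csv(res[[arm]]$importances, file.path(out, paste0("importances_", arm, ".csv")))
      .write_csv(data.frame(variable = res[[arm]]$selected),
                 file.path(out, paste0("selection_", arm, ".csv")))
      m <- res[[arm]]$metrics
      .write_csv(data.frame(metric = names(m), value = unlist(m)),
                 file.path(out, paste0("metrics_", arm, ".csv")))
    }
    res
  })
  for (arm in names(arms)) {
    if (!is.null(arms[[arm]]$importances))
      add_output("select", file.path(out, paste0("importances_", arm, ".csv")))
    add_output("select", file.path(out, paste0("selection_", arm, ".csv")),
               file.path(out, paste0("metrics_", arm, ".csv")))
  }

  # -- score / network / communities, per arm -------------------------
  report_arms <- list()
  for (arm in names(arms)) {
    selected <- arms[[arm]]$selected
    stage_sc <- paste0("score_", arm)
    stages[[stage_sc]] <- list(seed = NA)
    scores <- run_stage(stage_sc, function() {
      if (length(selected) == 0) return(NULL)
      sc <- logistic_zscores(curated$x, curated$y, selected, alpha = config$alpha)
      .write_csv(sc, file.path(out, paste0("node_scores_", arm, ".csv")))
      sc
    })
    if (!is.null(scores))
      add_output(stage_sc, file.path(out, paste0("node_scores_", arm, ".csv")))

    stage_nw <- paste0("network_", arm)
    net_seed <- stage_seed(config$seed, stage_nw)
    stages[[stage_nw]] <- list(seed = net_seed)
    net <- run_stage(stage_nw, function() {
      if (is.null(scores) || sum(scores$significant) < 2) {
        warning("arm '", arm, "': fewer than 2 significant nodes; network skipped")
        return(NULL)
      }
      nw <- build_network(curated, scores, B = config$B, alpha = config$alpha,
                          correction = config$correction,
                          min_patients = config$min_patients, seed = net_seed)
      write_graphml(nw, file.path(out, paste0("network_", arm, ".graphml")))
      write_network_csv(nw, file.path(out, paste0("network_nodes_", arm, ".csv")),
                        file.path(out, paste0("network_edges_", arm, ".csv")))
      nw
    })
    if (!is.null(net))
      add_output(stage_nw, file.path(out, paste0("network_", arm, ".graphml")),
                 file.path(out, paste0("network_nodes_", arm, ".csv")),
                 file.path(out, paste0("network_edges_", arm, ".csv")))

    stage_cm <- paste0("communities_", arm)
    stages[[stage_cm]] <- list(seed = NA)
    comm <- run_stage(stage_cm, function() {
      if (is.null(net) || nrow(net$edges) == 0) return(NULL)
      dn <- fast_greedy(net, weighted = config$weighted)
      .write_csv(data.frame(variable = names(dn$membership),
                            community = unname(dn$membership)),
                 file.path(out, paste0("communities_", arm, ".csv")))
      .write_csv(dn$merges, file.path(out, paste0("dendrogram_", arm, ".csv")))
      .write_csv(community_summary(dn, net),
                 file.path(out, paste0("community_summary_", arm, ".csv")))
      dn
    })
    if (!is.null(comm))
      add_output(stage_cm, file.path(out, paste0("communities_", arm, ".csv")),
                 file.path(out, paste0("dendrogram_", arm, ".csv")),
                 file.path(out, paste0("community_summary_", arm, ".csv")))

    report_arms[[arm]] <- list(selection = arms[[arm]], scores = scores,
                               network = net, communities = comm,
                               selected = selected,
                               membership = if (!is.null(comm)) comm$membership)
  }

  # -- manifest -------------------------------------------------------
  manifest <- list(
    package = "ehrnet",
    version = as.character(utils::packageVersion("ehrnet")),
    seed = config$seed,
    parameters = list(methods = config$methods, num_trees = config$num_trees,
                      alpha = config$alpha, B = config$B,
                      correction = config$correction,
                      min_patients = config$min_patients,
                      weighted = config$weighted,
                      train_fraction = config$plan$train_fraction,
                      cv_folds = config$plan$cv_folds),
    stages = lapply(names(stages), function(s) {
      outs <- stages[[s]]$outputs
      list(stage = s, seed = stages[[s]]$seed,
           outputs = if (length(outs)) lapply(unname(outs), function(f)
             list(file = basename(f), md5 = unname(tools::md5sum(f)))) else list())
    }))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(list(out_dir = out, arms = report_arms, curated = curated,
                 paths = paths, manifest_path = manifest_path),
            class = "run_report")
}

#' Compare the two selection arms
#'
#' Reports the overlap of the selected variable sets and, where both
#' arms produced communities, the Jaccard overlap between the two
#' partitions' communities (each community matched to its best
#' counterpart in the other arm).
#'
#' @param rf_result,lasso_result Arm entries of a [run_pipeline()]
#'   report (lists with `$selected` and optionally `$membership`), or
#'   any lists with those fields.
#' @return List with `selected` (intersection, union, jaccard) and,
#'   when available, `community_jaccard` (matrix) and `best_match`
#'   (per-community best Jaccard, both directions).
#' @export
compare_arms <- function(rf_result, lasso_result) {
  if (is.null(rf_result) || is.null(lasso_result) ||
      is.null(rf_result$selected) || is.null(lasso_result$selected))
    stop("both arms (with their selected sets) are required")
  sa <- rf_result$selected; sb <- lasso_result$selected
  inter <- intersect(sa, sb); uni <- union(sa, sb)
  out <- list(selected = list(
    intersection = inter, union = uni,
    jaccard = if (length(uni)) length(inter) / length(uni) else NA_real_))
  ma <- rf_result$membership; mb <- lasso_result$membership
  if (!is.null(ma) && !is.null(mb)) {
    ca <- split(names(ma), ma); cb <- split(names(mb), mb)
    jm <- outer(seq_along(ca), seq_along(cb), Vectorize(function(i, j) {
      u <- union(ca[[i]], cb[[j]])
      if (!length(u)) return(NA_real_)
      length(intersect(ca[[i]], cb[[j]])) / length(u)
    }))
    dimnames(jm) <- list(names(ca), names(cb))
    out$community_jaccard <- jm
    out$best_match <- list(rf_to_lasso = apply(jm, 1, max),
                           lasso_to_rf = apply(jm, 2, max))
  }
  out
}
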