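# Synthetic EHR cohort generator: dichotomous diagnosis/medication style
# features with block-correlated comorbidity groups, demographics, a
# logistic outcome model, redundant near-duplicate columns and MCAR
# missingness. Every draw is governed by the spec seed, so a spec is a
# complete, reproducible description of a cohort.

#' Describe one correlated feature block
#'
#' A block is a group of dichotomous features tied together by a shared
#' latent binary factor, emulating a comorbidity or risk-factor cluster in
#' which diagnoses and medications co-occur within patients.
#'
#' @param name Block name; features are named `<name>_1`, `<name>_2`, ...
#' @param n_features Number of features in the block (>= 1).
#' @param within_block_association Target pairwise odds ratio between any
#'   two features of the block (>= 1; 1 means independent).
#' @param baseline_prevalence Marginal prevalence of each feature, in (0,1).
#' @return A `cohort_block` list.
#' @seealso [cohort_spec()]
#' @export
cohort_block <- function(name, n_features, within_block_association = 1,
                         baseline_prevalence = 0.1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(n_features) || length(n_features) != 1L || n_features < 1)
    stop("invalid block field 'n_features': must be a count >= 1")
  if (!is.numeric(within_block_association) || within_block_association < 1)
    stop("invalid block field 'within_block_association': odds ratio must be >= 1")
  if (!is.numeric(baseline_prevalence) ||
      baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("invalid block field 'baseline_prevalence': must be in (0,1)")
  structure(list(name = name, n_features = as.integer(n_features),
                 within_block_association = within_block_association,
                 baseline_prevalence = baseline_prevalence),
            class = "cohort_block")
}

#' Specify a synthetic EHR cohort
#'
#' @param n_patients Number of medical records (>= 1).
#' @param blocks List of [cohort_block()] objects (possibly empty).
#' @param n_noise_features Number of independent dichotomous features with
#'   no relation to the outcome; prevalences are drawn uniformly on
#'   (0.02, 0.30) to mimic the spread of diagnosis-code frequencies.
#' @param outcome_coefficients Named numeric vector (or named list) of
#'   log-odds coefficients; names must refer to generated feature columns
#'   (block features, noise features, `age`, `sex` or `bmi`).
#' @param outcome_intercept Intercept of the logistic outcome model.
#' @param n_redundant Number of near-duplicate columns: existing binary
#'   features copied with 2 percent flip noise, emulating the redundant
#'   variables real EHR extracts carry.
#' @param missing_rate Completely-at-random missingness probability per
#'   non-outcome cell, in `[0, 1)`.
#' @param seed Integer seed; together with the other fields it determines
#'   the generated table bit-exactly.
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(n_patients, blocks = list(), n_noise_features = 0,
                        outcome_coefficients = numeric(), outcome_intercept = 0,
                        n_redundant = 0, missing_rate = 0, seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("invalid spec field 'n_patients': must be >= 1")
  if (inherits(blocks, "cohort_block")) blocks <- list(blocks)
  stopifnot(is.list(blocks))
  blocks <- lapply(blocks, function(b) {
    if (!inherits(b, "cohort_block")) stop("invalid spec field 'blocks': entries must be cohort_block objects")
    b
  })
  bnames <- vapply(blocks, `[[`, character(1), "name")
  if (anyDuplicated(bnames)) stop("invalid spec field 'blocks': block names must be unique")
  if (!is.numeric(n_noise_features) || n_noise_features < 0)
    stop("invalid spec field 'n_noise_features'")
  if (is.list(outcome_coefficients)) outcome_coefficients <- unlist(outcome_coefficients)
  if (length(outcome_coefficients) &&
      (is.null(names(outcome_coefficients)) || any(!nzchar(names(outcome_coefficients)))))
    stop("invalid spec field 'outcome_coefficients': must be named")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("invalid spec field 'missing_rate': must be in [0,1)")
  if (!is.numeric(n_redundant) || n_redundant < 0)
    stop("invalid spec field 'n_redundant'")
  spec <- structure(list(
    n_patients = as.integer(n_patients), blocks = blocks,
    n_noise_features = as.integer(n_noise_features),
    outcome_coefficients = outcome_coefficients,
    outcome_intercept = outcome_intercept,
    n_redundant = as.integer(n_redundant),
    missing_rate = missing_rate, seed = as.integer(seed)), class = "cohort_spec")
  known <- c(feature_names(spec), "age", "sex", "bmi")
  bad <- setdiff(names(outcome_coefficients), known)
  if (length(bad))
    stop("invalid spec field 'outcome_coefficients': unknown feature(s) ",
         paste(bad, collapse = ", "))
  spec
}

# Binary feature names implied by a spec (blocks then noise; redundant
# duplicates are named at generation time from their sources).
feature_names <- function(spec) {
  bl <- unlist(lapply(spec$blocks, function(b) paste0(b$name, "_", seq_len(b$n_features))))
  no <- if (spec$n_noise_features > 0) paste0("noise_", seq_len(spec$n_noise_features)) else character()
  c(bl, no)
}

# Flip rate achieving a target within-block pairwise odds ratio.
#
# Each feature equals the latent block factor Z ~ Bern(pi) with
# independent flip probability eps. The marginal prevalence constraint
# fixes pi = (p - eps)/(1 - 2 eps); the pairwise odds ratio is then a
# monotone decreasing function of eps, from +Inf at eps = 0 to 1 as the
# latent factor washes out, so a bracketed root search suffices.
.block_flip_rate <- function(target_or, prevalence) {
  if (target_or <= 1 + 1e-9) return(NA_real_)  # independent features
  or_of_eps <- function(eps) {
    p <- prevalence
    pi <- (p - eps) / (1 - 2 * eps)
    a <- 1 - eps; b <- eps
    p11 <- pi * a^2 + (1 - pi) * b^2
    p10 <- pi * a * (1 - a) + (1 - pi) * b * (1 - b)
    p00 <- pi * (1 - a)^2 + (1 - pi) * (1 - b)^2
    (p11 * p00) / (p10 * p10)
  }
  hi <- min(prevalence, 1 - prevalence)
  f <- function(eps) log(or_of_eps(eps)) - log(target_or)
  uniroot(f, lower = 1e-9, upper = hi * (1 - 1e-9), tol = 1e-12)$root
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a patient-by-variable table per the spec: block features from a
#' shared latent Bernoulli factor with calibrated flip noise (so each
#' within-block pair attains approximately the requested odds ratio),
#' independent noise features, demographics (integer age uniform on
#' 18--76, binary sex with 1 = male, lognormal BMI around 27 rounded to
#' one decimal), a binary outcome from the logistic model
#' `logit(p) = intercept + sum(beta_j * x_j)`, near-duplicate redundant
#' columns, and finally a completely-at-random missingness mask over
#' non-outcome cells.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `table` (a `cohort_table`: `$data` data frame plus
#'   `$meta` variable kind/role table) and `truth` (a `ground_truth`:
#'   `predictive_set`, `block_membership`, `generating_params`).
#' @examples
#' spec <- cohort_spec(200, list(cohort_block("cardio", 4, 6, 0.2)),
#'                     n_noise_features = 5,
#'                     outcome_coefficients = c(cardio_1 = 1), seed = 7)
#' gc <- generate_cohort(spec)
#' dim(gc$table$data)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  n <- spec$n_patients
  set.seed(spec$seed)
  cols <- list()
  block_membership <- character()

  for (b in spec$blocks) {
    eps <- .block_flip_rate(b$within_block_association, b$baseline_prevalence)
    if (is.na(eps)) {
      for (j in seq_len(b$n_features))
        cols[[paste0(b$name, "_", j)]] <- rbinom(n, 1L, b$baseline_prevalence)
    } else {
      pi <- (b$baseline_prevalence - eps) / (1 - 2 * eps)
      z <- rbinom(n, 1L, pi)
      for (j in seq_len(b$n_features)) {
        flip <- rbinom(n, 1L, eps)
        cols[[paste0(b$name, "_", j)]] <- as.integer((z + flip) %% 2L)
      }
    }
    bm <- rep(b$name, b$n_features)
    names(bm) <- paste0(b$name, "_", seq_len(b$n_features))
    block_membership <- c(block_membership, bm)
  }

  if (spec$n_noise_features > 0) {
    prevs <- runif(spec$n_noise_features, 0.02, 0.30)
    for (j in seq_len(spec$n_noise_features))
      cols[[paste0("noise_", j)]] <- rbinom(n, 1L, prevs[j])
  }

  age <- sample(18:76, n, replace = TRUE)
  sex <- rbinom(n, 1L, 0.5)
  bmi <- round(rlnorm(n, meanlog = log(27), sdlog = 0.18), 1)

  lp <- rep(spec$outcome_intercept, n)
  demo <- list(age = age, sex = sex, bmi = bmi)
  for (nm in names(spec$outcome_coefficients)) {
    v <- if (nm %in% names(cols)) cols[[nm]] else demo[[nm]]
    lp <- lp + spec$outcome_coefficients[[nm]] * v
  }
  outcome <- rbinom(n, 1L, plogis(lp))

  # redundant near-duplicates, cycling deterministically over the binary
  # features, with 2% flip noise
  red_roles <- character()
  if (spec$n_redundant > 0) {
    src_pool <- names(cols)
    if (!length(src_pool)) stop("n_redundant > 0 requires at least one binary feature")
    for (k in seq_len(spec$n_redundant)) {
      src <- src_pool[((k - 1L) %% length(src_pool)) + 1L]
      flip <- rbinom(n, 1L, 0.02)
      nm <- paste0(src, "_dup", ((k - 1L) %/% length(src_pool)) + 1L)
      cols[[nm]] <- as.integer((cols[[src]] + flip) %% 2L)
      red_roles[nm] <- src
    }
  }

  data <- as.data.frame(cols, optional = TRUE)
  data$age <- age; data$sex <- sex; data$bmi <- bmi
  data$outcome <- outcome

  if (spec$missing_rate > 0) {
    nonout <- setdiff(names(data), "outcome")
    mask <- matrix(runif(n * length(nonout)) < spec$missing_rate, nrow = n)
    for (j in seq_along(nonout)) data[[nonout[j]]][mask[, j]] <- NA
  }

  binaries <- setdiff(names(data), c("age", "sex", "bmi", "outcome"))
  meta <- data.frame(
    variable = names(data),
    kind = ifelse(names(data) %in% c("age"), "discrete",
           ifelse(names(data) %in% c("bmi"), "continuous", "dichotomous")),
    role = ifelse(names(data) %in% c("age", "sex", "bmi"), "demographic",
           ifelse(names(data) == "outcome", "outcome", "diagnosis")),
    stringsAsFactors = FALSE)

  table <- structure(list(data = data, meta = meta), class = "cohort_table")
  coefs <- spec$outcome_coefficients
  truth <- structure(list(
    predictive_set = names(coefs)[coefs != 0],
    block_membership = block_membership,
    redundant_sources = red_roles,
    generating_params = spec), class = "ground_truth")
  list(table = table, truth = truth)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$data), "records x", ncol(x$data), "variables\n")
  tab <- table(x$meta$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$data)), "\n")
  invisible(x)
}

#' Study-scale synthetic cohort specification
#'
#' A convenience spec whose curated matrix matches the dimensions of a
#' mid-size single-centre EHR extract: 8,482 records by 286 binary
#' variables (281 diagnosis/medication-style columns plus sex and the
#' four BMI category indicators), with roughly 20 percent outcome
#' prevalence. Structure: a 10-feature comorbidity block and a
#' 10-feature risk-factor block (within-block odds ratio 4), 256
#' independent noise features, 5 redundant near-duplicates, and outcome
#' coefficients on ten block features.
#'
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
study_cohort_spec <- function(seed = 1L) {
  coefs <- c(setNames(seq(0.8, 0.3, length.out = 6), paste0("comorbidity_", 1:6)),
             setNames(seq(0.6, 0.3, length.out = 4), paste0("riskfactor_", 1:4)))
  cohort_spec(
    n_patients = 8482,
    blocks = list(
      cohort_block("comorbidity", 10, within_block_association = 4,
                   baseline_prevalence = 0.12),
      cohort_block("riskfactor", 10, within_block_association = 4,
                   baseline_prevalence = 0.25)),
    n_noise_features = 256,
    outcome_coefficients = coefs,
    outcome_intercept = -2.4,
    n_redundant = 5,
    missing_rate = 0,
    seed = seed)
}
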