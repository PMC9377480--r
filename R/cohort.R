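# Synthetic study cohorts.  The generator emulates the structure of a
# 63-patient dialysis-clinic cohort: exact categorical marginals
# (race, gender, education, prior transplant), truncated-normal ages on the
# [21, 80] inclusion window, lognormal dialysis vintages per race, a
# 10-item knowledge test with calibrated pre and change scores, permuted-
# block arm assignment, and per-patient latent utilities drawn through a
# single shared uniform rank so that within-patient orderings across
# states and methods are coherent while every (state, method) marginal is
# moment-matched to its target.

#' Cohort calibration configuration
#'
#' Holds every target the synthetic-cohort generator matches.  Categorical
#' counts are matched exactly per cohort; continuous targets are matched in
#' distribution via the moment-matching calibrators
#' ([calibrate_cohort_model()]).
#'
#' @param n_patients Cohort size.
#' @param race_counts,gender_counts,education_counts Named integer counts;
#'   each must sum to `n_patients`.
#' @param age_range Inclusion window in years, `c(low, high)`.
#' @param age_mean,age_sd Target age moments within the window.
#' @param vintage_mean Named per-race mean dialysis vintage in years.
#' @param vintage_cv Common coefficient of variation of the lognormal
#'   vintage model.
#' @param knowledge_pre,knowledge_change Named numeric `c(mean, sd)` of the
#'   realized (10-point-grid) pretest score and pre-to-post change score.
#' @param utility_targets Data frame with columns `state`, `method`,
#'   `mean`, `sd` on the 0-100 scale, one row per (state, method).
#' @param prior_transplant_count Number of patients with a prior (failed)
#'   kidney transplant.
#' @param response_noise_sd Respondent threshold noise SD (fraction scale);
#'   0 gives noise-free respondents.
#' @param arm_effect Additive shift of the mean knowledge change in the
#'   MATCHED arm (points); defaults to 0 (no arm effect).
#' @param block_size Permuted-block size for arm randomization.
#' @return Object of class `calibration_config`.
#' @export
calibration_config <- function(n_patients = 63L,
                               race_counts = c("African American" = 44L,
                                               "European American" = 19L),
                               gender_counts = c(male = 33L, female = 30L),
                               education_counts = c(
                                 "less than high school" = 10L,
                                 "high school or GED"    = 25L,
                                 "some college"          = 11L,
                                 "associate degree"      = 5L,
                                 "bachelor's degree"     = 9L,
                                 "master's degree"       = 3L),
                               age_range = c(21L, 80L),
                               age_mean = 57.8, age_sd = 12.3,
                               vintage_mean = c("African American" = 7.3,
                                                "European American" = 2.79),
                               vintage_cv = 8.1 / 5.9,
                               knowledge_pre = c(mean = 79.0, sd = 17.3),
                               knowledge_change = c(mean = 10.0, sd = 13.8),
                               utility_targets = default_utility_targets(),
                               prior_transplant_count = 9L,
                               response_noise_sd = 0,
                               arm_effect = 0,
                               block_size = 4L) {
  check_number(n_patients, "n_patients", 1, Inf)
  n_patients <- as.integer(n_patients)
  for (nm in c("race_counts", "gender_counts", "education_counts")) {
    counts <- get(nm)
    if (is.null(names(counts)) || any(counts < 0))
      abort_validation(sprintf("`%s` must be named non-negative counts", nm))
    if (sum(counts) != n_patients)
      abort_validation(sprintf("`%s` must sum to n_patients (%d), got %d",
                               nm, n_patients, sum(counts)))
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    abort_validation("`age_range` must be c(low, high) with low < high")
  check_number(age_mean, "age_mean", age_range[1], age_range[2])
  check_number(age_sd, "age_sd", 0, Inf)
  if (is.null(names(vintage_mean)) ||
      !setequal(names(vintage_mean), names(race_counts)))
    abort_validation("`vintage_mean` must be named by the race categories")
  if (any(vintage_mean <= 0)) abort_validation("vintage means must be positive")
  check_number(vintage_cv, "vintage_cv", 0, Inf)
  for (nm in c("knowledge_pre", "knowledge_change")) {
    kv <- get(nm)
    if (!is.numeric(kv) || !all(c("mean", "sd") %in% names(kv)))
      abort_validation(sprintf("`%s` must be c(mean = , sd = )", nm))
    if (kv[["sd"]] < 0) abort_validation(sprintf("`%s` SD must be >= 0", nm))
  }
  check_number(knowledge_pre[["mean"]], "knowledge_pre mean", 0, 100)
  ut <- as.data.frame(utility_targets)
  need <- c("state", "method", "mean", "sd")
  if (!all(need %in% names(ut)))
    abort_validation("`utility_targets` must have columns state, method, mean, sd")
  if (any(!ut$state %in% assessed_states()) ||
      any(!ut$method %in% assessment_methods()))
    abort_validation("`utility_targets` contains unknown states or methods")
  if (any(ut$mean <= 0 | ut$mean >= 100) || any(ut$sd <= 0))
    abort_validation("utility targets must have means inside (0, 100) and positive SDs")
  if (anyDuplicated(ut[c("state", "method")]))
    abort_validation("duplicate (state, method) rows in `utility_targets`")
  check_number(prior_transplant_count, "prior_transplant_count", 0, n_patients)
  check_number(response_noise_sd, "response_noise_sd", 0, Inf)
  check_number(arm_effect, "arm_effect")
  structure(list(
    n_patients = n_patients,
    race_counts = race_counts, gender_counts = gender_counts,
    education_counts = education_counts,
    age_range = as.numeric(age_range), age_mean = age_mean, age_sd = age_sd,
    vintage_mean = as.list(vintage_mean), vintage_cv = vintage_cv,
    knowledge_pre = knowledge_pre[c("mean", "sd")],
    knowledge_change = knowledge_change[c("mean", "sd")],
    utility_targets = `rownames<-`(ut[order(ut$method, ut$state), need], NULL),
    prior_transplant_count = as.integer(prior_transplant_count),
    response_noise_sd = response_noise_sd,
    arm_effect = arm_effect,
    block_size = as.integer(block_size)
  ), class = "calibration_config")
}

#' @rdname calibration_config
#' @export
default_utility_targets <- function() {
  data.frame(
    state = rep(c("HEMODIALYSIS", "TX_UNEXPOSED", "TX_HCV_VIREMIC"), 3),
    method = rep(c("VAS", "SG", "TTO"), each = 3),
    mean = c(57.9, 88.2, 66.3,
             82.5, 89.0, 75.5,
             80.3, 84.8, 73.8),
    sd   = c(25.9, 17.8, 27.3,
             23.1, 18.0, 28.2,
             20.5, 22.0, 28.1))
}

#' Default study calibration
#'
#' The calibration populated with the published overall-column summary
#' statistics of the study cohort: 63 patients (44 African American, 19
#' European American; 33 male, 30 female), ages 21-80 with mean 57.8 (SD
#' 12.3), the education mix, per-race dialysis vintages, pretest knowledge
#' 79.0 (17.3) with mean change 10.0 (13.8), the nine (state, method)
#' utility targets, and 9 patients with a prior kidney transplant.
#'
#' @return A [calibration_config()].
#' @export
#' @examples
#' default_calibration()$n_patients
default_calibration <- function() calibration_config()

#' @export
print.calibration_config <- function(x, ...) {
  cat(sprintf("<calibration_config> n=%d; races: %s; noise sd: %g\n",
              x$n_patients,
              paste(sprintf("%s=%d", names(x$race_counts), x$race_counts),
                    collapse = ", "),
              x$response_noise_sd))
  invisible(x)
}

#' Read and write calibration configurations as JSON
#'
#' @param calibration A [calibration_config()].
#' @param path File path.
#' @return `read_calibration()` returns a validated
#'   [calibration_config()]; `write_calibration()` returns `path`
#'   invisibly.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "calibration_config"))
  x <- unclass(calibration)
  # named atomic vectors must become JSON objects, not bare arrays
  for (nm in c("race_counts", "gender_counts", "education_counts",
               "knowledge_pre", "knowledge_change"))
    x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("calibration file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("n_patients", "race_counts", "gender_counts", "education_counts",
            "age_range", "age_mean", "age_sd", "vintage_mean", "vintage_cv",
            "knowledge_pre", "knowledge_change", "utility_targets",
            "prior_transplant_count")
  missing <- setdiff(need, names(x))
  if (length(missing))
    abort_format(sprintf("calibration JSON is missing field(s): %s",
                         paste(missing, collapse = ", ")))
  calibration_config(
    n_patients = x$n_patients,
    race_counts = unlist(x$race_counts),
    gender_counts = unlist(x$gender_counts),
    education_counts = unlist(x$education_counts),
    age_range = unlist(x$age_range),
    age_mean = x$age_mean, age_sd = x$age_sd,
    vintage_mean = unlist(x$vintage_mean),
    vintage_cv = x$vintage_cv,
    knowledge_pre = unlist(x$knowledge_pre),
    knowledge_change = unlist(x$knowledge_change),
    utility_targets = as.data.frame(x$utility_targets),
    prior_transplant_count = x$prior_transplant_count,
    response_noise_sd = if (is.null(x$response_noise_sd)) 0 else x$response_noise_sd,
    arm_effect = if (is.null(x$arm_effect)) 0 else x$arm_effect,
    block_size = if (is.null(x$block_size)) 4L else x$block_size)
}

round10 <- function(x) 10 * round_half_up(x / 10)

#' Generate a synthetic cohort
#'
#' Deterministic given `(calibration, seed)`.  Categorical fields are drawn
#' as seeded permutations of the exact configured counts; ages come from
#' the calibrated truncated normal on the inclusion window (rounded to
#' whole years); vintages from per-race lognormals; knowledge scores from
#' the calibrated 10-point-grid models with `post = pre + change` clamped
#' to `[0, 100]`; arms from permuted-block randomization; and each
#' patient's latent utilities for every (state, method) are that patient's
#' shared uniform rank pushed through the calibrated censored-normal
#' marginals.
#'
#' @param calibration A [calibration_config()] or fitted
#'   [calibrate_cohort_model()].
#' @param seed Integer seed.
#' @return Object of class `hua_cohort`: `$patients` (one row per patient),
#'   `$latents` (array `n x state x method`, fractions on `[0, 1]`),
#'   `$seed`, `$calibration`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_calibration(), seed = 1)
#' table(cohort$patients$race)
generate_cohort <- function(calibration, seed) {
  fit <- calibrate_cohort_model(calibration)
  cfg <- fit$config
  n <- cfg$n_patients
  with_seed(seed, {
    ids <- sprintf("P%03d", seq_len(n))
    race <- sample(rep(names(cfg$race_counts), cfg$race_counts))
    sex <- sample(rep(names(cfg$gender_counts), cfg$gender_counts))
    education <- sample(rep(names(cfg$education_counts), cfg$education_counts))
    prior_tx <- sample(c(rep(TRUE, cfg$prior_transplant_count),
                         rep(FALSE, n - cfg$prior_transplant_count)))

    a <- stats::pnorm(cfg$age_range[1], fit$age[["mu"]], fit$age[["sigma"]])
    b <- stats::pnorm(cfg$age_range[2], fit$age[["mu"]], fit$age[["sigma"]])
    age_raw <- stats::qnorm(a + stats::runif(n) * (b - a),
                            fit$age[["mu"]], fit$age[["sigma"]])
    age <- pmin(pmax(as.integer(round_half_up(age_raw)),
                     as.integer(cfg$age_range[1])), as.integer(cfg$age_range[2]))

    vintage <- numeric(n)
    for (r in names(fit$vintage)) {
      idx <- race == r
      vintage[idx] <- stats::rlnorm(sum(idx), fit$vintage[[r]][["meanlog"]],
                                    fit$vintage[[r]][["sdlog"]])
    }
    vintage <- round(vintage, 2)

    arm_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    arms <- randomize_arm(ids, seed = arm_seed, block_size = cfg$block_size)

    pre <- sample(seq(0, 100, by = 10), n, replace = TRUE,
                  prob = fit$knowledge_pre_probs)
    change_mu <- fit$knowledge_change[["mu"]] +
      ifelse(arms$arm == "MATCHED", cfg$arm_effect, 0)
    change_raw <- stats::rnorm(n, change_mu, fit$knowledge_change[["sigma"]])
    post <- round10(pmin(pmax(pre + change_raw, 0), 100))

    rank <- stats::runif(n)
    states <- assessed_states()
    methods <- assessment_methods()
    latents <- array(NA_real_, dim = c(n, length(states), length(methods)),
                     dimnames = list(ids, states, methods))
    for (st in states) for (m in methods)
      latents[, st, m] <- latent_quantile(fit, st, m, rank)

    patients <- data.frame(
      patient_id = ids, age = age, sex = sex, race = race,
      education = education, vintage_years = vintage,
      prior_transplant = prior_tx, arm = arms$arm,
      knowledge_pre = as.numeric(pre), knowledge_post = as.numeric(post),
      stringsAsFactors = FALSE)

    structure(list(patients = patients, latents = latents,
                   seed = seed, calibration = cfg),
              class = "hua_cohort")
  })
}

#' @export
print.hua_cohort <- function(x, ...) {
  cat(sprintf("<hua_cohort> %d patients (seed %s); arms: %s\n",
              nrow(x$patients), format(x$seed),
              paste(sprintf("%s=%d", names(table(x$patients$arm)),
                            table(x$patients$arm)), collapse = ", ")))
  invisible(x)
}

#' Simulate the full elicitation study on a synthetic cohort
#'
#' For every patient and requested method, runs the study's two-part
#' protocol with the adaptive engines: hemodialysis and HCV-unexposed
#' transplant on Well/Dead anchors first, then the chained HCV-viremic
#' assessment anchored on that patient's just-elicited transplant utility
#' and Dead.  Chained results are normalized back to the common scale.
#' Respondents answer from their latent utilities
#' ([respondent_profile()]); with the default noise-free calibration every
#' elicited utility lands within the titration resolution of its latent
#' target.
#'
#' @param calibration A [calibration_config()] or fitted model.
#' @param elicit_config A [titration_config()].
#' @param seed Integer seed (also seeds the cohort unless one is given).
#' @param methods Assessment methods to run (default all three).
#' @param cohort Optional pre-generated [generate_cohort()] cohort.
#' @param life_table Life table for TTO horizons; defaults to the bundled
#'   synthetic table.
#' @return Object of class `hua_results`: `$results` (one row per patient,
#'   state and method, with raw and normalized utilities), `$patients`,
#'   `$cohort`.
#' @export
simulate_study <- function(calibration, elicit_config = titration_config(),
                           seed, methods = assessment_methods(),
                           cohort = NULL, life_table = NULL) {
  fit <- calibrate_cohort_model(calibration)
  cfg <- fit$config
  if (is.null(cohort)) cohort <- generate_cohort(fit, seed)
  stopifnot(inherits(cohort, "hua_cohort"))
  methods <- vapply(methods, check_method, character(1))
  if (is.null(life_table))
    life_table <- read_life_table(system.file("extdata", "life_table_synthetic.csv",
                                              package = "huassess"))
  pts <- cohort$patients
  n <- nrow(pts)
  rows <- vector("list", n * length(methods) * 3L)
  k <- 0L
  for (i in seq_len(n)) {
    horizon <- tto_horizon(pts$age[i], pts$sex[i], life_table)
    for (m in methods) {
      profile <- respondent_profile(
        cohort$latents[i, , m],
        response_noise_sd = cfg$response_noise_sd,
        rng_seed = (cohort$seed %% 100000L) * 10000L + i)
      hz <- if (m == "TTO") horizon else NULL
      u_hd <- run_auto_session(m, "HEMODIALYSIS", default_anchors(),
                               elicit_config, profile, horizon_years = hz)
      u_tx <- run_auto_session(m, "TX_UNEXPOSED", default_anchors(),
                               elicit_config, profile, horizon_years = hz)
      if (cohort$latents[i, "TX_UNEXPOSED", m] > 0) {
        anchors_hcv <- chained_anchors(u_tx$normalized)
        u_hcv <- run_auto_session(m, "TX_HCV_VIREMIC", anchors_hcv,
                                  elicit_config, profile, horizon_years = hz)
      } else {
        # degenerate chained scale: the respondent rates the anchor state
        # (transplant) no better than dead, so the HCV-viremic state pins
        # to 0 on the common scale and no chained fraction is defined
        u_hcv <- list(state = "TX_HCV_VIREMIC", method = m,
                      raw_fraction = NA_real_, normalized = 0, chained = TRUE)
      }
      for (u in list(u_hd, u_tx, u_hcv)) {
        k <- k + 1L
        rows[[k]] <- data.frame(patient_id = pts$patient_id[i],
                                state = u$state, method = u$method,
                                raw_fraction = u$raw_fraction,
                                normalized = u$normalized,
                                chained = u$chained,
                                stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, patients = pts, cohort = cohort),
            class = "hua_results")
}

#' @export
print.hua_results <- function(x, ...) {
  cat(sprintf("<hua_results> %d utility rows over %d patients and methods: %s\n",
              nrow(x$results), nrow(x$patients),
              paste(unique(x$results$method), collapse = ", ")))
  invisible(x)
}
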