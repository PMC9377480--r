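# Behavioral model of a simulated respondent.  A respondent holds latent
# utilities on the common Well/Dead [0, 1] scale, an additive per-method
# bias (the simplest mechanism that reproduces the documented tendency of
# standard-gamble utilities to sit above TTO/VAS values for risk-averse
# respondents), and an optional per-question Gaussian perturbation of the
# comparison threshold.  With zero noise the respondent is a deterministic
# threshold responder: SURE/STAY whenever the offered fraction is at or
# above the (biased) target, which the nested-bracket engine recovers to
# within the titration resolution.

#' Simulated respondent profile
#'
#' @param latent_utilities Named numeric vector of true utilities on the
#'   `[0, 1]` Well/Dead scale for (at least) the assessed states.  `WELL`
#'   and `DEAD` are fixed at 1 and 0.
#' @param method_bias Named additive shift per assessment method on the
#'   `[0, 1]` scale (targets are clamped back to `[0, 1]`).
#' @param response_noise_sd Standard deviation of a per-question Gaussian
#'   perturbation of the comparison threshold; 0 gives deterministic
#'   responses.
#' @param rng_seed Integer seed making noisy response sequences
#'   reproducible.
#' @return Object of class `respondent_profile`.
#' @export
#' @examples
#' r <- respondent_profile(c(HEMODIALYSIS = 0.825, TX_UNEXPOSED = 0.89,
#'                           TX_HCV_VIREMIC = 0.755))
#' target_indifference(r, "SG", "HEMODIALYSIS", default_anchors())
respondent_profile <- function(latent_utilities,
                               method_bias = c(VAS = 0, SG = 0, TTO = 0),
                               response_noise_sd = 0,
                               rng_seed = 1L) {
  if (is.null(names(latent_utilities)) ||
      !all(names(latent_utilities) %in% unname(health_states())))
    abort_validation("`latent_utilities` must be named by health state")
  if (any(latent_utilities < 0 | latent_utilities > 1))
    abort_validation("latent utilities must lie in [0, 1]")
  lat <- c(latent_utilities, WELL = 1, DEAD = 0)
  lat <- lat[!duplicated(names(lat))]
  bias <- c(VAS = 0, SG = 0, TTO = 0)
  if (length(method_bias)) {
    if (is.null(names(method_bias)) ||
        !all(names(method_bias) %in% assessment_methods()))
      abort_validation("`method_bias` must be named by assessment method")
    bias[names(method_bias)] <- method_bias
  }
  check_number(response_noise_sd, "response_noise_sd", 0, Inf)
  structure(list(latent_utilities = lat, method_bias = bias,
                 response_noise_sd = response_noise_sd,
                 rng_seed = as.integer(rng_seed),
                 state = as.environment(list(k = 0L))),
            class = "respondent_profile")
}

#' @export
print.respondent_profile <- function(x, ...) {
  u <- x$latent_utilities[intersect(assessed_states(), names(x$latent_utilities))]
  cat(sprintf("<respondent_profile> latents: %s  noise sd: %g  seed: %d\n",
              paste(sprintf("%s=%.3f", names(u), u), collapse = " "),
              x$response_noise_sd, x$rng_seed))
  invisible(x)
}

#' Target indifference fraction for a question type
#'
#' The (biased) latent utility of the target state, re-expressed on the
#' session's anchor pair: for a default Well/Dead session this is
#' `clamp(latent + bias, 0, 1)`; for a chained session it is divided by the
#' respondent's (biased) latent utility of the chained best anchor and
#' clamped to `[0, 1]`.
#'
#' @param profile A [respondent_profile()].
#' @param method Assessment method.
#' @param target_state Assessed health state.
#' @param anchors The session's [anchor_pair()].
#' @return Fraction in `[0, 1]`.
#' @export
target_indifference <- function(profile, method, target_state,
                                anchors = default_anchors()) {
  stopifnot(inherits(profile, "respondent_profile"))
  method <- check_method(method)
  target_state <- check_state(target_state, allow_anchor = FALSE)
  stopifnot(inherits(anchors, "anchor_pair"))
  lat <- profile$latent_utilities
  if (!(target_state %in% names(lat)))
    abort_validation(sprintf("profile has no latent utility for state '%s'", target_state))
  bias <- profile$method_bias[[method]]
  target <- clamp01(lat[[target_state]] + bias)
  if (is_chained(anchors)) {
    if (!(anchors$best %in% names(lat)))
      abort_validation(sprintf("profile has no latent utility for chained anchor '%s'", anchors$best))
    denom <- clamp01(lat[[anchors$best]] + bias)
    if (denom <= 0)
      abort_degenerate("chained anchor state has latent utility 0; the chained scale is degenerate")
    target <- clamp01(target / denom)
  }
  target
}

# deterministic per-question noise draw: seeded from (rng_seed, counter) so
# a profile replays the identical choice sequence on a rerun
next_noise <- function(profile) {
  if (profile$response_noise_sd == 0) return(0)
  k <- profile$state$k + 1L
  profile$state$k <- k
  with_seed((as.numeric(profile$rng_seed) * 1000003 + k) %% 2147483647,
            stats::rnorm(1, 0, profile$response_noise_sd))
}

#' Answer an elicitation question
#'
#' Compares the question's offered fraction (`p_best` for a gamble,
#' `offered/horizon` for a trade) against [target_indifference()] plus a
#' noise draw: at or above the threshold the respondent keeps the sure/stay
#' option, below it they gamble/trade.  A placement request returns the
#' (noisy) target on the 0-100 scale.  Deterministic when
#' `response_noise_sd = 0`.
#'
#' @param profile A [respondent_profile()].
#' @param question A question produced by the session engine
#'   ([current_question()]).
#' @return `"SURE"`/`"GAMBLE"`, `"STAY"`/`"TRADE"`, or a numeric placement.
#' @export
respond <- function(profile, question) {
  stopifnot(inherits(profile, "respondent_profile"))
  if (is.null(question$type))
    abort_protocol("malformed question: no `type` field")
  target <- target_indifference(profile, question$method, question$target_state,
                                question$anchors)
  threshold <- clamp01(target + next_noise(profile))
  switch(question$type,
    placement = 100 * threshold,
    gamble = if (question$fraction >= threshold) "SURE" else "GAMBLE",
    trade  = if (question$fraction >= threshold) "STAY" else "TRADE",
    abort_protocol(sprintf("unknown question type '%s'", question$type)))
}

#' Draw a respondent from a cohort calibration
#'
#' Bridges the cohort calibrator to the respondent model: a single uniform
#' rank is drawn and mapped through the calibrated latent-utility marginal
#' of every assessed state for the given method, so within-respondent
#' orderings are coherent.
#'
#' @param calibration A [calibration_config()] (or the fitted model from
#'   [calibrate_cohort_model()]).
#' @param seed Integer seed; the same seed always yields the same profile.
#' @param method Method whose marginals drive the latent utilities
#'   (default `"SG"`, the reference method of the chained design).
#' @param response_noise_sd,method_bias Passed to [respondent_profile()].
#' @return A [respondent_profile()].
#' @export
make_respondent <- function(calibration, seed, method = "SG",
                            response_noise_sd = 0,
                            method_bias = c(VAS = 0, SG = 0, TTO = 0)) {
  fit <- calibrate_cohort_model(calibration)
  method <- check_method(method)
  rank <- with_seed(seed, stats::runif(1))
  lat <- vapply(assessed_states(), function(st)
    latent_quantile(fit, st, method, rank), numeric(1))
  respondent_profile(lat, method_bias = method_bias,
                     response_noise_sd = response_noise_sd,
                     rng_seed = as.integer(seed))
}
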