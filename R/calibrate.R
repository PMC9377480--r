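# Moment-matching calibrators.
#
# The synthetic cohort needs latent distributions whose observable moments
# reproduce the published summary statistics.  Three families are used:
#
# * truncated normal on [low, high] - for fields like age where the window
#   is a hard inclusion criterion.  Note that the truncated-normal family
#   has a hard ceiling on the attainable SD at a given mean (the
#   exponential-tilt limit as sigma -> Inf); targets beyond it raise a
#   calibration error naming the binding bound.
# * censored (clamped) normal on [low, high] - for bounded rating scales
#   such as utilities, where real data pile up at the bounds (many
#   respondents rate transplantation at exactly 100).  The censored family
#   attains any SD below the two-point bound sqrt((m-low)(high-m)).
# * discrete grid models for the 10-item knowledge test, where the
#   observable is rounded to multiples of 10 and the post score is clamped
#   to [0, 100]; the calibrator matches the moments of the *realized*
#   (rounded, clamped) scores, not of the latent draw.
#
# All solvers use nested root-finding: for each sigma the location is
# matched to the target mean (the mean is strictly increasing in mu), and
# the resulting SD - strictly increasing in sigma - is matched in an outer
# root search.  Solutions are verified to 1e-6 in both moments.

MOMENT_TOL <- 1e-6

# truncated-normal moments by normalized quadrature on [low, high]; stable
# for arbitrarily extreme (mu, sigma), unlike the closed form whose
# normalizing constant underflows in the tails
trunc_normal_moments <- function(mu, sigma, low, high, n = 8193L) {
  x <- seq(low, high, length.out = n)
  lw <- stats::dnorm(x, mu, sigma, log = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  m <- sum(w * x)
  c(mean = m, sd = sqrt(sum(w * (x - m)^2)))
}

# censored-normal moments, closed form
censored_normal_moments <- function(mu, sigma, low, high) {
  a <- (low - mu) / sigma
  b <- (high - mu) / sigma
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  P <- Fb - Fa
  m <- low * Fa + high * (1 - Fb) + mu * P + sigma * (fa - fb)
  ex2 <- low^2 * Fa + high^2 * (1 - Fb) +
    mu^2 * P + 2 * mu * sigma * (fa - fb) +
    sigma^2 * (P + a * fa - b * fb)
  v <- max(ex2 - m^2, 0)
  c(mean = m, sd = sqrt(v))
}

# supremum of the truncated-normal SD at a fixed truncated mean: the
# sigma -> Inf limit of the family is the exponential tilt exp(c*x) on
# [low, high]
tilt_moments <- function(c_, low, high, n = 8193L) {
  x <- seq(low, high, length.out = n)
  lw <- c_ * (x - high)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m <- sum(w * x)
  c(mean = m, sd = sqrt(sum(w * (x - m)^2)))
}

max_truncated_sd <- function(target_mean, low, high) {
  f <- function(c_) tilt_moments(c_, low, high)[1] - target_mean
  span <- high - low
  cmax <- 500 / span
  if (f(-cmax) > 0 || f(cmax) < 0) return(0)
  c_ <- stats::uniroot(f, c(-cmax, cmax), tol = 1e-10)$root
  tilt_moments(c_, low, high)[2]
}

# nested two-moment solver; moments(mu, sigma) must return c(mean, sd) with
# mean increasing in mu and matched-mean sd increasing in sigma
fit_two_moments <- function(moments, target_mean, target_sd, low, high,
                            what = "distribution") {
  span <- high - low
  mu_for_mean <- function(sigma) {
    lo <- target_mean - span - 10 * sigma
    hi <- target_mean + span + 10 * sigma
    for (i in 1:30) {
      flo <- moments(lo, sigma)[1] - target_mean
      fhi <- moments(hi, sigma)[1] - target_mean
      if (is.finite(flo) && is.finite(fhi) && flo <= 0 && fhi >= 0) break
      lo <- lo - 10 * sigma - span
      hi <- hi + 10 * sigma + span
    }
    stats::uniroot(function(mu) moments(mu, sigma)[1] - target_mean,
                   c(lo, hi), tol = 1e-11)$root
  }
  sd_at <- function(sigma) moments(mu_for_mean(sigma), sigma)[2]

  sig_hi <- max(target_sd, span / 100)
  for (i in 1:60) {
    if (sd_at(sig_hi) >= target_sd) break
    sig_hi <- sig_hi * 2
    if (sig_hi > 1e7 * span)
      abort_calibration(sprintf(
        "target SD %.6g is not attainable for the %s at mean %.6g near the %s bound",
        target_sd, what, target_mean,
        if (target_mean >= (low + high) / 2) "upper" else "lower"))
  }
  sig_lo <- sig_hi / 2
  while (sd_at(sig_lo) > target_sd) sig_lo <- sig_lo / 2
  sigma <- stats::uniroot(function(s) sd_at(s) - target_sd,
                          c(sig_lo, sig_hi), tol = 1e-11)$root
  mu <- mu_for_mean(sigma)
  got <- moments(mu, sigma)
  if (abs(got[1] - target_mean) > MOMENT_TOL || abs(got[2] - target_sd) > MOMENT_TOL)
    abort_calibration(sprintf(
      "calibration of the %s did not converge to (%.6g, %.6g): reached (%.6g, %.6g)",
      what, target_mean, target_sd, got[1], got[2]))
  c(mu = mu, sigma = sigma)
}

#' Calibrate a truncated normal by moment matching
#'
#' Finds parameters `(mu, sigma)` of the underlying normal such that the
#' `[low, high]`-truncated normal has the requested mean and SD to within
#' 1e-6, by nested root-finding on the truncated-moment equations.  The
#' truncated family cannot reach arbitrarily large SDs: at a given mean the
#' SD is bounded by its exponential-tilt (`sigma -> Inf`) limit, and an
#' unattainable target raises a calibration error naming the binding bound.
#'
#' @param target_mean,target_sd Moments of the truncated distribution;
#'   `low < target_mean < high`, `target_sd > 0`.
#' @param low,high Truncation bounds.
#' @return Named numeric `c(mu, sigma)` of the underlying normal.
#' @export
#' @examples
#' calibrate_truncated_normal(50, 5, 0, 100)  # truncation mass negligible
calibrate_truncated_normal <- function(target_mean, target_sd,
                                       low = 0, high = 100) {
  check_number(low, "low"); check_number(high, "high")
  if (low >= high) abort_validation("`low` must be below `high`")
  check_number(target_mean, "target_mean")
  if (target_mean <= low || target_mean >= high)
    abort_validation("`target_mean` must lie strictly inside (low, high)")
  check_number(target_sd, "target_sd")
  if (target_sd <= 0) abort_validation("`target_sd` must be positive")
  sup_sd <- max_truncated_sd(target_mean, low, high)
  if (target_sd >= sup_sd * (1 - 1e-9))
    abort_calibration(sprintf(
      "target SD %.6g exceeds the maximum attainable truncated-normal SD %.4g at mean %.6g on [%g, %g] (binding %s bound)",
      target_sd, sup_sd, target_mean, low, high,
      if (target_mean >= (low + high) / 2) "upper" else "lower"))
  fit_two_moments(function(mu, sigma) trunc_normal_moments(mu, sigma, low, high),
                  target_mean, target_sd, low, high,
                  what = "truncated normal")
}

#' Calibrate a censored (clamped) normal by moment matching
#'
#' Finds `(mu, sigma)` such that a normal draw clamped to `[low, high]` has
#' the requested mean and SD to within 1e-6.  Unlike truncation, censoring
#' places point mass at the bounds and attains any SD below the two-point
#' limit `sqrt((mean - low)(high - mean))`; this is the model used for the
#' latent utility marginals, where real rating data pile up at 100.
#'
#' @inheritParams calibrate_truncated_normal
#' @return Named numeric `c(mu, sigma)` of the underlying normal.
#' @export
#' @examples
#' calibrate_censored_normal(82.5, 23.1, 0, 100)
calibrate_censored_normal <- function(target_mean, target_sd,
                                      low = 0, high = 100) {
  check_number(low, "low"); check_number(high, "high")
  if (low >= high) abort_validation("`low` must be below `high`")
  check_number(target_mean, "target_mean")
  if (target_mean <= low || target_mean >= high)
    abort_validation("`target_mean` must lie strictly inside (low, high)")
  check_number(target_sd, "target_sd")
  if (target_sd <= 0) abort_validation("`target_sd` must be positive")
  sup_sd <- sqrt((target_mean - low) * (high - target_mean))
  if (target_sd >= sup_sd * (1 - 1e-9))
    abort_calibration(sprintf(
      "target SD %.6g exceeds the two-point bound %.4g at mean %.6g on [%g, %g] (binding %s bound)",
      target_sd, sup_sd, target_mean, low, high,
      if (target_mean >= (low + high) / 2) "upper" else "lower"))
  fit_two_moments(function(mu, sigma) censored_normal_moments(mu, sigma, low, high),
                  target_mean, target_sd, low, high,
                  what = "censored normal")
}

# ---- 10-point knowledge-grid models ---------------------------------------

# probabilities of the rounded scores 0, 10, ..., 100 for a [0,100]
# truncated normal rounded to the nearest multiple of 10; computed from
# normalized log-density weights so it stays stable for extreme (mu, sigma)
knowledge_grid_probs <- function(mu, sigma, n = 8193L) {
  x <- seq(0, 100, length.out = n)
  lw <- stats::dnorm(x, mu, sigma, log = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  cell <- pmin(round_half_up(x / 10), 10)
  as.vector(tapply(w, factor(cell, levels = 0:10), sum))
}

knowledge_pre_moments <- function(mu, sigma) {
  v <- seq(0, 100, by = 10)
  p <- knowledge_grid_probs(mu, sigma)
  m <- sum(p * v)
  c(mean = m, sd = sqrt(sum(p * (v - m)^2)))
}

# realized change-score moments when post = round10(clamp(pre + d)),
# d ~ N(mu, sigma), pre on the 10-point grid with probabilities pre_probs
knowledge_change_moments_given_pre <- function(mu, sigma, pre_probs) {
  v <- seq(0, 100, by = 10)
  m1 <- 0; m2 <- 0
  cuts <- seq(5, 95, by = 10)
  for (j in seq_along(v)) {
    pk <- diff(c(0, stats::pnorm(cuts, v[j] + mu, sigma), 1))
    ch <- v - v[j]
    m1 <- m1 + pre_probs[j] * sum(pk * ch)
    m2 <- m2 + pre_probs[j] * sum(pk * ch^2)
  }
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# ---- whole-cohort calibration ---------------------------------------------

.calib_cache <- new.env(parent = emptyenv())

#' Fit the full cohort generative model to a calibration config
#'
#' Solves every moment-matching problem the generator needs: censored-normal
#' parameters for each (state, method) latent utility marginal,
#' truncated-normal parameters for age on its inclusion window, and the
#' knowledge-test models whose REALIZED (grid-rounded, ceiling-clamped)
#' pretest and change-score moments match the configured targets.  Results
#' are cached per configuration, so repeated cohort generation does not
#' re-solve.
#'
#' @param calibration A [calibration_config()] (a fitted model passes
#'   through unchanged).
#' @return An object of class `hua_cohort_model`.
#' @export
calibrate_cohort_model <- function(calibration) {
  if (inherits(calibration, "hua_cohort_model")) return(calibration)
  stopifnot(inherits(calibration, "calibration_config"))
  key <- paste(utils::capture.output(utils::str(unclass(calibration), digits.d = 15)),
               collapse = "\n")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)

  ut <- calibration$utility_targets
  upar <- vector("list", nrow(ut))
  for (i in seq_len(nrow(ut))) {
    upar[[i]] <- calibrate_censored_normal(ut$mean[i], ut$sd[i], 0, 100)
  }
  ut$mu <- vapply(upar, `[[`, numeric(1), "mu")
  ut$sigma <- vapply(upar, `[[`, numeric(1), "sigma")

  age <- calibrate_truncated_normal(calibration$age_mean, calibration$age_sd,
                                    calibration$age_range[1], calibration$age_range[2])
  pre <- fit_two_moments(knowledge_pre_moments,
                         calibration$knowledge_pre[["mean"]],
                         calibration$knowledge_pre[["sd"]],
                         0, 100, what = "rounded knowledge pretest")
  pre_probs <- knowledge_grid_probs(pre[["mu"]], pre[["sigma"]])
  chg <- fit_two_moments(function(mu, sigma)
    knowledge_change_moments_given_pre(mu, sigma, pre_probs),
    calibration$knowledge_change[["mean"]],
    calibration$knowledge_change[["sd"]],
    -100, 100, what = "realized knowledge change score")

  # lognormal vintage per race: mean from config, SD = mean * common CV
  vint <- lapply(names(calibration$vintage_mean), function(race) {
    m <- calibration$vintage_mean[[race]]
    s <- m * calibration$vintage_cv
    s2 <- log(1 + (s / m)^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  })
  names(vint) <- names(calibration$vintage_mean)

  fit <- structure(list(config = calibration, utility = ut, age = age,
                        knowledge_pre = pre, knowledge_pre_probs = pre_probs,
                        knowledge_change = chg, vintage = vint),
                   class = "hua_cohort_model")
  .calib_cache[[key]] <- fit
  fit
}

# latent utility quantile (on [0,1]) for a shared-rank draw
latent_quantile <- function(fit, state, method, rank) {
  ut <- fit$utility
  i <- which(ut$state == state & ut$method == method)
  if (length(i) != 1L)
    abort_validation(sprintf("no utility target for (%s, %s)", state, method))
  pmin(pmax(stats::qnorm(rank, ut$mu[i], ut$sigma[i]), 0), 100) / 100
}

#' @export
print.hua_cohort_model <- function(x, ...) {
  cat(sprintf("<hua_cohort_model> fitted for n=%d; %d utility marginals (censored normal)\n",
              x$config$n_patients, nrow(x$utility)))
  invisible(x)
}
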