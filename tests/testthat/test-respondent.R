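test_that("target indifference applies bias, clamping and chained rescaling", {
  r <- respondent_profile(c(HEMODIALYSIS = 0.755, TX_UNEXPOSED = 0.90,
                            TX_HCV_VIREMIC = 0.675))
  expect_equal(target_indifference(r, "SG", "HEMODIALYSIS"), 0.755)
  rb <- respondent_profile(c(HEMODIALYSIS = 0.72), method_bias = c(SG = 0.05))
  expect_equal(target_indifference(rb, "SG", "HEMODIALYSIS"), 0.77)
  expect_equal(target_indifference(rb, "TTO", "HEMODIALYSIS"), 0.72)
  rc <- respondent_profile(c(HEMODIALYSIS = 0.98), method_bias = c(SG = 0.1))
  expect_equal(target_indifference(rc, "SG", "HEMODIALYSIS"), 1)  # clamped
  # chained: latent HCV / latent TX
  expect_equal(target_indifference(r, "SG", "TX_HCV_VIREMIC", chained_anchors(90)),
               0.675 / 0.90)
  rz <- respondent_profile(c(TX_HCV_VIREMIC = 0.1, TX_UNEXPOSED = 0))
  expect_error(target_indifference(rz, "SG", "TX_HCV_VIREMIC", chained_anchors(50)),
               class = "hua_degenerate_error")
})

test_that("responses compare the offered fraction to the threshold", {
  r <- threshold_respondent(0.60)
  s <- start_session("SG", "HEMODIALYSIS")
  q95 <- current_question(s)
  expect_equal(respond(r, q95), "SURE")      # probe 0.95 above threshold
  q05 <- q95; q05$p_best <- 0.05; q05$fraction <- 0.05
  expect_equal(respond(r, q05), "GAMBLE")    # probe below threshold
  q60 <- q95; q60$p_best <- 0.60; q60$fraction <- 0.60
  expect_equal(respond(r, q60), "SURE")      # tie resolves to the sure option
})

test_that("noisy respondents replay identical choice sequences under one seed", {
  run_once <- function() {
    r <- respondent_profile(c(HEMODIALYSIS = 0.6), response_noise_sd = 0.02,
                            rng_seed = 42L)
    u <- run_auto_session("SG", "HEMODIALYSIS", respondent = r)
    vapply(attr(u, "session")$transcript, `[[`, character(1), "response")
  }
  expect_identical(run_once(), run_once())
})

test_that("respondents drawn from a calibration are seed-reproducible with in-range latents", {
  cfg <- default_calibration()
  r1 <- make_respondent(cfg, seed = 7)
  r2 <- make_respondent(cfg, seed = 7)
  expect_identical(r1$latent_utilities, r2$latent_utilities)
  expect_true(all(r1$latent_utilities >= 0 & r1$latent_utilities <= 1))
  expect_equal(r1$latent_utilities[["WELL"]], 1)
  expect_equal(r1$latent_utilities[["DEAD"]], 0)
})

test_that("sampled latents match the calibrated marginal's analytic moments", {
  # independent quadrature oracle for the censored-normal mean
  cfg <- default_calibration()
  fit <- calibrate_cohort_model(cfg)
  row <- fit$utility[fit$utility$state == "HEMODIALYSIS" & fit$utility$method == "SG", ]
  x <- seq(-400, 600, length.out = 200001)
  w <- dnorm(x, row$mu, row$sigma); w <- w / sum(w)
  oracle_mean <- sum(w * pmin(pmax(x, 0), 100))
  expect_equal(oracle_mean, 82.5, tolerance = 1e-4)

  lat <- vapply(1:1000, function(s)
    make_respondent(cfg, seed = s)$latent_utilities[["HEMODIALYSIS"]], numeric(1))
  se <- sd(lat) / sqrt(length(lat))
  expect_lt(abs(mean(lat) * 100 - oracle_mean), 3 * 100 * se)
})

test_that("a positive SG bias elevates elicited SG utilities above TTO and VAS", {
  cfg <- default_calibration()
  means <- sapply(c("SG", "TTO", "VAS"), function(m) {
    us <- vapply(1:40, function(s) {
      r <- make_respondent(cfg, seed = s, method_bias = c(SG = 0.05))
      run_auto_session(m, "HEMODIALYSIS", respondent = r,
                       horizon_years = 20)$normalized
    }, numeric(1))
    mean(us)
  })
  expect_gt(means[["SG"]], means[["TTO"]])
  expect_gt(means[["SG"]], means[["VAS"]])
})

test_that("degenerate point-mass calibrations yield constant latents", {
  ut <- default_utility_targets()
  ut$mean <- 80; ut$sd <- 1e-4
  cfg <- calibration_config(utility_targets = ut)
  r <- make_respondent(cfg, seed = 3)
  expect_equal(unname(r$latent_utilities[assessed_states()]),
               rep(0.8, 3), tolerance = 1e-4)
})
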