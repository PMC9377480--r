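test_that("the default calibration carries the published cohort structure", {
  cfg <- default_calibration()
  expect_equal(cfg$n_patients, 63L)
  expect_equal(cfg$race_counts[["African American"]], 44L)
  expect_equal(cfg$race_counts[["European American"]], 19L)
  expect_equal(sum(cfg$gender_counts), 63L)
  expect_equal(sum(cfg$education_counts), 63L)
  ut <- cfg$utility_targets
  expect_equal(ut$mean[ut$state == "HEMODIALYSIS" & ut$method == "SG"], 82.5)
  expect_equal(ut$mean[ut$state == "TX_UNEXPOSED" & ut$method == "SG"], 89.0)
  expect_equal(ut$mean[ut$state == "TX_HCV_VIREMIC" & ut$method == "SG"], 75.5)
  expect_equal(cfg$knowledge_change[["mean"]], 10.0)
  expect_equal(cfg$prior_transplant_count, 9L)
})

test_that("mismatched count configurations are rejected", {
  expect_error(calibration_config(race_counts = c("African American" = 40L,
                                                  "European American" = 19L)),
               class = "hua_validation_error")
  ut <- default_utility_targets(); ut$sd[1] <- -2
  expect_error(calibration_config(utility_targets = ut),
               class = "hua_validation_error")
})

test_that("cohorts are reproducible and match categorical counts exactly for any seed", {
  cfg <- default_calibration()
  c1 <- generate_cohort(cfg, seed = 1)
  c2 <- generate_cohort(cfg, seed = 1)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cfg, seed = 2)
  expect_false(identical(c1$patients, c3$patients))
  for (co in list(c1, c3)) {
    p <- co$patients
    expect_equal(sum(p$race == "African American"), 44)
    expect_equal(sum(p$sex == "male"), 33)
    expect_equal(sum(p$prior_transplant), 9)
    expect_equal(as.vector(table(p$education)[names(cfg$education_counts)]),
                 unname(cfg$education_counts))
    expect_true(all(p$age >= 21 & p$age <= 80))
    expect_true(all(p$knowledge_pre %% 10 == 0 & p$knowledge_post %% 10 == 0))
    expect_true(all(p$knowledge_post >= 0 & p$knowledge_post <= 100))
    expect_true(all(co$latents >= 0 & co$latents <= 1))
  }
})

test_that("calibration configs survive a JSON round trip", {
  cfg <- default_calibration()
  p <- withr::local_tempfile(fileext = ".json")
  write_calibration(cfg, p)
  back <- read_calibration(p)
  expect_equal(back, cfg, tolerance = 1e-12)
  expect_identical(generate_cohort(back, 5)$patients,
                   generate_cohort(cfg, 5)$patients)
})

test_that("a simulated study emits one row per patient, state and method", {
  cfg <- default_calibration()
  res <- simulate_study(cfg, seed = 11)
  expect_equal(nrow(res$results), 63 * 3 * 3)
  expect_equal(sort(unique(res$results$method)), sort(assessment_methods()))
  expect_true(all(res$results$normalized >= 0 & res$results$normalized <= 100))
  # chained rows never exceed the patient's transplant utility (same method)
  for (m in assessment_methods()) {
    sub <- res$results[res$results$method == m, ]
    hcv <- sub$normalized[sub$state == "TX_HCV_VIREMIC"]
    tx <- sub$normalized[sub$state == "TX_UNEXPOSED"]
    expect_true(all(hcv <= tx + 1e-9))
    expect_true(all(sub$chained[sub$state == "TX_HCV_VIREMIC"]))
  }
})

test_that("noise-free elicitation lands within resolution of every latent target", {
  cfg <- default_calibration()
  co <- generate_cohort(cfg, seed = 21)
  res <- simulate_study(cfg, seed = 21, cohort = co, methods = "SG")
  sub <- res$results
  for (st in c("HEMODIALYSIS", "TX_UNEXPOSED")) {
    got <- sub$normalized[sub$state == st] / 100
    want <- co$latents[, st, "SG"]
    expect_lte(max(abs(got - want)), titration_config()$resolution)
  }
  # chained rows: normalized/anchor recovers the chained target fraction
  hcv <- sub[sub$state == "TX_HCV_VIREMIC", ]
  tx <- sub[sub$state == "TX_UNEXPOSED", ]
  ok <- is.finite(hcv$raw_fraction)
  want_frac <- pmin(co$latents[, "TX_HCV_VIREMIC", "SG"][ok] /
                      co$latents[, "TX_UNEXPOSED", "SG"][ok], 1)
  expect_lte(max(abs(hcv$raw_fraction[ok] - want_frac)),
             titration_config()$resolution)
})

test_that("small replicate ensembles track the configured utility means", {
  cfg <- default_calibration()
  ms <- vapply(1:25, function(s) {
    r <- simulate_study(cfg, seed = 400 + s, methods = "SG")
    mean(r$results$normalized[r$results$state == "HEMODIALYSIS"])
  }, numeric(1))
  se <- sd(ms) / sqrt(length(ms))
  expect_lt(abs(mean(ms) - 82.5), 4 * se)
})
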