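test_that("change scores difference post minus pre with a cohort summary", {
  sc <- data.frame(patient_id = c("a", "b", "c"),
                   pre = c(79, 50, 100), post = c(89, 50, 90))
  out <- change_scores(sc)
  expect_equal(out$per_patient$change, c(10, 0, -10))
  expect_equal(unname(out$summary["mean"]), 0)
  expect_equal(unname(out$summary["median"]), 0)
  bad <- sc; bad$post[2] <- NA
  expect_error(change_scores(bad), "b", class = "hua_validation_error")
})

test_that("Cronbach alpha matches the hand-computed fixture and its bounds", {
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  expect_equal(cronbach_alpha(m), 0.75)
  # identical items with variance -> alpha 1
  v <- c(1, 0, 1, 1, 0)
  expect_equal(cronbach_alpha(cbind(v, v, v)), 1)
  expect_error(cronbach_alpha(matrix(1, 4, 3)), class = "hua_degenerate_error")
  expect_error(cronbach_alpha(matrix(1, 1, 3)), class = "hua_validation_error")
  # alpha never exceeds 1 on random graded matrices
  set.seed(1)
  for (i in 1:20) {
    mm <- matrix(sample(0:3, 40, TRUE), nrow = 8)
    a <- tryCatch(cronbach_alpha(mm), hua_degenerate_error = function(e) NA)
    if (!is.na(a)) expect_lte(a, 1)
  }
})

test_that("exact rank-sum p-values equal full enumeration (and wilcox.test where exact)", {
  out <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(out$p_value, 1 / 3)
  expect_identical(out$method, "exact_permutation")
  tied <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$p_value, 1)
  set.seed(42)
  for (i in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:8, na, TRUE); b <- sample(1:8, nb, TRUE)  # ties likely
    for (alt in c("two.sided", "greater", "less")) {
      got <- rank_sum_test(a, b, alternative = alt)
      expect_identical(got$method, "exact_permutation")
      expect_equal(got$p_value, brute_rank_sum_p(a, b, alt), info = alt)
    }
    if (!any(duplicated(c(a, b)))) {
      expect_equal(rank_sum_test(a, b)$p_value,
                   stats::wilcox.test(a, b, exact = TRUE)$p.value)
    }
  }
  expect_error(rank_sum_test(numeric(0), 1:3), class = "hua_validation_error")
})

test_that("exact signed-rank p-values equal sign enumeration (and wilcox.test where exact)", {
  expect_equal(signed_rank_test(c(1, 2, 3))$p_value, 0.25)
  expect_error(signed_rank_test(c(0, 0, 0)), class = "hua_degenerate_error")
  set.seed(43)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    d <- sample(-6:6, n, TRUE)
    if (all(d == 0)) d[1] <- 1
    for (alt in c("two.sided", "greater", "less")) {
      got <- signed_rank_test(d, alternative = alt)
      expect_identical(got$method, "exact_permutation")
      expect_equal(got$p_value, brute_signed_rank_p(d, alt), info = alt)
    }
    dd <- d[d != 0]
    if (!any(duplicated(abs(dd)))) {
      expect_equal(signed_rank_test(d)$p_value,
                   stats::wilcox.test(dd, exact = TRUE)$p.value)
    }
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(35, 0.5)
  got <- rank_sum_test(a, b)
  expect_identical(got$method, "normal_approximation")
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-8)
  d <- rnorm(40, 0.3)
  got2 <- signed_rank_test(d)
  expect_identical(got2$method, "normal_approximation")
  ref2 <- stats::wilcox.test(d, correct = TRUE, exact = FALSE)$p.value
  expect_equal(got2$p_value, ref2, tolerance = 1e-8)
})

test_that("ranking proportions count strict HCV-below-hemodialysis orderings", {
  pts <- make_patients(63)
  hcv <- c(rep(50, 47), rep(90, 16))   # exactly 47 of 63 below
  hd <- rep(80, 63)
  res <- make_results(pts, list(SG = list(HEMODIALYSIS = hd, TX_HCV_VIREMIC = hcv),
                                TTO = list(HEMODIALYSIS = hd,
                                           TX_HCV_VIREMIC = c(rep(50, 39), rep(90, 24)))))
  sg <- ranking_proportions(res, "SG")
  expect_equal(sg$count, 47); expect_equal(sg$percent, 75L)
  tto <- ranking_proportions(res, "TTO")
  expect_equal(tto$count, 39); expect_equal(tto$percent, 62L)
  all_lower <- make_results(pts, list(SG = list(HEMODIALYSIS = rep(80, 63),
                                                TX_HCV_VIREMIC = rep(10, 63))))
  expect_equal(ranking_proportions(all_lower, "SG")$percent, 100L)
  none <- make_results(pts, list(SG = list(HEMODIALYSIS = rep(10, 63),
                                           TX_HCV_VIREMIC = rep(80, 63))))
  expect_equal(ranking_proportions(none, "SG")$percent, 0L)
  # order and affine invariance
  perm <- res; perm$results <- perm$results[sample(nrow(perm$results)), ]
  expect_equal(ranking_proportions(perm, "SG")$count, 47)
  aff <- res; aff$results$normalized <- aff$results$normalized * 0.5 + 10
  expect_equal(ranking_proportions(aff, "SG")$count, 47)
})

test_that("the vintage correlation is Pearson r on the SG decrement", {
  pts <- make_patients(5, vintage_years = c(1, 2, 3, 4, 5))
  hd <- rep(80, 5)
  hcv <- hd + c(10, 5, 0, -5, -10)  # decrement exactly linear, negative slope
  res <- make_results(pts, list(SG = list(HEMODIALYSIS = hd, TX_HCV_VIREMIC = hcv)))
  expect_equal(vintage_correlation(res), -1)
  # hand-computed toy: r = cov / (sd sd)
  hcv2 <- hd + c(3, -1, 4, 0, -2)
  res2 <- make_results(pts, list(SG = list(HEMODIALYSIS = hd, TX_HCV_VIREMIC = hcv2)))
  d <- c(3, -1, 4, 0, -2); v <- 1:5
  hand <- sum((d - mean(d)) * (v - mean(v))) /
    sqrt(sum((d - mean(d))^2) * sum((v - mean(v))^2))
  expect_equal(vintage_correlation(res2), hand)
  flat <- make_patients(5, vintage_years = rep(2, 5))
  res3 <- make_results(flat, list(SG = list(HEMODIALYSIS = hd, TX_HCV_VIREMIC = hcv2)))
  expect_error(vintage_correlation(res3), class = "hua_degenerate_error")
})

test_that("the prior-transplant subgroup contrast returns per-level means and a comparison", {
  pts <- make_patients(12, prior_transplant = rep(c(TRUE, FALSE), c(3, 9)))
  hd <- rep(80, 12)
  hcv <- hd + c(rep(-15.6, 3), rep(-5.5, 9))
  res <- make_results(pts, list(SG = list(HEMODIALYSIS = hd, TX_HCV_VIREMIC = hcv)))
  out <- subgroup_decrement(res)
  expect_equal(unname(out$means["TRUE"]), -15.6)
  expect_equal(unname(out$means["FALSE"]), -5.5)
  expect_s3_class(out$comparison, "group_comparison")
  same <- make_results(pts, list(SG = list(HEMODIALYSIS = hd, TX_HCV_VIREMIC = hd - 5)))
  out2 <- subgroup_decrement(same)
  expect_equal(unname(diff(out2$means)), 0)
  expect_equal(out2$comparison$p_value, 1)
  nall <- make_patients(4, prior_transplant = rep(FALSE, 4))
  res3 <- make_results(nall, list(SG = list(HEMODIALYSIS = rep(1, 4),
                                            TX_HCV_VIREMIC = rep(0, 4))))
  expect_error(subgroup_decrement(res3), class = "hua_validation_error")
})

test_that("the power routine reproduces noncentral-t sample sizes", {
  expect_equal(sample_size_two_sample_t(delta = 1, sd = 1), 17L)
  expect_equal(sample_size_two_sample_t(delta = 12, sd = 16.3), 30L)
  expect_equal(sample_size_two_sample_t(delta = 1000, sd = 1), 2L)
  # oracle: smallest integer n at/above power.t.test's fractional solution
  for (case in list(c(5, 10), c(8, 10), c(12, 16.3), c(1, 2.5))) {
    want <- ceiling(stats::power.t.test(delta = case[1], sd = case[2],
                                        sig.level = 0.05, power = 0.8)$n - 1e-9)
    expect_equal(sample_size_two_sample_t(case[1], case[2]), want)
  }
  # monotonicity
  expect_gte(sample_size_two_sample_t(6, 16.3), sample_size_two_sample_t(12, 16.3))
  expect_gte(sample_size_two_sample_t(12, 20), sample_size_two_sample_t(12, 16.3))
  expect_gte(sample_size_two_sample_t(12, 16.3, power = 0.9),
             sample_size_two_sample_t(12, 16.3, power = 0.8))
  expect_error(sample_size_two_sample_t(0, 1), class = "hua_validation_error")
  expect_error(sample_size_two_sample_t(1, 1, alpha = 0.5, power = 0.2),
               class = "hua_validation_error")
})

test_that("stratified summaries emit the study-table layout and are order-invariant", {
  cfg <- default_calibration()
  res <- simulate_study(cfg, seed = 31, methods = "SG")
  tab <- stratified_summary(res, "race")
  expect_equal(nrow(tab), 3)  # one row per assessed state for the method run
  sg_rows <- tab[tab$method == "SG", ]
  expect_true(all(is.finite(sg_rows$overall_mean)))
  expect_true(all(sg_rows$p_value > 0 & sg_rows$p_value <= 1))
  # permuting patients leaves the table unchanged
  perm <- res
  idx <- sample(nrow(perm$results))
  perm$results <- perm$results[idx, ]
  expect_equal(stratified_summary(perm, "race"), stratified_summary(res, "race"))
  one_level <- res
  one_level$patients$race <- "African American"
  expect_error(stratified_summary(one_level, "race"), class = "hua_validation_error")
  kn <- knowledge_summary(res, "arm")
  expect_equal(kn$table$test, c("pretest", "posttest", "change_score"))
  expect_s3_class(kn$paired_change, "group_comparison")
})
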