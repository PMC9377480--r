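test_that("titration config validates its schedule", {
  cfg <- titration_config()
  expect_equal(cfg$ladder[1], 0.95)
  expect_equal(cfg$resolution, 0.005)
  expect_gte(cfg$max_questions, ceiling(log2(1 / cfg$resolution)) + length(cfg$ladder))
  expect_error(titration_config(ladder = c(0.95, 0.9, 0.8)),
               class = "hua_validation_error")  # not alternating
  expect_error(titration_config(ladder = c(1.0, 0.05)), class = "hua_validation_error")
  expect_error(titration_config(resolution = 0), class = "hua_validation_error")
  expect_error(titration_config(max_questions = 3), class = "hua_validation_error")
})

test_that("sessions start with the first admissible ladder probe and a unit bracket", {
  s <- start_session("SG", "HEMODIALYSIS")
  expect_equal(c(s$bracket_low, s$bracket_high), c(0, 1))
  expect_equal(s$phase, "LADDER")
  q <- current_question(s)
  expect_equal(q$type, "gamble")
  expect_equal(q$p_best, 0.95)
  expect_identical(q$gamble_worst, "DEAD")

  lt <- bundled_life_table()
  s2 <- start_session("TTO", "TX_UNEXPOSED",
                      patient_age = 59, patient_sex = "female", life_table = lt)
  expect_equal(s2$horizon_years, 25L)
  expect_equal(current_question(s2)$type, "trade")

  expect_error(start_session("SG", "TX_HCV_VIREMIC", chained_anchors()),
               class = "hua_sequencing_error")
  expect_error(start_session("TTO", "HEMODIALYSIS"), class = "hua_validation_error")
})

test_that("responses shrink the bracket monotonically and trigger bisection on reversal", {
  s <- start_session("SG", "HEMODIALYSIS")
  s <- record_response(s, "SURE")    # probe 0.95 -> high = 0.95
  expect_equal(s$bracket_high, 0.95)
  s <- record_response(s, "GAMBLE")  # probe 0.05 -> low = 0.05, reversal
  expect_equal(c(s$bracket_low, s$bracket_high), c(0.05, 0.95))
  expect_equal(s$phase, "BISECTION")

  # widths never increase while driving to completion
  widths <- s$bracket_high - s$bracket_low
  r <- threshold_respondent(0.60)
  while (s$phase != "DONE") {
    s <- record_response(s, respond(r, current_question(s)))
    widths <- c(widths, s$bracket_high - s$bracket_low)
  }
  expect_true(all(diff(widths) <= 0))
  expect_lte(s$bracket_high - s$bracket_low, s$config$resolution + 1e-12)
  expect_error(record_response(s, "SURE"), class = "hua_sequencing_error")
  expect_error(indifference_point(start_session("SG", "HEMODIALYSIS")),
               class = "hua_sequencing_error")
})

test_that("invalid choices raise protocol errors", {
  s <- start_session("SG", "HEMODIALYSIS")
  expect_error(record_response(s, "TRADE"), class = "hua_protocol_error")
  v <- start_session("VAS", "HEMODIALYSIS")
  expect_error(record_response(v, 150), class = "hua_protocol_error")
})

test_that("indifference point is the bracket midpoint (or placement/100 for VAS)", {
  v <- start_session("VAS", "HEMODIALYSIS")
  expect_equal(current_question(v)$type, "placement")
  v <- record_response(v, 57.9)
  expect_equal(v$phase, "DONE")
  expect_equal(indifference_point(v), 0.579)
})

test_that("noise-free threshold respondents are recovered over the full 0.005 grid (SG and TTO)", {
  cfg <- titration_config()
  lens <- integer(0)
  for (t in seq(0, 1, by = 0.025)) {   # coarse sweep here; exhaustive in acceptance
    r <- threshold_respondent(t)
    u_sg <- run_auto_session("SG", "HEMODIALYSIS", respondent = r, config = cfg)
    expect_lte(abs(u_sg$raw_fraction - t), cfg$resolution)
    u_tto <- run_auto_session("TTO", "HEMODIALYSIS", respondent = r,
                              config = cfg, horizon_years = 25)
    expect_lte(abs(u_tto$raw_fraction - t), cfg$resolution)
    lens <- c(lens, attr(u_sg, "session")$n_questions,
              attr(u_tto, "session")$n_questions)
  }
  expect_true(all(lens <= cfg$max_questions))
})

test_that("a respondent who always gambles is pinned to the top of the scale", {
  always <- respondent_profile(c(HEMODIALYSIS = 1))
  u <- run_auto_session("SG", "HEMODIALYSIS", respondent = always)
  res <- titration_config()$resolution
  expect_gte(u$normalized, 100 * (1 - res))
  expect_lte(u$normalized, 100)
})

test_that("conversions reproduce the anchors at the extremes and hand-computed interiors", {
  d <- default_anchors()
  expect_equal(sg_utility_from_indifference(0.755, d), 75.5)
  expect_equal(sg_utility_from_indifference(1, chained_anchors(89)), 89)
  expect_equal(sg_utility_from_indifference(0.5, anchor_pair("WELL", "DEAD", 89, 0)), 44.5)
  expect_equal(tto_utility_from_indifference(25, 25, d), 100)
  expect_equal(tto_utility_from_indifference(0, 25, d), 0)
  expect_equal(tto_utility_from_indifference(6.6, 10, d), 66.0)
  expect_equal(vas_utility_from_placement(100, d), 100)
  expect_equal(vas_utility_from_placement(0, d), 0)
  expect_equal(vas_utility_from_placement(50, anchor_pair("WELL", "DEAD", 88.2, 0)), 44.1)
  expect_error(tto_utility_from_indifference(26, 25, d), class = "hua_validation_error")
  expect_error(sg_utility_from_indifference(1.5, d), class = "hua_validation_error")
  expect_error(vas_utility_from_placement(101, d), class = "hua_validation_error")
})

test_that("chained auto-sessions normalize through the anchor and never exceed it", {
  r <- respondent_profile(c(TX_HCV_VIREMIC = 0.72, TX_UNEXPOSED = 0.90))
  u <- run_auto_session("SG", "TX_HCV_VIREMIC", chained_anchors(90), respondent = r)
  expect_true(u$chained)
  expect_equal(u$normalized, 72.0, tolerance = 0.5 / 72)
  expect_lte(u$normalized, 90)
  # also across a sweep of anchors
  for (anchor in c(40, 65, 95)) {
    u2 <- run_auto_session("SG", "TX_HCV_VIREMIC", chained_anchors(anchor),
                           respondent = r)
    expect_lte(u2$normalized, anchor + 1e-9)
  }
})

test_that("transcripts serialize to JSON lines with bracket provenance", {
  r <- threshold_respondent(0.35)
  u <- run_auto_session("SG", "HEMODIALYSIS", respondent = r)
  s <- attr(u, "session")
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_transcript(s, p)
  lines <- readLines(p)
  expect_equal(length(lines), s$n_questions)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("ts", "method", "state", "phase", "question", "response",
                    "bracket_low", "bracket_high") %in% names(rec)))
  expect_equal(rec$method, "SG")
})
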