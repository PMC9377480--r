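# Randomization, exemplar-clip selection, cohort file formats and the
# command-line interface.

#' Permuted-block arm randomization
#'
#' Seeded assignment of patients to the race-matched (`MATCHED`) or
#' race-mismatched (`MISMATCHED`) video arm.  Within each complete block of
#' `block_size` patients the arms are balanced 1:1; an incomplete final
#' block takes the leading entries of one more shuffled block, so arm sizes
#' differ by at most `block_size / 2`.  `block_size = 0` requests simple
#' (unblocked) randomization.
#'
#' @param patient_ids Nonempty character vector of ids.
#' @param seed Integer seed; assignments are reproducible per seed.
#' @param block_size Even block size (default 4), or 0 for simple
#'   randomization.
#' @return Data frame with columns `patient_id`, `arm`, `block`, `seed`.
#' @export
randomize_arm <- function(patient_ids, seed, block_size = 4L) {
  if (!length(patient_ids)) abort_validation("`patient_ids` must be nonempty")
  if (anyDuplicated(patient_ids)) abort_validation("`patient_ids` contains duplicates")
  check_number(block_size, "block_size", 0, Inf)
  arms <- c("MATCHED", "MISMATCHED")
  n <- length(patient_ids)
  if (block_size == 0) {
    arm <- with_seed(seed, sample(arms, n, replace = TRUE))
    block <- rep(NA_integer_, n)
  } else {
    if (block_size %% 2 != 0)
      abort_config("`block_size` must be even for 1:1 permuted blocks")
    b <- as.integer(block_size)
    n_blocks <- ceiling(n / b)
    arm <- with_seed(seed, {
      unlist(lapply(seq_len(n_blocks), function(i)
        sample(rep(arms, b / 2))))[seq_len(n)]
    })
    block <- rep(seq_len(n_blocks), each = b)[seq_len(n)]
  }
  data.frame(patient_id = as.character(patient_ids), arm = arm,
             block = block, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Exemplar video-clip inventory and selection
#'
#' The study's exemplar inventory holds one clip per combination of the 3
#' assessed health states, 2 races and 2 genders (12 clips).  The matched
#' arm selects the clip matching the patient's race and gender; the
#' mismatched arm flips race while preserving gender.
#'
#' @return `exemplar_inventory()` returns the 12-row clip data frame.
#' @export
exemplar_inventory <- function() {
  races <- c("African American", "European American")
  inv <- expand.grid(state = assessed_states(), race = races,
                     gender = c("female", "male"),
                     stringsAsFactors = FALSE)
  inv$clip_id <- sprintf("%s__%s__%s", inv$state,
                         gsub(" ", "_", inv$race), inv$gender)
  inv
}

#' @rdname exemplar_inventory
#' @param race,gender Patient demographics (must be inventory categories).
#' @param state Assessed health state.
#' @param arm `"MATCHED"` or `"MISMATCHED"`.
#' @return `select_exemplar()` returns the selected clip (one-row data
#'   frame).
#' @export
select_exemplar <- function(race, gender, state, arm) {
  inv <- exemplar_inventory()
  if (!is.character(race) || length(race) != 1L || !(race %in% unique(inv$race)))
    abort_validation(sprintf("unknown race category '%s'", paste(race, collapse = ",")))
  if (!is.character(gender) || length(gender) != 1L || !(gender %in% c("female", "male")))
    abort_validation(sprintf("unknown gender category '%s'", paste(gender, collapse = ",")))
  state <- check_state(state, allow_anchor = FALSE)
  if (!is.character(arm) || length(arm) != 1L || !(arm %in% c("MATCHED", "MISMATCHED")))
    abort_validation(sprintf("unknown arm '%s'", paste(arm, collapse = ",")))
  clip_race <- if (arm == "MATCHED") race else setdiff(unique(inv$race), race)
  out <- inv[inv$state == state & inv$race == clip_race & inv$gender == gender, ]
  rownames(out) <- NULL
  out
}

# ---- cohort results CSV ----------------------------------------------------

utility_col <- function(method, state) sprintf("u_%s_%s", tolower(method), tolower(state))
raw_col <- function(method) sprintf("raw_%s_tx_hcv_viremic", tolower(method))

PATIENT_COLS <- c("patient_id", "age", "sex", "race", "education",
                  "vintage_years", "prior_transplant", "arm",
                  "knowledge_pre", "knowledge_post")

#' Write and read the cohort results table as CSV
#'
#' One row per patient: demographics and knowledge scores, one column per
#' (state, method) normalized utility (stored to 0.1), and one raw chained
#' fraction per method (stored to 4 decimals).  The round trip is lossless
#' at that declared precision.
#'
#' @param results A [simulate_study()] result.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `hua_results`-compatible object.
#' @export
write_cohort_csv <- function(results, path) {
  pts <- results$patients[PATIENT_COLS]
  res <- results$results
  wide <- pts
  for (m in unique(res$method)) for (st in assessed_states()) {
    sub <- res[res$method == m & res$state == st, c("patient_id", "normalized")]
    wide[[utility_col(m, st)]] <- round(
      sub$normalized[match(pts$patient_id, sub$patient_id)], 1)
  }
  for (m in unique(res$method)) {
    sub <- res[res$method == m & res$state == "TX_HCV_VIREMIC", c("patient_id", "raw_fraction")]
    wide[[raw_col(m)]] <- round(
      sub$raw_fraction[match(pts$patient_id, sub$patient_id)], 4)
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("cohort file not found: %s", path))
  if (file.size(path) == 0) abort_format("cohort file is empty")
  wide <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) abort_format(sprintf("cannot parse cohort CSV: %s",
                                                            conditionMessage(e))))
  if (nrow(wide) == 0L) abort_format("cohort file has no rows")
  missing <- setdiff(PATIENT_COLS, names(wide))
  if (length(missing))
    abort_format(sprintf("cohort CSV is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  ucols <- grep("^u_(vas|sg|tto)_", names(wide), value = TRUE)
  if (!length(ucols)) abort_format("cohort CSV has no utility columns (u_<method>_<state>)")
  known <- c(PATIENT_COLS,
             as.vector(outer(c("VAS", "SG", "TTO"), assessed_states(), utility_col)),
             vapply(c("VAS", "SG", "TTO"), raw_col, character(1)))
  unknown <- setdiff(names(wide), known)
  if (length(unknown))
    abort_format(sprintf("cohort CSV has unknown column(s): %s",
                         paste(unknown, collapse = ", ")))
  methods <- intersect(c("VAS", "SG", "TTO"), toupper(sub("^u_([a-z]+)_.*", "\\1", ucols)))
  rows <- list(); k <- 0L
  for (m in methods) {
    for (st in assessed_states()) {
      col <- utility_col(m, st)
      if (!col %in% names(wide))
        abort_format(sprintf("cohort CSV is missing column %s", col))
      u <- wide[[col]]
      if (!is.numeric(u) || any(is.finite(u) & (u < 0 | u > 100)))
        abort_format(sprintf("column %s has utilities outside [0, 100]", col))
      chained <- st == "TX_HCV_VIREMIC"
      raw <- if (chained) {
        rc <- raw_col(m)
        if (!rc %in% names(wide))
          abort_format(sprintf("cohort CSV is missing chained raw column %s", rc))
        wide[[rc]]
      } else u / 100
      k <- k + 1L
      rows[[k]] <- data.frame(patient_id = wide$patient_id, state = st,
                              method = m, raw_fraction = raw, normalized = u,
                              chained = chained, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, patients = wide[PATIENT_COLS],
                 cohort = NULL),
            class = "hua_results")
}

# proportional count rescaling preserving the total (largest remainder)
rescale_counts <- function(counts, n_new) {
  raw <- counts * n_new / sum(counts)
  base <- floor(raw)
  short <- n_new - sum(base)
  if (short > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(short)]] <- base[order_idx[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

rescale_calibration <- function(config, n_new) {
  calibration_config(
    n_patients = n_new,
    race_counts = rescale_counts(config$race_counts, n_new),
    gender_counts = rescale_counts(config$gender_counts, n_new),
    education_counts = rescale_counts(config$education_counts, n_new),
    age_range = config$age_range, age_mean = config$age_mean,
    age_sd = config$age_sd,
    vintage_mean = unlist(config$vintage_mean), vintage_cv = config$vintage_cv,
    knowledge_pre = config$knowledge_pre,
    knowledge_change = config$knowledge_change,
    utility_targets = config$utility_targets,
    prior_transplant_count = max(1L, as.integer(round(
      config$prior_transplant_count * n_new / config$n_patients))),
    response_noise_sd = config$response_noise_sd,
    arm_effect = config$arm_effect, block_size = config$block_size)
}

# ---- command-line interface ------------------------------------------------

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      abort_validation(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (key == "verbose") { out$verbose <- TRUE; i <- i + 1L; next }
    if (i == length(args))
      abort_validation(sprintf("flag --%s needs a value", key))
    out[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

cli_log <- function(flags, ...) {
  if (isTRUE(flags$verbose)) message(...)
}

cli_simulate <- function(flags) {
  config <- if (!is.null(flags$config)) read_calibration(flags$config)
            else default_calibration()
  if (!is.null(flags$n)) {
    n <- as.integer(flags$n)
    if (is.na(n) || n < 2) abort_validation("--n must be an integer >= 2")
    if (n != config$n_patients) config <- rescale_calibration(config, n)
  }
  seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
  out <- if (is.null(flags$out)) "cohort.csv" else flags$out
  cli_log(flags, "simulating cohort of ", config$n_patients, " (seed ", seed, ")")
  results <- simulate_study(config, seed = seed)
  write_cohort_csv(results, out)
  cli_log(flags, "wrote ", out)
  0L
}

cli_analyze <- function(flags) {
  if (is.null(flags$`in`) && is.null(flags$in_)) abort_validation("--in is required")
  infile <- if (!is.null(flags$`in`)) flags$`in` else flags$in_
  outdir <- if (is.null(flags$tables)) "tables" else flags$tables
  results <- read_cohort_csv(infile)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  k_arm <- knowledge_summary(results, "arm")
  k_race <- knowledge_summary(results, "race")
  utils::write.csv(k_arm$table, file.path(outdir, "knowledge_by_arm.csv"),
                   row.names = FALSE)
  utils::write.csv(k_race$table, file.path(outdir, "knowledge_by_race.csv"),
                   row.names = FALSE)
  utils::write.csv(stratified_summary(results, "arm"),
                   file.path(outdir, "utilities_by_arm.csv"), row.names = FALSE)
  utils::write.csv(stratified_summary(results, "race"),
                   file.path(outdir, "utilities_by_race.csv"), row.names = FALSE)
  sg <- results$results[results$results$method == "SG" &
                          results$results$state == "TX_HCV_VIREMIC", ]
  derived <- list(
    paired_knowledge_change_p = knowledge_summary(results, "arm")$paired_change$p_value,
    implied_death_risk_pct = implied_death_risk(mean(sg$normalized)),
    ranking = lapply(stats::setNames(nm = unique(results$results$method)),
                     function(m) ranking_proportions(results, m)[c("count", "n", "percent")]),
    vintage_correlation = vintage_correlation(results),
    subgroup_decrement = as.list(subgroup_decrement(results)$means))
  jsonlite::write_json(derived, file.path(outdir, "derived.json"),
                       auto_unbox = TRUE, digits = NA)
  cli_log(flags, "wrote tables to ", outdir)
  0L
}

cli_power <- function(flags) {
  for (f in c("delta", "sd")) if (is.null(flags[[f]]))
    abort_validation(sprintf("--%s is required", f))
  n <- sample_size_two_sample_t(
    delta = as.numeric(flags$delta), sd = as.numeric(flags$sd),
    alpha = if (is.null(flags$alpha)) 0.05 else as.numeric(flags$alpha),
    power = if (is.null(flags$power)) 0.80 else as.numeric(flags$power))
  cat(n, "\n", sep = "")
  0L
}

cli_elicit <- function(flags, input) {
  method <- if (is.null(flags$method)) abort_validation("--method is required")
            else check_method(toupper(flags$method))
  state <- if (is.null(flags$state)) abort_validation("--state is required")
           else check_state(toupper(flags$state), allow_anchor = FALSE)
  anchors <- if (is.null(flags$chained_anchor)) default_anchors()
             else chained_anchors(as.numeric(flags$chained_anchor))
  lt <- if (!is.null(flags$life_table)) read_life_table(flags$life_table)
        else read_life_table(system.file("extdata", "life_table_synthetic.csv",
                                         package = "huassess"))
  session <- start_session(method, state, anchors,
                           patient_age = if (is.null(flags$age)) NULL else as.numeric(flags$age),
                           patient_sex = flags$sex, life_table = lt)
  con <- input
  while (session$phase != "DONE") {
    q <- session$pending
    prompt <- switch(q$type,
      gamble = sprintf("Gamble: %.1f%% chance of %s, otherwise death - or stay with %s for sure? [SURE/GAMBLE] ",
                       100 * q$p_best, q$gamble_best, q$sure_state),
      trade = sprintf("Trade %d years in %s for %.1f years in %s? [STAY/TRADE] ",
                      q$full_horizon_years, q$target_state, q$offered_years, q$anchors$best),
      placement = sprintf("Place %s on the 0-100 thermometer: ", q$target_state))
    cat(prompt)
    line <- readLines(con, n = 1L)
    if (!length(line)) abort_protocol("input ended before the session finished")
    ans <- trimws(line)
    if (q$type == "placement") ans <- as.numeric(ans) else ans <- toupper(ans)
    session <- record_response(session, ans)
  }
  p <- indifference_point(session)
  value <- utility_value(state, method, p, anchors)
  cat(sprintf("indifference %.4f -> utility %.1f on 0-100\n", p, value$normalized))
  if (!is.null(flags$out)) write_transcript(session, flags$out)
  0L
}

#' Command-line interface
#'
#' Subcommands: `simulate` (`--config`, `--n`, `--seed`, `--out`),
#' `analyze` (`--in`, `--tables`), `power` (`--delta`, `--sd`, `--alpha`,
#' `--power`), and `elicit` (interactive plain-text session: `--method`,
#' `--state`, `--age`, `--sex`, `--life-table`, `--chained-anchor`,
#' `--out`).  `--verbose` logs progress to stderr.  A thin Rscript wrapper
#' is installed under `inst/scripts/hua`.
#'
#' @param argv Character vector of command-line arguments.
#' @param input Connection answers are read from in `elicit` mode
#'   (defaults to stdin).
#' @return Integer exit status (0 on success), invisibly.
#' @export
hua_cli <- function(argv = commandArgs(trailingOnly = TRUE), input = "stdin") {
  status <- tryCatch({
    if (!length(argv)) {
      message("usage: hua <simulate|analyze|power|elicit> [--flags]")
      return(invisible(2L))
    }
    cmd <- argv[[1]]
    flags <- parse_flags(argv[-1])
    switch(cmd,
      simulate = cli_simulate(flags),
      analyze = cli_analyze(flags),
      power = cli_power(flags),
      elicit = cli_elicit(flags, if (identical(input, "stdin")) file("stdin") else input),
      abort_validation(sprintf("unknown subcommand '%s'", cmd)))
  }, hua_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
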