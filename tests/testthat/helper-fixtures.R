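# shared fixtures built in code

bundled_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_synthetic.csv",
                              package = "huassess"))
}

# deterministic threshold respondent with a single latent utility
threshold_respondent <- function(threshold, state = "HEMODIALYSIS", ...) {
  lat <- stats::setNames(rep(threshold, 3), assessed_states())
  lat[state] <- threshold
  respondent_profile(lat, ...)
}

# assemble a hua_results object from per-patient utility vectors
make_results <- function(patients, utilities) {
  rows <- list()
  for (m in names(utilities)) {
    for (st in names(utilities[[m]])) {
      u <- utilities[[m]][[st]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patients$patient_id, state = st, method = m,
        raw_fraction = u / 100, normalized = u,
        chained = st == "TX_HCV_VIREMIC", stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, rows), patients = patients,
                 cohort = NULL),
            class = "hua_results")
}

make_patients <- function(n, ...) {
  extra <- list(...)
  base <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = rep(60L, n), sex = rep(c("female", "male"), length.out = n),
    race = rep(c("African American", "European American"), length.out = n),
    education = rep("high school or GED", n),
    vintage_years = seq_len(n) / 2,
    prior_transplant = rep(FALSE, n),
    arm = rep(c("MATCHED", "MISMATCHED"), length.out = n),
    knowledge_pre = rep(70, n), knowledge_post = rep(80, n),
    stringsAsFactors = FALSE)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}
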