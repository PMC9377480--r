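# Study statistics: knowledge change scores and internal consistency,
# rank-based two-group and paired comparisons (exact by enumeration on
# small samples, tie-corrected normal approximation otherwise),
# within-patient ranking proportions, the vintage correlation, the
# prior-transplant subgroup contrast, the design-stage power computation,
# and the stratified summary tables.

# caps under which exact enumeration is used (beyond them the
# approximation is preferred; full enumeration stays well under a second
# at these sizes)
RANK_SUM_EXACT_CAP <- 12L
SIGNED_RANK_EXACT_CAP <- 15L

#' Pre/post knowledge change scores
#'
#' @param scores Data frame with columns `patient_id`, `pre`, `post`
#'   (scores on 0-100).
#' @return List with `per_patient` (adds `change = post - pre`) and
#'   `summary` (mean, median, SD of the change).
#' @export
change_scores <- function(scores) {
  scores <- as.data.frame(scores)
  need <- c("patient_id", "pre", "post")
  if (!all(need %in% names(scores)))
    abort_validation("`scores` must have columns patient_id, pre, post")
  bad <- scores$patient_id[!is.finite(scores$pre) | !is.finite(scores$post)]
  if (length(bad))
    abort_validation(sprintf("missing pre or post score for patient(s): %s",
                             paste(bad, collapse = ", ")))
  if (any(scores$pre < 0 | scores$pre > 100 | scores$post < 0 | scores$post > 100))
    abort_validation("knowledge scores must lie in [0, 100]")
  scores$change <- scores$post - scores$pre
  list(per_patient = scores,
       summary = c(mean = mean(scores$change),
                   median = stats::median(scores$change),
                   sd = stats::sd(scores$change)))
}

#' Cronbach alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of total
#' scores)` with sample (n-1) variances, for a patients x items matrix of
#' 0/1 or graded item scores.
#'
#' @param item_matrix Numeric matrix, one row per patient, one column per
#'   item; at least 2 rows and 2 columns.
#' @return Alpha (a number `<= 1`).
#' @export
#' @examples
#' m <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
#' cronbach_alpha(m)  # 0.75
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L)
    abort_validation("`item_matrix` must be a numeric matrix with >= 2 patients and >= 2 items")
  if (anyNA(m)) abort_validation("`item_matrix` contains missing values")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0)
    abort_degenerate("total-score variance is zero; alpha is undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

new_group_comparison <- function(statistic, p_value, method, n, note = "") {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> statistic = %g, p = %.4g (%s; n = %s)%s\n",
              x$statistic, x$p_value, x$method,
              paste(x$n, collapse = "/"),
              if (nzchar(x$note)) paste0("  [", x$note, "]") else ""))
  invisible(x)
}

resolve_alternative <- function(sides, alternative) {
  if (!is.null(alternative)) {
    match.arg(alternative, c("two.sided", "greater", "less"))
  } else {
    sides <- as.character(sides)
    if (!sides %in% c("one", "two", "1", "2"))
      abort_validation("`sides` must be 'one' or 'two'")
    if (sides %in% c("two", "2")) "two.sided" else "greater"
  }
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties.  The p-value is exact (full
#' enumeration of group assignments) when the total sample size is at most
#' 12, otherwise a tie-corrected normal approximation with continuity
#' correction is used.  Two-sided exact p-values count assignments whose
#' rank sum deviates from its null mean by at least the observed amount.
#'
#' @param group_a,group_b Numeric vectors, both nonempty.
#' @param sides `"two"` (default) or `"one"` (one-sided: `group_a` tends
#'   larger).
#' @param alternative Optional explicit alternative (`"two.sided"`,
#'   `"greater"`, `"less"`); overrides `sides`.
#' @return A `group_comparison` with the rank-sum statistic of `group_a`.
#' @export
rank_sum_test <- function(group_a, group_b, sides = "two", alternative = NULL) {
  if (!length(group_a) || !length(group_b))
    abort_validation("both groups must be nonempty")
  if (anyNA(group_a) || anyNA(group_b))
    abort_validation("groups must not contain missing values")
  alt <- resolve_alternative(sides, alternative)
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))
  w_obs <- sum(r[seq_len(na)])
  e_w <- na * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (n <= RANK_SUM_EXACT_CAP) {
    combs <- utils::combn(n, na)
    w_all <- colSums(matrix(r[combs], nrow = na))
    p <- switch(alt,
      two.sided = mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9),
      greater   = mean(w_all >= w_obs - 1e-9),
      less      = mean(w_all <= w_obs + 1e-9))
    meth <- "exact_permutation"
  } else {
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v_w <- na * nb / 12 * ((n + 1) - tie_term)
    if (v_w <= 0) {
      p <- 1
    } else {
      z_num <- w_obs - e_w
      cc <- 0.5
      p <- switch(alt,
        two.sided = 2 * stats::pnorm(-(abs(z_num) - cc) / sqrt(v_w)),
        greater   = stats::pnorm(-(z_num - cc) / sqrt(v_w)),
        less      = stats::pnorm((z_num + cc) / sqrt(v_w)))
      p <- min(1, max(p, .Machine$double.xmin))
    }
    meth <- "normal_approximation"
  }
  new_group_comparison(w_obs, p, meth, c(na, nb),
                       note = if (has_ties) "midranks used for ties" else "")
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped, tied magnitudes get midranks.  Exact by
#' enumeration of all sign patterns when at most 15 nonzero differences
#' remain, otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param differences Numeric vector of paired differences with at least
#'   one nonzero value.
#' @inheritParams rank_sum_test
#' @return A `group_comparison` with the positive-rank sum statistic.
#' @export
signed_rank_test <- function(differences, sides = "two", alternative = NULL) {
  if (!length(differences) || anyNA(differences))
    abort_validation("`differences` must be nonempty without missing values")
  alt <- resolve_alternative(sides, alternative)
  d <- differences[differences != 0]
  if (!length(d))
    abort_degenerate("all differences are zero; the signed-rank test is degenerate")
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  e_v <- n * (n + 1) / 4
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (n <= SIGNED_RANK_EXACT_CAP) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- switch(alt,
      two.sided = mean(abs(v_all - e_v) >= abs(v_obs - e_v) - 1e-9),
      greater   = mean(v_all >= v_obs - 1e-9),
      less      = mean(v_all <= v_obs + 1e-9))
    meth <- "exact_permutation"
  } else {
    v_v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_num <- v_obs - e_v
    cc <- 0.5
    p <- switch(alt,
      two.sided = 2 * stats::pnorm(-(abs(z_num) - cc) / sqrt(v_v)),
      greater   = stats::pnorm(-(z_num - cc) / sqrt(v_v)),
      less      = stats::pnorm((z_num + cc) / sqrt(v_v)))
    p <- min(1, max(p, .Machine$double.xmin))
    meth <- "normal_approximation"
  }
  new_group_comparison(v_obs, p, meth, n,
                       note = paste(c(if (length(differences) > n) "zeros dropped",
                                      if (has_ties) "midranks used for ties"),
                                    collapse = "; "))
}

results_wide <- function(results, method, states = c("TX_HCV_VIREMIC", "HEMODIALYSIS")) {
  res <- results$results
  sub <- res[res$method == method & res$state %in% states, ]
  out <- stats::reshape(sub[c("patient_id", "state", "normalized")],
                        idvar = "patient_id", timevar = "state",
                        direction = "wide")
  names(out) <- sub("^normalized\\.", "", names(out))
  out
}

#' Within-patient ranking proportion
#'
#' Count (and integer percent) of patients who rate transplantation with an
#' HCV-viremic kidney strictly lower than hemodialysis under the given
#' method.  Patients missing either utility are excluded and reported.
#'
#' @param results A [simulate_study()] result (or compatible object with a
#'   `$results` data frame).
#' @param method Assessment method.
#' @return List with `count`, `n`, `percent` (nearest integer), and
#'   `excluded`.
#' @export
ranking_proportions <- function(results, method) {
  method <- check_method(method)
  wide <- results_wide(results, method)
  ok <- is.finite(wide$TX_HCV_VIREMIC) & is.finite(wide$HEMODIALYSIS)
  excluded <- sum(!ok)
  wide <- wide[ok, ]
  count <- sum(wide$TX_HCV_VIREMIC < wide$HEMODIALYSIS)
  n <- nrow(wide)
  if (n == 0L) abort_validation("no patients with both utilities present")
  list(count = count, n = n,
       percent = as.integer(round_half_up(100 * count / n)),
       excluded = excluded)
}

#' Correlation of the HCV-vs-hemodialysis SG decrement with vintage
#'
#' Pearson correlation between each patient's `U_SG(HCV-viremic
#' transplant) - U_SG(hemodialysis)` and their dialysis vintage in years.
#'
#' @param results A [simulate_study()] result.
#' @return Pearson r.
#' @export
vintage_correlation <- function(results) {
  wide <- results_wide(results, "SG")
  merged <- merge(wide, results$patients[c("patient_id", "vintage_years")],
                  by = "patient_id")
  diffs <- merged$TX_HCV_VIREMIC - merged$HEMODIALYSIS
  if (nrow(merged) < 3L)
    abort_validation("need at least 3 patients for a correlation")
  if (stats::sd(diffs) == 0 || stats::sd(merged$vintage_years) == 0)
    abort_degenerate("correlation undefined: an input is constant")
  stats::cor(diffs, merged$vintage_years)
}

#' Prior-transplant subgroup contrast of the SG decrement
#'
#' Mean `U_SG(HCV-viremic) - U_SG(hemodialysis)` per prior-transplant
#' status, plus the rank-sum comparison between the two subgroups.
#'
#' @param results A [simulate_study()] result.
#' @return List with `means` (named by `TRUE`/`FALSE` prior-transplant
#'   status) and `comparison` (a `group_comparison`).
#' @export
subgroup_decrement <- function(results) {
  wide <- results_wide(results, "SG")
  merged <- merge(wide, results$patients[c("patient_id", "prior_transplant")],
                  by = "patient_id")
  diffs <- merged$TX_HCV_VIREMIC - merged$HEMODIALYSIS
  flag <- merged$prior_transplant
  if (!any(flag) || all(flag))
    abort_validation("both prior-transplant subgroups must be nonempty")
  means <- c("TRUE" = mean(diffs[flag]), "FALSE" = mean(diffs[!flag]))
  list(means = means,
       comparison = rank_sum_test(diffs[flag], diffs[!flag]))
}

#' Per-arm sample size for a two-sample t test
#'
#' Smallest integer n per arm at which the two-sample t test (equal
#' allocation, common SD) attains the target power, from the noncentral-t
#' power function evaluated at increasing n.
#'
#' @param delta Smallest difference in means to detect (> 0).
#' @param sd Common standard deviation (> 0).
#' @param alpha Type-I error rate (two-sided by default).
#' @param power Target power in (0, 1).
#' @param sides 1 or 2.
#' @return Integer n per arm (>= 2).
#' @export
#' @examples
#' sample_size_two_sample_t(delta = 1, sd = 1)           # 17 per arm
#' sample_size_two_sample_t(delta = 12, sd = 16.3)       # 30 per arm
sample_size_two_sample_t <- function(delta, sd, alpha = 0.05, power = 0.80,
                                     sides = 2) {
  check_number(delta, "delta"); check_number(sd, "sd")
  if (delta <= 0) abort_validation("`delta` must be positive")
  if (sd <= 0) abort_validation("`sd` must be positive")
  check_number(alpha, "alpha"); check_number(power, "power")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    abort_validation("`alpha` and `power` must lie strictly inside (0, 1)")
  if (power <= alpha)
    abort_validation("target power must exceed alpha")
  if (!sides %in% c(1, 2)) abort_validation("`sides` must be 1 or 2")
  power_at <- function(n) {
    df <- 2 * (n - 1)
    ncp <- delta / (sd * sqrt(2 / n))
    crit <- stats::qt(1 - alpha / sides, df)
    pw <- 1 - stats::pt(crit, df, ncp)
    if (sides == 2) pw <- pw + stats::pt(-crit, df, ncp)
    pw
  }
  n <- 2L
  while (power_at(n) < power) {
    n <- n + 1L
    if (n > 1e7) abort_validation("sample size search did not converge")
  }
  n
}

#' Stratified utility summary (study-table layout)
#'
#' Mean (SD) of the normalized utility per (method, state) overall and per
#' stratum, with a rank-sum p-value comparing the two strata on each row.
#'
#' @param results A [simulate_study()] result.
#' @param stratifier `"arm"` or `"race"`.
#' @return Data frame with one row per (method, state); attribute
#'   `"strata"` holds the stratum labels.  Row order follows the method
#'   then state ordering of the assessment.
#' @export
stratified_summary <- function(results, stratifier = c("arm", "race")) {
  stratifier <- match.arg(stratifier)
  res <- merge(results$results,
               results$patients[c("patient_id", stratifier)],
               by = "patient_id")
  res <- res[order(res$patient_id), ]
  strata <- sort(unique(res[[stratifier]]))
  if (length(strata) < 2L)
    abort_validation(sprintf("stratifier '%s' must have at least 2 levels present", stratifier))
  grid <- expand.grid(state = intersect(assessed_states(), unique(res$state)),
                      method = intersect(assessment_methods(), unique(res$method)),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- res[res$state == grid$state[i] & res$method == grid$method[i], ]
    row <- data.frame(method = grid$method[i], state = grid$state[i],
                      overall_mean = mean(sub$normalized),
                      overall_sd = stats::sd(sub$normalized),
                      stringsAsFactors = FALSE)
    for (s in strata) {
      vals <- sub$normalized[sub[[stratifier]] == s]
      row[[paste0(make.names(s), "_mean")]] <- mean(vals)
      row[[paste0(make.names(s), "_sd")]] <- stats::sd(vals)
    }
    g1 <- sub$normalized[sub[[stratifier]] == strata[1]]
    g2 <- sub$normalized[sub[[stratifier]] == strata[2]]
    row$p_value <- if (length(strata) == 2L)
      rank_sum_test(g1, g2)$p_value else NA_real_
    row
  })
  out <- do.call(rbind, out)
  attr(out, "strata") <- strata
  out
}

#' Knowledge summary stratified by arm or race (study-table layout)
#'
#' Mean (SD) of the pretest, posttest and change score overall and per
#' stratum, with a rank-sum p-value per row, plus the paired signed-rank
#' test of the overall pre-to-post change.
#'
#' @inheritParams stratified_summary
#' @return List with `table` (data frame) and `paired_change` (a
#'   `group_comparison` for the overall change).
#' @export
knowledge_summary <- function(results, stratifier = c("arm", "race")) {
  stratifier <- match.arg(stratifier)
  pts <- results$patients
  strata <- sort(unique(pts[[stratifier]]))
  if (length(strata) < 2L)
    abort_validation(sprintf("stratifier '%s' must have at least 2 levels present", stratifier))
  pts$change <- pts$knowledge_post - pts$knowledge_pre
  vars <- c(pretest = "knowledge_pre", posttest = "knowledge_post",
            change_score = "change")
  out <- lapply(names(vars), function(v) {
    x <- pts[[vars[[v]]]]
    row <- data.frame(test = v, overall_mean = mean(x),
                      overall_sd = stats::sd(x), stringsAsFactors = FALSE)
    for (s in strata) {
      vals <- x[pts[[stratifier]] == s]
      row[[paste0(make.names(s), "_mean")]] <- mean(vals)
      row[[paste0(make.names(s), "_sd")]] <- stats::sd(vals)
    }
    row$p_value <- rank_sum_test(x[pts[[stratifier]] == strata[1]],
                                 x[pts[[stratifier]] == strata[2]])$p_value
    row
  })
  list(table = do.call(rbind, out),
       paired_change = signed_rank_test(pts$change))
}
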