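# Adaptive question-generation state machines for SG, TTO and VAS.
#
# SG and TTO sessions search for the respondent's indifference point with a
# "ping-pong" ladder of probe fractions (alternating high/low) followed by
# bisection, maintaining a nested bracket [bracket_low, bracket_high] that
# never widens.  The titration convention throughout: a SURE/STAY response
# at probe fraction p brackets the indifference point at or below p
# (bracket_high := p); a GAMBLE/TRADE response brackets it above p
# (bracket_low := p).  A session is DONE when the bracket width reaches the
# configured resolution (or, for TTO, when the whole-month grid is
# exhausted), and the indifference point is the final bracket midpoint.
# VAS is a single thermometer placement, not adaptive.

#' Titration schedule configuration
#'
#' @param ladder Ordered probe fractions in (0, 1), alternating high/low.
#'   Ladder probes falling outside the current bracket are skipped; the
#'   first response reversal ends the ladder and starts bisection.
#' @param resolution Terminal bracket width as a fraction of the scale
#'   (default 0.005, i.e. 0.5 points on the 0-100 scale).
#' @param max_questions Cap on the number of questions per session; must be
#'   at least `ceil(log2(1/resolution)) + length(ladder)`.
#' @return Object of class `titration_config`.
#' @export
titration_config <- function(ladder = c(0.95, 0.05, 0.85, 0.15, 0.75, 0.25),
                             resolution = 0.005,
                             max_questions = NULL) {
  if (!is.numeric(ladder) || length(ladder) < 1L ||
      any(ladder <= 0) || any(ladder >= 1))
    abort_validation("`ladder` must be probe fractions strictly inside (0, 1)")
  if (length(ladder) > 1L) {
    s <- sign(diff(ladder))
    if (any(s == 0) || any(s[-1] == s[-length(s)]))
      abort_validation("`ladder` probes must alternate high/low")
  }
  check_number(resolution, "resolution", 1e-6, 1)
  floor_q <- ceiling(log2(1 / resolution)) + length(ladder)
  if (is.null(max_questions)) max_questions <- floor_q
  if (!is.numeric(max_questions) || max_questions < floor_q)
    abort_validation(sprintf("`max_questions` must be at least %d", floor_q))
  structure(list(ladder = as.numeric(ladder),
                 resolution = resolution,
                 max_questions = as.integer(max_questions)),
            class = "titration_config")
}

# ---- question constructors -------------------------------------------------

new_gamble_question <- function(session, p_best) {
  list(type = "gamble", method = "SG",
       target_state = session$target_state,
       sure_state = session$target_state,
       gamble_best = session$anchors$best,
       gamble_worst = "DEAD",
       p_best = p_best, fraction = p_best,
       anchors = session$anchors)
}

new_trade_question <- function(session, months) {
  horizon <- session$horizon_years
  list(type = "trade", method = "TTO",
       target_state = session$target_state,
       full_horizon_years = horizon,
       offered_years = months / 12,
       offered_months = months,
       fraction = months / (12 * horizon),
       anchors = session$anchors)
}

new_placement_request <- function(session) {
  list(type = "placement", method = "VAS",
       target_state = session$target_state,
       anchors = session$anchors)
}

# Next probe for an SG/TTO session, honouring the ladder-then-bisection
# schedule.  Returns list(fraction, months, ladder_index, phase) or NULL if
# no admissible probe remains (TTO month grid exhausted).
next_probe <- function(session) {
  cfg <- session$config
  tto <- session$method == "TTO"
  grid_m <- if (tto) 12L * session$horizon_years else NA_integer_
  interior <- function(frac) {
    if (tto) {
      m <- as.integer(round(frac * grid_m))
      if (m > session$low_m && m < session$high_m) m else NA_integer_
    } else {
      if (frac > session$bracket_low + 1e-12 &&
          frac < session$bracket_high - 1e-12) frac else NA
    }
  }
  phase <- session$phase
  if (phase == "LADDER") {
    i <- session$ladder_index
    while (i <= length(cfg$ladder)) {
      hit <- interior(cfg$ladder[i])
      if (!is.na(hit)) {
        return(list(fraction = if (tto) hit / grid_m else hit,
                    months = if (tto) hit else NA_integer_,
                    ladder_index = i, phase = "LADDER"))
      }
      i <- i + 1L
    }
    phase <- "BISECTION"  # ladder exhausted
  }
  if (tto) {
    m <- (session$low_m + session$high_m) %/% 2L
    if (m <= session$low_m || m >= session$high_m) return(NULL)
    list(fraction = m / grid_m, months = m,
         ladder_index = session$ladder_index, phase = phase)
  } else {
    list(fraction = (session$bracket_low + session$bracket_high) / 2,
         months = NA_integer_,
         ladder_index = session$ladder_index, phase = phase)
  }
}

make_pending <- function(session) {
  if (session$method == "VAS") return(new_placement_request(session))
  probe <- next_probe(session)
  if (is.null(probe)) return(NULL)
  session$phase <- probe$phase
  q <- if (session$method == "SG") new_gamble_question(session, probe$fraction)
       else new_trade_question(session, probe$months)
  q$ladder_index <- probe$ladder_index
  q$phase <- probe$phase
  q
}

#' Start an elicitation session
#'
#' Initializes the adaptive bracket to (0, 1) and draws the first question:
#' the first ladder probe for SG/TTO, or a single placement request for VAS.
#' TTO sessions need a horizon, either given directly via `horizon_years` or
#' resolved from the patient's age and sex through a life table
#' ([tto_horizon()]).  Chained sessions (anchor pair whose best state is not
#' `WELL`) require the anchor's utility to have been elicited already.
#'
#' @param method `"VAS"`, `"SG"` or `"TTO"`.
#' @param target_state One of the three assessed health states.
#' @param anchors An [anchor_pair()]; defaults to Well = 100 / Dead = 0.
#' @param config A [titration_config()].
#' @param patient_age,patient_sex,life_table Used to resolve the TTO horizon
#'   when `horizon_years` is not given.
#' @param horizon_years TTO horizon in whole years (>= 1).
#' @return Object of class `hua_session`; the next question is in
#'   `$pending` (see [current_question()]).
#' @export
start_session <- function(method, target_state, anchors = default_anchors(),
                          config = titration_config(),
                          patient_age = NULL, patient_sex = NULL,
                          life_table = NULL, horizon_years = NULL) {
  method <- check_method(method)
  target_state <- check_state(target_state, allow_anchor = FALSE)
  stopifnot(inherits(anchors, "anchor_pair"), inherits(config, "titration_config"))
  if (is_chained(anchors) && is.na(anchors$best_utility))
    abort_sequencing("chained session requested before the anchor state's utility was elicited")
  if (method == "TTO") {
    if (is.null(horizon_years)) {
      if (is.null(patient_age) || is.null(patient_sex) || is.null(life_table))
        abort_validation("TTO needs `horizon_years` or (`patient_age`, `patient_sex`, `life_table`)")
      horizon_years <- tto_horizon(patient_age, patient_sex, life_table)
    }
    check_number(horizon_years, "horizon_years", 1, Inf)
    horizon_years <- as.integer(horizon_years)
  } else horizon_years <- NA_integer_
  session <- structure(list(
    method = method, target_state = target_state,
    anchors = anchors, config = config,
    horizon_years = horizon_years,
    bracket_low = 0, bracket_high = 1,
    low_m = 0L,
    high_m = if (is.na(horizon_years)) NA_integer_ else 12L * horizon_years,
    phase = "LADDER", ladder_index = 1L,
    placement = NA_real_, last_choice = NULL,
    n_questions = 0L, transcript = list(), pending = NULL
  ), class = "hua_session")
  session$pending <- make_pending(session)
  if (!is.null(session$pending$phase)) session$phase <- session$pending$phase
  session
}

#' @rdname start_session
#' @param session A `hua_session`.
#' @return `current_question()` returns the pending question (a list with a
#'   `type` of `"gamble"`, `"trade"` or `"placement"`), or `NULL` for a
#'   finished session.
#' @export
current_question <- function(session) {
  stopifnot(inherits(session, "hua_session"))
  session$pending
}

#' Record a response and advance the session
#'
#' For SG the choice is `"SURE"` (prefer the certain intermediate state) or
#' `"GAMBLE"`; for TTO it is `"STAY"` (keep the full horizon in the target
#' state) or `"TRADE"`; for VAS it is a numeric placement on 0-100.  A
#' SURE/STAY response caps the bracket above at the probe fraction, a
#' GAMBLE/TRADE response raises the bracket floor to it, so the bracket
#' width never increases.  The first reversal ends the ladder phase; the
#' session is DONE when the width reaches the configured resolution.
#'
#' @param session A `hua_session` that is not DONE.
#' @param choice Response to the pending question (see Details).
#' @return The updated `hua_session`.
#' @export
record_response <- function(session, choice) {
  stopifnot(inherits(session, "hua_session"))
  if (session$phase == "DONE")
    abort_sequencing("session is already DONE; no further responses accepted")
  q <- session$pending
  if (is.null(q)) abort_sequencing("session has no pending question")

  if (session$method == "VAS") {
    if (!is.numeric(choice) || length(choice) != 1L || !is.finite(choice) ||
        choice < 0 || choice > 100)
      abort_protocol("VAS placement must be a number on 0-100")
    session$placement <- as.numeric(choice)
    session$phase <- "DONE"
    session$n_questions <- session$n_questions + 1L
    session$transcript[[length(session$transcript) + 1L]] <- list(
      ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
      method = "VAS", state = session$target_state, phase = "LADDER",
      question = list(type = "placement"), response = session$placement,
      bracket_low = session$placement / 100, bracket_high = session$placement / 100,
      reversal = FALSE)
    session$pending <- NULL
    return(session)
  }

  valid <- if (session$method == "SG") c("SURE", "GAMBLE") else c("STAY", "TRADE")
  if (!is.character(choice) || length(choice) != 1L || !(choice %in% valid))
    abort_protocol(sprintf("invalid choice '%s' for a %s question (expected %s)",
                           paste(choice, collapse = ","), session$method,
                           paste(valid, collapse = "/")))
  tto <- session$method == "TTO"
  upper <- choice %in% c("SURE", "STAY")
  if (upper) {
    session$bracket_high <- q$fraction
    if (tto) session$high_m <- q$offered_months
  } else {
    session$bracket_low <- q$fraction
    if (tto) session$low_m <- q$offered_months
  }
  reversal <- !is.null(session$last_choice) && choice != session$last_choice
  if (session$phase == "LADDER") {
    session$ladder_index <- q$ladder_index + 1L
    if (reversal) session$phase <- "BISECTION"
  }
  session$last_choice <- choice
  session$n_questions <- session$n_questions + 1L
  session$transcript[[length(session$transcript) + 1L]] <- list(
    ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    method = session$method, state = session$target_state, phase = q$phase,
    question = if (tto)
      list(type = "trade", offered_years = q$offered_years,
           full_horizon_years = q$full_horizon_years)
    else list(type = "gamble", p_best = q$p_best),
    response = choice,
    bracket_low = session$bracket_low, bracket_high = session$bracket_high,
    reversal = reversal)

  width <- session$bracket_high - session$bracket_low
  done <- width <= session$config$resolution + 1e-12 ||
    session$n_questions >= session$config$max_questions
  if (!done) {
    session$pending <- make_pending(session)
    if (is.null(session$pending)) done <- TRUE
    else if (!is.null(session$pending$phase)) session$phase <- session$pending$phase
  }
  if (done) {
    session$phase <- "DONE"
    session$pending <- NULL
  }
  session
}

#' Indifference point of a finished session
#'
#' The midpoint of the final bracket for SG/TTO, or placement/100 for VAS,
#' as a fraction in `[0, 1]` on the session's anchor pair.
#'
#' @param session A DONE `hua_session`.
#' @return Fraction in `[0, 1]`.
#' @export
indifference_point <- function(session) {
  stopifnot(inherits(session, "hua_session"))
  if (session$phase != "DONE")
    abort_sequencing("session is not DONE; cannot extract an indifference point")
  if (session$method == "VAS") return(session$placement / 100)
  (session$bracket_low + session$bracket_high) / 2
}

#' @export
print.hua_session <- function(x, ...) {
  cat(sprintf("<hua_session> %s / %s  phase: %s  bracket: [%.4f, %.4f]  questions: %d%s\n",
              x$method, x$target_state, x$phase,
              x$bracket_low, x$bracket_high, x$n_questions,
              if (!is.na(x$horizon_years)) sprintf("  horizon: %dy", x$horizon_years) else ""))
  invisible(x)
}

# ---- indifference -> utility conversions ----------------------------------

#' Convert indifference points to utilities on the 0-100 scale
#'
#' Each conversion is the linear interpolation between the anchor pair's
#' utilities: `p * best_utility + (1 - p) * worst_utility` with `p` the
#' indifference fraction (`p_best` for SG, `offered/horizon` for TTO,
#' `placement/100` for VAS).  At the extremes they reproduce the anchor
#' utilities exactly.
#'
#' @param p_star Indifference probability for the standard gamble, in
#'   `[0, 1]`.
#' @param anchors An [anchor_pair()].
#' @return Utility on the common 0-100 scale.
#' @export
#' @examples
#' sg_utility_from_indifference(0.755, default_anchors())  # 75.5
sg_utility_from_indifference <- function(p_star, anchors = default_anchors()) {
  check_number(p_star, "p_star", 0, 1)
  stopifnot(inherits(anchors, "anchor_pair"))
  p_star * anchors$best_utility + (1 - p_star) * anchors$worst_utility
}

#' @rdname sg_utility_from_indifference
#' @param offered_years Years in the best-anchor state at indifference.
#' @param horizon_years Full horizon in the target state (>= 1).
#' @export
tto_utility_from_indifference <- function(offered_years, horizon_years,
                                          anchors = default_anchors()) {
  check_number(horizon_years, "horizon_years", 1, Inf)
  check_number(offered_years, "offered_years", 0, Inf)
  if (offered_years > horizon_years)
    abort_validation("`offered_years` cannot exceed `horizon_years`")
  stopifnot(inherits(anchors, "anchor_pair"))
  frac <- offered_years / horizon_years
  frac * anchors$best_utility + (1 - frac) * anchors$worst_utility
}

#' @rdname sg_utility_from_indifference
#' @param placement VAS thermometer placement on 0-100.
#' @export
vas_utility_from_placement <- function(placement, anchors = default_anchors()) {
  check_number(placement, "placement", 0, 100)
  stopifnot(inherits(anchors, "anchor_pair"))
  frac <- placement / 100
  frac * anchors$best_utility + (1 - frac) * anchors$worst_utility
}

#' Run a full session against a simulated respondent
#'
#' Drives [start_session()] / [record_response()] to completion using
#' [respond()] for every question, then converts the indifference point to
#' a [utility_value()] (applying chained normalization through the anchor
#' pair when the session is chained).
#'
#' @inheritParams start_session
#' @param respondent A [respondent_profile()].
#' @return A [utility_value()]; the finished session is attached as
#'   attribute `"session"`.
#' @export
run_auto_session <- function(method, target_state, anchors = default_anchors(),
                             config = titration_config(), respondent,
                             patient_age = NULL, patient_sex = NULL,
                             life_table = NULL, horizon_years = NULL) {
  session <- start_session(method, target_state, anchors, config,
                           patient_age, patient_sex, life_table, horizon_years)
  while (session$phase != "DONE") {
    choice <- respond(respondent, session$pending)
    session <- record_response(session, choice)
  }
  value <- utility_value(target_state, method, indifference_point(session), anchors)
  attr(value, "session") <- session
  value
}

#' Write a session transcript as JSON lines
#'
#' One JSON object per question with fields `ts`, `method`, `state`,
#' `phase`, the question parameters, the response, and the post-response
#' bracket.
#'
#' @param session A `hua_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(session, path) {
  stopifnot(inherits(session, "hua_session"))
  lines <- vapply(session$transcript, function(rec)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
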