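# Health-state and utility-scale data model.
#
# Utilities live on a 0-100 scale anchored by "Well" (without ESKD) = 100 and
# "Dead" = 0.  The three assessed states are hemodialysis, transplantation
# with an HCV-unexposed kidney, and transplantation with an HCV-viremic
# kidney; the last is assessed on a chained scale whose best anchor is the
# HCV-unexposed transplant, and is mapped back to the common scale by
# multiplying the raw chained fraction by the anchor's utility.
# Internally every indifference value is a fraction in [0, 1]; 0-100 is
# presentation.

#' Health states
#'
#' The five health states of the assessment model: the three states whose
#' utility is elicited, plus the two anchor states `WELL` and `DEAD` that
#' define the ends of the common utility scale and are never themselves
#' targets of elicitation.
#'
#' @return Named character vector of state identifiers; names are display
#'   labels.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("Hemodialysis"                      = "HEMODIALYSIS",
    "Kidney transplant (HCV-unexposed)" = "TX_UNEXPOSED",
    "Kidney transplant (HCV-viremic)"   = "TX_HCV_VIREMIC",
    "Well (without ESKD)"               = "WELL",
    "Dead"                              = "DEAD")
}

#' @rdname health_states
#' @export
assessed_states <- function() unname(health_states()[1:3])

#' Assessment methods
#'
#' The three health-utility assessment techniques: visual analog scale
#' (`VAS`, a "feeling thermometer" placement), standard gamble (`SG`), and
#' time trade-off (`TTO`).
#'
#' @return Character vector `c("VAS", "SG", "TTO")`.
#' @export
assessment_methods <- function() c("VAS", "SG", "TTO")

check_state <- function(state, allow_anchor = TRUE) {
  states <- unname(health_states())
  if (!is.character(state) || length(state) != 1L || !(state %in% states))
    abort_validation(sprintf("unknown health state '%s'", paste(state, collapse = ",")))
  if (!allow_anchor && state %in% c("WELL", "DEAD"))
    abort_validation(sprintf("'%s' is an anchor state and cannot be a target of elicitation", state))
  state
}

check_method <- function(method) {
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% assessment_methods()))
    abort_validation(sprintf("unknown assessment method '%s'", paste(method, collapse = ",")))
  method
}

#' Anchor pair for an elicitation scale
#'
#' An elicitation session is anchored by a best and a worst state with known
#' utilities on the common 0-100 scale.  The default pair is Well = 100 /
#' Dead = 0; the chained pair used for the HCV-viremic transplant state is
#' the HCV-unexposed transplant (with its previously elicited utility) /
#' Dead = 0.
#'
#' @param best,worst Health state identifiers (see [health_states()]).
#' @param best_utility,worst_utility Utilities of the anchors on the 0-100
#'   scale.  `best_utility` may be `NA` to build a chained pair whose anchor
#'   utility has not yet been elicited; a session cannot start until it is
#'   filled in.
#' @return An object of class `anchor_pair`.
#' @export
#' @examples
#' default_anchors()
#' chained_anchors(89)
anchor_pair <- function(best, worst = "DEAD", best_utility = 100,
                        worst_utility = 0) {
  best <- check_state(best)
  worst <- check_state(worst)
  if (best == worst) abort_validation("anchor states must differ")
  if (!is.na(best_utility)) {
    check_number(best_utility, "best_utility", 0, 100)
    check_number(worst_utility, "worst_utility", 0, 100)
    if (best_utility <= worst_utility)
      abort_validation("best_utility must exceed worst_utility")
  }
  structure(list(best = best, worst = worst,
                 best_utility = as.numeric(best_utility),
                 worst_utility = as.numeric(worst_utility)),
            class = "anchor_pair")
}

#' @rdname anchor_pair
#' @export
default_anchors <- function() anchor_pair("WELL", "DEAD", 100, 0)

#' @rdname anchor_pair
#' @export
chained_anchors <- function(best_utility = NA_real_) {
  anchor_pair("TX_UNEXPOSED", "DEAD", best_utility, 0)
}

#' @rdname anchor_pair
#' @param anchors An `anchor_pair`.
#' @export
is_chained <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_pair"))
  anchors$best != "WELL"
}

#' @export
print.anchor_pair <- function(x, ...) {
  cat(sprintf("<anchor_pair> best: %s (%s)  worst: %s (%s)%s\n",
              x$best, format(x$best_utility), x$worst, format(x$worst_utility),
              if (is_chained(x)) "  [chained]" else ""))
  invisible(x)
}

#' Map a chained raw utility back to the common scale
#'
#' A chained assessment elicits a raw fraction on an anchor pair whose best
#' state is itself intermediate (here, transplantation with an HCV-unexposed
#' kidney).  Normalization multiplies the raw fraction by the anchor's
#' utility on the common Well/Dead 0-100 scale, so the normalized value can
#' never exceed the anchor's own utility.
#'
#' @param raw_fraction Indifference value in `[0, 1]` on the chained anchor
#'   pair.
#' @param anchor_utility Utility of the chained best anchor, 0-100.
#' @return Normalized utility on the common 0-100 scale.
#' @export
#' @examples
#' normalize_chained_utility(0.80, 90.7)
normalize_chained_utility <- function(raw_fraction, anchor_utility) {
  check_number(raw_fraction, "raw_fraction", 0, 1)
  check_number(anchor_utility, "anchor_utility", 0, 100)
  raw_fraction * anchor_utility
}

#' Implied death risk of a standard-gamble utility
#'
#' The standard gamble reads a utility `u` (0-100) as indifference between
#' the sure state and a gamble whose worst outcome is immediate death; the
#' maximum acceptable probability of death is therefore `100 - u`, in
#' percent.
#'
#' @param sg_utility Standard-gamble utility on the 0-100 scale.
#' @return Implied maximum acceptable death risk, percent in `[0, 100]`.
#' @export
#' @examples
#' implied_death_risk(75.5)  # 24.5% risk of death accepted
implied_death_risk <- function(sg_utility) {
  check_number(sg_utility, "sg_utility", 0, 100)
  100 - sg_utility
}

#' Convert between the fraction and percent utility scales
#'
#' @param value Number on the source scale.
#' @param from,to `"fraction"` (`[0, 1]`) or `"percent"` (`[0, 100]`).
#' @return `value` re-expressed on the target scale.
#' @export
scale_convert <- function(value, from, to) {
  scales <- c(fraction = 1, percent = 100)
  if (!is.character(from) || length(from) != 1L || !(from %in% names(scales)))
    abort_validation(sprintf("unknown scale '%s'", paste(from, collapse = ",")))
  if (!is.character(to) || length(to) != 1L || !(to %in% names(scales)))
    abort_validation(sprintf("unknown scale '%s'", paste(to, collapse = ",")))
  check_number(value, "value", 0, scales[[from]])
  # snap away float dust from the two-decade rescale so round trips are
  # exact at the 0.5-point resolution of the instruments
  round(value * scales[[to]] / scales[[from]], 9)
}

#' Elicited utility value
#'
#' Couples a raw indifference fraction (on its session's anchor pair) with
#' its normalized value on the common Well/Dead 0-100 scale.  For a
#' non-chained session normalized = 100 x raw; for a chained session the raw
#' fraction is multiplied by the chained anchor's utility.
#'
#' @param state Assessed health state.
#' @param method Assessment method.
#' @param raw_fraction Indifference value in `[0, 1]`.
#' @param anchors The session's `anchor_pair`.
#' @return Object of class `utility_value` with fields `state`, `method`,
#'   `raw_fraction`, `normalized`, `chained`.
#' @export
utility_value <- function(state, method, raw_fraction, anchors = default_anchors()) {
  state <- check_state(state, allow_anchor = FALSE)
  method <- check_method(method)
  check_number(raw_fraction, "raw_fraction", 0, 1)
  stopifnot(inherits(anchors, "anchor_pair"))
  if (is.na(anchors$best_utility))
    abort_sequencing("anchor utility has not been elicited yet")
  normalized <- raw_fraction * anchors$best_utility +
    (1 - raw_fraction) * anchors$worst_utility
  structure(list(state = state, method = method,
                 raw_fraction = raw_fraction,
                 normalized = normalized,
                 chained = is_chained(anchors)),
            class = "utility_value")
}

#' @export
print.utility_value <- function(x, ...) {
  cat(sprintf("<utility_value> %s / %s: raw %.4f -> %.1f on 0-100%s\n",
              x$state, x$method, x$raw_fraction, x$normalized,
              if (x$chained) " (chained)" else ""))
  invisible(x)
}
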