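#' @title Interaction rules of the seven profiles
#' @description
#' These functions encode, one cell at a time, how each personality
#' profile behaves in a daily meeting and how it responds to the three
#' interaction events (policing, offering to cooperate, tempting to
#' defect). They form the reference semantics of the model; the compiled
#' engine reimplements the same table for speed and is tested against
#' this surface.
#'
#' An agent is a list (or one data-frame row) with fields `type`
#' (1..7), `state` (`"C"` or `"D"`) and `timer` (days remaining of an
#' event-induced cooperative spell; 0 means the current state is
#' untimed). The majority signal is the previous day's end-of-day
#' cooperator fraction classified by [majority_from_fraction()].
#' @name rules
NULL

#' Classify a cooperator fraction into a majority signal
#'
#' @param frac Cooperator fraction in \[0, 1\].
#' @return `"C"` if more than half cooperate, `"D"` if fewer than half,
#'   `"tie"` at exactly one half. A tie satisfies neither majority
#'   condition, so majority-gated transitions do not fire.
#' @examples
#' majority_from_fraction(76 / 150)
#' @export
majority_from_fraction <- function(frac) {
  if (!is.numeric(frac) || length(frac) != 1 || is.na(frac) ||
      frac < 0 || frac > 1)
    stop("frac must be a single number in [0, 1]")
  if (frac > 0.5) "C" else if (frac < 0.5) "D" else "tie"
}

# Internal helper: a single agent as a plain list.
as_agent <- function(type, state, timer = 0L) {
  list(type = as.integer(type), state = state, timer = as.integer(timer))
}

#' Resolve one meeting for the focal agent
#'
#' Applies the focal agent's row of the rule table given the partner's
#' current state and the majority signal. Probability draws (the 50%
#' cells) consume the session RNG stream in a fixed order: the focal
#' transition draw first, then event-emission draws in emission order.
#'
#' @param focal Agent (list with `type`, `state`, `timer`).
#' @param partner_state `"C"` or `"D"`, the partner's current state.
#' @param majority `"C"`, `"D"` or `"tie"`.
#' @param params A [control_params()] object.
#' @return List with `agent` (the updated focal) and `events`, a
#'   character vector among `"police"`, `"offer"`, `"tempt"` directed at
#'   the partner.
#' @examples
#' meeting_outcome(list(type = 7, state = "C", timer = 0), "D",
#'                 "C", control_params(0.5, 10))
#' @export
meeting_outcome <- function(focal, partner_state, majority, params) {
  stopifnot(partner_state %in% c("C", "D"),
            majority %in% c("C", "D", "tie"))
  t <- focal$type
  s <- focal$state
  if (t %in% c(2L, 3L, 7L) && s == "D")
    stop("internal inconsistency: type ", t, " cannot be in state D")
  events <- character(0)
  if (t == 1L) {
    if (s == "C" && partner_state == "D") {
      focal$state <- "D"; focal$timer <- 0L
    } else if (s == "D" && partner_state == "C") {
      events <- "tempt"
    }
  } else if (t == 2L) {
    if (partner_state == "D") {
      events <- "offer"
      if (stats::runif(1) < 0.5) events <- c(events, "police")
    }
  } else if (t == 3L) {
    if (partner_state == "D" && stats::runif(1) < 0.5) events <- "offer"
  } else if (t == 4L) {
    if (s == "C" && partner_state == "D") {
      focal$state <- "D"; focal$timer <- 0L
    } else if (s == "D" && partner_state == "C") {
      focal$state <- "C"; focal$timer <- params$d
    }
  } else if (t == 5L) {
    if (s == "C" && partner_state == "D") {
      if (majority == "D") { focal$state <- "D"; focal$timer <- 0L }
    } else if (s == "D" && partner_state == "C") {
      if (majority == "C") { focal$state <- "C"; focal$timer <- 0L }
    }
  } else if (t == 6L) {
    if (s == "C" && partner_state == "D") {
      if (stats::runif(1) < 0.5) { focal$state <- "D"; focal$timer <- 0L }
    } else if (s == "D" && partner_state == "C") {
      if (stats::runif(1) < 0.5) { focal$state <- "C"; focal$timer <- 0L }
    }
  } else if (t == 7L) {
    if (partner_state == "D") events <- "police"
  }
  list(agent = focal, events = events)
}

#' Respond to being policed
#'
#' Types 2, 3 and 7 are unaffected. Types 1 and 4 switch to cooperation
#' with probability `h` for `d` days; type 5 does so only under a
#' cooperator majority; type 6 likewise switches with probability `h`
#' for `d` days. A target already cooperating without a timer is left
#' unchanged (policing never downgrades voluntary cooperation); a timed
#' cooperator has its timer renewed to `d` with probability `h`. No RNG
#' draw is consumed when no change is possible.
#'
#' @inheritParams meeting_outcome
#' @param target The policed agent.
#' @return The updated agent.
#' @export
apply_police <- function(target, majority, params) {
  t <- target$type
  if (t %in% c(2L, 3L, 7L)) return(target)
  if (target$state == "C" && target$timer == 0L) return(target)
  if (t == 5L && majority != "C") return(target)
  if (stats::runif(1) < params$h) {
    target$state <- "C"; target$timer <- params$d
  }
  target
}

#' Respond to an offer to cooperate
#'
#' Type 1 ignores offers. Type 4 accepts and cooperates for `d` days.
#' Type 5 accepts, without a timer, only under a cooperator majority.
#' Type 6 accepts with probability one half, without a timer. Types 2,
#' 3 and 7 already cooperate and are unaffected, as is any target
#' cooperating without a timer.
#'
#' @inheritParams apply_police
#' @return The updated agent.
#' @export
apply_offer <- function(target, majority, params) {
  t <- target$type
  if (t %in% c(1L, 2L, 3L, 7L)) return(target)
  if (target$state == "C" && target$timer == 0L) return(target)
  if (t == 4L) {
    target$state <- "C"; target$timer <- params$d
  } else if (t == 5L) {
    if (majority == "C") { target$state <- "C"; target$timer <- 0L }
  } else if (t == 6L) {
    if (stats::runif(1) < 0.5) { target$state <- "C"; target$timer <- 0L }
  }
  target
}

#' Respond to a temptation to defect
#'
#' Types 1 and 4 defect immediately, clearing any habit timer. Type 5
#' defects only under a defector majority. Type 6 defects with
#' probability one half. Types 2, 3 and 7 are immune. A target already
#' defecting is unchanged and consumes no draw.
#'
#' @inheritParams apply_police
#' @return The updated agent.
#' @export
apply_tempt <- function(target, majority, params) {
  t <- target$type
  if (t %in% c(2L, 3L, 7L) || target$state == "D") return(target)
  if (t %in% c(1L, 4L)) {
    target$state <- "D"; target$timer <- 0L
  } else if (t == 5L) {
    if (majority == "D") { target$state <- "D"; target$timer <- 0L }
  } else if (t == 6L) {
    if (stats::runif(1) < 0.5) { target$state <- "D"; target$timer <- 0L }
  }
  target
}

#' End-of-day habit-timer bookkeeping
#'
#' Called once per agent at the end of each day: a positive timer is
#' decremented and, on reaching zero, the event-induced cooperative
#' spell ends and the agent reverts to defection. Untimed states are
#' unaffected. An agent set to cooperate "for d days" therefore
#' cooperates on the day of the event and the following `d - 1` days.
#'
#' @param agent The agent to update.
#' @return The updated agent.
#' @examples
#' expire_timer(list(type = 1, state = "C", timer = 1))
#' @export
expire_timer <- function(agent) {
  if (agent$timer > 0L) {
    agent$timer <- agent$timer - 1L
    if (agent$timer == 0L) agent$state <- "D"
  }
  agent
}

#' The interaction rule table in serializable form
#'
#' One record per profile and situation, suitable for diffing against
#' an independent transcription of the behavioural rules. The built-in
#' functions are the normative copy; this table is descriptive.
#'
#' @return A data frame with columns `type`, `situation`, `rule`.
#' @export
rule_table <- function() {
  rec <- function(type, situation, rule)
    data.frame(type = type, situation = situation, rule = rule,
               stringsAsFactors = FALSE)
  rbind(
    rec(1, "initial", "D"),
    rec(1, "C meets D", "D"),
    rec(1, "D meets C", "D, tempts partner"),
    rec(1, "policed", "h% to be C for d days"),
    rec(1, "offered", "no effect"),
    rec(1, "tempted", "D"),
    rec(2, "initial", "C"),
    rec(2, "C meets D", "C, offers; polices with prob 0.5"),
    rec(3, "initial", "C"),
    rec(3, "C meets D", "C, offers with prob 0.5"),
    rec(4, "initial", "D"),
    rec(4, "C meets D", "D"),
    rec(4, "D meets C", "C for d days"),
    rec(4, "policed", "h% to be C for d days"),
    rec(4, "offered", "C for d days"),
    rec(4, "tempted", "D"),
    rec(5, "initial", "D"),
    rec(5, "C meets D", "D if D majority, else C"),
    rec(5, "D meets C", "C if C majority, else D"),
    rec(5, "policed", "h% to be C for d days if C majority"),
    rec(5, "offered", "C if C majority"),
    rec(5, "tempted", "D if D majority"),
    rec(6, "initial", "C or D with prob 0.5"),
    rec(6, "C meets D", "D with prob 0.5"),
    rec(6, "D meets C", "C with prob 0.5"),
    rec(6, "policed", "h% to be C for d days"),
    rec(6, "offered", "C with prob 0.5"),
    rec(6, "tempted", "D with prob 0.5"),
    rec(7, "initial", "C"),
    rec(7, "C meets D", "C, polices")
  )
}
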