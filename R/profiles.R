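#' The seven time-perspective behavioural profiles
#'
#' Each agent in the village carries one of seven personality profiles
#' derived from cluster analysis of Zimbardo Time Perspective Inventory
#' survey data. The profile id (1..7) indexes every rule table in the
#' package; the label is the profile's descriptive name.
#'
#' Profiles 2 (Orderly), 3 (Laborious) and 7 (Committed) are
#' unconditional cooperators; profiles 1 (Opportunistic), 4 (Steadfast),
#' 5 (Precarious) and 6 (Traumatized) are the non-cooperative types whose
#' behaviour the policing (`h`) and habit-duration (`d`) parameters act on.
#'
#' @return A data frame with columns `id` (integer 1..7), `label`
#'   (character) and `initial_state` (`"C"`, `"D"` or `"coin"` for the
#'   type that starts cooperating with probability one half).
#' @examples
#' tp_profiles()
#' @export
tp_profiles <- function() {
  data.frame(
    id = 1:7,
    label = c("Opportunistic", "Orderly", "Laborious", "Steadfast",
              "Precarious", "Traumatized", "Committed"),
    initial_state = c("D", "C", "C", "D", "D", "coin", "C"),
    stringsAsFactors = FALSE
  )
}

#' Control parameters of the model
#'
#' `h` is the probability that a policed (or, for some types, offered)
#' non-cooperative agent switches to cooperation; `d` is the number of
#' days such an event-induced cooperative spell lasts before the agent
#' reverts to defection, unless interrupted by temptation.
#'
#' @param h Policing efficiency, a probability in \[0, 1\].
#' @param d Habit duration in days, a positive integer.
#' @return An object of class `tp_params`.
#' @examples
#' control_params(h = 0.5, d = 10)
#' @export
control_params <- function(h = 0.5, d = 10) {
  stopifnot(is.numeric(h), length(h) == 1, !is.na(h), h >= 0, h <= 1)
  stopifnot(is.numeric(d), length(d) == 1, !is.na(d), d >= 1,
            d == as.integer(d))
  structure(list(h = as.numeric(h), d = as.integer(d)),
            class = "tp_params")
}

#' @export
print.tp_params <- function(x, ...) {
  cat(sprintf("Control parameters: h = %.3f, d = %d days\n", x$h, x$d))
  invisible(x)
}

# Internal: validate an agent roster data frame.
check_agents <- function(agents) {
  stopifnot(is.data.frame(agents),
            all(c("id", "type", "state", "timer") %in% names(agents)))
  stopifnot(all(agents$type %in% 1:7),
            all(agents$state %in% c("C", "D")),
            all(agents$timer >= 0))
  if (any(agents$timer > 0 & agents$state != "C"))
    stop("internal inconsistency: positive timer on a defecting agent")
  if (any(agents$type %in% c(2L, 3L, 7L) & agents$state == "D"))
    stop("internal inconsistency: cooperative type in state D")
  invisible(agents)
}
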