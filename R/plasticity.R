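# Stateless weight and delay modification rules with saturating 4-bit
# arithmetic. Sign convention throughout: dt < 0 means the pre-synaptic spike
# preceded the post-synaptic spike (potentiation side). A window observation
# encodes the same information as (polarity, remaining): the elapsed time is
# duration - remaining, signed by which spike started the window.

#' Rule parameters
#'
#' Parameters shared by the STDP/STDDP modification rules. `a_plus`/`a_minus`
#' are the maximum modification magnitudes of the proportional rule (and the
#' amplitudes of the reference exponential rule), `step` the magnitude of the
#' fixed-step rules, `window_duration` the time-window length in ticks
#' (1 tick = 1 ms). Weights and delays are unsigned 4-bit integers, so
#' `w_max` is fixed at 15.
#'
#' @param a_plus,a_minus Positive integers; default 16.
#' @param tau_plus,tau_minus Positive reals (reference exponential rule only).
#' @param step Positive integer; default 1.
#' @param w_max Upper bound of stored values; must be 15 (4-bit storage).
#' @param window_duration Time window length in ticks; default 16.
#' @return An object of class `rule_params`.
#' @export
rule_params <- function(a_plus = 16L, a_minus = 16L, tau_plus = 16,
                        tau_minus = 16, step = 1L, w_max = 15L,
                        window_duration = 16L) {
  if (tau_plus <= 0 || tau_minus <= 0)
    stop("tau_plus and tau_minus must be positive")
  if (a_plus <= 0 || a_minus <= 0 || step <= 0 || window_duration <= 0)
    stop("a_plus, a_minus, step and window_duration must be positive")
  if (w_max != 15L)
    stop("w_max must be 15: weights and delays are stored as 4-bit integers")
  structure(list(a_plus = as.integer(a_plus), a_minus = as.integer(a_minus),
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 step = as.integer(step), w_max = 15L,
                 window_duration = as.integer(window_duration)),
            class = "rule_params")
}

#' Observation of a time window at spike arrival
#'
#' Snapshot of one slot's time-window generator at the moment a spike of the
#' kind opposite to the window's polarity arrives. `remaining` is the value of
#' the down-counter; the elapsed time |dt| is `window duration - remaining`.
#'
#' @param t_active Logical; is the window active (remaining > 0)?
#' @param polarity `"pre_started"` or `"post_started"`: which spike kind
#'   started the window.
#' @param remaining Integer in `[0, 16]`: down-counter value at observation.
#' @param simultaneous Logical; did pre and post arrive in the same tick?
#' @return An object of class `window_observation`; all fields may be vectors
#'   of a common length.
#' @export
window_observation <- function(t_active, polarity, remaining,
                               simultaneous = FALSE) {
  remaining <- as.integer(remaining)
  if (!all(polarity %in% c("pre_started", "post_started")))
    stop("polarity must be 'pre_started' or 'post_started'")
  if (any(remaining < 0L) || any(remaining > 16L))
    stop("remaining must lie in [0, 16]")
  if (any((remaining > 0L) != t_active))
    stop("window invariant violated: remaining > 0 iff t_active")
  structure(list(t_active = as.logical(t_active), polarity = polarity,
                 remaining = remaining,
                 simultaneous = as.logical(simultaneous)),
            class = "window_observation")
}

#' Fixed-step STDP weight modification
#'
#' `+step` when an active pre-started window is hit by a post spike (pre
#' before post), `-step` when an active post-started window is hit by a pre
#' spike. No modification when the window is inactive (the spike starts a new
#' window instead) or when pre and post arrive simultaneously.
#'
#' @param obs A [window_observation()].
#' @param params [rule_params()].
#' @return Signed integer weight change (vectorized over `obs`).
#' @export
stdp_delta_fixed <- function(obs, params = rule_params()) {
  stopifnot(inherits(obs, "window_observation"))
  sgn <- ifelse(obs$polarity == "pre_started", 1L, -1L)
  as.integer(ifelse(obs$simultaneous | !obs$t_active, 0L, sgn * params$step))
}

#' Proportional STDP weight modification
#'
#' Weight change proportional to the time difference: with the window
#' duration equal to `a_plus` (= `a_minus`), the down-counter value at
#' observation equals `a_plus - |dt|`, so the change is `+remaining` for
#' pre-before-post and `-remaining` for post-before-pre. Zero outside the
#' window and for simultaneous arrivals.
#'
#' @inheritParams stdp_delta_fixed
#' @return Signed integer weight change.
#' @export
stdp_delta_proportional <- function(obs, params = rule_params()) {
  stopifnot(inherits(obs, "window_observation"))
  sgn <- ifelse(obs$polarity == "pre_started", 1L, -1L)
  as.integer(ifelse(obs$simultaneous | !obs$t_active, 0L,
                    sgn * obs$remaining))
}

#' Reference exponential STDP curve
#'
#' The classical double-exponential STDP modification function:
#' `a_plus * exp(dt / tau_plus)` for `dt < 0` (pre before post),
#' `-a_minus * exp(-dt / tau_minus)` for `dt >= 0`. This continuous rule is
#' the reference used for sign and shape checks only; the hardware-faithful
#' engine never evaluates it.
#'
#' @param dt Signed time difference in ms (negative: pre before post).
#' @param params [rule_params()].
#' @return Real-valued weight change.
#' @export
stdp_delta_exponential <- function(dt, params = rule_params()) {
  if (params$tau_plus <= 0 || params$tau_minus <= 0)
    stop("tau_plus and tau_minus must be positive")
  ifelse(dt < 0, params$a_plus * exp(dt / params$tau_plus),
         -params$a_minus * exp(-dt / params$tau_minus))
}

#' STDDP delay modification
#'
#' Observed at post-synaptic spike arrival (only pre spikes start STDDP
#' windows): `-step` while the window is still active (the delayed spike
#' would come too late), `+step` once it has expired (too early), and no
#' change on the falling-edge tick itself -- the delayed pre-synaptic spike
#' then coincides with the post spike and the delay is perfectly tuned.
#'
#' @param obs A [window_observation()] taken at post spike arrival.
#' @param falling_edge Logical; did the window's falling edge occur this tick?
#' @param params [rule_params()].
#' @return Signed integer delay change.
#' @export
stddp_delta <- function(obs, falling_edge, params = rule_params()) {
  stopifnot(inherits(obs, "window_observation"))
  as.integer(ifelse(falling_edge, 0L,
                    ifelse(obs$t_active, -params$step, params$step)))
}

#' Saturating 4-bit addition
#'
#' Adds a signed change to an unsigned 4-bit value, clamping the result to
#' `[0, 15]`.
#'
#' @param value Integer vector in `[0, 15]`.
#' @param delta Signed integer vector.
#' @return Integer vector in `[0, 15]`.
#' @export
#' @examples
#' saturating_add(15, +1)  # 15
#' saturating_add(0, -3)   # 0
saturating_add <- function(value, delta) {
  value <- as.integer(value)
  if (any(is.na(value)) || any(value < 0L) || any(value > 15L))
    stop("value out of 4-bit range [0, 15]")
  pmin(15L, pmax(0L, value + as.integer(delta)))
}
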