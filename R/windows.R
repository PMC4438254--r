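# Array of per-slot time-window generators. Canonical state is the
# remaining-time down-counter; a window started at tick t with duration d is
# active on ticks t+1 .. t+d-1 and raises its falling edge exactly at t+d.
# The "analog" backend models aVLSI device mismatch as a per-slot
# multiplicative log-normal factor on the window duration, frozen at
# construction; sigma = 0 reproduces the digital model bit-exactly.

POL_PRE <- 0L
POL_POST <- 1L

pol_code <- function(polarity) {
  if (!all(polarity %in% c("pre_started", "post_started")))
    stop("polarity must be 'pre_started' or 'post_started'")
  ifelse(polarity == "pre_started", POL_PRE, POL_POST)
}

#' Create an array of time-window generators
#'
#' @param n_slots Number of generators (one per TM slot); default 8192.
#' @param backend `"digital"` (deterministic down-counter) or `"analog"`
#'   (stochastic-duration variant with frozen per-slot mismatch).
#' @param mismatch_sigma Standard deviation of the log-normal multiplicative
#'   duration mismatch (analog backend); 0 reproduces the digital model.
#' @param mismatch_seed Seed from which the per-slot mismatch factors are
#'   drawn once at construction.
#' @return An environment of class `window_array`.
#' @export
window_array <- function(n_slots = 8192L, backend = c("digital", "analog"),
                         mismatch_sigma = 0, mismatch_seed = 1L) {
  backend <- match.arg(backend)
  if (mismatch_sigma < 0) stop("mismatch_sigma must be non-negative")
  n_slots <- as.integer(n_slots)
  wa <- new.env(parent = emptyenv())
  wa$n_slots <- n_slots
  wa$remaining <- integer(n_slots)
  wa$polarity <- integer(n_slots)
  wa$duration <- integer(n_slots)
  wa$started <- logical(n_slots)
  wa$falling <- integer(0)
  wa$backend <- backend
  wa$sigma <- mismatch_sigma
  wa$factor <- if (backend == "analog") {
    withr::with_seed(as.integer(mismatch_seed),
                     exp(stats::rnorm(n_slots, 0, mismatch_sigma)))
  } else {
    rep(1, n_slots)
  }
  class(wa) <- "window_array"
  wa
}

check_slot <- function(wa, slot) {
  slot <- as.integer(slot)
  if (any(is.na(slot)) || any(slot < 0L) || any(slot >= wa$n_slots))
    stop("slot out of range [0, ", wa$n_slots, ")")
  slot
}

#' Start (or restart) time windows
#'
#' Sets the down-counter of each given slot to the requested duration
#' (digital) or to the mismatch-distorted duration `round(d * factor)`
#' clipped to `[1, 16]` (analog). A restart during an active window simply
#' reloads the counter.
#'
#' @param wa A [window_array()].
#' @param slot Integer vector of slot indices (0-based).
#' @param duration Integer ticks in `[1, 16]` (scalar or per-slot vector).
#' @param polarity `"pre_started"` or `"post_started"`.
#' @return The array, invisibly.
#' @export
start_window <- function(wa, slot, duration, polarity) {
  slot <- check_slot(wa, slot)
  duration <- as.integer(duration)
  if (any(is.na(duration)) || any(duration < 1L) || any(duration > 16L))
    stop("duration out of range [1, 16]")
  eff <- if (wa$backend == "analog") {
    pmin(16L, pmax(1L, as.integer(round(duration * wa$factor[slot + 1L]))))
  } else {
    rep_len(duration, length(slot))
  }
  wa$remaining[slot + 1L] <- eff
  wa$duration[slot + 1L] <- eff
  wa$polarity[slot + 1L] <- rep_len(pol_code(polarity), length(slot))
  wa$started[slot + 1L] <- TRUE
  invisible(wa)
}

#' Advance all time windows by one tick
#'
#' Decrements every active window's counter. A window whose counter drops
#' from 1 to 0 raises a falling-edge flag readable (via [window_observe()])
#' for exactly this tick.
#'
#' @param wa A [window_array()].
#' @return Integer vector of slots (0-based) whose falling edge occurred this
#'   tick, invisibly.
#' @export
windows_tick <- function(wa) {
  act <- which(wa$remaining > 0L)
  if (length(act)) {
    wa$remaining[act] <- wa$remaining[act] - 1L
    wa$falling <- act[wa$remaining[act] == 0L] - 1L
  } else {
    wa$falling <- integer(0)
  }
  invisible(wa$falling)
}

#' Observe one slot's time window
#'
#' Pure read of a single generator's state after the current tick's
#' decrement.
#'
#' @param wa A [window_array()].
#' @param slot Slot index (0-based).
#' @return List with `t_active`, `remaining`, `polarity` (`NA` if the slot
#'   was never started), and `falling_edge`.
#' @export
window_observe <- function(wa, slot) {
  slot <- check_slot(wa, slot)
  stopifnot(length(slot) == 1L)
  i <- slot + 1L
  list(t_active = wa$remaining[i] > 0L,
       remaining = wa$remaining[i],
       polarity = if (!wa$started[i]) NA_character_
                  else c("pre_started", "post_started")[wa$polarity[i] + 1L],
       falling_edge = slot %in% wa$falling)
}
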