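# Synthetic inputs (Poisson trains, paired-pulse protocols) and a minimal
# leaky integrate-and-fire neuron stub for the closed-loop balanced
# excitation experiment.

#' Poisson pre-synaptic spike train
#'
#' Discrete-time Poisson process: an independent Bernoulli trial per 1 ms
#' tick with success probability `rate_hz / 1000` (at most one spike per
#' tick).
#'
#' @param rate_hz Mean rate in spikes per second; `rate_hz / 1000` must not
#'   exceed 1.
#' @param duration_s Duration in seconds.
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return Integer vector of spike ticks (0-based).
#' @export
poisson_train <- function(rate_hz, duration_s, seed = 1L) {
  p <- rate_hz / 1000
  if (p < 0 || p > 1) stop("per-tick spike probability rate_hz/1000 must lie in [0, 1]")
  n <- as.integer(round(duration_s * 1000))
  if (p == 0) return(integer(0))
  withr::with_seed(as.integer(seed), which(stats::runif(n) < p) - 1L)
}

#' Paired-pulse STDDP protocol
#'
#' Per adaptor, one pre-synaptic spike at a fixed random tick inside
#' `pre_range` and one post-synaptic spike at `post_tick`, repeated every
#' `period` ticks; each adaptor's pre tick is frozen across periods. Adaptor
#' `i` uses address `prefix * 8192 + i`.
#'
#' @param n_adaptors Number of adaptors (slots `0 .. n_adaptors - 1`).
#' @param period Period in ticks; default 32.
#' @param post_tick Post spike tick within the period; default 16.
#' @param pre_range Length-2 integer range for the random pre tick; default
#'   `c(1, 15)`.
#' @param n_periods How many periods to emit.
#' @param seed Seed freezing the per-adaptor pre ticks.
#' @param prefix DA prefix of all adaptors; default 0.
#' @return Event `data.frame` sorted by tick, with the per-adaptor pre ticks
#'   in attribute `"pre_ticks"`.
#' @export
paired_pulse_protocol <- function(n_adaptors = 128L, period = 32L,
                                  post_tick = 16L, pre_range = c(1L, 15L),
                                  n_periods = 15L, seed = 1L, prefix = 0L) {
  period <- as.integer(period)
  post_tick <- as.integer(post_tick)
  pre_range <- as.integer(pre_range)
  if (pre_range[1L] < 1L || pre_range[2L] >= period || pre_range[1L] > pre_range[2L])
    stop("pre_range must lie within [1, period)")
  if (post_tick < 0L || post_tick >= period) stop("post_tick must lie in [0, period)")
  pre_ticks <- withr::with_seed(as.integer(seed),
    sample(seq(pre_range[1L], pre_range[2L]), n_adaptors, replace = TRUE))
  addr <- as.integer(prefix) * N_SLOTS + (seq_len(n_adaptors) - 1L)
  per <- rep((seq_len(n_periods) - 1L) * period, each = n_adaptors)
  ev <- data.frame(
    tick = c(per + rep(pre_ticks, n_periods), per + post_tick),
    kind = rep(c("pre", "post"), each = n_adaptors * n_periods),
    address = rep(addr, 2L * n_periods),
    weight = NA_integer_, stringsAsFactors = FALSE)
  ev <- ev[order(ev$tick), , drop = FALSE]
  rownames(ev) <- NULL
  ev <- validate_events(ev)
  attr(ev, "pre_ticks") <- pre_ticks
  ev
}

#' Leaky integrate-and-fire neuron stub
#'
#' Minimal discrete-time LIF used as the shared post-synaptic neuron of the
#' balanced excitation experiment. Post-synaptic currents sum linearly: the
#' per-tick input is the summed weight of the arriving weighted spikes, added
#' to an exponentially leaking membrane value. The neuron fires when the
#' membrane reaches threshold and then resets.
#'
#' The defaults are calibrated once against the reference operating point of
#' the balanced excitation experiment: with 1024 inputs at mid-range weights,
#' a 10 Hz input rate yields a post rate in the tens of Hz (and roughly
#' 2.5x that at 20 Hz), keeping the post-spike interval above the 16 ms
#' plasticity window.
#'
#' @param tau_ms Membrane leak time constant in ticks; must be positive.
#' @param threshold Firing threshold in summed-weight units.
#' @param reset Post-spike reset value.
#' @return An environment of class `lif_neuron`.
#' @export
lif_neuron <- function(tau_ms = 60, threshold = 2.8 * 1024, reset = 0) {
  if (tau_ms <= 0) stop("tau_ms must be positive")
  nr <- new.env(parent = emptyenv())
  nr$decay <- exp(-1 / tau_ms)
  nr$tau_ms <- tau_ms
  nr$threshold <- threshold
  nr$reset <- reset
  nr$v <- 0
  class(nr) <- "lif_neuron"
  nr
}

#' Advance the neuron stub one tick
#'
#' @param neuron A [lif_neuron()].
#' @param input Summed weighted input of the tick.
#' @return `TRUE` iff the neuron fired this tick (its spike is the
#'   post-synaptic spike fed back to all connected adaptors in the same
#'   tick).
#' @export
neuron_step <- function(neuron, input) {
  v <- neuron$v * neuron$decay + input
  fired <- v >= neuron$threshold
  neuron$v <- if (fired) neuron$reset else v
  fired
}
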