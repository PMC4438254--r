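# Experiment drivers: balanced excitation (competitive STDP with a shared
# post-synaptic neuron), dynamic-assignment validation, polychronization via
# STDDP, and the architecture's capacity arithmetic.

#' Quantify the strong/weak split of a weight distribution
#'
#' Fractions of weights in the weak (`<= 3`), middle (`4 .. 11`) and strong
#' (`>= 12`) quartiles of the 4-bit range. The quartile cutoffs quantify the
#' "bimodal distribution of strong and weak weights" and are constants of
#' this package, not measured values.
#'
#' @param weights Integer vector in `[0, 15]`.
#' @return Named numeric vector `c(low, middle, high)` summing to 1.
#' @export
bimodality_fractions <- function(weights) {
  weights <- as.integer(weights)
  if (any(weights < 0L) || any(weights > 15L))
    stop("weights out of [0, 15]")
  n <- length(weights)
  c(low = sum(weights <= 3L) / n,
    middle = sum(weights > 3L & weights < 12L) / n,
    high = sum(weights >= 12L) / n)
}

#' Histogram of 4-bit weights
#'
#' @param weights Integer vector in `[0, 15]`.
#' @return List with `counts` (named, one bin per value 0..15), `fractions`
#'   (see [bimodality_fractions()]) and `n`.
#' @export
weight_histogram <- function(weights) {
  weights <- as.integer(weights)
  if (any(weights < 0L) || any(weights > 15L))
    stop("weights out of [0, 15]")
  counts <- tabulate(weights + 1L, nbins = 16L)
  names(counts) <- 0:15
  list(counts = counts, fractions = bimodality_fractions(weights),
       n = length(weights))
}

# Closed loop shared by the balanced-excitation and DA-validation drivers:
# n Poisson sources -> n STDP adaptors -> one LIF neuron whose firing is the
# shared post-synaptic spike, fed back within the same tick. The per-tick
# drive equals the summed cached weights of the spiking slots, which is
# identical to the engine's emissions while every slot stays assigned (true
# here: all pre spikes carry the run's own prefix).
balanced_core <- function(aa, n_adaptors, prefix, rate_hz, n_ticks, seed,
                          neuron) {
  p <- rate_hz / 1000
  if (p > 1) stop("rate_hz/1000 must not exceed 1")
  draws <- withr::with_seed(as.integer(seed), {
    list(w0 = sample(0:15, n_adaptors, replace = TRUE),
         spikes = matrix(stats::runif(n_ticks * n_adaptors) < p,
                         nrow = n_ticks))
  })
  slots <- seq_len(n_adaptors) - 1L
  init_assign(aa, slots, prefix, draws$w0)
  fires <- 0L
  for (t in seq_len(n_ticks) - 1L) {
    ps <- slots[draws$spikes[t + 1L, ]]
    drive <- sum(aa$cache[ps + 1L])
    fired <- neuron_step(neuron, drive)
    if (fired) fires <- fires + 1L
    step_stdp(aa, t, ps, rep(prefix, length(ps)),
              if (fired) slots else integer(0))
  }
  list(weights = aa$cache[slots + 1L], post_spikes = fires)
}

derived_seeds <- function(seed) {
  seed <- as.integer(seed)
  list(lfsr = seed %% 65535L + 1L, threshold = seed, mismatch = seed + 1L)
}

#' Balanced excitation experiment
#'
#' A single post-synaptic neuron driven by `n_adaptors` STDP adaptors, each
#' fed an independent Poisson pre-synaptic train of the same rate; the
#' neuron's spikes are the shared post-synaptic input fed back to every
#' adaptor. Initial weights are uniform integers on `[0, 15]`. Competitive
#' STDP drives the weights to a bimodal strong/weak distribution.
#'
#' @param n_adaptors Number of adaptors; default 1024.
#' @param rate_hz Poisson input rate (10 or 20 Hz in the reference protocol).
#' @param duration_s Simulated duration; default 1.25 s.
#' @param rule,window_backend,mismatch_sigma Engine configuration.
#' @param seed Seed for initial weights and input trains (matched-seed runs
#'   at different rates share initial weights and thinned spike trains).
#' @param prefix DA prefix of all adaptors; default 0.
#' @param neuron Optional [lif_neuron()]; the default threshold scales with
#'   the fan-in (`2.8 * n_adaptors`) so the post rate lands in the tens of
#'   Hz for mid-range weights.
#' @return List with `weights`, `histogram` (see [weight_histogram()]),
#'   `fractions`, `post_rate_hz` and `post_spikes`.
#' @export
run_balanced_excitation <- function(n_adaptors = 1024L, rate_hz = 10,
                                    duration_s = 1.25,
                                    rule = c("proportional", "fixed"),
                                    window_backend = c("digital", "analog"),
                                    mismatch_sigma = 0, seed = 1L,
                                    prefix = 0L, neuron = NULL) {
  rule <- match.arg(rule)
  window_backend <- match.arg(window_backend)
  sd <- derived_seeds(seed)
  aa <- adaptor_array("stdp", rule, window_backend,
                      mismatch_sigma = mismatch_sigma,
                      mismatch_seed = sd$mismatch, lfsr_seed = sd$lfsr,
                      threshold_seed = sd$threshold)
  if (is.null(neuron)) neuron <- lif_neuron(threshold = 2.8 * n_adaptors)
  n_ticks <- as.integer(round(duration_s * 1000))
  res <- balanced_core(aa, as.integer(n_adaptors), as.integer(prefix),
                       rate_hz, n_ticks, seed, neuron)
  hist <- weight_histogram(res$weights)
  list(weights = res$weights, histogram = hist, fractions = hist$fractions,
       post_spikes = res$post_spikes,
       post_rate_hz = res$post_spikes / duration_s)
}

#' Dynamic-assignment validation experiment
#'
#' Reuses the same `n_tm` TM slots for `n_runs` sequential balanced
#' excitation runs, each run assigning the slots a distinct DA prefix
#' (`0, prefix_step, 2 * prefix_step, ...`). Weights persist in the Master
#' RAM under each run's own addresses, so later runs must leave earlier
#' runs' entries untouched.
#'
#' @param n_tm TM slots reused per run; default 128.
#' @param n_runs Number of runs; default 16.
#' @param rate_hz Poisson input rate; default 20 Hz.
#' @param duration_s Per-run duration; default 1.25 s.
#' @param prefix_step DA prefix increment between runs; default 512 (0x200).
#' @param window_backend Window generator backend.
#' @param seed Base seed; run `r` uses `seed + r - 1`.
#' @return List with `counts` (runs x 16 histogram matrix), `fractions`
#'   (runs x 3), `mean_counts`, `sd_counts` (per-bin across-run statistics),
#'   `prefixes` and `masters` (Master RAM snapshot after each run).
#' @export
run_da_validation <- function(n_tm = 128L, n_runs = 16L, rate_hz = 20,
                              duration_s = 1.25, prefix_step = 512L,
                              window_backend = c("digital", "analog"),
                              seed = 1L) {
  window_backend <- match.arg(window_backend)
  prefixes <- (seq_len(n_runs) - 1L) * as.integer(prefix_step)
  if (any(prefixes >= N_SLOTS))
    stop("prefix overflow: n_runs * prefix_step exceeds the 13-bit space")
  sd <- derived_seeds(seed)
  aa <- adaptor_array("stdp", "proportional", window_backend,
                      lfsr_seed = sd$lfsr, threshold_seed = sd$threshold,
                      mismatch_seed = sd$mismatch)
  n_ticks <- as.integer(round(duration_s * 1000))
  counts <- matrix(0L, n_runs, 16L, dimnames = list(NULL, 0:15))
  fracs <- matrix(0, n_runs, 3L, dimnames = list(NULL, c("low", "middle", "high")))
  masters <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    neuron <- lif_neuron(threshold = 2.8 * n_tm)
    res <- balanced_core(aa, as.integer(n_tm), prefixes[r], rate_hz, n_ticks,
                         as.integer(seed) + r - 1L, neuron)
    h <- weight_histogram(res$weights)
    counts[r, ] <- h$counts
    fracs[r, ] <- h$fractions
    masters[[r]] <- master_snapshot(aa$master)
  }
  list(counts = counts, fractions = fracs,
       mean_counts = colMeans(counts), sd_counts = apply(counts, 2, stats::sd),
       prefixes = prefixes, masters = masters)
}

#' Polychronization experiment (STDDP)
#'
#' Runs the paired-pulse protocol through an STDDP array: all delays start at
#' zero and are tuned, one step per period, until every delayed pre-synaptic
#' spike coincides with the shared post-spike tick.
#'
#' @param n_adaptors Number of adaptors; default 128.
#' @param n_periods Periods to simulate; default 16 (15 adaptation periods
#'   plus one observation period).
#' @param period,post_tick,pre_range Protocol parameters (see
#'   [paired_pulse_protocol()]).
#' @param window_backend,mismatch_sigma Window generator configuration.
#' @param seed Protocol / mismatch seed.
#' @return List with `coincident` (per-period count of adaptors whose delayed
#'   pre spike lands exactly on the post tick), `delay_errors` (final-period
#'   emission tick minus post tick, per adaptor; `NA` if no emission),
#'   `delays` (final stored delays), `pre_ticks` and `discarded`.
#' @export
run_polychronization <- function(n_adaptors = 128L, n_periods = 16L,
                                 period = 32L, post_tick = 16L,
                                 pre_range = c(1L, 15L),
                                 window_backend = c("digital", "analog"),
                                 mismatch_sigma = 0, seed = 1L) {
  window_backend <- match.arg(window_backend)
  ev <- paired_pulse_protocol(n_adaptors, period, post_tick, pre_range,
                              n_periods, seed)
  sd <- derived_seeds(seed)
  aa <- adaptor_array("stddp", window_backend = window_backend,
                      mismatch_sigma = mismatch_sigma,
                      mismatch_seed = sd$mismatch)
  slots <- seq_len(n_adaptors) - 1L
  init_assign(aa, slots, 0L, 0L)
  res <- run_array(aa, ev, until = as.integer(n_periods) * period - 1L)
  em_slot <- res$emissions$address %% N_SLOTS
  coincident <- integer(n_periods)
  for (k in seq_len(n_periods)) {
    tk <- (k - 1L) * period + post_tick
    coincident[k] <- length(unique(em_slot[res$emissions$tick == tk]))
  }
  last0 <- (n_periods - 1L) * period
  tk <- last0 + post_tick
  delay_errors <- rep(NA_integer_, n_adaptors)
  in_last <- res$emissions$tick >= last0 & res$emissions$tick < last0 + period
  delay_errors[em_slot[in_last] + 1L] <- res$emissions$tick[in_last] - tk
  list(coincident = coincident, delay_errors = delay_errors,
       delays = aa$cache[slots + 1L], pre_ticks = attr(ev, "pre_ticks"),
       discarded = res$discarded)
}

#' Capacity arithmetic of the time-multiplexed architecture
#'
#' How many virtual adaptors one physical circuit supports: `tm_count`
#' time-multiplexed slots per physical adaptor (update period over clock
#' period), `total_da` dynamically-assigned adaptors (slots times DA adaptors
#' per slot), the maximum sustainable active fraction of those synapses, and
#' the maximum event (memory update) rate given the per-slot cycle budget.
#'
#' @param clock_hz System clock; default 200 MHz.
#' @param update_period_s Per-slot update period; default 1 ms.
#' @param slot_cycles Clock cycles per slot; default 25.
#' @param n_slots TM slots; default 8192.
#' @param da_per_slot DA adaptors multiplexed per slot; default 8192.
#' @return List with `tm_count`, `total_da`, `max_active_rate` (fraction),
#'   `max_active_rate_pct` and `max_event_rate_hz`.
#' @export
#' @examples
#' capacity_report()  # 200000 TM, 64M DA, 1/8192, 8 MHz
capacity_report <- function(clock_hz = 200e6, update_period_s = 1e-3,
                            slot_cycles = 25, n_slots = 8192,
                            da_per_slot = 8192) {
  vals <- c(clock_hz, update_period_s, slot_cycles, n_slots, da_per_slot)
  if (any(vals <= 0)) stop("all capacity parameters must be positive")
  list(tm_count = update_period_s * clock_hz,
       total_da = n_slots * da_per_slot,
       max_active_rate = 1 / da_per_slot,
       max_active_rate_pct = 100 / da_per_slot,
       max_event_rate_hz = clock_hz / slot_cycles)
}
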