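# The time-multiplexed engine. Each simulated tick: advance every slot's time
# window, then process the tick's aligned pre/post spikes slot by slot in
# ascending slot order (assignment -> window observation -> modification /
# emission -> window start or restart). Pipeline clock cycles are not
# modeled; their only functional consequences -- write ordering and last-wins
# collisions -- are preserved explicitly.

#' Create a time-multiplexed adaptor array
#'
#' One array instance hosts `n_slots` time-multiplexed plasticity adaptors of
#' a single mode (STDP weight adaptation or STDDP delay adaptation), each
#' dynamically assignable to any of 8192 DA adaptors sharing its slot index.
#'
#' @param mode `"stdp"` or `"stddp"`.
#' @param rule STDP modification rule: `"proportional"` (change by the
#'   window counter value) or `"fixed"` (change by `step`).
#' @param window_backend `"digital"` or `"analog"` (see [window_array()]).
#' @param n_slots Number of TM slots; default 8192.
#' @param params [rule_params()].
#' @param stddp_weight Fixed, configurable weight carried by delayed
#'   pre-synaptic spikes (STDDP mode).
#' @param stddp_pre_restart Should a pre spike arriving during an active
#'   STDDP window restart it? Default `TRUE`.
#' @param stdp_restart_on_mod Should the spike that triggers an STDP weight
#'   modification also restart the window with its own polarity? Default
#'   `FALSE`: each incoming spike either starts/restarts a time window (same
#'   polarity, or inactive window) or performs a modification, never both,
#'   so an active window can drive several modifications before it expires.
#' @param mismatch_sigma,mismatch_seed Analog-backend mismatch model.
#' @param lfsr_seed Seed of the bistable-expansion LFSR.
#' @param threshold_seed Seed of the re-binarization threshold stream.
#' @return An environment of class `adaptor_array`.
#' @export
adaptor_array <- function(mode = c("stdp", "stddp"),
                          rule = c("proportional", "fixed"),
                          window_backend = c("digital", "analog"),
                          n_slots = 8192L,
                          params = rule_params(),
                          stddp_weight = 15L,
                          stddp_pre_restart = TRUE,
                          stdp_restart_on_mod = FALSE,
                          mismatch_sigma = 0,
                          mismatch_seed = 1L,
                          lfsr_seed = 0xACE1L,
                          threshold_seed = 1L) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  window_backend <- match.arg(window_backend)
  n_slots <- as.integer(n_slots)
  if (n_slots < 1L || n_slots > N_SLOTS) stop("n_slots must lie in [1, 8192]")
  aa <- new.env(parent = emptyenv())
  aa$mode <- mode
  aa$rule <- rule
  aa$params <- params
  aa$n_slots <- n_slots
  aa$windows <- window_array(n_slots, window_backend,
                             mismatch_sigma, mismatch_seed)
  aa$cache <- integer(n_slots)
  aa$prefix <- integer(n_slots)
  aa$assigned <- logical(n_slots)
  aa$master <- master_new()
  aa$lfsr <- lfsr_new(lfsr_seed)
  aa$thr <- threshold_rng(threshold_seed)
  aa$stddp_weight <- as.integer(stddp_weight)
  aa$stddp_pre_restart <- isTRUE(stddp_pre_restart)
  aa$stdp_restart_on_mod <- isTRUE(stdp_restart_on_mod)
  aa$discarded <- 0L
  class(aa) <- "adaptor_array"
  aa
}

#' Pre-assign slots with explicit initial values
#'
#' Experiment setup helper: marks slots as assigned to a DA prefix with given
#' initial cache values (weights or delays), without touching the Master RAM
#' -- like the hardware, initial working values become persistent only on
#' their first committed modification.
#'
#' @param aa An [adaptor_array()].
#' @param slots Integer vector of slot indices (0-based).
#' @param prefix Scalar 13-bit DA prefix (or per-slot vector).
#' @param values Initial 4-bit values, recycled to `length(slots)`.
#' @return The array, invisibly.
#' @export
init_assign <- function(aa, slots, prefix, values) {
  slots <- as.integer(slots)
  if (any(slots < 0L) || any(slots >= aa$n_slots)) stop("slot out of range")
  prefix <- rep_len(as.integer(prefix), length(slots))
  if (any(prefix < 0L) || any(prefix >= N_SLOTS)) stop("prefix out of range")
  values <- rep_len(as.integer(values), length(slots))
  if (any(values < 0L) || any(values > 15L)) stop("values out of [0, 15]")
  aa$cache[slots + 1L] <- values
  aa$prefix[slots + 1L] <- prefix
  aa$assigned[slots + 1L] <- TRUE
  invisible(aa)
}

#' Read the Local cache
#'
#' @param aa An [adaptor_array()].
#' @return A `data.frame` with one row per slot: `slot`, `assigned`,
#'   `prefix`, `value` (the cached 4-bit weight or delay).
#' @export
local_state <- function(aa) {
  data.frame(slot = seq_len(aa$n_slots) - 1L, assigned = aa$assigned,
             prefix = aa$prefix, value = aa$cache)
}

# STDP delta for an engine modification: window always active, polarity is
# the polarity of the observed (opposite-started) window.
rule_delta <- function(aa, window_polarity, remaining) {
  obs <- window_observation(rep(TRUE, length(remaining)), window_polarity,
                            remaining, FALSE)
  if (aa$rule == "fixed") stdp_delta_fixed(obs, aa$params)
  else stdp_delta_proportional(obs, aa$params)
}

step_stdp <- function(aa, tick, ps, ppre, qs) {
  wa <- aa$windows
  windows_tick(wa)
  emit_addr <- integer(0)
  emit_w <- integer(0)
  if (length(ps)) {
    o <- order(ps)
    ps <- ps[o]; ppre <- ppre[o]
    st <- ps + 1L
    miss <- which(!aa$assigned[st] | aa$prefix[st] != ppre)
    for (i in miss) assign_slot(aa, ps[i], ppre[i])
    emit_addr <- ppre * N_SLOTS + ps
    emit_w <- aa$cache[st]           # post-assignment, pre-modification
  }
  qs <- sort(qs)
  sim <- ps %in% qs
  pre_only <- ps[!sim]
  post_only <- qs[!(qs %in% ps)]
  # observe before any start/restart of this tick
  mods_slot <- integer(0)
  mods_delta <- integer(0)
  if (length(pre_only)) {
    r <- wa$remaining[pre_only + 1L]
    hit <- r > 0L & wa$polarity[pre_only + 1L] == POL_POST
    if (any(hit)) {
      mods_slot <- c(mods_slot, pre_only[hit])
      mods_delta <- c(mods_delta, rule_delta(aa, "post_started", r[hit]))
    }
  }
  if (length(post_only)) {
    r <- wa$remaining[post_only + 1L]
    hit <- r > 0L & wa$polarity[post_only + 1L] == POL_PRE
    if (any(hit)) {
      mods_slot <- c(mods_slot, post_only[hit])
      mods_delta <- c(mods_delta, rule_delta(aa, "pre_started", r[hit]))
    }
  }
  if (length(mods_slot)) {
    for (i in order(mods_slot)) {
      s <- mods_slot[i]
      commit_modification(aa, s,
                          saturating_add(aa$cache[s + 1L], mods_delta[i]))
    }
  }
  start_pre <- ps
  start_post <- post_only
  if (!aa$stdp_restart_on_mod) {
    start_pre <- setdiff(start_pre, mods_slot)
    start_post <- setdiff(start_post, mods_slot)
  }
  dur <- aa$params$window_duration
  if (length(start_pre)) start_window(wa, start_pre, dur, "pre_started")
  if (length(start_post)) start_window(wa, start_post, dur, "post_started")
  list(address = emit_addr, weight = emit_w)
}

step_stddp <- function(aa, tick, ps, ppre, qs) {
  wa <- aa$windows
  fall <- sort(windows_tick(wa))
  emit_addr <- integer(0)
  emit_w <- integer(0)
  if (length(fall)) {
    # delayed pre spikes emitted at the falling edge, fixed configured weight
    emit_addr <- aa$prefix[fall + 1L] * N_SLOTS + fall
    emit_w <- rep(aa$stddp_weight, length(fall))
  }
  if (length(ps)) {
    o <- order(ps)
    ps <- ps[o]; ppre <- ppre[o]
    st <- ps + 1L
    miss <- which(!aa$assigned[st] | aa$prefix[st] != ppre)
    for (i in miss) assign_slot(aa, ps[i], ppre[i])
  }
  if (length(qs)) {
    qs <- sort(qs)
    keep <- aa$assigned[qs + 1L]   # post to a never-assigned slot: no resident
    qs <- qs[keep]
  }
  if (length(qs)) {
    r <- wa$remaining[qs + 1L]
    act <- r > 0L
    fe <- qs %in% fall
    obs <- window_observation(act, "pre_started", r)
    d <- stddp_delta(obs, fe, aa$params)
    for (i in which(d != 0L)) {
      s <- qs[i]
      commit_modification(aa, s, saturating_add(aa$cache[s + 1L], d[i]))
    }
  }
  if (length(ps)) {
    active <- wa$remaining[ps + 1L] > 0L
    tostart <- if (aa$stddp_pre_restart) ps else ps[!active]
    if (length(tostart)) {
      # stored delay 0..15 realizes an emission delay of 1..16 ticks
      start_window(wa, tostart, aa$cache[tostart + 1L] + 1L, "pre_started")
    }
  }
  list(address = emit_addr, weight = emit_w)
}

#' Advance the array by one tick
#'
#' Processes the (already aligned: at most one pre and one post per slot)
#' spikes of one tick and advances every time window. Most callers should use
#' [run_array()]; this entry point exists for closed-loop drivers that must
#' react to emissions within the tick.
#'
#' @param aa An [adaptor_array()].
#' @param tick Current tick.
#' @param pre_slots,pre_prefix Slots (0-based) and 13-bit prefixes of the
#'   tick's pre-synaptic spikes.
#' @param post_slots Slots of the tick's post-synaptic spikes (the prefix of
#'   a post spike is not stored; a mismatching post acts on the resident DA
#'   adaptor -- the documented collision hazard).
#' @return List with integer vectors `address` and `weight`: the weighted or
#'   delayed pre-synaptic spikes emitted this tick.
#' @export
array_step <- function(aa, tick, pre_slots = integer(0),
                       pre_prefix = integer(0), post_slots = integer(0)) {
  pre_slots <- as.integer(pre_slots)
  pre_prefix <- as.integer(pre_prefix)
  post_slots <- as.integer(post_slots)
  if (length(pre_slots) != length(pre_prefix))
    stop("pre_slots and pre_prefix must have equal length")
  if (anyDuplicated(pre_slots) || anyDuplicated(post_slots))
    stop("array_step expects aligned events: at most one per slot and kind")
  if (aa$mode == "stdp") step_stdp(aa, tick, pre_slots, pre_prefix, post_slots)
  else step_stddp(aa, tick, pre_slots, pre_prefix, post_slots)
}

#' Run the array over an event trace
#'
#' Per tick: align the tick's events (last-wins collision resolution), sweep
#' the slots, collect emitted weighted/delayed pre-synaptic spikes. The run
#' is deterministic given the configuration and seeds.
#'
#' @param aa An [adaptor_array()].
#' @param events Event `data.frame` (see [spike_events()]), sorted by tick.
#' @param until Last tick to simulate; defaults to the last event tick plus
#'   one full window duration so pending STDDP emissions drain.
#' @return List with `emissions` (event `data.frame` of weighted/delayed pre
#'   spikes), `master` (Master RAM snapshot), `local` (Local cache state) and
#'   `discarded` (collision-discarded event count).
#' @export
run_array <- function(aa, events, until = NULL) {
  events <- validate_events(events)
  if (nrow(events) && is.unsorted(events$tick))
    stop("input events must be sorted by tick")
  tmax <- if (nrow(events)) max(events$tick) else 0L
  if (is.null(until)) until <- tmax + aa$params$window_duration + 1L
  until <- as.integer(until)
  idx <- if (nrow(events)) split(seq_len(nrow(events)), events$tick) else list()
  out_tick <- vector("list", until + 1L)
  for (t in 0:until) {
    rows <- idx[[as.character(t)]]
    ps <- integer(0); ppre <- integer(0); qs <- integer(0)
    if (!is.null(rows)) {
      b <- align_tick_events(events[rows, , drop = FALSE], t)
      aa$discarded <- aa$discarded + b$discarded
      if (nrow(b$pre)) {
        sp <- split_address(b$pre$address)
        ps <- sp$slot; ppre <- sp$prefix
      }
      if (nrow(b$post)) qs <- split_address(b$post$address)$slot
    }
    em <- array_step(aa, t, ps, ppre, qs)
    if (length(em$address))
      out_tick[[t + 1L]] <- cbind(t, em$address, em$weight)
  }
  got <- !vapply(out_tick, is.null, logical(1))
  emissions <- if (any(got)) {
    m <- do.call(rbind, out_tick[got])
    data.frame(tick = as.integer(m[, 1L]), kind = "pre",
               address = as.integer(m[, 2L]), weight = as.integer(m[, 3L]),
               stringsAsFactors = FALSE)
  } else {
    spike_events(integer(0), character(0), integer(0))
  }
  list(emissions = emissions, master = master_snapshot(aa$master),
       local = local_state(aa), discarded = aa$discarded)
}
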