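# Straight-line per-adaptor replay: no time multiplexing, no cache, no LFSR.
# Independent reference for the engine's final weights/delays on
# single-adaptor-per-slot, collision-free traces.

# events: data.frame(tick, kind) for ONE adaptor, sorted by tick.
oracle_stdp_replay <- function(events, init_w, rule = "proportional",
                               params = rule_params(),
                               restart_on_mod = FALSE) {
  w <- as.integer(init_w)
  ws <- -Inf; wd <- 0L; wp <- NA_character_
  for (t in unique(events$tick)) {
    kinds <- events$kind[events$tick == t]
    active <- is.finite(ws) && (t - ws) < wd
    if (all(c("pre", "post") %in% kinds)) {      # simultaneous: no mod
      ws <- t; wd <- params$window_duration; wp <- "pre"
    } else {
      k <- kinds[1L]
      if (!active) {
        ws <- t; wd <- params$window_duration; wp <- k
      } else if (wp == k) {
        ws <- t; wd <- params$window_duration    # same-polarity restart
      } else {
        rem <- wd - (t - ws)
        mag <- if (rule == "fixed") params$step else rem
        delta <- if (k == "post") mag else -mag  # k opposite to window pol
        w <- min(15L, max(0L, w + delta))
        if (restart_on_mod) {
          ws <- t; wd <- params$window_duration; wp <- k
        }
      }
    }
  }
  w
}

oracle_stddp_replay <- function(events, init_d, params = rule_params(),
                                pre_restart = TRUE) {
  d <- as.integer(init_d)
  ws <- -Inf; wd <- 0L
  for (t in unique(events$tick)) {
    kinds <- events$kind[events$tick == t]
    if ("post" %in% kinds) {                     # observe pre-restart window
      el <- t - ws
      if (!is.finite(ws) || el > wd) d <- min(15L, d + params$step)
      else if (el < wd) d <- max(0L, d - params$step)
      # el == wd: falling edge, perfectly tuned, no change
    }
    if ("pre" %in% kinds) {
      active <- is.finite(ws) && (t - ws) < wd
      if (!active || pre_restart) {
        ws <- t; wd <- d + 1L
      }
    }
  }
  d
}

# One random collision-free trace over k distinct slots.
random_single_adaptor_trace <- function(k = 6L, n_ticks = 50L,
                                        p_pre = 0.12, p_post = 0.08) {
  slots <- sample(0:8191, k)
  prefixes <- sample(0:8191, k, replace = TRUE)
  rows <- list()
  for (i in seq_len(k)) {
    pre_t <- which(runif(n_ticks) < p_pre) - 1L
    post_t <- which(runif(n_ticks) < p_post) - 1L
    addr <- prefixes[i] * 8192L + slots[i]
    rows[[i]] <- data.frame(
      tick = c(pre_t, post_t),
      kind = rep(c("pre", "post"), c(length(pre_t), length(post_t))),
      address = addr, weight = NA_integer_, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$tick), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, slots = slots, prefixes = prefixes,
       init = sample(0:15, k, replace = TRUE))
}

# Run engine + oracle on one trace and return both final value vectors.
engine_vs_oracle <- function(tr, mode, rule = "proportional") {
  aa <- adaptor_array(mode, rule)
  init_assign(aa, tr$slots, tr$prefixes, tr$init)
  run_array(aa, tr$events)
  eng <- aa$cache[tr$slots + 1L]
  orc <- vapply(seq_along(tr$slots), function(i) {
    sub <- tr$events[tr$events$address %/% 8192L == tr$prefixes[i] &
                     tr$events$address %% 8192L == tr$slots[i], , drop = FALSE]
    if (mode == "stdp") oracle_stdp_replay(sub, tr$init[i], rule)
    else oracle_stddp_replay(sub, tr$init[i])
  }, integer(1))
  list(engine = eng, oracle = orc)
}
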