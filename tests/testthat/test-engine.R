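test_that("a pre spike emits a weighted spike at the composed DA address", {
  aa <- adaptor_array("stdp")
  init_assign(aa, 3L, 9L, 9L)
  r <- run_array(aa, spike_events(2, "pre", 9 * 8192 + 3))
  expect_equal(nrow(r$emissions), 1L)
  expect_equal(r$emissions$tick, 2)
  expect_equal(r$emissions$address, 9 * 8192 + 3)
  expect_equal(r$emissions$weight, 9)
  o <- window_observe(aa$windows, 3)
  expect_equal(o$polarity, "pre_started")
})

test_that("post arriving inside a pre-started window potentiates by the counter value", {
  aa <- adaptor_array("stdp", rule = "proportional")
  init_assign(aa, 0L, 0L, 1L)
  r <- run_array(aa, spike_events(c(10, 14), c("pre", "post"), c(0, 0)))
  expect_equal(aa$cache[1], 1L + 12L)       # remaining 16 - 4 = 12
  expect_equal(r$master$value, 1L)          # 13 > 11 >= threshold
  expect_equal(r$master$address, 0L)
})

test_that("a second same-kind spike restarts the window without modification", {
  aa <- adaptor_array("stdp")
  init_assign(aa, 0L, 0L, 6L)
  r <- run_array(aa, spike_events(c(5, 8), c("pre", "pre"), c(0, 0)))
  expect_equal(aa$cache[1], 6L)             # unmodified
  expect_equal(nrow(r$emissions), 2L)       # both pres emit weighted spikes
  expect_equal(nrow(r$master), 0L)          # nothing committed
})

test_that("simultaneous pre and post perform no modification but the pre still emits", {
  aa <- adaptor_array("stdp")
  init_assign(aa, 0L, 0L, 7L)
  r <- run_array(aa, spike_events(c(3, 3), c("pre", "post"), c(0, 0)))
  expect_equal(aa$cache[1], 7L)
  expect_equal(nrow(r$emissions), 1L)
  expect_equal(window_observe(aa$windows, 0)$polarity, "pre_started")
})

test_that("one window can drive several modifications before it expires", {
  # post starts a window; two pres inside it are each depressed (fixed rule)
  aa <- adaptor_array("stdp", rule = "fixed")
  init_assign(aa, 0L, 0L, 8L)
  run_array(aa, spike_events(c(2, 5, 9), c("post", "pre", "pre"), c(0, 0, 0)))
  expect_equal(aa$cache[1], 6L)
})

test_that("delayed pre spikes realize stored delay + 1 ticks and adapt by one step", {
  aa <- adaptor_array("stddp")
  init_assign(aa, 0L, 0L, 0L)
  r <- run_array(aa, spike_events(5, "pre", 0))
  expect_equal(r$emissions$tick, 6)         # stored 0 -> 1 tick
  expect_equal(r$emissions$weight, 15)      # fixed configurable weight

  aa <- adaptor_array("stddp", stddp_weight = 4L)
  init_assign(aa, 0L, 0L, 5L)
  # post at tick 8 while the window (duration 6, started at 5) is active
  r <- run_array(aa, spike_events(c(5, 8), c("pre", "post"), c(0, 0)))
  expect_equal(aa$cache[1], 4L)
  expect_equal(r$master$value, 4L)          # write-through of the new delay
  expect_equal(r$emissions$weight, 4)

  # post exactly on the falling edge: no adaptation, spike emitted same tick
  aa <- adaptor_array("stddp")
  init_assign(aa, 0L, 0L, 2L)
  r <- run_array(aa, spike_events(c(5, 8), c("pre", "post"), c(0, 0)))
  expect_equal(r$emissions$tick, 8)
  expect_equal(aa$cache[1], 2L)
  expect_equal(nrow(r$master), 0L)
})

test_that("a mismatching post spike modifies the resident adaptor (documented hazard)", {
  aa <- adaptor_array("stdp", rule = "fixed")
  init_assign(aa, 0L, 3L, 8L)               # resident DA prefix 3
  run_array(aa, spike_events(c(1, 4), c("pre", "post"),
                             c(3 * 8192, 7 * 8192)))  # post carries prefix 7
  expect_equal(aa$cache[1], 9L)             # modified anyway
  expect_equal(aa$prefix[1], 3L)            # prefix not stored for posts
})

test_that("empty and unsorted inputs are handled as specified", {
  aa <- adaptor_array("stdp")
  r <- run_array(aa, spike_events(integer(0), character(0), integer(0)))
  expect_equal(nrow(r$emissions), 0L)
  expect_equal(nrow(r$master), 0L)
  expect_false(any(aa$assigned))
  expect_error(run_array(aa, spike_events(c(5, 2), c("pre", "pre"), c(0, 1))),
               "sorted")
})

test_that("the engine matches the straight-line replay on random collision-free traces", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      tr <- random_single_adaptor_trace()
      for (cfg in list(c("stdp", "proportional"), c("stdp", "fixed"),
                       c("stddp", "proportional"))) {
        r <- engine_vs_oracle(tr, cfg[1], cfg[2])
        expect_identical(r$engine, r$oracle)
        expect_true(all(r$engine >= 0 & r$engine <= 15))
      }
    }
  })
})

test_that("full runs are deterministic under fixed seeds", {
  run_once <- function() {
    withr::with_seed(77, tr <- random_single_adaptor_trace(k = 10, n_ticks = 80))
    aa <- adaptor_array("stdp", lfsr_seed = 55, threshold_seed = 66)
    r <- run_array(aa, tr$events)   # no init: misses exercise the LFSR path
    list(m = r$master, w = aa$cache, em = r$emissions)
  }
  expect_identical(run_once(), run_once())
})

test_that("run_array counts collision-discarded events", {
  aa <- adaptor_array("stdp")
  ev <- spike_events(c(0, 0, 0), c("pre", "pre", "post"),
                     c(1 * 8192 + 5, 2 * 8192 + 5, 5))
  r <- run_array(aa, ev)
  expect_equal(r$discarded, 1L)
  expect_equal(aa$prefix[6], 2L)            # last arriving pre won
})
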