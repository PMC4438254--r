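obs <- function(active, pol, rem, sim = FALSE)
  window_observation(active, pol, rem, sim)

test_that("fixed-step rule: +step pre-before-post, -step after, 0 simultaneous/inactive", {
  p <- rule_params()
  expect_equal(stdp_delta_fixed(obs(TRUE, "pre_started", 12), p), 1L)
  expect_equal(stdp_delta_fixed(obs(TRUE, "post_started", 12), p), -1L)
  expect_equal(stdp_delta_fixed(obs(TRUE, "pre_started", 12, sim = TRUE), p), 0L)
  expect_equal(stdp_delta_fixed(obs(FALSE, "pre_started", 0), p), 0L)
  p3 <- rule_params(step = 3L)
  expect_equal(stdp_delta_fixed(obs(TRUE, "post_started", 5), p3), -3L)
})

test_that("proportional rule equals the window counter value, signed by polarity", {
  p <- rule_params()  # window 16 = A+ = A-
  # |dt| = 4: counter remaining 12
  expect_equal(stdp_delta_proportional(obs(TRUE, "pre_started", 16 - 4), p), 12L)
  expect_equal(stdp_delta_proportional(obs(TRUE, "post_started", 16 - 4), p), -12L)
  # |dt| = 16: window just expired
  expect_equal(stdp_delta_proportional(obs(FALSE, "pre_started", 0), p), 0L)
  expect_equal(stdp_delta_proportional(obs(TRUE, "pre_started", 8, sim = TRUE), p), 0L)
})

test_that("reference exponential curve has the classical form", {
  p <- rule_params()
  expect_equal(stdp_delta_exponential(-1e-12, p), 16, tolerance = 1e-9)
  expect_equal(stdp_delta_exponential(-16, p), 16 / exp(1), tolerance = 1e-12)
  expect_equal(stdp_delta_exponential(1e9, p), 0, tolerance = 1e-12)
  expect_lt(stdp_delta_exponential(0, p), 0)  # dt >= 0 is the depression side
  expect_error(stdp_delta_exponential(-1, rule_params(tau_plus = -1)), "positive")
})

test_that("delay rule: -step while active, +step when expired, 0 on falling edge", {
  p <- rule_params()
  expect_equal(stddp_delta(obs(TRUE, "pre_started", 5), FALSE, p), -1L)
  expect_equal(stddp_delta(obs(FALSE, "pre_started", 0), FALSE, p), 1L)
  expect_equal(stddp_delta(obs(FALSE, "pre_started", 0), TRUE, p), 0L)
})

test_that("saturating 4-bit addition clamps to [0, 15]", {
  expect_equal(saturating_add(15, 1), 15L)
  expect_equal(saturating_add(0, -3), 0L)
  expect_equal(saturating_add(7, 12), 15L)
  expect_equal(saturating_add(c(3, 14), c(-5, 4)), c(0L, 15L))
  expect_error(saturating_add(16, 0), "range")
  # repeated +1 from 0 reaches exactly 15 in 15 steps
  w <- 0L
  for (i in 1:15) w <- saturating_add(w, 1L)
  expect_identical(w, 15L)
  expect_identical(saturating_add(w, 1L), 15L)
})

test_that("rules are antisymmetric under polarity swap and agree in sign with the exponential curve", {
  p <- rule_params()
  for (adt in 1:15) {
    o_pre <- obs(TRUE, "pre_started", 16 - adt)
    o_post <- obs(TRUE, "post_started", 16 - adt)
    expect_equal(stdp_delta_fixed(o_pre, p), -stdp_delta_fixed(o_post, p))
    expect_equal(stdp_delta_proportional(o_pre, p),
                 -stdp_delta_proportional(o_post, p))
    # pre_started window observed by the post spike means dt = -adt
    signs <- c(sign(stdp_delta_proportional(o_pre, p)),
               sign(stdp_delta_fixed(o_pre, p)),
               sign(stdp_delta_exponential(-adt, p)))
    expect_true(all(signs == 1))
    expect_equal(sign(stdp_delta_exponential(adt, p)), -1)
  }
  # proportional magnitude strictly decreasing in |dt| inside the window
  mags <- vapply(1:15, function(adt)
    abs(stdp_delta_proportional(obs(TRUE, "pre_started", 16 - adt), p)),
    integer(1))
  expect_true(all(diff(mags) < 0))
})

test_that("window observation enforces the active/remaining invariant", {
  expect_error(window_observation(TRUE, "pre_started", 0), "invariant")
  expect_error(window_observation(FALSE, "pre_started", 3), "invariant")
  expect_error(window_observation(TRUE, "sideways", 3), "polarity")
  expect_error(window_observation(TRUE, "pre_started", 17), "remaining")
})
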