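test_that("LFSR is deterministic and maximal with near-uniform 3-bit output", {
  s1 <- lfsr_new(0xACE1)
  s2 <- lfsr_new(0xACE1)
  for (i in 1:50) {
    a <- lfsr_next(s1); b <- lfsr_next(s2)
    expect_identical(a, b)
    s1 <- a$state; s2 <- b$state
  }
  expect_error(lfsr_new(0), "nonzero")
  expect_error(lfsr_next(0), "nonzero")

  # full period: visits every nonzero 16-bit state exactly once
  seen <- logical(65536)
  counts <- integer(8)
  s <- lfsr_new(1)
  revisit <- FALSE
  for (i in 1:65535) {
    if (seen[s + 1L]) revisit <- TRUE
    seen[s + 1L] <- TRUE
    nx <- lfsr_next(s, 3L)
    counts[nx$value + 1L] <- counts[nx$value + 1L] + 1L
    s <- nx$state
  }
  expect_false(revisit)
  expect_identical(s, lfsr_new(1))          # back to the seed
  expect_equal(sum(seen), 65535L)
  # low 3 bits of a maximal sequence: every value 8192 times except 0 (8191)
  expect_true(all(abs(counts - 65535 / 8) <= 1))
})

test_that("bistable expansion places the stored bit as weight MSB", {
  expect_equal(expand_bistable(1, 0), 8L)
  expect_equal(expand_bistable(0, 7), 7L)
  expect_equal(expand_bistable(1, 7), 15L)
  expect_true(all(expand_bistable(1, 0:7) %in% 8:15))
  expect_true(all(expand_bistable(0, 0:7) %in% 0:7))
  expect_error(expand_bistable(2, 0), "bit")
  expect_error(expand_bistable(0, 8), "range")
})

test_that("bistable encoding is strict > against a threshold in [4, 11]", {
  expect_equal(encode_bistable(12, 11), 1L)
  expect_equal(encode_bistable(4, 4), 0L)
  expect_true(all(encode_bistable(rep(15, 8), 4:11) == 1L))
  expect_true(all(encode_bistable(rep(3, 8), 4:11) == 0L))
  expect_error(encode_bistable(5, 3), "threshold")
  expect_error(encode_bistable(16, 5), "range")
})

test_that("threshold stream is uniform on {4..11} and reproducible", {
  rng <- threshold_rng(123)
  draws <- vapply(1:100000, function(i) threshold_next(rng), integer(1))
  expect_true(all(draws >= 4L & draws <= 11L))
  expect_setequal(unique(draws), 4:11)
  counts <- tabulate(draws - 3L, 8)
  sd3 <- 3 * sqrt(100000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - 100000 / 8) < sd3))
  r1 <- threshold_rng(7); r2 <- threshold_rng(7)
  expect_identical(vapply(1:20, function(i) threshold_next(r1), integer(1)),
                   vapply(1:20, function(i) threshold_next(r2), integer(1)))
})

test_that("slot assignment: miss refills the cache from the Master RAM, hit changes nothing", {
  aa <- adaptor_array("stdp")
  master_set(aa$master, 9 * 8192 + 4, 1L)        # strong bistable weight
  expect_false(assign_slot(aa, 4, 9))            # miss
  expect_true(aa$cache[5] %in% 8:15)
  expect_equal(aa$prefix[5], 9L)

  w <- aa$cache[5]
  master_set(aa$master, 9 * 8192 + 4, 0L)        # external master change
  expect_true(assign_slot(aa, 4, 9))             # hit: cache untouched
  expect_equal(aa$cache[5], w)

  # direct-mapped aliasing: a different prefix fully overwrites the slot
  expect_false(assign_slot(aa, 4, 2))
  expect_equal(aa$prefix[5], 2L)
  expect_true(aa$cache[5] %in% 0:7)              # unwritten master reads 0

  dd <- adaptor_array("stddp")
  master_set(dd$master, 3 * 8192 + 7, 9L)
  assign_slot(dd, 7, 3)
  expect_equal(dd$cache[8], 9L)                  # exact 4-bit copy
})

test_that("commits write through: the Master RAM is never stale", {
  aa <- adaptor_array("stdp")
  init_assign(aa, 0L, 5L, 7L)
  commit_modification(aa, 0, 12L)                # 12 > 11 >= any threshold
  expect_equal(master_get(aa$master, 5 * 8192), 1L)
  commit_modification(aa, 0, 3L)                 # 3 < 4 <= any threshold
  expect_equal(master_get(aa$master, 5 * 8192), 0L)
  expect_error(commit_modification(aa, 1, 5L), "assigned")

  # re-assignment after a commit reproduces the committed MSB
  commit_modification(aa, 0, 13L)
  assign_slot(aa, 0, 6)                          # evict
  assign_slot(aa, 0, 5)                          # back: expand stored bit
  expect_true(aa$cache[1] %in% 8:15)

  dd <- adaptor_array("stddp")
  init_assign(dd, 2L, 1L, 0L)
  commit_modification(dd, 2, 7L)
  expect_equal(master_get(dd$master, 1 * 8192 + 2), 7L)
  assign_slot(dd, 2, 4); assign_slot(dd, 2, 1)
  expect_equal(dd$cache[3], 7L)                  # exact value restored
})

test_that("Master RAM snapshots round-trip through CSV", {
  m <- master_new()
  master_set(m, 123456, 9L)
  master_set(m, 42, 1L)
  snap <- master_snapshot(m)
  expect_equal(snap$address, c(42L, 123456L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_master_snapshot(snap, path)
  expect_identical(read_master_snapshot(path), snap)
  expect_equal(master_get(m, 999), 0L)           # unwritten reads 0
})
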