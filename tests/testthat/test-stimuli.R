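test_that("schedule length, cue channel and sample-hold structure", {
  sch <- upe_schedule(upe_context(5, 0.4), n_samples = 1000, duration = 10,
                      seed = 1)
  expect_s3_class(sch, "upe_schedule")
  expect_identical(nrow(sch), 10000L)
  expect_true(all(sch$a %in% c(0, 1)))
  expect_identical(sch$t, seq_len(10000L))
  # every drawn sample is held for exactly D consecutive timesteps
  runs <- rle(sch$s)$lengths
  expect_true(all(runs %% 10L == 0L))
  expect_identical(sum(runs), 10000L)
  expect_true(all(sch$phase == "train"))
})

test_that("drawn samples match the requested Gaussian", {
  n <- 10000
  sch <- upe_schedule(upe_context(5, 0.4), n_samples = n, duration = 1,
                      seed = 99)
  s <- sch$s
  expect_lt(abs(mean(s) - 5), 3 * 0.4 / sqrt(n))       # CLT bound
  expect_lt(abs(sd(s) - 0.4) / 0.4, 0.05)
  expect_gt(ks.test(s, "pnorm", 5, 0.4)$p.value, 0.01)  # distributional fit
})

test_that("schedules are reproducible and seed-gated", {
  a <- upe_schedule(upe_context(2, 0.3), 100, 10, seed = 7)
  b <- upe_schedule(upe_context(2, 0.3), 100, 10, seed = 7)
  expect_identical(a, b)
  c <- upe_schedule(upe_context(2, 0.3), 100, 10, seed = 8)
  expect_false(identical(a$s, c$s))
  expect_error(upe_schedule(upe_context(2, 0.3), 100, 10), "seed")
})

test_that("multi-context schedules: one-hot blocks and interleaving", {
  ctx <- rbind(upe_context(2, 0.3, id = 1), upe_context(6, 0.6, id = 2))
  blocked <- upe_schedule(ctx, n_samples = 50, duration = 5, seed = 3)
  expect_identical(nrow(blocked), 2L * 50L * 5L)
  expect_identical(unique(rle(blocked$context_id)$values), c(1L, 2L))
  inter <- upe_schedule(ctx, n_samples = 50, duration = 5, seed = 3,
                        interleave = TRUE)
  expect_identical(rle(inter$context_id)$lengths,
                   rep(5L, 100L))  # alternating per sample
  # per-context draws identical across orderings (same seed)
  expect_setequal(unique(inter$s[inter$context_id == 1L]),
                  unique(blocked$s[blocked$context_id == 1L]))
})

test_that("step-change schedule concatenates epochs with tagged phases", {
  sch <- upe_step_schedule(c(1, 5), sigma = 0.4, samples_per_epoch = 1000,
                           duration = 10, seed = 2)
  expect_identical(nrow(sch), 20000L)
  expect_identical(sch$phase[10000], "train.epoch1")
  expect_identical(sch$phase[10001], "train.epoch2")
  expect_lt(mean(sch$s[1:10000]), mean(sch$s[10001:20000]))
  # degenerate single-epoch case equals a plain schedule
  one <- upe_step_schedule(3, sigma = 0.4, samples_per_epoch = 100,
                           duration = 10, seed = 2)
  plain <- upe_schedule(upe_context(3, 0.4), 100, 10, seed = 2)
  expect_equal(one$s, plain$s)
  expect_identical(upe_step_schedule(c(1, 5), 0.4, 1000, 10, seed = 2)$s,
                   upe_step_schedule(c(1, 5), 0.4, 1000, 10, seed = 2)$s)
})

test_that("mismatch probes carry the trained cue and the exact offsets", {
  pr <- upe_probe_schedule(5, c(-1, 0, 1), duration = 4, context_id = 1L)
  expect_identical(nrow(pr), 12L)
  expect_identical(unique(pr$phase), "probe")
  expect_identical(unique(pr$context_id), 1L)
  expect_equal(unique(pr$s), c(4, 5, 6))
  expect_error(upe_probe_schedule(5, numeric(0)), "empty deviation")
})

test_that("invalid distributions and empty context lists are rejected", {
  expect_error(upe_context(5, 0), "sigma")
  expect_error(upe_context(5, -1), "sigma")
  expect_error(upe_schedule(NULL, 10, 10, seed = 1), "empty context")
  expect_error(upe_schedule(upe_context(5, 1), 0, 10, seed = 1),
               "n_samples")
  expect_error(upe_schedule(upe_context(5, 1), 10, 0, seed = 1), "duration")
  expect_error(
    upe_schedule(rbind(upe_context(1, 1, 1), upe_context(2, 1, 1)), 5, 5,
                 seed = 1),
    "unique")
  expect_error(upe_step_schedule(numeric(0), 1, 10, seed = 1), "means")
})

test_that("schedules round-trip through CSV", {
  sch <- upe_schedule(upe_context(5, 0.4), 50, 10, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_equal(back$s, sch$s)
  expect_identical(back$context_id, sch$context_id)
  expect_identical(back$phase, sch$phase)
  expect_identical(attr(back, "duration"), 10L)
  # cue-only rows survive as missing stimulus
  cue <- upe_cue_schedule(5)
  write_schedule(cue, path)
  expect_true(all(is.na(read_schedule(path)$s)))
})
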