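mk_labels <- function(...) {
  spec <- list(...)
  unlist(lapply(spec, function(s) rep(s[[1]], s[[2]])))
}

test_that("relabeling rules fire exactly as specified", {
  fs <- 500
  # sub-threshold saccade (8 ms < 10 ms) merges into the fixation
  l <- mk_labels(list("fixation", 10), list("saccade", 4),
                 list("fixation", 10))
  expect_equal(relabel(l, fs), rep("fixation", 24))
  # PSO after a non-saccade is relabeled to the previous event
  l <- mk_labels(list("fixation", 10), list("pso", 5), list("saccade", 8))
  expect_equal(relabel(l, fs),
               mk_labels(list("fixation", 15), list("saccade", 8)))
  # nothing fires: 16 ms saccade, PSO follows the saccade
  l <- mk_labels(list("fixation", 10), list("saccade", 8), list("pso", 5))
  expect_equal(relabel(l, fs), l)
  # exactly 10 ms (5 samples at 500 Hz) is kept: strictly-below rule
  l <- mk_labels(list("fixation", 10), list("saccade", 5),
                 list("fixation", 10))
  expect_equal(relabel(l, fs), l)
  # one-sample fixations and pursuits are absorbed
  l <- mk_labels(list("pursuit", 10), list("fixation", 1),
                 list("pursuit", 10))
  expect_equal(relabel(l, fs), rep("pursuit", 21))
  # a leading offending run merges forward
  l <- mk_labels(list("pso", 3), list("fixation", 10))
  expect_equal(relabel(l, fs), rep("fixation", 13))
})

test_that("relabeling cascades and is idempotent", {
  fs <- 500
  set.seed(41)
  # cascading case: removing the short saccade creates a long fixation
  # run that must coalesce before the PSO rule is evaluated
  l <- mk_labels(list("fixation", 10), list("saccade", 3),
                 list("fixation", 2), list("pso", 4), list("fixation", 10))
  out <- relabel(l, fs)
  expect_equal(out, rep("fixation", 29))
  # idempotence and rule invariants on random label soups
  for (rep in 1:20) {
    l <- sample(c("fixation", "saccade", "pso", "pursuit"), 60,
                replace = TRUE)
    out <- relabel(l, fs)
    expect_identical(relabel(out, fs), out)
    runs <- gazehmm:::label_runs(out)
    sacc <- runs$type == "saccade"
    expect_true(all(runs$length[sacc] >= 5))
    expect_true(all(runs$length[runs$type %in% c("fixation", "pursuit")] > 1))
    pso <- which(runs$type == "pso")
    expect_true(all(pso > 1) && all(runs$type[pso - 1] == "saccade"))
  }
})

test_that("noise labeling overrides decoded labels and splits events", {
  l <- rep("fixation", 10)
  miss <- rep(FALSE, 10)
  expect_identical(label_noise(l, miss), l)
  expect_identical(label_noise(l, rep(TRUE, 10)), rep("noise", 10))
  miss[4:6] <- TRUE
  out <- label_noise(l, miss)
  ev <- build_events(out, (0:9) / 500)
  expect_equal(ev$type, c("fixation", "noise", "fixation"))
})

test_that("event durations follow the max(t_e) - max(t_(e-1)) convention", {
  fs <- 500
  t <- (0:19) / fs
  l <- mk_labels(list("fixation", 10), list("saccade", 10))
  ev <- build_events(l, t)
  expect_equal(nrow(ev), 2)
  # first event spans its own run; later events start at the previous
  # event's last sample
  expect_equal(ev$duration[1], t[10] - t[1])
  expect_equal(ev$duration[2], t[20] - t[10])
  # durations telescope to the recording span
  expect_equal(sum(ev$duration), max(t) - min(t))

  l2 <- rep(c("fixation", "saccade"), 5)
  ev2 <- build_events(l2, (0:9) / fs)
  expect_equal(nrow(ev2), 10)

  # explicit numbers: last samples at 0.9 s and 1.0 s give 0.1 s
  t3 <- c(0, 0.5, 0.9, 0.95, 1.0)
  ev3 <- build_events(c("fixation", "fixation", "fixation",
                        "saccade", "saccade"), t3)
  expect_equal(ev3$duration[2], 0.1)

  desc <- event_descriptives(ev)
  expect_equal(desc$n, c(1, 1))
  expect_equal(desc$type, c("fixation", "saccade"))
})
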