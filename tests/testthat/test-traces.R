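mk_trace <- function(d, dt = 10, div = integer(0)) {
  distance_trace(seq(0, by = dt, length.out = length(d)), d,
                 division_frames = div)
}

test_that("qc_trace implements the 80% signal rule", {
  d <- c(rep(0.3, 85), rep(NA, 15))
  expect_true(qc_trace(mk_trace(d))$passes)
  expect_equal(qc_trace(mk_trace(d))$fraction_frames_with_signal, 0.85)
  d2 <- c(rep(0.3, 79), rep(NA, 21))
  expect_false(qc_trace(mk_trace(d2))$passes)
  expect_equal(qc_trace(mk_trace(rep(0.2, 10)))$fraction_frames_with_signal, 1)
})

test_that("formation requires three continuous co-localized frames", {
  f <- call_formation(mk_trace(c(0.8, 0.3, 0.3, 0.3, 0.9)))
  expect_identical(f$formation_frame, 2L)  # first frame of the run (0-based: 1)
  expect_equal(f$formation_time, 10)
  expect_true(is.na(call_formation(mk_trace(c(0.3, 0.3, 0.8, 0.3, 0.3)))$formation_frame))
  expect_identical(call_formation(mk_trace(rep(0.35, 6)))$formation_frame, 1L)
  # undetected frames break a run
  expect_true(is.na(call_formation(mk_trace(c(0.3, NA, 0.3, NA, 0.3)))$formation_frame))
  # exact threshold is co-localized (inclusive boundary)
  expect_identical(call_formation(mk_trace(c(0.4, 0.4, 0.4, 0.9)))$formation_frame, 1L)
})

test_that("disruption rules: hard threshold and two-losses-in-four", {
  # distance > 0.6 disrupts immediately
  tr <- mk_trace(c(0.3, 0.3, 0.3, 0.7, 0.3))
  expect_identical(call_disruption(tr, 1L), 4L)
  # two losses within four frames; timestamp at the second loss
  tr2 <- mk_trace(c(0.3, 0.3, 0.3, 0.5, 0.3, 0.5, 0.3))
  expect_identical(call_disruption(tr2, 1L), 6L)
  # a single blip is not a disruption
  tr3 <- mk_trace(c(0.3, 0.3, 0.3, 0.5, 0.3, 0.3, 0.3, 0.3))
  expect_identical(call_disruption(tr3, 1L), integer(0))
  # two losses more than four frames apart do not disrupt
  tr4 <- mk_trace(c(0.3, 0.3, 0.3, 0.5, 0.3, 0.3, 0.3, 0.5, 0.3))
  expect_identical(call_disruption(tr4, 1L), integer(0))
  expect_error(call_disruption(tr, 99L), "out of range")
})

test_that("state machine alternates formation and disruption", {
  d <- c(0.9, 0.3, 0.3, 0.3, 0.7, 0.9, 0.3, 0.3, 0.3, 0.3)
  ev <- call_events(mk_trace(d))
  expect_identical(ev$formation_frames, c(2L, 7L))
  expect_identical(ev$disruption_frames, 5L)
  # no disruption is ever called before a formation
  expect_true(all(ev$disruption_frames[1] > ev$formation_frames[1]))
})

test_that("event calls match the literal-rule oracle on mixed sequences", {
  # ternary alphabet {co-localized, lost, above hard threshold}, lengths 4-8
  for (len in 4:8) {
    seqs <- enumerate_sequences(len, c(0.3, 0.5, 0.7))
    for (i in seq_len(nrow(seqs))) {
      d <- seqs[i, ]
      got <- call_events(mk_trace(d))
      want <- oracle_events(d)
      expect_identical(got$formation_frames, want$formation_frames)
      expect_identical(got$disruption_frames, want$disruption_frames)
    }
  }
})

test_that("missing frames count as neither co-localized nor lost", {
  # oracle equivalence including NA frames
  seqs <- enumerate_sequences(6, c(0.3, 0.5, NA))
  for (i in seq_len(nrow(seqs))) {
    d <- seqs[i, ]
    got <- call_events(mk_trace(d))
    want <- oracle_events(d)
    expect_identical(got$formation_frames, want$formation_frames)
    expect_identical(got$disruption_frames, want$disruption_frames)
  }
  # an NA between two losses still lets the window rule fire
  ev <- call_events(mk_trace(c(0.3, 0.3, 0.3, 0.5, NA, 0.5, 0.3)))
  expect_identical(ev$disruption_frames, 6L)
})

test_that("raising the co-localization threshold never delays formation", {
  set.seed(42)
  for (rep in 1:200) {
    d <- round(runif(12, 0, 1), 2)
    f1 <- call_formation(mk_trace(d), coloc_threshold = 0.4)$formation_frame
    f2 <- call_formation(mk_trace(d), coloc_threshold = 0.6)$formation_frame
    if (!is.na(f1)) {
      expect_false(is.na(f2))
      expect_lte(f2, f1)
    }
  }
})

test_that("window readings agree where they should, and the boundary holds", {
  # with 2 losses required, the sliding and re-anchoring readings coincide
  # (a 4-frame window holds two losses iff two successive losses are <= 3
  # frames apart); check agreement over all ternary sequences of length 7
  seqs <- enumerate_sequences(7, c(0.3, 0.5, 0.7))
  for (i in seq_len(nrow(seqs))) {
    d <- seqs[i, ]
    expect_identical(call_events(mk_trace(d), window_mode = "sliding"),
                     call_events(mk_trace(d), window_mode = "anchored"))
  }
  # two losses exactly 4 frames apart: no 4-frame window holds both
  d2 <- c(0.3, 0.3, 0.3, 0.5, 0.3, 0.3, 0.3, 0.5)
  expect_identical(call_events(mk_trace(d2))$disruption_frames, integer(0))
  # 3 frames apart: the window just holds both
  d3 <- c(0.3, 0.3, 0.3, 0.5, 0.3, 0.3, 0.5, 0.3)
  expect_identical(call_events(mk_trace(d3))$disruption_frames, 7L)
})

test_that("simulator round-trip: caller recovers noiseless ground truth", {
  for (s in 1:40) {
    cfg <- diffusion_config(localization_noise_sd = 0, seed = 100 + s,
                            n_frames = 50L, bind_prob_per_frame = 0.6)
    sim <- simulate_distance_trace(cfg)
    called <- call_formation(sim$trace)$formation_frame
    truth <- sim$truth$true_formation_frame
    expect_identical(called, truth)
  }
  # with 0.05 um localization noise, >= 95% of calls within +/- 1 frame
  hits <- 0L; n_ev <- 0L
  for (s in 1:100) {
    cfg <- diffusion_config(localization_noise_sd = 0.05, seed = 300 + s,
                            n_frames = 50L, bind_prob_per_frame = 0.6)
    sim <- simulate_distance_trace(cfg)
    truth <- sim$truth$true_formation_frame  # defined on the noiseless path
    called <- call_formation(sim$trace)$formation_frame
    if (!is.na(truth)) {
      n_ev <- n_ev + 1L
      if (!is.na(called) && abs(called - truth) <= 1) hits <- hits + 1L
    }
  }
  expect_gte(hits / n_ev, 0.95)
})

test_that("disruption times are referenced to the division midpoint", {
  # disruption at 220 min, budneck marker gone between 224 and 234 min:
  # division midpoint 229, relative time -9
  times <- seq(4, by = 10, length.out = 24)     # frames at 4, 14, ..., 234
  tr <- distance_trace(times, rep(0.3, 24), division_frames = 24L)
  ev <- structure(list(cell_id = 1L, formation_frames = 1L,
                       formation_times = times[1],
                       disruption_frames = NA_integer_,
                       disruption_times = 220),
                  class = "cici_events")
  rel <- disruption_relative_to_division(ev, tr)
  expect_equal(rel$relative_time_min, -9)
  expect_equal(rel$division_time, 229)
  expect_false(rel$flagged_no_later_division)
  # disruption exactly at the division midpoint gives 0
  ev$disruption_times <- 229
  expect_equal(disruption_relative_to_division(ev, tr)$relative_time_min, 0)
  # two disruptions before one division reference the same division
  ev$disruption_times <- c(204, 214)
  rel3 <- disruption_relative_to_division(ev, tr)
  expect_equal(rel3$division_time, c(229, 229))
  expect_equal(rel3$relative_time_min, c(-25, -15))
})

test_that("relative division times follow the midpoint convention", {
  times <- seq(0, by = 10, length.out = 30)
  dist <- rep(0.3, 30); dist[23] <- 0.9
  tr <- distance_trace(times, dist, division_frames = c(24L, 29L))
  ev <- call_events(tr)
  rel <- disruption_relative_to_division(ev, tr)
  # disruption at 220; division midpoint 235 - 5 = ... frame 24 -> time 230,
  # midpoint 225; relative = -5
  expect_equal(rel$relative_time_min, 220 - 225)
  # disruption after the last division: referenced back, flagged
  dist2 <- rep(0.3, 30); dist2[29] <- 0.9
  tr2 <- distance_trace(times, dist2, division_frames = 10L)
  ev2 <- call_events(tr2)
  rel2 <- disruption_relative_to_division(ev2, tr2)
  expect_true(rel2$flagged_no_later_division)
  expect_gt(rel2$relative_time_min, 0)
  expect_error(disruption_relative_to_division(ev, mk_trace(rep(0.3, 5))),
               "no division")
})

test_that("persistence through division matches the simulator's odds", {
  # continuous co-localization across a division persists
  times <- seq(0, by = 10, length.out = 20)
  tr <- distance_trace(times, rep(0.2, 20), division_frames = 10L)
  expect_true(persistence_through_division(call_events(tr), tr))
  # disruption right before the division does not
  d <- rep(0.2, 20); d[9] <- 0.9
  tr2 <- distance_trace(times, d, division_frames = 10L)
  expect_false(persistence_through_division(call_events(tr2), tr2))
  # too few post-division frames: undetermined
  tr3 <- distance_trace(times, rep(0.2, 20), division_frames = 19L)
  expect_true(is.na(persistence_through_division(call_events(tr3), tr3)))
})

test_that("division disruption frequency matches the stated odds (11/58)", {
  p_true <- 11 / 58
  outcomes <- logical(0)
  for (s in 1:400) {
    cfg <- diffusion_config(seed = 5000 + s, n_frames = 40L,
                            bind_prob_per_frame = 1, unbind_prob_per_frame = 0,
                            localization_noise_sd = 0.05)
    sim <- simulate_distance_trace(cfg)
    tr <- sim$trace
    ev <- call_events(tr)
    if (!length(ev$formation_frames)) next
    divs <- tr$division_frames[tr$division_frames > min(ev$formation_frames)]
    if (!length(divs)) next
    per <- persistence_through_division(ev, tr, division_frame = divs[1])
    if (!is.na(per)) outcomes <- c(outcomes, !per)
  }
  m <- length(outcomes)
  expect_gt(m, 100)
  se <- sqrt(p_true * (1 - p_true) / m)
  expect_lt(abs(mean(outcomes) - p_true), 3 * se)
})

test_that("formation_time_histogram uses left-closed bins", {
  h <- formation_time_histogram(c(5, 15, 15))
  expect_identical(h$count, c(1L, 2L))
  expect_equal(h$bin_left, c(0, 10))
  expect_identical(nrow(formation_time_histogram(numeric(0))), 0L)
  h2 <- formation_time_histogram(c(10, 10, 19.9))
  expect_identical(h2$count, c(0L, 3L))
  expect_error(formation_time_histogram(c(-1, 3)), "non-negative")
})

test_that("traces survive a CSV round trip", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  cfg <- diffusion_config(seed = 8, n_frames = 15L,
                          detection_dropout_prob = 0.1)
  sims <- simulate_cohort(3, cfg)
  traces <- lapply(sims, `[[`, "trace")
  write_traces(traces, tmp)
  back <- read_traces(tmp)
  expect_length(back, 3L)
  for (i in 1:3) {
    orig <- traces[[i]]
    got <- back[[as.character(orig$cell_id)]]
    expect_equal(got$distance, orig$distance)
    expect_identical(got$division_frames, orig$division_frames)
  }
})
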