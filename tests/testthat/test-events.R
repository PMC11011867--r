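random_trace <- function(n_frames) {
  # noise plus occasional boxcar excursions, exercising boundary cases
  x <- stats::rnorm(n_frames, 0, 0.1)
  for (k in seq_len(sample(0:4, 1))) {
    at <- sample(n_frames, 1)
    len <- sample(1:25, 1)
    idx <- at:min(n_frames, at + len)
    x[idx] <- x[idx] + stats::runif(1, 0.1, 0.6)
  }
  x
}

oracle_protocol <- function() {
  build_protocol(character(0),
    baseline_s = 88, pulse_s = 5, wash_s = 5,
    frame_interval_s = 0.2, high_k_s = 10
  )
}

test_that("detector with merging disabled equals the brute-force oracle", {
  p <- oracle_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  base_frames <- 1:440
  withr::with_seed(99, {
    for (rep in 1:200) {
      x <- random_trace(nf)
      tr <- make_traces(matrix(x, nrow = 1), p)
      ev <- detect_events(tr,
        threshold_abs = 0.2, min_duration_s = 0.2,
        merge_gap_s = 0, cells = 1L
      )
      want <- detect_runs_naive(x[base_frames], 0.2)
      expect_equal(nrow(ev), nrow(want))
      if (nrow(want)) {
        expect_equal(round(ev$onset_s / 0.2) + 1, want$start)
        expect_equal(round(ev$end_s / 0.2), want$end)
      }
    }
  })
})

test_that("oracle handles saturated and empty traces", {
  expect_equal(nrow(detect_runs_naive(rep(1, 50), 0.2)), 1)
  expect_equal(detect_runs_naive(rep(1, 50), 0.2)$start, 1)
  expect_equal(detect_runs_naive(rep(1, 50), 0.2)$end, 50)
  expect_equal(nrow(detect_runs_naive(rep(0, 50), 0.2)), 0)
})

test_that("raising the threshold never creates events", {
  p <- oracle_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  withr::with_seed(7, {
    for (rep in 1:30) {
      x <- random_trace(nf)
      tr <- make_traces(matrix(x, nrow = 1), p)
      counts <- vapply(seq(2, 8, by = 0.5), function(k) {
        nrow(detect_events(tr, threshold_k = k, cells = 1L))
      }, numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("injected transients are recovered with frame-accurate onsets", {
  p <- oracle_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  onsets <- c(5, 25, 50, 70)
  x <- numeric(nf)
  for (o in onsets) {
    seg <- suppressWarnings(render_transient("fast", 0.8,
      onset_s = o,
      frame_interval_s = 0.2, duration_s = nf * 0.2
    ))
    x <- x + seg
  }
  tr <- make_traces(matrix(x, nrow = 1), p, noise_sd = 0.02, baseline_level = 0)
  ev <- detect_events(tr, threshold_abs = 0.2, cells = 1L)
  expect_equal(nrow(ev), 4)
  expect_true(all(abs(ev$onset_s - onsets) <= 0.6))
  expect_true(all(ev$shape_class == "fast"))
})

test_that("flat traces yield no events", {
  p <- oracle_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  tr <- make_traces(matrix(0, nrow = 1, ncol = nf), p, noise_sd = 0.01,
                    baseline_level = 0)
  expect_equal(nrow(detect_events(tr, cells = 1L)), 0)
})

test_that("a sustained 25-s transient is classed prolonged", {
  p <- oracle_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  x <- numeric(nf)
  seg <- suppressWarnings(render_transient("prolonged", 0.9,
    onset_s = 10,
    frame_interval_s = 0.2, duration_s = nf * 0.2
  ))
  x <- x + seg
  tr <- make_traces(matrix(x, nrow = 1), p, noise_sd = 0.02, baseline_level = 0)
  ev <- detect_events(tr, threshold_abs = 0.1, cells = 1L)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration_s, 10)
  expect_equal(ev$shape_class, "prolonged")
})

test_that("baseline shorter than the minimum duration is rejected", {
  p <- build_protocol(character(0),
    baseline_s = 0.4, pulse_s = 5, wash_s = 5,
    frame_interval_s = 0.2
  )
  tr <- make_traces(matrix(0, nrow = 1, ncol = 60), p, noise_sd = 0.01)
  expect_error(detect_events(tr, min_duration_s = 0.6, cells = 1L), "shorter")
})

test_that("per-cell counts and rates follow the counting arithmetic", {
  run <- scenario_run("tumor2")
  tr <- run$traces
  # 6 events in a 180-s baseline is 2 per minute
  one <- run$spontaneous[run$spontaneous$n_events == 6, ]
  if (nrow(one)) expect_true(all(one$rate_per_min == 2))
  expect_equal(
    run$spontaneous$rate_per_min,
    run$spontaneous$n_events / 3
  )
  expect_equal(run$spontaneous$is_spontaneous, run$spontaneous$n_events >= 1)
})

test_that("detected event counts match ground truth for nearly all cells", {
  run <- scenario_run("tumor2")
  gt <- run$recording$ground_truth
  counts <- run$spontaneous |>
    dplyr::left_join(
      dplyr::select(gt, "cell_id", true_n = "n_spontaneous_events"),
      by = "cell_id"
    )
  agree <- mean(counts$n_events == counts$true_n)
  expect_gte(agree, 0.95)
})

test_that("the spontaneous fraction ignores cell ordering", {
  run <- scenario_run("tumor2")
  ev <- run$events
  perm <- ev[sample(nrow(ev)), ]
  s1 <- summarize_spontaneous(ev, run$traces)
  s2 <- summarize_spontaneous(perm, run$traces)
  expect_equal(attr(s1, "pct_spontaneous"), attr(s2, "pct_spontaneous"))
})
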