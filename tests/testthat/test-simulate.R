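test_that("identical seeds give bit-identical recordings", {
  spec <- population_spec(
    n_cells = 12, frac_spontaneous = 0.5,
    frac_non = 0.5, frac_mono = 0.25, frac_multi = 0.25, seed = 21
  )
  r1 <- simulate_recording(spec, small_protocol())
  r2 <- simulate_recording(spec, small_protocol())
  expect_identical(r1$fluorescence, r2$fluorescence)
  expect_identical(r1$ground_truth, r2$ground_truth)
})

test_that("different seeds keep ground-truth counts but move event times", {
  mk <- function(seed) {
    simulate_recording(
      population_spec(
        n_cells = 40, frac_spontaneous = 0.5,
        frac_non = 0.5, frac_mono = 0.25, frac_multi = 0.25, seed = seed
      ),
      small_protocol()
    )
  }
  ra <- mk(1)
  rb <- mk(2)
  expect_equal(table(ra$ground_truth$category), table(rb$ground_truth$category))
  expect_equal(sum(ra$ground_truth$spontaneous), sum(rb$ground_truth$spontaneous))
  expect_false(identical(ra$event_log$onset_s, rb$event_log$onset_s))
})

test_that("a silent noiseless population is pure baseline times bleach", {
  spec <- population_spec(
    n_cells = 8, frac_non = 1, noise_sd = 0,
    bleach_depth = 0.3, bleach_tau_s = 100, seed = 4
  )
  p <- small_protocol()
  rec <- simulate_recording(spec, p)
  t <- frame_times(rec)
  hk <- p[p$label == "high_K", ]
  pre_hk <- t < hk$start_s
  want <- spec$f0 * bleach_curve(t[pre_hk], 0.3, 100)
  for (i in 1:8) {
    expect_lt(max(abs(rec$fluorescence[i, pre_hk] - want)), 1e-9)
  }
})

test_that("exact-fraction construction holds inside the recording", {
  spec <- population_spec(n_cells = 100, frac_spontaneous = 0.574, seed = 6)
  rec <- simulate_recording(spec, small_protocol())
  expect_equal(sum(rec$ground_truth$spontaneous), 57)
  # and the event log places baseline events for exactly those cells
  base_cells <- unique(rec$event_log$cell_id[rec$event_log$context == "baseline"])
  expect_setequal(base_cells, rec$ground_truth$cell_id[rec$ground_truth$spontaneous])
})

test_that("realized noise matches the requested level", {
  spec <- population_spec(n_cells = 50, frac_non = 1, noise_sd = 0.05, seed = 8)
  rec <- simulate_recording(spec, small_protocol())
  # residual after dividing out the known bleach, minus signal-free baseline
  t <- frame_times(rec)
  b <- bleach_curve(t, spec$bleach_depth, spec$bleach_tau_s)
  hk <- small_protocol()[small_protocol()$label == "high_K", ]
  pre <- t < hk$start_s
  for (i in c(1, 25, 50)) {
    resid <- rec$fluorescence[i, pre] / (spec$f0 * b[pre]) - 1
    expect_lt(abs(stats::sd(resid) - 0.05), 0.006)
  }
  expect_lt(max(abs(rec$noise_sd_realized - 0.05)), 0.01)
})

test_that("transients stay inside their designated epochs", {
  spec <- population_spec(
    n_cells = 25, frac_spontaneous = 0.8,
    frac_non = 0.2, frac_mono = 0.4, frac_multi = 0.4,
    noise_sd = 0, bleach_depth = 0, seed = 13
  )
  p <- test_protocol()
  rec <- simulate_recording(spec, p)
  s <- rec$fluorescence / spec$f0 - 1
  fi <- rec$frame_interval_s
  # at the onset frame of every secretagogue pulse, no residue of baseline
  # or earlier-stimulus transients may remain in non-responding cells
  for (stim in SECRETAGOGUES) {
    ep <- p[p$label == stim, ]
    frame <- floor(ep$start_s / fi) + 1L
    responders <- which(purrr::map_lgl(
      rec$ground_truth$responds_to, ~ stim %in% .x
    ))
    silent <- setdiff(seq_len(25), responders)
    expect_true(all(abs(s[silent, frame]) < 1e-12))
  }
})

test_that("a protocol without high_K is rejected", {
  p <- build_protocol(character(0), baseline_s = 10, pulse_s = 5, wash_s = 5)
  p_broken <- p[p$label != "high_K", ]
  attr(p_broken, "frame_interval_s") <- 0.2
  attr(p_broken, "total_duration_s") <- 10
  spec <- population_spec(5)
  expect_error(simulate_recording(spec, p_broken), "high_K")
})
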