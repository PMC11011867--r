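test_that("known bleaching is divided out to within 0.5%", {
  spec <- population_spec(
    n_cells = 6, frac_non = 1, noise_sd = 0,
    bleach_depth = 0.3, bleach_tau_s = 200, seed = 2
  )
  p <- small_protocol()
  rec <- correct_photobleach(simulate_recording(spec, p))
  t <- frame_times(rec)
  pre <- t < p[p$label == "high_K", ]$start_s
  for (i in 1:6) {
    x <- rec$fluorescence[i, pre]
    expect_lt((max(x) - min(x)) / mean(x), 0.005)
  }
  expect_true(all(rec$bleach_params$method == "exponential"))
  expect_lt(max(abs(rec$bleach_params$tau_s - 200)) / 200, 0.2)
})

test_that("correction is near-identity when there is no bleaching", {
  spec <- population_spec(
    n_cells = 5, frac_non = 1, noise_sd = 0.03, bleach_depth = 0, seed = 3
  )
  rec <- simulate_recording(spec, small_protocol())
  cor <- correct_photobleach(rec)
  rel <- abs(cor$fluorescence - rec$fluorescence) / rec$fluorescence
  expect_lt(stats::median(rel), 0.01)
})

test_that("event amplitudes survive bleach correction within 2%", {
  spec <- population_spec(
    n_cells = 10, frac_non = 1, frac_spontaneous = 1,
    noise_sd = 0, bleach_depth = 0, seed = 5
  )
  rec <- simulate_recording(spec, test_protocol()) # full 180-s baseline
  cor <- correct_photobleach(rec)
  base_frames <- 1:900
  for (i in 1:10) {
    raw_pk <- max(rec$fluorescence[i, base_frames])
    cor_pk <- max(cor$fluorescence[i, base_frames])
    expect_lt(abs(cor_pk - raw_pk) / raw_pk, 0.02)
  }
})

test_that("dF/Fmin inverts a known multiplicative signal", {
  p <- small_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  t <- (seq_len(nf) - 1) * 0.2
  s <- suppressWarnings(render_transient("fast", 0.7,
    onset_s = 100,
    frame_interval_s = 0.2, duration_s = nf * 0.2
  ))
  f <- matrix(120 * (1 + s), nrow = 1)
  rec <- structure(
    list(fluorescence = f, frame_interval_s = 0.2, protocol = p,
         ground_truth = NULL,
         truncations = tibble::tibble(cell_id = integer(), context = character(),
                                      onset_s = double())),
    class = "ca_recording"
  )
  tr <- normalize_dff(rec)
  expect_lt(max(abs(tr$dff[1, ] - s)), 1e-6)
  # dff is exactly 0 at the frame attaining Fmin
  expect_true(any(tr$dff[1, ] == 0))
})

test_that("a flat trace with one event gives the hand-computed peak dff", {
  p <- small_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  f <- matrix(100, nrow = 1, ncol = nf)
  f[1, 150:155] <- 180
  rec <- structure(
    list(fluorescence = f, frame_interval_s = 0.2, protocol = p,
         ground_truth = NULL,
         truncations = tibble::tibble(cell_id = integer(), context = character(),
                                      onset_s = double())),
    class = "ca_recording"
  )
  tr <- normalize_dff(rec)
  expect_lt(abs(max(tr$dff[1, ]) - 0.8), 0.02)
})

test_that("dF/Fmin is invariant to overall trace scale", {
  spec <- population_spec(n_cells = 5, frac_non = 1, noise_sd = 0.04, seed = 7)
  rec <- correct_photobleach(simulate_recording(spec, small_protocol()))
  tr1 <- normalize_dff(rec)
  rec2 <- rec
  rec2$fluorescence <- rec$fluorescence * 3.7
  tr2 <- normalize_dff(rec2)
  expect_lt(max(abs(tr1$dff - tr2$dff)), 1e-9)
})

test_that("correct-then-normalize recovers ground-truth dF/F", {
  spec <- population_spec(
    n_cells = 20, frac_spontaneous = 0.5,
    frac_non = 0.4, frac_mono = 0.3, frac_multi = 0.3,
    noise_sd = 0, bleach_depth = 0.3, bleach_tau_s = 300, seed = 10
  )
  rec <- simulate_recording(spec, test_protocol())
  truth <- rebuild_signal(rec)
  tr <- normalize_dff(correct_photobleach(rec))
  expect_lt(max(abs(tr$dff - truth)), 0.02)
})

test_that("viability gate recovers the exact generator allocation", {
  vt <- viability_traces()
  truth <- vt$rec$ground_truth$viable
  got <- vt$traces$viable_mask
  expect_equal(sum(truth), 450)
  sens <- sum(got & truth) / sum(truth)
  spec_ <- sum(!got & !truth) / sum(!truth)
  expect_gte(sens, 0.99)
  expect_gte(spec_, 0.99)
})

test_that("gate decision is stable across k_K in 3..8 at high SNR", {
  # cells with a high-K response (40x noise by default) stay gated viable
  # at any reasonable k_K; their decisions never depend on the multiplier
  vt <- viability_traces()
  responders <- vt$rec$ground_truth$viable
  masks <- lapply(c(3, 5, 8), function(k) {
    gate_viability(vt$traces, k_k = k)$viable_mask[responders]
  })
  expect_identical(masks[[1]], masks[[2]])
  expect_identical(masks[[2]], masks[[3]])
  expect_true(all(masks[[2]]))
})

test_that("an unresponsive matrix leaves no viable cells and errors", {
  p <- small_protocol()
  nf <- as.integer(attr(p, "total_duration_s") / 0.2)
  f <- matrix(100, nrow = 3, ncol = nf)
  rec <- structure(
    list(fluorescence = f, frame_interval_s = 0.2, protocol = p,
         ground_truth = NULL,
         truncations = tibble::tibble(cell_id = integer(), context = character(),
                                      onset_s = double())),
    class = "ca_recording"
  )
  tr <- normalize_dff(rec)
  expect_error(gate_viability(tr), "viability gate")
})
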