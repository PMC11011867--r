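# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# 10x-compressed full five-stimulus protocol (the standard test protocol)
test_protocol <- function() {
  fixture("protocol10", function() build_protocol(compress = 10))
}

# Small two-stimulus protocol for cheap structural tests
small_protocol <- function() {
  fixture("protocol_small", function() {
    build_protocol(c("TRH", "GnRH"),
      baseline_s = 60, pulse_s = 30, wash_s = 60,
      frame_interval_s = 0.2, high_k_s = 30
    )
  })
}

# Full processed run of a printed-scenario recording at n cells
scenario_run <- function(name, n_cells = 500, seed = 1L) {
  fixture(sprintf("run_%s_%d_%d", name, n_cells, seed), function() {
    rec <- simulate_recording(
      tumor_scenario(name, n_cells = n_cells, seed = seed),
      test_protocol()
    )
    run <- analyze_recording(rec)
    run
  })
}

# 500-cell recording with 10% non-viable cells, for the viability gate
viability_traces <- function() {
  fixture("viability500", function() {
    spec <- population_spec(
      n_cells = 500, frac_viable = 0.9, frac_spontaneous = 0.2,
      frac_non = 0.6, frac_mono = 0.2, frac_multi = 0.2, seed = 11L
    )
    rec <- simulate_recording(spec, test_protocol())
    list(rec = rec, traces = gate_viability(normalize_dff(correct_photobleach(rec))))
  })
}

# Minimal hand-built ca_traces around a given dff matrix (baseline-only use)
make_traces <- function(dff, protocol, noise_sd = NULL, baseline_level = NULL) {
  n <- nrow(dff)
  fi <- attr(protocol, "frame_interval_s")
  base_ep <- protocol[protocol$label == "baseline", ]
  idx <- seq.int(
    floor(base_ep$start_s / fi) + 1L,
    min(ncol(dff), ceiling(base_ep$end_s / fi))
  )
  if (is.null(noise_sd)) {
    noise_sd <- apply(dff[, idx, drop = FALSE], 1, function(x) {
      stats::mad(diff(x), constant = 1.4826) / sqrt(2)
    })
  }
  if (is.null(baseline_level)) {
    baseline_level <- apply(dff[, idx, drop = FALSE], 1, stats::median)
  }
  structure(
    list(
      dff = dff, fmin = rep(1, n), bleach_params = NULL, protocol = protocol,
      frame_interval_s = fi, valid_mask = rep(TRUE, n),
      viable_mask = rep(TRUE, n), noise_sd = noise_sd,
      baseline_level = baseline_level, ground_truth = NULL
    ),
    class = "ca_traces"
  )
}

# Rebuild the noiseless dff signal of a recording from its event log using
# render_transient (an independent composition of the same kernels).
rebuild_signal <- function(rec) {
  n <- nrow(rec$fluorescence)
  nf <- ncol(rec$fluorescence)
  fi <- rec$frame_interval_s
  out <- matrix(0, n, nf)
  for (k in seq_len(nrow(rec$event_log))) {
    e <- rec$event_log[k, ]
    seg <- suppressWarnings(render_transient(
      e$shape_class, e$amplitude,
      onset_s = e$onset_s, frame_interval_s = fi,
      duration_s = e$clip_end_s
    ))
    m <- min(length(seg), nf)
    out[e$cell_id, seq_len(m)] <- out[e$cell_id, seq_len(m)] + seg[seq_len(m)]
  }
  out
}
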