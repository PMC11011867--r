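#' Mono-exponential photobleaching curve
#'
#' Multiplicative bleaching factor applied to baseline fluorescence:
#' `b(t) = (1 - depth) + depth * exp(-t / tau)`, so `b(0) = 1` and the trace
#' loses a fraction `depth` of its initial brightness at long times.
#'
#' @param t Time in seconds (vector).
#' @param bleach_depth Fraction of initial fluorescence lost asymptotically.
#' @param bleach_tau_s Decay time constant (s).
#' @return Numeric vector of factors in `(1 - depth, 1]`.
#' @export
bleach_curve <- function(t, bleach_depth, bleach_tau_s) {
  (1 - bleach_depth) + bleach_depth * exp(-t / bleach_tau_s)
}

#' Simulate a multi-cell calcium recording with known ground truth
#'
#' Generates the raw fluorescence matrix for a cell population under a
#' stimulation protocol. Per cell,
#' `F(t) = f0 * bleach(t) * (1 + s(t) + noise)`, where `s(t)` is the sum of
#' the cell's transient kernels in dF/F units and the Gaussian noise SD is
#' `noise_sd` (dF/F units). Events are placed as:
#'
#' * spontaneous events: inside the baseline epoch only, onsets stratified
#'   into equal slots with uniform jitter (randomized but non-overlapping,
#'   so ground-truth event counts are recoverable);
#' * secretagogue responses: one transient per stimulus the cell responds to,
#'   onset uniform within 5 s of pulse start;
#' * viability: every viable cell gets a high-amplitude transient at the
#'   terminal high-K pulse; non-viable cells receive no transients at all.
#'
#' Transients are clipped at the end of their designated epoch span (baseline
#' events before the first stimulus; responses before the next stimulus);
#' clippings are tallied in the `truncations` element, never silent.
#' The result is bit-identical for identical spec + protocol; a different
#' seed changes event times and noise but not ground-truth label counts.
#'
#' @param spec A [population_spec()].
#' @param protocol A [build_protocol()] result; must contain a high_K epoch.
#' @return A `ca_recording`: list with `fluorescence` (cells x frames matrix,
#'   all values >= 0), `frame_interval_s`, `protocol`, `ground_truth` tibble
#'   (see [sample_population()]), `spec`, `noise_sd_realized` (per-cell SD of
#'   the actual noise draws), `event_log` (every placed transient: cell,
#'   context epoch, shape, amplitude, onset), and `truncations` tibble.
#' @examples
#' rec <- simulate_recording(
#'   population_spec(20, frac_spontaneous = 0.5, seed = 7),
#'   build_protocol(c("TRH", "GnRH"), compress = 10)
#' )
#' dim(rec$fluorescence)
#' @export
simulate_recording <- function(spec, protocol = build_protocol()) {
  stopifnot(inherits(spec, "population_spec"))
  validate_protocol(protocol)
  if (!any(protocol$label == "high_K")) {
    abort("Protocol lacks a high_K epoch; viability gating would be impossible.")
  }
  # responds_to may reference stimuli absent from a reduced protocol; those
  # responses are simply never elicited
  stimuli <- protocol_stimuli(protocol)
  fi <- attr(protocol, "frame_interval_s")
  n_frames <- protocol_n_frames(protocol)
  t <- (seq_len(n_frames) - 1L) * fi
  n <- spec$n_cells

  truth <- sample_population(spec)
  base_ep <- protocol_epoch(protocol, "baseline")
  hk_ep <- protocol_epoch(protocol, "high_K")
  non_wash <- protocol[protocol$label != "wash", , drop = FALSE]

  signal <- matrix(0, nrow = n, ncol = n_frames)
  trunc_log <- list()
  event_log <- list()
  log_event <- function(cell_id, context, shape, amplitude, onset_s, clip_end_s) {
    event_log[[length(event_log) + 1L]] <<- tibble::tibble(
      cell_id = cell_id, context = context, shape_class = shape,
      amplitude = amplitude, onset_s = onset_s, clip_end_s = clip_end_s
    )
  }

  with_seed(spec$seed + 1L, {
    for (i in seq_len(n)) {
      if (!truth$viable[i]) next
      tr <- numeric(n_frames)
      amp_jitter <- truth$amplitude_scale[i]

      # spontaneous baseline events
      ne <- truth$n_spontaneous_events[i]
      if (ne > 0) {
        shape <- if (ne == 1L && truth$shape_class[i] == "prolonged") "prolonged" else "fast"
        support <- kernel_support_s(shape)
        slot <- base_ep$duration_s / ne
        for (j in seq_len(ne)) {
          slot_start <- base_ep$start_s + (j - 1) * slot
          onset <- slot_start + stats::runif(1, 0, max(0, slot - support))
          amp <- spec$amplitude_spont * amp_jitter
          log_event(i, "baseline", shape, amp, onset, base_ep$end_s)
          tr <- add_transient(tr, shape, amp, onset, fi,
            clip_end_s = base_ep$end_s
          )
          if (isTRUE(attr(tr, "truncated"))) {
            trunc_log[[length(trunc_log) + 1L]] <-
              tibble::tibble(cell_id = i, context = "baseline", onset_s = onset)
          }
        }
      }

      # secretagogue responses: onset within 5 s of pulse start, clipped at
      # the start of the next non-wash epoch
      for (stim in intersect(truth$responds_to[[i]], stimuli)) {
        ep <- protocol_epoch(protocol, stim)
        nxt <- non_wash$start_s[non_wash$start_s > ep$start_s + 1e-9]
        clip_end <- if (length(nxt)) min(nxt) else attr(protocol, "total_duration_s")
        onset <- ep$start_s + stats::runif(1, 0, 5)
        amp <- spec$amplitude_response * amp_jitter
        log_event(i, stim, truth$shape_class[i], amp, onset, clip_end)
        tr <- add_transient(
          tr, truth$shape_class[i], amp, onset, fi, clip_end
        )
        if (isTRUE(attr(tr, "truncated"))) {
          trunc_log[[length(trunc_log) + 1L]] <-
            tibble::tibble(cell_id = i, context = stim, onset_s = onset)
        }
      }

      # high-K depolarization response (all viable cells)
      onset <- hk_ep$start_s + stats::runif(1, 0, 2)
      amp <- spec$amplitude_high_k * amp_jitter
      log_event(i, "high_K", "fast", amp, onset, attr(protocol, "total_duration_s"))
      tr <- add_transient(
        tr, "fast", amp, onset, fi,
        clip_end_s = attr(protocol, "total_duration_s")
      )
      if (isTRUE(attr(tr, "truncated"))) {
        trunc_log[[length(trunc_log) + 1L]] <-
          tibble::tibble(cell_id = i, context = "high_K", onset_s = onset)
      }
      signal[i, ] <- tr
    }

    noise <- if (spec$noise_sd > 0) {
      matrix(stats::rnorm(n * n_frames, 0, spec$noise_sd), nrow = n)
    } else {
      matrix(0, nrow = n, ncol = n_frames)
    }
    bleach <- bleach_curve(t, spec$bleach_depth, spec$bleach_tau_s)
    f <- spec$f0 * (1 + signal + noise) * rep(bleach, each = n)
    f[f < 0] <- 0

    structure(
      list(
        fluorescence = f,
        frame_interval_s = fi,
        protocol = protocol,
        ground_truth = truth,
        spec = spec,
        noise_sd_realized = apply(noise, 1, stats::sd),
        event_log = if (length(event_log)) {
          dplyr::bind_rows(event_log)
        } else {
          tibble::tibble(
            cell_id = integer(), context = character(),
            shape_class = character(), amplitude = double(),
            onset_s = double(), clip_end_s = double()
          )
        },
        truncations = if (length(trunc_log)) {
          dplyr::bind_rows(trunc_log)
        } else {
          tibble::tibble(
            cell_id = integer(), context = character(), onset_s = double()
          )
        }
      ),
      class = "ca_recording"
    )
  })
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf(
    "<ca_recording> %d cells x %d frames (%.1f s at %.3g s/frame)%s\n",
    nrow(x$fluorescence), ncol(x$fluorescence),
    ncol(x$fluorescence) * x$frame_interval_s, x$frame_interval_s,
    if (!is.null(x$ground_truth)) ", ground truth attached" else ""
  ))
  if (nrow(x$truncations)) {
    cat(sprintf("  %d transient(s) truncated at epoch boundaries\n", nrow(x$truncations)))
  }
  invisible(x)
}

#' Frame times of a recording
#' @param x A `ca_recording` or `ca_traces` object.
#' @return Numeric vector of frame times in seconds (first frame at 0).
#' @export
frame_times <- function(x) {
  nf <- if (inherits(x, "ca_recording")) ncol(x$fluorescence) else ncol(x$dff)
  (seq_len(nf) - 1L) * x$frame_interval_s
}
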