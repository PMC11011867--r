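# Run-length detection of supra-threshold segments in one dff trace.
# Returns a tibble of runs in frame indices (relative to the input vector).
detect_runs <- function(x, threshold, min_frames = 1L, merge_gap_frames = 0L) {
  above <- !is.na(x) & x >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(
    start = starts[r$values], end = ends[r$values]
  )
  if (!nrow(runs)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  if (merge_gap_frames > 0L && nrow(runs) > 1L) {
    merged <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      gap <- runs$start[k] - last$end - 1L
      if (gap < merge_gap_frames) {
        last$end <- runs$end[k]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- runs[k, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  runs <- runs[runs$end - runs$start + 1L >= min_frames, , drop = FALSE]
  tibble::tibble(start = as.integer(runs$start), end = as.integer(runs$end))
}

# Event segmentation for one trace. With merging enabled and a re-arm level
# below the threshold, an event is a maximal excursion above `end_level`
# (merged across sub-`gap` interruptions) that holds `thr` for at least
# `min_frames` consecutive frames: the excursion set is independent of `thr`
# and the qualifying predicate can only lose events as `thr` rises, so the
# event count is monotone non-increasing in the threshold. With merging
# disabled (gap 0) this reduces to raw maximal runs above `thr` — the
# brute-force oracle semantics.
segment_events <- function(x, thr, min_frames, gap_frames, end_level = NULL) {
  if (gap_frames == 0L || is.null(end_level) || end_level >= thr) {
    return(detect_runs(x, thr, min_frames, gap_frames))
  }
  exc <- detect_runs(x, end_level, min_frames = 1L, merge_gap_frames = gap_frames)
  if (!nrow(exc)) return(exc)
  keep <- vapply(seq_len(nrow(exc)), function(k) {
    r <- rle(x[exc$start[k]:exc$end[k]] >= thr)
    any(r$values & r$lengths >= min_frames)
  }, logical(1))
  exc[keep, , drop = FALSE]
}

#' Detect spontaneous calcium transients in the baseline epoch
#'
#' An event is a calcium excursion that exceeds the detection threshold for
#' at least `min_duration_s`. The per-cell threshold is the cell's resting
#' baseline dff level (baseline-epoch median; nonzero because Fmin is a low
#' percentile, not the mean) plus `threshold_k` times its robust baseline
#' noise SD — an increase relative to Fmin of at least `threshold_k` noise
#' SDs. `threshold_abs`, when given, is used as an absolute dff threshold
#' instead.
#'
#' Event boundaries use hysteresis: an event starts when the trace leaves the
#' re-arm level (baseline level + `rearm_k` noise SDs, always below the
#' detection threshold) and ends when it returns there, with interruptions
#' shorter than `merge_gap_s` bridged. Because the excursion segmentation
#' does not depend on the detection threshold, raising the threshold can
#' only remove events, never create them. With `merge_gap_s = 0` the
#' detector reduces to raw maximal runs above the threshold (the
#' [detect_runs_naive()] oracle semantics). Events lasting at least
#' `prolonged_cutoff_s` are classed `"prolonged"`, otherwise `"fast"`,
#' separating sustained single mobilizations from rapid peaks.
#'
#' Only viable (or, before gating, valid) cells are scanned, unless `cells`
#' is given explicitly.
#'
#' @param traces A `ca_traces` object.
#' @param epoch Label of the epoch to scan (default `"baseline"`).
#' @param threshold_k Noise-SD multiple for the detection threshold.
#' @param threshold_abs Absolute dF/F threshold overriding `threshold_k`.
#' @param threshold_floor Lower bound on the per-cell threshold (guards
#'   near-zero noise estimates).
#' @param min_duration_s Minimum event duration (default 0.6 s = 3 frames at
#'   5 Hz).
#' @param merge_gap_s Excursion interruptions shorter than this are bridged
#'   (default 0.4 s); 0 disables hysteresis and merging.
#' @param rearm_k Noise-SD multiple above the baseline level defining the
#'   hysteresis re-arm level (default 1).
#' @param prolonged_cutoff_s Duration at or above which an event is
#'   `"prolonged"`.
#' @param cells Optional integer vector of cell ids to scan.
#' @return Tibble of events: `cell_id`, `onset_s`, `peak_s`, `end_s`,
#'   `peak_dff`, `duration_s`, `shape_class`; non-overlapping and
#'   time-ordered within each cell.
#' @export
detect_events <- function(traces, epoch = "baseline",
                          threshold_k = 3.5, threshold_abs = NULL,
                          threshold_floor = 0.02,
                          min_duration_s = 0.6, merge_gap_s = 0.4,
                          rearm_k = 1, prolonged_cutoff_s = 10, cells = NULL) {
  stopifnot(inherits(traces, "ca_traces"))
  fi <- traces$frame_interval_s
  ep <- protocol_epoch(traces$protocol, epoch)
  if (ep$duration_s < min_duration_s) {
    abort(sprintf(
      "Epoch '%s' (%.1f s) is shorter than min_duration_s (%.1f s).",
      epoch, ep$duration_s, min_duration_s
    ))
  }
  idx <- frames_in_window(ep$start_s, ep$end_s, fi, ncol(traces$dff))
  if (is.null(cells)) {
    cells <- which(if (all(is.na(traces$viable_mask))) {
      traces$valid_mask
    } else {
      !is.na(traces$viable_mask) & traces$viable_mask
    })
  }
  min_frames <- max(1L, as.integer(ceiling(min_duration_s / fi - 1e-9)))
  gap_frames <- as.integer(ceiling(merge_gap_s / fi - 1e-9))

  out <- purrr::map(cells, function(i) {
    x <- traces$dff[i, idx]
    thr <- if (!is.null(threshold_abs)) {
      threshold_abs
    } else {
      traces$baseline_level[i] +
        max(threshold_k * traces$noise_sd[i], threshold_floor, na.rm = TRUE)
    }
    rearm <- traces$baseline_level[i] + rearm_k * traces$noise_sd[i]
    runs <- segment_events(x, thr, min_frames, gap_frames, end_level = rearm)
    if (!nrow(runs)) return(NULL)
    t0 <- (idx[1] - 1L) * fi
    purrr::pmap_dfr(runs, function(start, end) {
      seg <- x[start:end]
      pk <- which.max(seg)
      dur <- (end - start + 1L) * fi
      tibble::tibble(
        cell_id = i,
        onset_s = t0 + (start - 1L) * fi,
        peak_s = t0 + (start + pk - 2L) * fi,
        end_s = t0 + end * fi,
        peak_dff = seg[pk],
        duration_s = dur,
        shape_class = if (dur >= prolonged_cutoff_s) "prolonged" else "fast"
      )
    })
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble::tibble(
      cell_id = integer(0), onset_s = double(0), peak_s = double(0),
      end_s = double(0), peak_dff = double(0), duration_s = double(0),
      shape_class = character(0)
    )
  }
  out
}

#' Brute-force threshold-crossing oracle
#'
#' Reference implementation of supra-threshold run detection: an explicit
#' frame-by-frame scan with no merging and no minimum-duration rule, intended
#' for validating [detect_events()] on short traces (<= 5000 frames).
#' [detect_events()] with merging disabled and a one-frame minimum duration
#' must reproduce its run boundaries exactly.
#'
#' @param x Numeric dff trace (single cell).
#' @param threshold Absolute dF/F threshold.
#' @return Tibble with integer columns `start`, `end` (1-based frame indices
#'   of maximal runs with `x >= threshold`).
#' @export
detect_runs_naive <- function(x, threshold) {
  if (length(x) > 5000L) abort("Oracle is intended for traces of <= 5000 frames.")
  starts <- integer(0)
  ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(x)) {
    hit <- !is.na(x[i]) && x[i] >= threshold
    if (hit && !in_run) {
      starts <- c(starts, i)
      in_run <- TRUE
    }
    if (!hit && in_run) {
      ends <- c(ends, i - 1L)
      in_run <- FALSE
    }
  }
  if (in_run) ends <- c(ends, length(x))
  tibble::tibble(start = starts, end = ends)
}

#' Summarize spontaneous baseline activity per cell
#'
#' Counts baseline events per viable cell and converts them to rates over the
#' baseline epoch. A cell is spontaneously active iff it has at least one
#' baseline event. The population-level spontaneous fraction is computed over
#' viable cells only (the high-K denominator).
#'
#' @param events Event tibble from [detect_events()] (baseline epoch).
#' @param traces The `ca_traces` the events came from (for the viable set and
#'   baseline duration).
#' @return Tibble with one row per viable cell: `cell_id`, `n_events`,
#'   `rate_per_min`, `is_spontaneous`; the spontaneous fraction (of viable
#'   cells, in percent) is attached as attribute `pct_spontaneous`.
#' @export
summarize_spontaneous <- function(events, traces) {
  stopifnot(inherits(traces, "ca_traces"))
  base_ep <- protocol_epoch(traces$protocol, "baseline")
  viable <- which(!is.na(traces$viable_mask) & traces$viable_mask)
  if (!length(viable)) abort("No viable cells; run gate_viability() first.")
  counts <- events |>
    dplyr::filter(.data$cell_id %in% viable) |>
    dplyr::count(.data$cell_id, name = "n_events")
  out <- tibble::tibble(cell_id = viable) |>
    dplyr::left_join(counts, by = "cell_id") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      rate_per_min = .data$n_events / (base_ep$duration_s / 60),
      is_spontaneous = .data$n_events >= 1L
    )
  attr(out, "pct_spontaneous") <- 100 * mean(out$is_spontaneous)
  out
}
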