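#' Call a single cell's response to one secretagogue pulse
#'
#' The response window runs from pulse start to pulse end plus
#' `post_window_s` (default 30 s: a mobilization beginning shortly after the
#' pulse still counts). The call is positive iff an event — same detector and
#' threshold semantics as [detect_events()] — has its *onset* inside the
#' window, so ongoing baseline/wash activity drifting into the window does
#' not fire the call. The window peak dF/F is returned either way.
#'
#' @param traces A `ca_traces` object (viability gated).
#' @param cell_id Cell index.
#' @param stimulus One of the protocol's secretagogue labels.
#' @param post_window_s Seconds after pulse end still in the window.
#' @param ... Detector parameters passed to [detect_events()]
#'   (`threshold_k`, `threshold_abs`, `min_duration_s`, `merge_gap_s`, ...).
#' @return One-row tibble: `cell_id`, `stimulus`, `responds`, `peak_dff`.
#' @export
call_response <- function(traces, cell_id, stimulus, post_window_s = 30, ...) {
  classify_responses(traces,
    post_window_s = post_window_s, cells = cell_id,
    stimuli = stimulus, ...
  )
}

#' Call per-stimulus responses for all viable cells
#'
#' Vectorized form of [call_response()]: scans every secretagogue pulse
#' window for every viable cell and calls a response where an event onset
#' falls inside the window. Windows extending past the end of the recording
#' are truncated with a report.
#'
#' @inheritParams call_response
#' @param stimuli Stimulus labels to scan (default: all in the protocol).
#' @param cells Optional cell ids (default: all viable cells).
#' @return Tibble with one row per cell x stimulus: `cell_id`, `stimulus`,
#'   `responds` (logical), `peak_dff` (window peak, reported either way).
#' @export
classify_responses <- function(traces, post_window_s = 30, stimuli = NULL,
                               cells = NULL, ...) {
  stopifnot(inherits(traces, "ca_traces"))
  if (is.null(stimuli)) stimuli <- protocol_stimuli(traces$protocol)
  if (!length(stimuli)) abort("Protocol contains no secretagogue epochs.")
  if (is.null(cells)) {
    if (all(is.na(traces$viable_mask))) {
      abort("Run gate_viability() before classifying responses.")
    }
    cells <- which(!is.na(traces$viable_mask) & traces$viable_mask)
  }
  fi <- traces$frame_interval_s
  n_frames <- ncol(traces$dff)
  t_end <- n_frames * fi

  purrr::map_dfr(stimuli, function(stim) {
    ep <- protocol_epoch(traces$protocol, stim)
    win_end <- ep$end_s + post_window_s
    if (win_end > t_end + 1e-9) {
      inform(sprintf(
        "Response window for %s truncated at recording end (%.1f -> %.1f s).",
        stim, win_end, t_end
      ))
      win_end <- t_end
    }
    # temporary single-epoch protocol view so the detector scans the window
    win_events <- detect_window_events(traces, ep$start_s, win_end, cells, ...)
    idx <- frames_in_window(ep$start_s, win_end, fi, n_frames)
    peaks <- apply(traces$dff[cells, idx, drop = FALSE], 1, max, na.rm = TRUE)
    responded <- cells %in% win_events$cell_id
    tibble::tibble(
      cell_id = cells, stimulus = stim,
      responds = responded, peak_dff = peaks
    )
  })
}

# Detect events whose onset lies inside [start_s, end_s) for the given cells,
# using the same run semantics as detect_events().
detect_window_events <- function(traces, start_s, end_s, cells,
                                 threshold_k = 3.5, threshold_abs = NULL,
                                 threshold_floor = 0.02,
                                 min_duration_s = 0.6, merge_gap_s = 0.4,
                                 rearm_k = 1) {
  fi <- traces$frame_interval_s
  idx <- frames_in_window(start_s, end_s, fi, ncol(traces$dff))
  if (!length(idx)) {
    return(tibble::tibble(cell_id = integer(0), onset_s = double(0)))
  }
  min_frames <- max(1L, as.integer(ceiling(min_duration_s / fi - 1e-9)))
  gap_frames <- as.integer(ceiling(merge_gap_s / fi - 1e-9))
  out <- purrr::map_dfr(cells, function(i) {
    thr <- if (!is.null(threshold_abs)) {
      threshold_abs
    } else {
      traces$baseline_level[i] +
        max(threshold_k * traces$noise_sd[i], threshold_floor, na.rm = TRUE)
    }
    rearm <- traces$baseline_level[i] + rearm_k * traces$noise_sd[i]
    runs <- segment_events(traces$dff[i, idx], thr, min_frames, gap_frames,
      end_level = rearm
    )
    if (!nrow(runs)) return(NULL)
    onset <- (idx[1] - 1L + runs$start - 1L) * fi
    # an event clipped at the window start (trace already elevated in the
    # preceding frame) began earlier — baseline/wash activity, not a response
    start_level <- min(thr, max(rearm, -Inf), na.rm = TRUE)
    if (gap_frames == 0L) start_level <- thr
    first_run_carryover <- runs$start[1] == 1L && idx[1] > 1L &&
      !is.na(traces$dff[i, idx[1] - 1L]) &&
      traces$dff[i, idx[1] - 1L] >= start_level
    keep <- rep(TRUE, nrow(runs))
    if (first_run_carryover) keep[1] <- FALSE
    if (!any(keep)) return(NULL)
    tibble::tibble(cell_id = i, onset_s = onset[keep])
  })
  if (!nrow(out)) {
    out <- tibble::tibble(cell_id = integer(0), onset_s = double(0))
  }
  out
}

#' Classify viable cells as non-, mono-, or multi-responsive
#'
#' Applies the counting rule to the per-stimulus response calls:
#' non-responsive cells answer no secretagogue (only high K), mono-responsive
#' cells exactly one, multi-responsive cells two or more. The spontaneous
#' flag is carried over from the baseline analysis independently of the
#' category (a spontaneously active but stimulus-silent cell stays
#' non-responsive with `spontaneous = TRUE`).
#'
#' @param responses Tibble from [classify_responses()].
#' @param spontaneous Tibble from [summarize_spontaneous()] (optional; if
#'   omitted, all spontaneous flags are `FALSE`).
#' @param protocol The recording's protocol; used to check that every applied
#'   stimulus has a call for every cell.
#' @param collapse_trh If `TRUE`, TRH and TRH_DA are collapsed into a single
#'   TRH axis before counting (default `FALSE`: they are distinct stimuli).
#' @return Tibble with one row per cell: `cell_id`, `spontaneous`,
#'   `responds_<stimulus>` flag and `peak_<stimulus>` amplitude columns,
#'   `n_responses`, `category`.
#' @export
classify_cells <- function(responses, spontaneous = NULL, protocol = NULL,
                           collapse_trh = FALSE) {
  if (!all(c("cell_id", "stimulus", "responds") %in% names(responses))) {
    abort("`responses` must have columns cell_id, stimulus, responds.")
  }
  if (!is.null(protocol)) {
    need <- protocol_stimuli(protocol)
    have <- responses |>
      dplyr::count(.data$cell_id, .data$stimulus) |>
      dplyr::count(.data$cell_id, name = "n_stim")
    if (any(have$n_stim != length(need)) ||
      !all(need %in% unique(responses$stimulus))) {
      abort(sprintf(
        "Response vector incomplete: every cell needs a call for each of %s.",
        paste(need, collapse = ", ")
      ))
    }
  }
  resp <- responses
  if (collapse_trh && all(c("TRH", "TRH_DA") %in% resp$stimulus)) {
    resp <- resp |>
      dplyr::mutate(stimulus = ifelse(.data$stimulus == "TRH_DA", "TRH", .data$stimulus)) |>
      dplyr::group_by(.data$cell_id, .data$stimulus) |>
      dplyr::summarise(
        responds = any(.data$responds),
        peak_dff = max(.data$peak_dff),
        .groups = "drop"
      )
  }
  wide <- resp |>
    tidyr::pivot_wider(
      id_cols = "cell_id", names_from = "stimulus",
      values_from = c("responds", "peak_dff"),
      names_glue = "{.value}_{stimulus}"
    ) |>
    dplyr::rename_with(~ sub("^peak_dff_", "peak_", .x))
  flag_cols <- grep("^responds_", names(wide), value = TRUE)
  wide$n_responses <- rowSums(as.matrix(wide[flag_cols]))
  wide$category <- dplyr::case_when(
    wide$n_responses == 0 ~ "non_responsive",
    wide$n_responses == 1 ~ "mono_responsive",
    TRUE ~ "multi_responsive"
  )
  if (!is.null(spontaneous)) {
    wide <- wide |>
      dplyr::left_join(
        dplyr::select(spontaneous, "cell_id", "is_spontaneous"),
        by = "cell_id"
      ) |>
      dplyr::mutate(spontaneous = dplyr::coalesce(.data$is_spontaneous, FALSE)) |>
      dplyr::select(-"is_spontaneous")
  } else {
    wide$spontaneous <- FALSE
  }
  dplyr::relocate(wide, "cell_id", "spontaneous", "category", "n_responses")
}

#' Tumor-level responsiveness profile
#'
#' Aggregates per-cell classifications into the tumor fingerprint: the
#' percentages of spontaneously active, non-, mono-, and multi-responsive
#' cells, and the per-secretagogue response percentages, all over viable
#' cells (the high-K 100% denominator). The three category percentages sum
#' to 100 by construction.
#'
#' @param classifications Tibble from [classify_cells()] (viable cells only).
#' @param tumor_id Identifier for the tumor.
#' @param max_diameter_cm Optional maximum tumor diameter (cm).
#' @param recurrent_observed Optional observed recurrence flag.
#' @return One-row tibble: `tumor_id`, `n_viable`, `pct_spontaneous`,
#'   `pct_non`, `pct_mono`, `pct_multi`, `pct_<stimulus>` columns,
#'   `max_diameter_cm`, `recurrent_observed`.
#' @export
tumor_summary <- function(classifications, tumor_id = "tumor",
                          max_diameter_cm = NA_real_,
                          recurrent_observed = NA) {
  n <- nrow(classifications)
  if (n < 1) abort("Zero viable cells: tumor profile undefined.")
  flag_cols <- grep("^responds_", names(classifications), value = TRUE)
  per_stim <- purrr::map_dbl(flag_cols, ~ 100 * mean(classifications[[.x]]))
  names(per_stim) <- sub("^responds_", "pct_", flag_cols)
  out <- tibble::tibble(
    tumor_id = tumor_id,
    n_viable = n,
    pct_spontaneous = 100 * mean(classifications$spontaneous),
    pct_non = 100 * mean(classifications$category == "non_responsive"),
    pct_mono = 100 * mean(classifications$category == "mono_responsive"),
    pct_multi = 100 * mean(classifications$category == "multi_responsive")
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble_row(as.list(per_stim)))
  out$max_diameter_cm <- max_diameter_cm
  out$recurrent_observed <- recurrent_observed
  out
}
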