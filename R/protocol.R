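#' The five hypothalamic secretagogue labels
#'
#' Stimulus channels used throughout the package: corticotropin-releasing
#' hormone (CRH), growth-hormone-releasing hormone (GHRH),
#' gonadotropin-releasing hormone (GnRH), thyrotropin-releasing hormone (TRH),
#' and TRH combined with dopamine (TRH_DA). TRH_DA is a distinct stimulus
#' channel: it separates cells carrying both TRH and dopamine receptors
#' (lactotroph-like, inhibited by DA) from pure TRH responders.
#'
#' @export
SECRETAGOGUES <- c("CRH", "GHRH", "GnRH", "TRH", "TRH_DA")

epoch_labels_all <- c("baseline", SECRETAGOGUES, "wash", "high_K")

snap_down <- function(x, frame_interval_s) {
  floor(x / frame_interval_s + 1e-9) * frame_interval_s
}

#' Build a stimulation protocol
#'
#' Constructs the timed epoch table for a recording: an unstimulated baseline,
#' then for each secretagogue a short pulse followed by a wash, and finally a
#' terminal high-potassium (high_K) depolarization pulse that defines cell
#' viability. Defaults follow the acquisition scheme for perifused pituitary
#' adenoma tissue: frames every 0.2 s, a 3-min baseline, 30-s secretagogue
#' pulses separated by 15-min washes, and a 30-s high-K pulse.
#'
#' All epoch durations are snapped down to integral multiples of
#' `frame_interval_s` and recorded as snapped.
#'
#' @param stimulus_order Character vector: which secretagogues to apply and in
#'   what order. Must be a duplicate-free subset of [SECRETAGOGUES]. May be
#'   empty (baseline + high_K only).
#' @param baseline_s Baseline duration in seconds.
#' @param pulse_s Secretagogue pulse duration in seconds.
#' @param wash_s Wash duration between pulses in seconds.
#' @param frame_interval_s Seconds per acquired frame.
#' @param high_k_s High-potassium pulse duration in seconds.
#' @param compress Protocol compression factor (>= 1): wash durations are
#'   divided by this factor so test recordings stay short while pulse timing
#'   and response windows are untouched. `compress = 1` is the full protocol.
#' @return A `stim_protocol`: a tibble of epochs with columns `label`,
#'   `start_s`, `duration_s`, `end_s`, and attributes `frame_interval_s` and
#'   `total_duration_s`.
#' @examples
#' build_protocol()                      # full 4860-s protocol
#' build_protocol(compress = 10)         # washes shrunk 10x for fast runs
#' build_protocol(character(0), baseline_s = 10, wash_s = 5)
#' @export
build_protocol <- function(stimulus_order = SECRETAGOGUES,
                           baseline_s = 180,
                           pulse_s = 30,
                           wash_s = 900,
                           frame_interval_s = 0.2,
                           high_k_s = 30,
                           compress = 1) {
  if (frame_interval_s <= 0) abort("`frame_interval_s` must be > 0.")
  if (any(c(baseline_s, pulse_s, wash_s, high_k_s) <= 0)) {
    abort("All epoch durations must be > 0.")
  }
  if (length(compress) != 1L || compress < 1) {
    abort("`compress` must be a single factor >= 1.")
  }
  stimulus_order <- as.character(stimulus_order)
  if (anyDuplicated(stimulus_order)) {
    abort("Duplicate stimulus label in `stimulus_order`: each secretagogue may appear at most once.")
  }
  bad <- setdiff(stimulus_order, SECRETAGOGUES)
  if (length(bad)) {
    abort(sprintf("Unknown stimulus label(s): %s", paste(bad, collapse = ", ")))
  }

  wash_s <- wash_s / compress
  baseline_s <- snap_down(baseline_s, frame_interval_s)
  pulse_s <- snap_down(pulse_s, frame_interval_s)
  wash_s <- snap_down(wash_s, frame_interval_s)
  high_k_s <- snap_down(high_k_s, frame_interval_s)
  if (wash_s <= 0) abort("Compressed wash duration snapped to zero; use a smaller `compress`.")

  labels <- "baseline"
  durs <- baseline_s
  for (s in stimulus_order) {
    labels <- c(labels, s, "wash")
    durs <- c(durs, pulse_s, wash_s)
  }
  labels <- c(labels, "high_K")
  durs <- c(durs, high_k_s)
  starts <- cumsum(c(0, durs[-length(durs)]))

  epochs <- tibble::tibble(
    label = labels,
    start_s = starts,
    duration_s = durs,
    end_s = starts + durs
  )
  new_stim_protocol(epochs, frame_interval_s)
}

new_stim_protocol <- function(epochs, frame_interval_s) {
  out <- tibble::new_tibble(
    epochs,
    frame_interval_s = frame_interval_s,
    total_duration_s = max(epochs$end_s),
    class = "stim_protocol"
  )
  validate_protocol(out)
  out
}

#' Validate a stimulation protocol
#'
#' Checks the structural invariants of a [build_protocol()] epoch table:
#' ordered non-overlapping epochs, exactly one baseline and one terminal
#' high_K epoch, and no repeated secretagogue.
#'
#' @param protocol A `stim_protocol`.
#' @return `protocol`, invisibly, if valid; otherwise an error.
#' @export
validate_protocol <- function(protocol) {
  ep <- protocol
  if (!all(c("label", "start_s", "duration_s", "end_s") %in% names(ep))) {
    abort("Protocol must have columns label, start_s, duration_s, end_s.")
  }
  if (!all(ep$label %in% epoch_labels_all)) {
    abort(sprintf(
      "Unknown epoch label(s): %s",
      paste(setdiff(ep$label, epoch_labels_all), collapse = ", ")
    ))
  }
  if (is.unsorted(ep$start_s, strictly = TRUE)) {
    abort("Epochs must be strictly ordered by start_s.")
  }
  if (any(ep$end_s[-nrow(ep)] > ep$start_s[-1] + 1e-9)) {
    abort("Epochs must not overlap.")
  }
  if (sum(ep$label == "baseline") != 1L) abort("Exactly one baseline epoch required.")
  if (sum(ep$label == "high_K") != 1L) abort("Exactly one high_K epoch required.")
  stim <- ep$label[ep$label %in% SECRETAGOGUES]
  if (anyDuplicated(stim)) abort("Each secretagogue may appear at most once.")
  non_wash <- which(ep$label != "wash")
  if (ep$label[max(non_wash)] != "high_K") {
    abort("high_K must be the last stimulus epoch.")
  }
  tot <- attr(ep, "total_duration_s")
  if (is.null(tot) || tot < max(ep$end_s) - 1e-9) {
    abort("total_duration_s must cover the last epoch.")
  }
  invisible(protocol)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d epochs, %.1f s total, frame interval %.3g s\n",
    nrow(x), attr(x, "total_duration_s"), attr(x, "frame_interval_s")
  ))
  NextMethod()
}

# Single epoch row for a label (error if absent or not unique).
protocol_epoch <- function(protocol, label) {
  row <- protocol[protocol$label == label, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("Protocol must contain exactly one '%s' epoch.", label))
  }
  row
}

protocol_stimuli <- function(protocol) {
  protocol$label[protocol$label %in% SECRETAGOGUES]
}

protocol_n_frames <- function(protocol) {
  as.integer(ceiling(attr(protocol, "total_duration_s") / attr(protocol, "frame_interval_s") - 1e-9))
}
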