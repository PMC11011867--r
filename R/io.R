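protocol_to_list <- function(protocol) {
  list(
    frame_interval_s = attr(protocol, "frame_interval_s"),
    total_duration_s = attr(protocol, "total_duration_s"),
    epochs = purrr::pmap(
      protocol[c("label", "start_s", "duration_s")],
      function(label, start_s, duration_s) {
        list(label = label, start_s = start_s, duration_s = duration_s)
      }
    )
  )
}

protocol_from_list <- function(pl) {
  ep <- purrr::map_dfr(pl$epochs, tibble::as_tibble)
  ep$end_s <- ep$start_s + ep$duration_s
  new_stim_protocol(ep, pl$frame_interval_s)
}

#' Write a recording as delimited text plus a sidecar config
#'
#' Writes `<name>_traces.tsv` (cells x frames; first column `cell_id`, then
#' one column per frame headed by its time in seconds), `<name>_meta.yaml`
#' (protocol epochs, frame interval, seed and generator parameters), and,
#' when ground truth is attached, `<name>_ground_truth.tsv` with
#' `responds_to` collapsed to a `|`-separated list.
#'
#' @param rec A `ca_recording`.
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(rec, dir, name = "recording") {
  stopifnot(inherits(rec, "ca_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- frame_times(rec)
  tab <- tibble::as_tibble(rec$fluorescence, .name_repair = ~ sprintf("%.3f", t))
  tab <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(nrow(rec$fluorescence))), tab)
  traces_path <- file.path(dir, paste0(name, "_traces.tsv"))
  readr::write_tsv(tab, traces_path, progress = FALSE)

  meta <- list(
    frame_interval_s = rec$frame_interval_s,
    protocol = protocol_to_list(rec$protocol),
    spec = if (!is.null(rec$spec)) unclass(rec$spec)
  )
  meta_path <- file.path(dir, paste0(name, "_meta.yaml"))
  yaml::write_yaml(meta, meta_path)

  paths <- c(traces = traces_path, meta = meta_path)
  if (!is.null(rec$ground_truth)) {
    gt <- rec$ground_truth |>
      dplyr::mutate(responds_to = purrr::map_chr(
        .data$responds_to, ~ paste(.x, collapse = "|")
      ))
    gt_path <- file.path(dir, paste0(name, "_ground_truth.tsv"))
    readr::write_tsv(gt, gt_path, progress = FALSE)
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory holding the files.
#' @param name File stem used when writing.
#' @return A `ca_recording` (with ground truth if present on disk).
#' @export
read_recording <- function(dir, name = "recording") {
  traces_path <- file.path(dir, paste0(name, "_traces.tsv"))
  meta_path <- file.path(dir, paste0(name, "_meta.yaml"))
  if (!file.exists(traces_path) || !file.exists(meta_path)) {
    abort(sprintf("Recording files '%s_*' not found in %s", name, dir))
  }
  tab <- readr::read_tsv(traces_path, show_col_types = FALSE, progress = FALSE)
  meta <- yaml::read_yaml(meta_path)
  f <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(f) <- NULL
  rec <- structure(
    list(
      fluorescence = f,
      frame_interval_s = meta$frame_interval_s,
      protocol = protocol_from_list(meta$protocol),
      ground_truth = NULL,
      spec = meta$spec,
      truncations = tibble::tibble(
        cell_id = integer(), context = character(), onset_s = double()
      )
    ),
    class = "ca_recording"
  )
  gt_path <- file.path(dir, paste0(name, "_ground_truth.tsv"))
  if (file.exists(gt_path)) {
    gt <- readr::read_tsv(gt_path, show_col_types = FALSE, progress = FALSE)
    gt$responds_to <- purrr::map(gt$responds_to, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })
    rec$ground_truth <- gt
  }
  rec
}

#' Write normalized traces and the per-cell QC table
#'
#' Writes the dF/Fmin matrix in the same layout as [write_recording()] plus a
#' QC table with per-cell Fmin, bleach-fit parameters, robust noise SD,
#' validity and viability flags.
#'
#' @param traces A `ca_traces` object.
#' @param dir Output directory.
#' @param name File stem.
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(traces, dir, name = "normalized") {
  stopifnot(inherits(traces, "ca_traces"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- frame_times(traces)
  tab <- tibble::as_tibble(traces$dff, .name_repair = ~ sprintf("%.3f", t))
  tab <- dplyr::bind_cols(tibble::tibble(cell_id = seq_len(nrow(traces$dff))), tab)
  dff_path <- file.path(dir, paste0(name, "_dff.tsv"))
  readr::write_tsv(tab, dff_path, progress = FALSE)

  qc <- tibble::tibble(
    cell_id = seq_len(nrow(traces$dff)),
    fmin = traces$fmin,
    noise_sd = traces$noise_sd,
    valid = traces$valid_mask,
    viable = traces$viable_mask
  )
  if (!is.null(traces$bleach_params)) {
    qc <- dplyr::left_join(qc, traces$bleach_params, by = "cell_id")
  }
  qc_path <- file.path(dir, paste0(name, "_qc.tsv"))
  readr::write_tsv(qc, qc_path, progress = FALSE)
  invisible(c(dff = dff_path, qc = qc_path))
}

#' Export a recording as a single-channel multi-frame TIFF stack
#'
#' Renders each cell as a uniform disk on a square grid, frame by frame, so
#' ROI-extraction code can be exercised against known traces. Intensities
#' are scaled to the stack maximum. ROI centers/radii are returned for use
#' with [extract_roi_traces()]. Requires the `tiff` package.
#'
#' @param rec A `ca_recording`.
#' @param path Output `.tif` path.
#' @param roi_radius_px Disk radius in pixels.
#' @param frames Optional frame subset (indices) to keep the stack small.
#' @return Invisibly, a tibble of ROIs: `cell_id`, `x`, `y`, `radius`.
#' @export
write_recording_tiff <- function(rec, path, roi_radius_px = 3, frames = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required for TIFF export.")
  }
  f <- rec$fluorescence
  if (!is.null(frames)) f <- f[, frames, drop = FALSE]
  n <- nrow(f)
  side <- ceiling(sqrt(n))
  cell_px <- 2 * roi_radius_px + 3
  dim_px <- side * cell_px
  centers <- tibble::tibble(
    cell_id = seq_len(n),
    x = ((seq_len(n) - 1L) %% side) * cell_px + cell_px / 2,
    y = ((seq_len(n) - 1L) %/% side) * cell_px + cell_px / 2,
    radius = roi_radius_px
  )
  xg <- matrix(rep(seq_len(dim_px) - 0.5, dim_px), nrow = dim_px)
  yg <- t(xg)
  masks <- lapply(seq_len(n), function(i) {
    (xg - centers$x[i])^2 + (yg - centers$y[i])^2 <= roi_radius_px^2
  })
  fmax <- max(f)
  imgs <- lapply(seq_len(ncol(f)), function(j) {
    img <- matrix(0, dim_px, dim_px)
    for (i in seq_len(n)) img[masks[[i]]] <- f[i, j] / fmax
    img
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(centers)
}

#' Extract ROI mean-intensity traces from a TIFF stack
#'
#' Companion to [write_recording_tiff()]: averages pixel intensity inside
#' each fixed disk ROI, frame by frame. No ROI detection is performed; the
#' ROI geometry must be supplied.
#'
#' @param path TIFF stack path.
#' @param rois Tibble of `cell_id`, `x`, `y`, `radius` (as returned by
#'   [write_recording_tiff()]).
#' @return Matrix of cells x frames mean intensities (stack scale).
#' @export
extract_roi_traces <- function(path, rois) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required for TIFF import.")
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  dim_px <- nrow(imgs[[1]])
  xg <- matrix(rep(seq_len(dim_px) - 0.5, dim_px), nrow = dim_px)
  yg <- t(xg)
  masks <- lapply(seq_len(nrow(rois)), function(i) {
    (xg - rois$x[i])^2 + (yg - rois$y[i])^2 <= rois$radius[i]^2
  })
  out <- vapply(
    imgs,
    function(img) vapply(masks, function(m) mean(img[m]), numeric(1)),
    numeric(nrow(rois))
  )
  matrix(out, nrow = nrow(rois))
}
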