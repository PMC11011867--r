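#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a recording into a long tibble
#'
#' @param x A `ca_recording`.
#' @param ... Unused.
#' @return Tibble with `cell_id`, `time_s`, `fluorescence`.
#' @method tidy ca_recording
#' @export
tidy.ca_recording <- function(x, ...) {
  t <- frame_times(x)
  tibble::tibble(
    cell_id = rep(seq_len(nrow(x$fluorescence)), times = length(t)),
    time_s = rep(t, each = nrow(x$fluorescence)),
    fluorescence = as.vector(x$fluorescence)
  )
}

#' @rdname tidy.ca_recording
#' @method glance ca_recording
#' @export
glance.ca_recording <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$fluorescence),
    n_frames = ncol(x$fluorescence),
    frame_interval_s = x$frame_interval_s,
    duration_s = ncol(x$fluorescence) * x$frame_interval_s,
    has_ground_truth = !is.null(x$ground_truth),
    n_truncations = nrow(x$truncations)
  )
}

#' Tidy normalized traces into a long tibble
#'
#' @param x A `ca_traces`.
#' @param ... Unused.
#' @return Tibble with `cell_id`, `time_s`, `dff`, `viable`.
#' @method tidy ca_traces
#' @export
tidy.ca_traces <- function(x, ...) {
  t <- frame_times(x)
  n <- nrow(x$dff)
  tibble::tibble(
    cell_id = rep(seq_len(n), times = length(t)),
    time_s = rep(t, each = n),
    dff = as.vector(x$dff),
    viable = rep(x$viable_mask, times = length(t))
  )
}

#' @rdname tidy.ca_traces
#' @method glance ca_traces
#' @export
glance.ca_traces <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$dff),
    n_valid = sum(x$valid_mask),
    n_viable = sum(x$viable_mask, na.rm = TRUE),
    median_noise_sd = stats::median(x$noise_sd, na.rm = TRUE),
    fmin_median = stats::median(x$fmin, na.rm = TRUE)
  )
}

#' Tidy PCA results
#'
#' @param x A `ca_pca` from [run_pca()].
#' @param matrix Which component to return: `"scores"` (rows x PCs),
#'   `"loadings"` (features x PCs), or `"eigenvalues"` (one row per PC with
#'   explained variance percentages).
#' @param ... Unused.
#' @return A tibble in long form.
#' @method tidy ca_pca
#' @export
tidy.ca_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      PC = seq_along(x$explained_pct),
      percent = x$explained_pct,
      cumulative = cumsum(x$explained_pct)
    ))
  }
  m <- x[[if (matrix == "scores") "scores" else "loadings"]]
  id_col <- if (matrix == "scores") "row" else "feature"
  tibble::as_tibble(m, rownames = id_col) |>
    tidyr::pivot_longer(-dplyr::all_of(id_col), names_to = "PC", values_to = "value") |>
    dplyr::mutate(PC = as.integer(sub("^PC", "", .data$PC)))
}

#' @rdname tidy.ca_pca
#' @method glance ca_pca
#' @export
glance.ca_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$explained_pct),
    pc1_pct = x$explained_pct[1],
    pc2_pct = if (length(x$explained_pct) > 1) x$explained_pct[2] else NA_real_,
    pc12_pct = sum(x$explained_pct[seq_len(min(2, length(x$explained_pct)))])
  )
}
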