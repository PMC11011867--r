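# Difference-of-exponentials kernel constants (seconds).
# fast: rapid rise / decay, total width ~2-5 s at the 5% level;
# prolonged: slow mobilization, full-width-half-max >= 20 s.
kernel_taus <- list(
  fast = c(rise = 0.3, decay = 1.2),
  prolonged = c(rise = 4, decay = 25)
)

# Time at which the kernel has fallen back to `frac` of its peak (after the
# peak), found numerically once per call.
kernel_support_s <- function(shape_class, frac = 0.05) {
  tau <- kernel_taus[[shape_class]]
  tp <- tau[["rise"]] * tau[["decay"]] / (tau[["decay"]] - tau[["rise"]]) *
    log(tau[["decay"]] / tau[["rise"]])
  peak <- exp(-tp / tau[["decay"]]) - exp(-tp / tau[["rise"]])
  f <- function(t) exp(-t / tau[["decay"]]) - exp(-t / tau[["rise"]]) - frac * peak
  stats::uniroot(f, c(tp, 100 * tau[["decay"]]))$root
}

#' Render a single calcium transient as a sampled dF/F segment
#'
#' Evaluates a difference-of-exponentials kernel
#' `exp(-t/tau_decay) - exp(-t/tau_rise)` on the frame grid, scaled so the
#' sampled peak equals `amplitude`. Two shape classes mirror the two
#' morphologies seen in adenoma cells: `"fast"` (rise 0.3 s, decay 1.2 s;
#' rapidly increasing and decreasing peaks a few seconds wide) and
#' `"prolonged"` (rise 4 s, decay 25 s; a single sustained mobilization with
#' full-width-half-max above 20 s).
#'
#' If `duration_s` cuts the kernel off before it has decayed to 5% of its
#' peak, the segment is truncated and a `pitflux_truncation` warning is
#' signalled (never silently).
#'
#' @param shape_class `"fast"` or `"prolonged"`.
#' @param amplitude Peak dF/F of the transient; must be > 0.
#' @param onset_s Onset time within the returned segment (s).
#' @param frame_interval_s Seconds per frame.
#' @param duration_s Length of the returned segment (s).
#' @return Numeric vector of dF/F values of length
#'   `floor(duration_s / frame_interval_s)`, zero before `onset_s`,
#'   everywhere >= 0, with attribute `truncated` (logical).
#' @examples
#' seg <- render_transient("fast", 1, onset_s = 1, frame_interval_s = 0.2,
#'                         duration_s = 10)
#' max(seg)  # 1
#' @export
render_transient <- function(shape_class, amplitude, onset_s = 0,
                             frame_interval_s = 0.2, duration_s = 10) {
  shape_class <- match.arg(shape_class, c("fast", "prolonged"))
  if (length(amplitude) != 1L || is.na(amplitude) || amplitude <= 0) {
    abort("`amplitude` must be a single value > 0.")
  }
  if (frame_interval_s <= 0) abort("`frame_interval_s` must be > 0.")
  if (duration_s <= onset_s) abort("`duration_s` must exceed `onset_s`.")

  n <- as.integer(floor(duration_s / frame_interval_s + 1e-9))
  t <- (seq_len(n) - 1L) * frame_interval_s
  tau <- kernel_taus[[shape_class]]
  support <- kernel_support_s(shape_class)

  # normalize on the kernel's own sampled grid (same phase), so the sampled
  # peak equals `amplitude` exactly even though the grid may straddle the
  # analytic peak
  t_full <- seq(0, support + frame_interval_s, by = frame_interval_s)
  k_full <- exp(-t_full / tau[["decay"]]) - exp(-t_full / tau[["rise"]])
  scale <- amplitude / max(k_full)

  tt <- t - onset_s
  seg <- numeric(n)
  on_idx <- tt >= 0
  seg[on_idx] <- scale *
    (exp(-tt[on_idx] / tau[["decay"]]) - exp(-tt[on_idx] / tau[["rise"]]))
  seg[seg < 0] <- 0

  truncated <- (duration_s - onset_s) < support
  if (truncated) {
    warn(
      sprintf(
        "Transient truncated: %s kernel needs %.1f s to decay to 5%% of peak, window allows %.1f s.",
        shape_class, support, duration_s - onset_s
      ),
      class = "pitflux_truncation"
    )
  }
  attr(seg, "truncated") <- truncated
  seg
}

# Add one kernel to a trace in place (vector arithmetic on a frame range),
# clipped to [onset_s, clip_end_s). Returns the modified trace; truncation
# against clip_end_s is tallied by the caller via the returned attribute.
add_transient <- function(trace, shape_class, amplitude, onset_s,
                          frame_interval_s, clip_end_s) {
  n <- length(trace)
  tau <- kernel_taus[[shape_class]]
  support <- kernel_support_s(shape_class)
  idx <- frames_in_window(onset_s, clip_end_s, frame_interval_s, n)
  if (!length(idx)) {
    return(structure(trace, truncated = TRUE))
  }
  tt <- (idx - 1L) * frame_interval_s - onset_s
  t_full <- seq(0, support + frame_interval_s, by = frame_interval_s)
  k_full <- exp(-t_full / tau[["decay"]]) - exp(-t_full / tau[["rise"]])
  scale <- amplitude / max(k_full)
  k <- scale * (exp(-tt / tau[["decay"]]) - exp(-tt / tau[["rise"]]))
  k[k < 0 | tt < 0] <- 0
  trace[idx] <- trace[idx] + k
  structure(trace, truncated = (clip_end_s - onset_s) < support)
}
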