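# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort inform warn
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Largest-remainder allocation of counts to fractions
#'
#' Splits `n` items over categories so that realized counts are the exact
#' largest-remainder rounding of `n * fracs`: each category gets
#' `floor(n * f)` items and the leftover items go to the categories with the
#' largest fractional remainders (ties broken by category position, earlier
#' first). Used throughout the synthetic generator so that population
#' fractions are exact by construction rather than binomially sampled.
#'
#' @param n Total number of items (single non-negative integer).
#' @param fracs Numeric vector of fractions summing to 1 (tolerance 1e-9).
#' @return Integer vector of counts, same length and names as `fracs`,
#'   summing to `n`.
#' @examples
#' lr_allocate(1000, c(multi = 0.571, mono = 0.159, non = 0.270))
#' @export
lr_allocate <- function(n, fracs) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    abort("`n` must be a single non-negative count.")
  }
  if (any(fracs < -1e-12) || any(fracs > 1 + 1e-12)) {
    abort("All fractions must lie in [0, 1].")
  }
  if (abs(sum(fracs) - 1) > 1e-9) {
    abort(sprintf("Fractions must sum to 1 (got %.12f).", sum(fracs)))
  }
  raw <- n * fracs
  base <- floor(raw + 1e-9)
  rem <- raw - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))
    take <- ord[seq_len(left)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(round(base))
  names(out) <- names(fracs)
  out
}

# Robust noise SD of a dff trace segment: scaled MAD of the first difference
# divided by sqrt(2), insensitive to sparse calcium events.
robust_noise_sd <- function(x) {
  d <- diff(x)
  if (length(d) < 2L) return(0)
  stats::mad(d, constant = 1.4826) / sqrt(2)
}

# Frame indices (1-based) covered by [start_s, end_s) on a regular clock.
frames_in_window <- function(start_s, end_s, frame_interval_s, n_frames) {
  i0 <- max(1L, floor(start_s / frame_interval_s + 1e-9) + 1L)
  i1 <- min(n_frames, ceiling(end_s / frame_interval_s - 1e-9))
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}
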