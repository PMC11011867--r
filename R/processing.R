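#' Photobleach correction by lower-envelope exponential fitting
#'
#' Fits, per cell, a mono-exponential-plus-offset decay
#' `A * exp(-t / tau) + C` to a running lower envelope of the raw trace (the
#' rolling 10th percentile over a window of 5% of frames, evaluated on a
#' strided grid) and divides the fitted curve out, preserving the initial
#' scale. The envelope rather than the trace itself is fitted so that calcium
#' events do not bias the estimate, and an iterative robust reweighting sheds
#' envelope points sitting above the fit (calcium transients only ever push
#' the envelope up). A second pass masks event-carrying frames found against
#' the first-pass correction and refits each cell's amplitude and offset with
#' the decay constant pinned to the cross-cell median — bleaching kinetics
#' are a property of fluorophore and illumination shared by the field of
#' view, and cells dense with prolonged transients cannot otherwise anchor
#' the fit. Cells whose nonlinear fit fails to converge fall back to a
#' linear detrend of the envelope and are flagged.
#'
#' @param rec A `ca_recording` with >= 60 frames.
#' @param window_frac Envelope window length as a fraction of total frames.
#' @param envelope_quantile Quantile defining the lower envelope.
#' @return The recording with corrected `fluorescence` and an added
#'   `bleach_params` tibble (`cell_id`, `amplitude`, `tau_s`, `offset`,
#'   `method` = `"exponential"` or `"linear"`).
#' @export
correct_photobleach <- function(rec, window_frac = 0.05,
                                envelope_quantile = 0.10) {
  stopifnot(inherits(rec, "ca_recording"))
  f <- rec$fluorescence
  n_frames <- ncol(f)
  if (n_frames < 60) abort("Photobleach correction needs >= 60 frames per cell.")
  t <- frame_times(rec)
  fi <- rec$frame_interval_s

  win <- max(10L, as.integer(round(window_frac * n_frames)))
  stride <- max(1L, win %/% 4L)
  centers <- unique(c(
    seq(1L + win %/% 2L, n_frames - win %/% 2L, by = stride),
    n_frames - win %/% 2L
  ))
  # on a monotonically decaying baseline the q-th window quantile is attained
  # near the (1-q) position of the window, not its center; assign the
  # envelope point to that time so the fit is not systematically lagged
  tg <- t[centers] + (0.5 - envelope_quantile) * win * fi
  base_ep <- protocol_epoch(rec$protocol, "baseline")
  base_idx <- frames_in_window(base_ep$start_s, base_ep$end_s, fi, n_frames)

  n <- nrow(f)
  corrected <- f
  params <- vector("list", n)

  # pass 1: free per-cell fits give a cross-cell estimate of the bleaching
  # time constant (a property of fluorophore and illumination, shared by the
  # field of view, and much more robustly estimated from the cell majority)
  fits1 <- vector("list", n)
  for (i in seq_len(n)) {
    fits1[[i]] <- fit_envelope_robust(
      f[i, ], tg, centers, win, envelope_quantile,
      mask = NULL
    )
  }
  taus <- vapply(fits1, function(ft) {
    if (ft$method == "exponential") ft$tau_s else NA_real_
  }, numeric(1))
  tau_shared <- stats::median(taus, na.rm = TRUE)

  for (i in seq_len(n)) {
    fit1 <- fits1[[i]]
    # pass 2: mask frames carrying calcium events (detected against the
    # first-pass correction) so dense or prolonged transients cannot steer
    # the envelope, and refit amplitude/offset on the clean frames with the
    # shared time constant pinned
    curve1 <- pmax(fit1$fitted(t), 1e-6 * max(f[i, ]))
    flat1 <- f[i, ] / curve1
    m <- stats::median(flat1[base_idx])
    sigma <- robust_noise_sd(flat1[base_idx])
    # only sustained excursions (>= 3 frames) count as events; isolated
    # supra-threshold noise frames must not erode the clean-frame budget
    runs <- detect_runs(flat1, m + max(2 * sigma, 0.02 * m), min_frames = 3L)
    ev_mask <- rep(FALSE, n_frames)
    for (k in seq_len(nrow(runs))) ev_mask[runs$start[k]:runs$end[k]] <- TRUE
    ev_mask <- pad_mask(ev_mask, before = ceiling(5 / fi), after = ceiling(20 / fi))
    fitres <- if (!is.na(tau_shared) && any(ev_mask) && !all(ev_mask)) {
      fit_envelope_robust(
        f[i, ], tg, centers, win, envelope_quantile,
        mask = ev_mask, fallback = fit1,
        fit_fun = fit_bleach_fixed_tau(tau_shared)
      )
    } else {
      fit1
    }
    curve <- fitres$fitted(t)
    curve <- pmax(curve, 1e-6 * max(abs(curve)))
    corrected[i, ] <- f[i, ] / curve * curve[1]
    params[[i]] <- tibble::tibble(
      cell_id = i, amplitude = fitres$amplitude, tau_s = fitres$tau_s,
      offset = fitres$offset, method = fitres$method
    )
  }

  rec$fluorescence <- corrected
  rec$bleach_params <- dplyr::bind_rows(params)
  rec
}

# Extend a logical mask by `before`/`after` frames around every TRUE run.
pad_mask <- function(mask, before, after) {
  if (!any(mask)) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- mask
  for (k in which(r$values)) {
    i0 <- max(1L, starts[k] - before)
    i1 <- min(length(mask), ends[k] + after)
    out[i0:i1] <- TRUE
  }
  out
}

# Rolling lower-envelope extraction plus robust mono-exponential fit for one
# trace. `mask` marks frames to exclude from the envelope (event frames);
# grid windows left with fewer than a quarter of their frames are dropped.
fit_envelope_robust <- function(fvec, tg, centers, win, q, mask = NULL,
                                fallback = NULL, fit_fun = fit_bleach_envelope) {
  half <- win %/% 2L
  env <- rep(NA_real_, length(centers))
  for (k in seq_along(centers)) {
    idx <- (centers[k] - half):(centers[k] + half)
    if (!is.null(mask)) {
      idx <- idx[!mask[idx]]
      if (length(idx) < max(10L, win %/% 8L)) next
    }
    env[k] <- stats::quantile(fvec[idx], probs = q, names = FALSE, type = 7)
  }
  ok <- !is.na(env)
  if (sum(ok) < 5L) {
    if (!is.null(fallback)) return(fallback)
    ok <- rep(TRUE, length(env))
    env <- vapply(centers, function(c0) {
      stats::quantile(fvec[(c0 - half):(c0 + half)],
        probs = q, names = FALSE, type = 7
      )
    }, numeric(1))
  }
  tg <- tg[ok]
  env <- env[ok]

  fitres <- fit_fun(tg, env)
  # robust reweighting: envelope points sitting above the fit are event
  # contamination (calcium transients only push the envelope up), so the
  # residual scale is estimated from the lower side and high outliers are
  # shed iteratively until the fit tracks the clean envelope
  active <- rep(TRUE, length(env))
  min_keep <- max(5L, length(env) %/% 4L)
  for (pass in 1:12) {
    resid <- env - fitres$fitted(tg)
    ra <- resid[active]
    neg <- ra[ra < 0]
    s <- if (length(neg) >= 3) {
      1.4826 * stats::median(abs(neg))
    } else {
      stats::mad(ra, constant = 1.4826)
    }
    s <- max(s, 1e-9 * max(env))
    keep <- active & resid <= 3 * s
    if (sum(keep) == sum(active)) {
      # fit looks internally consistent, but a worst point far above the
      # lower-side scale means dense contamination is steering the fit:
      # peel the most elevated active points and refit
      if (max(ra) > 10 * s && sum(active) > min_keep) {
        n_drop <- max(1L, sum(active) %/% 10L)
        r2 <- resid
        r2[!active] <- -Inf
        worst <- order(r2, decreasing = TRUE)[seq_len(n_drop)]
        keep <- active
        keep[worst] <- FALSE
      } else {
        break
      }
    }
    if (sum(keep) < min_keep) break
    fitres2 <- fit_fun(tg[keep], env[keep])
    if (fitres2$method == "exponential" || fitres$method == "linear") {
      fitres <- fitres2
    }
    active <- keep
  }
  fitres
}

# Fixed-tau exponential fit: with the decay constant pinned, amplitude and
# offset are linear coefficients, so contaminated points cannot bend the
# curve and are exposed as residual structure.
fit_bleach_fixed_tau <- function(tau) {
  force(tau)
  function(tg, env) {
    x <- exp(-tg / tau)
    cf <- stats::coef(stats::lm(env ~ x))
    list(
      fitted = function(t) cf[[1]] + cf[[2]] * exp(-t / tau),
      amplitude = cf[[2]], tau_s = tau, offset = cf[[1]],
      method = "exponential"
    )
  }
}

# Fit A*exp(-t/tau)+C to envelope points; linear-detrend fallback.
fit_bleach_envelope <- function(tg, env) {
  c0 <- min(env)
  a0 <- max(env) - c0
  t_span <- max(tg) - min(tg)
  fit <- NULL
  if (a0 > 1e-9 * max(abs(env), 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        env ~ C + A * exp(-tg / tau),
        start = list(C = c0, A = a0, tau = t_span / 3),
        lower = c(C = 0, A = 0, tau = t_span / 200),
        upper = c(C = Inf, A = Inf, tau = t_span * 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    list(
      fitted = function(t) cf[["C"]] + cf[["A"]] * exp(-t / cf[["tau"]]),
      amplitude = cf[["A"]], tau_s = cf[["tau"]], offset = cf[["C"]],
      method = "exponential"
    )
  } else {
    lf <- stats::lm(env ~ tg)
    cf <- stats::coef(lf)
    list(
      fitted = function(t) cf[[1]] + cf[[2]] * t,
      amplitude = NA_real_, tau_s = NA_real_, offset = cf[[1]],
      method = "linear"
    )
  }
}

#' Normalize fluorescence to dF/Fmin
#'
#' Computes, per cell, the baseline fluorescence Fmin as the 5th percentile
#' of the photobleach-corrected trace over the *baseline epoch* (an attained
#' order statistic, so dF/Fmin is exactly 0 at the frame attaining Fmin;
#' robust to noise undershoot, unlike the global minimum), then
#' `dff = (F - Fmin) / Fmin`. Cells with `Fmin <= 0` are flagged invalid and
#' excluded downstream.
#'
#' @param rec A photobleach-corrected `ca_recording` (see
#'   [correct_photobleach()]; applying the correction first is the fixed
#'   processing order and is recorded in the output).
#' @param fmin_quantile Baseline-epoch quantile defining Fmin.
#' @return A `ca_traces` object: `dff` (cells x frames), `fmin`,
#'   `bleach_params`, `protocol`, `frame_interval_s`, `valid_mask`,
#'   `viable_mask` (all NA until [gate_viability()]), `noise_sd` (per-cell
#'   robust noise SD of baseline dff), plus pass-through `ground_truth`.
#' @export
normalize_dff <- function(rec, fmin_quantile = 0.05) {
  stopifnot(inherits(rec, "ca_recording"))
  protocol <- rec$protocol
  base_ep <- protocol_epoch(protocol, "baseline")
  idx <- frames_in_window(
    base_ep$start_s, base_ep$end_s, rec$frame_interval_s,
    ncol(rec$fluorescence)
  )
  if (!length(idx)) abort("Baseline epoch contains no frames.")

  f <- rec$fluorescence
  # type = 1 (inverse ECDF) returns an attained order statistic
  fmin <- apply(f[, idx, drop = FALSE], 1, stats::quantile,
    probs = fmin_quantile, names = FALSE, type = 1
  )
  valid <- fmin > 0
  if (any(!valid)) {
    inform(sprintf(
      "%d cell(s) flagged invalid (Fmin <= 0 after correction): %s",
      sum(!valid), paste(utils::head(which(!valid), 10), collapse = ", ")
    ))
  }
  dff <- (f - fmin) / ifelse(valid, fmin, NA_real_)

  noise_sd <- vapply(seq_len(nrow(dff)), function(i) {
    if (!valid[i]) return(NA_real_)
    robust_noise_sd(dff[i, idx])
  }, numeric(1))
  # resting dff level: with Fmin at the 5th percentile the noise floor sits
  # ~1.6 noise SDs above zero; excursions are measured from this level
  baseline_level <- vapply(seq_len(nrow(dff)), function(i) {
    if (!valid[i]) return(NA_real_)
    stats::median(dff[i, idx])
  }, numeric(1))

  structure(
    list(
      dff = dff,
      fmin = fmin,
      bleach_params = rec$bleach_params,
      protocol = protocol,
      frame_interval_s = rec$frame_interval_s,
      valid_mask = valid,
      viable_mask = rep(NA, nrow(dff)),
      noise_sd = noise_sd,
      baseline_level = baseline_level,
      ground_truth = rec$ground_truth,
      processing_order = "correct_photobleach -> normalize_dff"
    ),
    class = "ca_traces"
  )
}

#' @export
print.ca_traces <- function(x, ...) {
  nv <- sum(x$viable_mask, na.rm = TRUE)
  cat(sprintf(
    "<ca_traces> %d cells x %d frames, %d valid%s\n",
    nrow(x$dff), ncol(x$dff), sum(x$valid_mask),
    if (all(is.na(x$viable_mask))) " (viability not yet gated)"
    else sprintf(", %d viable", nv)
  ))
  invisible(x)
}

#' Gate cell viability on the high-potassium response
#'
#' A cell is viable iff its peak dF/F excursion above the resting baseline
#' level inside the high-K window (pulse start to pulse end + `post_s`)
#' exceeds `max(k_k * sigma, floor_dff)`, where `sigma` is the cell's robust
#' baseline noise SD (scaled MAD of the first difference of baseline dff /
#' sqrt(2)). Only cells that depolarize with high potassium
#' enter any downstream denominator: viable cells are "100% of analyzed
#' cells".
#'
#' @param traces A `ca_traces` from [normalize_dff()].
#' @param k_k Noise multiple for the gate (default 5).
#' @param floor_dff Absolute dF/F floor for the gate (default 0.05).
#' @param post_s Seconds after pulse end still counted as high-K response.
#' @return `traces` with `viable_mask` filled in. Errors if no cell passes
#'   (all downstream proportions would be undefined).
#' @export
gate_viability <- function(traces, k_k = 5, floor_dff = 0.05, post_s = 10) {
  stopifnot(inherits(traces, "ca_traces"))
  hk <- protocol_epoch(traces$protocol, "high_K")
  idx <- frames_in_window(
    hk$start_s, hk$end_s + post_s, traces$frame_interval_s, ncol(traces$dff)
  )
  if (!length(idx)) abort("high_K window contains no frames.")

  peak <- apply(traces$dff[, idx, drop = FALSE], 1, max)
  thr <- traces$baseline_level + pmax(k_k * traces$noise_sd, floor_dff)
  viable <- traces$valid_mask & !is.na(peak) & peak > thr
  if (!any(viable)) {
    abort("No cell passed the high-K viability gate; downstream proportions are undefined.")
  }
  traces$viable_mask <- viable
  traces
}
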