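#' Specify a synthetic cell population
#'
#' Bundles and validates the parameters of the synthetic-recording generator:
#' population size, the fractions of viable / spontaneously active /
#' non- / mono- / multi-responsive cells, stimulus assignment weights, and the
#' optical model (baseline fluorescence, photobleaching, noise). Fractions are
#' realized exactly by largest-remainder allocation (see [lr_allocate()]), so
#' a scenario's ground-truth proportions carry no sampling error.
#'
#' `frac_spontaneous`, `frac_non`, `frac_mono` and `frac_multi` are all
#' fractions *of viable cells*; the spontaneous flag is assigned independently
#' of the response category (a cell can be spontaneously active yet
#' stimulus-silent).
#'
#' @param n_cells Number of cells (ROIs) in the recording.
#' @param frac_viable Fraction of cells responding to the high-K pulse.
#' @param frac_spontaneous Fraction of viable cells with >= 1 baseline event.
#' @param frac_non,frac_mono,frac_multi Response-category fractions of viable
#'   cells; must sum to 1 (tolerance 1e-9).
#' @param per_stimulus_weights Named probability weights over
#'   [SECRETAGOGUES] used when drawing which stimuli a responsive cell
#'   answers to. Need not be normalized.
#' @param noise_sd Gaussian noise SD in dF/F units.
#' @param bleach_tau_s Photobleaching time constant (s).
#' @param bleach_depth Fraction of initial fluorescence lost at infinite time
#'   (mono-exponential decay toward `1 - bleach_depth`).
#' @param amplitude_spont Typical peak dF/F of a spontaneous baseline event.
#' @param amplitude_response Typical peak dF/F of a secretagogue response.
#' @param amplitude_high_k Peak dF/F of the high-K depolarization response.
#' @param frac_prolonged Fraction of cells whose single-event transients use
#'   the prolonged kernel shape instead of the fast one.
#' @param f0 Baseline fluorescence in arbitrary camera units.
#' @param seed Integer RNG seed; the whole recording is deterministic given it.
#' @return A validated `population_spec` list.
#' @seealso [sample_population()], [simulate_recording()], [tumor_scenario()]
#' @export
population_spec <- function(n_cells,
                            frac_viable = 1,
                            frac_spontaneous = 0,
                            frac_non = 1,
                            frac_mono = 0,
                            frac_multi = 0,
                            per_stimulus_weights = NULL,
                            noise_sd = 0.05,
                            bleach_tau_s = 300,
                            bleach_depth = 0.3,
                            amplitude_spont = 0.6,
                            amplitude_response = 1.0,
                            amplitude_high_k = 2.0,
                            frac_prolonged = 0.15,
                            f0 = 100,
                            seed = 1L) {
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 1) {
    abort("`n_cells` must be a single count >= 1.")
  }
  fr <- c(
    frac_viable = frac_viable, frac_spontaneous = frac_spontaneous,
    frac_non = frac_non, frac_mono = frac_mono, frac_multi = frac_multi,
    frac_prolonged = frac_prolonged
  )
  if (any(fr < -1e-12 | fr > 1 + 1e-12)) {
    abort("All fractions must lie in [0, 1].")
  }
  if (abs(frac_non + frac_mono + frac_multi - 1) > 1e-9) {
    abort(sprintf(
      "frac_non + frac_mono + frac_multi must equal 1 (got %.12f).",
      frac_non + frac_mono + frac_multi
    ))
  }
  if (is.null(per_stimulus_weights)) {
    per_stimulus_weights <- stats::setNames(rep(1, 5), SECRETAGOGUES)
  }
  if (!all(SECRETAGOGUES %in% names(per_stimulus_weights))) {
    abort("`per_stimulus_weights` must be named over all five secretagogues.")
  }
  if (any(per_stimulus_weights < 0) || sum(per_stimulus_weights) <= 0) {
    abort("`per_stimulus_weights` must be non-negative with positive sum.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (bleach_depth < 0 || bleach_depth >= 1) abort("`bleach_depth` must be in [0, 1).")
  if (bleach_tau_s <= 0) abort("`bleach_tau_s` must be > 0.")
  if (f0 <= 0) abort("`f0` must be > 0.")

  structure(
    list(
      n_cells = as.integer(n_cells),
      frac_viable = frac_viable,
      frac_spontaneous = frac_spontaneous,
      frac_non = frac_non,
      frac_mono = frac_mono,
      frac_multi = frac_multi,
      per_stimulus_weights = per_stimulus_weights[SECRETAGOGUES],
      noise_sd = noise_sd,
      bleach_tau_s = bleach_tau_s,
      bleach_depth = bleach_depth,
      amplitude_spont = amplitude_spont,
      amplitude_response = amplitude_response,
      amplitude_high_k = amplitude_high_k,
      frac_prolonged = frac_prolonged,
      f0 = f0,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<population_spec> %d cells (viable %.1f%%)\n",
      "  categories: non %.1f%% / mono %.1f%% / multi %.1f%%; spontaneous %.1f%%\n",
      "  noise_sd %.3g dF/F, bleach depth %.2f (tau %.0f s), seed %d\n"
    ),
    x$n_cells, 100 * x$frac_viable,
    100 * x$frac_non, 100 * x$frac_mono, 100 * x$frac_multi,
    100 * x$frac_spontaneous, x$noise_sd, x$bleach_depth, x$bleach_tau_s, x$seed
  ))
  invisible(x)
}

#' Draw per-cell ground truth for a synthetic population
#'
#' Assigns each cell its hidden labels: viability, spontaneous activity (with
#' an event count drawn uniformly from 1-12 for spontaneously active cells),
#' response category and the identity of the stimuli it answers
#' (mono-responsive cells draw exactly one secretagogue, multi-responsive
#' cells two to five distinct ones, weighted by `per_stimulus_weights`),
#' a per-cell amplitude multiplier, and a transient shape class. Category,
#' spontaneity and viability counts are exact largest-remainder allocations of
#' the spec fractions; which cells carry which label is randomized by the
#' seed, so different seeds give identical counts but different assignments.
#'
#' Non-viable cells respond to nothing and are never spontaneously active.
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per cell: `cell_id`, `viable`, `spontaneous`,
#'   `n_spontaneous_events`, `responds_to` (list-column of character vectors),
#'   `category` (`non_responsive` / `mono_responsive` / `multi_responsive`,
#'   `NA` for non-viable cells), `amplitude_scale`, `shape_class`.
#' @examples
#' pop <- sample_population(population_spec(
#'   n_cells = 100, frac_non = 0.27, frac_mono = 0.159, frac_multi = 0.571
#' ))
#' table(pop$category)
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_cells
  with_seed(spec$seed, {
    viable_counts <- lr_allocate(n, c(spec$frac_viable, 1 - spec$frac_viable))
    viable <- sample(rep(c(TRUE, FALSE), viable_counts))
    n_viable <- viable_counts[[1]]

    category <- rep(NA_character_, n)
    spontaneous <- rep(FALSE, n)
    if (n_viable > 0) {
      cat_counts <- lr_allocate(
        n_viable,
        c(
          non_responsive = spec$frac_non,
          mono_responsive = spec$frac_mono,
          multi_responsive = spec$frac_multi
        )
      )
      category[viable] <- sample(rep(names(cat_counts), cat_counts))
      sp_counts <- lr_allocate(n_viable, c(spec$frac_spontaneous, 1 - spec$frac_spontaneous))
      spontaneous[viable] <- sample(rep(c(TRUE, FALSE), sp_counts))
    }

    n_events <- integer(n)
    n_events[spontaneous] <- sample(1:12, sum(spontaneous), replace = TRUE)

    w <- spec$per_stimulus_weights
    responds_to <- purrr::map(category, function(cat) {
      if (is.na(cat) || cat == "non_responsive") return(character(0))
      if (cat == "mono_responsive") {
        sample(SECRETAGOGUES, 1, prob = w)
      } else {
        k <- sample(2:5, 1)
        sample(SECRETAGOGUES, k, prob = w)
      }
    })

    amplitude_scale <- stats::runif(n, 0.8, 1.2)
    shape_counts <- lr_allocate(n, c(spec$frac_prolonged, 1 - spec$frac_prolonged))
    shape_class <- sample(rep(c("prolonged", "fast"), shape_counts))

    tibble::tibble(
      cell_id = seq_len(n),
      viable = viable,
      spontaneous = spontaneous,
      n_spontaneous_events = n_events,
      responds_to = responds_to,
      category = category,
      amplitude_scale = amplitude_scale,
      shape_class = shape_class
    )
  })
}

#' Printed per-tumor scenarios from the adenoma series
#'
#' Returns a [population_spec()] parameterized with the responsiveness
#' fingerprint printed for one of three reference tumors in the 13-adenoma
#' series:
#'
#' * `"tumor2"` — the highly recurrent tumor: 57.4% spontaneously active,
#'   57.1% multi-responsive, 15.9% mono-responsive, 27.0% non-responsive.
#' * `"tumor4"` — overwhelmingly non-responsive (97.9%) and silent at
#'   baseline; the unprinted 2.1% remainder is split equally mono/multi.
#' * `"tumor8"` — overwhelmingly mono-responsive (96.3%; 3.16% non, 0.22%
#'   multi, renormalized to sum to 1) and silent at baseline, with responses
#'   concentrated on TRH_DA.
#'
#' @param name One of `"tumor2"`, `"tumor4"`, `"tumor8"`.
#' @param n_cells Number of (viable) cells to simulate.
#' @param seed RNG seed.
#' @param ... Further arguments passed to [population_spec()].
#' @return A `population_spec`.
#' @export
tumor_scenario <- function(name = c("tumor2", "tumor4", "tumor8"),
                           n_cells = 500, seed = 1L, ...) {
  name <- match.arg(name)
  pars <- switch(name,
    tumor2 = list(
      frac_spontaneous = 0.574,
      frac_non = 0.270, frac_mono = 0.159, frac_multi = 0.571
    ),
    tumor4 = list(
      frac_spontaneous = 0,
      frac_non = 0.979, frac_mono = 0.0105, frac_multi = 0.0105
    ),
    tumor8 = {
      f <- c(non = 3.16, mono = 96.3, multi = 0.22)
      f <- f / sum(f)
      list(
        frac_spontaneous = 0,
        frac_non = f[["non"]], frac_mono = f[["mono"]], frac_multi = f[["multi"]],
        per_stimulus_weights = c(CRH = 1, GHRH = 1, GnRH = 1, TRH = 1, TRH_DA = 20)
      )
    }
  )
  args <- c(list(n_cells = n_cells, frac_viable = 1, seed = seed), pars, list(...))
  do.call(population_spec, args)
}
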