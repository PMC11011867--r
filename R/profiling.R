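default_profile_features <- function(profiles) {
  cand <- c(
    "pct_spontaneous", "pct_non", "pct_mono", "pct_multi",
    paste0("pct_", SECRETAGOGUES), "max_diameter_cm"
  )
  intersect(cand, names(profiles))
}

#' Build a standardized tumor feature matrix
#'
#' Assembles the per-tumor responsiveness fingerprint — spontaneous and
#' category percentages, per-secretagogue percentages, and tumor size — into
#' a tumors x features matrix, standardizes every column to zero mean and
#' unit variance, and drops constant columns with a report.
#'
#' @param profiles Tibble of tumor profiles ([tumor_summary()] rows), >= 2
#'   tumors.
#' @param features Character vector of feature columns (default: all
#'   available fingerprint columns).
#' @return Standardized numeric matrix with tumor ids as row names; dropped
#'   constant features are recorded in attribute `dropped`.
#' @export
build_feature_table <- function(profiles, features = NULL) {
  if (nrow(profiles) < 2) abort("Need >= 2 tumors to build a feature table.")
  if (is.null(features)) features <- default_profile_features(profiles)
  missing <- setdiff(features, names(profiles))
  if (length(missing)) {
    abort(sprintf("Missing feature(s): %s", paste(missing, collapse = ", ")))
  }
  for (f in features) {
    bad <- which(is.na(profiles[[f]]))
    if (length(bad)) {
      abort(sprintf(
        "Missing value for feature '%s' in tumor '%s'.",
        f, profiles$tumor_id[bad[1]]
      ))
    }
  }
  x <- as.matrix(profiles[features])
  rownames(x) <- profiles$tumor_id
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    inform(sprintf(
      "Dropping constant feature(s): %s", paste(dropped, collapse = ", ")
    ))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(x)) abort("All features are constant; nothing to analyze.")
  x <- scale(x)
  attr(x, "dropped") <- dropped
  x
}

#' Principal component analysis of tumor fingerprints
#'
#' PCA of the standardized feature matrix (singular value decomposition of
#' the centered data, equivalent to an eigendecomposition of the feature
#' covariance). Component signs are fixed so that each loading vector's
#' largest-magnitude entry is positive, making results reproducible across
#' platforms.
#'
#' @param x Standardized feature matrix from [build_feature_table()].
#' @return A `ca_pca` object: `scores` (tumors x components), `loadings`
#'   (features x components), `explained_pct` (non-increasing, summing to
#'   100).
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 1) abort("PCA needs >= 2 rows and >= 1 column.")
  if (all(abs(x - mean(x)) < 1e-12)) abort("Degenerate (rank-0) matrix.")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  ev <- p$sdev^2
  structure(
    list(
      scores = scores,
      loadings = rot,
      explained_pct = 100 * ev / sum(ev)
    ),
    class = "ca_pca"
  )
}

#' @export
print.ca_pca <- function(x, ...) {
  k <- min(3L, length(x$explained_pct))
  cat(sprintf(
    "<ca_pca> %d x %d scores; explained %% : %s%s\n",
    nrow(x$scores), ncol(x$scores),
    paste(sprintf("PC%d %.1f", seq_len(k), x$explained_pct[seq_len(k)]),
      collapse = ", "
    ),
    if (length(x$explained_pct) > k) ", ..." else ""
  ))
  invisible(x)
}

#' Hierarchical clustering of tumors on correlation distance
#'
#' Agglomerative clustering of tumor fingerprints using correlation distance
#' (`1 - Pearson r` between tumor rows) and, by default, complete linkage —
#' the association analysis behind proportion heatmaps. Given a fixed input
#' order the result is deterministic; ties are resolved by `stats::hclust`'s
#' standard lowest-index merge ordering.
#'
#' @param x Feature matrix from [build_feature_table()] (>= 2 tumors).
#' @param k Number of clusters to cut the tree at.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return List with `hclust` (the tree), `order` (dendrogram leaf order),
#'   `clusters` (named integer vector of labels at `k`).
#' @export
cluster_tumors <- function(x, k = 2, linkage = "complete") {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Need >= 2 tumors to cluster.")
  if (k > nrow(x)) abort("Fewer tumors than requested clusters.")
  row_sd <- apply(x, 1, stats::sd)
  if (any(row_sd == 0)) {
    abort(sprintf(
      "Tumor row(s) with zero variance across features (correlation undefined): %s",
      paste(rownames(x)[row_sd == 0], collapse = ", ")
    ))
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = linkage)
  list(
    hclust = hc,
    order = hc$order,
    clusters = stats::cutree(hc, k = k)
  )
}

#' Predict tumor recurrence from the responsiveness fingerprint
#'
#' Formalizes the observed recurrence association as a conjunction of three
#' threshold clauses: a tumor is predicted recurrent iff it shows any
#' spontaneous baseline calcium activity (`pct_spontaneous > spont_gt`),
#' more than `multi_gt`% multi-responsive cells, and fewer than `non_lt`%
#' non-responsive cells. Default cut-offs: 0, 20 and 50. Each clause's
#' outcome is returned so the rule trace can be inspected.
#'
#' @param profiles Tibble with `pct_spontaneous`, `pct_multi`, `pct_non`
#'   columns (e.g. [tumor_summary()] rows).
#' @param spont_gt Spontaneous-percentage threshold (strictly greater).
#' @param multi_gt Multi-responsive threshold in percent (strictly greater).
#' @param non_lt Non-responsive threshold in percent (strictly less).
#' @return `profiles` with added logical columns `clause_spontaneous`,
#'   `clause_multi`, `clause_non`, and `recurrent_predicted`.
#' @examples
#' predict_recurrence(tibble::tibble(
#'   tumor_id = c("2", "4", "8"),
#'   pct_spontaneous = c(57.4, 0, 0),
#'   pct_non = c(27, 97.9, 3.16),
#'   pct_multi = c(57.1, 0.1, 0.22)
#' ))
#' @export
predict_recurrence <- function(profiles, spont_gt = 0, multi_gt = 20,
                               non_lt = 50) {
  need <- c("pct_spontaneous", "pct_multi", "pct_non")
  if (!all(need %in% names(profiles))) {
    abort(sprintf("`profiles` needs columns %s.", paste(need, collapse = ", ")))
  }
  pc <- profiles[need]
  if (any(unlist(pc) < -1e-9 | unlist(pc) > 100 + 1e-9, na.rm = TRUE)) {
    abort("Percentages must lie in [0, 100].")
  }
  profiles |>
    dplyr::mutate(
      clause_spontaneous = .data$pct_spontaneous > spont_gt,
      clause_multi = .data$pct_multi > multi_gt,
      clause_non = .data$pct_non < non_lt,
      recurrent_predicted = .data$clause_spontaneous &
        .data$clause_multi & .data$clause_non
    )
}

#' Simulate a cohort of tumor fingerprints from two latent factors
#'
#' Generates per-tumor responsiveness profiles driven by two latent axes —
#' overall responsiveness (multi vs non) and spontaneity — plus small
#' Gaussian noise, emulating the separation between recurrent-like
#' (responsive, spontaneously active) and non-recurrent-like tumors. Useful
#' for validating PCA and clustering behavior on profiles whose low-rank
#' structure is known.
#'
#' @param n_tumors Number of tumors.
#' @param frac_recurrent Fraction of recurrent-like tumors (largest-remainder
#'   allocation).
#' @param noise_sd SD of the Gaussian feature noise (percentage points).
#' @param seed RNG seed.
#' @return Tibble of profiles with `tumor_id`, the fingerprint columns,
#'   `max_diameter_cm`, and the generating `group`
#'   (`"recurrent_like"` / `"non_recurrent_like"`).
#' @export
simulate_cohort <- function(n_tumors = 13, frac_recurrent = 0.4,
                            noise_sd = 3, seed = 1L) {
  if (n_tumors < 2) abort("Need >= 2 tumors.")
  with_seed(seed, {
    counts <- lr_allocate(n_tumors, c(frac_recurrent, 1 - frac_recurrent))
    group <- sample(rep(c("recurrent_like", "non_recurrent_like"), counts))
    rec <- group == "recurrent_like"
    # latent axes
    resp <- ifelse(rec, stats::runif(n_tumors, 0.6, 0.95),
      stats::runif(n_tumors, 0.05, 0.35)
    )
    spont <- ifelse(rec, stats::runif(n_tumors, 0.5, 0.9),
      stats::runif(n_tumors, 0, 0.15)
    )
    clamp <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))
    pct_multi <- clamp(60 * resp + stats::rnorm(n_tumors, 0, noise_sd))
    pct_non <- clamp(90 * (1 - resp) + stats::rnorm(n_tumors, 0, noise_sd))
    over <- pct_multi + pct_non
    scale_down <- ifelse(over > 100, 100 / over, 1)
    pct_multi <- pct_multi * scale_down
    pct_non <- pct_non * scale_down
    pct_mono <- 100 - pct_multi - pct_non
    per_stim <- purrr::map(SECRETAGOGUES, function(s) {
      clamp(70 * resp + stats::rnorm(n_tumors, 0, noise_sd))
    })
    names(per_stim) <- paste0("pct_", SECRETAGOGUES)
    tibble::tibble(
      tumor_id = as.character(seq_len(n_tumors)),
      pct_spontaneous = clamp(100 * spont + stats::rnorm(n_tumors, 0, noise_sd)),
      pct_non = pct_non,
      pct_mono = pct_mono,
      pct_multi = pct_multi,
      !!!per_stim,
      max_diameter_cm = clamp(3 + 3 * spont + stats::rnorm(n_tumors, 0, 0.3), 1, 10),
      group = group
    )
  })
}
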