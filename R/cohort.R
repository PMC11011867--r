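cohort_schema <- c(
  "tumor_id", "age", "sex", "max_diameter_cm", "ihc_phenotype",
  "lineage_marker", "deficiency", "recurrent", "n_recurrences", "treatments"
)

deficiency_tokens <- c("TSH", "ACTH", "GH", "PRL", "LH", "FSH", "All", "None")

#' Load the packaged 13-patient cohort table
#'
#' Reads the clinical characteristics of the 13 adenoma patients (age, sex,
#' maximum tumor diameter, immunohistochemical phenotype, lineage marker,
#' pituitary hormone deficiencies, recurrence status and treatments) shipped
#' with the package, or an external table with the same schema. Multi-valued
#' fields (`deficiency`, `treatments`) are `;`-separated token lists;
#' `deficiency` may be `"All"` (every axis deficient) or `"None"`.
#'
#' @param path Path to a TSV with the cohort schema; defaults to the
#'   packaged fixture.
#' @return Tibble with one row per patient/tumor.
#' @export
load_cohort <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_table1.tsv", package = "pitflux")
  }
  ch <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_schema, names(ch))
  if (length(missing)) {
    abort(sprintf(
      "Cohort table lacks column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  ch
}

split_tokens <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), trimws)
}

#' Summarize the patient cohort
#'
#' Recomputes cohort-level counts and percentages from the clinical table by
#' exact string-category matching: recurrence, individual hormone-axis
#' deficiencies (an `"All"` entry counts toward every axis), lineage markers,
#' surgery/treatment modalities, plus recomputed age and tumor-diameter
#' means. Percentages are count / n patients, rounded to one decimal.
#'
#' @param cohort Tibble from [load_cohort()].
#' @return A list with `n_patients`, `age_mean`, `age_sd`, `n_female`,
#'   `diameter_mean_cm`, `diameter_sd_cm`, and a tibble `counts` with columns
#'   `group` (`recurrence` / `deficiency` / `lineage_marker` / `treatment`),
#'   `level`, `count`, `pct`.
#' @examples
#' cs <- summarize_cohort(load_cohort())
#' subset(cs$counts, group == "recurrence")
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) abort("Cohort table is empty; summaries undefined.")
  n <- nrow(cohort)
  pct <- function(k) round(100 * k / n, 1)

  if (!all(cohort$recurrent %in% c("Yes", "No"))) {
    bad <- setdiff(unique(cohort$recurrent), c("Yes", "No"))
    abort(sprintf("Unknown recurrence token(s): %s", paste(bad, collapse = ", ")))
  }
  defs <- split_tokens(cohort$deficiency)
  bad <- setdiff(unique(unlist(defs)), deficiency_tokens)
  if (length(bad)) {
    abort(sprintf("Unknown deficiency token(s): %s", paste(bad, collapse = ", ")))
  }
  axes <- setdiff(deficiency_tokens, c("All", "None"))
  def_counts <- purrr::map_int(axes, function(ax) {
    sum(purrr::map_lgl(defs, ~ ax %in% .x || "All" %in% .x))
  })
  trts <- split_tokens(cohort$treatments)
  trt_levels <- sort(unique(unlist(trts)))
  trt_counts <- purrr::map_int(trt_levels, function(tk) {
    sum(purrr::map_lgl(trts, ~ tk %in% .x))
  })
  lm_levels <- sort(unique(cohort$lineage_marker))
  lm_counts <- purrr::map_int(lm_levels, ~ sum(cohort$lineage_marker == .x))
  n_rec <- sum(cohort$recurrent == "Yes")

  counts <- dplyr::bind_rows(
    tibble::tibble(
      group = "recurrence", level = c("recurrent", "non_recurrent"),
      count = c(n_rec, n - n_rec)
    ),
    tibble::tibble(group = "deficiency", level = axes, count = def_counts),
    tibble::tibble(group = "lineage_marker", level = lm_levels, count = lm_counts),
    tibble::tibble(group = "treatment", level = trt_levels, count = trt_counts)
  ) |>
    dplyr::mutate(pct = pct(.data$count))

  list(
    n_patients = n,
    age_mean = mean(cohort$age),
    age_sd = stats::sd(cohort$age),
    n_female = sum(cohort$sex == "F"),
    diameter_mean_cm = mean(cohort$max_diameter_cm),
    diameter_sd_cm = stats::sd(cohort$max_diameter_cm),
    counts = counts
  )
}
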