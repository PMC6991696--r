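#' Per-sample delta-Ct against the spike-in reference
#'
#' Subtracts each sample's reference-assay Ct (the exogenous spike-in,
#' e.g. cel-miR-39) from every marker Ct of that sample:
#' \eqn{\Delta Ct_{ji} = Ct_{ji} - Ct_{ref,i}}. Nondetect marker wells are
#' imputed at the censoring limit before subtraction and flagged
#' `censored`; the flag is carried through all downstream summaries, never
#' silently dropped. A nondetect in the reference assay itself is an error
#' (the spike-in must amplify in every sample).
#'
#' @param ct Long Ct tibble (`assay_id`, `sample_id`, `ct`, `nondetect`),
#'   e.g. `simulate_cohort(...)$ct`.
#' @param reference_assay_id,nondetect_limit Defaults are taken from the
#'   attributes the cohort generator / reader attach to `ct`.
#' @return Tibble `assay_id`, `sample_id`, `dct`, `censored` (reference row
#'   removed), carrying the same attributes.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_markers_total = 5, seed = 3))
#' delta_ct(cohort$ct)
#' @export
delta_ct <- function(ct, reference_assay_id = NULL, nondetect_limit = NULL) {
  check_columns(ct, c("assay_id", "sample_id", "ct", "nondetect"), "Ct table")
  ref_id <- ct_attr(ct, "reference_assay_id", reference_assay_id)
  limit <- ct_attr(ct, "nondetect_limit", nondetect_limit)

  ref <- dplyr::filter(ct, .data$assay_id == ref_id)
  if (nrow(ref) == 0) {
    abort_exopanel(sprintf("reference assay '%s' not present", ref_id))
  }
  missing_ref <- setdiff(unique(ct$sample_id), ref$sample_id)
  if (length(missing_ref) > 0) {
    abort_exopanel(sprintf("reference assay missing for sample(s): %s",
                           paste(missing_ref, collapse = ", ")))
  }
  bad <- ref$sample_id[ref$nondetect | ref$ct >= limit]
  if (length(bad) > 0) {
    abort_exopanel(
      sprintf("reference assay is nondetect in sample(s): %s",
              paste(bad, collapse = ", ")),
      class = "exopanel_reference_nondetect"
    )
  }

  out <- ct |>
    dplyr::filter(.data$assay_id != ref_id) |>
    dplyr::mutate(censored = .data$nondetect,
                  ct_imp = pmin(.data$ct, limit)) |>
    dplyr::left_join(
      dplyr::select(ref, "sample_id", ref_ct = "ct"),
      by = "sample_id"
    ) |>
    dplyr::mutate(dct = .data$ct_imp - .data$ref_ct) |>
    dplyr::select("assay_id", "sample_id", "dct", "censored")
  attr(out, "reference_assay_id") <- ref_id
  attr(out, "nondetect_limit") <- limit
  out
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' Normalizes each marker to the spike-in reference within sample
#' (\eqn{\Delta Ct}) and to a baseline clinical group across samples
#' (\eqn{\Delta\Delta Ct_{ji} = \Delta Ct_{ji} - \overline{\Delta Ct}_{j,
#' baseline}}, arithmetic mean over baseline samples), then reports
#' relative expression \eqn{2^{-\Delta\Delta Ct}}. By construction the
#' per-marker geometric mean of expression over the baseline group equals 1.
#' Censoring flags from nondetect wells are propagated.
#'
#' @inheritParams delta_ct
#' @param annotation Sample annotation tibble (`sample_id`, `group`, ...).
#' @param baseline_group Group whose mean \eqn{\Delta Ct} anchors the scale
#'   (default `"NC"`, the cancer-free controls).
#' @return Tibble `assay_id`, `sample_id`, `dct`, `ddct`, `expr`,
#'   `censored`; attribute `baseline_group`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_markers_total = 5, seed = 3))
#' expr <- rel_expression(cohort$ct, cohort$annotation)
#' # baseline geometric mean is 1 by construction:
#' nc <- cohort$annotation$sample_id[cohort$annotation$group == "NC"]
#' exp(mean(log(expr$expr[expr$sample_id %in% nc & expr$assay_id == "lnc_0001"])))
#' @export
rel_expression <- function(ct, annotation, baseline_group = "NC",
                           reference_assay_id = NULL, nondetect_limit = NULL) {
  check_columns(annotation, c("sample_id", "group"), "annotation")
  base_groups <- resolve_groups(baseline_group)
  base_ids <- annotation$sample_id[annotation$group %in% base_groups]
  base_ids <- intersect(base_ids, unique(ct$sample_id))
  if (length(base_ids) == 0) {
    abort_exopanel(sprintf("baseline group '%s' has no samples in the Ct table",
                           paste(baseline_group, collapse = "+")))
  }
  dct <- delta_ct(ct, reference_assay_id, nondetect_limit)
  base_mean <- dct |>
    dplyr::filter(.data$sample_id %in% base_ids) |>
    dplyr::summarise(base_dct = mean(.data$dct), .by = "assay_id")
  out <- dct |>
    dplyr::left_join(base_mean, by = "assay_id") |>
    dplyr::mutate(ddct = .data$dct - .data$base_dct,
                  expr = 2^(-.data$ddct)) |>
    dplyr::select("assay_id", "sample_id", "dct", "ddct", "expr", "censored")
  attr(out, "reference_assay_id") <- attr(dct, "reference_assay_id")
  attr(out, "nondetect_limit") <- attr(dct, "nondetect_limit")
  attr(out, "baseline_group") <- baseline_group
  out
}

#' Per-assay detection rate within a clinical group
#'
#' Fraction of a group's samples in which each assay is detected (not a
#' nondetect, Ct below the limit). This is the quantity behind the
#' "detection rate > 75%" screening filter.
#'
#' @inheritParams rel_expression
#' @param group Group label (one of NC, CH, HCC-N, HCC-M, or the composite
#'   "HCC").
#' @return Tibble `assay_id`, `det_rate`, `n`, `n_censored`.
#' @export
detection_rate <- function(ct, annotation, group, nondetect_limit = NULL) {
  check_columns(ct, c("assay_id", "sample_id", "nondetect"), "Ct table")
  limit <- ct_attr(ct, "nondetect_limit", nondetect_limit)
  ids <- annotation$sample_id[annotation$group %in% resolve_groups(group)]
  ids <- intersect(ids, unique(ct$sample_id))
  if (length(ids) == 0) {
    abort_exopanel(sprintf("group '%s' has no samples", paste(group, collapse = "+")))
  }
  ct |>
    dplyr::filter(.data$sample_id %in% ids) |>
    dplyr::summarise(
      det_rate = mean(!.data$nondetect & .data$ct < limit),
      n = dplyr::n(),
      n_censored = sum(.data$nondetect),
      .by = "assay_id"
    )
}
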