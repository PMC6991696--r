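#' Define a two-group contrast
#'
#' A contrast names a lower and a higher clinical group along the disease
#' trajectory (e.g. CH vs NC); screening asks which markers are
#' up-regulated in the higher group. The composite label `"HCC"` may be
#' used for the union of HCC-N and HCC-M.
#'
#' @param group_low,group_high Group labels; must differ.
#' @param name Optional contrast name; defaults to
#'   `"<high>_vs_<low>"`.
#' @return A list of class `contrast`.
#' @export
contrast <- function(group_low, group_high, name = NULL) {
  if (identical(group_low, group_high)) {
    abort_exopanel("group_low and group_high must differ")
  }
  resolve_groups(c(group_low, group_high))
  if (is.null(name)) name <- sprintf("%s_vs_%s", group_high, group_low)
  structure(list(name = name, group_low = group_low, group_high = group_high),
            class = "contrast")
}

#' The three adjacent screening contrasts of the four-group design
#' @return List of [contrast()] objects: CH vs NC, HCC-N vs CH,
#'   HCC-M vs HCC-N.
#' @export
screening_contrasts <- function() {
  list(contrast("NC", "CH"), contrast("CH", "HCC-N"), contrast("HCC-N", "HCC-M"))
}

#' The evaluation contrasts: HCC vs NC, HCC vs CH, HCC-M vs HCC-N
#' @return List of [contrast()] objects.
#' @export
evaluation_contrasts <- function() {
  list(contrast("NC", "HCC"), contrast("CH", "HCC"), contrast("HCC-N", "HCC-M"))
}

# Pooled-variance (Student) or Welch two-sample t test, vectorized over
# markers from per-group summary statistics. Cross-checked against
# stats::t.test in the test suite.
student_t_rows <- function(m1, v1, n1, m2, v2, n2, var_equal = TRUE) {
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(statistic = t, p_value = p)
}

#' Screen one contrast for up-regulated markers
#'
#' Applies the three screening filters per assay: (a) two-sample Student's
#' t test on log2 relative expression with p below `alpha`; (b) mean raw Ct
#' in the higher-expression group below `ct_max` (a biomarker must be
#' measurable where it is claimed elevated); (c) detection rate above
#' `det_min` in both compared groups. A marker passes only when all three
#' hold and the fold change is positive (`direction == "up"`).
#'
#' @param expr Relative-expression tibble from [rel_expression()].
#' @param ct Long Ct tibble (raw scale, for the Ct and detection filters).
#' @param annotation Sample annotation tibble.
#' @param contr A [contrast()].
#' @param alpha P-value threshold (default 0.05, uncorrected, matching the
#'   original screening rule).
#' @param ct_max Mean-Ct ceiling in the high group (default 35).
#' @param det_min Detection-rate floor in each group (default 0.75).
#' @param var_equal Use the pooled-variance Student t test (default TRUE);
#'   FALSE gives Welch.
#' @param p_adjust Multiple-testing correction applied to the p values
#'   before the `alpha` comparison; `"none"` (default, mirroring raw
#'   p < .05 screening) or any method of [stats::p.adjust()].
#' @param min_abs_log2_fc Optional fold-change magnitude floor (default 0,
#'   i.e. no fold-change filter).
#' @return Tibble, one row per assay: `assay_id`, `contrast`, `log2_fc`,
#'   `p_value`, `det_rate_low`, `det_rate_high`, `mean_ct_high`,
#'   `n_censored`, `direction`, `pass`.
#' @export
screen_contrast <- function(expr, ct, annotation, contr,
                            alpha = 0.05, ct_max = 35, det_min = 0.75,
                            var_equal = TRUE, p_adjust = "none",
                            min_abs_log2_fc = 0) {
  stopifnot(inherits(contr, "contrast"))
  check_columns(expr, c("assay_id", "sample_id", "expr", "censored"), "expression table")
  lo_ids <- annotation$sample_id[annotation$group %in% resolve_groups(contr$group_low)]
  hi_ids <- annotation$sample_id[annotation$group %in% resolve_groups(contr$group_high)]
  lo_ids <- intersect(lo_ids, unique(expr$sample_id))
  hi_ids <- intersect(hi_ids, unique(expr$sample_id))
  if (length(lo_ids) < 2 || length(hi_ids) < 2) {
    abort_exopanel(sprintf("contrast '%s': both groups need >= 2 samples", contr$name))
  }

  stats_by <- function(ids) {
    expr |>
      dplyr::filter(.data$sample_id %in% ids) |>
      dplyr::summarise(
        m = mean(log2(.data$expr)), v = stats::var(log2(.data$expr)),
        n = dplyr::n(), n_cens = sum(.data$censored),
        .by = "assay_id"
      )
  }
  lo <- stats_by(lo_ids)
  hi <- stats_by(hi_ids)

  det_lo <- detection_rate(ct, annotation, contr$group_low)
  det_hi <- detection_rate(ct, annotation, contr$group_high)
  mean_ct_hi <- ct |>
    dplyr::filter(.data$sample_id %in% hi_ids) |>
    dplyr::summarise(mean_ct_high = mean(.data$ct), .by = "assay_id")

  res <- lo |>
    dplyr::inner_join(hi, by = "assay_id", suffix = c("_lo", "_hi")) |>
    dplyr::left_join(dplyr::select(det_lo, "assay_id", det_rate_low = "det_rate"),
                     by = "assay_id") |>
    dplyr::left_join(dplyr::select(det_hi, "assay_id", det_rate_high = "det_rate"),
                     by = "assay_id") |>
    dplyr::left_join(mean_ct_hi, by = "assay_id")

  tt <- student_t_rows(res$m_lo, res$v_lo, res$n_lo,
                       res$m_hi, res$v_hi, res$n_hi, var_equal = var_equal)
  log2_fc <- res$m_hi - res$m_lo
  p <- tt$p_value
  p_cmp <- stats::p.adjust(p, method = p_adjust)
  direction <- dplyr::case_when(log2_fc > 0 ~ "up", log2_fc < 0 ~ "down",
                                TRUE ~ "flat")
  pass <- !is.na(p_cmp) & p_cmp < alpha &
    res$mean_ct_high < ct_max &
    pmin(res$det_rate_low, res$det_rate_high) > det_min &
    direction == "up" & abs(log2_fc) >= min_abs_log2_fc

  tibble::tibble(
    assay_id = res$assay_id,
    contrast = contr$name,
    log2_fc = log2_fc,
    p_value = p,
    det_rate_low = res$det_rate_low,
    det_rate_high = res$det_rate_high,
    mean_ct_high = res$mean_ct_high,
    n_censored = res$n_cens_lo + res$n_cens_hi,
    direction = direction,
    pass = pass
  )
}

#' Intersect per-contrast pass lists into a candidate panel
#'
#' The Venn step: markers up-regulated (passing all filters) in every
#' supplied contrast form the candidate panel, ordered by combined evidence
#' (sum of -log10 p across contrasts).
#'
#' @param results A single screen-result tibble holding several contrasts
#'   (stacked with [dplyr::bind_rows()]) or a list of per-contrast tibbles
#'   from [screen_contrast()].
#' @return Tibble `assay_id`, `evidence`, sorted by decreasing evidence,
#'   with attribute `provenance` (the contrast names intersected). Empty
#'   (zero rows) when any contrast contributes an empty pass set.
#' @export
venn_candidates <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  check_columns(results, c("assay_id", "contrast", "p_value", "pass"), "screen results")
  contrasts <- unique(results$contrast)
  if (length(contrasts) < 2) {
    abort_exopanel("venn_candidates needs screen results for >= 2 contrasts")
  }
  rosters <- split(results$assay_id, results$contrast)
  first <- sort(unique(rosters[[1]]))
  for (r in rosters) {
    if (!identical(sort(unique(r)), first)) {
      abort_exopanel("screen results cover inconsistent assay rosters",
                     class = "exopanel_roster_mismatch")
    }
  }
  panel <- results |>
    dplyr::distinct(.data$assay_id, .data$contrast, .keep_all = TRUE) |>
    dplyr::summarise(
      n_pass = sum(.data$pass),
      evidence = sum(-log10(pmax(.data$p_value, .Machine$double.xmin))),
      .by = "assay_id"
    ) |>
    dplyr::filter(.data$n_pass == length(contrasts)) |>
    dplyr::arrange(dplyr::desc(.data$evidence)) |>
    dplyr::select("assay_id", "evidence")
  attr(panel, "provenance") <- contrasts
  panel
}

#' Re-test a candidate panel in an independent split
#'
#' Confirmation step: the candidate markers (and only those) are re-tested
#' by Student's t test on log2 expression in a new set of samples; a
#' marker is confirmed when it is up-regulated with p below `alpha`.
#'
#' @inheritParams screen_contrast
#' @param panel Character vector of assay ids, or a panel tibble from
#'   [venn_candidates()].
#' @param split Optional split label; when given, only annotation rows with
#'   that `split` are used.
#' @return Tibble `assay_id`, `contrast`, `log2_fc`, `p_value`,
#'   `confirmed`. Zero rows for an empty panel.
#' @export
confirm_in_set <- function(expr, annotation, panel, contr, alpha = 0.05,
                           split = NULL, var_equal = TRUE) {
  ids <- if (is.data.frame(panel)) panel$assay_id else panel
  if (length(ids) == 0) {
    return(tibble::tibble(assay_id = character(), contrast = character(),
                          log2_fc = double(), p_value = double(),
                          confirmed = logical()))
  }
  missing <- setdiff(ids, unique(expr$assay_id))
  if (length(missing) > 0) {
    abort_exopanel(sprintf("panel marker(s) absent from expression table: %s",
                           paste(missing, collapse = ", ")))
  }
  if (!is.null(split)) {
    annotation <- dplyr::filter(annotation, .data$split == !!split)
    expr <- dplyr::filter(expr, .data$sample_id %in% annotation$sample_id)
  }
  expr_sub <- dplyr::filter(expr, .data$assay_id %in% ids)
  lo_ids <- annotation$sample_id[annotation$group %in% resolve_groups(contr$group_low)]
  hi_ids <- annotation$sample_id[annotation$group %in% resolve_groups(contr$group_high)]
  stats_by <- function(sids) {
    expr_sub |>
      dplyr::filter(.data$sample_id %in% sids) |>
      dplyr::summarise(m = mean(log2(.data$expr)), v = stats::var(log2(.data$expr)),
                       n = dplyr::n(), .by = "assay_id")
  }
  lo <- stats_by(lo_ids)
  hi <- stats_by(hi_ids)
  res <- dplyr::inner_join(lo, hi, by = "assay_id", suffix = c("_lo", "_hi"))
  tt <- student_t_rows(res$m_lo, res$v_lo, res$n_lo,
                       res$m_hi, res$v_hi, res$n_hi, var_equal = var_equal)
  tibble::tibble(
    assay_id = res$assay_id,
    contrast = contr$name,
    log2_fc = res$m_hi - res$m_lo,
    p_value = tt$p_value,
    confirmed = !is.na(tt$p_value) & tt$p_value < alpha & (res$m_hi - res$m_lo) > 0
  )
}
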