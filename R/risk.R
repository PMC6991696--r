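#' Control-derived coding thresholds (upper 95% reference interval)
#'
#' For each panel marker, the threshold \eqn{\theta_j} above which a
#' sample's expression is coded positive is the upper limit of the control
#' group's reference interval: the empirical 95th percentile of control
#' expression (linear-interpolation quantile, [stats::quantile()] type 7,
#' sample maximum at p = 1). A parametric alternative uses
#' \eqn{\exp(\mu + z_{0.95}\sigma)} of log expression.
#'
#' @param expr Relative-expression tibble from [rel_expression()].
#' @param annotation Sample annotation tibble.
#' @param panel Character vector of marker ids (or panel tibble).
#' @param control_group Group supplying the reference interval (default
#'   `"NC"`).
#' @param method `"quantile"` (nonparametric, default) or `"parametric"`
#'   (log-normal).
#' @param prob Upper reference-interval probability (default 0.95).
#' @param split Optional split label restricting which control samples are
#'   used (e.g. `"train"`).
#' @return Tibble `marker_id`, `theta`, `n_control`, `n_censored`.
#' @export
fit_thresholds <- function(expr, annotation, panel, control_group = "NC",
                           method = c("quantile", "parametric"),
                           prob = 0.95, split = NULL) {
  method <- match.arg(method)
  ids <- if (is.data.frame(panel)) panel$assay_id else panel
  if (length(ids) == 0) abort_exopanel("panel is empty")
  missing <- setdiff(ids, unique(expr$assay_id))
  if (length(missing) > 0) {
    abort_exopanel(sprintf("panel marker(s) absent from expression table: %s",
                           paste(missing, collapse = ", ")))
  }
  if (!is.null(split)) {
    annotation <- dplyr::filter(annotation, .data$split == !!split)
  }
  ctrl_ids <- annotation$sample_id[annotation$group %in% resolve_groups(control_group)]
  ctrl_ids <- intersect(ctrl_ids, unique(expr$sample_id))
  if (length(ctrl_ids) == 0) abort_exopanel("control group is empty")
  if (length(ctrl_ids) < 5) {
    abort_exopanel(sprintf("need >= 5 control samples to fit thresholds, got %d",
                           length(ctrl_ids)))
  }
  expr |>
    dplyr::filter(.data$assay_id %in% ids, .data$sample_id %in% ctrl_ids) |>
    dplyr::summarise(
      theta = if (method == "quantile") {
        unname(stats::quantile(.data$expr, prob, type = 7))
      } else {
        exp(mean(log(.data$expr)) + stats::qnorm(prob) * stats::sd(log(.data$expr)))
      },
      n_control = dplyr::n(),
      n_censored = sum(.data$censored),
      .by = "assay_id"
    ) |>
    dplyr::rename(marker_id = "assay_id") |>
    dplyr::arrange(match(.data$marker_id, ids))
}

#' Binary-code samples against marker thresholds
#'
#' Codes sample i, marker j as \eqn{s_{ij} = 1} when expression strictly
#' exceeds \eqn{\theta_j}, else 0. Censored (nondetect) wells code 0:
#' a nondetect means expression below the quantifiable range, hence below
#' any positive threshold.
#'
#' @inheritParams fit_thresholds
#' @param theta Threshold tibble from [fit_thresholds()].
#' @return Long tibble `sample_id`, `marker_id`, `s` (integer 0/1).
#' @export
code_samples <- function(expr, theta) {
  check_columns(theta, c("marker_id", "theta"), "threshold table")
  missing <- setdiff(theta$marker_id, unique(expr$assay_id))
  if (length(missing) > 0) {
    abort_exopanel(sprintf("marker(s) absent from expression table: %s",
                           paste(missing, collapse = ", ")))
  }
  expr |>
    dplyr::inner_join(theta, by = c(assay_id = "marker_id")) |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      marker_id = .data$assay_id,
      s = as.integer(.data$expr > .data$theta & !.data$censored)
    )
}

#' Risk score function: weighted sum of marker codes
#'
#' \eqn{rsf_i = \sum_j W_j s_{ij}}. With the default unit weights the score
#' is simply the number of positive markers (an integer in 0..J).
#'
#' @param codes Long 0/1 code tibble from [code_samples()].
#' @param weights Named numeric vector of per-marker weights \eqn{W_j}
#'   (default: unit weight for every marker present). Negative weights are
#'   rejected unless `allow_negative = TRUE`.
#' @param allow_negative Permit negative weights (default FALSE).
#' @return Tibble `sample_id`, `rsf`.
#' @export
risk_scores <- function(codes, weights = NULL, allow_negative = FALSE) {
  check_columns(codes, c("sample_id", "marker_id", "s"), "code table")
  markers <- unique(codes$marker_id)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(markers)), markers)
  }
  missing <- setdiff(markers, names(weights))
  if (length(missing) > 0) {
    abort_exopanel(sprintf("no weight supplied for marker(s): %s",
                           paste(missing, collapse = ", ")))
  }
  if (!allow_negative && any(weights < 0)) {
    abort_exopanel("negative weights are not allowed (set allow_negative = TRUE to override)")
  }
  codes |>
    dplyr::mutate(w = unname(weights[.data$marker_id])) |>
    dplyr::summarise(rsf = sum(.data$w * .data$s), .by = "sample_id")
}

#' Fit the classification cut-off maximizing sensitivity + specificity
#'
#' Candidate cut-offs are the midpoints between adjacent distinct score
#' values plus minus/plus infinity; a sample is called high-risk when
#' `rsf >= cutoff`. The cut-off maximizing sensitivity + specificity (the
#' Youden-style rule) is returned; ties are broken in favour of higher
#' specificity, then the smaller cut-off. `rule = "median"` instead uses
#' the median score.
#'
#' @param rsf Numeric scores.
#' @param labels Logical (TRUE = case) or two-level factor/character where
#'   the second sorted level is the case.
#' @param rule `"youden"` (default) or `"median"`.
#' @return One-row tibble `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
fit_cutoff <- function(rsf, labels, rule = c("youden", "median")) {
  rule <- match.arg(rule)
  y <- as_case_logical(labels)
  if (length(y) != length(rsf)) abort_exopanel("scores and labels differ in length")
  if (!any(y) || all(y)) {
    abort_exopanel("both classes must be present to fit a cut-off",
                   class = "exopanel_single_class")
  }
  sens_spec <- function(c) {
    pred <- rsf >= c
    c(sens = mean(pred[y]), spec = mean(!pred[!y]))
  }
  if (rule == "median") {
    cut <- stats::median(rsf)
    ss <- sens_spec(cut)
    return(tibble::tibble(cutoff = cut, sensitivity = ss[["sens"]],
                          specificity = ss[["spec"]],
                          youden_j = ss[["sens"]] + ss[["spec"]] - 1))
  }
  v <- sort(unique(rsf))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  # integer counts keep the objective exact: sens + spec maximal iff
  # tp*n_neg + tn*n_pos is, avoiding float ties between rational sums
  tp <- vapply(cand, function(c) sum(rsf[y] >= c), 0L)
  tn <- vapply(cand, function(c) sum(rsf[!y] < c), 0L)
  obj <- tp * n_neg + tn * n_pos
  # lexicographic: max sens+spec, then max specificity, then smallest cutoff
  best <- order(-obj, -tn, cand)[1]
  tibble::tibble(cutoff = cand[best],
                 sensitivity = tp[best] / n_pos,
                 specificity = tn[best] / n_neg,
                 youden_j = tp[best] / n_pos + tn[best] / n_neg - 1)
}

as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) {
    abort_exopanel("labels must be logical or have exactly two levels")
  }
  f == levels(f)[2]
}

#' Append dichotomized AFP to a coded risk score
#'
#' AFP is dichotomized by the same control reference-interval rule as the
#' lncRNA markers (`afp > afp_theta` codes 1) and appended as an extra
#' marker with weight 1, so the extended score differs from the panel
#' score by exactly 0 or 1 on every sample.
#'
#' @param codes Long 0/1 code tibble from [code_samples()].
#' @param annotation Annotation tibble with `sample_id` and `afp` (ng/mL).
#' @param afp_theta AFP threshold (ng/mL), fitted on control AFP.
#' @param weights Per-marker weights passed to [risk_scores()].
#' @return Tibble `sample_id`, `rsf` (extended), `afp_positive`.
#' @export
combine_with_afp <- function(codes, annotation, afp_theta, weights = NULL) {
  check_columns(annotation, c("sample_id", "afp"), "annotation")
  base <- risk_scores(codes, weights)
  afp <- annotation[match(base$sample_id, annotation$sample_id), "afp", drop = TRUE]
  bad <- base$sample_id[is.na(afp)]
  if (length(bad) > 0) {
    abort_exopanel(sprintf("missing AFP value for sample(s): %s",
                           paste(bad, collapse = ", ")),
                   class = "exopanel_missing_afp")
  }
  dplyr::mutate(base,
                afp_positive = afp > afp_theta,
                rsf = .data$rsf + as.numeric(.data$afp_positive))
}

#' Fit the full risk-score model on the training split
#'
#' End-to-end fit: control-derived thresholds \eqn{\theta_j} (and an AFP
#' threshold by the same rule), per-marker weights (unit by default, or a
#' supplied numeric vector), 0/1 coding of the training samples, and a
#' frozen classification cut-off per evaluation contrast for both the
#' panel score and the panel+AFP score. Validation and blind evaluation
#' then apply the frozen model; nothing is re-estimated outside `train`.
#'
#' @inheritParams fit_thresholds
#' @param panel Character vector of marker ids (or panel tibble) forming
#'   the fitted roster.
#' @param contrasts List of [contrast()]s for which training cut-offs are
#'   fitted (default [evaluation_contrasts()]).
#' @param weights `NULL` for unit weights, or a named numeric vector.
#' @param cutoff_rule `"youden"` (maximal sensitivity + specificity,
#'   default) or `"median"`.
#' @param include_afp Also fit the AFP threshold and panel+AFP cut-offs.
#' @param train_split Split label used for fitting (default `"train"`).
#' @return An object of class `risk_model`.
#' @export
fit_risk_model <- function(expr, annotation, panel, control_group = "NC",
                           contrasts = evaluation_contrasts(),
                           weights = NULL,
                           theta_method = c("quantile", "parametric"),
                           cutoff_rule = c("youden", "median"),
                           include_afp = TRUE,
                           train_split = "train") {
  theta_method <- match.arg(theta_method)
  cutoff_rule <- match.arg(cutoff_rule)
  ids <- if (is.data.frame(panel)) panel$assay_id else panel
  if (length(ids) == 0) abort_exopanel("cannot fit a risk model on an empty panel")
  ann_tr <- dplyr::filter(annotation, .data$split == train_split)
  expr_tr <- dplyr::filter(expr, .data$sample_id %in% ann_tr$sample_id)

  theta <- fit_thresholds(expr_tr, ann_tr, ids, control_group, method = theta_method)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(ids)), ids)
  if (!all(ids %in% names(weights))) abort_exopanel("weights must name every panel marker")
  weights <- weights[ids]

  afp_theta <- NULL
  if (include_afp) {
    ctrl <- dplyr::filter(ann_tr, .data$group %in% resolve_groups(control_group))
    if (nrow(ctrl) < 5) abort_exopanel("need >= 5 control samples for the AFP threshold")
    afp_theta <- unname(stats::quantile(ctrl$afp, 0.95, type = 7))
  }

  codes <- code_samples(expr_tr, theta)
  rsf_panel <- risk_scores(codes, weights)
  rsf_ext <- if (include_afp) combine_with_afp(codes, ann_tr, afp_theta, weights) else NULL

  cut_rows <- purrr::map(contrasts, function(ctr) {
    lo <- ann_tr$sample_id[ann_tr$group %in% resolve_groups(ctr$group_low)]
    hi <- ann_tr$sample_id[ann_tr$group %in% resolve_groups(ctr$group_high)]
    fit_one <- function(scores, variant) {
      sc <- scores[match(c(lo, hi), scores$sample_id), , drop = FALSE]
      y <- c(rep(FALSE, length(lo)), rep(TRUE, length(hi)))
      keep <- !is.na(sc$rsf)
      fc <- fit_cutoff(sc$rsf[keep], y[keep], rule = cutoff_rule)
      dplyr::mutate(fc, contrast = ctr$name, variant = variant, .before = 1)
    }
    out <- fit_one(rsf_panel, "panel")
    if (include_afp) out <- dplyr::bind_rows(out, fit_one(rsf_ext, "panel_plus_afp"))
    out
  })

  structure(
    list(
      marker_ids = ids,
      theta = theta,
      weights = weights,
      afp_theta = afp_theta,
      cutoffs = dplyr::bind_rows(cut_rows),
      control_group = control_group,
      cutoff_rule = cutoff_rule,
      theta_method = theta_method,
      train_split = train_split,
      train_sample_ids = ann_tr$sample_id,
      frozen = TRUE
    ),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Risk-score model (", length(x$marker_ids), " markers, ",
      x$cutoff_rule, " cut-off)\n", sep = "")
  cat("  markers:", paste(x$marker_ids, collapse = ", "), "\n")
  cat("  thresholds (theta):",
      paste(sprintf("%s=%.3g", x$theta$marker_id, x$theta$theta), collapse = ", "), "\n")
  if (!is.null(x$afp_theta)) cat("  AFP threshold:", format(x$afp_theta, digits = 4), "ng/mL\n")
  cat("  training cut-offs:\n")
  print(x$cutoffs, ...)
  invisible(x)
}

#' Broom-style tidiers for risk models
#'
#' `tidy()` returns one row per panel marker (threshold and weight);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.risk_model <- function(x, ...) {
  dplyr::mutate(x$theta, weight = unname(x$weights[.data$marker_id]))
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    n_markers = length(x$marker_ids),
    afp_theta = ifelse(is.null(x$afp_theta), NA_real_, x$afp_theta),
    cutoff_rule = x$cutoff_rule,
    n_train = length(x$train_sample_ids),
    max_rsf = sum(x$weights)
  )
}

#' Score and classify samples with a frozen risk model
#'
#' @param object A `risk_model`.
#' @param expr Relative-expression tibble for the samples to score.
#' @param annotation Annotation tibble (needed for the AFP variant).
#' @param contrast_name Which training cut-off to apply.
#' @param variant `"panel"` or `"panel_plus_afp"`.
#' @param ... Unused.
#' @return Tibble `sample_id`, `rsf`, `risk_class` (`"low"`/`"high"`,
#'   high when `rsf >= cutoff`).
#' @export
predict.risk_model <- function(object, expr, annotation = NULL,
                               contrast_name = NULL,
                               variant = c("panel", "panel_plus_afp"), ...) {
  variant <- match.arg(variant)
  if (!isTRUE(object$frozen)) abort_exopanel("risk model is not frozen")
  codes <- code_samples(expr, object$theta)
  scores <- if (variant == "panel_plus_afp") {
    if (is.null(object$afp_theta)) abort_exopanel("model was fitted without AFP")
    combine_with_afp(codes, annotation, object$afp_theta, object$weights)
  } else {
    risk_scores(codes, object$weights)
  }
  if (is.null(contrast_name)) contrast_name <- object$cutoffs$contrast[1]
  row <- dplyr::filter(object$cutoffs, .data$contrast == contrast_name,
                       .data$variant == !!variant)
  if (nrow(row) != 1) {
    abort_exopanel(sprintf("no fitted cut-off for contrast '%s', variant '%s'",
                           contrast_name, variant))
  }
  dplyr::mutate(scores,
                risk_class = ifelse(.data$rsf >= row$cutoff, "high", "low"))
}

#' Serialize / restore a fitted risk model (JSON)
#'
#' The JSON file carries marker ids, thresholds, weights, the AFP
#' threshold, the per-contrast training cut-offs and the fitting
#' provenance; a restored model produces identical classifications.
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `write_risk_model()` the path invisibly; `read_risk_model()` a
#'   `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  payload <- list(
    marker_ids = model$marker_ids,
    theta = model$theta,
    weights = as.list(model$weights),
    afp_theta = model$afp_theta,
    cutoffs = model$cutoffs,
    control_group = model$control_group,
    cutoff_rule = model$cutoff_rule,
    theta_method = model$theta_method,
    train_split = model$train_split,
    train_sample_ids = model$train_sample_ids,
    frozen = model$frozen
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      marker_ids = p$marker_ids,
      theta = tibble::as_tibble(p$theta),
      weights = unlist(p$weights),
      afp_theta = p$afp_theta,
      cutoffs = tibble::as_tibble(p$cutoffs),
      control_group = p$control_group,
      cutoff_rule = p$cutoff_rule,
      theta_method = p$theta_method,
      train_split = p$train_split,
      train_sample_ids = p$train_sample_ids,
      frozen = isTRUE(p$frozen)
    ),
    class = "risk_model"
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
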