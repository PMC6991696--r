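#' ROC curve and AUC
#'
#' Builds the ROC curve over all distinct score thresholds (rule
#' `score >= threshold` calls a case) and computes the AUC as the
#' trapezoidal area, which for this step curve equals the Mann-Whitney
#' statistic \eqn{P(S_{case} > S_{control}) + \frac{1}{2} P(tie)}. A coded
#' risk score takes few distinct values, so its curve is honestly coarse —
#' no smoothing is applied. Scores are never direction-flipped: a score
#' that ranks controls above cases yields an AUC below 0.5 and is reported
#' as such.
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = case) or two-level factor/character
#'   (second sorted level = case).
#' @return Object of class `exo_roc`: list with `points` (tibble
#'   `threshold`, `tpr`, `fpr`, descending thresholds, from (0,0) to
#'   (1,1)), `auc`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
#' r$auc  # 0.75
#' @export
roc <- function(scores, labels) {
  y <- as_case_logical(labels)
  if (length(y) != length(scores)) abort_exopanel("scores and labels differ in length")
  if (anyNA(scores) || anyNA(y)) abort_exopanel("scores and labels must not contain NA")
  if (!any(y) || all(y)) {
    abort_exopanel("both classes must be present to compute a ROC curve",
                   class = "exopanel_single_class")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(y)
  n_neg <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t), 0) / n_neg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
         auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "exo_roc"
  )
}

#' @export
print.exo_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases vs %d controls, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @rdname tidy.risk_model
#' @export
tidy.exo_roc <- function(x, ...) x$points

#' @rdname tidy.risk_model
#' @export
glance.exo_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Confusion-matrix summary of a binary classification
#'
#' @param pred_class Logical predictions (TRUE = called case) or a
#'   two-level factor/character.
#' @param labels True classes, same convention.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (undefined rates are `NaN`).
#' @export
confusion <- function(pred_class, labels) {
  p <- as_case_logical(pred_class)
  y <- as_case_logical(labels)
  if (length(p) != length(y)) abort_exopanel("predictions and labels differ in length")
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    accuracy = (tp + tn) / length(y)
  )
}

#' Evaluate a frozen risk model on one contrast and split
#'
#' Produces one ROC + confusion row per score variant: each single panel
#' marker (continuous relative expression as the score, its own threshold
#' \eqn{\theta_j} as the classification rule), AFP alone (continuous AFP,
#' AFP threshold rule), the coded panel score, and the coded panel + AFP
#' score. Panel variants are classified at the frozen training cut-off —
#' the same cut-off on every split. Evaluating a non-training split that
#' shares samples with the fitting split is a leakage error.
#'
#' @param model A frozen `risk_model` from [fit_risk_model()].
#' @param expr Relative-expression tibble covering the evaluation samples.
#' @param annotation Annotation tibble with `group`, `afp`, `split`.
#' @param contr A [contrast()]; its name must match a fitted cut-off.
#' @param split Split label to evaluate (default `"valid"`).
#' @return Tibble, one row per variant: `contrast`, `split`, `variant`,
#'   `n_pos`, `n_neg`, `n_censored`, `auc`, `cutoff`, plus the
#'   [confusion()] columns.
#' @export
evaluate_contrast <- function(model, expr, annotation, contr, split = "valid") {
  stopifnot(inherits(model, "risk_model"), inherits(contr, "contrast"))
  if (!isTRUE(model$frozen)) abort_exopanel("risk model is not frozen")
  ann <- dplyr::filter(annotation, .data$split == !!split)
  if (split != model$train_split) {
    leak <- intersect(ann$sample_id, model$train_sample_ids)
    if (length(leak) > 0) {
      abort_exopanel(
        sprintf("split leakage: %d sample(s) shared with the fitting split (e.g. %s)",
                length(leak), leak[1]),
        class = "exopanel_leakage"
      )
    }
  }
  lo <- ann[ann$group %in% resolve_groups(contr$group_low), ]
  hi <- ann[ann$group %in% resolve_groups(contr$group_high), ]
  ids <- c(lo$sample_id, hi$sample_id)
  y <- c(rep(FALSE, nrow(lo)), rep(TRUE, nrow(hi)))
  ann_sub <- dplyr::bind_rows(lo, hi)
  expr_sub <- dplyr::filter(expr, .data$sample_id %in% ids)

  rows <- list()
  # single-marker variants: continuous expression scored, theta as the rule
  for (j in seq_along(model$marker_ids)) {
    mk <- model$marker_ids[j]
    e <- expr_sub[expr_sub$assay_id == mk, ]
    e <- e[match(ids, e$sample_id), ]
    th <- model$theta$theta[model$theta$marker_id == mk]
    rows[[length(rows) + 1]] <- eval_row(
      contr$name, split, paste0("single_", mk),
      scores = e$expr, y = y, pred = e$expr > th & !e$censored,
      cutoff = th, n_censored = sum(e$censored)
    )
  }
  if (!is.null(model$afp_theta)) {
    afp <- ann_sub$afp[match(ids, ann_sub$sample_id)]
    rows[[length(rows) + 1]] <- eval_row(
      contr$name, split, "afp_only",
      scores = afp, y = y, pred = afp > model$afp_theta,
      cutoff = model$afp_theta, n_censored = 0L
    )
  }
  codes <- code_samples(expr_sub, model$theta)
  n_cens_panel <- sum(expr_sub$censored[expr_sub$assay_id %in% model$marker_ids])
  panel_variants <- unique(model$cutoffs$variant)
  for (v in panel_variants) {
    sc <- if (v == "panel_plus_afp") {
      combine_with_afp(codes, ann_sub, model$afp_theta, model$weights)
    } else {
      risk_scores(codes, model$weights)
    }
    sc <- sc[match(ids, sc$sample_id), ]
    row <- dplyr::filter(model$cutoffs, .data$contrast == contr$name,
                         .data$variant == v)
    if (nrow(row) != 1) {
      abort_exopanel(sprintf("no fitted cut-off for contrast '%s', variant '%s'",
                             contr$name, v))
    }
    rows[[length(rows) + 1]] <- eval_row(
      contr$name, split, v,
      scores = sc$rsf, y = y, pred = sc$rsf >= row$cutoff,
      cutoff = row$cutoff, n_censored = n_cens_panel
    )
  }
  dplyr::bind_rows(rows)
}

eval_row <- function(contrast, split, variant, scores, y, pred, cutoff, n_censored) {
  r <- roc(scores, y)
  dplyr::bind_cols(
    tibble::tibble(contrast = contrast, split = split, variant = variant,
                   n_pos = r$n_pos, n_neg = r$n_neg,
                   n_censored = n_censored, auc = r$auc, cutoff = cutoff),
    confusion(pred, y)
  )
}

#' Double-blind classification accuracy
#'
#' Classifies the blind-split samples belonging to a contrast's two groups
#' with the frozen model and reports the fraction whose risk class matches
#' the adjudicated truth (high-risk = the contrast's higher group).
#'
#' @inheritParams evaluate_contrast
#' @param variant `"panel"` (default) or `"panel_plus_afp"`.
#' @param blind_split Split label of the blind set (default `"blind"`).
#' @return One-row tibble `contrast`, `variant`, `n`, `n_correct`,
#'   `accuracy`.
#' @export
blind_accuracy <- function(model, expr, annotation, contr,
                           variant = c("panel", "panel_plus_afp"),
                           blind_split = "blind") {
  variant <- match.arg(variant)
  if (!isTRUE(model$frozen)) abort_exopanel("risk model is not frozen")
  ann <- dplyr::filter(annotation, .data$split == blind_split)
  leak <- intersect(ann$sample_id, model$train_sample_ids)
  if (length(leak) > 0) {
    abort_exopanel("split leakage between blind set and fitting split",
                   class = "exopanel_leakage")
  }
  keep <- ann$group %in% resolve_groups(c(contr$group_low, contr$group_high))
  ann <- ann[keep, ]
  if (nrow(ann) == 0) abort_exopanel("no blind samples in the contrast's groups")
  expr_sub <- dplyr::filter(expr, .data$sample_id %in% ann$sample_id)
  pred <- predict(model, expr_sub, ann, contrast_name = contr$name,
                  variant = variant)
  pred <- pred[match(ann$sample_id, pred$sample_id), ]
  truth_high <- ann$group %in% resolve_groups(contr$group_high)
  correct <- (pred$risk_class == "high") == truth_high
  tibble::tibble(contrast = contr$name, variant = variant,
                 n = nrow(ann), n_correct = sum(correct),
                 accuracy = mean(correct))
}

#' Handling-condition stability of marker expression
#'
#' Compares each marker's expression under stress conditions (e.g.
#' room-temperature incubation, repeated freeze-thaw) against the baseline
#' condition with a paired two-sided t test on log2 expression over
#' subjects, and reports the worst-case mean fold change. Because absence
#' of significance alone is weak evidence of stability, both the minimum
#' p value and the maximum absolute mean log2 ratio are emitted; the
#' `stable` flag is `min p > 0.05`.
#'
#' @param data Tibble `assay_id`, `sample_id`, `condition`, `expr` with
#'   every (assay, condition) measured on the same subjects (paired).
#' @param baseline Baseline condition label; defaults to the first
#'   condition appearing in `data`.
#' @return Tibble, one row per assay x non-baseline condition:
#'   `assay_id`, `condition`, `p_value`, `mean_log2_ratio`, plus
#'   per-assay `min_p`, `max_abs_log2_ratio`, `stable` (repeated across
#'   the assay's rows).
#' @export
stability_compare <- function(data, baseline = NULL) {
  check_columns(data, c("assay_id", "sample_id", "condition", "expr"), "stability data")
  conds <- unique(data$condition)
  if (length(conds) < 2) abort_exopanel("need >= 2 handling conditions")
  if (is.null(baseline)) baseline <- conds[1]
  if (!baseline %in% conds) abort_exopanel("baseline condition not present")

  subjects <- sort(unique(data$sample_id))
  pairing_ok <- data |>
    dplyr::summarise(ok = identical(sort(.data$sample_id), subjects),
                     .by = c("assay_id", "condition"))
  if (!all(pairing_ok$ok)) {
    abort_exopanel("unpaired input: every (assay, condition) must cover the same subjects",
                   class = "exopanel_unpaired")
  }

  base <- data |>
    dplyr::filter(.data$condition == baseline) |>
    dplyr::select("assay_id", "sample_id", base_expr = "expr")
  out <- data |>
    dplyr::filter(.data$condition != baseline) |>
    dplyr::inner_join(base, by = c("assay_id", "sample_id")) |>
    dplyr::summarise(
      p_value = paired_log2_p(.data$expr, .data$base_expr),
      mean_log2_ratio = mean(log2(.data$expr / .data$base_expr)),
      .by = c("assay_id", "condition")
    ) |>
    dplyr::mutate(
      min_p = min(.data$p_value),
      max_abs_log2_ratio = max(abs(.data$mean_log2_ratio)),
      stable = min(.data$p_value) > 0.05,
      .by = "assay_id"
    )
  out
}

paired_log2_p <- function(x, y) {
  d <- log2(x) - log2(y)
  if (all(d == d[1])) {
    # constant differences: zero shift is certain (p = 1), nonzero certain change
    return(if (d[1] == 0) 1 else 0)
  }
  stats::t.test(d)$p.value
}
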