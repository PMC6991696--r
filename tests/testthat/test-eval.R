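test_that("roc reproduces hand-counted AUCs", {
  # pos {3, 1}, neg {2, 0}: 3 of 4 pairs correctly ordered
  r <- roc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(roc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_equal(roc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_error(roc(1:3, rep(TRUE, 3)), class = "exopanel_single_class")
  # curve anchored at (0,0) and (1,1), monotone
  expect_equal(unlist(r$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$tpr) >= 0) && all(diff(r$points$fpr) >= 0))
})

test_that("trapezoidal AUC equals the pair-counting oracle on small instances", {
  set.seed(91)
  for (i in 1:250) {
    n <- sample(3:12, 1)
    scores <- sample(0:5, n, replace = TRUE)  # ties likely
    y <- runif(n) < 0.5
    if (all(y) || !any(y)) next
    expect_equal(roc(scores, y)$auc, auc_pair_count(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("roc agrees with pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(92)
  scores <- rnorm(80)
  y <- runif(80) < 0.5
  y[1:2] <- c(TRUE, FALSE)
  ours <- roc(scores, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC complements under score negation and survives monotone maps", {
  set.seed(93)
  scores <- runif(40)  # tie-free almost surely
  y <- runif(40) < 0.5
  y[1:2] <- c(TRUE, FALSE)
  expect_equal(roc(scores, y)$auc + roc(-scores, y)$auc, 1)
  expect_equal(roc(qlogis(scores), y)$auc, roc(scores, y)$auc)
})

test_that("confusion identities hold", {
  cs <- confusion(rep(c(TRUE, FALSE), c(10, 10)),
                  c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 9)))
  expect_equal(cs$tp, 9); expect_equal(cs$fp, 1)
  expect_equal(cs$tn, 9); expect_equal(cs$fn, 1)
  expect_equal(cs$ppv, 0.9); expect_equal(cs$npv, 0.9)
  expect_equal(cs$accuracy, 0.9)
  all_right <- confusion(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unlist(all_right[, c("sensitivity", "specificity", "ppv",
                                    "npv", "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1, accuracy = 1))
  expect_error(confusion(c(TRUE, FALSE), TRUE), "length")
})

test_that("confusion matches a brute-force tally on random tables", {
  set.seed(94)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    pred <- runif(n) < 0.5
    y <- runif(n) < 0.5
    cs <- confusion(pred, y)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (k in seq_len(n)) {
      if (pred[k] && y[k]) tp <- tp + 1
      if (pred[k] && !y[k]) fp <- fp + 1
      if (!pred[k] && !y[k]) tn <- tn + 1
      if (!pred[k] && y[k]) fn <- fn + 1
    }
    expect_equal(unlist(cs[, c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(cs$sensitivity, tp / (tp + fn))
    expect_equal(cs$accuracy, (tp + tn) / n)
  }
})

test_that("sensitivity/specificity are prevalence-invariant, PPV/NPV are not", {
  set.seed(95)
  cfg <- tiny_sim_config(seed = 95, n_per_group_valid = 100)
  coh <- simulate_cohort(cfg)
  expr <- rel_expression(coh$ct, coh$annotation)
  model <- fit_risk_model(expr, coh$annotation,
                          c("lnc_0001", "lnc_0002", "lnc_0003"))
  ann_v <- dplyr::filter(coh$annotation, .data$split == "valid")
  pred <- predict(model, expr, coh$annotation, contrast_name = "HCC_vs_NC",
                  variant = "panel")
  keep <- ann_v[ann_v$group %in% c("NC", "HCC-N", "HCC-M"), ]
  p <- pred$risk_class[match(keep$sample_id, pred$sample_id)] == "high"
  y <- keep$group != "NC"
  base <- confusion(p, y)
  # triple the case class by within-class resampling
  idx_case <- which(y); idx_ctrl <- which(!y)
  idx <- c(rep(idx_case, 3), idx_ctrl)
  boosted <- confusion(p[idx], y[idx])
  expect_equal(boosted$sensitivity, base$sensitivity)
  expect_equal(boosted$specificity, base$specificity)
  # higher prevalence pushes PPV up and NPV down (Bayes' rule direction)
  expect_gte(boosted$ppv, base$ppv)
  expect_lte(boosted$npv, base$npv)
})

test_that("training-split evaluation attains the fitted maximal sens+spec", {
  cfg <- tiny_sim_config(seed = 97)
  coh <- simulate_cohort(cfg)
  expr <- rel_expression(coh$ct, coh$annotation)
  model <- fit_risk_model(expr, coh$annotation,
                          c("lnc_0001", "lnc_0002", "lnc_0003"))
  ev <- evaluate_contrast(model, expr, coh$annotation, contrast("NC", "HCC"),
                          split = "train")
  row <- ev[ev$variant == "panel", ]
  fitted <- model$cutoffs[model$cutoffs$contrast == "HCC_vs_NC" &
                            model$cutoffs$variant == "panel", ]
  expect_equal(row$sensitivity + row$specificity,
               fitted$sensitivity + fitted$specificity)
  expect_setequal(
    ev$variant,
    c(paste0("single_", c("lnc_0001", "lnc_0002", "lnc_0003")),
      "afp_only", "panel", "panel_plus_afp")
  )
})

test_that("split leakage between fitting and evaluation is an error", {
  cfg <- tiny_sim_config(seed = 98)
  coh <- simulate_cohort(cfg)
  expr <- rel_expression(coh$ct, coh$annotation)
  model <- fit_risk_model(expr, coh$annotation, c("lnc_0001", "lnc_0002"))
  ann_bad <- coh$annotation
  # relabel a training sample as validation: same id in both splits
  ann_bad$split[match(model$train_sample_ids[1], ann_bad$sample_id)] <- "valid"
  expect_error(evaluate_contrast(model, expr, ann_bad, contrast("NC", "HCC")),
               class = "exopanel_leakage")
  tampered <- model
  tampered$frozen <- FALSE
  expect_error(evaluate_contrast(tampered, expr, coh$annotation,
                                 contrast("NC", "HCC")), "frozen")
  expect_error(blind_accuracy(tampered, expr, coh$annotation,
                              contrast("NC", "HCC")), "frozen")
})

test_that("permuted labels drive all variant AUCs to chance", {
  cfg <- tiny_sim_config(seed = 99, n_per_group_valid = 150)
  coh <- simulate_cohort(cfg)
  ann <- coh$annotation
  # permute group labels within the validation split
  idx <- which(ann$split == "valid")
  set.seed(1)
  ann$group[idx] <- sample(ann$group[idx])
  expr <- rel_expression(coh$ct, ann)
  model <- fit_risk_model(expr, ann, c("lnc_0001", "lnc_0002", "lnc_0003"))
  ev <- evaluate_contrast(model, expr, ann, contrast("NC", "HCC"))
  n1 <- ev$n_pos[1]; n0 <- ev$n_neg[1]
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_true(all(abs(ev$auc - 0.5) < 4 * se))
})

test_that("blind accuracy matches direct reclassification", {
  cfg <- tiny_sim_config(seed = 101, delta_dct_per_stage = 3, sigma_dct = 0.5)
  coh <- simulate_cohort(cfg)
  expr <- rel_expression(coh$ct, coh$annotation)
  model <- fit_risk_model(expr, coh$annotation,
                          c("lnc_0001", "lnc_0002", "lnc_0003"))
  ba <- blind_accuracy(model, expr, coh$annotation, contrast("NC", "HCC"))
  expect_equal(ba$n_correct / ba$n, ba$accuracy)
  # huge effects separate the blind set essentially perfectly
  expect_gte(ba$accuracy, 0.9)
  # generalization: blind accuracy within simulation noise of validation
  ev <- evaluate_contrast(model, expr, coh$annotation, contrast("NC", "HCC"))
  acc_v <- ev$accuracy[ev$variant == "panel"]
  expect_lt(abs(ba$accuracy - acc_v), 3 * sqrt(0.25 / ba$n) + 0.05)
})

test_that("stability: identical replicates are flagged stable with p = 1", {
  d <- tidyr::expand_grid(assay_id = c("m1", "m2"),
                          sample_id = sprintf("P%02d", 1:4),
                          condition = c("baseline", "RT_12h"))
  d$expr <- rep(c(2, 3), each = 8)[seq_len(nrow(d))]
  d$expr <- ifelse(d$assay_id == "m1", 2, 3)  # identical across conditions
  s <- stability_compare(d)
  expect_true(all(s$p_value == 1))
  expect_true(all(s$mean_log2_ratio == 0))
  expect_true(all(s$stable))
})

test_that("a 3-sigma shifted condition is detected as unstable", {
  unstable <- vapply(1:20, function(s) {
    d <- simulate_stability_data(
      n_subjects = 10, marker_ids = "m1",
      conditions = c("baseline", "shifted"),
      log2_shift_by_condition = c(shifted = 1.5),  # 3 x sigma_log2
      sigma_log2 = 0.5, seed = 500 + s
    )
    !stability_compare(d)$stable[1]
  }, TRUE)
  expect_gte(mean(unstable), 0.99)
})

test_that("null conditions are called stable at about the nominal rate", {
  res <- vapply(1:15, function(s) {
    d <- simulate_stability_data(n_subjects = 8,
                                 marker_ids = sprintf("m%02d", 1:8),
                                 conditions = c("baseline", "c1", "c2", "c3"),
                                 seed = 700 + s)
    out <- stability_compare(d)
    mean(out$stable[!duplicated(out$assay_id)])
  }, 0)
  rate <- mean(res)
  # three comparisons per marker at alpha .05: stable rate ~ 0.95^3 ~ 0.86
  expect_gt(rate, 0.70)
  expect_lt(rate, 0.98)
})

test_that("unpaired stability input is rejected", {
  d <- simulate_stability_data(n_subjects = 4, marker_ids = "m1",
                               conditions = c("baseline", "RT"))
  expect_error(stability_compare(d[-1, ]), class = "exopanel_unpaired")
  expect_error(stability_compare(dplyr::filter(d, condition == "baseline")),
               ">= 2")
})

test_that("plot builders return ggplot objects", {
  r <- roc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$auc, 0.75)
  scr <- tibble::tibble(assay_id = c("a", "b"), contrast = "c1",
                        log2_fc = c(1, -1), p_value = c(0.01, 0.5),
                        pass = c(TRUE, FALSE))
  expect_s3_class(plot_screen(scr), "ggplot")
  sc <- tibble::tibble(sample_id = c("a", "b"), rsf = c(0, 2))
  expect_s3_class(plot_risk_scores(sc, c(FALSE, TRUE), cutoff = 1), "ggplot")
})
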