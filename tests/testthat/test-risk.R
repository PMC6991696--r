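make_expr_table <- function(values_by_marker, sample_ids = NULL, censored = NULL) {
  n_s <- length(values_by_marker[[1]])
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n_s))
  out <- purrr::imap(values_by_marker, function(v, id) {
    tibble::tibble(assay_id = id, sample_id = sample_ids, expr = v,
                   censored = if (is.null(censored)) FALSE else censored[[id]])
  })
  dplyr::bind_rows(out)
}

test_that("the control 95th percentile uses the linear-interpolation quantile", {
  expr <- make_expr_table(list(m1 = as.numeric(1:100)))
  ann <- make_annotation(unique(expr$sample_id), rep("NC", 100))
  th <- fit_thresholds(expr, ann, "m1")
  expect_equal(th$theta, 95.05)
  # constant controls give theta equal to that constant
  expr2 <- make_expr_table(list(m1 = rep(3.7, 10)))
  ann2 <- make_annotation(unique(expr2$sample_id), rep("NC", 10))
  expect_equal(fit_thresholds(expr2, ann2, "m1")$theta, 3.7)
})

test_that("the parametric threshold converges to the log-normal quantile", {
  set.seed(41)
  x <- exp(rnorm(50000))
  expr <- make_expr_table(list(m1 = x))
  ann <- make_annotation(unique(expr$sample_id), rep("NC", 50000))
  th <- fit_thresholds(expr, ann, "m1", method = "parametric")
  expect_equal(th$theta, exp(qnorm(0.95)), tolerance = 0.03)
})

test_that("threshold fitting demands enough controls", {
  expr <- make_expr_table(list(m1 = c(1, 2, 3, 4)))
  ann <- make_annotation(unique(expr$sample_id), rep("NC", 4))
  expect_error(fit_thresholds(expr, ann, "m1"), ">= 5")
  ann_ch <- make_annotation(unique(expr$sample_id), rep("CH", 4))
  expect_error(fit_thresholds(expr, ann_ch, "m1"), "control group is empty")
  expect_error(fit_thresholds(expr, ann, "other"), "absent")
})

test_that("coding is strict at the threshold and censored wells code 0", {
  theta <- tibble::tibble(marker_id = "m1", theta = 2)
  expr <- make_expr_table(
    list(m1 = c(2, 2 + 1e-9, 1, 5)),
    censored = list(m1 = c(FALSE, FALSE, FALSE, TRUE))
  )
  s <- code_samples(expr, theta)
  expect_equal(s$s, c(0L, 1L, 0L, 0L))  # boundary, above, below, censored-high
  expect_error(code_samples(make_expr_table(list(m2 = 1)), theta), "absent")
})

test_that("control coding rate calibrates to ~5% out of sample", {
  set.seed(57)
  n <- 4000
  train <- exp(rnorm(n))
  fresh <- exp(rnorm(n))
  expr_tr <- make_expr_table(list(m1 = train))
  ann_tr <- make_annotation(unique(expr_tr$sample_id), rep("NC", n))
  th <- fit_thresholds(expr_tr, ann_tr, "m1")
  rate <- mean(fresh > th$theta)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("risk scores are the weighted sum of codes", {
  codes <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 3),
    marker_id = rep(c("m1", "m2", "m3"), 2),
    s = c(1L, 1L, 1L, 0L, 0L, 0L)
  )
  rs <- risk_scores(codes)
  expect_equal(rs$rsf[rs$sample_id == "a"], 3)
  expect_equal(rs$rsf[rs$sample_id == "b"], 0)
  rs_w <- risk_scores(codes, c(m1 = 0.5, m2 = 2, m3 = 1))
  expect_equal(rs_w$rsf[rs_w$sample_id == "a"], 3.5)
  expect_error(risk_scores(codes, c(m1 = -1, m2 = 1, m3 = 1)), "negative")
  expect_silent(risk_scores(codes, c(m1 = -1, m2 = 1, m3 = 1),
                            allow_negative = TRUE))
})

test_that("risk scores equal the brute-force sum on random draws", {
  set.seed(63)
  n_s <- 500; n_m <- 7
  s_mat <- matrix(rbinom(n_s * n_m, 1, 0.4), n_s, n_m)
  w <- runif(n_m, 0, 2)
  ids <- sprintf("S%05d", seq_len(n_s))
  mks <- sprintf("m%d", seq_len(n_m))
  codes <- tibble::tibble(
    sample_id = rep(ids, times = n_m),
    marker_id = rep(mks, each = n_s),
    s = as.integer(as.vector(s_mat))
  )
  rs <- risk_scores(codes, stats::setNames(w, mks))
  expect_equal(rs$rsf[match(ids, rs$sample_id)], as.vector(s_mat %*% w))
})

test_that("fit_cutoff recovers perfect separation and forced intervals", {
  fc <- fit_cutoff(c(0, 1, 2, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(fc$sensitivity, 1)
  expect_equal(fc$specificity, 1)
  fc2 <- fit_cutoff(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(fc2$cutoff > 1 && fc2$cutoff <= 2)
  expect_equal(fc2$sensitivity + fc2$specificity, 2)
  expect_error(fit_cutoff(1:4, rep(TRUE, 4)), class = "exopanel_single_class")
  expect_error(fit_cutoff(1:4, rep(c(TRUE, FALSE), 2)[1:3]), "length")
})

test_that("fit_cutoff matches the exhaustive oracle with its tie-breaks", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    rsf <- sample(0:4, n, replace = TRUE)
    y <- runif(n) < 0.5
    if (all(y) || !any(y)) next
    fc <- fit_cutoff(rsf, y)
    oracle <- cutoff_brute_force(rsf, y)
    expect_equal(fc$sensitivity + fc$specificity, oracle$tot)
    expect_equal(fc$cutoff, oracle$c)
    # deterministic under input permutation
    p <- sample(n)
    expect_equal(fit_cutoff(rsf[p], y[p])$cutoff, fc$cutoff)
  }
})

test_that("the median cut-off rule is available", {
  rsf <- c(0, 1, 1, 2, 3, 3)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fc <- fit_cutoff(rsf, y, rule = "median")
  expect_equal(fc$cutoff, median(rsf))
})

test_that("cut-off classifications are invariant to increasing transforms", {
  set.seed(72)
  rsf <- sample(0:3, 30, replace = TRUE)
  y <- runif(30) < 0.4
  if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
  c1 <- fit_cutoff(rsf, y)
  c2 <- fit_cutoff(exp(rsf), y)
  expect_identical(rsf >= c1$cutoff, exp(rsf) >= c2$cutoff)
})

test_that("AFP extension adds exactly zero or one", {
  codes <- tibble::tibble(sample_id = c("a", "b"), marker_id = "m1",
                          s = c(0L, 1L))
  ann <- make_annotation(c("a", "b"), c("NC", "HCC-N"), afp = c(2, 50))
  ext <- combine_with_afp(codes, ann, afp_theta = 20)
  base <- risk_scores(codes)
  expect_equal(ext$rsf - base$rsf[match(ext$sample_id, base$sample_id)],
               c(0, 1))
  # AFP below threshold everywhere leaves the score unchanged
  ext0 <- combine_with_afp(codes, ann, afp_theta = 100)
  expect_equal(ext0$rsf, base$rsf[match(ext0$sample_id, base$sample_id)])
  # panel score 0 with positive AFP gives exactly 1
  expect_equal(ext$rsf[ext$sample_id == "b"] -
                 base$rsf[base$sample_id == "b"], 1)
  ann_na <- make_annotation(c("a", "b"), c("NC", "HCC-N"),
                            afp = c(2, NA))
  expect_error(combine_with_afp(codes, ann_na, 20),
               class = "exopanel_missing_afp")
})

test_that("raising expression never decreases the risk score", {
  set.seed(81)
  theta <- tibble::tibble(marker_id = c("m1", "m2"), theta = c(1.5, 2.5))
  for (i in 1:25) {
    v1 <- runif(6, 0, 4); v2 <- runif(6, 0, 4)
    expr <- make_expr_table(list(m1 = v1, m2 = v2))
    rs <- risk_scores(code_samples(expr, theta))
    j <- sample(6, 1)
    v1b <- v1; v1b[j] <- v1b[j] + runif(1, 0, 3)
    rs2 <- risk_scores(code_samples(make_expr_table(list(m1 = v1b, m2 = v2)), theta))
    expect_true(all(rs2$rsf >= rs$rsf))
    expect_true(all(rs2$rsf <= 2), info = "rsf bounded by sum of unit weights")
  }
})

test_that("a fitted model round-trips through JSON with identical classifications", {
  cfg <- tiny_sim_config(seed = 23)
  coh <- simulate_cohort(cfg)
  expr <- rel_expression(coh$ct, coh$annotation)
  model <- fit_risk_model(expr, coh$annotation,
                          c("lnc_0001", "lnc_0002", "lnc_0003"))
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(model, path)
  model2 <- read_risk_model(path)
  expect_equal(model2$theta$theta, model$theta$theta)
  expect_equal(model2$cutoffs$cutoff, model$cutoffs$cutoff)
  for (v in c("panel", "panel_plus_afp")) {
    p1 <- predict(model, expr, coh$annotation,
                  contrast_name = "HCC_vs_NC", variant = v)
    p2 <- predict(model2, expr, coh$annotation,
                  contrast_name = "HCC_vs_NC", variant = v)
    expect_identical(p1$risk_class, p2$risk_class)
  }
})

test_that("tidy and glance summarize the fitted model", {
  cfg <- tiny_sim_config(seed = 29)
  coh <- simulate_cohort(cfg)
  expr <- rel_expression(coh$ct, coh$annotation)
  model <- fit_risk_model(expr, coh$annotation, c("lnc_0001", "lnc_0002"))
  td <- tidy(model)
  expect_equal(td$marker_id, c("lnc_0001", "lnc_0002"))
  expect_equal(td$weight, c(1, 1))
  gl <- glance(model)
  expect_equal(gl$n_markers, 2)
  expect_equal(gl$max_rsf, 2)
  expect_output(print(model), "Risk-score model")
})
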