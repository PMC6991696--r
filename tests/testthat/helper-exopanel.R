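# Fixture builders and independent oracles used across the suite.

# Long-format Ct table from an assays x samples matrix, with a reference row.
make_ct_table <- function(ct_mat, ref_ct, assay_ids = NULL, sample_ids = NULL,
                          nondetect_limit = 35, reference_assay_id = "cel-miR-39") {
  n_m <- nrow(ct_mat)
  n_s <- ncol(ct_mat)
  if (is.null(assay_ids)) assay_ids <- sprintf("lnc_%04d", seq_len(n_m))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n_s))
  full <- rbind(ct_mat, ref_ct)
  nondetect <- full >= nondetect_limit
  full <- pmin(full, nondetect_limit)
  ct <- tibble::tibble(
    assay_id = rep(c(assay_ids, reference_assay_id), times = n_s),
    sample_id = rep(sample_ids, each = n_m + 1L),
    ct = as.vector(full),
    nondetect = as.vector(nondetect)
  )
  attr(ct, "reference_assay_id") <- reference_assay_id
  attr(ct, "nondetect_limit") <- nondetect_limit
  ct
}

make_annotation <- function(sample_ids, groups, afp = NULL, split = "train") {
  tibble::tibble(
    sample_id = sample_ids,
    group = groups,
    afp = if (is.null(afp)) rep(10, length(sample_ids)) else afp,
    split = split
  )
}

# Mann-Whitney pair-counting AUC: P(case > control) + 1/2 P(tie),
# by explicit enumeration of all case-control pairs.
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive cut-off search with the documented tie-break
# (max sens+spec, then max specificity, then smallest cut-off), carried out
# in exact integer counts sample by sample.
cutoff_brute_force <- function(rsf, y) {
  v <- sort(unique(rsf))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  n_pos <- sum(y); n_neg <- sum(!y)
  best <- NULL
  for (c in cand) {
    tp <- 0L; tn <- 0L
    for (k in seq_along(rsf)) {
      if (y[k] && rsf[k] >= c) tp <- tp + 1L
      if (!y[k] && rsf[k] < c) tn <- tn + 1L
    }
    obj <- tp * n_neg + tn * n_pos  # = (sens + spec) * n_pos * n_neg
    if (is.null(best) || obj > best$obj ||
        (obj == best$obj && tn > best$tn)) {
      best <- list(c = c, obj = obj, tp = tp, tn = tn,
                   tot = tp / n_pos + tn / n_neg,
                   sens = tp / n_pos, spec = tn / n_neg)
    }
  }
  best
}

# Small fast cohort for integration-style tests.
tiny_sim_config <- function(seed = 1, ...) {
  args <- list(
    n_per_group_screen = 3, n_per_group_train = 10, n_per_group_valid = 30,
    n_blind = 20, n_markers_total = 20,
    delta_dct_per_stage = 1.5, sigma_dct = 1, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
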