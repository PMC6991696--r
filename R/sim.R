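#' Simulation configuration for a synthetic multiphase cohort
#'
#' Describes the study design of a four-group (NC, CH, HCC-N, HCC-M)
#' case-control cohort with screen / train / valid / blind splits, a marker
#' roster with a small set of planted up-regulated lncRNAs against a null
#' background, right-censoring of Ct values at the nondetect limit, and an
#' AFP covariate with weak group separation.
#'
#' Expression acts on the \eqn{\Delta Ct} scale (marker Ct minus spike-in
#' reference Ct); planted markers shift the \eqn{\Delta Ct} location down by
#' `delta_dct_per_stage` per group step along NC, CH, HCC-N, HCC-M (lower Ct
#' means higher expression) with constant within-group standard deviation
#' `sigma_dct`. Null markers share one group-independent \eqn{\Delta Ct}
#' distribution.
#'
#' @param n_per_group_screen,n_per_group_train,n_per_group_valid Samples per
#'   clinical group in the screen, training and validation splits. Defaults
#'   mirror the multiphase design: 3 / 20 / 180 per group.
#' @param n_blind Total double-blind samples, allocated as evenly as
#'   possible across the four groups. Default 100.
#' @param n_markers_total Number of lncRNA assays (the spike-in reference is
#'   added on top of these).
#' @param planted_marker_ids Assay ids carrying the planted group effect;
#'   must be a subset of the roster `lnc_0001 ... lnc_<n>`.
#' @param delta_dct_per_stage Decrease in mean \eqn{\Delta Ct} (Ct units)
#'   per group step for planted markers.
#' @param sigma_dct Within-group SD of \eqn{\Delta Ct} (Ct units).
#' @param nondetect_limit Ct value at and above which a well is a nondetect;
#'   simulated Ct values are right-censored here. Default 35.
#' @param baseline_dct_range Range of per-marker baseline mean
#'   \eqn{\Delta Ct} (uniform draw), placing typical marker Ct well below
#'   the nondetect limit.
#' @param afp_log_mean_by_group Named vector of log-AFP means (natural log,
#'   AFP in ng/mL) for NC, CH, HCC-N, HCC-M. The defaults give AFP-alone
#'   discrimination of HCC from NC an AUC of roughly 0.6, i.e. a
#'   deliberately mediocre single covariate.
#' @param afp_log_sd Log-scale SD of AFP, shared across groups.
#' @param reference_ct_mean,reference_ct_sd Spike-in reference assay Ct
#'   distribution, independent of group (the spike-in is exogenous).
#' @param seed Integer seed; the generated cohort is a deterministic
#'   function of the configuration including the seed.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_group_screen = 3,
                       n_per_group_train = 20,
                       n_per_group_valid = 180,
                       n_blind = 100,
                       n_markers_total = 200,
                       planted_marker_ids = c("lnc_0001", "lnc_0002", "lnc_0003"),
                       delta_dct_per_stage = 1.0,
                       sigma_dct = 1.0,
                       nondetect_limit = 35,
                       baseline_dct_range = c(5, 10),
                       afp_log_mean_by_group = c(
                         "NC" = 2.30, "CH" = 2.60, "HCC-N" = 2.85, "HCC-M" = 2.95
                       ),
                       afp_log_sd = 1.5,
                       reference_ct_mean = 20,
                       reference_ct_sd = 0.25,
                       seed = 1L) {
  counts <- c(n_per_group_screen, n_per_group_train, n_per_group_valid, n_blind)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort_exopanel("all design counts must be integers >= 1")
  }
  if (sigma_dct <= 0) abort_exopanel("sigma_dct must be > 0")
  if (nondetect_limit <= 0) abort_exopanel("nondetect_limit must be > 0")
  if (n_markers_total < 1) abort_exopanel("n_markers_total must be >= 1")
  roster <- sprintf("lnc_%04d", seq_len(n_markers_total))
  bad <- setdiff(planted_marker_ids, roster)
  if (length(bad) > 0) {
    abort_exopanel(
      sprintf("planted marker id(s) not in assay roster: %s",
              paste(bad, collapse = ", ")),
      class = "exopanel_bad_config"
    )
  }
  if (!all(GROUP_LEVELS %in% names(afp_log_mean_by_group))) {
    abort_exopanel("afp_log_mean_by_group must name all four groups")
  }
  structure(
    list(
      n_per_group_screen = as.integer(n_per_group_screen),
      n_per_group_train = as.integer(n_per_group_train),
      n_per_group_valid = as.integer(n_per_group_valid),
      n_blind = as.integer(n_blind),
      n_markers_total = as.integer(n_markers_total),
      assay_ids = roster,
      planted_marker_ids = planted_marker_ids,
      delta_dct_per_stage = delta_dct_per_stage,
      sigma_dct = sigma_dct,
      nondetect_limit = nondetect_limit,
      baseline_dct_range = baseline_dct_range,
      afp_log_mean_by_group = afp_log_mean_by_group,
      afp_log_sd = afp_log_sd,
      reference_ct_mean = reference_ct_mean,
      reference_ct_sd = reference_ct_sd,
      reference_assay_id = "cel-miR-39",
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic multiphase qPCR cohort
#'
#' Draws a seeded synthetic Ct table (assays x samples, long format) plus a
#' per-sample annotation table with the group structure, planted effect
#' sizes, Ct censoring and AFP covariate described by the configuration.
#' Marker Ct is `reference Ct + baseline dCt - stage effect + noise`;
#' values at or above the nondetect limit are recorded at the limit with
#' `nondetect = TRUE` (right-censoring, a single mechanism so the nondetect
#' fraction rises monotonically as the limit is lowered).
#'
#' @param config A [sim_config()].
#' @return A list of class `exo_cohort` with elements
#'   \describe{
#'     \item{ct}{tibble with columns `assay_id`, `sample_id`, `ct`,
#'       `nondetect`; includes the spike-in reference row, which is never a
#'       nondetect. Carries `reference_assay_id` and `nondetect_limit` as
#'       attributes.}
#'     \item{annotation}{tibble with `sample_id`, `group`, `afp`, `split`.}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_markers_total = 10, seed = 7))
#' dplyr::count(cohort$annotation, group, split)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ann <- simulate_annotation(config)
    n_s <- nrow(ann)
    n_m <- config$n_markers_total
    assays <- config$assay_ids
    stage <- match(ann$group, GROUP_LEVELS) - 1L

    ref_ct <- stats::rnorm(n_s, config$reference_ct_mean, config$reference_ct_sd)
    mu <- stats::runif(n_m, config$baseline_dct_range[1], config$baseline_dct_range[2])
    planted <- assays %in% config$planted_marker_ids

    # assays vary fastest: matrix is n_m x n_s
    shift <- outer(planted * config$delta_dct_per_stage, stage)
    dct <- mu + matrix(stats::rnorm(n_m * n_s, 0, config$sigma_dct), n_m, n_s) - shift
    ct_raw <- sweep(dct, 2, ref_ct, "+")
    nondetect <- ct_raw >= config$nondetect_limit
    ct_cens <- pmin(ct_raw, config$nondetect_limit)

    ct <- tibble::tibble(
      assay_id = rep(c(assays, config$reference_assay_id), times = n_s),
      sample_id = rep(ann$sample_id, each = n_m + 1L),
      ct = as.vector(rbind(ct_cens, ref_ct)),
      nondetect = as.vector(rbind(nondetect, rep(FALSE, n_s)))
    )
    attr(ct, "reference_assay_id") <- config$reference_assay_id
    attr(ct, "nondetect_limit") <- config$nondetect_limit

    structure(list(ct = ct, annotation = ann), class = "exo_cohort")
  })
}

simulate_annotation <- function(config) {
  per_split <- list(
    screen = rep(config$n_per_group_screen, 4),
    train = rep(config$n_per_group_train, 4),
    valid = rep(config$n_per_group_valid, 4)
  )
  # blind samples spread as evenly as possible over the four groups
  base <- config$n_blind %/% 4L
  extra <- config$n_blind %% 4L
  per_split$blind <- base + as.integer(seq_len(4) <= extra)

  rows <- purrr::map(names(per_split), function(sp) {
    tibble::tibble(
      group = rep(GROUP_LEVELS, times = per_split[[sp]]),
      split = sp
    )
  })
  ann <- dplyr::bind_rows(rows)
  ann$sample_id <- sprintf("S%05d", seq_len(nrow(ann)))
  mu_afp <- config$afp_log_mean_by_group[ann$group]
  ann$afp <- exp(stats::rnorm(nrow(ann), mu_afp, config$afp_log_sd))
  tibble::as_tibble(ann[, c("sample_id", "group", "afp", "split")])
}

#' Write / read a cohort as plain-text TSV
#'
#' `write_cohort()` serializes the Ct table as a wide TSV (rows = assays,
#' columns = samples, first column `assay_id`) with nondetect wells encoded
#' as the sentinel token `"ND"` (never as a fake numeric Ct), the annotation
#' as TSV, and the reference assay id / nondetect limit as a small JSON
#' sidecar. `read_cohort()` restores the cohort losslessly (in-memory,
#' censored wells hold the numeric nondetect limit, so the round trip is
#' exact).
#'
#' @param cohort An `exo_cohort` list as from [simulate_cohort()].
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns the directory invisibly;
#'   `read_cohort()` returns an `exo_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  ct <- cohort$ct
  ann <- cohort$annotation
  if (!setequal(unique(ct$sample_id), ann$sample_id)) {
    abort_exopanel("sample ids of Ct table and annotation do not match")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- ct |>
    dplyr::mutate(
      value = ifelse(.data$nondetect, "ND", format_nums(.data$ct)),
      assay_id = factor(.data$assay_id, levels = unique(.data$assay_id))
    ) |>
    dplyr::select("assay_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  readr::write_tsv(wide, file.path(dir, "ct.tsv"))
  readr::write_tsv(
    dplyr::mutate(ann, afp = format_nums(.data$afp)),
    file.path(dir, "annotation.tsv")
  )
  jsonlite::write_json(
    list(
      reference_assay_id = attr(ct, "reference_assay_id"),
      nondetect_limit = attr(ct, "nondetect_limit")
    ),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# full-precision decimal representation that round-trips doubles exactly:
# 15 significant digits where that suffices, 17 otherwise
format_nums <- function(x) {
  s <- sprintf("%.15g", x)
  redo <- as.numeric(s) != x
  s[redo] <- sprintf("%.17g", x[redo])
  s
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  wide <- readr::read_tsv(
    file.path(dir, "ct.tsv"),
    col_types = readr::cols(assay_id = readr::col_character(),
                            .default = readr::col_character())
  )
  ct <- wide |>
    tidyr::pivot_longer(-"assay_id", names_to = "sample_id", values_to = "value") |>
    dplyr::mutate(
      nondetect = .data$value == "ND",
      ct = ifelse(.data$nondetect, meta$nondetect_limit, suppressWarnings(as.numeric(.data$value)))
    ) |>
    dplyr::select("assay_id", "sample_id", "ct", "nondetect") |>
    dplyr::arrange(match(.data$sample_id, unique(.data$sample_id)))
  ann <- readr::read_tsv(
    file.path(dir, "annotation.tsv"),
    col_types = readr::cols(
      sample_id = readr::col_character(), group = readr::col_character(),
      afp = readr::col_character(), split = readr::col_character()
    )
  )
  # base-R strtod parsing round-trips the full-precision decimal text exactly
  ann$afp <- as.numeric(ann$afp)
  # restore generation order: samples outermost, assays within sample
  ct <- tibble::as_tibble(ct[order(match(ct$sample_id, ann$sample_id),
                                   match(ct$assay_id, wide$assay_id)), ])
  attr(ct, "reference_assay_id") <- meta$reference_assay_id
  attr(ct, "nondetect_limit") <- meta$nondetect_limit
  structure(list(ct = ct, annotation = tibble::as_tibble(ann)),
            class = "exo_cohort")
}

#' Simulate paired handling-condition stability data
#'
#' Generates per-marker, per-subject relative-expression measurements under
#' a baseline handling condition and one or more stress conditions (e.g.
#' room-temperature incubation, freeze-thaw cycles), as used to assess
#' whether circulating markers are stable in plasma. Expression is
#' log-normal around a per-marker level; `log2_shift_by_condition` moves
#' selected conditions' log2 expression.
#'
#' @param n_subjects Paired subjects per condition.
#' @param marker_ids Character vector of marker ids.
#' @param conditions Condition labels; the first is the baseline.
#' @param log2_shift_by_condition Named numeric vector of log2 shifts
#'   (0 for unnamed conditions).
#' @param sigma_log2 Within-condition SD of log2 expression.
#' @param seed Integer seed.
#' @return Tibble with `assay_id`, `sample_id`, `condition`, `expr`.
#' @export
simulate_stability_data <- function(n_subjects = 4,
                                    marker_ids = c("lnc_0001", "lnc_0002", "lnc_0003"),
                                    conditions = c("baseline", "RT_12h", "RT_24h", "freeze_thaw"),
                                    log2_shift_by_condition = NULL,
                                    sigma_log2 = 0.5,
                                    seed = 1L) {
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      assay_id = marker_ids,
      sample_id = sprintf("P%02d", seq_len(n_subjects)),
      condition = conditions
    )
    shift <- rep(0, nrow(grid))
    if (!is.null(log2_shift_by_condition)) {
      hit <- grid$condition %in% names(log2_shift_by_condition)
      shift[hit] <- log2_shift_by_condition[grid$condition[hit]]
    }
    base <- stats::setNames(stats::runif(length(marker_ids), -2, 2), marker_ids)
    subj <- stats::rnorm(n_subjects, 0, 0.3)
    names(subj) <- sprintf("P%02d", seq_len(n_subjects))
    grid$expr <- 2^(base[grid$assay_id] + subj[grid$sample_id] + shift +
                      stats::rnorm(nrow(grid), 0, sigma_log2))
    grid
  })
}
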