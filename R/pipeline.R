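#' Configuration for the end-to-end multiphase pipeline
#'
#' Exactly one of `sim` (a [sim_config()], cohort simulated at run time) or
#' `input_dir` (a cohort previously written with [write_cohort()]) supplies
#' the data. Splits are fixed in the annotation and never re-randomized
#' inside stages; all stochastic behaviour flows from the single seed in
#' the simulation config.
#'
#' @param sim A [sim_config()], or NULL when reading from files.
#' @param input_dir Cohort directory, or NULL when simulating.
#' @param screen_split Split used for the differential screen (default
#'   `"screen"`, the small microarray-style phase).
#' @param contrasts Screening contrasts (default the three adjacent group
#'   steps, [screening_contrasts()]).
#' @param confirm_contrasts Contrasts a candidate must confirm in on the
#'   training split (default HCC vs NC and HCC vs CH); a marker must be
#'   confirmed in all of them to enter the risk model.
#' @param eval_contrasts Contrasts evaluated on validation/blind splits
#'   (default [evaluation_contrasts()]).
#' @param alpha,ct_max,det_min Screening filter parameters (p < alpha,
#'   mean Ct in the high group < ct_max, detection rate > det_min in both
#'   groups).
#' @param baseline_group Baseline group of the 2^-ddCt scale.
#' @param control_group Control group for reference-interval thresholds.
#' @param weights `NULL` (unit weights) or named numeric vector.
#' @param theta_method,cutoff_rule Passed to [fit_risk_model()].
#' @param include_afp Fit and evaluate the AFP-extended score.
#' @param candidate_panel Optional character vector of prespecified
#'   candidate markers carried directly into the training confirmation
#'   (mirroring a design where candidates are fixed upstream); when given,
#'   the Venn screen still runs and is logged, but the panel is taken as
#'   supplied.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL,
                            screen_split = "screen",
                            contrasts = screening_contrasts(),
                            confirm_contrasts = list(contrast("NC", "HCC"),
                                                     contrast("CH", "HCC")),
                            eval_contrasts = evaluation_contrasts(),
                            alpha = 0.05, ct_max = 35, det_min = 0.75,
                            baseline_group = "NC", control_group = "NC",
                            weights = NULL,
                            theta_method = "quantile",
                            cutoff_rule = "youden",
                            include_afp = TRUE,
                            candidate_panel = NULL) {
  if (is.null(sim) == is.null(input_dir)) {
    abort_exopanel("supply exactly one of `sim` or `input_dir`")
  }
  structure(
    list(sim = sim, input_dir = input_dir, screen_split = screen_split,
         contrasts = contrasts, confirm_contrasts = confirm_contrasts,
         eval_contrasts = eval_contrasts, alpha = alpha, ct_max = ct_max,
         det_min = det_min, baseline_group = baseline_group,
         control_group = control_group, weights = weights,
         theta_method = theta_method, cutoff_rule = cutoff_rule,
         include_afp = include_afp, candidate_panel = candidate_panel),
    class = "pipeline_config"
  )
}

#' Run the multiphase pipeline end-to-end
#'
#' Orchestrates simulate/load, 2^-ddCt quantification, the per-contrast
#' differential screen on the screen split, Venn candidate intersection,
#' training-split confirmation, risk-model fitting (frozen thereafter),
#' validation-split evaluation and blind-split accuracy. Every artifact is
#' written under `out_dir` (TSV/JSON) and stamped with the configuration
#' hash and seed; re-running with the same configuration reproduces
#' byte-identical numerical outputs. The log records each filter's
#' decision counts (assays in / passing per filter) per contrast, so the
#' screening funnel is auditable. An empty candidate panel or empty
#' confirmed roster ends the run cleanly with status `"no candidates"` /
#' `"none confirmed"`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; default a tempdir subfolder).
#' @return Invisibly, a list with `status`, the artifact tibbles
#'   (`screen`, `panel`, `confirmation`, `evaluation`, `blind`), the
#'   `model`, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("exopanel_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  stamp <- list(config_hash = rlang::hash(config),
                seed = if (!is.null(config$sim)) config$sim$seed else NA)
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage), stamp, list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  fail <- function(stage, e) {
    abort_exopanel(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)),
                   class = "exopanel_stage_error", parent = e)
  }

  # --- data ---------------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$sim)) simulate_cohort(config$sim) else read_cohort(config$input_dir)
  }, error = function(e) fail("data", e))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  log_line("data", n_samples = nrow(cohort$annotation),
           n_assays = length(unique(cohort$ct$assay_id)) - 1L)

  expr <- tryCatch(
    rel_expression(cohort$ct, cohort$annotation, config$baseline_group),
    error = function(e) fail("quantification", e)
  )

  # --- screen -------------------------------------------------------------
  ann_screen <- dplyr::filter(cohort$annotation, .data$split == config$screen_split)
  screen_res <- tryCatch({
    purrr::map(config$contrasts, function(ctr) {
      sub_ids <- ann_screen$sample_id
      res <- screen_contrast(
        dplyr::filter(expr, .data$sample_id %in% sub_ids),
        dplyr::filter(cohort$ct, .data$sample_id %in% sub_ids) |>
          (\(x) { attributes(x)[c("reference_assay_id", "nondetect_limit")] <-
                    attributes(cohort$ct)[c("reference_assay_id", "nondetect_limit")]; x })(),
        ann_screen, ctr,
        alpha = config$alpha, ct_max = config$ct_max, det_min = config$det_min
      )
      log_line("screen", contrast = ctr$name,
               assays_in = nrow(res),
               pass_p = sum(!is.na(res$p_value) & res$p_value < config$alpha),
               pass_ct = sum(res$mean_ct_high < config$ct_max),
               pass_det = sum(pmin(res$det_rate_low, res$det_rate_high) > config$det_min),
               pass_up = sum(res$direction == "up"),
               pass_all = sum(res$pass))
      res
    })
  }, error = function(e) fail("screen", e))
  screen_all <- dplyr::bind_rows(screen_res)
  readr::write_tsv(screen_all, file.path(out_dir, "screen_results.tsv"))

  # --- candidate panel ----------------------------------------------------
  panel <- tryCatch(venn_candidates(screen_res), error = function(e) fail("venn", e))
  provenance <- attr(panel, "provenance")
  if (!is.null(config$candidate_panel)) {
    panel <- tibble::tibble(assay_id = config$candidate_panel,
                            evidence = NA_real_)
    provenance <- "prespecified"
  }
  jsonlite::write_json(
    list(assay_ids = panel$assay_id, evidence = panel$evidence,
         provenance = provenance, config_hash = stamp$config_hash,
         seed = stamp$seed),
    file.path(out_dir, "candidate_panel.json"), auto_unbox = TRUE, digits = NA
  )
  log_line("venn", n_candidates = nrow(panel), provenance = provenance)
  if (nrow(panel) == 0) {
    status <- list(status = "no candidates", config_hash = stamp$config_hash,
                   seed = stamp$seed)
    jsonlite::write_json(status, file.path(out_dir, "status.json"),
                         auto_unbox = TRUE)
    log_line("end", status = "no candidates")
    return(invisible(list(status = "no candidates", screen = screen_all,
                          panel = panel, out_dir = out_dir)))
  }

  # --- training confirmation ----------------------------------------------
  confirmation <- tryCatch({
    dplyr::bind_rows(purrr::map(
      config$confirm_contrasts,
      function(ctr) confirm_in_set(expr, cohort$annotation, panel, ctr,
                                   alpha = config$alpha, split = "train")
    ))
  }, error = function(e) fail("confirm", e))
  readr::write_tsv(confirmation, file.path(out_dir, "confirmation.tsv"))
  confirmed <- confirmation |>
    dplyr::summarise(all_confirmed = all(.data$confirmed), .by = "assay_id") |>
    dplyr::filter(.data$all_confirmed)
  roster <- intersect(panel$assay_id, confirmed$assay_id)
  log_line("confirm", candidates_in = nrow(panel), confirmed = length(roster))
  if (length(roster) == 0) {
    status <- list(status = "none confirmed", config_hash = stamp$config_hash,
                   seed = stamp$seed)
    jsonlite::write_json(status, file.path(out_dir, "status.json"),
                         auto_unbox = TRUE)
    log_line("end", status = "none confirmed")
    return(invisible(list(status = "none confirmed", screen = screen_all,
                          panel = panel, confirmation = confirmation,
                          out_dir = out_dir)))
  }

  # --- risk model (frozen after this point) -------------------------------
  model <- tryCatch(
    fit_risk_model(expr, cohort$annotation, roster,
                   control_group = config$control_group,
                   contrasts = config$eval_contrasts,
                   weights = config$weights,
                   theta_method = config$theta_method,
                   cutoff_rule = config$cutoff_rule,
                   include_afp = config$include_afp,
                   train_split = "train"),
    error = function(e) fail("fit", e)
  )
  write_risk_model(model, file.path(out_dir, "risk_model.json"))
  log_line("fit", n_markers = length(model$marker_ids),
           afp_theta = model$afp_theta)

  # --- validation evaluation ----------------------------------------------
  evaluation <- tryCatch({
    dplyr::bind_rows(purrr::map(
      config$eval_contrasts,
      function(ctr) evaluate_contrast(model, expr, cohort$annotation, ctr,
                                      split = "valid")
    ))
  }, error = function(e) fail("evaluate", e))
  readr::write_tsv(evaluation, file.path(out_dir, "evaluation_valid.tsv"))
  log_line("evaluate", rows = nrow(evaluation))

  # --- blind accuracy ------------------------------------------------------
  blind <- tryCatch({
    dplyr::bind_rows(purrr::map(
      config$eval_contrasts,
      function(ctr) blind_accuracy(model, expr, cohort$annotation, ctr)
    ))
  }, error = function(e) fail("blind", e))
  readr::write_tsv(blind, file.path(out_dir, "blind_accuracy.tsv"))
  log_line("blind", accuracies = blind$accuracy)

  jsonlite::write_json(
    list(status = "ok", config_hash = stamp$config_hash, seed = stamp$seed,
         n_candidates = nrow(panel), n_markers = length(roster)),
    file.path(out_dir, "status.json"), auto_unbox = TRUE
  )
  log_line("end", status = "ok")
  invisible(list(status = "ok", screen = screen_all, panel = panel,
                 confirmation = confirmation, model = model,
                 evaluation = evaluation, blind = blind, out_dir = out_dir))
}
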