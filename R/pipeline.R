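#' Study configuration
#'
#' Settings shared by the per-animal and group-study drivers.
#'
#' @param n_starts Multistart count for calibration.
#' @param maxiter Optimizer iteration cap per start.
#' @param seed Base RNG seed.
#' @param theta Calibrated parameter names.
#' @param sens_h Sensitivity log-step.
#' @param sens_threshold Influence threshold.
#' @return A `rh_config` list.
#' @export
study_config <- function(n_starts = 20, maxiter = 40, seed = 1,
                         theta = theta_opt_default(), sens_h = 0.01,
                         sens_threshold = 0.1) {
  stopifnot(n_starts >= 1, maxiter >= 1, sens_h > 0)
  structure(as.list(environment()), class = "rh_config")
}

#' Run the full per-animal pipeline
#'
#' Data preparation (when raw beats are supplied), nominal
#' parameterization, multistart calibration, steady-state simulation at the
#' optimum, and derived metrics.
#'
#' @param record Animal record (see [nominal_parameters()]).
#' @param lv_beats,rv_beats Raw beat tibbles; when `NULL`, calibration-
#'   ready `prepared` data must be given.
#' @param prepared Optional `rh_prepared` object (skips preprocessing).
#' @param cfg A [study_config()].
#' @param ref_edp Group-reference EDPs for the negative-EDP correction.
#' @return An `rh_subject` list: `record`, `prepared`, `nominal`,
#'   `calibration`, `cycle`, `metrics`, `failed_stage` (`NA` on success).
#' @export
run_subject <- function(record, lv_beats = NULL, rv_beats = NULL,
                        prepared = NULL, cfg = study_config(),
                        ref_edp = c(LV = 4, RV = 3)) {
  out <- list(record = record, failed_stage = NA_character_)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      out$failed_stage <<- sprintf("%s: %s", name, conditionMessage(e))
      NULL
    })
  }
  out$prepared <- prepared %||%
    stage("data_prep", prepare_animal(lv_beats, rv_beats, ref_edp))
  out$nominal <- stage("parameterization", {
    p <- nominal_parameters(record)
    if (identical(record$condition, "Hx")) p <- apply_hyperoxia_modifiers(p)
    p
  })
  if (is.null(out$prepared) || is.null(out$nominal))
    return(structure(out, class = "rh_subject"))
  out$calibration <- stage("calibration",
    multistart_calibrate(out$prepared, out$nominal, theta = cfg$theta,
                         n_starts = cfg$n_starts, maxiter = cfg$maxiter,
                         seed = cfg$seed))
  if (is.null(out$calibration))
    return(structure(out, class = "rh_subject"))
  out$cycle <- stage("simulation",
    out$calibration$cycle %||% run_to_steady_state(out$calibration$params))
  if (!is.null(out$cycle))
    out$metrics <- stage("metrics",
      compute_metrics(out$cycle, out$calibration$params))
  structure(out, class = "rh_subject")
}

#' @export
print.rh_subject <- function(x, ...) {
  cat("<rh_subject>", if (is.na(x$failed_stage)) "complete"
      else paste("FAILED at", x$failed_stage), "\n")
  if (!is.null(x$calibration))
    cat(sprintf("  best J = %.4g\n", x$calibration$J))
  invisible(x)
}

#' One-line subject summary
#'
#' @param x An `rh_subject`.
#' @param ... Unused.
#' @return One-row tibble: id, condition, cost, key metrics.
#' @export
glance.rh_subject <- function(x, ...) {
  dplyr::bind_cols(
    tibble(id = as.character(x$record$id %||% NA),
           condition = x$record$condition,
           failed = !is.na(x$failed_stage),
           J = if (!is.null(x$calibration)) x$calibration$J else NA_real_),
    if (!is.null(x$metrics)) x$metrics else tibble()
  )
}

#' Run a cohort study
#'
#' Per-animal pipelines over a synthetic cohort, followed by group
#' statistics (condition comparisons, correlation tests) and the
#' three-feature-set linear-discriminant separability analysis (measured
#' data alone, calibrated parameters alone, and both combined).
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param spec The [cohort_spec()] used to synthesize recordings.
#' @param cfg A [study_config()].
#' @param anchor Anchor synthetic recordings to each animal's record.
#' @return An `rh_study` list: `subjects`, `metrics` (per-animal table),
#'   `comparisons`, `correlations`, `lda`, `failures`.
#' @export
run_group_study <- function(cohort, spec, cfg = study_config(),
                            anchor = FALSE) {
  subjects <- purrr::map(seq_len(nrow(cohort)), function(k) {
    recs <- tryCatch(
      synthesize_recordings(cohort$params[[k]], spec,
                            record = cohort$record[[k]], anchor = anchor),
      error = function(e) NULL)
    if (is.null(recs))
      return(structure(list(record = cohort$record[[k]],
                            failed_stage = "synthesis"),
                       class = "rh_subject"))
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    run_subject(cohort$record[[k]], recs$lv, recs$rv, cfg = cfg_k)
  })
  ok <- !vapply(subjects, function(s) is.na(s$failed_stage) == FALSE, TRUE)
  ok <- vapply(subjects, function(s) is.na(s$failed_stage), TRUE)
  metrics <- purrr::map_dfr(subjects[ok], glance)
  metrics$condition <- vapply(subjects[ok], function(s)
    s$record$condition, "")
  theta_tab <- purrr::map_dfr(subjects[ok], function(s)
    tibble::as_tibble_row(s$calibration$theta))
  metrics <- dplyr::bind_cols(metrics,
                              setNames(theta_tab, names(theta_tab)))
  comparisons <- group_comparisons(metrics)
  correlations <- correlation_table(metrics)
  data_feats <- purrr::map_dfr(subjects[ok], function(s)
    tibble::as_tibble_row(unlist(s$record[c("BW", "T", "SV", "ESV_LV",
                                            "ESV_RV", "EDP_LV", "EDP_RV",
                                            "ESP_LV", "ESP_RV")])))
  lda <- lda_separability(
    list(data = data_feats, parameters = theta_tab,
         combined = dplyr::bind_cols(data_feats, theta_tab)),
    labels = metrics$condition)
  structure(
    list(subjects = subjects, metrics = metrics,
         comparisons = comparisons, correlations = correlations,
         lda = lda,
         failures = vapply(subjects[!ok], function(s)
           s$failed_stage, "")),
    class = "rh_study")
}

#' @export
print.rh_study <- function(x, ...) {
  cat(sprintf("<rh_study> %d subjects (%d failed)\n",
              length(x$subjects), length(x$failures)))
  cat("LDA separation indices:\n")
  print(round(attr(x$lda, "separation"), 2))
  invisible(x)
}
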