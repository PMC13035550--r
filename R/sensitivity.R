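#' Organ-scale sensitivity parameter set
#'
#' The 18 organ-scale and cardiac-timing parameters whose influence on the
#' LV/RV pressure and volume signals is screened: the four compliances,
#' the two vascular and four valve resistances, the three midwall reference
#' areas, the three wall volumes, and the two Ca2+ timing fractions.
#'
#' @return Character vector of registry names, in the canonical order.
#' @export
sens_parameter_names <- function() {
  c("C_SA", "C_SV", "C_PA", "C_PV", "R_SA", "R_PA", "R_m", "R_a", "R_t",
    "R_p", "Am_ref_RV", "Am_ref_LV", "Am_ref_SEP", "Vw_RV", "Vw_LV",
    "Vw_SEP", "k_TS", "k_TR")
}

# concatenated LV/RV volume and pressure output vector on the N-point grid
pv_output_vector <- function(cyc) {
  c(cyc$V_LV, cyc$V_RV, cyc$P_LV, cyc$P_RV)
}

# centered difference of f on the log scale: (f(e^{l+h}) - f(e^{l-h}))/(2h)
log_centered_diff <- function(f, log_theta, h) {
  (f(exp(log_theta + h)) - f(exp(log_theta - h))) / (2 * h)
}

#' Local log-scale sensitivity matrix
#'
#' Centered-difference derivatives of the concatenated LV/RV pressure and
#' volume outputs with respect to the log-parameters: for each parameter,
#' two steady-state simulations at `exp(log(theta) +/- h)`.
#'
#' @param p Baseline `rh_params` set.
#' @param theta Parameter names (default the 18-parameter organ-scale set).
#' @param h Log-scale step (default 0.01).
#' @param tol,max_cycles Steady-state settings shared with
#'   [run_to_steady_state()].
#' @return A `4N x length(theta)` matrix (rows: V_LV, V_RV, P_LV, P_RV
#'   blocks) with attribute `baseline` (the baseline cycle).
#' @export
local_sensitivity <- function(p, theta = sens_parameter_names(), h = 0.01,
                              tol = 1e-3, max_cycles = 40) {
  base <- run_to_steady_state(p, tol = tol, max_cycles = max_cycles)
  y0 <- attr(base, "final_state")
  cols <- lapply(theta, function(nm) {
    f <- function(val) {
      pp <- modify_params(p, setNames(val, nm))
      cyc <- tryCatch(
        suppressWarnings(run_to_steady_state(pp, y0 = y0, tol = tol,
                                             max_cycles = max_cycles)),
        error = function(e)
          abort(sprintf("perturbed simulation failed for parameter %s: %s",
                        nm, conditionMessage(e))))
      pv_output_vector(cyc)
    }
    log_centered_diff(f, log(p[[nm]]), h)
  })
  S <- do.call(cbind, cols)
  colnames(S) <- theta
  attr(S, "baseline") <- base
  S
}

#' Normalize and rank sensitivities
#'
#' Reduces each animal's sensitivity matrix to one scalar per parameter
#' (the Euclidean norm of the parameter's column over the concatenated
#' output grid), normalizes by the animal's maximum so values span
#' `[0, 1]`, and ranks parameters by group-mean normalized sensitivity.
#' Parameters with normalized sensitivity above 0.1 are flagged
#' influential.
#'
#' @param S_list Named list of sensitivity matrices, one per animal.
#' @param threshold Influence threshold (default 0.1).
#' @return A `rh_ranking` tibble: animal, parameter, sensitivity,
#'   normalized, plus group columns `mean_normalized`, `rank`,
#'   `influential`.
#' @export
normalize_and_rank <- function(S_list, threshold = 0.1) {
  if (is.null(names(S_list)))
    names(S_list) <- paste0("animal", seq_along(S_list))
  per <- purrr::map_dfr(names(S_list), function(a) {
    S <- S_list[[a]]
    s <- sqrt(colSums(S^2))
    if (max(s) == 0) abort("all-zero sensitivity matrix")
    tibble(animal = a, parameter = colnames(S), sensitivity = s,
           normalized = s / max(s))
  })
  grp <- per |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_normalized = mean(.data$normalized),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_normalized)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  influential = .data$mean_normalized > threshold)
  out <- dplyr::left_join(per, grp, by = "parameter")
  structure(out, class = c("rh_ranking", class(out)), threshold = threshold)
}

#' Fisher-information condition number of a parameter subset
#'
#' Forms the approximate Fisher information matrix `F = S^T S` restricted
#' to the subset columns and returns its condition number (the squared
#' singular-value ratio of the restricted sensitivity matrix). Subsets are
#' identifiable when the condition number is below `1e8`.
#'
#' @param S Sensitivity matrix.
#' @param subset Column names (default all columns).
#' @return Condition number (may be `Inf` for rank-deficient subsets).
#' @export
fim_condition <- function(S, subset = colnames(S)) {
  d <- svd(S[, subset, drop = FALSE], nu = 0, nv = 0)$d
  if (min(d) <= max(d) * 1e-14) return(Inf)
  (max(d) / min(d))^2
}

#' Select the calibration parameter subset
#'
#' Parameters influential (group-mean normalized sensitivity above the
#' threshold) in every condition group are retained; the marginal
#' compliances `C_SA`/`C_SV` are dropped when they clear the threshold in
#' only some groups (the harmonization rule that keeps the subset common
#' across conditions). The resulting subset must pass the
#' Fisher-information screen.
#'
#' @param rankings Named list of `rh_ranking` tables, one per condition
#'   group.
#' @param S A sensitivity matrix used for the FIM screen (typically the
#'   group-average animal's).
#' @param threshold Influence threshold.
#' @param fim_limit Condition-number acceptance limit.
#' @return Character vector of selected parameter names (registry order of
#'   [sens_parameter_names()]).
#' @export
select_parameter_subset <- function(rankings, S, threshold = 0.1,
                                    fim_limit = 1e8) {
  sets <- lapply(rankings, function(r) {
    g <- dplyr::distinct(as_tibble(r), .data$parameter,
                         .data$mean_normalized)
    g$parameter[g$mean_normalized > threshold]
  })
  # common subset across conditions: parameters only borderline in one
  # group (the marginal compliances in normoxia) drop out here
  common <- Reduce(intersect, sets)
  if (!length(common)) abort("no parameters above the influence threshold")
  subset <- intersect(sens_parameter_names(), common)
  cond <- fim_condition(S, subset)
  if (!(cond < fim_limit))
    abort(sprintf(
      "selected subset fails the FIM screen (condition %.3e >= %.0e)",
      cond, fim_limit))
  subset
}
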