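# group-average hemodynamics (mean, sd) used to anchor synthetic cohorts
group_table <- function() {
  tibble(
    field = rep(c("BW", "T", "SV", "ESV_LV", "ESV_RV",
                  "EDP_LV", "EDP_RV", "ESP_LV", "ESP_RV"), 2),
    condition = rep(c("Nx", "Hx"), each = 9),
    mean = c(49.9, 0.177, 28, 16, 24, 4.4, 2.9, 65, 26,
             53.4, 0.178, 28, 18, 23, 5.1, 3.8, 72, 38),
    sd = c(1.2, 0.016, 9, 9, 11, 2.0, 1.5, 9, 3,
           2.8, 0.015, 7, 8, 9, 1.4, 1.5, 11, 6)
  )
}

#' Synthetic cohort specification
#'
#' Settings of the in-silico rat cohort generator. `cv` is the
#' between-animal dispersion scale: it sets the lognormal coefficient of
#' variation of the calibration-type parameters and scales the
#' group-anchored record draw (at `cv = 0` every same-condition animal is
#' identical).
#'
#' @param n_Nx,n_Hx Group sizes.
#' @param sex_ratio_Nx,sex_ratio_Hx Fraction of females per group.
#' @param seed RNG seed; all generator randomness flows through it.
#' @param cv Between-animal parameter coefficient of variation.
#' @param pressure_sd,volume_sd Additive measurement-noise SDs (mmHg, uL).
#' @param p_neg_edp Probability of the negative-EDP calibration artifact.
#' @param p_iso_spike Probability of an isovolumic volume-spike artifact.
#' @param n_beats Beats per recording (protocol selects 20-50).
#' @param jitter_sd SD of the relative beat-period jitter (independent for
#'   the sequential LV and RV acquisitions).
#' @return A `rh_cohort_spec` list.
#' @export
cohort_spec <- function(n_Nx = 7, n_Hx = 12, sex_ratio_Nx = 2 / 7,
                        sex_ratio_Hx = 5 / 12, seed = 1, cv = 0.10,
                        pressure_sd = 1.0, volume_sd = 1.5,
                        p_neg_edp = 0.2, p_iso_spike = 0.3,
                        n_beats = 30, jitter_sd = 0.02) {
  stopifnot(n_Nx >= 1, n_Hx >= 1, cv >= 0,
            p_neg_edp >= 0, p_neg_edp <= 1,
            p_iso_spike >= 0, p_iso_spike <= 1,
            n_beats >= 1, jitter_sd >= 0)
  structure(as.list(environment()), class = "rh_cohort_spec")
}

#' Sample an in-silico cohort
#'
#' Draws per-animal records around the group-average hemodynamics (SDs
#' scaled by `cv / 0.1`), builds each animal's nominal parameter set,
#' applies lognormal between-animal jitter (CV = `cv`) to the
#' calibration-type parameters, and applies the hyperoxia cellular
#' modifiers to the Hx animals. True parameters are retained as ground
#' truth. Hyperoxic pulmonary afterload elevation arises through the
#' record-driven nominal build (higher RV end-systolic pressures imply
#' higher nominal pulmonary resistance).
#'
#' @param spec A [cohort_spec()].
#' @param build_params Also build the per-animal true parameter sets
#'   (disable for record-level checks on large cohorts).
#' @return Tibble: id, condition, sex, record (list), params (list of true
#'   `rh_params`).
#' @export
sample_cohort <- function(spec, build_params = TRUE) {
  stopifnot(inherits(spec, "rh_cohort_spec"))
  set.seed(spec$seed)
  gt <- group_table()
  draw_record <- function(cond, sex, id) {
    g <- gt[gt$condition == cond, ]
    vals <- rnorm(nrow(g), g$mean, g$sd * spec$cv / 0.1)
    vals <- pmax(vals, 0.3 * g$mean)  # keep fields physiological
    rec <- as.list(setNames(vals, g$field))
    c(list(id = id, condition = cond, sex = sex), rec)
  }
  plan <- dplyr::bind_rows(
    tibble(condition = "Nx", i = seq_len(spec$n_Nx),
           sex = ifelse(seq_len(spec$n_Nx) <=
                          round(spec$sex_ratio_Nx * spec$n_Nx), "F", "M")),
    tibble(condition = "Hx", i = seq_len(spec$n_Hx),
           sex = ifelse(seq_len(spec$n_Hx) <=
                          round(spec$sex_ratio_Hx * spec$n_Hx), "F", "M"))
  )
  plan$id <- sprintf("%s%02d", tolower(plan$condition), plan$i)
  plan$record <- purrr::map(seq_len(nrow(plan)), function(k)
    draw_record(plan$condition[k], plan$sex[k], plan$id[k]))
  plan$params <- if (!build_params) vector("list", nrow(plan)) else
    purrr::map(seq_len(nrow(plan)), function(k) {
    p <- nominal_parameters(plan$record[[k]])
    if (spec$cv > 0) {
      jit <- exp(rnorm(length(theta_opt_default()), 0, spec$cv))
      p <- modify_params(p, setNames(
        as.numeric(p[theta_opt_default()]) * jit, theta_opt_default()))
      # keep the timing fractions inside their physiological boxes
      p <- modify_params(p, c(
        k_TS = min(max(p[["k_TS"]], 0.002), 0.099),
        k_TR = min(max(p[["k_TR"]], 0.30), 0.50)))
    } else {
      rnorm(length(theta_opt_default()))  # keep the RNG stream aligned
    }
    if (plan$condition[k] == "Hx") p <- apply_hyperoxia_modifiers(p)
    p
  })
  plan[c("id", "condition", "sex", "record", "params")]
}

# map a trace affinely so its endpoints match target extrema
affine_anchor <- function(x, lo_from, hi_from, lo_to, hi_to) {
  if (abs(hi_from - lo_from) < 1e-12) return(x + (lo_to - lo_from))
  lo_to + (x - lo_from) * (hi_to - lo_to) / (hi_from - lo_from)
}

#' Synthesize catheter-like beat recordings for one animal
#'
#' Replicates the animal's steady-state cycle into a train of beats with
#' independent period jitter for the LV and RV recordings (sequential
#' acquisition), additive Gaussian pressure and volume noise, and, with the
#' configured probabilities, a negative-EDP offset artifact and an
#' isovolumic volume-spike artifact. With `anchor = TRUE` the traces are
#' first mapped affinely so their endpoint octet matches the animal's
#' record (catheter emulation); with `anchor = FALSE` the pure model output
#' is replicated (parameter-recovery studies).
#'
#' @param p True `rh_params` for the animal.
#' @param spec A [cohort_spec()] (noise/artifact settings).
#' @param record The animal record (required when `anchor = TRUE`).
#' @param anchor Anchor traces to the record's octet.
#' @param cycle Optional precomputed steady-state cycle.
#' @return List: `lv`, `rv` raw beat tibbles (`t`, `P`, `V`, `beat`),
#'   `truth` (the noise-free cycle), `artifacts` applied.
#' @export
synthesize_recordings <- function(p, spec, record = NULL, anchor = TRUE,
                                  cycle = NULL) {
  cyc <- cycle %||% run_to_steady_state(p)
  T <- attr(cyc, "period")
  make_side <- function(P, V, rec_octet = NULL) {
    if (!is.null(rec_octet)) {
      # reference points follow the endpoint convention: minimum pressure
      # over the near-EDV band, maximum over the near-ESV band
      svb <- max(V) - min(V)
      edp_ref <- min(P[V >= max(V) - 0.02 * svb])
      esp_ref <- max(P[V <= min(V) + 0.02 * svb])
      P <- affine_anchor(P, edp_ref, esp_ref,
                         rec_octet[["EDP"]], rec_octet[["ESP"]])
      V <- affine_anchor(V, min(V), max(V),
                         rec_octet[["ESV"]], rec_octet[["EDV"]])
    }
    neg_edp <- runif(1) < spec$p_neg_edp
    iso_spike <- runif(1) < spec$p_iso_spike
    phase <- cyc$t / T
    beats <- purrr::map_dfr(seq_len(spec$n_beats), function(b) {
      Tb <- T * (1 + rnorm(1, 0, spec$jitter_sd))
      tibble(t = phase * Tb, P = P, V = V, beat = b)
    })
    # stack beats in time
    offs <- c(0, cumsum(tapply(beats$t, beats$beat, max) +
                          stats::median(diff(cyc$t))))
    beats$t <- beats$t + offs[beats$beat]
    beats$P <- beats$P + rnorm(nrow(beats), 0, spec$pressure_sd)
    beats$V <- beats$V + rnorm(nrow(beats), 0, spec$volume_sd)
    if (neg_edp) {
      edp <- P[which.max(V)]
      beats$P <- beats$P - (edp + 0.5 + abs(rnorm(1, 1, 0.3)))
    }
    if (iso_spike) {
      # volume bump early in contraction of every beat
      ph <- (beats$t - offs[beats$beat]) / T
      bump <- 3 * spec$volume_sd * exp(-((ph - 0.06) / 0.025)^2)
      beats$V <- beats$V + bump
    }
    list(beats = beats, artifacts = c(neg_edp = neg_edp,
                                      iso_spike = iso_spike))
  }
  oct_lv <- oct_rv <- NULL
  if (anchor) {
    if (is.null(record)) abort("anchoring requires the animal record")
    record <- as.list(record)
    oct_lv <- list(EDV = record$ESV_LV + record$SV, ESV = record$ESV_LV,
                   EDP = record$EDP_LV, ESP = record$ESP_LV)
    oct_rv <- list(EDV = record$ESV_RV + record$SV, ESV = record$ESV_RV,
                   EDP = record$EDP_RV, ESP = record$ESP_RV)
  }
  lv <- make_side(cyc$P_LV, cyc$V_LV, oct_lv)
  rv <- make_side(cyc$P_RV, cyc$V_RV, oct_rv)
  list(lv = lv$beats, rv = rv$beats, truth = cyc,
       artifacts = list(lv = lv$artifacts, rv = rv$artifacts))
}

#' Parameter-recovery study on a synthetic cohort
#'
#' Runs the full pipeline (recording synthesis, preprocessing, multistart
#' calibration) for each synthetic animal and reports per-parameter
#' relative bias and RMSE of the recovered values against the generating
#' truth.
#'
#' @param spec A [cohort_spec()].
#' @param n_starts,maxiter Calibration settings (reduced defaults keep the
#'   study tractable).
#' @param theta Calibrated parameter names.
#' @param animals Optional subset of animal indices to process.
#' @return List: `per_animal` (tibble id, parameter, truth, estimate,
#'   rel_error), `summary` (per-parameter bias/RMSE), `failures`.
#' @export
recovery_study <- function(spec, n_starts = 2, maxiter = 25,
                           theta = theta_opt_default(), animals = NULL) {
  cohort <- sample_cohort(spec)
  idx <- animals %||% seq_len(nrow(cohort))
  failures <- character()
  per <- purrr::map_dfr(idx, function(k) {
    p_true <- cohort$params[[k]]
    res <- tryCatch({
      recs <- synthesize_recordings(p_true, spec,
                                    record = cohort$record[[k]],
                                    anchor = FALSE)
      prep <- prepare_animal(recs$lv, recs$rv)
      base <- nominal_parameters(cohort$record[[k]])
      if (cohort$condition[k] == "Hx") base <- apply_hyperoxia_modifiers(base)
      fit <- multistart_calibrate(prep, base, theta = theta,
                                  n_starts = n_starts, maxiter = maxiter,
                                  seed = spec$seed + k)
      tibble(id = cohort$id[k], parameter = theta,
             truth = as.numeric(p_true[theta]),
             estimate = unname(fit$theta[theta]))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", cohort$id[k],
                                       conditionMessage(e)))
      NULL
    })
    res
  })
  per$rel_error <- per$estimate / per$truth - 1
  summary <- per |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(bias = mean(.data$rel_error),
                     rmse = sqrt(mean(.data$rel_error^2)),
                     median_abs = median(abs(.data$rel_error)),
                     .groups = "drop")
  list(per_animal = per, summary = summary, failures = failures)
}
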