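# shared fixtures, built lazily and memoized across test files
.fx <- new.env()

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

group_avg_record <- function(cond = "Nx") {
  gt <- ratheart:::group_table()
  g <- gt[gt$condition == cond, ]
  c(list(id = paste0(tolower(cond), "_avg"), condition = cond, sex = "M"),
    as.list(stats::setNames(g$mean, g$field)))
}

fx_params <- function(cond = "Nx") {
  memo(paste0("params_", cond), {
    p <- nominal_parameters(group_avg_record(cond))
    if (cond == "Hx") p <- apply_hyperoxia_modifiers(p)
    p
  })
}

fx_cycle <- function(cond = "Nx") {
  memo(paste0("cycle_", cond),
       suppressWarnings(run_to_steady_state(fx_params(cond))))
}

fx_fpca <- function(cond = "Nx") {
  memo(paste0("fpca_", cond), simulate_force_pca(fx_params(cond)))
}

fx_sens <- function(cond = "Nx") {
  memo(paste0("sens_", cond), local_sensitivity(fx_params(cond)))
}

# noise-free single-animal recovery (shared by the calibration tests and
# the acceptance property block)
fx_recovery <- function() {
  memo("recovery", {
    spec <- cohort_spec(n_Nx = 1, n_Hx = 1, seed = 3, cv = 0.05,
                        pressure_sd = 0, volume_sd = 0, p_neg_edp = 0,
                        p_iso_spike = 0, jitter_sd = 0)
    co <- sample_cohort(spec)
    p_true <- co$params[[1]]
    recs <- suppressWarnings(
      synthesize_recordings(p_true, spec, record = co$record[[1]],
                            anchor = FALSE))
    prep <- prepare_animal(recs$lv, recs$rv)
    base <- nominal_parameters(co$record[[1]])
    fit <- suppressWarnings(
      multistart_calibrate(prep, base, n_starts = 2, maxiter = 40,
                           seed = 5))
    list(truth = p_true, fit = fit, prep = prep, base = base)
  })
}
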