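#' Average selected beats into one representative cycle
#'
#' Beats are time-normalized to unit phase and averaged pointwise, which
#' tolerates beat-to-beat period jitter. Fewer than 20 beats triggers a
#' warning (the protocol selects 20-50); zero beats is an error.
#'
#' @param beats Tibble with columns `t` (s), `P` (mmHg), `V` (uL), `beat`
#'   (beat identifier).
#' @param n_phase Phase grid size used for averaging.
#' @return Tibble (`phase`, `t`, `P`, `V`) with attribute `period` (mean
#'   beat duration, s) and `n_beats`.
#' @export
average_beats <- function(beats, n_phase = 200) {
  ids <- unique(beats$beat)
  if (!length(ids)) abort("no beats to average")
  if (length(ids) < 20)
    warn(sprintf("only %d beats selected (protocol uses 20-50)", length(ids)))
  phase <- (seq_len(n_phase) - 1) / n_phase
  acc_P <- acc_V <- matrix(NA_real_, length(ids), n_phase)
  periods <- numeric(length(ids))
  for (i in seq_along(ids)) {
    b <- beats[beats$beat == ids[i], ]
    dt <- stats::median(diff(b$t))
    periods[i] <- max(b$t) - min(b$t) + dt
    ph <- (b$t - min(b$t)) / periods[i]
    acc_P[i, ] <- stats::approx(ph, b$P, xout = phase, rule = 2)$y
    acc_V[i, ] <- stats::approx(ph, b$V, xout = phase, rule = 2)$y
  }
  T_mean <- mean(periods)
  out <- tibble(phase = phase, t = phase * T_mean,
                P = colMeans(acc_P), V = colMeans(acc_V))
  attr(out, "period") <- T_mean
  attr(out, "n_beats") <- length(ids)
  out
}

#' Harmonize LV and RV timing and volumes
#'
#' Sequential (asynchronous) catheter recordings yield different cycle
#' durations and stroke volumes for the two ventricles. The common period
#' is the mean of the two; the common stroke volume is the LV stroke volume
#' (the conductance measurement is more reliable for LV geometry); the RV
#' trace keeps its measured ESV and is rescaled affinely so
#' `RV EDV = RV ESV + SV`.
#'
#' @param lv,rv Averaged single-cycle traces from [average_beats()].
#' @return List: `T_common` (s), `SV_common` (uL), `lv`, `rv` (both on the
#'   common period; only the RV volume trace is rescaled).
#' @export
harmonize_timing_volumes <- function(lv, rv) {
  T_common <- mean(c(attr(lv, "period"), attr(rv, "period")))
  SV_common <- max(lv$V) - min(lv$V)
  esv_rv <- min(rv$V)
  span <- max(rv$V) - min(rv$V)
  rv$V <- esv_rv + (rv$V - esv_rv) * SV_common / span
  lv$t <- lv$phase * T_common
  rv$t <- rv$phase * T_common
  attr(lv, "period") <- attr(rv, "period") <- T_common
  list(T_common = T_common, SV_common = SV_common, lv = lv, rv = rv)
}

#' Group-reference end-diastolic pressure
#'
#' Mean measured EDP of the animals in the same condition-and-sex group
#' whose recorded EDP is nonnegative; used to correct calibration errors
#' that produced negative EDPs.
#'
#' @param records Data frame of animal records (columns `condition`, `sex`,
#'   and the EDP field named by `field`).
#' @param condition,sex Group selectors.
#' @param field `"EDP_LV"` or `"EDP_RV"`.
#' @return Scalar reference EDP (mmHg).
#' @export
group_reference_edp <- function(records, condition, sex, field = "EDP_RV") {
  grp <- records[records$condition == condition & records$sex == sex, ]
  ok <- grp[[field]][grp[[field]] >= 0]
  if (!length(ok))
    abort("no valid reference animals in the condition-and-sex group")
  mean(ok)
}

#' Correct a negative end-diastolic pressure
#'
#' If the trace's EDP (pressure at maximal volume) is negative, the whole
#' pressure curve is shifted upward so EDP equals the group reference;
#' otherwise the trace is returned unchanged. A constant shift preserves
#' pulse pressure exactly.
#'
#' @param trace Single-cycle tibble with `P` and `V`.
#' @param reference_edp Group reference EDP (mmHg).
#' @return The (possibly shifted) trace; attribute `edp_shift` records the
#'   applied offset.
#' @export
correct_edp_offset <- function(trace, reference_edp) {
  edp <- trace$P[which.max(trace$V)]
  shift <- 0
  if (edp < 0) {
    shift <- reference_edp - edp
    trace$P <- trace$P + shift
  }
  attr(trace, "edp_shift") <- shift
  trace
}

#' Enforce isovolumetric contraction and relaxation
#'
#' Catheter artifacts during the isovolumic phases are not physiological:
#' within a window of 15% of stroke volume around end diastole the volume
#' is clamped to EDV (contraction), and around end systole to ESV
#' (relaxation). Ejection and filling segments are untouched, so stroke
#' volume is preserved exactly.
#'
#' @param cycle Single-cycle tibble with `P` and `V`.
#' @param frac Fraction of stroke volume defining the plateau-flattening
#'   band around each volume extreme.
#' @return Corrected cycle.
#' @export
enforce_isovolumic <- function(cycle, frac = 0.02) {
  v <- cycle$V
  n <- length(v)
  if (max(v) == min(v)) abort("phase landmarks not found (flat volume trace)")
  # circular running median: exact on monotone and plateau segments, so
  # ejection and filling are untouched while impulsive catheter artifacts
  # (spikes that depart and return) are removed
  k <- max(5L, 2L * floor(n / 12) + 1L)
  pad <- (k - 1L) / 2L
  vv <- c(v[(n - pad + 1L):n], v, v[1:pad])
  v <- stats::runmed(vv, k, endrule = "keep")[pad + seq_len(n)]
  # flatten the plateaus around the extremes to square the corners
  sv <- max(v) - min(v)
  thr <- frac * sv
  flatten <- function(i0, sgn) {
    inband <- sgn * (v[i0] - v) < thr
    idx <- i0
    i <- i0
    repeat {
      i <- if (i == n) 1L else i + 1L
      if (!inband[i] || i == i0) break
      idx <- c(idx, i)
    }
    i <- i0
    repeat {
      i <- if (i == 1L) n else i - 1L
      if (!inband[i] || i == i0) break
      idx <- c(idx, i)
    }
    v[idx] <<- stats::median(v[idx])
  }
  flatten(which.max(v), +1)
  flatten(which.min(v), -1)
  cycle$V <- v
  cycle
}

#' Prepare one animal's recordings for calibration
#'
#' Runs the full correction chain in the documented order: beat averaging,
#' LV/RV timing and volume harmonization, negative-EDP correction,
#' isovolumic enforcement, and resampling to the common 50-point grid.
#'
#' @param lv_beats,rv_beats Raw beat tibbles (`t`, `P`, `V`, `beat`).
#' @param ref_edp Named reference EDPs `c(LV = , RV = )` for the animal's
#'   condition-and-sex group (used only when a measured EDP is negative).
#' @param n Output grid size.
#' @return An `rh_prepared` list: `T` (s), `SV` (uL), `lv`, `rv` (tibbles
#'   `t`, `P`, `V` on the half-open `[0, T)` grid), `octet` (named vector
#'   EDV/ESV/EDP/ESP for both ventricles), and `corrections`.
#' @export
prepare_animal <- function(lv_beats, rv_beats, ref_edp = c(LV = 4, RV = 3),
                           n = 50) {
  lv <- average_beats(lv_beats)
  rv <- average_beats(rv_beats)
  h <- harmonize_timing_volumes(lv, rv)
  lv <- correct_edp_offset(h$lv, ref_edp[["LV"]])
  rv <- correct_edp_offset(h$rv, ref_edp[["RV"]])
  shifts <- c(LV = attr(lv, "edp_shift"), RV = attr(rv, "edp_shift"))
  lv <- enforce_isovolumic(lv)
  rv <- enforce_isovolumic(rv)
  resample <- function(tr) {
    grid <- h$T_common * (seq_len(n) - 1) / n
    tibble(t = grid,
           P = stats::approx(tr$t, tr$P, xout = grid, rule = 2)$y,
           V = stats::approx(tr$t, tr$V, xout = grid, rule = 2)$y)
  }
  lv50 <- resample(lv)
  rv50 <- resample(rv)
  octet <- cycle_endpoints(list(V_LV = lv50$V, V_RV = rv50$V,
                                P_LV = lv50$P, P_RV = rv50$P))
  structure(
    list(T = h$T_common, SV = h$SV_common, lv = lv50, rv = rv50,
         octet = octet, corrections = list(edp_shifts = shifts)),
    class = "rh_prepared"
  )
}

#' @export
print.rh_prepared <- function(x, ...) {
  cat(sprintf("<rh_prepared> T = %.4f s, SV = %.1f uL\n", x$T, x$SV))
  print(round(x$octet, 2))
  invisible(x)
}
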