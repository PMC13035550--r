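#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames
NULL

# Fixed model constants. These are structural choices of the model form
# (documented in the methods vignette), not free parameters: the troponin
# cooperativity exponent, the strain-energy stress scale that saturates the
# stiffness -> force map, the thick-filament overlap knots, and the reference
# metabolite pool used to normalize metabolite-dependent rate factors so that
# the nominal metabolite state reproduces the nominal rate constants exactly.
rh_constants <- function() {
  list(
    n_H      = 3.60,    # troponin-C Ca2+ cooperativity (unitless)
    sigma_B  = 1232.5,     # kPa; Boltzmann scale of stroke-energy assisted exit
    ov_knots = c(La0 = 1.50, Lp1 = 1.95, Lp2 = 2.40, Ld0 = 3.30),  # um
    ATP_nom  = 8.0,     # mM cytosolic reference pool
    ADP_nom  = 0.05,    # mM
    Pi_nom   = 1.0,     # mM
    KT_nom   = 0.5,     # mM
    KD_nom   = 0.194,   # mM
    Ls_ed    = 1.97,    # um; target end-diastolic sarcomere length used to
                        # anchor the midwall reference areas
    vun_weights = c(SA = 0.21, SV = 0.60, PA = 0.08, PV = 0.11),
    kPa_per_mmHg = 0.133322
  )
}

# registry: 54 named parameters, grouped in blocks
rh_registry_blocks <- function() {
  list(
    calcium    = c("ca_dia", "ca_amp", "k_TS", "k_TR", "T_cycle"),
    crossbridge = c("k_a", "k_d", "k_1", "k_m1", "k_2", "k_3", "k_Pi",
                    "k_ADP", "k_ATP", "k_SR", "k_mSR", "k_on",
                    "k_off", "k_off_RV", "K_D", "K_T",
                    "k_stiff1", "k_stiff1_RV", "k_stiff2", "k_stiff2_RV",
                    "dr", "ATP", "ADP", "Pi"),
    myofiber   = c("k_passive", "k_passive_RV", "gamma", "L_sc0", "eta",
                   "K_SE", "L_s_ref"),
    triseg     = c("Am_ref_LV", "Am_ref_SEP", "Am_ref_RV",
                   "Vw_LV", "Vw_SEP", "Vw_RV"),
    circulation = c("C_SA", "C_SV", "C_PA", "C_PV",
                    "R_SA", "R_PA", "R_m", "R_a", "R_t", "R_p",
                    "V_total", "v_un_frac")
  )
}

#' Parameter registry
#'
#' The full model carries 54 named parameters partitioned into calcium,
#' crossbridge, myofiber, TriSeg, and circulation blocks. This returns the
#' registry as a tibble (name, block, units).
#'
#' @return A tibble with one row per parameter.
#' @export
param_registry <- function() {
  blocks <- rh_registry_blocks()
  units <- c(
    ca_dia = "uM", ca_amp = "uM", k_TS = "1", k_TR = "1", T_cycle = "s",
    k_a = "1/s", k_d = "1/s", k_1 = "1/s", k_m1 = "1/s", k_2 = "1/s",
    k_3 = "1/s", k_Pi = "1/s", k_ADP = "1/s", k_ATP = "1/s",
    k_SR = "1/s", k_mSR = "1/s", k_on = "1/(uM s)",
    k_off = "1/s", k_off_RV = "1/s", K_D = "mM", K_T = "mM",
    k_stiff1 = "kPa/um", k_stiff1_RV = "kPa/um",
    k_stiff2 = "kPa/um", k_stiff2_RV = "kPa/um", dr = "um",
    ATP = "mM", ADP = "mM", Pi = "mM",
    k_passive = "kPa/um^gamma", k_passive_RV = "kPa/um^gamma",
    gamma = "1", L_sc0 = "um", eta = "kPa s/um", K_SE = "kPa/um",
    L_s_ref = "um",
    Am_ref_LV = "cm2", Am_ref_SEP = "cm2", Am_ref_RV = "cm2",
    Vw_LV = "mL", Vw_SEP = "mL", Vw_RV = "mL",
    C_SA = "mL/mmHg", C_SV = "mL/mmHg", C_PA = "mL/mmHg", C_PV = "mL/mmHg",
    R_SA = "mmHg s/mL", R_PA = "mmHg s/mL", R_m = "mmHg s/mL",
    R_a = "mmHg s/mL", R_t = "mmHg s/mL", R_p = "mmHg s/mL",
    V_total = "mL", v_un_frac = "1"
  )
  nm <- unlist(blocks, use.names = FALSE)
  tibble(
    name  = nm,
    block = rep(names(blocks), lengths(blocks)),
    units = unname(units[nm])
  )
}

#' Wall-weight-to-bodyweight ratios
#'
#' Group-average wall-weight-to-bodyweight ratios (mg wall per g bodyweight)
#' for the combined LV+septum and the RV free wall, by condition. The LV
#' takes 2/3 and the septum 1/3 of the combined LV+SEP wall weight.
#'
#' @param condition `"Nx"` (normoxia) or `"Hx"` (hyperoxia).
#' @return Named list with `WR_LVSEP` and `WR_RV` (mg/g).
#' @export
wall_weight_ratios <- function(condition = c("Nx", "Hx")) {
  condition <- match.arg(condition)
  if (condition == "Nx") list(WR_LVSEP = 3.8, WR_RV = 0.86)
  else                   list(WR_LVSEP = 3.2, WR_RV = 1.00)
}

# nominal cellular-scale values (pediatric rat). k_a already carries the
# 20% pediatric reduction from the adult attachment rate of 350 /s.
rh_cell_defaults <- function() {
  cc <- rh_constants()
  c(
    ca_dia = 0.1610, ca_amp = 2.0, k_TS = 0.08, k_TR = 0.32,
    k_a = 0.8 * 350, k_d = 150, k_1 = 250, k_m1 = 10, k_2 = 400, k_3 = 150,
    k_Pi = 500, k_ADP = 200, k_ATP = 300, k_SR = 10, k_mSR = 50,
    k_on = 30, k_off = 400, k_off_RV = 400,
    K_D = cc$KD_nom, K_T = cc$KT_nom,
    k_stiff1 = 3750, k_stiff1_RV = 3750,
    k_stiff2 = 1e5, k_stiff2_RV = 1e5, dr = 0.01,
    ATP = cc$ATP_nom, ADP = cc$ADP_nom, Pi = cc$Pi_nom,
    k_passive = 75, k_passive_RV = 75, gamma = 3.5, L_sc0 = 1.75,
    eta = 0.025, K_SE = 500, L_s_ref = 2.2
  )
}

new_rh_params <- function(values, condition = "Nx",
                          record_id = NA_character_, edv = NULL) {
  reg <- param_registry()
  stopifnot(setequal(names(values), reg$name))
  structure(
    values[reg$name],
    class = "rh_params",
    condition = condition,
    record_id = record_id,
    edv = edv
  )
}

# copy of a parameter set with some entries replaced, metadata preserved
modify_params <- function(p, replacements) {
  v <- unclass(p)
  v[names(replacements)] <- replacements
  new_rh_params(v, condition = attr(p, "condition"),
                record_id = attr(p, "record_id"), edv = attr(p, "edv"))
}

#' @export
print.rh_params <- function(x, ...) {
  cat("<rh_params> 54 parameters, condition =", attr(x, "condition"), "\n")
  print(tidy(x), n = 12)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set
#'
#' @param x An `rh_params` object.
#' @param ... Unused.
#' @return Tibble with name, block, units, value.
#' @export
tidy.rh_params <- function(x, ...) {
  reg <- param_registry()
  reg$value <- as.numeric(x)[match(reg$name, names(x))]
  reg
}

#' Nominal model parameterization from an animal record
#'
#' Builds the 54-parameter nominal set for one animal: total blood volume at
#' 0.06 mL per g bodyweight, ventricular wall volumes from the condition's
#' wall-weight-to-bodyweight ratios (LV 2/3, septum 1/3 of the combined
#' LV+SEP weight; cardiac wall density 1.055 g/mL), midwall reference areas
#' from measured end-diastolic volumes under spherical midwall geometry, a
#' 20% pediatric reduction of the actin-myosin attachment rate, and
#' record-driven circulation parameters (resistances from mean-pressure/flow
#' targets, compliances from pulse-pressure targets).
#'
#' @param record A one-row data frame / list with fields `id`, `condition`
#'   ("Nx"/"Hx"), `sex`, `BW` (g), `T` (s), `SV` (uL), `ESV_LV`, `ESV_RV`
#'   (uL), `EDP_LV`, `EDP_RV`, `ESP_LV`, `ESP_RV` (mmHg).
#' @param wr Wall-weight ratios; default from [wall_weight_ratios()] for the
#'   record's condition. Note the nominal build always uses the record's
#'   measured hemodynamics; `wr` only sets wall masses.
#' @return An `rh_params` object (condition attribute `"Nx"`: hyperoxia
#'   cellular modifiers are applied separately by
#'   [apply_hyperoxia_modifiers()]).
#' @export
nominal_parameters <- function(record, wr = NULL) {
  record <- as.list(record)
  need <- c("condition", "BW", "T", "SV", "ESV_LV", "ESV_RV",
            "EDP_LV", "EDP_RV", "ESP_LV", "ESP_RV")
  miss <- setdiff(need, names(record))
  if (length(miss))
    abort(paste("incomplete animal record; missing:",
                paste(miss, collapse = ", ")))
  for (f in setdiff(need, "condition"))
    if (!is.finite(record[[f]]) || record[[f]] <= 0)
      abort(paste("invalid animal record field:", f))
  wr <- wr %||% wall_weight_ratios(record$condition)

  v <- rh_cell_defaults()
  v["T_cycle"] <- record$T

  # wall volumes from wall-weight ratios (mg/g), density 1.055 g/mL
  W_lvsep <- wr$WR_LVSEP * record$BW / 1000  # g
  W_rv    <- wr$WR_RV    * record$BW / 1000
  v["Vw_LV"]  <- (2 / 3) * W_lvsep / 1.055
  v["Vw_SEP"] <- (1 / 3) * W_lvsep / 1.055
  v["Vw_RV"]  <- W_rv / 1.055

  # Midwall reference areas from measured EDV under spherical-cap midwall
  # geometry. The cap equilibrium at uniform wall stress is independent of
  # the reference areas, so the balanced end-diastolic geometry can be
  # solved first; Am_ref is then anchored so the end-diastolic wall
  # sarcomere length equals the target Ls_ed (with the wall-thickness
  # curvature corrections evaluated at that geometry).
  cc <- rh_constants()
  EDV_LV <- (record$ESV_LV + record$SV) / 1000  # mL
  EDV_RV <- (record$ESV_RV + record$SV) / 1000
  v["Am_ref_LV"] <- v["Am_ref_SEP"] <- v["Am_ref_RV"] <- 1
  p_tmp <- new_rh_params(c(v,
    C_SA = 1, C_SV = 1, C_PA = 1, C_PV = 1, R_SA = 1, R_PA = 1,
    R_m = 1, R_a = 1, R_t = 1, R_p = 1, V_total = 1, v_un_frac = 0.5
  )[param_registry()$name])
  # Anchor each wall's end-diastolic strain so the passive curve carries the
  # measured end-diastolic pressures: cap pressure is linear in wall stress,
  # so the per-unit-stress tensions give the per-wall stress targets (septum
  # anchored with the LV, same tissue). The balanced geometry depends on the
  # non-uniform stress pattern, so anchor by short fixed-point iteration.
  sig_ed <- c(1, 1, 1)
  guess <- NULL
  for (it in 1:4) {
    geom <- solve_triseg_geometry(EDV_LV, EDV_RV, sig_ed, p_tmp,
                                  guess = guess)
    guess <- c(geom$x, geom$y_m)
    kP <- 2 * abs(geom$Tx) / (geom$y_m * sig_ed)  # kPa cavity / kPa stress
    # The RV is anchored at the model's characteristic flat end-diastolic
    # pressure (~1.4 mmHg) rather than the measured RV EDP: the thin RV
    # wall otherwise has to carry an implausibly large diastolic stress
    # share, which suppresses the systolic septal dynamics.
    edp_rv_anchor <- min(record$EDP_RV, 1.4)
    sig_ed <- c(record$EDP_LV, record$EDP_LV, edp_rv_anchor) *
      cc$kPa_per_mmHg / kP
    sig_ed[2] <- sig_ed[1]
  }
  zc <- numeric(3)  # per-wall z strain correction
  for (w in 1:3) {
    z <- 3 * geom$Cm[w] * as.numeric(v[c("Vw_LV", "Vw_SEP", "Vw_RV")])[w] /
      (2 * geom$Am[w])
    zc[w] <- z^2 / 12 + 0.019 * z^4
  }
  ls_ed <- v[["L_sc0"]] + (sig_ed / v[["k_passive"]])^(1 / v[["gamma"]])
  ls_ed <- pmin(pmax(ls_ed, 1.85), 2.15)
  amref <- geom$Am * exp(-2 * (log(ls_ed / v[["L_s_ref"]]) + zc))
  v["Am_ref_LV"]  <- amref[1]
  v["Am_ref_SEP"] <- amref[2]
  v["Am_ref_RV"]  <- amref[3]

  # circulation: record-driven targets (mean systemic pressure ~ 0.75 ESP_LV,
  # mean PA pressure ~ 0.88 ESP_RV, venous/pulmonary-venous filling targets)
  SV_mL <- record$SV / 1000
  CO    <- SV_mL / record$T
  MAP   <- 0.75 * record$ESP_LV
  mPAPn <- 0.88 * record$ESP_RV
  P_sv  <- 1.6
  P_pv  <- record$EDP_LV + 1
  v["R_SA"] <- (MAP - P_sv) / CO
  v["R_PA"] <- (mPAPn - P_pv) / CO
  v["C_SA"] <- SV_mL / (0.50 * MAP)
  v["C_SV"] <- 18 * v[["C_SA"]]
  v["C_PA"] <- SV_mL / (0.35 * mPAPn)
  v["C_PV"] <- 8 * v[["C_PA"]]
  v["R_m"] <- 0.3; v["R_t"] <- 0.3; v["R_a"] <- 1.2; v["R_p"] <- 1.2
  v["V_total"] <- 0.06 * record$BW
  # unstressed fraction: what is left of the vascular pool once each
  # compartment holds its target-pressure stressed volume
  stressed <- v[["C_SA"]] * MAP + v[["C_SV"]] * P_sv +
    v[["C_PA"]] * mPAPn + v[["C_PV"]] * P_pv
  mean_heart <- (EDV_LV + EDV_RV + (record$ESV_LV + record$ESV_RV) / 1000) / 2
  v["v_un_frac"] <- (v[["V_total"]] - mean_heart - stressed) /
    v[["V_total"]]

  new_rh_params(v, condition = "Nx",
                record_id = as.character(record$id %||% NA_character_),
                edv = c(LV = EDV_LV, RV = EDV_RV))
}

#' Apply hyperoxia parameter modifiers
#'
#' Applies the hyperoxia-induced cellular changes to a normoxia nominal set:
#' cytosolic ATP -5%, ADP +5%, Pi +5% (text convention) or -5%
#' (`pi_sign = "printed"`); and, for the RV wall only, passive stiffness
#' +100%, troponin Ca2+ off-rate -40%, and both crossbridge stiffness
#' constants +70%. LV and septal entries are untouched.
#'
#' @param p An `rh_params` set with condition `"Nx"`.
#' @param pi_sign `"text"` (+5%) or `"printed"` (-5%).
#' @return Modified `rh_params` with condition `"Hx"`.
#' @export
apply_hyperoxia_modifiers <- function(p, pi_sign = c("text", "printed")) {
  pi_sign <- match.arg(pi_sign)
  stopifnot(inherits(p, "rh_params"))
  if (identical(attr(p, "condition"), "Hx"))
    abort("hyperoxia modifiers already applied (idempotence guard)")
  v <- unclass(p)
  v["ATP"] <- v["ATP"] * 0.95
  v["ADP"] <- v["ADP"] * 1.05
  v["Pi"]  <- v["Pi"] * if (pi_sign == "text") 1.05 else 0.95
  v["k_passive_RV"] <- v["k_passive_RV"] * 2.0
  v["k_off_RV"]     <- v["k_off_RV"] * 0.6
  v["k_stiff1_RV"]  <- v["k_stiff1_RV"] * 1.7
  v["k_stiff2_RV"]  <- v["k_stiff2_RV"] * 1.7
  new_rh_params(v, condition = "Hx", record_id = attr(p, "record_id"),
                edv = attr(p, "edv"))
}

#' Effective crossbridge transition rates
#'
#' Folds the cytosolic metabolite pool into the crossbridge transition
#' rates. The loose-to-strong transition is rate-limited in series by Pi
#' release (`k_Pi`) and the isomerization (`k_1`); its reverse carries the
#' Pi-rebinding pathway and scales with \[Pi\] (exactly zero at \[Pi\] = 0).
#' Exit from the post-ratchet state passes through ADP release (competitively
#' slowed by \[ADP\] via `K_D`) and ATP binding (saturably accelerated by
#' \[ATP\] via `K_T`) in series; factors are normalized so the nominal
#' metabolite pool reproduces the nominal rate constants.
#'
#' @param p An `rh_params` set.
#' @return Named list of effective rates: `f_a`, `g_d`, `f12`, `g21`, `f23`,
#'   `f3m`, `k_on`, `k_off` (length-3, LV/SEP/RV), `k_SR`, `k_mSR`.
#' @export
effective_rates <- function(p) {
  cc <- rh_constants()
  v <- as.numeric(p); names(v) <- names(p)
  # Pi = 0 is admitted so the Pi-rebinding pathway vanishes exactly
  if (v[["ATP"]] <= 0 || v[["ADP"]] <= 0 || v[["Pi"]] < 0)
    abort("metabolite concentrations must be positive")
  f12 <- v[["k_1"]] * v[["k_Pi"]] / (v[["k_1"]] + v[["k_Pi"]])
  g21 <- v[["k_m1"]] * v[["Pi"]] / cc$Pi_nom
  r_adp <- v[["k_ADP"]] * (1 + cc$ADP_nom / cc$KD_nom) /
    (1 + v[["ADP"]] / v[["K_D"]])
  r_atp <- v[["k_ATP"]] * (v[["ATP"]] / (v[["K_T"]] + v[["ATP"]])) /
    (cc$ATP_nom / (cc$KT_nom + cc$ATP_nom))
  tau_nom <- 1 / v[["k_ADP"]] + 1 / v[["k_ATP"]]
  tau     <- 1 / r_adp + 1 / r_atp
  f3m <- v[["k_3"]] * tau_nom / tau
  list(
    f_a = v[["k_a"]], g_d = v[["k_d"]], f12 = f12, g21 = g21,
    f23 = v[["k_2"]], f3m = f3m, k_on = v[["k_on"]],
    k_off = c(LV = v[["k_off"]], SEP = v[["k_off"]], RV = v[["k_off_RV"]]),
    k_SR = v[["k_SR"]], k_mSR = v[["k_mSR"]]
  )
}

# pack the 54-parameter set + model constants into the flat vector the
# compiled core indexes (order mirrors src/model.c)
pack_sim_params <- function(p) {
  cc <- rh_constants()
  r <- effective_rates(p)
  v <- as.numeric(p); names(v) <- names(p)
  V_un <- v[["v_un_frac"]] * v[["V_total"]] * cc$vun_weights
  out <- c(
    v[["T_cycle"]], v[["ca_dia"]], v[["ca_amp"]], v[["k_TS"]], v[["k_TR"]],
    cc$n_H, r$k_on,
    r$k_off,                                   # 7..9
    r$f_a, r$g_d, r$f12, r$g21, r$f23, r$f3m,  # 10..15
    v[["k_stiff1"]], v[["k_stiff1"]], v[["k_stiff1_RV"]],  # 16..18
    v[["k_stiff2"]], v[["k_stiff2"]], v[["k_stiff2_RV"]],  # 19..21
    v[["dr"]], cc$sigma_B, v[["k_SR"]], v[["k_mSR"]],
    v[["k_passive"]], v[["k_passive"]], v[["k_passive_RV"]],  # 26..28
    v[["gamma"]], v[["L_sc0"]], v[["eta"]], v[["K_SE"]], v[["L_s_ref"]],
    v[["Am_ref_LV"]], v[["Am_ref_SEP"]], v[["Am_ref_RV"]],
    v[["Vw_LV"]], v[["Vw_SEP"]], v[["Vw_RV"]],
    v[["C_SA"]], v[["C_SV"]], v[["C_PA"]], v[["C_PV"]],
    v[["R_SA"]], v[["R_PA"]], v[["R_m"]], v[["R_a"]], v[["R_t"]], v[["R_p"]],
    V_un,                                      # 50..53
    cc$ov_knots                                # 54..57
  )
  unname(out)
}

pack_sarc_params <- function(p, ca_mode = 0, ca_value = 2, ls_wall = 2.2,
                             wall = c("RV", "LV", "SEP")) {
  wall <- match.arg(wall)
  wi <- c(LV = 0, SEP = 1, RV = 2)[[wall]]
  c(pack_sim_params(p), ca_mode, ca_value, ls_wall, wi)
}

#' Serialize / restore a parameter set
#'
#' Round-trip safe JSON serialization with a schema-version field.
#'
#' @param p An `rh_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` the set.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "rh_params"))
  obj <- list(
    schema_version = 1L,
    condition = attr(p, "condition"),
    record_id = attr(p, "record_id"),
    edv = as.list(attr(p, "edv")),
    values = as.list(setNames(as.numeric(p), names(p)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version)) abort("not a parameter-set file")
  edv <- if (length(obj$edv)) unlist(obj$edv) else NULL
  new_rh_params(unlist(obj$values), condition = obj$condition,
                record_id = obj$record_id %||% NA_character_, edv = edv)
}
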