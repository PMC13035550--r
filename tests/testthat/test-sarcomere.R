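test_that("active stress follows the moment formula", {
  p <- ratheart:::modify_params(fx_params("Nx"), c(
    k_stiff1 = 100, k_stiff1_RV = 100, k_stiff2 = 100, k_stiff2_RV = 100,
    dr = 0.01))
  w0 <- wall_state()
  expect_identical(active_stress(w0, 1, p), 0)
  w <- wall_state(p2 = c(0, 0.01, 0), p3 = c(0.2, 0.01, 0))
  expect_equal(active_stress(w, 1, p), 100 * 0.02 + 100 * 0.01 * 0.2)
  p2x <- ratheart:::modify_params(p, c(
    k_stiff1 = 200, k_stiff1_RV = 200, k_stiff2 = 200, k_stiff2_RV = 200))
  expect_equal(active_stress(w, 1, p2x), 2 * active_stress(w, 1, p))
})

test_that("passive stress is a one-sided power law", {
  p <- ratheart:::modify_params(fx_params("Nx"), c(
    k_passive = 10, k_passive_RV = 10, gamma = 2, L_sc0 = 1.51))
  expect_identical(passive_stress(p[["L_sc0"]], p), 0)
  expect_identical(passive_stress(1.2, p), 0)  # below slack: no compression
  expect_equal(passive_stress(2.2, p), 10 * 0.69^2)
})

test_that("hyperoxia doubles RV passive stress at any fixed length", {
  pN <- fx_params("Nx")
  pH <- apply_hyperoxia_modifiers(pN)
  for (ls in c(1.9, 2.0, 2.2, 2.4)) {
    expect_equal(passive_stress(ls, pH, "RV") / passive_stress(ls, pN, "RV"),
                 2, tolerance = 1e-12)
    expect_equal(passive_stress(ls, pH, "LV"), passive_stress(ls, pN, "LV"))
  }
})

test_that("viscous stress is linear and odd in velocity", {
  expect_identical(viscous_stress(0, 1), 0)
  expect_identical(viscous_stress(-0.5, 1), -0.5)
  v <- seq(-3, 3, by = 0.5)
  expect_equal(viscous_stress(-v, 0.7), -viscous_stress(v, 0.7))
})

test_that("myofiber force balance closes identically", {
  p <- fx_params("Nx")
  b <- myofiber_force_balance(2.0, 2.0, 0, 0, p)
  expect_identical(b$dLs_dt, 0)
  # static limit: zero velocity implies sigma_SE = sigma_XB + sigma_pas
  sXB <- 5; spas <- 2
  ls <- 2.0 - (sXB + spas) / p[["K_SE"]]
  b2 <- myofiber_force_balance(2.0, ls, sXB, spas, p)
  expect_equal(b2$dLs_dt, 0, tolerance = 1e-12)
  expect_equal(b2$sigma_SE, sXB + spas)
  p0 <- ratheart:::modify_params(p, c(eta = 0))
  expect_error(myofiber_force_balance(2, 2, 0, 0, p0), "singular")
})

test_that("unloaded series element relaxes exponentially at rate K_SE/eta", {
  # closed-form linear ODE oracle: dL/dt = K_SE (Lw - L) / eta
  p <- ratheart:::modify_params(fx_params("Nx"),
                                c(K_SE = 40, eta = 2, L_sc0 = 3))
  lw <- 2.0
  f <- function(t, y, parms)
    list(myofiber_force_balance(lw, y, 0, 0, p)$dLs_dt)
  tt <- seq(0, 0.5, length.out = 21)
  num <- deSolve::lsoda(1.6, tt, f, NULL, rtol = 1e-11, atol = 1e-12)[, 2]
  exact <- lw + (1.6 - lw) * exp(-p[["K_SE"]] / p[["eta"]] * tt)
  expect_equal(num, exact, tolerance = 1e-6)
})

test_that("crossbridge derivatives vanish in the absorbing resting state", {
  p <- fx_params("Nx")
  w <- wall_state(N_np = 1, U_SR = 0)
  d <- crossbridge_derivatives(w, Ca = 0, overlap = 0.9, p)
  expect_equal(unname(d[c(1, 4, 7, 10)]), rep(0, 4))
})

test_that("with zero attachment the attached pool only decays", {
  p <- ratheart:::modify_params(fx_params("Nx"), c(k_a = 0))
  w <- wall_state(p1 = c(0.2, 0, 0), p2 = c(0.3, 0, 0), p3 = c(0.3, 0, 0),
                  N_np = 0.1, U_SR = 0.1)
  d <- crossbridge_derivatives(w, Ca = 2, overlap = 1, p)
  # total attached fraction strictly decreasing (individual states may
  # exchange internally)
  expect_lt(d[["p1_0"]] + d[["p2_0"]] + d[["p3_0"]], 0)
})

test_that("moment ordering violations are rejected", {
  p <- fx_params("Nx")
  w <- wall_state()
  w[3] <- -0.1
  expect_error(crossbridge_derivatives(w, 1, 0.5, p), "second moments")
})

test_that("kinetics conserve the five-state pool exactly", {
  p <- fx_params("Nx")
  set.seed(42)
  for (i in 1:25) {
    fr <- runif(5)
    fr <- fr / sum(fr)
    w <- wall_state(p1 = c(fr[1], runif(1, -0.01, 0.01), runif(1, 0, 1e-3)),
                    p2 = c(fr[2], runif(1, -0.01, 0.01), runif(1, 0, 1e-3)),
                    p3 = c(fr[3], runif(1, -0.01, 0.01), runif(1, 0, 1e-3)),
                    N_np = fr[4] * 0.9, U_SR = fr[5])
    ca <- runif(1, 0, 3)
    ov <- runif(1)
    d <- crossbridge_derivatives(w, Ca = ca, overlap = ov, p,
                                 v = runif(1, -2, 2))
    # dual route: reassemble the 0th-moment fluxes from the effective
    # rates in R and verify the compiled kinetics match term by term;
    # pairwise fluxes make conservation of the five-state pool exact
    r <- effective_rates(p)
    nH <- ratheart:::rh_constants()$n_H
    U <- 1 - w[["p1_0"]] - w[["p2_0"]] - w[["p3_0"]] - w[["U_SR"]]
    P <- max(U - w[["N_np"]], 0)
    expect_equal(unname(d[["p1_0"]]),
                 r$f_a * ov * P - (r$g_d + r$f12) * w[["p1_0"]] +
                   r$g21 * w[["p2_0"]], tolerance = 1e-12)
    expect_equal(unname(d[["p2_0"]]),
                 r$f12 * w[["p1_0"]] - (r$g21 + r$f23) * w[["p2_0"]],
                 tolerance = 1e-12)
    expect_equal(unname(d[["N_np"]]),
                 -r$k_on * ca^nH * w[["N_np"]] + r$k_off[["RV"]] * P,
                 tolerance = 1e-12)
    expect_equal(unname(d[["U_SR"]]),
                 r$k_SR * P - r$k_mSR * w[["U_SR"]], tolerance = 1e-12)
  }
})

test_that("crossbridge step response matches a fine-step Euler oracle", {
  p <- fx_params("Nx")
  w <- ratheart:::resting_wall_state(p)
  ca <- 2.16
  ov <- thick_filament_overlap(2.2)
  # brute-force explicit Euler, dt = 1e-6 s
  dt <- 1e-6
  w_e <- unname(w)
  pp <- ratheart:::pack_sim_params(p)
  for (i in seq_len(50000)) {
    d <- .Call(ratheart:::C_xb_derivs, w_e, ca, ov, 0, 2L, pp)
    w_e <- w_e + dt * d
  }
  # adaptive integrator on the same kinetics
  f <- function(t, y, parms)
    list(.Call(ratheart:::C_xb_derivs, y, ca, ov, 0, 2L, pp))
  sol <- deSolve::lsoda(unname(w), c(0, 0.05), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, 1 + 7]), w_e[7], tolerance = 1e-4)  # p3_0, 4 digits
  expect_equal(unname(sol[2, -1]), w_e, tolerance = 1e-3)
})

test_that("simulated cycles keep state fractions conserved and bounded", {
  cyc <- fx_cycle("Nx")
  g <- attr(cyc, "state_grid")
  for (wall in 0:2) {
    blk <- g[, 1 + wall * 11 + c(1, 4, 7, 10, 11)]  # p1_0,p2_0,p3_0,Nnp,USR
    U <- 1 - rowSums(g[, 1 + wall * 11 + c(1, 4, 7, 11)])
    expect_true(all(blk >= -1e-8 & blk <= 1 + 1e-8))
    expect_true(all(U >= -1e-8 & U <= 1 + 1e-8))
    total <- rowSums(g[, 1 + wall * 11 + c(1, 4, 7, 11)]) + U
    expect_true(all(abs(total - 1) < 1e-8))
  }
})

test_that("the force balance closes at every output point of a cycle", {
  cyc <- fx_cycle("Nx")
  p <- attr(cyc, "params")
  g <- attr(cyc, "state_grid")
  walls <- c("LV", "SEP", "RV")
  vw    <- as.numeric(p[c("Vw_LV", "Vw_SEP", "Vw_RV")])
  amref <- as.numeric(p[c("Am_ref_LV", "Am_ref_SEP", "Am_ref_RV")])
  for (i in seq(1, nrow(g), by = 7)) {
    st <- g[i, 1 + 1:46]
    d <- assemble_rhs(st, g[i, "time"], p)
    # series-element stress from the geometry states, independently of the
    # balance used inside the integrator
    tri <- .Call(ratheart:::C_triseg, unname(st[37:40]),
                 unname(st[41:42]), c(0, 0, 0), vw, amref, p[["L_s_ref"]])
    lsw <- tri[11:13]
    for (wi in 1:3) {
      ls <- st[[33 + wi]]
      w <- st[(wi - 1) * 11 + 1:11]
      sSE  <- p[["K_SE"]] * (lsw[wi] - ls)
      sXB  <- active_stress(w, thick_filament_overlap(ls), p, walls[wi])
      spas <- passive_stress(ls, p, walls[wi])
      svis <- viscous_stress(d[[33 + wi]], p[["eta"]])
      expect_lt(abs(sSE - sXB - spas - svis), 1e-8 * max(1, abs(sSE)))
    }
  }
})
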