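mirror_params <- function(p = fx_params("Nx")) {
  ratheart:::modify_params(p, c(
    Vw_RV = p[["Vw_LV"]], Am_ref_RV = p[["Am_ref_LV"]],
    Vw_SEP = 0.3 * p[["Vw_LV"]], Am_ref_SEP = 0.4 * p[["Am_ref_LV"]]))
}

test_that("mirror-symmetric ventricles give a flat septum", {
  pm <- mirror_params()
  # with the elastic (strain-dependent) wall stress the flat septum is the
  # unique equilibrium, reached even from a buckled starting shape
  g <- solve_triseg_geometry(0.05, 0.05,
                             ratheart:::diastolic_sigma_fun(pm), pm)
  expect_lt(abs(g$x[2]), 1e-8)
  expect_lt(abs(g$Cm[2]), 1e-7)
  expect_equal(g$P_LV, g$P_RV, tolerance = 1e-6)
  g2 <- solve_triseg_geometry(0.05, 0.05,
                              ratheart:::diastolic_sigma_fun(pm), pm,
                              guess = c(-0.45, -0.14, 0.34, 0.34))
  expect_lt(abs(g2$x[2]), 1e-8)
  # brute-force 2-D oracle: scan (x_SEP, y); solve the free-wall heights
  # from the cap-volume constraints; evaluate the junction tension
  # residuals under the elastic wall-stress closure. The residual norm is
  # minimized at the flat septum.
  vw <- as.numeric(pm[c("Vw_LV", "Vw_SEP", "Vw_RV")])
  amref <- as.numeric(pm[c("Am_ref_LV", "Am_ref_SEP", "Am_ref_RV")])
  vcap <- function(x, y) pi / 6 * x * (x^2 + 3 * y^2)
  sig_fun <- ratheart:::diastolic_sigma_fun(pm)
  tension_norm <- function(xs, y) {
    vl <- 0.05 + 0.5 * vw[1] + 0.5 * vw[2]
    vr <- 0.05 + 0.5 * vw[3] + 0.5 * vw[2]
    x_lv <- stats::uniroot(function(x) vcap(xs, y) - vcap(x, y) - vl,
                           c(-2, -1e-4), tol = 1e-13)$root
    x_rv <- stats::uniroot(function(x) vcap(x, y) - vcap(xs, y) - vr,
                           c(1e-4, 2), tol = 1e-13)$root
    g <- c(x_lv, xs, x_rv, y)
    base <- .Call(ratheart:::C_triseg, g, c(0.05, 0.05), c(0, 0, 0),
                  vw, amref, pm[["L_s_ref"]])
    out <- .Call(ratheart:::C_triseg, g, c(0.05, 0.05),
                 as.double(sig_fun(base[11:13])), vw, amref,
                 pm[["L_s_ref"]])
    sqrt(sum(out[3:4]^2))
  }
  xs_grid <- seq(-0.08, 0.08, length.out = 17)
  norms <- vapply(xs_grid, function(xs) {
    min(vapply(seq(0.9, 1.1, length.out = 9) * g$y_m,
               function(y) tension_norm(xs, y), 0))
  }, 0)
  expect_equal(xs_grid[which.min(norms)], 0, tolerance = 1e-9)
})

test_that("geometric similarity: s^2 areas and s^3 volumes scale x, y by s", {
  p <- fx_params("Nx")
  g1 <- solve_triseg_geometry(0.044, 0.052, c(3, 3, 3), p)
  s <- 1.3
  ps <- ratheart:::modify_params(p, c(
    Am_ref_LV = p[["Am_ref_LV"]] * s^2, Am_ref_SEP = p[["Am_ref_SEP"]] * s^2,
    Am_ref_RV = p[["Am_ref_RV"]] * s^2, Vw_LV = p[["Vw_LV"]] * s^3,
    Vw_SEP = p[["Vw_SEP"]] * s^3, Vw_RV = p[["Vw_RV"]] * s^3))
  g2 <- solve_triseg_geometry(0.044 * s^3, 0.052 * s^3, c(3, 3, 3), ps,
                              guess = c(g1$x * s, g1$y_m * s))
  expect_equal(g2$x, g1$x * s, tolerance = 1e-6)
  expect_equal(g2$y_m, g1$y_m * s, tolerance = 1e-6)
})

test_that("cap-volume identity reconstructs the cavity volumes", {
  p <- fx_params("Nx")
  g <- solve_triseg_geometry(0.0441, 0.0525, c(2, 3, 4), p)
  expect_equal(g$V_LV_reconstructed, 0.0441, tolerance = 1e-8)
  expect_equal(g$V_RV_reconstructed, 0.0525, tolerance = 1e-8)
})

test_that("pressures are linear in wall stress and vanish with it", {
  p <- fx_params("Nx")
  g <- solve_triseg_geometry(0.044, 0.052, c(2, 2, 2), p)
  expect_equal(unname(ventricular_pressures(g, c(0, 0, 0), p)), c(0, 0))
  p1 <- ventricular_pressures(g, c(2, 2, 2), p)
  p2 <- ventricular_pressures(g, c(4, 4, 4), p)
  expect_equal(unname(p2), 2 * unname(p1), tolerance = 1e-12)
})

test_that("the degenerate sphere reproduces thin-wall Laplace pressure", {
  # mirror ventricles with a negligibly thin septum and thin free walls:
  # the radial balance forces exact hemispheres (x* = y = r), so each
  # cavity is half of a sphere and the closed-form Laplace pressure
  # P = 2 sigma h / r applies
  p <- fx_params("Nx")
  pm <- ratheart:::modify_params(p, c(
    Vw_LV = 0.012, Vw_RV = 0.012, Vw_SEP = 1e-7,
    Am_ref_RV = p[["Am_ref_LV"]], Am_ref_SEP = 0.3))
  vw <- as.numeric(pm[c("Vw_LV", "Vw_SEP", "Vw_RV")])
  amref <- as.numeric(pm[c("Am_ref_LV", "Am_ref_SEP", "Am_ref_RV")])
  sig <- 5
  V_enc <- 0.05 + 0.5 * vw[1] + 0.5 * vw[2]
  r <- (V_enc * 3 / (2 * pi))^(1 / 3)  # hemisphere of cap volume V_enc
  out <- .Call(ratheart:::C_triseg, c(-r, 0, r, r), c(0.05, 0.05),
               rep(sig, 3), vw, amref, pm[["L_s_ref"]])
  expect_lt(max(abs(out[1:4])), 1e-5)  # the hemisphere pair is the root
  h <- vw[1] / (2 * pi * r^2)
  laplace <- 2 * sig * h / r / ratheart:::rh_constants()$kPa_per_mmHg
  expect_equal(out[20], laplace, tolerance = 0.02)
})

test_that("Newton reports non-convergence with diagnostics", {
  p <- fx_params("Nx")
  expect_error(
    solve_triseg_geometry(0.04, 0.05, c(1, 1, 1), p,
                          guess = c(-1e-6, 1e-7, 1e-6, 1e-8), tol = 1e-30),
    "failed to converge")
})
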