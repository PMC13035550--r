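test_that("cycle endpoints find the extremes and ignore cycle rotation", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  loop <- list(V_LV = 30 + 14 * cos(th), P_LV = 35 - 30 * sin(th),
               V_RV = 38 + 14 * cos(th), P_RV = 16 - 12 * sin(th))
  oct <- cycle_endpoints(loop)
  expect_equal(oct[["EDV_LV"]], 44)
  expect_equal(oct[["ESV_LV"]], 16)
  rot <- lapply(loop, function(x) c(x[31:120], x[1:30]))
  expect_equal(cycle_endpoints(rot), oct, tolerance = 1e-9)
})

test_that("relative shortening is a unit-free zero-anchored trace", {
  ls <- c(2, 1.9, 1, 2.1)
  rs <- relative_shortening(ls)
  expect_identical(rs[1], 0)
  expect_equal(rs[3], -0.5)
  expect_equal(relative_shortening(ls * 1000), rs)  # nm vs um invariant
  expect_equal(relative_shortening(rep(1.8, 5)), rep(0, 5))
})

test_that("power intensity matches the analytic product bound", {
  # sigma = s0 sin(wt), L = L0 + a cos(wt): max |sigma dL/dt| = s0 a w
  T <- 0.2; w <- 2 * pi / T
  t <- seq(0, T, length.out = 2001)
  s0 <- 10; a <- 0.1
  sig <- s0 * sin(w * t)
  ls <- 2 + a * cos(w * t)
  got <- power_intensity(sig, ls, t)
  expect_equal(got, s0 * a * w * 1e-3, tolerance = 1e-3)
  expect_identical(power_intensity(0 * sig, ls, t), 0)
  expect_identical(power_intensity(sig, rep(2, length(t)), t), 0)
})

test_that("septal metrics respect the analysis window", {
  cm <- rep(3, 50)
  expect_equal(septal_metrics(cm, 1:25)$delta_cm, 0)
  dip <- cm; dip[10:14] <- c(2.6, 2.2, 2.0, 2.2, 2.6)  # V-shaped, depth 1
  expect_equal(septal_metrics(dip, 1:25)$delta_cm, 1)
  late <- cm; late[40:44] <- 2.0                        # dip in diastasis
  expect_equal(septal_metrics(late, 1:25)$delta_cm, 0)
  expect_equal(septal_metrics(dip, 1:25)$mean_systolic, mean(dip[1:25]))
})

test_that("stroke work equals the loop area by two quadratures", {
  # rectangle: 20 mmHg x 20 uL, counterclockwise
  V <- c(20, 40, 40, 20); P <- c(5, 5, 25, 25)
  expect_equal(stroke_work(P, V), 400)
  expect_equal(stroke_work(c(5, 10, 15), c(20, 20, 20)), 0)  # degenerate
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  Ve <- 30 + 12 * cos(th); Pe <- 40 - 25 * sin(th)  # ccw ellipse
  sw <- stroke_work(Pe, Ve)
  # independent quadrature: -closed trapezoid of P dV
  Vc <- c(Ve, Ve[1]); Pc <- c(Pe, Pe[1])
  sw2 <- -sum(0.5 * (Pc[-1] + Pc[-length(Pc)]) * diff(Vc))
  expect_equal(abs(sw / sw2 - 1), 0, tolerance = 1e-3)
  expect_equal(sw, pi * 12 * 25, tolerance = 0.01 * pi * 12 * 25)
})

test_that("afterload metrics are simple invariants of R, C and P_PA", {
  a <- afterload_metrics(2, 0.25, rep(30, 50))
  expect_equal(a$mPAP, 30)
  expect_equal(a$R_over_C, 8)
  expect_equal(a$RC, 0.5)
  b <- afterload_metrics(4, 0.125, rep(30, 50))
  expect_equal(b$RC, a$RC)              # R doubled, C halved: RC fixed
  expect_equal(b$R_over_C, 4 * a$R_over_C)
  # mPAP shifts with a uniform pressure offset
  p_pa <- 25 + 6 * sin(seq(0, 2 * pi, length.out = 50))
  expect_equal(afterload_metrics(2, 0.25, p_pa + 3)$mPAP,
               afterload_metrics(2, 0.25, p_pa)$mPAP + 3)
})

test_that("group comparisons handle identical and degenerate groups", {
  m <- tibble::tibble(condition = rep(c("Nx", "Hx"), each = 4),
                      x = rep(1.5, 8),
                      y = c(1, 2, 3, 4, 5, 6, 7, 8))
  out <- group_comparisons(m)
  row_x <- out[out$metric == "x", ]
  expect_equal(row_x$t, 0)
  expect_equal(row_x$p, 1)
  # swapping labels flips the t statistic
  m2 <- m
  m2$condition <- ifelse(m$condition == "Nx", "Hx", "Nx")
  expect_equal(group_comparisons(m2)$t[2], -out$t[2])
  # tiny groups are skipped with a note
  m3 <- m[c(1, 5, 6, 7, 8), ]
  expect_match(group_comparisons(m3)$note[1], "skipped")
})

test_that("t-test p-values agree with a permutation oracle", {
  set.seed(31)
  x <- rnorm(7, 0, 1); y <- rnorm(12, 0.9, 1)
  m <- tibble::tibble(condition = rep(c("Nx", "Hx"), c(7, 12)),
                      v = c(x, y))
  p_t <- group_comparisons(m)$p[1]
  obs <- mean(y) - mean(x)
  pool <- c(x, y)
  perm <- replicate(1e5, {
    idx <- sample(19, 12)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("correlation table reports perfect linear relations", {
  m <- tibble::tibble(a = 1:10, b = 2 * (1:10) + 3, c = rnorm(10))
  out <- correlation_table(m, pairs = list(c("a", "b"), c("a", "missing")))
  expect_equal(out$rho[1], 1, tolerance = 1e-12)
  expect_true(is.na(out$rho[2]))
})

test_that("LDA separates distant clouds and not identical ones", {
  set.seed(5)
  X1 <- matrix(rnorm(40 * 3), 40)
  X2 <- X1; X2[21:40, 1] <- X2[21:40, 1] + 10  # 10 SD apart on axis 1
  labs <- rep(c("Nx", "Hx"), each = 20)
  res <- lda_separability(list(apart = X2, same = X1), labs)
  sep <- attr(res, "separation")
  expect_gt(sep[["apart"]], 25)
  expect_lt(sep[["same"]], 1)
  # cross-check the discriminant direction against MASS::lda projections
  skip_if_not_installed("MASS")
  fit <- MASS::lda(X2, grouping = labs)
  z_mass <- as.numeric(scale(X2 %*% fit$scaling))
  z_ours <- res$projection[res$feature_set == "apart"]
  expect_gt(abs(stats::cor(z_mass, scale(z_ours))), 0.99)
})
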