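test_that("the registry holds exactly 54 parameters in five blocks", {
  reg <- param_registry()
  expect_equal(nrow(reg), 54)
  expect_equal(length(unique(reg$name)), 54)
  p <- fx_params("Nx")
  expect_length(p, 54)
})

test_that("nominal build follows the bodyweight rules", {
  rec <- group_avg_record("Nx")
  p <- nominal_parameters(rec)
  expect_equal(p[["V_total"]], 0.06 * 49.9)
  rec50 <- rec; rec50$BW <- 50
  expect_equal(nominal_parameters(rec50)[["V_total"]], 3.0)
  # wall weights: 3.8 mg/g of bodyweight for LV+SEP, split 2/3 : 1/3,
  # converted at density 1.055 g/mL
  W <- 3.8 * 49.9 / 1000
  expect_equal(p[["Vw_LV"]], (2 / 3) * W / 1.055)
  expect_equal(p[["Vw_SEP"]], (1 / 3) * W / 1.055)
  expect_equal(p[["Vw_RV"]], 0.86 * 49.9 / 1000 / 1.055)
  # pediatric attachment-rate reduction: 20% below the adult value
  expect_equal(p[["k_a"]], 0.8 * 350)
})

test_that("hyperoxia wall-weight ratios apply to Hx animals", {
  rec <- group_avg_record("Hx")
  p <- nominal_parameters(rec)
  expect_equal(p[["Vw_RV"]], 1.00 * rec$BW / 1000 / 1.055)
  expect_equal(p[["Vw_LV"]] + p[["Vw_SEP"]], 3.2 * rec$BW / 1000 / 1.055)
})

test_that("reference areas reconstruct the measured end-diastolic volumes", {
  p <- fx_params("Nx")
  rec <- group_avg_record("Nx")
  g <- solve_triseg_geometry((rec$ESV_LV + rec$SV) / 1000,
                             (rec$ESV_RV + rec$SV) / 1000,
                             ratheart:::diastolic_sigma_fun(p), p)
  expect_equal(g$V_LV_reconstructed, (rec$ESV_LV + rec$SV) / 1000,
               tolerance = 1e-6)
  expect_equal(g$V_RV_reconstructed, (rec$ESV_RV + rec$SV) / 1000,
               tolerance = 1e-6)
  # and the anchored diastolic state carries the measured LV EDP
  y0 <- initial_state(p)
  o <- attr(assemble_rhs(y0, 0.99 * p[["T_cycle"]], p), "outputs")
  expect_equal(unname(o["P_LV"]), rec$EDP_LV, tolerance = 0.15 * rec$EDP_LV)
})

test_that("incomplete or invalid records are rejected", {
  rec <- group_avg_record("Nx")
  rec$SV <- NULL
  expect_error(nominal_parameters(rec), "incomplete")
  rec2 <- group_avg_record("Nx")
  rec2$BW <- -1
  expect_error(nominal_parameters(rec2), "invalid")
})

test_that("hyperoxia modifiers change exactly the documented entries", {
  pN <- fx_params("Nx")
  pH <- apply_hyperoxia_modifiers(pN)
  expect_equal(pH[["k_passive_RV"]] / pN[["k_passive_RV"]], 2)
  expect_equal(pH[["k_off_RV"]] / pN[["k_off_RV"]], 0.6)
  expect_equal(pH[["k_stiff1_RV"]] / pN[["k_stiff1_RV"]], 1.7)
  expect_equal(pH[["k_stiff2_RV"]] / pN[["k_stiff2_RV"]], 1.7)
  expect_equal(pH[["ATP"]] / pN[["ATP"]], 0.95)
  expect_equal(pH[["ADP"]] / pN[["ADP"]], 1.05)
  expect_equal(pH[["Pi"]] / pN[["Pi"]], 1.05)  # text convention
  pH2 <- apply_hyperoxia_modifiers(pN, pi_sign = "printed")
  expect_equal(pH2[["Pi"]] / pN[["Pi"]], 0.95)
  # LV and septal entries bit-identical
  lv_sep <- setdiff(names(pN), c("ATP", "ADP", "Pi", "k_passive_RV",
                                 "k_off_RV", "k_stiff1_RV", "k_stiff2_RV"))
  expect_identical(unclass(pH)[lv_sep], unclass(pN)[lv_sep])
  expect_error(apply_hyperoxia_modifiers(pH), "idempotence")
})

test_that("serialization round-trips a parameter set exactly", {
  p <- fx_params("Hx")
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(as.numeric(q), as.numeric(p), tolerance = 1e-12)
  expect_identical(names(q), names(p))
  expect_identical(attr(q, "condition"), "Hx")
  expect_equal(attr(q, "edv"), attr(p, "edv"), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("nominal build is deterministic and bodyweight-local", {
  rec <- group_avg_record("Nx")
  expect_identical(as.numeric(nominal_parameters(rec)),
                   as.numeric(nominal_parameters(rec)))
  rec2 <- rec; rec2$BW <- rec$BW * 1.1
  p1 <- nominal_parameters(rec); p2 <- nominal_parameters(rec2)
  differing <- names(p1)[as.numeric(p1) != as.numeric(p2)]
  expect_true(all(differing %in%
                    c("V_total", "Vw_LV", "Vw_SEP", "Vw_RV",
                      "Am_ref_LV", "Am_ref_SEP", "Am_ref_RV",
                      "v_un_frac")))
})

test_that("effective rates reduce to nominal constants at the reference pool", {
  p <- fx_params("Nx")
  r <- effective_rates(p)
  expect_equal(r$f3m, p[["k_3"]], tolerance = 1e-12)
  expect_equal(r$g21, p[["k_m1"]], tolerance = 1e-12)
  # Pi = 0: the rebinding pathway vanishes exactly
  p0 <- ratheart:::modify_params(p, c(Pi = 0))
  expect_identical(effective_rates(p0)$g21, 0)
  expect_error(effective_rates(ratheart:::modify_params(p, c(ATP = -1))),
               "positive")
  # perturbed metabolites move every affected rate in the direction given
  # by direct evaluation of the published-rate-style expressions
  pH <- apply_hyperoxia_modifiers(p)
  rH <- effective_rates(pH)
  expect_lt(rH$f3m, r$f3m)   # less ATP, more ADP: slower post-ratchet exit
  expect_gt(rH$g21, r$g21)   # more Pi: faster rebinding (text convention)
})
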