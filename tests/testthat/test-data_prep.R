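# build a beat train from an analytic cycle template
template_cycle <- function(T = 0.18, n = 120) {
  t <- T * (seq_len(n) - 1) / n
  ph <- t / T
  V <- 40 - 24 * pmin(pmax((ph - 0.1) / 0.3, 0), 1) +
    24 * pmin(pmax((ph - 0.55) / 0.35, 0), 1)
  P <- 5 + 60 * exp(-((ph - 0.25) / 0.16)^2)
  tibble::tibble(t = t, P = P, V = V)
}

beats_from_template <- function(n_beats = 25, jitter = 0, noise = 0,
                                T = 0.18, seed = 1) {
  set.seed(seed)
  tpl <- template_cycle(T)
  off <- 0
  purrr::map_dfr(seq_len(n_beats), function(b) {
    Tb <- T * (1 + stats::rnorm(1, 0, jitter))
    out <- tibble::tibble(
      t = off + tpl$t / T * Tb,
      P = tpl$P + stats::rnorm(nrow(tpl), 0, noise),
      V = tpl$V + stats::rnorm(nrow(tpl), 0, noise),
      beat = b)
    off <<- off + Tb
    out
  })
}

test_that("averaging identical beats reproduces any single beat", {
  beats <- beats_from_template(25)
  avg <- average_beats(beats)
  tpl <- template_cycle()
  ref <- stats::approx(tpl$t / 0.18, tpl$P, xout = avg$phase, rule = 2)$y
  expect_equal(avg$P, ref, tolerance = 1e-6)
  expect_equal(attr(avg, "period"), 0.18, tolerance = 1e-9)
})

test_that("averaging symmetric offsets recovers the midline", {
  beats <- beats_from_template(2)
  beats$P[beats$beat == 1] <- beats$P[beats$beat == 1] + 3
  beats$P[beats$beat == 2] <- beats$P[beats$beat == 2] - 3
  expect_warning(avg <- average_beats(beats), "beats")
  tpl <- template_cycle()
  ref <- stats::approx(tpl$t / 0.18, tpl$P, xout = avg$phase, rule = 2)$y
  expect_equal(avg$P, ref, tolerance = 1e-6)
})

test_that("phase-space averaging suppresses jitter noise like 1/sqrt(n)", {
  # Monte-Carlo oracle with a known template
  beats <- beats_from_template(40, jitter = 0.03, noise = 2, seed = 8)
  avg <- suppressWarnings(average_beats(beats))
  tpl <- template_cycle()
  ref <- stats::approx(tpl$t / 0.18, tpl$P, xout = avg$phase, rule = 2)$y
  rms <- sqrt(mean((avg$P - ref)^2))
  expect_lt(rms, 3 * 2 / sqrt(40) + 0.5)
  expect_error(average_beats(beats[0, ]), "no beats")
})

test_that("harmonization sets a common period and reconciles RV volumes", {
  lv <- suppressWarnings(average_beats(beats_from_template(24, seed = 2)))
  rv <- suppressWarnings(
    average_beats(beats_from_template(24, T = 0.20, seed = 3)))
  rv$V <- rv$V * 0.8  # mismatched RV conductance gain
  h <- harmonize_timing_volumes(lv, rv)
  expect_equal(h$T_common, (0.18 + 0.20) / 2, tolerance = 1e-9)
  expect_equal(h$SV_common, max(lv$V) - min(lv$V), tolerance = 1e-9)
  expect_equal(max(h$rv$V), min(h$rv$V) + h$SV_common, tolerance = 1e-9)
  expect_equal(min(h$rv$V), min(rv$V), tolerance = 1e-9)  # RV ESV kept
  expect_equal(h$lv$V, lv$V)                              # LV untouched
  # the Table-1 arithmetic: RV EDV = RV ESV + SV
  expect_equal(24 + 28, 52)
})

test_that("negative EDP correction shifts uniformly, otherwise no-ops", {
  tr <- template_cycle()
  tr$P <- tr$P - 11  # EDP at max V becomes negative
  edp0 <- tr$P[which.max(tr$V)]
  expect_lt(edp0, 0)
  fixed <- correct_edp_offset(tr, 3.0)
  expect_equal(fixed$P[which.max(fixed$V)], 3.0)
  expect_equal(diff(range(fixed$P)), diff(range(tr$P)))  # pulse preserved
  expect_equal(attr(fixed, "edp_shift"), 3.0 - edp0)
  clean <- correct_edp_offset(template_cycle(), 3.0)
  expect_equal(clean$P, template_cycle()$P)
  expect_equal(attr(clean, "edp_shift"), 0)
})

test_that("group-reference EDP averages valid same-group animals", {
  recs <- tibble::tibble(condition = c("Nx", "Nx", "Nx", "Hx"),
                         sex = c("M", "M", "M", "M"),
                         EDP_RV = c(2, 4, -1, 9))
  expect_equal(group_reference_edp(recs, "Nx", "M"), 3)
  expect_error(group_reference_edp(recs, "Nx", "F"), "no valid reference")
})

test_that("isovolumic enforcement removes artifacts and preserves SV", {
  tr <- template_cycle()
  clean <- enforce_isovolumic(tr)
  expect_equal(clean$V, tr$V, tolerance = 1e-9)  # already isovolumetric
  # inject a 2 uL spike during isovolumic contraction
  bad <- tr
  ph <- tr$t / 0.18
  bad$V <- bad$V + 2 * exp(-((ph - 0.05) / 0.02)^2)
  fixed <- enforce_isovolumic(bad)
  expect_lt(max(fixed$V), max(bad$V) - 1)        # spike flattened
  expect_equal(max(fixed$V) - min(fixed$V),
               max(tr$V) - min(tr$V), tolerance = 0.3)  # SV preserved
  iso <- fixed$V[ph < 0.1]
  expect_lt(stats::sd(iso), 0.05)                # corner squared
})

test_that("prepared octets are reproducible bit-exactly", {
  lv <- beats_from_template(22, jitter = 0.01, noise = 1, seed = 5)
  rv <- beats_from_template(22, jitter = 0.01, noise = 1, seed = 6,
                            T = 0.185)
  p1 <- suppressWarnings(prepare_animal(lv, rv))
  p2 <- suppressWarnings(prepare_animal(lv, rv))
  expect_identical(p1$octet, p2$octet)
  expect_identical(p1$T, p2$T)
  expect_s3_class(p1, "rh_prepared")
})
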