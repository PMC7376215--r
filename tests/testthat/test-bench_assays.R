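make_curve <- function(a = 3.885, b = -0.9, concs = 3000 / 2^(0:7)) {
  fit_standard_curve(data.frame(conc = concs,
                                b_over_b0 = plogis(a + b * log(concs))))
}

test_that("standard curve: exact recovery, inversion, midpoint closed form", {
  a_true <- 3.885
  b_true <- -0.9
  curve <- make_curve(a_true, b_true)
  expect_equal(curve$a, a_true, tolerance = 1e-10)
  expect_equal(curve$b, b_true, tolerance = 1e-10)
  expect_equal(curve$midpoint_conc, exp(-a_true / b_true), tolerance = 1e-9)
  expect_lt(curve$sensitivity_conc, curve$midpoint_conc)

  for (x in c(20, 100, 1500)) {
    bb <- curve_forward(curve, x)
    expect_equal(interpolate_concentration(curve, bb)$apparent_conc, x,
                 tolerance = 1e-9)
  }

  # rising curve is not competitive
  expect_error(
    fit_standard_curve(data.frame(conc = c(11, 100, 1000),
                                  b_over_b0 = c(0.2, 0.5, 0.8))),
    "not a competitive curve")
  # saturated standards are excluded with a warning
  expect_warning(
    fit_standard_curve(data.frame(conc = c(11, 50, 200, 900, 2900),
                                  b_over_b0 = c(1.05, 0.8, 0.5, 0.2, 0.05))),
    "B/B0 >= 1")
})

test_that("interpolation respects dilution and the linear range", {
  curve <- make_curve()
  mid <- interpolate_concentration(curve, 0.5)
  expect_equal(mid$apparent_conc, curve$midpoint_conc, tolerance = 1e-9)
  d2 <- interpolate_concentration(curve, 0.5, dilution_factor = 2)
  expect_equal(d2$apparent_conc, 2 * mid$apparent_conc, tolerance = 1e-12)

  # read-off below the linear range flags out-of-range
  low_bb <- curve_forward(curve, 5)
  expect_false(interpolate_concentration(curve, low_bb)$in_range)
  expect_error(interpolate_concentration(curve, 1.0), "\\(0, 1\\)")
})

test_that("cross-reactivity correction modes are mutual inverses", {
  expect_equal(correct_cross_reactivity(38, 0.38), 100)
  expect_equal(correct_cross_reactivity(7, 1), 7)
  expect_equal(
    correct_cross_reactivity(correct_cross_reactivity(55, 0.38, "divide"),
                             0.38, "multiply"), 55, tolerance = 1e-12)
  expect_error(correct_cross_reactivity(10, 0), "factor")
})

test_that("dilution disparity arithmetic and QC threshold", {
  r <- dilution_concordance(c(100, 100))
  expect_equal(r$disparity_percent, 0)
  expect_true(r$qc_pass)
  r2 <- dilution_concordance(c(100, 110))
  expect_equal(r2$disparity_percent, 100 * 10 / 105, tolerance = 1e-12)
  expect_true(r2$qc_pass)
  r3 <- dilution_concordance(c(100, 130))
  expect_equal(r3$disparity_percent, 100 * 30 / 115, tolerance = 1e-12)
  expect_false(r3$qc_pass)
  expect_error(dilution_concordance(100), ">= 2")
})

test_that("unit conversion reproduces both reported concentration pairs", {
  expect_equal(nm_to_pg_per_ug(1.68), 75.6, tolerance = 0.005)
  expect_equal(nm_to_pg_per_ug(1.46), 65.9, tolerance = 0.01)
  for (x in c(0.5, 1.46, 1.68, 3)) {
    expect_equal(pg_per_ug_to_nm(nm_to_pg_per_ug(x)), x, tolerance = 1e-12)
  }
  expect_error(nm_to_pg_per_ug(-1))
})

test_that("IP efficiency: reported magnitude, background, clipping", {
  expect_equal(ip_efficiency(300, 1000)$percent, 30)
  expect_equal(ip_efficiency(300, 1000, 50)$percent, 100 * 250 / 950,
               tolerance = 1e-12)
  expect_equal(ip_efficiency(1000, 1000)$percent, 100)
  over <- ip_efficiency(1200, 1000)
  expect_equal(over$percent, 100)
  expect_true(over$clipped)
  expect_error(ip_efficiency(10, 50, 60), "exceed background")
})

test_that("dot-blot linearity: exact line, flat line, OLS closed form", {
  marks <- c(1L, 2L, 3L, 4L)
  exact <- dotblot_linearity(marks, 3 + 2 * marks)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  flat <- dotblot_linearity(marks, rep(5, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)

  # 3-point hand example via normal equations
  x <- c(1, 2, 4)
  y <- c(2, 3, 9)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- dotblot_linearity(x, y)
  expect_equal(fit$slope, slope_hand, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope_hand * mean(x),
               tolerance = 1e-12)
  expect_error(dotblot_linearity(c(2, 2, 2), y), "constant")
})

test_that("truncation index: symmetry, arithmetic, reciprocal swap, errors", {
  flat <- list(exposed = list(target_proximal = 100, target_distal = 100,
                              norm_proximal = 100, norm_distal = 100),
               control = list(target_proximal = 100, target_distal = 100,
                              norm_proximal = 100, norm_distal = 100))
  r <- truncation_index(flat)
  expect_equal(r$oxidation_index, 1)
  expect_false(r$oxidized)

  half <- flat
  half$exposed$target_distal <- 50
  r2 <- truncation_index(half)
  expect_equal(r2$oxidation_index, 0.5)
  expect_true(r2$oxidized)

  swapped <- list(exposed = half$control, control = half$exposed)
  expect_equal(truncation_index(swapped)$oxidation_index,
               1 / r2$oxidation_index, tolerance = 1e-12)

  bad <- flat
  bad$control$norm_distal <- 0
  expect_error(truncation_index(bad), "norm_distal")
})

test_that("loading normalization is a pure ratio of ratios", {
  expect_equal(loading_normalize(10, 5, 10, 5), 1)
  expect_equal(loading_normalize(10, 5, 5, 5), 2)
  # invariant to rescaling one lane's signals jointly
  expect_equal(loading_normalize(10 * 7, 5 * 7, 6, 3),
               loading_normalize(10, 5, 6, 3), tolerance = 1e-12)
  expect_error(loading_normalize(1, 0, 1, 1), "> 0")
})
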