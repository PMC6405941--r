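cst <- bc_constants()

test_that("supported 210Pb estimation follows the declared conventions", {
  core <- make_core(c(210, 110, 60, 35, 26, 25, 25))
  expect_equal(estimate_supported(core, "deep_plateau", n_deep = 2), 25)

  core$slices$pb210_supported <- 20
  expect_equal(estimate_supported(core, "given"), 20)

  # plateau estimate above the shallow minimum flags a suspect profile
  suspect <- make_core(c(210, 110, 24, 35, 26, 25))
  expect_warning(estimate_supported(suspect, "deep_plateau", n_deep = 3),
                 "plateau")

  flat <- make_core(rep(30, 6))
  expect_equal(estimate_supported(flat, "deep_plateau", n_deep = 3), 30)
  # zero excess everywhere -> no fittable decay trend downstream
  expect_error(fit_cfcs(flat, cst, supported = 30), "positive excess")

  expect_error(estimate_supported(make_core(c(50, 40)), "deep_plateau", 3),
               "n_deep")
})

test_that("cumulative mass accrues dry mass down to slice midpoints", {
  expect_equal(cumulative_mass(make_core(rep(100, 5))),
               c(0.5, 1.5, 2.5, 3.5, 4.5))
  core2 <- make_core(c(100, 50), dbd = c(0.5, 1.0), thickness = 2)
  expect_equal(cumulative_mass(core2), c(0.5, 2.0))
  # strictly increasing on arbitrary generated cores
  for (s in 1:5) {
    core <- generate_core(core_scenario(dbd_gradient = 0.05, seed = s))
    expect_true(all(diff(cumulative_mass(core)) > 0))
  }
})

test_that("CF:CS recovers a noiseless profile exactly", {
  core <- make_cfcs_core(mar = 0.10, n = 10)
  ch <- fit_cfcs(core, cst, supported = 25)
  expect_equal(ch$mar, 0.10, tolerance = 1e-6)
  expect_equal(ch$sar, 0.10, tolerance = 1e-6)  # uniform DBD of 1
  expect_equal(ch$r_squared, 1, tolerance = 1e-9)
  expect_equal(ch$surface_excess, 500, tolerance = 1e-6)
  expect_equal(ch$slope, -cst$lambda_pb210 / 0.10, tolerance = 1e-9)
  # ages are mass/MAR, increasing, and years = coring_year - age
  expect_equal(ch$slice_ages, cumulative_mass(core) / 0.10, tolerance = 1e-6)
  expect_true(all(diff(ch$slice_ages) > 0))
  expect_equal(ch$slice_years, 2015 - ch$slice_ages)
})

test_that("closed-form slope on an exact exponential gives MAR = 0.05", {
  # three points on excess(m) = 100 exp(-lambda m / 0.05), m = 0.5, 1.5, 2.5
  core <- make_cfcs_core(mar = 0.05, n = 3, surface_excess = 100)
  ch <- fit_cfcs(core, cst, supported = 25)
  expect_equal(ch$slope, -cst$lambda_pb210 / 0.05, tolerance = 1e-9)
  expect_equal(ch$mar, 0.05, tolerance = 1e-9)
})

test_that("MAR and SAR are invariant to scaling all excess activities", {
  core <- make_cfcs_core(mar = 0.08, n = 8)
  ch1 <- fit_cfcs(core, cst, supported = 25)
  scaled <- core
  scaled$slices$pb210_total <- 25 + (core$slices$pb210_total - 25) * 7.3
  ch2 <- fit_cfcs(scaled, cst, supported = 25)
  expect_equal(ch2$mar, ch1$mar, tolerance = 1e-9)
  expect_equal(ch2$sar, ch1$sar, tolerance = 1e-9)
  expect_equal(ch2$surface_excess, ch1$surface_excess * 7.3,
               tolerance = 1e-6)
})

test_that("non-positive excess slices are excluded yet still dated", {
  core <- make_cfcs_core(mar = 0.10, n = 8)
  core$slices$pb210_total[6] <- 20  # below supported level
  ch <- fit_cfcs(core, cst, supported = 25)
  expect_equal(ch$n_points, 7)
  expect_equal(ch$mar, 0.10, tolerance = 1e-6)  # other points are exact
  expect_length(ch$slice_ages, 8)
  expect_true(all(is.finite(ch$slice_ages)))
})

test_that("degenerate profiles raise fit errors", {
  increasing <- make_core(c(30, 40, 60, 90, 140))
  expect_error(fit_cfcs(increasing, cst, supported = 25), "no decay trend")
  expect_error(fit_cfcs(make_core(c(100, 20, 20, 20, 20)), cst,
                        supported = 25), "positive excess")
})

test_that("depth-coordinate and weighted variants agree on clean uniform cores", {
  core <- make_cfcs_core(mar = 0.12, n = 10)
  core$slices$pb210_total_err <- 0.05 * core$slices$pb210_total
  ch_mass <- fit_cfcs(core, cst, supported = 25)
  ch_depth <- fit_cfcs(core, cst, supported = 25, coordinate = "depth")
  ch_w <- fit_cfcs(core, cst, supported = 25, weighting = "activity_err")
  expect_equal(ch_depth$sar, ch_mass$sar, tolerance = 1e-9)
  expect_equal(ch_depth$mar, ch_mass$mar, tolerance = 1e-9)
  expect_equal(ch_w$mar, ch_mass$mar, tolerance = 1e-9)
})

test_that("median fitted SAR stays within 5% of truth under 10% noise", {
  set.seed(2024)
  scn <- core_scenario(true_sar = 0.22, noise_cv = 0.1, seed = NULL)
  fits <- replicate(200, fit_cfcs(generate_core(scn), cst, supported = 25)$sar)
  expect_lt(abs(stats::median(fits) - 0.22) / 0.22, 0.05)
})

test_that("post-1900 mask follows slice midpoint years", {
  core <- make_core(c(200, 100), coring_year = 2010)
  chron <- structure(list(slice_years = 2010 - c(50, 200)),
                     class = "cfcs_chronology")
  expect_equal(post1900_mask(core, chron), c(TRUE, FALSE))

  # MAR 0.05, midpoint masses {1, 6} -> ages {20, 120}, coring year 2000
  core2 <- make_core(c(200, 100), dbd = c(2, 8), coring_year = 2000)
  expect_equal(cumulative_mass(core2), c(1, 6))
  chron2 <- structure(list(slice_years = 2000 - cumulative_mass(core2) / 0.05),
                      class = "cfcs_chronology")
  expect_equal(post1900_mask(core2, chron2), c(TRUE, FALSE))

  all_young <- structure(list(slice_years = c(1990, 1985)),
                         class = "cfcs_chronology")
  expect_equal(post1900_mask(core, all_young), c(TRUE, TRUE))
  expect_error(post1900_mask(core, structure(list(slice_years = 1:3),
                                             class = "cfcs_chronology")),
               "3 slices|2 slices")
})
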