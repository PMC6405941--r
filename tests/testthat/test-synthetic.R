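cst <- bc_constants()

test_that("generators are deterministic and leave the caller's RNG alone", {
  expect_identical(generate_core(core_scenario(seed = 3)),
                   generate_core(core_scenario(seed = 3)))
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_core(core_scenario(seed = 3)))
  expect_identical(runif(1), before)
  expect_identical(generate_dataset(dataset_scenario(n_locations = 3,
                                                     seed = 5)),
                   generate_dataset(dataset_scenario(n_locations = 3,
                                                     seed = 5)))
})

test_that("a noiseless synthetic core inverts exactly through CF:CS", {
  core <- generate_core(core_scenario(true_sar = 0.22, noise_cv = 0,
                                      seed = 2))
  ch <- fit_cfcs(core, cst, supported = 25)
  expect_equal(ch$sar, 0.22, tolerance = 1e-6)
  expect_equal(ch$mar, 0.22, tolerance = 1e-6)
  truth <- attr(core, "truth")
  expect_equal(ch$slice_ages, truth$slice_ages, tolerance = 1e-6)
})

test_that("generated cores pass the package's own validators and round-trip", {
  cores <- generate_dataset(dataset_scenario(n_locations = 5, seed = 31,
                                             paired_unvegetated = TRUE))
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_core_table(cores, sp, mp)
  back <- read_core_table(sp, mp)
  expect_length(back, length(cores))
  for (i in seq_along(cores))
    expect_identical(back[[i]]$slices, cores[[i]]$slices)
})

test_that("dataset scenarios reproduce the compiled study's structure", {
  cores <- generate_dataset(dataset_scenario(n_locations = 17,
                                             cores_per_location = c(3, 3),
                                             seed = 41))
  expect_length(cores, 51)
  expect_length(unique(vapply(cores, `[[`, character(1), "location_key")),
                17)
  # paired design adds matched unvegetated partners per location
  paired <- generate_dataset(dataset_scenario(n_locations = 6, seed = 42,
                                              paired_unvegetated = TRUE))
  eco <- vapply(paired, `[[`, character(1), "ecosystem")
  expect_equal(sum(eco == "unvegetated"), 18)
  expect_equal(sum(eco == "seagrass"), 18)
})

test_that("paired generator under the null yields non-significant pooled effects", {
  set.seed(314)
  scn_base <- core_scenario(n_slices = 10)
  nonsig <- replicate(100, {
    ds <- generate_dataset(dataset_scenario(
      n_locations = 7, cores_per_location = c(3, 3),
      paired_unvegetated = TRUE, base_scenario = scn_base, seed = NULL))
    caco3 <- vapply(ds, function(co) mean(co$slices$caco3_pct), numeric(1))
    eco <- vapply(ds, `[[`, character(1), "ecosystem")
    key <- vapply(ds, `[[`, character(1), "location_key")
    studies <- do.call(rbind, lapply(unique(key), function(k) {
      v <- caco3[key == k & eco != "unvegetated"]
      u <- caco3[key == k & eco == "unvegetated"]
      data.frame(study_id = k, mean_veg = mean(v), sd_veg = sd(v),
                 n_veg = length(v), mean_unveg = mean(u), sd_unveg = sd(u),
                 n_unveg = length(u))
    }))
    paired_vegetation_contrast(studies)$p_value > 0.05
  })
  expect_gte(mean(nonsig), 0.90)
})

test_that("CaCO3 distribution is bimodal when sources are mixed", {
  cores <- generate_dataset(dataset_scenario(n_locations = 40,
                                             cores_per_location = c(2, 2),
                                             fraction_with_sources = 0.6,
                                             seed = 51))
  caco3 <- unlist(lapply(cores, function(co) co$slices$caco3_pct))
  in_valley <- mean(caco3 > 10 & caco3 < 50)
  low_mode <- mean(caco3 <= 10)
  high_mode <- mean(caco3 >= 50)
  expect_lt(in_valley, low_mode)
  expect_lt(in_valley, high_mode)
})

test_that("recovery harness reports zero error without noise", {
  rep0 <- recovery_report(core_scenario(noise_cv = 0), replicates = 10,
                          seed = 6)
  expect_true(all(abs(rep0$bias) < 1e-10))
  expect_true(all(rep0$rmse < 1e-10))
  expect_true(all(rep0$n_failed == 0))
})

test_that("recovery RMSE grows with activity noise", {
  scns <- lapply(c(0, 0.05, 0.1, 0.2), function(cv)
    core_scenario(noise_cv = cv))
  rep <- recovery_report(scns, replicates = 50, seed = 8)
  sar_rmse <- rep$rmse[rep$parameter == "sar"]
  expect_equal(order(sar_rmse), 1:4)  # monotone in noise_cv
})

test_that("generator truth burial matches the closed-form hand computation", {
  core <- generate_core(core_scenario(noise_cv = 0, seed = 14))
  tr <- attr(core, "truth")
  mask <- tr$slice_years >= 1900
  by_hand <- tr$true_sar *
    mean(tr$dbd[mask]) * mean(tr$caco3_pct[mask]) / 100 * cst$f_c * 1e4
  expect_equal(blueCinorg:::true_burial(core, cst), by_hand)
  # and the fitted pipeline reproduces it exactly in the noiseless case
  carb <- core_carbonate(core, fit_cfcs(core, cst, supported = 25), cst)
  expect_equal(carb$cinorg_burial, by_hand, tolerance = 1e-9)
})
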