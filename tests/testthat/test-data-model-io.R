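test_that("default constants carry the accounting values", {
  cst <- bc_constants()
  expect_equal(cst$f_c, 0.12)
  expect_equal(cst$psi, 0.6)
  expect_equal(cst$lambda_pb210, log(2) / 22.3)
  expect_equal(cst$seagrass_area_low, 150000)
  expect_equal(cst$seagrass_area_high, 600000)
  expect_equal(cst$mangrove_area, 137760)
  expect_equal(cst$tropical_area_fraction, 2 / 3)
  expect_identical(load_config(NULL), cst)
})

test_that("config overrides are applied and validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("f_c: 0.12001\nmangrove_area: 140000", path)
  cst <- load_config(path)
  expect_equal(cst$f_c, 0.12001)
  expect_equal(cst$mangrove_area, 140000)
  expect_equal(cst$psi, 0.6)  # untouched fields keep defaults

  writeLines("psi: 0.0", path)
  expect_error(load_config(path), "psi")
  writeLines("seagrass_area_high: 100", path)
  expect_error(load_config(path), "seagrass_area_low")
  writeLines("made_up_field: 1", path)
  expect_error(load_config(path), "unknown config field")
  expect_error(load_config("/nonexistent.yaml"), "not found")
})

test_that("core validation rejects malformed slice tables by core and row", {
  good <- data.frame(depth_top = 0:4, depth_bottom = 1:5,
                     dry_bulk_density = 1,
                     pb210_total = c(200, 120, 80, 50, 35), caco3_pct = 50)
  expect_s3_class(sediment_core("OK", good, coring_year = 2015),
                  "sediment_core")

  bad <- good; bad$depth_bottom[3] <- 1.5  # bottom < top
  expect_error(sediment_core("C9", bad, coring_year = 2015),
               "C9.*row\\(s\\) 3")
  bad <- good; bad$dry_bulk_density[2] <- -1
  expect_error(sediment_core("C9", bad, coring_year = 2015), "bulk density")
  bad <- good; bad$pb210_total[4] <- -5
  expect_error(sediment_core("C9", bad, coring_year = 2015),
               "negative pb210_total.*4")
  bad <- good; bad$caco3_pct[1] <- 120
  expect_error(sediment_core("C9", bad, coring_year = 2015), "caco3_pct")
  bad <- good; bad$depth_top[2] <- 0.2  # overlaps slice 1
  expect_error(sediment_core("C9", bad, coring_year = 2015), "overlap")
  expect_error(sediment_core("C9", good, coring_year = 2015,
                             location_key = ""), "location_key")
})

test_that("two-core tables round-trip through read_core_table", {
  cores <- list(
    make_core(c(210, 110, 60, 35, 26), core_id = "A",
              location_key = "siteA", ecosystem = "seagrass"),
    make_core(c(150, 90, 55, 40, 30), dbd = 1.3, core_id = "B",
              location_key = "siteB", ecosystem = "mangrove")
  )
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_core_table(cores, sp, mp)
  back <- read_core_table(sp, mp)
  expect_length(back, 2)
  expect_equal(vapply(back, function(x) nrow(x$slices), integer(1)), c(5L, 5L))
  expect_identical(back[[1]]$slices, cores[[1]]$slices)
  expect_identical(back[[2]]$ecosystem, "mangrove")
})

test_that("write/read round trip is bit-identical on synthetic cores", {
  cores <- generate_dataset(dataset_scenario(n_locations = 4, seed = 77))
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  write_core_table(cores, sp, mp)
  back <- read_core_table(sp, mp)
  for (i in seq_along(cores)) {
    expect_identical(back[[i]]$slices, cores[[i]]$slices)
    expect_identical(back[[i]]$core_id, cores[[i]]$core_id)
    expect_identical(back[[i]]$location_key, cores[[i]]$location_key)
    expect_identical(back[[i]]$coral_reef_present,
                     cores[[i]]$coral_reef_present)
  }
})

test_that("reader reports schema problems and supports column mapping", {
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("core_id,top_cm,bot_cm,dbd,pb210,caco3",
               "A,0,1,1.0,200,50", "A,1,2,1.0,120,50",
               "A,2,3,1.0,80,50", "A,3,4,1.0,50,50"), sp)
  writeLines(c("core_id,ecosystem,coring_year,location_key",
               "A,seagrass,2015,siteA"), mp)
  expect_error(read_core_table(sp, mp), "missing column")
  cores <- read_core_table(sp, mp, schema = c(
    depth_top = "top_cm", depth_bottom = "bot_cm",
    dry_bulk_density = "dbd", pb210_total = "pb210", caco3_pct = "caco3"))
  expect_equal(cores[[1]]$slices$pb210_total, c(200, 120, 80, 50))
  # validation error names the offending core when depths are inverted
  writeLines(c("core_id,top_cm,bot_cm,dbd,pb210,caco3",
               "A,0,1,1.0,200,50", "A,2,1,1.0,120,50",
               "A,2,3,1.0,80,50", "A,3,4,1.0,50,50"), sp)
  expect_error(read_core_table(sp, mp, schema = c(
    depth_top = "top_cm", depth_bottom = "bot_cm",
    dry_bulk_density = "dbd", pb210_total = "pb210", caco3_pct = "caco3")),
    "'A'")
})
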