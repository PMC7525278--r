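test_that("mg/L to meq/L conversion matches hand arithmetic and is linear", {
  # equivalent weight of Ca is 40.08/2 = 20.04
  expect_equal(to_meq(40.08, "ca"), 2.0)
  expect_equal(to_meq(23.0, "na"), 23.0 / 22.99)
  expect_equal(to_meq(0, "so4"), 0)
  # linearity in the concentration for a fixed ion
  a <- 13.7; b <- 5.21
  for (ion in c("na", "ca", "hco3", "so4")) {
    expect_equal(to_meq(a + b, ion), to_meq(a, ion) + to_meq(b, ion))
  }
  expect_error(to_meq(7, "ph"), "not an ionic parameter")
})

test_that("descriptive statistics use the sample sd and se = sd/sqrt(n)", {
  df <- toy_samples()
  df$zn <- c(1, 2, 3)
  st <- descriptive_stats(df)
  zn <- st[st$parameter == "zn", ]
  expect_equal(zn$mean, 2)
  expect_equal(zn$sd, 1)
  expect_equal(zn$se, 1 / sqrt(3))
  # constant column: sd = se = 0
  df$cu <- c(5, 5, 5)
  st <- descriptive_stats(df)
  expect_equal(st[st$parameter == "cu", "sd"], 0)
  expect_equal(st[st$parameter == "cu", "se"], 0)
  # single sample: undefined markers, mean equals the row
  one <- fx$table1_means
  st1 <- descriptive_stats(one)
  expect_true(all(is.na(st1$sd)))
  expect_true(all(is.na(st1$se)))
  expect_equal(st1$mean[st1$parameter == "pb"], 9.3)
})

test_that("reader round-trips the writer and reports bad cells", {
  ds <- fx$n30_default
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(ds, path)
  back <- read_samples(path)
  expect_equal(nrow(back$samples), 30)
  # stats identical between the in-memory table and the round trip
  # (writer emits 6 significant digits)
  expect_equal(descriptive_stats(back)$mean, descriptive_stats(ds)$mean,
               tolerance = 1e-5)
  # missing mandatory column is fatal and names the column
  df <- toy_samples()
  df$pb <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_samples(path2), "pb")
  # unparseable numeric is reported, not dropped
  df <- toy_samples()
  df$ni <- as.character(df$ni)
  df$ni[2] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path3, row.names = FALSE)
  expect_warning(ds3 <- read_samples(path3), "unparseable")
  expect_equal(nrow(ds3$samples), 3)
  expect_true(is.na(ds3$samples$ni[2]))
})

test_that("validation rejects negative concentrations and absurd pH", {
  df <- toy_samples()
  df$cu[2] <- -1
  expect_error(water_dataset(df), "negative concentration.*cu")
  df <- toy_samples()
  df$ph[1] <- 15
  expect_error(water_dataset(df), "pH outside")
})

test_that("exceedance counts strict violations; pH uses a two-sided range", {
  df <- toy_samples()
  df$ni <- c(5, 15, 25)  # guideline 20
  expect_equal(exceedance_fraction(df, "ni"), 1 / 3)
  # ties are compliant
  df$ni <- c(20, 20, 20)
  expect_equal(exceedance_fraction(df, "ni"), 0)
  # pH outside [6.5, 8.5] on either side counts
  df$ph <- c(6.0, 7.0, 9.0)
  expect_equal(exceedance_fraction(df, "ph"), 2 / 3)
  expect_error(exceedance_fraction(df, "unobtainium"), "unknown parameter")
})

test_that("exceedance is monotone nonincreasing in the guideline", {
  ds <- fx$n30_default
  specs <- ds$specs
  fracs <- vapply(c(5, 15, 25, 40, 80), function(si) {
    specs$si[specs$parameter == "ni"] <- si
    exceedance_fraction(water_dataset(ds$samples, specs), "ni")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("guideline screening summarises all fifteen parameters", {
  sc <- screen_guidelines(fx$n30_default)
  expect_equal(nrow(sc), 15)
  expect_true(all(sc$exceedance_fraction >= 0 & sc$exceedance_fraction <= 1))
  expect_equal(sc$exceedance_percent, sc$exceedance_fraction * 100)
})
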