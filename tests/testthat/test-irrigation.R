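test_that("the five indices match hand arithmetic", {
  expect_equal(sar(4, 2, 2), 2.0)
  expect_equal(sar(0, 2, 2), 0)
  expect_equal(sar(4, 2, 2, convention = "standard"), 4 / sqrt(2))
  expect_equal(na_percent(3, 1, 4, 2), 40.0)
  expect_equal(na_percent(3, 1, 0, 0), 100.0)
  expect_equal(na_percent(0, 0, 4, 2), 0.0)
  expect_equal(rsc(5, 0, 2, 1), 2.0)
  expect_equal(rsc(2, 1, 2, 1), 0)
  expect_equal(rsc(1, 0, 3, 1), -3.0)
  expect_equal(mar(1, 1), 50.0)
  expect_equal(mar(3, 0), 0.0)
  expect_equal(mar(3, 1), 25.0)
  expect_equal(kelly_ratio(2, 1, 1), 1.0)
  expect_equal(kelly_ratio(0, 1, 1), 0)
  expect_equal(kelly_ratio(6, 2, 1), 2.0)
})

test_that("zero alkaline-earth denominators give NA, not errors", {
  expect_true(is.na(sar(4, 0, 0)))
  expect_true(is.na(mar(0, 0)))
  expect_true(is.na(kelly_ratio(4, 0, 0)))
  expect_true(is.na(na_percent(0, 0, 0, 0)))
})

test_that("indices scale as expected under uniform cation scaling", {
  na <- 3.2; k <- 0.8; ca <- 2.5; mg <- 1.5; kf <- 4
  # ratio indices are scale-invariant
  expect_equal(na_percent(kf * na, kf * k, kf * ca, kf * mg),
               na_percent(na, k, ca, mg))
  expect_equal(mar(kf * ca, kf * mg), mar(ca, mg))
  expect_equal(kelly_ratio(kf * na, kf * ca, kf * mg),
               kelly_ratio(na, ca, mg))
  # SAR scales by sqrt(k)
  expect_equal(sar(kf * na, kf * ca, kf * mg), sqrt(kf) * sar(na, ca, mg))
})

test_that("Na% decomposition: the complement is the Ca+Mg cation share", {
  na <- 2.1; k <- 0.4; ca <- 3.3; mg <- 1.2
  expect_equal(100 - na_percent(na, k, ca, mg),
               100 * (ca + mg) / (na + k + ca + mg))
})

test_that("salinity and sodium classes partition with lower-inclusive bounds", {
  expect_equal(as.character(classify_salinity(c(426, 250, 3000, 0, 749, 750,
                                                2249, 2250))),
               c("C2", "C2", "C4", "C1", "C2", "C3", "C3", "C4"))
  expect_equal(as.character(classify_sodium(c(13.51, 18, 5, 0, 9.99, 10,
                                              25.9, 26))),
               c("S2", "S3", "S1", "S1", "S1", "S2", "S3", "S4"))
  # every nonnegative value maps to exactly one class
  grid <- seq(0, 5000, by = 0.5)
  expect_false(anyNA(classify_salinity(grid)))
  grid <- seq(0, 60, by = 0.01)
  expect_false(anyNA(classify_sodium(grid)))
})

test_that("suitability verdicts follow the published cut-offs", {
  expect_equal(classify_suitability("na_percent", c(10, 40, 70)),
               c("suitable", "marginal", "unsuitable"))
  expect_equal(classify_suitability("rsc", c(1.0, 2.0, 3.0)),
               c("suitable", "marginal", "unsuitable"))
  expect_equal(classify_suitability("mar", c(50, 50.1)),
               c("suitable", "unsuitable"))
  expect_equal(classify_suitability("kr", c(0.5, 2, 4)),
               c("suitable", "marginal", "unsuitable"))
  expect_error(classify_suitability("nope", 1), "unknown index")
})

test_that("per-sample assessment converts to meq/L and is internally consistent", {
  ir <- irrigation_assess(toy_samples())
  # T1: na=1, k=1, ca=2, mg=2, hco3=1, cl=1, so4=1 meq/L
  expect_equal(ir$sar[1], 1 / sqrt(4))
  expect_equal(ir$na_percent[1], 2 * 100 / 6)
  expect_equal(ir$rsc[1], 1 - 4)
  expect_equal(ir$mar[1], 50)
  expect_equal(ir$kr[1], 1 / 4)
  expect_equal(ir$salinity_class, c("C1", "C2", "C4"))
  # standard convention divides Ca+Mg by 2 inside the root
  ir_std <- irrigation_assess(toy_samples(), sar_convention = "standard")
  expect_equal(ir_std$sar, ir$sar * sqrt(2))
  # summary counts total to n per hazard
  sm <- irrigation_summary(ir)
  expect_equal(sum(sm$n[sm$hazard == "salinity"]), 3)
  expect_equal(sum(sm$n[sm$hazard == "alkalinity"]), 3)
})
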