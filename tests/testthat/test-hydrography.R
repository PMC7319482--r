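test_that("cast preprocessing keeps the descending limb and bin-averages", {
  # V-shaped trace: down then up; only the descending limb is retained
  down <- seq(0.1, 10, by = 0.1)
  up <- seq(10, 0.1, by = -0.25)
  raw <- data.frame(depth_m = c(down, up),
                    temperature_c = c(rep(10, length(down)),
                                      rep(20, length(up))),
                    sigma_kg_m3 = 25)
  prof <- preprocess_cast(raw)
  expect_true(all(prof$temperature_c == 10))
  # two samples in one bin average
  raw2 <- data.frame(depth_m = c(seq(0.2, 1.6, 0.2), 1.95, 2.05),
                     temperature_c = c(rep(5, 8), 10.0, 10.2),
                     sigma_kg_m3 = 25)
  prof2 <- preprocess_cast(raw2)
  expect_equal(prof2$temperature_c[prof2$depth_m == 2], 10.1)
  # grouping oracle on a synthetic cast
  set.seed(1)
  z <- sort(runif(60, 0.1, 12))
  tc <- 15 - 0.3 * z + rnorm(60, sd = 0.1)
  raw3 <- data.frame(depth_m = z, temperature_c = tc, sigma_kg_m3 = 24)
  prof3 <- preprocess_cast(raw3)
  oracle <- tapply(tc, round(z / 0.2) * 0.2, mean)
  expect_equal(prof3$temperature_c,
               as.numeric(oracle[as.character(prof3$depth_m)]))
  expect_error(preprocess_cast(raw3[1:5, ]), "10")
})

test_that("density profiles classify into the three stratification classes", {
  z <- seq(0.2, 15, 0.2)
  uniform <- data.frame(depth_m = z, sigma_kg_m3 = 24.5)
  expect_equal(as.character(classify_stratification(uniform)), "well_mixed")
  step6 <- data.frame(depth_m = z, sigma_kg_m3 = 24.5 + 0.3 * (z > 6))
  expect_equal(as.character(classify_stratification(step6)),
               "stratified_below_3m")
  surf <- data.frame(depth_m = z, sigma_kg_m3 = 24.5 + 0.3 * (z > 1.5))
  expect_equal(as.character(classify_stratification(surf)), "surface_only")
  # invariant to adding a constant to the whole profile
  for (prof in list(uniform, step6, surf)) {
    shifted <- transform(prof, sigma_kg_m3 = sigma_kg_m3 + 3.7)
    expect_identical(as.character(classify_stratification(shifted)),
                     as.character(classify_stratification(prof)))
  }
})

test_that("temperature-density regression recovers a printed calibration line", {
  dsig <- seq(-0.5, 0.1, by = 0.01)
  dth <- -0.0354 - 3.24 * dsig
  f <- regress_theta_sigma(dsig, dth)
  expect_equal(f$slope, -3.24, tolerance = 1e-10)
  expect_equal(f$intercept, -0.0354, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # degenerate cases
  fc <- regress_theta_sigma(dsig, rep(1, length(dsig)))
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 0, tolerance = 1e-12)
  fz <- regress_theta_sigma(rep(0.1, 5), 1:5)
  expect_identical(fz$flag, "zero_variance")
  # noisy line: slope within 3 SE of truth
  set.seed(2)
  x <- runif(1e4, -0.5, 0)
  yy <- -0.0354 - 3.24 * x + rnorm(1e4, sd = 0.2)
  fn <- regress_theta_sigma(x, yy)
  se <- 0.2 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fn$slope + 3.24), 3 * se)
})

test_that("daily stratification applies the strict two-thirds daylight rule", {
  daylight <- c(rep(FALSE, 6), rep(TRUE, 12), rep(FALSE, 6))
  all_high <- rep(1.0, 24)
  expect_true(daily_stratification(all_high, daylight)$daily_flag)
  all_low <- rep(0.5, 24)
  expect_false(daily_stratification(all_low, daylight)$daily_flag)
  # exactly two-thirds is NOT stratified (strict inequality)
  dth <- rep(0, 24)
  dth[daylight][1:8] <- 1.0       # 8 of 12 = 2/3 exactly
  r <- daily_stratification(dth, daylight)
  expect_equal(r$frac_stratified, 2 / 3)
  expect_false(r$daily_flag)
  dth[daylight][9] <- 1.0         # 9 of 12 > 2/3
  expect_true(daily_stratification(dth, daylight)$daily_flag)
  # missing hours leave numerator and denominator; no data -> NA not FALSE
  dth_na <- rep(NA_real_, 24)
  rna <- daily_stratification(dth_na, daylight)
  expect_true(is.na(rna$daily_flag))
  # monotone: raising any hour never flips stratified -> not stratified
  set.seed(3)
  for (r in 1:20) {
    base <- runif(24, 0, 1.2)
    before <- daily_stratification(base, daylight)$daily_flag
    i <- sample(24, 1)
    base[i] <- base[i] + 1
    after <- daily_stratification(base, daylight)$daily_flag
    expect_false(isTRUE(before) && !isTRUE(after))
  }
})

test_that("temperature gap filling is regression-adjusted and provenance-flagged", {
  n <- 24 * 70
  month <- rep(1:3, length.out = n)
  sec <- 10 + sin(seq_len(n) / 50)
  # identity relationship
  pri <- sec
  pri[c(100:120, 900:920)] <- NA
  out <- fill_temperature_gaps(pri, sec, month)
  expect_equal(out$filled[100:120], sec[100:120], tolerance = 1e-9)
  expect_true(all(out$source[100:120] == "secondary"))
  # exact affine offset recovered
  pri2 <- sec + 1.5
  pri2[200:260] <- NA
  out2 <- fill_temperature_gaps(pri2, sec, month)
  expect_equal(out2$filled[200:260], sec[200:260] + 1.5, tolerance = 1e-9)
  # non-missing primary values never altered
  expect_identical(out2$filled[-(200:260)], pri2[-(200:260)])
  # held-out accuracy: RMSE of filled values <= noise SD
  set.seed(4)
  truth <- 12 + 2 * sin(seq_len(n) / 300)
  sec3 <- truth - 0.8 + rnorm(n, sd = 0.3)
  pri3 <- truth
  holes <- sample(n, 300)
  pri3[holes] <- NA
  out3 <- fill_temperature_gaps(pri3, sec3, month)
  rmse <- sqrt(mean((out3$filled[holes] - truth[holes])^2))
  expect_lte(rmse, 0.3 * 1.05)
  # tertiary spot values fill what regression cannot
  sec4 <- sec
  sec4[500:505] <- NA
  pri4 <- sec
  pri4[500:505] <- NA
  ter <- rep(NA_real_, n)
  ter[500:505] <- 7
  out4 <- fill_temperature_gaps(pri4, sec4, month, tertiary = ter)
  expect_true(all(out4$filled[500:505] == 7))
  expect_true(all(out4$source[500:505] == "tertiary"))
})
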