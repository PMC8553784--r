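years_ctl <- 1801:2100

test_that("control statistics recover known slope, mean and noise", {
  # pure line: exact fit, zero residual noise -> error path
  line <- 2 + 0.01 * (years_ctl - 1801)
  expect_error(control_stats(line, years_ctl), "noise")
  # white noise of unit variance
  set.seed(101)
  st <- control_stats(rnorm(300, mean = 5, sd = 1), years_ctl)
  expect_equal(st$sd, 1, tolerance = 0.1)
  expect_equal(st$mean, 5, tolerance = 0.15)
  expect_equal(st$slope, 0, tolerance = 0.002)
  # AR(1) with marginal SD 1 by the closed form innov_sd / sqrt(1 - phi^2)
  set.seed(202)
  reps <- replicate(200, {
    e <- as.numeric(stats::filter(rnorm(300, 0, 0.8), 0.6, method = "recursive"))
    control_stats(e, years_ctl)$sd
  })
  expect_equal(mean(reps), 0.8 / sqrt(1 - 0.36), tolerance = 0.03)
  expect_error(control_stats(rnorm(10), 1:10), ">= 30")
})

test_that("the hand-rolled column OLS agrees with lm", {
  set.seed(11)
  y <- 3 + 0.02 * (years_ctl - 1950) + rnorm(300)
  st <- control_stats(y, years_ctl)
  fit <- lm(y ~ I(years_ctl - mean(years_ctl)))
  expect_equal(st$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(st$mean, unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(st$sd, sd(residuals(fit)), tolerance = 1e-9)
})

test_that("anomalies detrend the control and expose scenario drift", {
  set.seed(33)
  ctl <- 4 + 0.005 * (years_ctl - 1801) + rnorm(300, 0, 0.3)
  st <- control_stats(ctl, years_ctl)
  anom <- toe_anomaly(ctl, years_ctl, st)
  expect_lt(abs(mean(anom)), 1e-10)
  expect_lt(abs(unname(coef(lm(anom ~ years_ctl))[2])), 1e-10)
  # a scenario with extra drift b' keeps residual slope b' - b
  scn <- ctl + 0.02 * (years_ctl - 1801)
  anom_s <- toe_anomaly(scn, years_ctl, st)
  expect_equal(unname(coef(lm(anom_s ~ years_ctl))[2]), 0.02, tolerance = 1e-10)
  # step perturbation passes through as a step
  stp <- ctl + ifelse(years_ctl >= 2000, 5, 0)
  expect_equal(toe_anomaly(stp, years_ctl, st) - anom,
               ifelse(years_ctl >= 2000, 5, 0))
})

test_that("boxcar smoothing matches the naive oracle including shrunk edges", {
  expect_equal(boxcar_smooth(rep(3, 40)), rep(3, 40))
  expect_identical(boxcar_smooth(1:10, window = 1), as.numeric(1:10))
  imp <- rep(0, 41); imp[21] <- 11
  sm <- boxcar_smooth(imp, 11)
  expect_equal(sm[16:26], rep(1, 11))
  expect_equal(sum(sm > 0), 11)
  set.seed(5)
  x <- rnorm(60)
  for (w in c(3, 7, 11)) {
    expect_equal(boxcar_smooth(x, w), oracle_boxcar(x, w), tolerance = 1e-12)
  }
  expect_error(boxcar_smooth(x, 10), "odd")
})

test_that("toe_year enforces persistent exceedance to the series end", {
  yrs <- 2000:2100
  expect_true(is.na(toe_year(rep(0, 101), yrs, noise_sd = 1)))
  a <- ifelse(yrs >= 2040, 3, 0)
  expect_identical(toe_year(a, yrs, noise_sd = 1, k = 2), 2040L)
  # temporary excursion 2030-2035 is rejected; 2050-on counts
  b <- ifelse(yrs %in% 2030:2035 | yrs >= 2050, 3, 0)
  expect_identical(toe_year(b, yrs, noise_sd = 1, k = 2), 2050L)
  # negative-going signals emerge on the absolute anomaly
  expect_identical(toe_year(-a, yrs, noise_sd = 1, k = 2), 2040L)
  # agreement with the enumeration oracle on random exceedance patterns
  set.seed(9)
  for (i in 1:25) {
    exc <- runif(30) > 0.4
    idx <- oracle_toe_index(exc)
    got <- toe_year(ifelse(exc, 10, 0), 1:30, noise_sd = 1, k = 2)
    expect_identical(got, if (is.na(idx)) NA_integer_ else as.integer(idx))
  }
})

test_that("noiseless ramps emerge at the analytic year", {
  yrs <- 1901:2100
  sd0 <- 0.5
  for (r in c(0.02, 0.05, 0.2)) {
    ramp <- pmax(0, yrs - 2000) * r
    expected <- yrs[which(ramp > 2 * sd0)[1]]  # monotone: persistence automatic
    expect_identical(toe_year(ramp, yrs, sd0, k = 2), as.integer(expected))
    expect_identical(as.integer(expected), as.integer(2000 + floor(2 * sd0 / r) + 1))
  }
})

test_that("toe_map applies the chain per cell and flags unusable cells", {
  spec <- synth_spec(nlat = 4, nlon = 6, years = 1901:2100, mean = 5,
                     phi = 0.3, innovation_sd = 0.1, onset_year = 2000,
                     ramp_rate = 0.05, amplitude = 1, seed = 77)
  ctl <- gen_control(spec)
  scn <- gen_scenario(spec)
  tm <- toe_map(scn, ctl)
  expect_true(all(!is.na(tm$toe)))          # strong ramps: everything emerges
  expect_true(all(tm$toe >= 1901 & tm$toe <= 2100))
  # single-cell grid reduces to the series chain
  one_ctl <- annual_grid(array(ctl$values[, 1, 1], c(200, 1, 1)), ctl$years, 0, 10)
  one_scn <- annual_grid(array(scn$values[, 1, 1], c(200, 1, 1)), scn$years, 0, 10)
  st <- control_stats(ctl$values[, 1, 1], ctl$years)
  manual <- toe_year(boxcar_smooth(toe_anomaly(scn$values[, 1, 1], scn$years, st)),
                     scn$years, st$sd, k = 2)
  expect_identical(toe_map(one_scn, one_ctl)$toe[1, 1], manual)
  expect_identical(manual, tm$toe[1, 1])
  # masked data yields missing, not a bogus year
  scn_na <- scn
  scn_na$values[10, 2, 3] <- NA
  tm_na <- toe_map(scn_na, ctl)
  expect_true(tm_na$missing[2, 3])
  expect_true(is.na(tm_na$toe[2, 3]))
  # geometry mismatch is structural
  off <- annual_grid(scn$values, scn$years, spec$lat + 1, spec$lon)
  expect_error(toe_map(off, ctl), "geometry")
})

test_that("scenario equal to a control realization almost never emerges", {
  spec <- synth_spec(nlat = 8, nlon = 8, years = 1801:2100, phi = 0.5,
                     innovation_sd = 0.1, ramp_rate = 0, seed = 1234)
  tm <- toe_map(gen_scenario(spec), gen_control(spec))
  expect_lt(sum(!is.na(tm$toe)) / length(tm$toe), 0.15)
})

test_that("emerged fraction is area-weighted and monotone", {
  toe <- matrix(c(1990L, NA), 1, 2)
  tm <- structure(list(toe = toe, missing = matrix(FALSE, 1, 2),
                       lat = 0, lon = c(0, 180),
                       weights = matrix(1, 1, 2), k = 2, window = 11,
                       end_year = 2100L), class = "toe_map")
  expect_equal(emerged_fraction(tm, 1980), 0)
  expect_equal(emerged_fraction(tm, 2000), 50)
  # two cells at different latitudes weight as cos(lat)
  toe2 <- matrix(c(2000L, NA), 2, 1)
  w <- cos(c(10, 60) * pi / 180)
  tm2 <- structure(list(toe = toe2, missing = matrix(FALSE, 2, 1),
                        lat = c(10, 60), lon = 0,
                        weights = matrix(w, 2, 1), k = 2, window = 11,
                        end_year = 2100L), class = "toe_map")
  expect_equal(emerged_fraction(tm2, 2050, region = c(-90, 90)),
               100 * w[1] / sum(w))
  # full-map monotonicity on synthetic output
  spec <- synth_spec(nlat = 6, nlon = 6, years = 1901:2100, phi = 0.4,
                     innovation_sd = 0.1, onset_year = 2000, ramp_rate = 0.02,
                     lat_range = c(-45, 45), seed = 3)
  tmf <- toe_map(gen_scenario(spec), gen_control(spec))
  curve <- emerged_fraction(tmf, 1901:2100)
  expect_true(all(diff(curve) >= 0))
  expect_true(all(curve >= 0 & curve <= 100))
  expect_error(emerged_fraction(tmf, 2000, region = c(89, 90)), "no usable")
})

test_that("pattern agreement is a Spearman rank correlation", {
  set.seed(8)
  a <- matrix(rnorm(40), 5)
  expect_equal(pattern_agreement(a, a), 1)
  expect_equal(pattern_agreement(a, -a), -1)
  expect_equal(pattern_agreement(a, exp(a)), 1)       # monotone transform
  b <- matrix(rnorm(40), 5)
  expect_equal(pattern_agreement(a, b),
               cor(as.vector(a), as.vector(b), method = "spearman"))
  a_na <- a; a_na[1, 1] <- NA
  expect_equal(pattern_agreement(a_na, b),
               cor(as.vector(a_na[-1 * 1]), as.vector(b[-1]), method = "spearman"))
  expect_error(pattern_agreement(matrix(1:2), matrix(2:1)), "at least 3")
})
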