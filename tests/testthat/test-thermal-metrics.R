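test_that("series validation interpolates short gaps and rejects long ones", {
  weeks <- seq(as.Date("2000-01-03"), by = 7L, length.out = 10L)
  s <- sst_series("X", weeks[-4], (29 + seq_len(10) / 10)[-4])
  expect_equal(length(s$sst), 10L)
  expect_equal(s$sst[4], 29.4)  # linear between 29.3 and 29.5

  expect_error(sst_series("X", weeks[-(4:6)], rnorm(7, 29)),
               "more than 2 missing weeks")
  expect_error(sst_series("X", c(weeks[1], weeks[2] + 3), c(29, 29)),
               "7-day grid")
})

test_that("SST series round-trip through delimited text", {
  s <- make_sst(29 + sin(1:60 / 5))
  path <- tempfile(fileext = ".csv")
  write_sst_series(list(s), path)
  back <- read_sst_series(path, baseline = s$baseline)[[1]]
  expect_equal(back$sst, s$sst)
  expect_equal(back$week_start, s$week_start)
})

test_that("monthly climatology and MMM match a brute-force month oracle", {
  const <- make_sst(rep(29, 106), baseline = c(2000, 2001))
  clim <- monthly_climatology_mmm(const)
  expect_true(all(clim$monthly_means == 29))
  expect_equal(clim$MMM, 29)

  # sinusoid peaking in April: MMM equals the April bin mean
  weeks <- seq(as.Date("2000-01-03"), by = 7L, length.out = 313L)
  doy <- as.numeric(format(weeks, "%j"))
  sst <- 29 + cos(2 * pi * (doy - 105) / 365.25)
  s <- sst_series("X", weeks, sst, baseline = c(2000, 2005))
  clim2 <- monthly_climatology_mmm(s)
  mon <- as.integer(format(weeks, "%m"))
  yr <- as.integer(format(weeks, "%Y"))
  base <- yr <= 2005
  oracle <- vapply(1:12, function(m) mean(sst[base & mon == m]), numeric(1))
  expect_equal(unname(clim2$monthly_means), oracle)
  expect_equal(clim2$MMM, oracle[4])

  one_year <- make_sst(rep(29, 52), baseline = c(2000, 2000))
  expect_error(monthly_climatology_mmm(one_year), "complete years")
})

test_that("DHW accumulates thresholded hotspots over a trailing window", {
  flat <- make_sst(rep(29, 30))
  expect_true(all(dhw_series(flat, mmm = 29) == 0))

  pulse <- rep(29, 30); pulse[1:4] <- 31
  d <- dhw_series(make_sst(pulse), mmm = 29)
  expect_equal(d[4], 8)
  expect_equal(d[15], 2)   # week 4 hotspot still inside the 12-week window
  expect_equal(d[16], 0)

  warm <- make_sst(rep(29.5, 30))
  expect_true(all(dhw_series(warm, mmm = 29) == 0))
})

test_that("DHW equals the brute-force rolling-sum oracle on random series", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(30:200, 1)
    sst <- 29 + rnorm(n, sd = 1.5)
    mmm <- 29 + runif(1, -0.5, 0.5)
    s <- make_sst(sst)
    expect_identical(dhw_series(s, mmm), dhw_oracle(sst, mmm))
  }
})

test_that("DHW is invariant to joint translation of SST and MMM", {
  set.seed(32)
  sst <- 29 + rnorm(100, sd = 1.2)
  d0 <- dhw_series(make_sst(sst), mmm = 29)
  d_shift <- dhw_series(make_sst(sst + 3.7), mmm = 32.7)
  expect_equal(d_shift, d0)
  # warming SST alone weakly increases every DHW value
  d_warm <- dhw_series(make_sst(sst + 0.6), mmm = 29)
  expect_true(all(d_warm >= d0))
})

test_that("event metrics count exceedance weeks within the window", {
  pulse <- rep(29, 40); pulse[5:12] <- 31
  s <- make_sst(pulse)
  d <- dhw_series(s, mmm = 29)
  ev <- event_stress_metrics(s, d, c(s$week_start[1], s$week_start[40]))
  expect_equal(ev$MaxSST_event, 31)
  expect_equal(ev$MaxDHW_event, 16)
  expect_equal(ev$WkDHW4, sum(d > 4))
  expect_equal(ev$weeks_alert1, sum(d >= 4))
  expect_true(ev$WkDHW8 <= ev$WkDHW4)

  calm <- event_stress_metrics(s, d, c(s$week_start[30], s$week_start[40]))
  expect_equal(calm$MaxDHW_event, 0)
  expect_equal(calm$WkDHW4, 0)
  expect_error(event_stress_metrics(s, d, as.Date(c("2050-01-01",
                                                    "2050-02-01"))),
               "no weeks")
})

test_that("historical metrics: degenerate, planted and hand-computed cases", {
  const <- make_sst(rep(29, 52 * 6), baseline = c(2000, 2005))
  h <- historical_climate_metrics(const, min_years = 5L)
  expect_equal(h$CV_SST, 0)
  expect_equal(h$sigma_wk, 0)
  expect_equal(h$fDHW4, 0)

  # plant DHW > 4 in exactly 3 of 10 years
  weeks <- seq(as.Date("2000-01-03"), by = 7L, length.out = 522L)
  sst <- rep(29, 522)
  yr <- as.integer(format(weeks, "%Y"))
  for (y in c(2001, 2004, 2008)) sst[which(yr == y)[20:25]] <- 31
  s <- sst_series("X", weeks, sst, baseline = c(2000, 2009))
  # hold MMM at the flat level so the planted pulses are the only hotspots
  d <- dhw_series(s, mmm = 29)
  ann_max <- tapply(d, yr, max)[as.character(2000:2009)]
  expect_equal(unname(mean(ann_max > 4)), 0.3)
  expect_equal(historical_climate_metrics(s, min_years = 5L)$fDHW4, 0.3)

  # two years with annual weekly maxima 30 and 31: sigma_wk = sd(c(30,31))
  sst2 <- rep(29, 104)
  sst2[20] <- 30; sst2[72] <- 31
  s2 <- make_sst(sst2, baseline = c(2000, 2001))
  h2 <- historical_climate_metrics(s2, min_years = 2L)
  expect_equal(h2$sigma_wk, sd(c(30, 31)))
  expect_equal(h2$sigma_wk, 0.7071068, tolerance = 1e-6)
  expect_equal(h2$MaxSST_avg, 30.5)

  expect_error(historical_climate_metrics(const, min_years = 10L),
               "baseline years")
})
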