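# Independent oracle: explicit double loop over all i < j pairs.
sens_slope_bruteforce <- function(values, times) {
  slopes <- c()
  n <- length(values)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    slopes <- c(slopes, (values[j] - values[i]) / (times[j] - times[i]))
  median(slopes)
}

test_that("Sen's slope equals the pairwise-median oracle", {
  expect_equal(sens_slope(c(1, 2, 3, 4)), 1)
  expect_equal(sens_slope(rep(2.5, 7)), 0)
  # enumerated pairs of x = (1, 3, 2): slopes {2, 0.5, -1}, median 0.5
  expect_equal(sens_slope(c(1, 3, 2), c(1, 2, 3)), 0.5)

  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    x <- rnorm(n)
    t <- sort(sample(1:100, n))
    expect_identical(sens_slope(x, t), sens_slope_bruteforce(x, t))
  }

  # exact linear series recover their slope to machine precision,
  # irregular spacing included
  t <- c(1, 2, 5, 9, 10)
  expect_equal(sens_slope(3 - 0.27 * t, t), -0.27, tolerance = 1e-14)

  expect_error(sens_slope(1), class = "fireveg_input_error")
  expect_error(sens_slope(c(1, 2), c(3, 3)), class = "fireveg_input_error")
})

test_that("annual max composite is nodata-aware", {
  r <- function(v) index_raster(matrix(v, 1, 2), index_name = "EVI")
  out <- annual_max_composite(list(r(c(0.2, NA)), r(c(0.5, NA)), r(c(NA, 0.1))),
                              years = c(2001, 2001, 2002))
  expect_equal(out$years, c(2001L, 2002L))
  expect_equal(out$rasters[[1]]$values[1, 1], 0.5)   # max over valid values
  expect_true(is.na(out$rasters[[1]]$values[1, 2]))  # all-invalid -> nodata
  expect_equal(out$rasters[[2]]$values[1, 2], 0.1)   # single raster: identity

  # month filter restricts the composite
  out2 <- annual_max_composite(list(r(c(0.2, 0.2)), r(c(0.5, 0.5))),
                               years = c(2001, 2001), months = c(6, 12),
                               month_filter = 6)
  expect_equal(out2$rasters[[1]]$values[1, 1], 0.2)
})

test_that("slope raster matches the per-pixel brute-force oracle", {
  set.seed(8)
  years <- 2001:2008
  stack <- lapply(years, function(y)
    index_raster(matrix(runif(256, -0.5, 0.5), 16, 16), index_name = "EVI"))
  sl <- slope_raster(stack, years)
  V <- vapply(stack, function(r) as.vector(r$values), numeric(256))
  for (px in sample(256, 40)) {
    expect_equal(sl$values[px], sens_slope_bruteforce(V[px, ], years),
                 tolerance = 1e-12)
  }

  # pixel valid in < 2 years is nodata
  stack2 <- stack[1:2]
  stack2[[1]]$values[1, 1] <- NA
  sl2 <- slope_raster(stack2, 2001:2002)
  expect_true(is.na(sl2$values[1, 1]))
  expect_error(slope_raster(stack[1], 2001), class = "fireveg_input_error")
})

test_that("greening/browning fractions, areas, and the neutral band behave", {
  sl <- matrix(c(rep(0.01, 60), rep(-0.01, 40)), 10, 10)
  s <- greening_browning(sl, zero_band = 0, pixel_size_m = 250)
  expect_equal(s$greening_fraction, 0.6)
  expect_equal(s$browning_fraction, 0.4)
  expect_equal(s$greening_fraction + s$browning_fraction + s$neutral_fraction, 1)
  # 16 greening pixels at 250 m are exactly 1 km2
  s16 <- greening_browning(matrix(0.02, 4, 4), pixel_size_m = 250)
  expect_equal(s16$greening_km2, 1)
  # areas scale quadratically with pixel size
  s2 <- greening_browning(sl, pixel_size_m = 500)
  expect_equal(s2$greening_km2, 4 * s$greening_km2)
  # all slopes inside the neutral band
  s0 <- greening_browning(matrix(0.001, 3, 3), zero_band = 0.01)
  expect_equal(s0$greening_fraction, 0)
  expect_equal(s0$browning_fraction, 0)
  # empty raster
  se <- greening_browning(matrix(NA_real_, 2, 2))
  expect_equal(se$greening_fraction, 0)
})

test_that("slope histogram conserves counts and finds the bimodal pattern", {
  sl <- matrix(c(rep(0.01, 60), rep(-0.01, 40)), 10, 10)
  f <- withr::local_tempfile(fileext = ".png")
  h <- slope_histogram(sl, bins = 20, path = f)
  expect_equal(sum(h$count), 100)
  expect_true(file.exists(f))
  occupied <- h$mid[h$count > 0]
  expect_length(occupied, 2)
  expect_equal(sort(h$count[h$count > 0]), c(40, 60))

  hc <- slope_histogram(matrix(0.5, 3, 3), bins = 10)
  expect_equal(sum(hc$count > 0), 1)  # constant raster: one occupied bin
})

test_that("regional trend export writes one CSV row per year", {
  years <- 2001:2005
  stack <- lapply(seq_along(years), function(i)
    index_raster(matrix(0.1 * i, 4, 4), index_name = "EVI"))
  fp <- withr::local_tempfile(fileext = ".png")
  fc <- withr::local_tempfile(fileext = ".csv")
  df <- evi_trend_plot(stack, years, png_path = fp, csv_path = fc)
  expect_equal(nrow(read.csv(fc)), 5)
  expect_equal(df$mean_index, 0.1 * 1:5)      # spatial mean of constant rasters
  expect_true(all(diff(df$mean_index) > 0))   # monotone stack stays monotone
  expect_true(file.exists(fp))
})
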