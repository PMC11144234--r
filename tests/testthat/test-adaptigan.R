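test_that("gan config validates architectural constraints", {
  expect_error(gan_config(image_size = 20), class = "fireveg_config_error")
  expect_error(gan_config(n_down = 2), class = "fireveg_config_error")
  expect_error(gan_config(attention_after = 5, n_down = 4,
                          image_size = 64), class = "fireveg_config_error")
  expect_error(gan_config(dropout_rate = 1), class = "fireveg_config_error")
  expect_s3_class(gan_config(image_size = 64, n_down = 4), "gan_config")
})

test_that("generator preserves shape, bounds output via tanh, and starts gated", {
  cfg <- gan_config(image_size = 32, base_channels = 4, dropout_rate = 0,
                    seed = 2)
  set.seed(2)
  G <- build_generator(cfg)
  x <- array(runif(32 * 32 * 2, -1, 1), c(32, 32, 1, 2))
  out <- fireveg:::gen_fw(G, x)$y
  expect_equal(dim(out), c(32L, 32L, 1L, 2L))
  expect_true(all(out > -1 & out < 1))   # strictly inside the tanh range
  # attention gate initialized at 0: block output equals block input
  expect_identical(G$params$attn$gamma, 0)
  h <- array(rnorm(4 * 4 * 16 * 1), c(4, 4, 16, 1))
  at <- fireveg:::attn_fw(h, G$params$attn)
  expect_equal(at$y, h)
})

test_that("discriminator emits the closed-form patch logit map", {
  cfg <- gan_config(image_size = 64, base_channels = 4, seed = 3)
  set.seed(3)
  D <- build_discriminator(cfg)
  # 64 -> 32 -> 16 -> 8 by three stride-2 convs; final stride-1 conv keeps 8x8
  o <- fireveg:::disc_fw(D, array(0.5, c(64, 64, 2, 1)))$y
  expect_equal(dim(o), c(8L, 8L, 1L, 1L))
  # finite logits at extreme inputs
  for (v in c(-1, 1)) {
    oe <- fireveg:::disc_fw(D, array(v, c(64, 64, 2, 1)))$y
    expect_true(all(is.finite(oe)))
  }
  # leaky slope 0.2: activation of -1 pre-norm is -0.2
  expect_equal(fireveg:::lrelu_fw(-1, 0.2)$y, -0.2)
  expect_error(build_discriminator(gan_config(image_size = 8, n_down = 3,
                                              seed = 1)),
               class = "fireveg_config_error")
})

test_that("smoke training reduces generator loss deterministically", {
  rp <- make_recovery_pairs(24, size = 16, seed = 5, noise_sd = 0.02)
  cfg <- gan_config(image_size = 16, base_channels = 4, epochs = 8, batch = 8,
                    lr_g = 2e-3, lr_d = 2e-3, seed = 6)
  m1 <- train_adaptigan(rp$pairs, cfg)
  expect_lt(tail(m1$loss_log$loss_g, 1), m1$loss_log$loss_g[1])
  expect_true(all(is.finite(as.matrix(m1$loss_log[-1]))))
  # bitwise-identical loss log under the same seed
  set.seed(4242)
  m2 <- train_adaptigan(rp$pairs, cfg)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_error(train_adaptigan(list(), cfg), class = "fireveg_input_error")
  expect_error(train_adaptigan(rp$pairs, gan_config(image_size = 32, seed = 1)),
               class = "fireveg_input_error")
})

test_that("recovery-map inference is deterministic, bounded, and tiles", {
  rp <- make_recovery_pairs(24, size = 16, seed = 5)
  cfg <- gan_config(image_size = 16, base_channels = 4, epochs = 5, batch = 8,
                    seed = 6)
  model <- train_adaptigan(rp$pairs, cfg)
  r <- index_raster(rp$pairs[[1]]$input, index_name = "NDVI")
  a <- generate_recovery_map(model, r)
  b <- generate_recovery_map(model, r)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= -1 & a$values <= 1))
  expect_equal(dim(a$values), dim(r$values))
  expect_true(all(a$level_map[!is.na(a$level_map)] %in% -1:2))
  # larger raster is tiled and stitched back to the input shape
  big <- index_raster(matrix(runif(24 * 40, -0.5, 0.5), 24, 40),
                      index_name = "NDVI")
  ab <- generate_recovery_map(model, big, levels = FALSE)
  expect_equal(dim(ab$values), c(24L, 40L))
  # nodata propagates; nodata-only input errors
  r2 <- r; r2$values[1:3, 1:3] <- NA
  am <- generate_recovery_map(model, r2, levels = FALSE)
  expect_true(all(is.na(am$values[1:3, 1:3])))
  expect_error(generate_recovery_map(model,
                                     index_raster(matrix(NA_real_, 16, 16))),
               class = "fireveg_input_error")
})

test_that("checkpoint archive restores identical inference", {
  rp <- make_recovery_pairs(12, size = 16, seed = 5)
  model <- train_adaptigan(rp$pairs,
                           gan_config(image_size = 16, base_channels = 4,
                                      epochs = 3, batch = 6, seed = 6))
  dir <- withr::local_tempdir()
  save_adaptigan(model, dir)
  m2 <- load_adaptigan(dir)
  r <- index_raster(rp$pairs[[2]]$input, index_name = "NDVI")
  expect_identical(generate_recovery_map(m2, r, levels = FALSE)$values,
                   generate_recovery_map(model, r, levels = FALSE)$values)
})

test_that("regression metrics obey their identities", {
  set.seed(10)
  a <- matrix(runif(100, -1, 1), 10, 10)
  # y == y_hat: every metric 0
  m0 <- regression_metrics(a, a)
  expect_equal(unlist(m0[c("mae", "mse", "msle", "rmse", "huber")]),
               c(mae = 0, mse = 0, msle = 0, rmse = 0, huber = 0))
  # single-residual Huber branches
  one <- function(r) regression_metrics(matrix(r), matrix(0), delta = 1)$huber
  expect_equal(one(0.5), 0.125)           # quadratic branch r^2/2
  expect_equal(one(3), 1 * (3 - 0.5))     # linear branch delta(|r| - delta/2)
  # branch continuity at |r| = delta: both give delta^2/2
  d <- 0.7
  expect_equal(regression_metrics(matrix(d), matrix(0), delta = d)$huber,
               d^2 / 2, tolerance = 1e-12)
  # rmse^2 = mse
  b <- matrix(runif(100, -1, 1), 10, 10)
  m <- regression_metrics(a, b)
  expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
  # huber -> mse/2 as delta -> Inf; -> delta*mae - delta^2/2 for residuals >> delta
  expect_equal(regression_metrics(a, b, delta = 1e6)$huber, m$mse / 2,
               tolerance = 1e-9)
  big <- matrix(100 + runif(25), 5, 5)
  mb <- regression_metrics(big, matrix(0, 5, 5), delta = 0.5)
  expect_equal(mb$huber, 0.5 * mb$mae - 0.125, tolerance = 1e-9)
  # masked pixels are excluded
  a[1, 1] <- NA
  expect_no_error(regression_metrics(a, b))
  expect_error(regression_metrics(a, matrix(0, 2, 2)),
               class = "fireveg_input_error")
})

test_that("homoscedasticity check separates null from heteroscedastic data", {
  set.seed(31)
  reps <- 40
  p_null <- p_het <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(1000 + i)
    f <- runif(500, 1, 3)
    p_null[i] <- homoscedasticity_check(rnorm(500), f)$p_value
    p_het[i] <- homoscedasticity_check(rnorm(500, sd = sqrt(f)), f)$p_value
  }
  expect_gte(mean(p_null > 0.05), 0.9)
  expect_gte(mean(p_het <= 0.05), 0.9)

  # degenerate fitted values
  expect_identical(homoscedasticity_check(rnorm(50), rep(1, 50))$verdict,
                   "degenerate")
  expect_error(homoscedasticity_check(rnorm(10), rnorm(10)),
               class = "fireveg_input_error")
  # diagnostic plot lands on disk
  f <- withr::local_tempfile(fileext = ".png")
  homoscedasticity_check(rnorm(100), runif(100), plot_path = f)
  expect_true(file.exists(f))
})

test_that("statistic agrees with the studentized Breusch-Pagan reference", {
  set.seed(77)
  x <- runif(300)
  y <- 1 + 2 * x + rnorm(300, sd = 0.3 + 0.5 * x)
  fit <- lm(y ~ x)
  ours <- homoscedasticity_check(residuals(fit), fitted(fit))
  ref <- lmtest::bptest(fit, studentize = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-8)
})
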