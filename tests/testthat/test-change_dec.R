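test_that("patch extraction counts rows and handles masks", {
  v <- matrix(seq(0, 1, length.out = 16), 4, 4)
  r <- index_raster(v)
  # patch 1: rows equal pixel values
  f1 <- extract_patches(r, patch = 1)
  expect_equal(as.vector(f1), as.vector(v))
  # 4x4 raster, patch 3: 16 rows of width 9
  f3 <- extract_patches(r, patch = 3)
  expect_equal(dim(f3), c(16L, 9L))
  # centre column holds the pixel values (column-major order preserved)
  expect_equal(f3[, 5], as.vector(v))
  # fully masked raster: zero rows
  fm <- extract_patches(index_raster(matrix(NA_real_, 4, 4)), patch = 3)
  expect_equal(nrow(fm), 0)
  expect_error(extract_patches(r, patch = 2), class = "fireveg_input_error")
  # class map labels are scaled to [0, 1]
  cm <- class_map(matrix(4L, 4, 4))
  expect_equal(as.vector(extract_patches(cm, 1)), rep(1, 16))
})

test_that("sparsity penalties follow their algebraic forms", {
  cfg1 <- sparse_ae_config(sparsity_mode = "L1", lambda = 1)
  x0 <- matrix(0, 1, 2)
  # lambda = 0, perfect reconstruction: zero loss
  cfg0 <- sparse_ae_config(sparsity_mode = "L1", lambda = 0)
  expect_equal(sparse_ae_loss(x0, x0, matrix(5, 1, 1), cfg0), 0)
  # L1: lambda * sum |a|
  expect_equal(sparse_ae_loss(x0, x0, matrix(c(1, -2), 1, 2), cfg1), 3)
  # Bernoulli KL at rho 0.2, rho_hat 0.5
  cfgk <- sparse_ae_config(sparsity_mode = "KL", rho = 0.2, kl_weight = 1)
  expected <- 0.2 * log(0.2 / 0.5) + 0.8 * log(0.8 / 0.5)
  expect_equal(sparse_ae_loss(x0, x0, matrix(0.5, 1, 1), cfgk), expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.1927, tolerance = 1e-3)
  # zero at rho_hat == rho
  expect_equal(sparse_ae_loss(x0, x0, matrix(0.2, 1, 1), cfgk), 0,
               tolerance = 1e-12)
  # out-of-range rho_hat clamps instead of erroring
  expect_no_error(suppressMessages(
    sparse_ae_loss(x0, x0, matrix(0, 1, 1), cfgk)))
  # with both sparsity weights 0 the loss is the plain reconstruction error
  cfg_off <- sparse_ae_config(sparsity_mode = "L1", lambda = 0)
  xh <- matrix(c(0, 1), 1, 2)
  expect_equal(sparse_ae_loss(x0, xh, matrix(9, 1, 1), cfg_off),
               mean((x0 - xh)^2))
  expect_error(sparse_ae_loss(matrix(0, 1, 2), matrix(0, 2, 2),
                              matrix(0, 1, 1), cfg1),
               class = "fireveg_input_error")
})

test_that("sparse autoencoder trains down to the data and obeys its contracts", {
  # constant features: reconstruction goes to ~0
  f <- matrix(0.5, 300, 9)
  net <- train_sparse_ae(f, sparse_ae_config(hidden = c(6, 3),
                                             sparsity_mode = "L1", lambda = 0,
                                             epochs = 200, seed = 2))
  expect_lt(tail(net$trajectory, 1), 1e-4)
  expect_lte(tail(net$trajectory, 1), net$trajectory[1])
  # encoder maps input width to bottleneck width
  expect_equal(dim(ae_encode(net, f)), c(300L, 3L))

  # determinism: identical loss trajectory under a fixed seed
  set.seed(99)  # trajectory must not depend on ambient RNG state
  net2 <- train_sparse_ae(f, sparse_ae_config(hidden = c(6, 3),
                                              sparsity_mode = "L1", lambda = 0,
                                              epochs = 200, seed = 2))
  expect_identical(net$trajectory, net2$trajectory)

  # strong KL pull drags the designated layer's mean activation to rho
  set.seed(1)
  g <- matrix(runif(2000 * 6), 2000, 6)
  netk <- train_sparse_ae(g, sparse_ae_config(hidden = c(10, 3),
                                              kl_weight = 5, rho = 0.15,
                                              epochs = 150, seed = 9))
  expect_lt(abs(mean(ae_hidden(netk, g)) - 0.15), 0.1)

  expect_error(train_sparse_ae(matrix(0, 5, 2),
                               sparse_ae_config(hidden = c(4, 2))),
               class = "fireveg_config_error")
})

test_that("soft assignment is a row-stochastic t-kernel", {
  # equidistant point splits evenly
  q <- soft_assignment(matrix(c(0, 0), 1, 2),
                       rbind(c(1, 0), c(-1, 0)))
  expect_equal(as.vector(q), c(0.5, 0.5))
  # k = 1 collapses to certainty
  expect_equal(as.vector(soft_assignment(matrix(rnorm(10), 5, 2),
                                         matrix(0, 1, 2))), rep(1, 5))
  # a point at one centroid, far from the other
  q2 <- soft_assignment(matrix(c(0, 0), 1, 2),
                        rbind(c(0, 0), c(30, 0)))
  expect_gt(q2[1, 1], 0.99)
  # rows sum to 1 and q decreases with distance
  set.seed(3)
  z <- matrix(rnorm(60), 30, 2)
  mu <- matrix(rnorm(8), 4, 2)
  Q <- soft_assignment(z, mu, alpha = 1)
  expect_equal(rowSums(Q), rep(1, 30), tolerance = 1e-6)
  d2 <- as.matrix(dist(rbind(z[1, ], mu)))[1, -1]^2
  expect_equal(order(Q[1, ]), order(-d2))  # ascending q is descending distance
  expect_error(soft_assignment(z, mu[0, , drop = FALSE]),
               class = "fireveg_input_error")
})

test_that("target distribution sharpens assignments and fixes symmetric rows", {
  # symmetric row with equal frequencies is a fixed point
  Q <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(target_distribution(Q), Q)
  # frozen value from the q^2/f formula at equal frequencies
  Qr <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  P <- target_distribution(Qr)
  expect_equal(P[1, 1], 0.81 / (0.81 + 0.01), tolerance = 1e-12)
  expect_equal(P[1, 1], 0.988, tolerance = 1e-3)
  # one-hot rows are idempotent
  Q1 <- diag(2)
  expect_equal(target_distribution(Q1), Q1)
  # sharper than Q (entropy non-increasing) in the uniform-frequency case
  set.seed(4)
  Qs <- matrix(rexp(50 * 4), 50, 4); Qs <- Qs / rowSums(Qs)
  Qs <- rbind(Qs, Qs[, c(2, 1, 4, 3)], Qs[, c(3, 4, 1, 2)],
              Qs[, c(4, 3, 2, 1)])  # symmetrize cluster frequencies
  Ps <- target_distribution(Qs)
  ent <- function(M) -rowSums(M * log(pmax(M, 1e-12)))
  expect_true(all(ent(Ps) <= ent(Qs) + 1e-9))
  expect_equal(rowSums(Ps), rep(1, nrow(Ps)), tolerance = 1e-6)
  # zero column survives through the frequency floor
  expect_no_error(target_distribution(cbind(rep(1, 3), 0)))
})

test_that("DEC clustering gradients match finite differences", {
  set.seed(6)
  x <- matrix(runif(40), 10, 4)
  cfg <- sparse_ae_config(hidden = c(5, 2), epochs = 5, seed = 1)
  enc <- train_sparse_ae(x, cfg)
  mu <- matrix(rnorm(4), 2, 2)
  z <- ae_encode(enc, x)
  P <- target_distribution(soft_assignment(z, mu, 1))
  g <- fireveg:::dec_grad(enc, x, mu, P, 1)
  kl_at <- function(enc, mu) {
    z <- ae_encode(enc, x)
    Q <- soft_assignment(z, mu, 1)
    sum(P * (log(pmax(P, 1e-12)) - log(pmax(Q, 1e-12))))
  }
  eps <- 1e-6
  # centroid gradient
  for (i in 1:3) {
    mup <- mu; mup[i] <- mu[i] + eps
    mum <- mu; mum[i] <- mu[i] - eps
    expect_equal(g$grads$mu[i], (kl_at(enc, mup) - kl_at(enc, mum)) / (2 * eps),
                 tolerance = 1e-5)
  }
  # encoder weight gradient
  for (i in 1:3) {
    ep <- enc; ep$enc[[1]]$W[i] <- ep$enc[[1]]$W[i] + eps
    em <- enc; em$enc[[1]]$W[i] <- em$enc[[1]]$W[i] - eps
    expect_equal(g$grads$enc[[1]]$W[i],
                 (kl_at(ep, mu) - kl_at(em, mu)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("DEC separates Gaussian blobs and handles the n = k degenerate case", {
  b <- make_blobs(31)
  st <- train_dec(b$x, k = 3,
                  cfg = sparse_ae_config(hidden = c(16, 4), epochs = 200,
                                         seed = 1))
  acc <- perm3_accuracy(dec_predict(st, b$x), b$labels)
  expect_gte(acc, 0.95)
  expect_equal(rowSums(st$Q), rep(1, nrow(st$Q)), tolerance = 1e-6)
  expect_equal(rowSums(st$P), rep(1, nrow(st$P)), tolerance = 1e-6)

  # distinct points, k = n: each point its own cluster
  zz <- matrix(c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5, 0.9, 0.9, 0.9), 3, 3,
               byrow = TRUE)
  st2 <- train_dec(zz, k = 3, cfg = sparse_ae_config(hidden = c(4, 2),
                                                     epochs = 100,
                                                     batch_size = 3, seed = 5))
  expect_setequal(dec_predict(st2, zz), 1:3)
})

test_that("DEC checkpoints round-trip through the plain-text archive", {
  b <- make_blobs(7, n = 40)
  st <- train_dec(b$x, k = 3, cfg = sparse_ae_config(hidden = c(8, 2),
                                                     epochs = 30, seed = 2))
  dir <- withr::local_tempdir()
  save_dec(st, dir)
  st2 <- load_dec(dir)
  expect_equal(st2$mu, unname(st$mu), tolerance = 1e-12)
  expect_identical(dec_predict(st2, b$x), dec_predict(st, b$x))
  expect_equal(st2$k, 3)
})

test_that("change detection is null on identical scenes and symmetric on swap", {
  sc <- make_burn_pair(scene_config(size = 32, seed = 5))
  cfg <- sparse_ae_config(hidden = c(16, 4), epochs = 30, seed = 1)
  cm0 <- detect_change(sc$pre, sc$pre, cfg = cfg)
  expect_equal(sum(cm0$binary, na.rm = TRUE), 0)

  cm1 <- detect_change(sc$pre, sc$post, cfg = cfg)
  cm2 <- detect_change(sc$post, sc$pre, cfg = cfg)
  expect_identical(cm1$binary, cm2$binary)

  # changed pixels are a subset of unmasked pixels
  masked <- sc$pre
  masked$values[1:4, 1:4] <- NA
  cm3 <- detect_change(masked, sc$post, cfg = cfg)
  expect_true(all(is.na(cm3$binary[1:4, 1:4])))
  expect_false(anyNA(cm3$binary[10:20, 10:20]))

  expect_error(detect_change(sc$pre, index_raster(matrix(0, 2, 2))),
               class = "fireveg_input_error")
})

test_that("change overlay blends the highlight colour correctly", {
  v <- matrix(-1, 4, 4)  # black background
  r <- index_raster(v)
  cmap <- structure(list(binary = matrix(c(TRUE, rep(FALSE, 15)), 4, 4),
                         pixel_size_m = 250), class = "change_map")
  # alpha 1: changed pixel exactly the highlight colour
  o1 <- overlay_change(r, cmap, color = "red", alpha = 1)
  expect_equal(o1[1, 1, ], c(1, 0, 0))
  # alpha 0.5, white on black: mid-gray
  o2 <- overlay_change(r, cmap, color = "white", alpha = 0.5)
  expect_equal(o2[1, 1, ], c(0.5, 0.5, 0.5))
  # all-false map: grayscale render
  cmap$binary[] <- FALSE
  o3 <- overlay_change(r, cmap, alpha = 0.7)
  expect_equal(o3[, , 1], (v + 1) / 2)
  expect_equal(o3[, , 1], o3[, , 2])
  expect_error(overlay_change(r, cmap, alpha = 2), class = "fireveg_input_error")
})

test_that("change metrics satisfy the F1 identity and zero-division contract", {
  # hand-counted confusion table: TP 9, FP 1, FN 3, TN 7
  truth <- c(rep(TRUE, 12), rep(FALSE, 8))
  pred <- c(rep(TRUE, 9), rep(FALSE, 3), TRUE, rep(FALSE, 7))
  m <- change_metrics(truth, pred)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  expect_equal(m$accuracy, 16 / 20)
  # F1 identity on random maps
  set.seed(12)
  for (i in 1:20) {
    t <- runif(50) > 0.5; p <- runif(50) > 0.5
    mm <- suppressWarnings(change_metrics(t, p))
    if (mm$precision + mm$recall > 0)
      expect_equal(mm$f1, 2 * mm$precision * mm$recall / (mm$precision + mm$recall))
  }
  expect_warning(m0 <- change_metrics(c(TRUE, FALSE), c(FALSE, FALSE)),
                 "precision")
  expect_equal(m0$recall, 0)
})
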