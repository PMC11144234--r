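#' Recovery-mapping GAN configuration
#'
#' Desk-scale defaults: 32x32 tiles, 3 downsampling stages, 16 base channels.
#' `image_size` must be divisible by 2^`n_down`; the self-attention block
#' sits after downsampling stage `attention_after` (default 3).
#'
#' @param image_size Square input side (power of 2).
#' @param base_channels Channels after the first downsampling stage
#'   (doubling per stage).
#' @param n_down Downsampling stages (>= 3).
#' @param attention_after Stage index after which self-attention is applied.
#' @param dropout_rate Dropout rate in the decoding stages.
#' @param l2_weight Weight-decay coefficient on all conv weights.
#' @param rec_weight Weight of the L1 reconstruction term in the generator
#'   loss.
#' @param epochs,batch Training schedule.
#' @param lr_g,lr_d Adam learning rates for generator and discriminator.
#' @param seed RNG seed.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(image_size = 32, base_channels = 16, n_down = 3,
                       attention_after = 3, dropout_rate = 0.25,
                       l2_weight = 1e-4, rec_weight = 100, epochs = 30,
                       batch = 16, lr_g = 2e-3, lr_d = 2e-3, seed = 1) {
  if (n_down < 3) abort_config("'n_down' must be >= 3")
  if (image_size %% 2^n_down != 0)
    abort_config("'image_size' must be divisible by 2^n_down")
  if (attention_after > n_down)
    abort_config("'attention_after' must be <= n_down")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_config("'dropout_rate' must be in [0, 1)")
  structure(list(image_size = image_size, base_channels = base_channels,
                 n_down = n_down, attention_after = attention_after,
                 dropout_rate = dropout_rate, l2_weight = l2_weight,
                 rec_weight = rec_weight, epochs = epochs, batch = batch,
                 lr_g = lr_g, lr_d = lr_d, seed = seed),
            class = "gan_config")
}

#' Build the encoder-decoder generator
#'
#' `n_down` stride-2 3x3 convolutions (channels doubling, ReLU), a gated
#' self-attention residual block after stage `attention_after` (gate
#' initialized at 0 so the network starts as a plain encoder-decoder),
#' mirrored nearest-neighbour-upsample + conv stages with summation skip
#' connections, dropout after each skip merge, and a tanh-activated output
#' convolution producing one channel in (-1, 1).
#'
#' @param cfg A `gan_config`. Uses the current RNG state for initialization.
#' @return An object of class `gan_generator` (parameter list + config).
#' @export
build_generator <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$n_down) - 1)
  cin <- c(1, ch[-length(ch)])
  params <- list()
  for (i in seq_len(cfg$n_down))
    params[[paste0("enc", i)]] <- conv_init(3, cin[i], ch[i])
  params$attn <- attn_init(ch[cfg$attention_after])
  dec_out <- c(rev(ch)[-1], cfg$base_channels)  # mirrors encoder outputs
  dec_in <- rev(ch)
  for (i in seq_len(cfg$n_down))
    params[[paste0("dec", i)]] <- conv_init(3, dec_in[i], dec_out[i])
  params$out <- conv_init(3, cfg$base_channels, 1, gain = 1)
  structure(list(params = params, cfg = cfg), class = "gan_generator")
}

# x: (H, W, 1, N) in [-1, 1]. Returns y and caches for backward.
gen_fw <- function(G, x, train = FALSE) {
  cfg <- G$cfg; p <- G$params
  caches <- list()
  h <- x
  skips <- list()
  for (i in seq_len(cfg$n_down)) {
    cv <- conv_fw(h, p[[paste0("enc", i)]], stride = 2, pad = 1)
    ac <- relu_fw(cv$y)
    caches[[paste0("enc", i)]] <- list(conv = cv$cache, act = ac$cache)
    h <- ac$y
    if (i == cfg$attention_after) {
      at <- attn_fw(h, p$attn)
      caches$attn <- at$cache
      h <- at$y
    }
    skips[[i]] <- h
  }
  for (i in seq_len(cfg$n_down)) {
    up <- upsample_fw(h)
    cv <- conv_fw(up, p[[paste0("dec", i)]], stride = 1, pad = 1)
    ac <- relu_fw(cv$y)
    h <- ac$y
    skip_idx <- cfg$n_down - i            # encoder stage with matching shape
    if (skip_idx >= 1) h <- h + skips[[skip_idx]]
    dr <- dropout_fw(h, cfg$dropout_rate, train)
    caches[[paste0("dec", i)]] <- list(conv = cv$cache, act = ac$cache,
                                       drop = dr$cache, skip_idx = skip_idx)
    h <- dr$y
  }
  cv <- conv_fw(h, p$out, stride = 1, pad = 1)
  th <- tanh_fw(cv$y)
  caches$out <- list(conv = cv$cache, act = th$cache)
  list(y = th$y, caches = caches)
}

gen_bw <- function(G, caches, dy) {
  cfg <- G$cfg
  grads <- list()
  d <- tanh_bw(dy, caches$out$act)
  g <- conv_bw(d, caches$out$conv)
  grads$out <- list(W = g$dW, b = g$db)
  d <- g$dx
  skip_grads <- vector("list", cfg$n_down)
  for (i in rev(seq_len(cfg$n_down))) {
    cc <- caches[[paste0("dec", i)]]
    d <- dropout_bw(d, cc$drop)
    if (cc$skip_idx >= 1) {
      prev <- skip_grads[[cc$skip_idx]]
      skip_grads[[cc$skip_idx]] <- if (is.null(prev)) d else prev + d
    }
    d <- relu_bw(d, cc$act)
    g <- conv_bw(d, cc$conv)
    grads[[paste0("dec", i)]] <- list(W = g$dW, b = g$db)
    d <- upsample_bw(g$dx)
  }
  grads$attn <- list(Wq = G$params$attn$Wq * 0, Wk = G$params$attn$Wk * 0,
                     Wv = G$params$attn$Wv * 0, gamma = 0)
  for (i in rev(seq_len(cfg$n_down))) {
    sg <- skip_grads[[i]]
    if (!is.null(sg)) d <- d + sg
    if (i == cfg$attention_after) {
      ab <- attn_bw(d, caches$attn)
      grads$attn <- list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv,
                         gamma = ab$dgamma)
      d <- ab$dx
    }
    cc <- caches[[paste0("enc", i)]]
    d <- relu_bw(d, cc$act)
    g <- conv_bw(d, cc$conv)
    grads[[paste0("enc", i)]] <- list(W = g$dW, b = g$db)
    d <- g$dx
  }
  grads[names(G$params)]  # Adam pairs params and grads by position
}

#' Build the PatchGAN discriminator
#'
#' Three stride-2 3x3 leaky-ReLU (slope 0.2) convolutions with instance
#' normalization after convolutions 2 and 3, followed by a stride-1 3x3
#' convolution to a single-channel patch logit map (no global pooling):
#' each logit judges one local patch. The discriminator is conditional — it
#' sees the input composite and the candidate later composite as two
#' channels.
#'
#' @param cfg A `gan_config`. Uses the current RNG state for initialization.
#' @return An object of class `gan_discriminator`.
#' @export
build_discriminator <- function(cfg) {
  if (cfg$image_size < 16)  # must keep >= 2x2 spatial at the third conv
    abort_config("image smaller than the discriminator receptive field")
  C <- cfg$base_channels
  params <- list(
    c1 = conv_init(3, 2, C),
    c2 = conv_init(3, C, 2 * C), n2 = inorm_init(2 * C),
    c3 = conv_init(3, 2 * C, 4 * C), n3 = inorm_init(4 * C),
    c4 = conv_init(3, 4 * C, 1, gain = 1))
  structure(list(params = params, cfg = cfg), class = "gan_discriminator")
}

# x: (H, W, 2, N) = condition + candidate. Returns patch logits (H/8, W/8, 1, N).
disc_fw <- function(D, x) {
  p <- D$params
  c1 <- conv_fw(x, p$c1, stride = 2, pad = 1)
  a1 <- lrelu_fw(c1$y)
  c2 <- conv_fw(a1$y, p$c2, stride = 2, pad = 1)
  n2 <- inorm_fw(c2$y, p$n2)
  a2 <- lrelu_fw(n2$y)
  c3 <- conv_fw(a2$y, p$c3, stride = 2, pad = 1)
  n3 <- inorm_fw(c3$y, p$n3)
  a3 <- lrelu_fw(n3$y)
  c4 <- conv_fw(a3$y, p$c4, stride = 1, pad = 1)
  list(y = c4$y, caches = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                               n2 = n2$cache, a2 = a2$cache, c3 = c3$cache,
                               n3 = n3$cache, a3 = a3$cache, c4 = c4$cache))
}

disc_bw <- function(D, caches, dy) {
  g4 <- conv_bw(dy, caches$c4)
  d <- lrelu_bw(g4$dx, caches$a3)
  n3 <- inorm_bw(d, caches$n3)
  g3 <- conv_bw(n3$dx, caches$c3)
  d <- lrelu_bw(g3$dx, caches$a2)
  n2 <- inorm_bw(d, caches$n2)
  g2 <- conv_bw(n2$dx, caches$c2)
  d <- lrelu_bw(g2$dx, caches$a1)
  g1 <- conv_bw(d, caches$c1)
  list(grads = list(c1 = list(W = g1$dW, b = g1$db),
                    c2 = list(W = g2$dW, b = g2$db),
                    n2 = list(gamma = n2$dgamma, beta = n2$dbeta),
                    c3 = list(W = g3$dW, b = g3$db),
                    n3 = list(gamma = n3$dgamma, beta = n3$dbeta),
                    c4 = list(W = g4$dW, b = g4$db)),
       dx = g1$dx)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# L2 penalty over conv weight matrices of a param list; returns value and
# adds 2*l2*W to the matching grads in-place.
l2_penalty <- function(params, grads, l2) {
  val <- 0
  for (nm in names(params)) {
    if (!is.null(params[[nm]]$W)) {
      val <- val + sum(params[[nm]]$W^2)
      if (!is.null(grads)) grads[[nm]]$W <- grads[[nm]]$W + 2 * l2 * params[[nm]]$W
    }
  }
  list(value = l2 * val, grads = grads)
}

#' Train the recovery-mapping GAN on temporal pairs
#'
#' Alternating non-saturating adversarial training: the discriminator learns
#' to separate (input, true later composite) from (input, generated) patch
#' pairs; the generator minimizes the non-saturating adversarial loss plus
#' `rec_weight` times the L1 distance to the true later composite. Both
#' losses carry an L2 weight penalty over all convolution weights. All
#' randomness (init, batching, dropout) derives from `cfg$seed`; training
#' aborts with diagnostics if any loss becomes non-finite.
#'
#' @param pairs List of `list(input, target)` matrices in \[-1, 1\] (as from
#'   [make_recovery_pairs()]), all of size `cfg$image_size`.
#' @param cfg A `gan_config`.
#' @return An object of class `adaptigan`: generator, discriminator, config,
#'   and `loss_log` (data frame: epoch, loss_d, loss_g_adv, loss_g_rec,
#'   loss_g — per-epoch means).
#' @export
train_adaptigan <- function(pairs, cfg = gan_config()) {
  if (length(pairs) < 1) abort_input("at least one training pair required")
  s <- cfg$image_size
  for (pr in pairs)
    if (!all(dim(pr$input) == s) || !all(dim(pr$target) == s))
      abort_input("all pairs must match cfg$image_size")
  set.seed(cfg$seed)
  G <- build_generator(cfg)
  D <- build_discriminator(cfg)
  optG <- adam_new(G$params, lr = cfg$lr_g, beta1 = 0.5)
  optD <- adam_new(D$params, lr = cfg$lr_d, beta1 = 0.5)
  n <- length(pairs)
  bs <- min(cfg$batch, n)
  X <- array(vapply(pairs, function(p) p$input, matrix(0, s, s)), c(s, s, 1, n))
  Y <- array(vapply(pairs, function(p) p$target, matrix(0, s, s)), c(s, s, 1, n))
  log_rows <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    sums <- c(d = 0, adv = 0, rec = 0, g = 0); nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      xb <- X[, , , idx, drop = FALSE]
      yb <- Y[, , , idx, drop = FALSE]
      m <- length(idx)

      ## --- discriminator step -------------------------------------------
      gf <- gen_fw(G, xb, train = TRUE)
      fake <- gf$y
      real_in <- array(c(xb, yb), dim = c(s, s, 2, m))
      fake_in <- array(c(xb, fake), dim = c(s, s, 2, m))
      fr <- disc_fw(D, real_in)
      ff <- disc_fw(D, fake_in)
      loss_d <- mean(softplus(-fr$y)) + mean(softplus(ff$y))
      d_real <- -sigmoid(-fr$y) / length(fr$y)
      d_fake <- sigmoid(ff$y) / length(ff$y)
      br <- disc_bw(D, fr$caches, d_real)
      bf <- disc_bw(D, ff$caches, d_fake)
      gd <- Map(function(a, b) Map(`+`, a, b), br$grads, bf$grads)
      pen <- l2_penalty(D$params, gd, cfg$l2_weight)
      loss_d <- loss_d + pen$value
      st <- adam_step(optD, D$params, pen$grads)
      optD <- st$opt; D$params <- st$params

      ## --- generator step -----------------------------------------------
      gf <- gen_fw(G, xb, train = TRUE)
      fake <- gf$y
      fake_in <- array(c(xb, fake), dim = c(s, s, 2, m))
      ff <- disc_fw(D, fake_in)
      adv <- mean(softplus(-ff$y))
      rec <- mean(abs(fake - yb))
      d_logit <- -sigmoid(-ff$y) / length(ff$y)
      db <- disc_bw(D, ff$caches, d_logit)
      d_fake_img <- db$dx[, , 2, , drop = FALSE]        # grad wrt candidate
      d_rec <- sign(fake - yb) / length(fake)
      dgen_out <- d_fake_img * 1 + cfg$rec_weight * d_rec
      gg <- gen_bw(G, gf$caches, dgen_out)
      pen <- l2_penalty(G$params, gg, cfg$l2_weight)
      loss_g <- adv + cfg$rec_weight * rec + pen$value
      if (!is.finite(loss_d) || !is.finite(loss_g))
        abort_training("GAN training diverged (non-finite loss)",
                       diagnostics = list(epoch = ep, loss_d = loss_d,
                                          loss_g = loss_g))
      st <- adam_step(optG, G$params, pen$grads)
      optG <- st$opt; G$params <- st$params

      sums <- sums + c(loss_d, adv, rec, loss_g); nb <- nb + 1
    }
    log_rows[[ep]] <- data.frame(epoch = ep, loss_d = sums[1] / nb,
                                 loss_g_adv = sums[2] / nb,
                                 loss_g_rec = sums[3] / nb,
                                 loss_g = sums[4] / nb)
  }
  structure(list(generator = G, discriminator = D, cfg = cfg,
                 loss_log = do.call(rbind, log_rows)),
            class = "adaptigan")
}

#' Generate a recovery map for a post-fire composite
#'
#' Runs the trained generator on the raster (tiled with averaging over a
#' half-tile overlap when the raster exceeds the training size; inference is
#' deterministic — dropout off). The optional level map buckets the change
#' in NDVI class between input and generated output into recovery levels:
#' regressed (< 0), stable (0), recovering (+1), recovered (>= +2).
#'
#' @param model A trained `adaptigan`.
#' @param post_fire `index_raster` in \[-1, 1\] (or plain matrix).
#' @param levels Compute the recovery-level class map (default TRUE).
#' @return An object of class `recovery_map`: `values` (matrix in \[-1, 1\]),
#'   `source`, and optionally `level_map` (matrix with levels -1, 0, 1, 2 and
#'   attribute `"legend"`).
#' @export
generate_recovery_map <- function(model, post_fire, levels = TRUE) {
  v <- if (inherits(post_fire, "index_raster")) post_fire$values else post_fire
  ps <- if (inherits(post_fire, "index_raster")) post_fire$pixel_size_m else 250
  s <- model$cfg$image_size
  if (any(dim(v) < s)) abort_input("raster smaller than the model tile size")
  mask <- is.na(v)
  if (all(mask)) abort_input("nodata-only raster")
  vin <- v; vin[mask] <- mean(v[!mask])
  acc <- matrix(0, nrow(v), ncol(v)); cnt <- matrix(0, nrow(v), ncol(v))
  step <- max(1, s %/% 2)
  row_starts <- unique(pmin(seq(1, nrow(v), by = step), nrow(v) - s + 1))
  col_starts <- unique(pmin(seq(1, ncol(v), by = step), ncol(v) - s + 1))
  for (r0 in row_starts) for (c0 in col_starts) {
    tile <- vin[r0:(r0 + s - 1), c0:(c0 + s - 1)]
    out <- gen_fw(model$generator, array(tile, c(s, s, 1, 1)), train = FALSE)$y
    acc[r0:(r0 + s - 1), c0:(c0 + s - 1)] <-
      acc[r0:(r0 + s - 1), c0:(c0 + s - 1)] + out[, , 1, 1]
    cnt[r0:(r0 + s - 1), c0:(c0 + s - 1)] <-
      cnt[r0:(r0 + s - 1), c0:(c0 + s - 1)] + 1
  }
  gen <- acc / cnt
  gen[mask] <- NA_real_
  level_map <- NULL
  if (levels) {
    cl_in <- classify_ndvi(index_raster(pmin(pmax(vin, -1), 1), ps,
                                        index_name = "NDVI"))
    cl_gen <- classify_ndvi(index_raster(pmin(pmax(gen, -1), 1), ps,
                                         index_name = "NDVI"))
    dd <- cl_gen$labels - cl_in$labels
    level_map <- matrix(pmin(pmax(dd, -1), 2), nrow(v), ncol(v))
    level_map[mask] <- NA_integer_
    attr(level_map, "legend") <- c(`-1` = "regressed", `0` = "stable",
                                   `1` = "recovering", `2` = "recovered")
  }
  structure(list(values = gen, source = post_fire, level_map = level_map,
                 pixel_size_m = ps),
            class = "recovery_map")
}

#' Regression metrics between an observed and generated raster
#'
#' MAE, MSE, MSLE, RMSE and Huber loss over unmasked pixels. MSLE is
#' computed on values shifted by +1 so logs are defined on \[-1, 1\] data.
#' Huber uses the quadratic branch r^2/2 for |r| <= delta and the linear
#' branch delta(|r| - delta/2) beyond; both branches agree at |r| = delta.
#'
#' @param y,y_hat Observed and predicted rasters (`index_raster`,
#'   `recovery_map` or matrix), same shape.
#' @param delta Huber threshold (> 0), default 1.
#' @return An object of class `metrics_report`: mae, mse, msle, rmse, huber,
#'   delta, residuals (y - y_hat, with NAs removed).
#' @export
regression_metrics <- function(y, y_hat, delta = 1) {
  gv <- function(x) if (inherits(x, "index_raster")) x$values else
    if (inherits(x, "recovery_map")) x$values else x
  a <- gv(y); b <- gv(y_hat)
  if (!identical(dim(a), dim(b))) abort_input("shapes differ")
  if (delta <= 0) abort_input("'delta' must be > 0")
  ok <- !is.na(a) & !is.na(b)
  r <- a[ok] - b[ok]
  mse <- mean(r^2)
  huber <- mean(ifelse(abs(r) <= delta, r^2 / 2, delta * (abs(r) - delta / 2)))
  structure(list(mae = mean(abs(r)), mse = mse,
                 msle = mean((log1p(a[ok] + 1) - log1p(b[ok] + 1))^2),
                 rmse = sqrt(mse), huber = huber, delta = delta,
                 residuals = r),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> mae %.4f  mse %.4f  msle %.4f  rmse %.4f  huber %.4f (delta %g)\n",
              x$mae, x$mse, x$msle, x$rmse, x$huber, x$delta))
  invisible(x)
}

#' Breusch-Pagan-type homoscedasticity check
#'
#' Regresses the squared residuals on the fitted values; the test statistic
#' is n R^2, referred to a chi-square distribution with 1 degree of freedom.
#' The verdict is "homoscedastic" when p > 0.05, "heteroscedastic" when
#' p <= 0.05, and "degenerate" when the fitted values are constant (the
#' regression is undefined). Optionally writes a residual-vs-fitted scatter.
#'
#' @param residuals,fitted Paired numeric vectors (n >= 30).
#' @param plot_path Optional PNG path for the diagnostic scatter plot.
#' @return List: `statistic`, `p_value`, `verdict`.
#' @export
homoscedasticity_check <- function(residuals, fitted, plot_path = NULL) {
  if (length(residuals) != length(fitted)) abort_input("lengths differ")
  ok <- !is.na(residuals) & !is.na(fitted)
  residuals <- residuals[ok]; fitted <- fitted[ok]
  n <- length(residuals)
  if (n < 30) abort_input("at least 30 paired values required")
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 640, height = 480)
    graphics::plot(fitted, residuals, pch = 20, col = "grey30",
                   xlab = "Fitted", ylab = "Residual",
                   main = "Residuals vs fitted")
    graphics::abline(h = 0, col = "firebrick")
    grDevices::dev.off()
  }
  if (stats::sd(fitted) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, verdict = "degenerate"))
  fit <- stats::lm(I(residuals^2) ~ fitted)
  r2 <- summary(fit)$r.squared
  stat <- n * r2
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p,
       verdict = if (p > 0.05) "homoscedastic" else "heteroscedastic")
}

#' Save / load an AdaptiGAN checkpoint
#'
#' Directory with a JSON manifest (architecture + seed) and the parameters
#' serialized with [saveRDS()].
#'
#' @param model An `adaptigan`.
#' @param dir Checkpoint directory.
#' @export
save_adaptigan <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$cfg
  jsonlite::write_json(cfg[c("image_size", "base_channels", "n_down",
                             "attention_after", "seed")],
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_adaptigan
#' @export
load_adaptigan <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) abort_format(sprintf("no checkpoint at %s", dir))
  readRDS(f)
}
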