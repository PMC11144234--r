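#' Sparse autoencoder configuration
#'
#' A symmetric multilayer autoencoder with sigmoid hidden units whose
#' bottleneck activations are penalized for sparsity, either by an L1 term
#' `lambda * sum(|a|)` or by a Bernoulli KL term
#' `kl_weight * sum_j KL(rho || rho_hat_j)` where `rho_hat_j` is the batch
#' mean activation of bottleneck unit j. Sigmoid bottleneck units keep
#' `rho_hat` in (0, 1).
#'
#' @param hidden Encoder hidden widths, bottleneck last (decoder mirrors);
#'   the bottleneck must be narrower than the input.
#' @param sparsity_mode `"KL"` (default) or `"L1"`: both penalties are
#'   implemented; KL is the default because it targets a mean firing rate
#'   directly.
#' @param lambda L1 penalty weight (>= 0).
#' @param rho Target mean activation in (0, 1).
#' @param kl_weight Weight on the KL sparsity term (>= 0).
#' @param epochs,batch_size,learning_rate Training schedule (Adam).
#' @param seed RNG seed; all initialization and batching derive from it.
#' @return An object of class `sparse_ae_config`.
#' @export
sparse_ae_config <- function(hidden = c(16, 8), sparsity_mode = c("KL", "L1"),
                             lambda = 1e-3, rho = 0.1, kl_weight = 0.1,
                             epochs = 60, batch_size = 256,
                             learning_rate = 5e-3, seed = 1) {
  sparsity_mode <- match.arg(sparsity_mode)
  if (lambda < 0) abort_config("'lambda' must be >= 0")
  if (rho <= 0 || rho >= 1) abort_config("'rho' must be in (0, 1)")
  if (kl_weight < 0) abort_config("'kl_weight' must be >= 0")
  structure(list(hidden = hidden, sparsity_mode = sparsity_mode,
                 lambda = lambda, rho = rho, kl_weight = kl_weight,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed),
            class = "sparse_ae_config")
}

bernoulli_kl <- function(rho, rho_hat, eps = 1e-7) {
  clamped <- pmin(pmax(rho_hat, eps), 1 - eps)
  if (any(rho_hat <= 0 | rho_hat >= 1))
    message("sparse AE: rho_hat outside (0,1) clamped to [eps, 1-eps]")
  sum(rho * log(rho / clamped) + (1 - rho) * log((1 - rho) / (1 - clamped)))
}

#' Sparse autoencoder loss
#'
#' Reconstruction error (mean squared error over all entries) plus the
#' configured sparsity penalty on the designated hidden-layer activations:
#' L1 mode adds `lambda * sum(|a|)`; KL mode adds
#' `kl_weight * sum_j KL(rho || rho_hat_j)` with `rho_hat_j` the batch mean
#' of unit j (clamped into (0,1), never an exception).
#'
#' @param x,x_hat Input and reconstruction, same shape.
#' @param activations Matrix (n x units) of bottleneck activations.
#' @param cfg A `sparse_ae_config`.
#' @return Scalar loss.
#' @export
sparse_ae_loss <- function(x, x_hat, activations, cfg) {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(x_hat))))
    abort_input("x and x_hat shapes differ")
  recon <- mean((x - x_hat)^2)
  pen <- if (cfg$sparsity_mode == "L1") {
    cfg$lambda * sum(abs(activations))
  } else {
    rho_hat <- colMeans(as.matrix(activations))
    cfg$kl_weight * bernoulli_kl(cfg$rho, rho_hat)
  }
  recon + pen
}

# Architecture: encoder hidden layers are sigmoid except the bottleneck,
# which is linear (the clustering embedding must preserve geometry); the
# decoder mirrors with sigmoid hidden layers and a linear output. The
# sparsity penalty acts on the last sigmoid encoder layer — the "designated
# hidden layer" — whose activations are bounded in (0, 1) so the Bernoulli
# mean rho_hat is well defined. With a single hidden layer the bottleneck
# itself is sigmoid and carries the penalty.
ae_build <- function(din, hidden) {
  widths <- c(din, hidden)
  dec_widths <- c(rev(hidden), din)
  enc <- lapply(seq_len(length(widths) - 1),
                function(i) dense_init(widths[i], widths[i + 1]))
  dec <- lapply(seq_len(length(dec_widths) - 1),
                function(i) dense_init(dec_widths[i], dec_widths[i + 1]))
  list(enc = enc, dec = dec, din = din, hidden = hidden)
}

enc_is_sigmoid <- function(net) {
  L <- length(net$enc)
  if (L == 1) TRUE else c(rep(TRUE, L - 1), FALSE)
}

# index of the penalized (designated) encoder layer
ae_penalty_layer <- function(net) max(1L, length(net$enc) - 1L)

#' Encode features with a trained sparse autoencoder
#' @param net A `sparse_ae` model.
#' @param x Feature matrix (n x input width).
#' @return Bottleneck embedding matrix (n x bottleneck width).
#' @export
ae_encode <- function(net, x) {
  h <- as.matrix(x)
  sig <- enc_is_sigmoid(net)
  for (i in seq_along(net$enc)) {
    h <- dense_fw(h, net$enc[[i]])
    if (sig[i]) h <- sigmoid(h)
  }
  h
}

#' Designated-hidden-layer activations of a sparse autoencoder
#' @param net A `sparse_ae` model.
#' @param x Feature matrix.
#' @return Matrix of sigmoid activations of the penalized layer.
#' @export
ae_hidden <- function(net, x) {
  h <- as.matrix(x)
  sig <- enc_is_sigmoid(net)
  pl <- ae_penalty_layer(net)
  for (i in seq_along(net$enc)) {
    h <- dense_fw(h, net$enc[[i]])
    if (sig[i]) h <- sigmoid(h)
    if (i == pl) return(h)
  }
  h
}

# Full forward + backward for one batch; returns loss and grads.
ae_grad <- function(net, x, cfg) {
  n <- nrow(x)
  sig <- enc_is_sigmoid(net)
  pl <- ae_penalty_layer(net)
  hs <- list(x)          # inputs to each layer
  h <- x
  L <- length(net$enc)
  for (i in seq_len(L)) {
    h <- dense_fw(h, net$enc[[i]])
    if (sig[i]) h <- sigmoid(h)
    hs[[i + 1]] <- h
  }
  M <- length(net$dec)
  for (i in seq_len(M)) {
    z <- dense_fw(h, net$dec[[i]])
    h <- if (i < M) sigmoid(z) else z
    hs[[L + i + 1]] <- h
  }
  out <- h
  code <- hs[[pl + 1]]
  recon <- mean((x - out)^2)
  rho_hat <- colMeans(code)
  loss <- recon + if (cfg$sparsity_mode == "L1") cfg$lambda * sum(abs(code)) else
    cfg$kl_weight * bernoulli_kl(cfg$rho, rho_hat)

  genc <- vector("list", L); gdec <- vector("list", M)
  dh <- 2 * (out - x) / length(x)
  for (i in rev(seq_len(M))) {
    if (i < M) dh <- dh * hs[[L + i + 1]] * (1 - hs[[L + i + 1]])
    g <- dense_bw(dh, hs[[L + i]], net$dec[[i]])
    gdec[[i]] <- list(W = g$dW, b = g$db)
    dh <- g$dx
  }
  dpen <- if (cfg$sparsity_mode == "L1") {
    cfg$lambda * sign(code)
  } else {
    eps <- 1e-7
    ch <- pmin(pmax(rho_hat, eps), 1 - eps)
    drho <- cfg$kl_weight * (-cfg$rho / ch + (1 - cfg$rho) / (1 - ch))
    matrix(drho, n, ncol(code), byrow = TRUE) / n
  }
  for (i in rev(seq_len(L))) {
    if (i == pl) dh <- dh + dpen   # penalty enters at the designated layer
    if (sig[i]) dh <- dh * hs[[i + 1]] * (1 - hs[[i + 1]])
    g <- dense_bw(dh, hs[[i]], net$enc[[i]])
    genc[[i]] <- list(W = g$dW, b = g$db)
    dh <- g$dx
  }
  list(loss = loss, grads = list(enc = genc, dec = gdec))
}

#' Train a sparse autoencoder
#'
#' Minimizes reconstruction error plus the configured sparsity penalty with
#' Adam on seeded mini-batches. Aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param features Numeric matrix (n x d), one row per sample.
#' @param cfg A `sparse_ae_config`.
#' @return An object of class `sparse_ae`: the encoder/decoder weights plus
#'   the per-epoch loss trajectory (`$trajectory`).
#' @export
train_sparse_ae <- function(features, cfg = sparse_ae_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1) abort_input("empty feature matrix")
  if (cfg$hidden[length(cfg$hidden)] >= ncol(features))
    abort_config("bottleneck width must be smaller than the input width")
  set.seed(cfg$seed)
  net <- ae_build(ncol(features), cfg$hidden)
  params <- list(enc = net$enc, dec = net$dec)
  opt <- adam_new(params, lr = cfg$learning_rate)
  bs <- min(cfg$batch_size, n)
  traj <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      net$enc <- params$enc; net$dec <- params$dec
      g <- ae_grad(net, features[idx, , drop = FALSE], cfg)
      if (!is.finite(g$loss))
        abort_training("sparse AE training diverged (non-finite loss)",
                       diagnostics = list(epoch = ep, loss = g$loss))
      st <- adam_step(opt, params, g$grads)
      opt <- st$opt; params <- st$params
      ep_loss <- ep_loss + g$loss; nb <- nb + 1
    }
    traj[ep] <- ep_loss / nb
  }
  net$enc <- params$enc; net$dec <- params$dec
  structure(c(net, list(cfg = cfg, trajectory = traj)), class = "sparse_ae")
}
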