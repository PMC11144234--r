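#' Extract pixel-neighbourhood patch features
#'
#' Builds one feature row per unmasked pixel from its `patch` x `patch`
#' neighbourhood, reflect-padded at the borders. Class-map labels are scaled
#' to \[0, 1\] (code / 4) so features are commensurate with index values.
#' Masked neighbour values are replaced by the mean of the unmasked pixels
#' so every retained row is fully defined.
#'
#' @param r An `index_raster` or `class_map`.
#' @param patch Odd patch side length (>= 1).
#' @return Matrix (n_unmasked x patch^2) with attribute `"pixel_index"`
#'   giving the linear (column-major) index of each row's centre pixel and
#'   attribute `"dim"` with the raster shape.
#' @export
extract_patches <- function(r, patch = 3) {
  if (patch %% 2 == 0 || patch < 1) abort_input("'patch' must be odd and >= 1")
  v <- if (inherits(r, "class_map")) r$labels / 4 else if (inherits(r, "index_raster"))
    r$values else abort_input("'r' must be an index_raster or class_map")
  if (min(dim(v)) <= patch %/% 2)
    abort_input("raster too small for the requested patch")
  ok <- !is.na(v)
  if (!any(ok))
    return(structure(matrix(numeric(0), 0, patch^2),
                     pixel_index = integer(0), dim_raster = dim(v)))
  fill <- mean(v[ok])
  v[!ok] <- fill
  p <- patch %/% 2
  reflect <- function(n) c(rev(seq_len(p) + 1), seq_len(n), n - seq_len(p))
  vp <- v[reflect(nrow(v)), reflect(ncol(v))]
  # one column of the feature matrix per kernel offset
  H <- nrow(v); W <- ncol(v)
  cols <- matrix(0, H * W, patch^2)
  k <- 1
  for (dc in 0:(patch - 1)) for (dr in 0:(patch - 1)) {
    cols[, k] <- as.vector(vp[dr + seq_len(H), dc + seq_len(W)])
    k <- k + 1
  }
  feats <- cols[as.vector(ok), , drop = FALSE]
  structure(feats, pixel_index = which(as.vector(ok)), dim_raster = dim(v))
}

#' Soft cluster assignment with a Student-t kernel
#'
#' q_ij proportional to (1 + ||z_i - mu_j||^2 / alpha)^(-(alpha+1)/2), rows
#' normalized to 1 (alpha = 1 by default, the standard deep-embedded
#' clustering kernel).
#'
#' @param z Embedding matrix (n x d).
#' @param mu Centroid matrix (k x d).
#' @param alpha Degrees of freedom (> 0).
#' @return Row-stochastic matrix Q (n x k).
#' @export
soft_assignment <- function(z, mu, alpha = 1) {
  z <- as.matrix(z); mu <- as.matrix(mu)
  if (nrow(mu) < 1) abort_input("at least one centroid required")
  if (ncol(z) != ncol(mu)) abort_input("embedding and centroid dims differ")
  if (alpha <= 0) abort_input("'alpha' must be > 0")
  d2 <- outer(rowSums(z^2), rep(1, nrow(mu))) - 2 * z %*% t(mu) +
    outer(rep(1, nrow(z)), rowSums(mu^2))
  d2[d2 < 0] <- 0
  q <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  q / rowSums(q)
}

#' Auxiliary target distribution of deep embedded clustering
#'
#' p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j'), with cluster frequencies
#' f_j = sum_i q_ij (floored at a small epsilon to tolerate empty columns).
#' Sharpens high-confidence assignments.
#'
#' @param Q Row-stochastic soft-assignment matrix.
#' @return Row-stochastic matrix P of the same shape.
#' @export
target_distribution <- function(Q) {
  f <- pmax(colSums(Q), 1e-12)
  w <- sweep(Q^2, 2, f, "/")
  w / rowSums(w)
}

#' Train a deep-embedded-clustering model
#'
#' Initializes with a sparse autoencoder (features -> embeddings) and k-means
#' centroids, then alternates: compute the Student-t soft assignment Q and
#' sharpened target P, and minimize KL(P || Q) with respect to both the
#' centroids and the encoder weights (Adam). Training stops when fewer than
#' `tol` of the points change hard assignment between target updates, or
#' after `max_iter` updates.
#'
#' @param features Feature matrix (n x d).
#' @param k Number of clusters (>= 2 recommended; k >= 1 accepted).
#' @param cfg `sparse_ae_config` for the initialization autoencoder.
#' @param alpha Student-t degrees of freedom.
#' @param tol Stopping threshold on the fraction of relabelled points.
#' @param max_iter Maximum target updates.
#' @param inner_epochs Adam epochs per target update.
#' @param lr Learning rate of the clustering phase.
#' @return An object of class `dec_state`: `encoder`, `mu`, `Q`, `P`,
#'   `alpha`, `k`, `kl` (final KL(P||Q)), `kl_trajectory`.
#' @export
train_dec <- function(features, k, cfg = sparse_ae_config(), alpha = 1,
                      tol = 1e-3, max_iter = 30, inner_epochs = 4, lr = 1e-3) {
  features <- as.matrix(features)
  if (k < 1) abort_input("'k' must be >= 1")
  n <- nrow(features)
  encoder <- train_sparse_ae(features, cfg)
  z <- ae_encode(encoder, features)
  mu <- NULL
  if (nrow(z) == k) mu <- unname(as.matrix(z))  # each point its own centroid
  else for (att in seq_len(5)) {
    km <- suppressWarnings(tryCatch(
      stats::kmeans(z, centers = min(k, nrow(unique(z))), nstart = 10,
                    iter.max = 50),
      error = function(e) NULL))
    if (is.null(km)) next
    if (length(unique(km$cluster)) == k && nrow(km$centers) == k) {
      mu <- km$centers; break
    }
  }
  if (is.null(mu))
    abort_training("k-means initialization produced an empty cluster 5 times",
                   diagnostics = list(k = k, n = n))

  params <- list(enc = encoder$enc, mu = mu)
  opt <- adam_new(params, lr = lr)
  prev_hard <- max.col(soft_assignment(z, mu, alpha), ties.method = "first")
  kl_traj <- numeric(0)
  for (it in seq_len(max_iter)) {
    encoder$enc <- params$enc
    z <- ae_encode(encoder, features)
    Q <- soft_assignment(z, params$mu, alpha)
    P <- target_distribution(Q)
    for (ep in seq_len(inner_epochs)) {
      encoder$enc <- params$enc
      g <- dec_grad(encoder, features, params$mu, P, alpha)
      kl_traj <- c(kl_traj, g$kl)
      st <- adam_step(opt, params, g$grads)
      opt <- st$opt; params <- st$params
    }
    encoder$enc <- params$enc
    z <- ae_encode(encoder, features)
    hard <- max.col(soft_assignment(z, params$mu, alpha), ties.method = "first")
    changed <- mean(hard != prev_hard)
    prev_hard <- hard
    if (changed < tol) break
  }
  encoder$enc <- params$enc
  z <- ae_encode(encoder, features)
  Q <- soft_assignment(z, params$mu, alpha)
  P <- target_distribution(Q)
  kl <- sum(P * (log(pmax(P, 1e-12)) - log(pmax(Q, 1e-12))))
  structure(list(encoder = encoder, mu = params$mu, Q = Q, P = P,
                 alpha = alpha, k = k, kl = kl, kl_trajectory = kl_traj),
            class = "dec_state")
}

# KL(P||Q) and its gradients wrt encoder weights and centroids.
dec_grad <- function(encoder, x, mu, P, alpha) {
  # forward through encoder keeping layer activations
  hs <- list(x)
  h <- x
  L <- length(encoder$enc)
  sig <- enc_is_sigmoid(encoder)
  for (i in seq_len(L)) {
    h <- dense_fw(h, encoder$enc[[i]])
    if (sig[i]) h <- sigmoid(h)
    hs[[i + 1]] <- h
  }
  z <- h
  d2 <- outer(rowSums(z^2), rep(1, nrow(mu))) - 2 * z %*% t(mu) +
    outer(rep(1, nrow(z)), rowSums(mu^2))
  d2[d2 < 0] <- 0
  w <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  Q <- w / rowSums(w)
  kl <- sum(P * (log(pmax(P, 1e-12)) - log(pmax(Q, 1e-12))))
  # standard DEC gradients
  coef <- (alpha + 1) / alpha * (1 + d2 / alpha)^(-1) * (P - Q)  # n x k
  dz <- matrix(0, nrow(z), ncol(z))
  dmu <- matrix(0, nrow(mu), ncol(mu))
  for (j in seq_len(nrow(mu))) {
    diffj <- sweep(z, 2, mu[j, ], "-")
    dz <- dz + coef[, j] * diffj
    dmu[j, ] <- -colSums(coef[, j] * diffj)
  }
  genc <- vector("list", L)
  dh <- dz
  for (i in rev(seq_len(L))) {
    if (sig[i]) dh <- dh * hs[[i + 1]] * (1 - hs[[i + 1]])
    g <- dense_bw(dh, hs[[i]], encoder$enc[[i]])
    genc[[i]] <- list(W = g$dW, b = g$db)
    dh <- g$dx
  }
  list(kl = kl, grads = list(enc = genc, mu = dmu))
}

#' Predict hard cluster labels from a trained DEC model
#' @param state A `dec_state`.
#' @param features Feature matrix.
#' @return Integer vector of cluster labels (1..k).
#' @export
dec_predict <- function(state, features) {
  z <- ae_encode(state$encoder, as.matrix(features))
  max.col(soft_assignment(z, state$mu, state$alpha), ties.method = "first")
}

#' Bi-temporal change detection via shared deep embedded clustering
#'
#' Classifies both epochs into the five NDVI classes, extracts patch features
#' from both class maps, clusters the pooled features with ONE shared DEC
#' model (k = 5, one cluster per vegetation class), and flags a pixel as
#' changed where its pre- and post-fire cluster labels disagree. Pixels
#' masked in either epoch are masked in the result. The pooled training set
#' is ordered canonically (the epoch with the smaller value sum first) so the
#' binary map is invariant to swapping pre and post.
#'
#' @param pre,post Aligned NDVI `index_raster`s.
#' @param cfg `sparse_ae_config` for the DEC initialization.
#' @param patch Odd patch size for featureization.
#' @param scheme `class_scheme` used for both epochs.
#' @param k Number of clusters (default 5).
#' @param ... Passed on to [train_dec()].
#' @return An object of class `change_map`: `binary` (logical matrix, `NA`
#'   at nodata), `pre_labels`, `post_labels` (`class_map`s), `pixel_size_m`,
#'   and the fitted `dec` state.
#' @export
detect_change <- function(pre, post, cfg = sparse_ae_config(), patch = 5,
                          scheme = class_scheme(), k = 5, ...) {
  if (!inherits(pre, "index_raster") || !inherits(post, "index_raster"))
    abort_input("'pre' and 'post' must be index_rasters")
  if (!identical(dim(pre$values), dim(post$values)) ||
      pre$pixel_size_m != post$pixel_size_m)
    abort_input("pre and post rasters are not aligned")
  pre_cm <- classify_ndvi(pre, scheme)
  post_cm <- classify_ndvi(post, scheme)
  fa <- extract_patches(pre_cm, patch)
  fb <- extract_patches(post_cm, patch)
  # canonical order makes training invariant to argument swap
  swap <- sum(pre$values, na.rm = TRUE) > sum(post$values, na.rm = TRUE)
  pooled <- if (swap) rbind(fb, fa) else rbind(fa, fb)
  state <- train_dec(pooled, k = k, cfg = cfg, ...)
  la <- dec_predict(state, fa)
  lb <- dec_predict(state, fb)
  # Clusters represent vegetation classes: map each cluster to the majority
  # NDVI class (centre pixel) of its members, pooled over both epochs, so
  # two clusters splitting one class do not register spurious change.
  # Ties break to the lower class code (deterministic).
  ctr <- c(pre_cm$labels[attr(fa, "pixel_index")],
           post_cm$labels[attr(fb, "pixel_index")])
  memb <- c(la, lb)
  cluster_class <- vapply(seq_len(k), function(j) {
    cls <- ctr[memb == j]
    if (!length(cls)) return(NA_integer_)
    tt <- table(cls)
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  d <- dim(pre$values)
  lab_a <- rep(NA_integer_, prod(d)); lab_a[attr(fa, "pixel_index")] <- cluster_class[la]
  lab_b <- rep(NA_integer_, prod(d)); lab_b[attr(fb, "pixel_index")] <- cluster_class[lb]
  binary <- matrix(lab_a != lab_b, d[1], d[2])  # NA where either missing
  structure(list(binary = binary, pre_labels = pre_cm, post_labels = post_cm,
                 pixel_size_m = pre$pixel_size_m, dec = state),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  b <- x$binary
  cat(sprintf("<change_map> %d x %d  changed %d / %d unmasked\n",
              nrow(b), ncol(b), sum(b, na.rm = TRUE), sum(!is.na(b))))
  invisible(x)
}

#' Overlay a change map on the pre-fire image
#'
#' Unchanged pixels render the pre-fire index as grayscale ((v+1)/2);
#' changed pixels are alpha-blended with the highlight colour. Nodata pixels
#' render black.
#'
#' @param pre Pre-fire `index_raster`.
#' @param cm A `change_map` of the same shape.
#' @param color Highlight colour (any R colour).
#' @param alpha Blend weight in \[0, 1\] (1 = pure highlight).
#' @param path Optional PNG output path.
#' @return H x W x 3 array in \[0, 1\] (invisibly if written to file).
#' @export
overlay_change <- function(pre, cm, color = "red", alpha = 0.5, path = NULL) {
  if (!identical(dim(pre$values), dim(cm$binary)))
    abort_input("raster and change map shapes differ")
  if (alpha < 0 || alpha > 1) abort_input("'alpha' must be in [0, 1]")
  g <- (pre$values + 1) / 2
  g[is.na(g)] <- 0
  rgbcol <- grDevices::col2rgb(color)[, 1] / 255
  changed <- !is.na(cm$binary) & cm$binary
  out <- array(0, dim = c(dim(g), 3))
  for (ch in 1:3) {
    plane <- g
    plane[changed] <- (1 - alpha) * g[changed] + alpha * rgbcol[ch]
    out[, , ch] <- plane
  }
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(path)) { png::writePNG(out, path); return(invisible(out)) }
  out
}

#' Binary classification / change-map metrics
#'
#' Precision, recall, F1, accuracy and intersection-over-union of a predicted
#' binary map against truth, over positions unmasked in both. Zero-division
#' cases yield 0 with a warning.
#'
#' @param truth,pred Logical (or 0/1) vectors or matrices of equal shape.
#' @return Named list: precision, recall, f1, accuracy, iou, tp, fp, fn, tn.
#' @export
change_metrics <- function(truth, pred) {
  t <- as.logical(truth); p <- as.logical(pred)
  if (length(t) != length(p)) abort_input("lengths differ")
  ok <- !is.na(t) & !is.na(p)
  t <- t[ok]; p <- p[ok]
  tp <- sum(t & p); fp <- sum(!t & p); fn <- sum(t & !p); tn <- sum(!t & !p)
  safe <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (zero division); returning 0", what)); 0 }
    else num / den
  }
  prec <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1,
       accuracy = (tp + tn) / length(t),
       iou = safe(tp, tp + fp + fn, "IoU"),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Save / load a DEC model checkpoint
#'
#' The checkpoint is a directory containing a JSON manifest (k, alpha, layer
#' widths, seed) plus the weights and centroids as CSV matrices — a plain-text
#' archive that round-trips exactly at double precision via full decimal
#' serialization.
#'
#' @param state A `dec_state`.
#' @param dir Checkpoint directory (created if needed).
#' @export
save_dec <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(k = state$k, alpha = state$alpha,
                   hidden = state$encoder$cfg$hidden,
                   seed = state$encoder$cfg$seed, kl = state$kl)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_mat <- function(m, f)
    utils::write.table(format(m, digits = 17),
                       file.path(dir, f), sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  write_mat(state$mu, "centroids.csv")
  for (i in seq_along(state$encoder$enc)) {
    write_mat(state$encoder$enc[[i]]$W, sprintf("enc%d_W.csv", i))
    write_mat(matrix(state$encoder$enc[[i]]$b, nrow = 1), sprintf("enc%d_b.csv", i))
  }
  invisible(dir)
}

#' @rdname save_dec
#' @export
load_dec <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  read_mat <- function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = ",", header = FALSE))
  enc <- list()
  i <- 1
  while (file.exists(file.path(dir, sprintf("enc%d_W.csv", i)))) {
    enc[[i]] <- list(W = unname(read_mat(sprintf("enc%d_W.csv", i))),
                     b = as.numeric(read_mat(sprintf("enc%d_b.csv", i))))
    i <- i + 1
  }
  encoder <- structure(list(enc = enc, dec = NULL,
                            cfg = sparse_ae_config(hidden = mf$hidden, seed = mf$seed)),
                       class = "sparse_ae")
  structure(list(encoder = encoder, mu = unname(read_mat("centroids.csv")),
                 Q = NULL, P = NULL, alpha = mf$alpha, k = mf$k, kl = mf$kl),
            class = "dec_state")
}
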