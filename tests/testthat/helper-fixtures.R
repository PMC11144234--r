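# Shared fixtures: all built in code, seeded.

# Three well-separated Gaussian blobs in d dimensions, rescaled to [0, 1].
make_blobs <- function(seed, n = 150, d = 8, sep = 6) {
  set.seed(seed)
  ctrs <- rbind(rep(0, d),
                c(rep(sep, d %/% 2), rep(0, d - d %/% 2)),
                c(rep(0, d - d %/% 2), rep(-sep, d %/% 2)))
  z <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n * d), n, d), 2, ctrs[k, ], "+")))
  list(x = (z - min(z)) / (max(z) - min(z)), labels = rep(1:3, each = n))
}

# Best-permutation clustering accuracy for k = 3.
perm3_accuracy <- function(pred, truth) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  max(vapply(perms, function(p) mean(p[pred] == truth), numeric(1)))
}

# Tiny raster with a known value layout.
tiny_raster <- function(values, ...) index_raster(values, ...)
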