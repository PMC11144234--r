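#' Synthetic scene configuration
#'
#' Study conditions for a bi-temporal burn pair: a spatially autocorrelated
#' background NDVI field (Gaussian-smoothed white noise), a polygonal burn
#' scar that depresses the index by `depth`, and i.i.d. observation noise.
#' Defaults emulate healthy conifer cover at 250 m pixels losing most of its
#' canopy inside the scar: background mean 0.55 (high vegetation), scar
#' depression 0.45 (dropping to bare/low classes), observation noise sd 0.02
#' (within the 0.02-0.05 cross-sensor NDVI uncertainty reported for
#' MODIS/VIIRS products).
#'
#' @param size Raster side length in pixels.
#' @param pixel_size_m Ground sampling distance (m).
#' @param bg_mean,bg_sd Mean and spatial standard deviation of the smooth
#'   background field.
#' @param smoothness Gaussian blur sigma (pixels) of the background field.
#' @param scar Polygon vertices as a two-column matrix of (row, col)
#'   coordinates in pixel units, or `NULL` for a default blob covering
#'   roughly a quarter of the scene.
#' @param depth NDVI depression inside the scar (index units).
#' @param noise_sd I.i.d. per-epoch observation noise sd.
#' @param seed Mandatory RNG seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(size = 64, pixel_size_m = 250, bg_mean = 0.55,
                         bg_sd = 0.08, smoothness = 4, scar = NULL,
                         depth = 0.45, noise_sd = 0.02, seed) {
  if (missing(seed)) abort_config("'seed' is mandatory for scene_config")
  if (depth < 0 || depth > 2) abort_config("'depth' must be in [0, 2]")
  if (is.null(scar)) {
    h <- size / 2
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    rad <- size * 0.28 * c(1, 0.85, 1.05, 0.9, 1, 0.8, 1.1, 0.95)
    scar <- cbind(h + rad * sin(ang), h + rad * cos(ang))
  }
  structure(list(size = size, pixel_size_m = pixel_size_m, bg_mean = bg_mean,
                 bg_sd = bg_sd, smoothness = smoothness, scar = scar,
                 depth = depth, noise_sd = noise_sd, seed = seed),
            class = "scene_config")
}

# Separable Gaussian blur of a matrix by kernel-matrix multiplication.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  blur_mat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  blur_mat(nrow(m)) %*% m %*% t(blur_mat(ncol(m)))
}

# Smooth correlated field with given mean and spatial sd.
smooth_field <- function(size, mean, sd, sigma) {
  f <- gaussian_blur(matrix(stats::rnorm(size * size), size, size), sigma)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- (f - base::mean(f)) / s
  mean + sd * f
}

# Even-odd-rule rasterization of a polygon onto a size x size pixel grid;
# vertices are (row, col) in pixel units, pixel centers at integer + 0.5.
rasterize_polygon <- function(vertices, size) {
  px <- as.vector(row(matrix(0, size, size))) - 0.5
  py <- as.vector(col(matrix(0, size, size))) - 0.5
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, size, size)
}

#' Generate a bi-temporal burn-scar scene with known truth
#'
#' @param cfg A `scene_config`.
#' @return A list with elements `pre`, `post` (`index_raster`s) and `truth`
#'   (a `change_map` whose `binary` field is the rasterized scar mask).
#' @export
make_burn_pair <- function(cfg) {
  if (!inherits(cfg, "scene_config")) abort_config("'cfg' must be a scene_config")
  set.seed(cfg$seed)
  bg <- smooth_field(cfg$size, cfg$bg_mean, cfg$bg_sd, cfg$smoothness)
  if (any(cfg$scar < 0) || any(cfg$scar > cfg$size))
    warning("scar polygon exceeds raster extent; clipping to the grid")
  scar <- rasterize_polygon(cfg$scar, cfg$size)
  clamp <- function(x) pmin(pmax(x, -1), 1)
  pre <- clamp(bg + stats::rnorm(cfg$size^2, sd = cfg$noise_sd))
  post <- clamp(bg - cfg$depth * scar + stats::rnorm(cfg$size^2, sd = cfg$noise_sd))
  truth <- structure(list(binary = scar, pre_labels = NULL, post_labels = NULL,
                          pixel_size_m = cfg$pixel_size_m),
                     class = "change_map")
  list(pre = index_raster(pre, cfg$pixel_size_m, index_name = "NDVI"),
       post = index_raster(post, cfg$pixel_size_m, index_name = "NDVI"),
       truth = truth)
}

#' Trend-stack configuration
#'
#' Study conditions for a multi-year index stack: designated greening pixels
#' gain `slope_magnitude` index units per year, browning pixels lose the
#' same, the rest stay flat, with i.i.d. noise on every observation. Defaults
#' match a decade of annual composites with trend slope an order of magnitude
#' above the noise.
#'
#' @param size Raster side in pixels.
#' @param years Number of annual composites (>= 3).
#' @param greening_fraction_true,browning_fraction_true True pixel fractions
#'   (sum <= 1).
#' @param slope_magnitude Trend magnitude (index units / year).
#' @param noise_sd Observation noise sd.
#' @param base Mean index level of the scene.
#' @param pixel_size_m Ground sampling distance (m).
#' @param seed Mandatory RNG seed.
#' @return An object of class `trend_stack_config`.
#' @export
trend_stack_config <- function(size = 64, years = 10,
                               greening_fraction_true = 0.6,
                               browning_fraction_true = 0.4,
                               slope_magnitude = 0.01, noise_sd = 0.001,
                               base = 0.3, pixel_size_m = 250, seed) {
  if (missing(seed)) abort_config("'seed' is mandatory for trend_stack_config")
  if (years < 3) abort_config("'years' must be >= 3")
  if (greening_fraction_true < 0 || browning_fraction_true < 0 ||
      greening_fraction_true + browning_fraction_true > 1)
    abort_config("fractions must be >= 0 and sum to at most 1")
  structure(list(size = size, years = years,
                 greening_fraction_true = greening_fraction_true,
                 browning_fraction_true = browning_fraction_true,
                 slope_magnitude = slope_magnitude, noise_sd = noise_sd,
                 base = base, pixel_size_m = pixel_size_m, seed = seed),
            class = "trend_stack_config")
}

#' Generate an annual index stack with known per-pixel trends
#'
#' @param cfg A `trend_stack_config`.
#' @return A list with `rasters` (list of EVI `index_raster`s, one per year),
#'   `years` (integer vector), and `truth` (list: `slopes` matrix,
#'   `greening_fraction`, `browning_fraction` — the exact realized fractions).
#' @export
make_trend_stack <- function(cfg) {
  if (!inherits(cfg, "trend_stack_config"))
    abort_config("'cfg' must be a trend_stack_config")
  set.seed(cfg$seed)
  npix <- cfg$size^2
  ng <- round(cfg$greening_fraction_true * npix)
  nb <- round(cfg$browning_fraction_true * npix)
  idx <- sample.int(npix, ng + nb)
  slopes <- matrix(0, cfg$size, cfg$size)
  slopes[idx[seq_len(ng)]] <- cfg$slope_magnitude
  if (nb > 0) slopes[idx[ng + seq_len(nb)]] <- -cfg$slope_magnitude
  years <- seq(2001, length.out = cfg$years)
  t0 <- (cfg$years - 1) / 2
  rasters <- lapply(seq_len(cfg$years), function(i) {
    v <- cfg$base + slopes * (i - 1 - t0) +
      matrix(stats::rnorm(npix, sd = cfg$noise_sd), cfg$size, cfg$size)
    index_raster(pmin(pmax(v, -1), 1), cfg$pixel_size_m, index_name = "EVI")
  })
  list(rasters = rasters, years = years,
       truth = list(slopes = slopes, greening_fraction = ng / npix,
                    browning_fraction = nb / npix))
}

#' Generate synthetic recovery training pairs
#'
#' Each pair is a post-fire composite at time t (background field with a
#' burn scar depressed by `depth`) and the same scene at t + delta where the
#' scar has relaxed toward the background by the recovery `coefficient`
#' (1 = full recovery, 0 = no recovery), plus observation noise.
#'
#' @param n Number of pairs (>= 1).
#' @param size Image side (pixels).
#' @param seed RNG seed.
#' @param depth Scar depression depth (index units).
#' @param coefficient Recovery coefficient in \[0, 1\].
#' @param noise_sd Observation noise sd on the target epoch.
#' @return List with `pairs` (list of `list(input, target)` matrices in
#'   \[-1, 1\]) and `truth` (`coefficient`, `depth`, per-pair scar fractions).
#' @export
make_recovery_pairs <- function(n, size = 32, seed, depth = 0.5,
                                coefficient = 0.6, noise_sd = 0.01) {
  if (n < 1) abort_config("'n' must be >= 1")
  if (missing(seed)) abort_config("'seed' is mandatory")
  set.seed(seed)
  clamp <- function(x) pmin(pmax(x, -1), 1)
  scar_fracs <- numeric(n)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    bg <- smooth_field(size, 0.5, 0.08, 3)
    ctr <- size / 2 + stats::runif(2, -size / 6, size / 6)
    rad <- size * stats::runif(1, 0.18, 0.3)
    ang <- seq(0, 2 * pi, length.out = 8)[-8]
    poly <- cbind(ctr[1] + rad * stats::runif(7, 0.75, 1.15) * sin(ang),
                  ctr[2] + rad * stats::runif(7, 0.75, 1.15) * cos(ang))
    scar <- rasterize_polygon(poly, size)
    scar_fracs[i] <- mean(scar)
    input <- clamp(bg - depth * scar)
    target <- clamp(bg - (1 - coefficient) * depth * scar +
                      matrix(stats::rnorm(size^2, sd = noise_sd), size, size))
    pairs[[i]] <- list(input = input, target = target)
  }
  list(pairs = pairs,
       truth = list(coefficient = coefficient, depth = depth,
                    scar_fractions = scar_fracs))
}

#' Generate a synthetic soil-attribute table with a known regrowth rule
#'
#' Attributes are drawn from plausible ranges (pH 3-9, nitrogen 0-10 g/kg,
#' organic carbon 0-80 g/kg, bulk density 0.8-1.8 g/cm3, five soil groups);
#' the binary regrowth label follows the decision rule
#' `possible <=> ph_lo <= pH <= ph_hi AND nitrogen > nitrogen_min`,
#' flipped with probability `noise_rate`.
#'
#' @param n Number of rows.
#' @param rule_params List with `ph_lo`, `ph_hi`, `nitrogen_min`.
#' @param noise_rate Label-flip probability in \[0, 0.5).
#' @param seed RNG seed.
#' @return A `data.frame` with columns latitude, longitude, ph, nitrogen,
#'   organic_carbon, bulk_density, soil_group, label; the generating rule is
#'   attached as attribute `"truth"` (including the analytic label
#'   prevalence under the uniform attribute model).
#' @export
make_soil_table <- function(n, rule_params = list(ph_lo = 5.5, ph_hi = 7.5,
                                                  nitrogen_min = 3),
                            noise_rate = 0.05, seed) {
  if (n < 1) abort_config("'n' must be >= 1")
  if (noise_rate < 0 || noise_rate >= 0.5)
    abort_config("'noise_rate' must be in [0, 0.5)")
  if (missing(seed)) abort_config("'seed' is mandatory")
  set.seed(seed)
  groups <- c("andosol", "cambisol", "luvisol", "podzol", "vertisol")
  tab <- data.frame(
    latitude = stats::runif(n, 30, 50),
    longitude = stats::runif(n, -125, -100),
    ph = stats::runif(n, 3, 9),
    nitrogen = stats::runif(n, 0, 10),
    organic_carbon = stats::runif(n, 0, 80),
    bulk_density = stats::runif(n, 0.8, 1.8),
    soil_group = sample(groups, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  clean <- with(tab, ph >= rule_params$ph_lo & ph <= rule_params$ph_hi &
                  nitrogen > rule_params$nitrogen_min)
  flip <- stats::runif(n) < noise_rate
  tab$label <- as.integer(xor(clean, flip))
  p_clean <- (rule_params$ph_hi - rule_params$ph_lo) / 6 *
    (10 - rule_params$nitrogen_min) / 10
  attr(tab, "truth") <- list(rule_params = rule_params, noise_rate = noise_rate,
                             clean_label = as.integer(clean),
                             analytic_prevalence = p_clean * (1 - noise_rate) +
                               (1 - p_clean) * noise_rate)
  tab
}
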