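#' Sen's slope of a time series
#'
#' Robust trend estimate: the median of all pairwise slopes
#' (x_j - x_i) / (t_j - t_i) over i < j. The median of an even number of
#' pairwise slopes is the mean of the two central values. Irregular year
#' gaps are handled naturally by the denominator.
#'
#' @param values Numeric vector of index values.
#' @param times Numeric vector of observation times (years); strictly
#'   unique, same length as `values`. Defaults to `seq_along(values)`.
#' @return The Sen's slope (index units per year).
#' @export
sens_slope <- function(values, times = seq_along(values)) {
  if (length(values) != length(times)) abort_input("lengths of values and times differ")
  if (length(values) < 2) abort_input("at least 2 observations required")
  if (anyDuplicated(times)) abort_input("duplicate times")
  dv <- outer(values, values, "-")
  dt <- outer(times, times, "-")
  stats::median(dv[lower.tri(dv)] / dt[lower.tri(dt)])
}

#' Annual maximum composite of a dated raster stack
#'
#' Collapses multiple observations per year to the per-pixel maximum over
#' that year's rasters (nodata-aware: the max of the valid values; all
#' invalid gives nodata). An optional month filter restricts which dates
#' enter each year's composite.
#'
#' @param rasters List of aligned `index_raster`s.
#' @param years Integer vector, the year of each raster.
#' @param months Optional integer vector, the month of each raster; used only
#'   when `month_filter` is given.
#' @param month_filter Optional months (1-12) to retain before compositing.
#' @return List with `rasters` (one composite per retained year, ascending)
#'   and `years`.
#' @export
annual_max_composite <- function(rasters, years, months = NULL,
                                 month_filter = NULL) {
  if (length(rasters) != length(years)) abort_input("one year per raster required")
  if (!is.null(month_filter)) {
    if (is.null(months)) abort_input("'months' needed for month filtering")
    keep <- months %in% month_filter
    rasters <- rasters[keep]; years <- years[keep]
  }
  check_aligned(rasters)
  uy <- sort(unique(years))
  out <- list()
  for (y in uy) {
    grp <- rasters[years == y]
    if (length(grp) == 0) { warning(sprintf("year %d has no rasters; dropped", y)); next }
    vals <- vapply(grp, function(r) r$values, grp[[1]]$values)
    vals <- array(vals, dim = c(dim(grp[[1]]$values), length(grp)))
    mx <- apply(vals, c(1, 2), function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    out[[as.character(y)]] <- index_raster(mx, grp[[1]]$pixel_size_m,
                                           grp[[1]]$origin, grp[[1]]$index_name)
  }
  list(rasters = unname(out), years = as.integer(names(out)))
}

check_aligned <- function(rasters) {
  if (length(rasters) == 0) abort_input("empty raster list")
  d <- dim(rasters[[1]]$values)
  for (r in rasters) {
    if (!inherits(r, "index_raster")) abort_input("all elements must be index_rasters")
    if (!identical(dim(r$values), d)) abort_input("rasters are not aligned")
  }
  invisible(d)
}

#' Per-pixel Sen's slope raster of an annual stack
#'
#' Computes the Sen's slope at every pixel with at least two valid yearly
#' observations; other pixels are nodata. Pairwise slopes are computed as
#' whole-raster operations; the per-pixel median ignores pairs with a
#' missing endpoint.
#'
#' @param rasters List of aligned yearly composites (one per year).
#' @param years Integer vector of the same length (>= 2), strictly increasing.
#' @return An `index_raster` (index_name `"raw-band"`) whose values are
#'   slopes in index units per year.
#' @export
slope_raster <- function(rasters, years) {
  if (length(rasters) < 2) abort_input("at least 2 years required")
  if (length(rasters) != length(years)) abort_input("one year per raster required")
  if (anyDuplicated(years)) abort_input("duplicate years")
  check_aligned(rasters)
  d <- dim(rasters[[1]]$values)
  n <- length(rasters)
  V <- vapply(rasters, function(r) as.vector(r$values), numeric(prod(d)))
  pairs <- utils::combn(n, 2)
  S <- matrix(NA_real_, nrow(V), ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    S[, p] <- (V[, j] - V[, i]) / (years[j] - years[i])
  }
  med <- apply(S, 1, function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE))
  # pixels with a single valid year produce no valid pair -> NA already;
  # pixels with < 2 valid years likewise
  index_raster(matrix(med, d[1], d[2]), rasters[[1]]$pixel_size_m,
               rasters[[1]]$origin, index_name = "raw-band")
}

#' Greening/browning fractions and areas from a slope raster
#'
#' Greening pixels have slope > `zero_band`, browning pixels slope
#' < -`zero_band`; the rest are neutral. Fractions are taken over unmasked
#' pixels; areas are pixel counts times the pixel area in km2.
#'
#' @param slopes Slope raster (`index_raster`) or numeric matrix.
#' @param zero_band Non-negative slope magnitude below which a pixel counts
#'   as "no trend". Default 0.
#' @param pixel_size_m Pixel size in metres (taken from the raster if given).
#' @return An object of class `trend_summary`: greening/browning/neutral
#'   fractions, greening/browning areas in km2, pixel counts, `zero_band`.
#' @export
greening_browning <- function(slopes, zero_band = 0, pixel_size_m = NULL) {
  if (zero_band < 0) abort_input("'zero_band' must be >= 0")
  if (inherits(slopes, "index_raster")) {
    if (is.null(pixel_size_m)) pixel_size_m <- slopes$pixel_size_m
    slopes <- slopes$values
  }
  if (is.null(pixel_size_m)) pixel_size_m <- 250
  v <- slopes[!is.na(slopes)]
  n <- length(v)
  ng <- sum(v > zero_band)
  nb <- sum(v < -zero_band)
  km2 <- (pixel_size_m / 1000)^2
  structure(list(
    greening_fraction = if (n) ng / n else 0,
    browning_fraction = if (n) nb / n else 0,
    neutral_fraction = if (n) (n - ng - nb) / n else 0,
    greening_km2 = ng * km2, browning_km2 = nb * km2,
    greening_pixels = ng, browning_pixels = nb, n_pixels = n,
    zero_band = zero_band, pixel_size_m = pixel_size_m),
    class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  cat(sprintf(paste0("<trend_summary> greening %.3f (%.3f km2)  browning %.3f",
                     " (%.3f km2)  neutral %.3f  [zero band %g]\n"),
              x$greening_fraction, x$greening_km2, x$browning_fraction,
              x$browning_km2, x$neutral_fraction, x$zero_band))
  invisible(x)
}

#' Histogram of per-pixel trend slopes
#'
#' @param slopes Slope raster or matrix.
#' @param bins Number of histogram bins (>= 1).
#' @param path Optional PNG path; when given, the histogram is plotted there.
#' @return Data frame with columns `mid`, `lower`, `upper`, `count`; counts
#'   sum to the number of unmasked pixels.
#' @export
slope_histogram <- function(slopes, bins = 50, path = NULL) {
  if (bins < 1) abort_input("'bins' must be >= 1")
  if (inherits(slopes, "index_raster")) slopes <- slopes$values
  v <- slopes[!is.na(slopes)]
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1e-6)
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(v, breaks = brk, plot = FALSE, include.lowest = TRUE)
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::plot(h, main = "Trend slope distribution",
                   xlab = "Sen's slope (index / year)", col = "darkseagreen")
  }
  data.frame(mid = h$mids, lower = utils::head(h$breaks, -1),
             upper = utils::tail(h$breaks, -1), count = h$counts)
}

#' Regional mean index trend plot
#'
#' Spatial mean of each yearly composite, plotted as a time series and
#' exported as CSV.
#'
#' @param rasters List of yearly composites.
#' @param years Integer years (>= 2).
#' @param png_path,csv_path Optional output paths.
#' @return Data frame with columns `year`, `mean_index`.
#' @export
evi_trend_plot <- function(rasters, years, png_path = NULL, csv_path = NULL) {
  if (length(years) < 2) abort_input("at least 2 years required")
  check_aligned(rasters)
  m <- vapply(rasters, function(r) mean(r$values, na.rm = TRUE), numeric(1))
  df <- data.frame(year = years, mean_index = m)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::plot(df$year, df$mean_index, type = "b", pch = 19,
                   col = "forestgreen", xlab = "Year",
                   ylab = "Spatial mean index", main = "Annual index trend")
  }
  df
}
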