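#' Georeferenced single-band index raster
#'
#' The core data container of the package: a 2D grid of vegetation-index
#' values (NDVI/EVI, dimensionless, in \[-1, 1\]) or raw band reflectances,
#' with a nodata mask, a ground sampling distance in metres, and opaque
#' placement metadata (origin of the top-left corner; row 0 is the top row).
#' Nodata pixels are stored as `NA` in `values`; `nodata_mask()` derives the
#' boolean mask. No reprojection is performed anywhere in the package: all
#' multi-raster operations require aligned grids.
#'
#' @param values Numeric matrix of index values; `NA` marks nodata.
#' @param pixel_size_m Ground sampling distance in metres (> 0).
#' @param origin Length-2 numeric, map coordinates of the top-left corner
#'   (carried as opaque metadata).
#' @param index_name One of `"NDVI"`, `"EVI"`, `"raw-band"`.
#' @param nodata Optional logical matrix; `TRUE` entries are masked in
#'   addition to any `NA` already present in `values`.
#' @return An object of class `index_raster`.
#' @export
index_raster <- function(values, pixel_size_m = 250, origin = c(0, 0),
                         index_name = c("NDVI", "EVI", "raw-band"),
                         nodata = NULL) {
  index_name <- match.arg(index_name)
  if (!is.matrix(values) || !is.numeric(values))
    abort_input("'values' must be a numeric matrix")
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1 || pixel_size_m <= 0)
    abort_input("'pixel_size_m' must be a single positive number")
  if (!is.null(nodata)) {
    if (!is.logical(nodata) || !identical(dim(nodata), dim(values)))
      abort_input("'nodata' must be a logical matrix with the shape of 'values'")
    values[nodata] <- NA_real_
  }
  if (index_name != "raw-band") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
      abort_input(sprintf("%s values must lie in [-1, 1]", index_name))
  }
  structure(list(values = values, pixel_size_m = pixel_size_m,
                 origin = as.numeric(origin), index_name = index_name),
            class = "index_raster")
}

#' @export
print.index_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<index_raster> %s  %d x %d  pixel %g m  %d nodata\n",
              x$index_name, nrow(x$values), ncol(x$values), x$pixel_size_m,
              sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  range [%.4f, %.4f]  mean %.4f\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' Nodata mask of a raster or class map
#'
#' @param x An `index_raster` or `class_map`.
#' @return Logical matrix, `TRUE` where the pixel is nodata.
#' @export
nodata_mask <- function(x) {
  if (inherits(x, "index_raster")) return(is.na(x$values))
  if (inherits(x, "class_map")) return(is.na(x$labels))
  abort_input("'x' must be an index_raster or class_map")
}

#' Five-class NDVI classification scheme
#'
#' Ordered breakpoints partitioning \[-1, 1\] into five half-open intervals
#' `[-1, b1) [b1, b2) [b2, b3) [b3, b4) [b4, 1]`. The default breakpoints
#' 0, 0.1, 0.25, 0.4 give the standard vegetation classes: no vegetation,
#' bare area, low, moderate and high vegetation. The published class table
#' prints overlapping low/moderate bounds (0.25 vs 0.24); the half-open
#' convention with breakpoint 0.25 resolves this deterministically and covers
#' \[-1, 1\] totally.
#'
#' @param boundaries Four strictly increasing breakpoints inside (-1, 1).
#' @param names Five class names, lowest first.
#' @return An object of class `class_scheme`.
#' @export
class_scheme <- function(boundaries = c(0, 0.1, 0.25, 0.4),
                         names = c("No vegetation", "Bare area",
                                   "Low vegetation", "Moderate vegetation",
                                   "High vegetation")) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 4 || any(diff(boundaries) <= 0) ||
      min(boundaries) <= -1 || max(boundaries) >= 1)
    abort_input("'boundaries' must be 4 strictly increasing values inside (-1, 1)")
  if (length(names) != 5) abort_input("exactly 5 class names required")
  structure(list(boundaries = boundaries, names = as.character(names)),
            class = "class_scheme")
}

#' Serialize / deserialize a class scheme as JSON
#' @param scheme A `class_scheme`.
#' @param path File path.
#' @export
write_class_scheme <- function(scheme, path) {
  jsonlite::write_json(list(boundaries = scheme$boundaries, names = scheme$names),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_class_scheme
#' @export
read_class_scheme <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  class_scheme(j$boundaries, j$names)
}

#' Categorical raster of vegetation classes
#'
#' @param labels Integer matrix with codes 0..4 (`NA` = nodata):
#'   0 no vegetation, 1 bare, 2 low, 3 moderate, 4 high.
#' @param pixel_size_m Ground sampling distance in metres.
#' @param scheme The `class_scheme` that produced the labels.
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, pixel_size_m = 250, scheme = class_scheme()) {
  if (!is.matrix(labels)) abort_input("'labels' must be a matrix")
  lv <- labels[!is.na(labels)]
  if (length(lv) && (any(lv != floor(lv)) || min(lv) < 0 || max(lv) > 4))
    abort_input("labels must be integer codes in 0..4")
  structure(list(labels = labels, pixel_size_m = pixel_size_m, scheme = scheme),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d x %d  pixel %g m\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_m))
  print(class_counts(x))
  invisible(x)
}

#' Per-class pixel counts of a class map
#' @param cm A `class_map`.
#' @return Named integer vector over the five classes.
#' @export
class_counts <- function(cm) {
  counts <- vapply(0:4, function(k) sum(cm$labels == k, na.rm = TRUE), integer(1))
  names(counts) <- cm$scheme$names
  counts
}

#' Compute NDVI from red and NIR reflectance rasters
#'
#' NDVI = (NIR - Red) / (NIR + Red), computed per pixel. Pixels where
#' NIR + Red = 0 (no signal) are masked as nodata, as are pixels masked in
#' either input.
#'
#' @param red,nir `index_raster` objects (index_name `"raw-band"`) or plain
#'   numeric matrices of non-negative reflectances, same shape.
#' @return An `index_raster` with `index_name = "NDVI"`.
#' @export
compute_ndvi <- function(red, nir) {
  b <- check_band_pair(red, nir)
  denom <- b$a + b$b
  v <- ifelse(!is.na(denom) & denom == 0, NA_real_, (b$b - b$a) / denom)
  index_raster(v, pixel_size_m = b$pixel_size_m, origin = b$origin,
               index_name = "NDVI")
}

#' Compute EVI from red, NIR and blue reflectance rasters
#'
#' EVI = G (NIR - Red) / (NIR + C1 Red - C2 Blue + L) with the standard
#' MODIS coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1 by default. Results
#' are clipped to \[-1, 1\]; zero-denominator pixels are masked.
#'
#' @param red,nir,blue Band rasters or matrices, same shape.
#' @param coeffs Named numeric vector with entries `G`, `C1`, `C2`, `L`.
#' @return An `index_raster` with `index_name = "EVI"`.
#' @export
compute_evi <- function(red, nir, blue,
                        coeffs = c(G = 2.5, C1 = 6, C2 = 7.5, L = 1)) {
  b <- check_band_pair(red, nir)
  blu <- band_values(blue)
  if (!identical(dim(blu), dim(b$a))) abort_input("band shapes differ")
  denom <- b$b + coeffs[["C1"]] * b$a - coeffs[["C2"]] * blu + coeffs[["L"]]
  v <- ifelse(!is.na(denom) & denom == 0, NA_real_,
              coeffs[["G"]] * (b$b - b$a) / denom)
  v <- pmin(pmax(v, -1), 1)
  index_raster(v, pixel_size_m = b$pixel_size_m, origin = b$origin,
               index_name = "EVI")
}

band_values <- function(x) {
  if (inherits(x, "index_raster")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else abort_input("bands must be index_raster objects or numeric matrices")
}

check_band_pair <- function(red, nir) {
  a <- band_values(red); b <- band_values(nir)
  if (!identical(dim(a), dim(b))) abort_input("band shapes differ")
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    abort_input("reflectances must be non-negative")
  ps <- if (inherits(red, "index_raster")) red$pixel_size_m else 250
  og <- if (inherits(red, "index_raster")) red$origin else c(0, 0)
  list(a = a, b = b, pixel_size_m = ps, origin = og)
}

#' Classify an NDVI raster into the five vegetation classes
#'
#' Assigns every unmasked pixel one of the codes 0..4 by the half-open
#' intervals of the scheme; nodata propagates. Total on \[-1, 1\]: every
#' unmasked pixel receives exactly one label.
#'
#' @param index An NDVI `index_raster`.
#' @param scheme A `class_scheme`.
#' @return A `class_map`.
#' @export
classify_ndvi <- function(index, scheme = class_scheme()) {
  if (!inherits(index, "index_raster")) abort_input("'index' must be an index_raster")
  if (index$index_name != "NDVI")
    abort_input(sprintf("classify_ndvi needs an NDVI raster, got %s", index$index_name))
  lab <- matrix(NA_integer_, nrow(index$values), ncol(index$values))
  ok <- !is.na(index$values)
  lab[ok] <- findInterval(index$values[ok], scheme$boundaries)
  class_map(lab, pixel_size_m = index$pixel_size_m, scheme = scheme)
}

#' Read / write index rasters
#'
#' TIFF files (`.tif`/`.tiff`) store the values as a 32-bit sample plane
#' rescaled from \[-1, 1\] to \[0, 1\] plus a second plane holding the nodata
#' mask; quantization error is below 5e-10. PNG files (`.png`) store an 8-bit
#' grey + alpha image (alpha 0 = nodata) with 1/255 quantization.
#' Georeferencing (pixel size, origin, index name) travels in a
#' `<path>.aux.json` sidecar; absent a sidecar, defaults are used.
#'
#' @param r An `index_raster`.
#' @param path Destination/source path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_raster` returns an `index_raster`; `write_raster` returns
#'   `path` invisibly.
#' @export
write_raster <- function(r, path) {
  if (!inherits(r, "index_raster")) abort_input("'r' must be an index_raster")
  ext <- tolower(tools::file_ext(path))
  v01 <- (r$values + 1) / 2
  mask <- is.na(r$values)
  v01[mask] <- 0
  if (ext %in% c("tif", "tiff")) {
    arr <- array(c(v01, as.numeric(!mask)), dim = c(dim(v01), 2))
    tiff::writeTIFF(arr, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  } else if (ext == "png") {
    arr <- array(c(pmin(pmax(v01, 0), 1), as.numeric(!mask)), dim = c(dim(v01), 2))
    png::writePNG(arr, path)
  } else abort_format(sprintf("unsupported raster format '.%s'", ext))
  jsonlite::write_json(list(pixel_size_m = r$pixel_size_m, origin = r$origin,
                            index_name = r$index_name),
                       paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    # the 2-plane layout (value + mask) triggers a benign ExtraSamples note
    tryCatch(suppressWarnings(tiff::readTIFF(path)), error = function(e)
      abort_format(sprintf("unreadable TIFF: %s", conditionMessage(e))))
  } else if (ext == "png") {
    tryCatch(png::readPNG(path), error = function(e)
      abort_format(sprintf("unreadable PNG: %s", conditionMessage(e))))
  } else abort_format(sprintf("unsupported raster format '.%s'", ext))
  if (length(dim(arr)) != 3 || dim(arr)[3] != 2)
    abort_format("expected a value plane plus a mask plane (2 channels)")
  v <- arr[, , 1] * 2 - 1
  v[arr[, , 2] < 0.5] <- NA_real_
  meta <- list(pixel_size_m = 250, origin = c(0, 0), index_name = "NDVI")
  aux <- paste0(path, ".aux.json")
  if (file.exists(aux)) {
    m <- jsonlite::read_json(aux, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  index_raster(v, pixel_size_m = meta$pixel_size_m, origin = meta$origin,
               index_name = meta$index_name)
}
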