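#' Severity levels for nuclear cataract grading
#'
#' The three-level ordinal grading scheme used throughout the package:
#' \code{normal < mild < severe}, with ordinal codes 1, 2 and 3.
#'
#' @return Character vector of the three level names, in ordinal order.
#' @export
severity_levels <- function() c("normal", "mild", "severe")

#' Coerce labels to the canonical severity factor
#'
#' @param x character, factor or integer codes (1 = normal, 2 = mild,
#'   3 = severe).
#' @return Ordered factor with levels \code{normal < mild < severe}.
#' @export
as_severity <- function(x) {
  lev <- severity_levels()
  if (is.numeric(x)) {
    if (!all(x %in% 1:3)) stop("severity codes must be 1, 2 or 3")
    x <- lev[x]
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), lev)
  if (length(bad) > 0)
    stop("unknown severity label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = lev, ordered = TRUE)
}

#' Construct a nucleus image
#'
#' Bundles an 8-bit grayscale AS-OCT image with the binary mask delimiting
#' the segmented lens nucleus. Segmentation itself is outside the scope of
#' this package: the mask is an input.
#'
#' @param pixels integer matrix of intensities in \[0, 255\].
#' @param mask binary matrix of the same dimensions; nonzero marks nucleus.
#' @param sample_id identifier string.
#' @param label optional severity label (see [as_severity()]).
#' @return An object of class \code{nucleus_image}.
#' @export
nucleus_image <- function(pixels, mask, sample_id = "sample", label = NULL) {
  pixels <- as.matrix(pixels)
  mask <- as.matrix(mask)
  if (!all(dim(pixels) == dim(mask)))
    stop("pixels and mask must have identical dimensions")
  if (any(pixels < 0 | pixels > 255) || any(pixels != round(pixels)))
    stop("pixels must be integer intensities in [0, 255] (8-bit)")
  mask <- (mask != 0) * 1L
  structure(
    list(pixels = pixels, mask = mask, sample_id = as.character(sample_id),
         label = if (is.null(label)) NULL else as_severity(label)),
    class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("<nucleus_image '%s'> %d x %d, %d nucleus pixels%s\n",
              x$sample_id, nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Histogram configuration
#'
#' Controls how the nucleus-intensity histogram is discretized. The default
#' range 5--150 discards the near-zero background mass and the sparse
#' high-intensity tail; the alternative full range 0--255 and interval 10
#' are provided for ablation comparisons.
#'
#' @param range_lo inclusive lower intensity bound (default 5).
#' @param range_hi inclusive upper intensity bound (default 150).
#' @param interval positive integer bin width (default 5).
#' @param denominator \code{"in_range"} (default) normalizes bin proportions
#'   over in-range pixels only; \code{"all"} normalizes over every masked
#'   pixel, so out-of-range mass deflates all proportions.
#' @return An object of class \code{hist_config}.
#' @export
hist_config <- function(range_lo = 5L, range_hi = 150L, interval = 5L,
                        denominator = c("in_range", "all")) {
  denominator <- match.arg(denominator)
  range_lo <- as.integer(range_lo); range_hi <- as.integer(range_hi)
  interval <- as.integer(interval)
  if (range_lo >= range_hi) stop("range_lo must be < range_hi")
  if (interval < 1 || interval > range_hi - range_lo)
    stop("interval must be a positive integer <= range_hi - range_lo")
  structure(list(range_lo = range_lo, range_hi = range_hi,
                 interval = interval, denominator = denominator),
            class = "hist_config")
}

#' Extract nucleus pixels from a masked image
#'
#' @param image a [nucleus_image()].
#' @return Integer vector of the pixel values at mask positions.
#' @export
extract_masked_pixels <- function(image) {
  stopifnot(inherits(image, "nucleus_image"))
  if (sum(image$mask) == 0) stop("empty nucleus mask")
  as.integer(image$pixels[image$mask == 1L])
}

#' Build the nucleus-intensity histogram
#'
#' Bins are half-open \code{[L_i, L_i + interval)}; the last bin is closed
#' at \code{range_hi} so the upper boundary value is counted exactly once.
#' Pixels outside \code{[range_lo, range_hi]} are discarded before counting.
#' \code{X_i} is the proportion of (by default in-range) pixels per bin and
#' \code{L_i} the left boundary of bin \code{i} (1-based, left to right).
#'
#' @param pixels integer vector of intensities.
#' @param config a [hist_config()].
#' @return Object of class \code{intensity_histogram} with fields \code{N},
#'   \code{L}, \code{X}, \code{interval}, \code{n_pixels}, \code{config}.
#' @export
build_histogram <- function(pixels, config = hist_config()) {
  stopifnot(inherits(config, "hist_config"))
  if (length(pixels) == 0) stop("empty pixel list")
  lo <- config$range_lo; hi <- config$range_hi; w <- config$interval
  N <- as.integer(ceiling((hi - lo) / w))
  keep <- pixels >= lo & pixels <= hi
  n_in <- sum(keep)
  if (n_in == 0) stop("empty histogram")
  idx <- pmin(floor((pixels[keep] - lo) / w) + 1L, N)
  counts <- tabulate(idx, nbins = N)
  denom <- if (config$denominator == "in_range") n_in else length(pixels)
  structure(
    list(N = N, L = lo + (seq_len(N) - 1L) * w, X = counts / denom,
         interval = w, n_pixels = n_in, config = config),
    class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins of width %d on [%d, %d], %d pixels\n",
              x$N, x$interval, x$config$range_lo, x$config$range_hi, x$n_pixels))
  invisible(x)
}

#' Cumulative bin proportions
#'
#' Partial sums \code{C_i = sum(X_1..X_i)} of the histogram proportions;
#' the backbone of the percentile-type features (median, 10th/90th
#' percentile, quartiles).
#'
#' @param h an [build_histogram()] result.
#' @return Numeric vector of length \code{N}, nondecreasing.
#' @export
cumulative_proportions <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  cumsum(h$X)
}

#' Assign pixels to histogram bins
#'
#' @param pixels integer intensities.
#' @param config a [hist_config()].
#' @return Integer bin index per in-range pixel (out-of-range dropped).
#' @keywords internal
bin_index <- function(pixels, config) {
  lo <- config$range_lo; hi <- config$range_hi; w <- config$interval
  N <- as.integer(ceiling((hi - lo) / w))
  keep <- pixels >= lo & pixels <= hi
  pmin(floor((pixels[keep] - lo) / w) + 1L, N)
}

# ---- image and histogram I/O --------------------------------------------

load_gray_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)"))
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    flat <- matrix(arr, ncol = ch)
    if (ch >= 3 && !all(flat[, 1] == flat[, 2] & flat[, 2] == flat[, 3]))
      stop("multi-channel image is not grayscale: ", path)
    arr <- arr[, , 1]
  }
  v <- arr * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop("image is not 8-bit: ", path)
  round(v)
}

#' Read an AS-OCT image and its nucleus mask
#'
#' @param image_path path to an 8-bit grayscale PNG or TIFF.
#' @param mask_path path to a mask image of identical size; nonzero pixels
#'   mark the nucleus.
#' @param sample_id,label forwarded to [nucleus_image()]; defaults to the
#'   image file name.
#' @return A [nucleus_image()].
#' @export
read_nucleus_image <- function(image_path, mask_path,
                               sample_id = tools::file_path_sans_ext(basename(image_path)),
                               label = NULL) {
  nucleus_image(load_gray_matrix(image_path),
                load_gray_matrix(mask_path) != 0,
                sample_id = sample_id, label = label)
}

#' Write a nucleus image and mask as PNG files
#'
#' @param image a [nucleus_image()].
#' @param image_path,mask_path output PNG paths.
#' @return Invisibly, \code{image_path}.
#' @export
write_nucleus_image <- function(image, image_path, mask_path) {
  png::writePNG(image$pixels / 255, image_path)
  png::writePNG(image$mask * 1.0, mask_path)
  invisible(image_path)
}

#' Serialize a histogram to CSV
#'
#' Writes columns \code{(i, L_i, X_i)} preceded by a one-line JSON comment
#' header carrying the histogram configuration.
#'
#' @param h an \code{intensity_histogram}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_histogram_csv <- function(h, path) {
  header <- paste0("# ", jsonlite::toJSON(unclass(h$config), auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(data.frame(i = seq_len(h$N), L_i = h$L, X_i = h$X),
                   con, row.names = FALSE)
  invisible(path)
}
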