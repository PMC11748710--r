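#' Canonical names of the 27 visual features
#'
#' 23 statistics of the nucleus-intensity histogram followed by 4 clinical
#' statistics of the raw masked pixels, in the catalog's canonical order.
#' Moment-type histogram features (mean, variance, skewness, kurtosis,
#' deviations, entropy, uniformity, percentile indices) are computed on bin
#' indices \code{i}; boundary-type features (minimum, maximum, interquartile,
#' range, quartile dispersion) on left boundaries \code{L_i}.
#'
#' @return Character vector of length 27.
#' @export
feature_names <- function() {
  c("D-Mean", "D-Variance", "D-Skewness", "D-Kurtosis", "D-Median",
    "IH-Mean", "IHR-Mean", "IH-Median", "IHC-Variation", "D-Entropy",
    "D-Uniformity", "D-Ten", "D-Ninety", "IH-Mode", "D-Minimum",
    "D-Maximum", "D-Interquartile", "D-Range", "IHC-Dispersion",
    "G-Maximum", "GI-Maximum", "G-Minimum", "GI-Minimum",
    "I-Mean", "I-Median", "I-STD", "I-Maximum")
}

# features whose value is a histogram bin index (used by the tie rule of
# select_features): location features rather than raw statistics
index_valued_features <- function() {
  c("D-Median", "D-Ten", "D-Ninety", "IH-Mode", "GI-Maximum", "GI-Minimum")
}

#' Histogram-based statistical features
#'
#' Computes the 23 statistics of a nucleus-intensity histogram. With
#' proportions \code{X_i} over bins \code{i = 1..N} and discretization mean
#' \code{mu = sum(i * X_i)}:
#' \itemize{
#'   \item moments: \code{D-Mean = mu}; \code{D-Variance = sum((i-mu)^2 X_i)};
#'     \code{D-Skewness} and \code{D-Kurtosis} are the standardized third and
#'     fourth moments, kurtosis in excess form (minus 3);
#'   \item deviations: \code{IH-Mean = sum(|i-mu| X_i)}; \code{IHR-Mean}
#'     restricts the sum to bins between the 10th and 90th percentile indices
#'     (no renormalization unless \code{ihr_renormalize}); \code{IH-Median}
#'     uses the median index \code{m} in place of \code{mu};
#'     \code{IHC-Variation = sigma / mu};
#'   \item distribution shape: \code{D-Entropy} in bits over occupied bins;
#'     \code{D-Uniformity = sum(X_i^2)};
#'   \item percentiles (indices): \code{D-Median}, \code{D-Ten},
#'     \code{D-Ninety} are the smallest indices where the cumulative
#'     proportion reaches 0.5, 0.10, 0.90; \code{IH-Mode} is the index of the
#'     largest proportion (first on ties);
#'   \item boundaries: \code{D-Minimum}/\code{D-Maximum} are the left
#'     boundaries of the lowest/highest occupied bin; \code{D-Interquartile},
#'     \code{D-Range} and \code{IHC-Dispersion} are boundary differences and
#'     the quartile coefficient of dispersion;
#'   \item gradient: forward differences \code{g_i = X_{i+1} - X_i};
#'     \code{G-Maximum}/\code{G-Minimum} with their first-occurrence indices
#'     \code{GI-Maximum}/\code{GI-Minimum}.
#' }
#' Degenerate cases are kept finite by convention: a single-occupied-bin
#' histogram has skewness and kurtosis 0 (0/0), and a zero quartile-boundary
#' sum gives dispersion 0; both emit a warning.
#'
#' @param h an [build_histogram()] result.
#' @param ihr_renormalize if TRUE, renormalize the truncated mass in
#'   \code{IHR-Mean} by the retained proportion (default FALSE: the literal
#'   truncated sum).
#' @return Named numeric vector of the 23 histogram features.
#' @export
histogram_features <- function(h, ihr_renormalize = FALSE) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$n_pixels == 0) stop("empty histogram")
  X <- h$X; N <- h$N; L <- h$L
  i <- seq_len(N)
  C <- cumsum(X)
  # total is 1 under the default in-range normalization; < 1 under
  # denominator = "all" when out-of-range mass exists. Moment formulas use X
  # literally; percentile crossings are taken relative to the binned mass so
  # they stay defined either way.
  total <- C[N]

  mu <- sum(i * X)
  v <- sum((i - mu)^2 * X)
  sigma <- sqrt(v)
  if (v > 0) {
    skew <- sum((i - mu)^3 * X) / v^1.5
    kurt <- sum((i - mu)^4 * X) / v^2 - 3
  } else {
    warning("single occupied bin: skewness and kurtosis set to 0")
    skew <- 0; kurt <- 0
  }

  first_reach <- function(q) which(C >= q * total - 1e-12)[1]
  med_i <- first_reach(0.5)
  p10 <- first_reach(0.10)
  p90 <- first_reach(0.90)
  q25 <- first_reach(0.25)
  q75 <- first_reach(0.75)

  ih_mean <- sum(abs(i - mu) * X)
  in_band <- i >= p10 & i <= p90
  ihr <- sum(abs(i[in_band] - mu) * X[in_band])
  if (ihr_renormalize) {
    band_mass <- sum(X[in_band])
    ihr <- if (band_mass > 0) ihr / band_mass else 0
  }
  ih_median <- sum(abs(i - med_i) * X)
  ihc_var <- if (mu > 0) sigma / mu else 0

  pos <- X > 0
  entropy <- -sum(X[pos] * log2(X[pos]))
  uniformity <- sum(X^2)

  mode_i <- which.max(X)
  occ <- which(pos)
  L_min <- L[occ[1]]
  L_max <- L[occ[length(occ)]]
  iqr <- L[q75] - L[q25]
  denom_q <- L[q75] + L[q25]
  if (denom_q != 0) {
    disp <- iqr / denom_q
  } else {
    if (iqr != 0) warning("quartile boundary sum is 0: IHC-Dispersion set to 0")
    disp <- 0
  }

  if (N >= 2) {
    g <- diff(X)
    g_max <- max(g); gi_max <- which.max(g)
    g_min <- min(g); gi_min <- which.min(g)
  } else {
    g_max <- 0; gi_max <- 1L; g_min <- 0; gi_min <- 1L
  }

  c("D-Mean" = mu, "D-Variance" = v, "D-Skewness" = skew,
    "D-Kurtosis" = kurt, "D-Median" = as.numeric(med_i),
    "IH-Mean" = ih_mean, "IHR-Mean" = ihr, "IH-Median" = ih_median,
    "IHC-Variation" = ihc_var, "D-Entropy" = entropy,
    "D-Uniformity" = uniformity, "D-Ten" = as.numeric(p10),
    "D-Ninety" = as.numeric(p90), "IH-Mode" = as.numeric(mode_i),
    "D-Minimum" = L_min, "D-Maximum" = L_max, "D-Interquartile" = iqr,
    "D-Range" = L_max - L_min, "IHC-Dispersion" = disp,
    "G-Maximum" = g_max, "GI-Maximum" = as.numeric(gi_max),
    "G-Minimum" = g_min, "GI-Minimum" = as.numeric(gi_min))
}

#' Clinical intensity-based features
#'
#' The four statistics computed on all masked nucleus pixels of the raw
#' image (no intensity-range filtering): mean, median, standard deviation
#' and maximum. The standard deviation uses the population denominator
#' \code{n} by default, switchable to the sample denominator \code{n - 1}.
#'
#' @param pixels integer vector of masked pixel values.
#' @param sd_denominator \code{"population"} (default) or \code{"sample"}.
#' @return Named numeric vector of the 4 intensity features.
#' @export
intensity_features <- function(pixels,
                               sd_denominator = c("population", "sample")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(pixels) == 0) stop("empty pixel list")
  n <- length(pixels)
  v <- if (n > 1) stats::var(pixels) * (n - 1) / n else 0
  if (sd_denominator == "sample") v <- if (n > 1) stats::var(pixels) else 0
  c("I-Mean" = mean(pixels), "I-Median" = stats::median(pixels),
    "I-STD" = sqrt(v), "I-Maximum" = as.numeric(max(pixels)))
}

#' Extract the full 27-feature vector from a nucleus image
#'
#' Composes [extract_masked_pixels()], [build_histogram()],
#' [histogram_features()] and [intensity_features()]: 23 histogram features
#' plus 4 intensity features, named and ordered canonically
#' (see [feature_names()]).
#'
#' @param image a [nucleus_image()].
#' @param config a [hist_config()].
#' @param ... forwarded to [histogram_features()].
#' @return Named numeric vector of length 27.
#' @export
extract_features <- function(image, config = hist_config(), ...) {
  px <- extract_masked_pixels(image)
  out <- c(histogram_features(build_histogram(px, config), ...),
           intensity_features(px))
  out[feature_names()]
}

#' Extract a labeled feature table from a list of images
#'
#' @param images list of [nucleus_image()] objects (labels taken from each
#'   image when present).
#' @param config a [hist_config()].
#' @return A \code{data.frame} with columns \code{sample_id}, the 27
#'   features, and \code{label}.
#' @export
extract_feature_table <- function(images, config = hist_config()) {
  rows <- lapply(images, function(im) extract_features(im, config))
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- cbind(sample_id = vapply(images, `[[`, "", "sample_id"), out,
               stringsAsFactors = FALSE)
  labels <- lapply(images, `[[`, "label")
  if (!any(vapply(labels, is.null, TRUE)))
    out$label <- as_severity(vapply(labels, as.character, ""))
  rownames(out) <- NULL
  out
}

#' Split a feature table into its matrix and label parts
#' @keywords internal
table_parts <- function(table, features = NULL) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (is.null(features))
    features <- setdiff(names(table), c("sample_id", "label", "participant"))
  missing <- setdiff(features, names(table))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  list(x = as.matrix(table[, features, drop = FALSE]),
       y = as_severity(table$label), features = features)
}

#' Write / read a feature table CSV
#'
#' One row per sample: \code{sample_id}, the 27 canonical feature columns,
#' \code{label}.
#'
#' @param table feature table data.frame.
#' @param path CSV path.
#' @return \code{write_feature_csv} invisibly returns \code{path};
#'   \code{read_feature_csv} returns the data.frame.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("label" %in% names(out)) out$label <- as_severity(out$label)
  out
}
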