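#' Per-class intensity profile for the synthetic generator
#'
#' Pixel intensities inside the synthetic nucleus follow a three-component
#' mixture: a near-zero background spike (uniform on 0..4), a truncated
#' normal opacity component, and a uniform high-intensity tail. The class
#' profiles differ in the opacity location/spread and the tail weight, which
#' is what makes the class histograms distinguishable while the raw images
#' look alike.
#'
#' @param label severity label.
#' @param mix_weight_background proportion of near-zero background pixels.
#' @param opacity_mean,opacity_sd truncated-normal opacity component
#'   (intensity units).
#' @param tail_weight proportion in the high-intensity tail.
#' @param tail_range support of the uniform tail (intensity units).
#' @return Object of class \code{class_profile}.
#' @export
class_profile <- function(label, mix_weight_background = 0.20,
                          opacity_mean = 55, opacity_sd = 12,
                          tail_weight = 0.05, tail_range = c(110, 180)) {
  stopifnot(mix_weight_background >= 0, tail_weight >= 0,
            mix_weight_background + tail_weight <= 1,
            opacity_sd > 0, length(tail_range) == 2,
            tail_range[1] < tail_range[2])
  structure(list(label = as.character(as_severity(label)),
                 mix_weight_background = mix_weight_background,
                 opacity_mean = opacity_mean, opacity_sd = opacity_sd,
                 tail_weight = tail_weight, tail_range = tail_range),
            class = "class_profile")
}

#' Default severity-class profiles
#'
#' Normal lenses concentrate mass at low intensities; increasing severity
#' shifts the opacity component upward, widens it, and adds a heavier
#' high-intensity tail. Defaults: normal mean 30 / sd 8 / no tail, mild mean
#' 55 / sd 12 / tail 0.05, severe mean 85 / sd 18 / tail 0.15. These are
#' package defaults for the simulation, not clinical measurements.
#'
#' @return Named list of three [class_profile()] objects.
#' @export
default_profiles <- function() {
  list(normal = class_profile("normal", opacity_mean = 30, opacity_sd = 8,
                              tail_weight = 0.00),
       mild = class_profile("mild", opacity_mean = 55, opacity_sd = 12,
                            tail_weight = 0.05),
       severe = class_profile("severe", opacity_mean = 85, opacity_sd = 18,
                              tail_weight = 0.15))
}

#' Collapsed (indistinguishable) class profiles
#'
#' All three classes share the mild profile, so labels carry no signal and
#' any classifier should fall to chance. Used to verify that reported
#' accuracies are earned, not artifacts.
#'
#' @return Named list of three identical-[class_profile()] objects bar label.
#' @export
collapsed_profiles <- function() {
  base <- default_profiles()$mild
  lapply(stats::setNames(severity_levels(), severity_levels()), function(cl) {
    p <- base; p$label <- cl; p
  })
}

#' Simulation configuration
#'
#' @param image_size c(height, width) in pixels.
#' @param center ellipse center c(row, col); default the image center.
#' @param axes ellipse semi-axes c(row, col) in pixels.
#' @param profiles one [class_profile()] per class.
#' @param n_per_class images per class.
#' @param seed base RNG seed; image k uses seed + k so any subset of the
#'   dataset is reproducible independently.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(image_size = c(64, 64), center = NULL,
                       axes = c(20, 26), profiles = default_profiles(),
                       n_per_class = 50, seed = 1) {
  if (is.null(center)) center <- (image_size + 1) / 2
  if (any(axes < 1)) stop("degenerate ellipse")
  if (center[1] - axes[1] < 1 || center[1] + axes[1] > image_size[1] ||
      center[2] - axes[2] < 1 || center[2] + axes[2] > image_size[2])
    stop("ellipse does not fit inside the image")
  stopifnot(n_per_class >= 1)
  structure(list(image_size = image_size, center = center, axes = axes,
                 profiles = profiles, n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "sim_config")
}

ellipse_mask <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - config$center[1]) / config$axes[1])^2 +
    ((c_ - config$center[2]) / config$axes[2])^2 <= 1
}

# draw from N(mean, sd) truncated to [0, 255] by inverse-CDF sampling
rtnorm255 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd); hi <- stats::pnorm(255, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Analytic mean of a profile's nucleus-intensity mixture
#'
#' Expected (pre-rounding) intensity of pixels drawn from a profile,
#' optionally restricted to an intensity window -- the closed-form
#' counterpart used to validate the sampler.
#'
#' @param profile a [class_profile()].
#' @param window optional c(lo, hi) intensity window; components and the
#'   truncated-normal mass are re-weighted to the window.
#' @return Expected intensity (numeric scalar).
#' @export
profile_mean <- function(profile, window = NULL) {
  w_bg <- profile$mix_weight_background
  w_tail <- profile$tail_weight
  w_op <- 1 - w_bg - w_tail
  mu <- profile$opacity_mean; s <- profile$opacity_sd
  tr <- profile$tail_range
  # truncated-normal mean on [a, b]
  tn_mean <- function(a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    Z <- stats::pnorm(be) - stats::pnorm(al)
    mu + s * (stats::dnorm(al) - stats::dnorm(be)) / Z
  }
  tn_mass <- function(a, b)
    (stats::pnorm(b, mu, s) - stats::pnorm(a, mu, s)) /
      (stats::pnorm(255, mu, s) - stats::pnorm(0, mu, s))
  if (is.null(window)) {
    bg_mean <- 2        # uniform on integers 0..4
    op_mean <- tn_mean(0, 255)
    tail_mean <- mean(tr)
    return(w_bg * bg_mean + w_op * op_mean + w_tail * tail_mean)
  }
  lo <- window[1]; hi <- window[2]
  # per-component mass falling inside the window and its conditional mean
  bg_vals <- 0:4
  bg_in <- bg_vals >= lo & bg_vals <= hi
  comp_mass <- c(w_bg * mean(bg_in),
                 w_op * tn_mass(max(lo, 0), min(hi, 255)),
                 w_tail * max(0, (min(hi, tr[2]) - max(lo, tr[1]))) / diff(tr))
  comp_mean <- c(if (any(bg_in)) mean(bg_vals[bg_in]) else 0,
                 tn_mean(max(lo, 0), min(hi, 255)),
                 (max(lo, tr[1]) + min(hi, tr[2])) / 2)
  sum(comp_mass * comp_mean) / sum(comp_mass)
}

#' Generate one synthetic AS-OCT-like nucleus image
#'
#' Pixels outside the elliptical nucleus are 0; inside, each pixel draws its
#' mixture component independently (background spike, truncated-normal
#' opacity, uniform tail), and values are rounded and clipped to \[0, 255\].
#' The mask is exactly the ellipse indicator. The same (profile, config,
#' seed) always yields a byte-identical image.
#'
#' @param profile a [class_profile()].
#' @param config a [sim_config()].
#' @param seed RNG seed for this image.
#' @param sample_id identifier.
#' @return A [nucleus_image()] carrying the profile's label.
#' @export
generate_image <- function(profile, config = sim_config(), seed = 1,
                           sample_id = paste0(profile$label, "_", seed)) {
  mask <- ellipse_mask(config)
  n <- sum(mask)
  set.seed(seed)
  comp <- sample(1:3, n, replace = TRUE,
                 prob = c(profile$mix_weight_background,
                          1 - profile$mix_weight_background - profile$tail_weight,
                          profile$tail_weight))
  v <- numeric(n)
  v[comp == 1] <- sample(0:4, sum(comp == 1), replace = TRUE)
  v[comp == 2] <- rtnorm255(sum(comp == 2), profile$opacity_mean,
                            profile$opacity_sd)
  v[comp == 3] <- stats::runif(sum(comp == 3), profile$tail_range[1],
                               profile$tail_range[2])
  pixels <- matrix(0L, config$image_size[1], config$image_size[2])
  pixels[mask] <- as.integer(pmin(pmax(round(v), 0), 255))
  nucleus_image(pixels, mask, sample_id = sample_id, label = profile$label)
}

#' Generate a labeled synthetic dataset
#'
#' \code{n_per_class} images per severity class with per-image seeds derived
#' as \code{config$seed + index}, so the whole dataset is a pure function of
#' the configuration.
#'
#' @param config a [sim_config()].
#' @param extract if TRUE, also extract the 27-feature table.
#' @param hist_config histogram settings for feature extraction.
#' @return List with \code{images} (list of [nucleus_image()]),
#'   \code{labels}, and, when \code{extract}, \code{table}.
#' @export
generate_dataset <- function(config = sim_config(), extract = FALSE,
                             hist_config = octgrade::hist_config()) {
  images <- list(); k <- 0L
  for (cl in severity_levels()) {
    profile <- config$profiles[[cl]]
    for (j in seq_len(config$n_per_class)) {
      k <- k + 1L
      images[[k]] <- generate_image(
        profile, config, seed = config$seed + k,
        sample_id = sprintf("%s_%03d", cl, j))
    }
  }
  out <- list(images = images,
              labels = as_severity(vapply(images, function(im)
                as.character(im$label), "")))
  if (extract) out$table <- extract_feature_table(images, hist_config)
  out
}
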