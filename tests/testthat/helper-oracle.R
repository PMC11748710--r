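# Brute-force oracles, independent of the package's vectorized paths.

# per-pixel bin assignment by linear scan over bin edges
oracle_bin_one <- function(v, lo, hi, w) {
  N <- ceiling((hi - lo) / w)
  for (i in seq_len(N)) {
    left <- lo + (i - 1) * w
    right <- if (i == N) hi else left + w
    if (i == N) {
      if (v >= left && v <= right) return(i)
    } else if (v >= left && v < right) return(i)
  }
  NA_integer_
}

# all 23 histogram statistics recomputed from raw per-pixel bin indices
oracle_histogram_stats <- function(pixels, lo = 5, hi = 150, w = 5) {
  N <- ceiling((hi - lo) / w)
  L <- lo + (seq_len(N) - 1) * w
  inr <- pixels[pixels >= lo & pixels <= hi]
  idx <- vapply(inr, oracle_bin_one, integer(1), lo = lo, hi = hi, w = w)
  n <- length(idx)
  p <- vapply(seq_len(N), function(i) sum(idx == i) / n, numeric(1))

  mu <- mean(idx)
  v <- mean((idx - mu)^2)
  skew <- if (v > 0) mean((idx - mu)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((idx - mu)^4) / v^2 - 3 else 0

  # percentile indices by scanning cumulative counts
  reach <- function(q) {
    acc <- 0
    for (i in seq_len(N)) {
      acc <- acc + sum(idx == i)
      if (acc / n >= q - 1e-12) return(i)
    }
    N
  }
  med <- reach(0.5); p10 <- reach(0.10); p90 <- reach(0.90)
  q25 <- reach(0.25); q75 <- reach(0.75)

  ih_mean <- mean(abs(idx - mu))
  ihr <- sum(abs(idx[idx >= p10 & idx <= p90] - mu)) / n
  ih_median <- mean(abs(idx - med))
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  uniformity <- sum(p^2)

  mode_i <- which.max(p)
  occ <- range(idx)
  iqr <- L[q75] - L[q25]
  disp <- if (L[q75] + L[q25] != 0) iqr / (L[q75] + L[q25]) else 0
  g <- p[-1] - p[-N]

  c("D-Mean" = mu, "D-Variance" = v, "D-Skewness" = skew,
    "D-Kurtosis" = kurt, "D-Median" = as.numeric(med),
    "IH-Mean" = ih_mean, "IHR-Mean" = ihr, "IH-Median" = ih_median,
    "IHC-Variation" = if (mu > 0) sqrt(v) / mu else 0,
    "D-Entropy" = entropy, "D-Uniformity" = uniformity,
    "D-Ten" = as.numeric(p10), "D-Ninety" = as.numeric(p90),
    "IH-Mode" = as.numeric(mode_i),
    "D-Minimum" = L[occ[1]], "D-Maximum" = L[occ[2]],
    "D-Interquartile" = iqr, "D-Range" = L[occ[2]] - L[occ[1]],
    "IHC-Dispersion" = disp,
    "G-Maximum" = max(g), "GI-Maximum" = as.numeric(which.max(g)),
    "G-Minimum" = min(g), "GI-Minimum" = as.numeric(which.min(g)))
}

# ridge objective minimized numerically (oracle for the closed form)
oracle_ridge_minimize <- function(X, Y, lambda) {
  obj <- function(w) sum((X %*% w - Y)^2) + lambda * sum(w^2)
  grad <- function(w) drop(2 * (crossprod(X) %*% w - crossprod(X, Y)) +
                             2 * lambda * w)
  stats::optim(rep(0, ncol(X)), obj, grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 5000))$par
}

# small labeled feature table with planted class signal in the first column
make_toy_table <- function(n_per_class = 20, n_features = 4, sep = 3,
                           seed = 1) {
  set.seed(seed)
  classes <- severity_levels()
  n <- n_per_class * 3
  x <- matrix(rnorm(n * n_features), n, n_features)
  y <- rep(classes, each = n_per_class)
  x[, 1] <- x[, 1] + sep * (match(y, classes) - 2)
  colnames(x) <- paste0("f", seq_len(n_features))
  out <- as.data.frame(x)
  out <- cbind(sample_id = sprintf("s%03d", seq_len(n)), out)
  out$label <- y
  out
}

# class means on a 2-D triangle: each class linearly separable one-vs-all
make_separable_table <- function(n_per_class = 20, n_features = 4, sep = 5,
                                 seed = 1) {
  out <- make_toy_table(n_per_class, max(2, n_features), sep = 0, seed = seed)
  code <- match(out$label, severity_levels())
  out$f1 <- out$f1 + sep * (code - 2)
  out$f2 <- out$f2 + sep * (code == 2)
  out
}
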