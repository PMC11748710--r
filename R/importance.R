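#' Pearson correlation with a constant-variable convention
#'
#' Plain Pearson correlation between two equal-length vectors. When either
#' variable is constant the coefficient is undefined (zero denominator); the
#' convention here returns 0 with attribute \code{constant = TRUE}, so
#' degenerate features (e.g. a minimum-boundary feature that is identically
#' its lowest value) propagate zeros rather than NAs through the
#' correlation matrix.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\]; attribute \code{constant} flags the
#'   degenerate case.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, constant = TRUE))
  structure(stats::cor(x, y), constant = FALSE)
}

#' Pairwise Pearson correlation matrix of a feature table
#'
#' Entry (a, b) is [pcc()] of columns a and b. The matrix is exactly
#' symmetric; the diagonal is 1 for non-constant features and 0 for constant
#' ones (matching the constant-variable convention).
#'
#' @param table feature table data.frame (non-feature columns ignored) or
#'   numeric matrix.
#' @param features optional subset of feature columns.
#' @return Symmetric numeric matrix with feature dimnames.
#' @export
pcc_matrix <- function(table, features = NULL) {
  x <- if (is.data.frame(table)) {
    if (is.null(features))
      features <- setdiff(names(table), c("sample_id", "label", "participant"))
    as.matrix(table[, features, drop = FALSE])
  } else as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  m <- suppressWarnings(stats::cor(x))
  m[!is.finite(m)] <- 0
  m[sds == 0, ] <- 0
  m[, sds == 0] <- 0
  diag(m) <- ifelse(sds > 0, 1, 0)
  (m + t(m)) / 2
}

#' EMRR model factory for Shapley attribution
#'
#' Returns a trainer suitable for [shap_values()]: given a feature submatrix
#' and labels it fits an EMRR model and returns a predictor mapping a full
#' feature matrix to per-class softmax probabilities. The empty feature set
#' trains nothing and predicts the training-label class frequencies.
#'
#' @param lambda,standardize forwarded to [fit_emrr()].
#' @return Function \code{(x, y) -> (newx -> n x C probability matrix)}.
#' @export
emrr_factory <- function(lambda = 1, standardize = TRUE) {
  function(x, y) {
    classes <- severity_levels()
    if (ncol(x) == 0) {
      freq <- as.numeric(prop.table(table(factor(y, classes))))
      return(function(newx) {
        n <- if (is.null(dim(newx))) 1L else nrow(newx)
        matrix(freq, nrow = n, ncol = length(classes), byrow = TRUE,
               dimnames = list(NULL, classes))
      })
    }
    model <- fit_emrr(x, labels = y, lambda = lambda,
                      standardize = standardize)
    cols <- colnames(x)
    function(newx) predict(model, newx[, cols, drop = FALSE], type = "prob")
  }
}

#' Retraining-based Shapley feature attribution
#'
#' Computes, for every feature, sample and class, the Shapley value of the
#' feature for the model's predicted class probability: the average over
#' feature subsets \code{S} (weighted by \code{|S|!(|T|-|S|-1)!/|T|!}) of
#' the change in prediction when the feature joins \code{S}, with the model
#' retrained from scratch on every subset. The empty-subset model predicts
#' the training class frequencies.
#'
#' \code{mode = "exact"} enumerates all \code{2^|T|} subsets and is limited
#' to at most 12 features. \code{mode = "sampled"} averages marginal
#' contributions over random feature orderings (an unbiased estimator of the
#' same sum), using antithetic permutation pairs (each ordering together
#' with its reverse) to reduce variance; retrained submodels are cached by
#' subset, so the cost is bounded by the number of distinct subsets
#' encountered.
#'
#' @param table feature table data.frame with a \code{label} column.
#' @param model_factory trainer, see [emrr_factory()] (the default).
#' @param mode \code{"exact"} or \code{"sampled"}.
#' @param n_permutations number of orderings in sampled mode.
#' @param seed RNG seed for sampled mode (mandatory determinism).
#' @param features optional subset of feature columns.
#' @return Object of class \code{shap_result}: array \code{phi} of dimension
#'   samples x features x classes, plus \code{baseline} (empty-set
#'   predictions) and \code{full} (all-feature predictions).
#' @export
shap_values <- function(table, model_factory = emrr_factory(),
                        mode = c("exact", "sampled"), n_permutations = 2000,
                        seed = 1, features = NULL) {
  mode <- match.arg(mode)
  parts <- table_parts(table, features)
  x <- parts$x; y <- parts$y
  M <- ncol(x); n <- nrow(x)
  classes <- severity_levels(); C <- length(classes)
  if (mode == "exact" && M > 12)
    stop("exact Shapley infeasible, use sampled")

  cache <- new.env(parent = emptyenv())
  predict_subset <- function(idx) {
    key <- paste0("s", paste(idx, collapse = "_"))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    p <- model_factory(x[, idx, drop = FALSE], y)(x)
    cache[[key]] <- p
    p
  }

  phi <- array(0, dim = c(n, M, C),
               dimnames = list(NULL, parts$features, classes))

  if (mode == "exact") {
    bits <- 2^(seq_len(M) - 1)
    masks <- 0:(2^M - 1)
    sizes <- vapply(masks, function(m) sum(bitwAnd(m, bits) > 0), numeric(1))
    w <- exp(lgamma(0:(M - 1) + 1) + lgamma(M - (0:(M - 1))) - lgamma(M + 1))
    preds <- lapply(masks, function(m)
      predict_subset(which(bitwAnd(m, bits) > 0)))
    for (i in seq_len(M)) {
      for (m in masks[bitwAnd(masks, bits[i]) == 0]) {
        dlt <- preds[[m + bits[i] + 1]] - preds[[m + 1]]
        phi[, i, ] <- phi[, i, ] + w[sizes[m + 1] + 1] * dlt
      }
    }
  } else {
    set.seed(seed)
    half <- ceiling(n_permutations / 2)
    perms <- vector("list", 2 * half)
    for (j in seq_len(half)) {
      p <- sample.int(M)
      perms[[2 * j - 1]] <- p
      perms[[2 * j]] <- rev(p)
    }
    perms <- perms[seq_len(n_permutations)]
    p_empty <- predict_subset(integer(0))
    for (perm in perms) {
      idx <- integer(0); prev <- p_empty
      for (i in perm) {
        idx <- sort(c(idx, i))
        cur <- predict_subset(idx)
        phi[, i, ] <- phi[, i, ] + (cur - prev)
        prev <- cur
      }
    }
    phi <- phi / length(perms)
  }

  structure(list(phi = phi, features = parts$features, classes = classes,
                 mode = mode,
                 n_permutations = if (mode == "sampled") n_permutations else NULL,
                 baseline = predict_subset(integer(0)),
                 full = predict_subset(seq_len(M))),
            class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("<shap_result> %d samples x %d features x %d classes (%s mode)\n",
              dim(x$phi)[1], dim(x$phi)[2], dim(x$phi)[3], x$mode))
  invisible(x)
}

#' Overall and per-class mean absolute Shapley values
#'
#' \code{overall_shap} averages \code{|phi|} over samples and classes per
#' feature; \code{per_class_shap} averages over samples only, keeping the
#' class dimension.
#'
#' @param shap a [shap_values()] result (or a bare phi array).
#' @return Named nonnegative vector (overall) or features x classes matrix.
#' @export
overall_shap <- function(shap) {
  phi <- if (inherits(shap, "shap_result")) shap$phi else shap
  apply(abs(phi), 2, mean)
}

#' @rdname overall_shap
#' @export
per_class_shap <- function(shap) {
  phi <- if (inherits(shap, "shap_result")) shap$phi else shap
  apply(abs(phi), c(2, 3), mean)
}

#' Stratified train/test split indicator
#' @keywords internal
split_train_test <- function(labels, fraction = 0.7, seed = 1) {
  labels <- as_severity(labels)
  set.seed(seed)
  train <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0) next
    k <- max(1, min(length(idx) - 1, round(fraction * length(idx))))
    if (length(idx) == 1) k <- 1
    train[idx[sample.int(length(idx), k)]] <- TRUE
  }
  train
}

#' Held-out accuracy of an EMRR trained on a single feature
#'
#' Trains the ridge ensemble on one feature alone (stratified split) and
#' returns plain classification accuracy on the held-out rows. A constant
#' feature degenerates to an intercept-only fit and returns the held-out
#' majority-class rate.
#'
#' @param table feature table with a \code{label} column.
#' @param feature feature column name.
#' @param split_fraction training fraction (default 0.7).
#' @param split_seed RNG seed for the split.
#' @param lambda ridge penalty.
#' @return Accuracy in \[0, 1\].
#' @export
single_feature_accuracy <- function(table, feature, split_fraction = 0.7,
                                    split_seed = 1, lambda = 1) {
  parts <- table_parts(table, feature)
  train <- split_train_test(parts$y, split_fraction, split_seed)
  model <- fit_emrr(parts$x[train, , drop = FALSE],
                    labels = parts$y[train], lambda = lambda)
  pred <- predict(model, parts$x[!train, , drop = FALSE])
  mean(pred == parts$y[!train])
}

#' Feature-selection rule
#'
#' Codifies the two-stage selection: (1) drop features whose overall
#' Shapley importance is below \code{shap_floor} (negligible contribution);
#' (2) for each redundant pair -- either listed explicitly in
#' \code{resolved_pairs} or detected by \code{|PCC| >=
#' redundancy_threshold} -- drop the member with the lower overall Shapley
#' value. On exact ties the raw-statistic partner of a location/index-valued
#' feature is dropped (keeping the index), otherwise the alphabetically
#' later name.
#'
#' @param shap_floor minimum overall Shapley value to retain (>= 0).
#' @param redundancy_threshold absolute-correlation threshold in (0, 1\];
#'   only applied when a correlation matrix is available.
#' @param resolved_pairs optional list of 2-element character vectors naming
#'   redundant pairs directly.
#' @return Object of class \code{selection_rule}.
#' @export
selection_rule <- function(shap_floor = 0.015, redundancy_threshold = 0.95,
                           resolved_pairs = NULL) {
  stopifnot(shap_floor >= 0,
            redundancy_threshold > 0, redundancy_threshold <= 1)
  structure(list(shap_floor = shap_floor,
                 redundancy_threshold = redundancy_threshold,
                 resolved_pairs = resolved_pairs),
            class = "selection_rule")
}

#' Select informative features from an importance report
#'
#' Applies a [selection_rule()] to per-feature overall Shapley values and
#' (optionally) a pairwise correlation matrix. The retained set preserves
#' the input feature order.
#'
#' @param report an [importance_report()] object, or a data.frame with
#'   columns \code{feature} and \code{overall_shap}.
#' @param rule a [selection_rule()].
#' @param pcc_mat optional feature x feature correlation matrix (taken from
#'   the report when present).
#' @return Character vector of retained feature names, in input order.
#' @export
select_features <- function(report, rule = selection_rule(), pcc_mat = NULL) {
  if (inherits(report, "importance_report")) {
    tab <- report$table
    if (is.null(pcc_mat)) pcc_mat <- report$pcc_matrix
  } else tab <- as.data.frame(report)
  stopifnot(all(c("feature", "overall_shap") %in% names(tab)))
  feats <- tab$feature
  shap <- stats::setNames(tab$overall_shap, feats)

  keep <- feats[shap[feats] >= rule$shap_floor]

  pairs <- list()
  if (!is.null(rule$resolved_pairs)) pairs <- rule$resolved_pairs
  if (!is.null(pcc_mat)) {
    common <- intersect(feats, rownames(pcc_mat))
    for (a_i in seq_along(common)) for (b_i in seq_len(a_i - 1)) {
      a <- common[a_i]; b <- common[b_i]
      if (abs(pcc_mat[a, b]) >= rule$redundancy_threshold)
        pairs <- c(pairs, list(c(b, a)))
    }
  }

  idx_feats <- index_valued_features()
  for (p in pairs) {
    a <- p[1]; b <- p[2]
    if (!(a %in% keep) || !(b %in% keep)) next
    drop <- if (shap[a] < shap[b]) a
      else if (shap[b] < shap[a]) b
      else if (a %in% idx_feats && !(b %in% idx_feats)) b
      else if (b %in% idx_feats && !(a %in% idx_feats)) a
      else sort(c(a, b))[2]
    keep <- setdiff(keep, drop)
  }
  if (length(keep) == 0) stop("empty selection")
  feats[feats %in% keep]
}

#' Full feature-importance report
#'
#' The per-feature importance payload: overall and per-class mean absolute
#' Shapley values (sampled mode by default, since the full catalog is far
#' beyond exact enumeration), Pearson correlation against the ordinal
#' severity code, held-out accuracy of a single-feature ridge ensemble, and
#' the pairwise feature correlation matrix.
#'
#' @param table feature table with a \code{label} column.
#' @param mode,n_permutations,seed forwarded to [shap_values()].
#' @param split_fraction,split_seed forwarded to [single_feature_accuracy()].
#' @param lambda ridge penalty used throughout.
#' @return Object of class \code{importance_report}: data.frame
#'   \code{table} (feature, overall_shap, shap_normal/mild/severe,
#'   pcc_vs_label, single_feature_acc) and matrix \code{pcc_matrix}.
#' @export
importance_report <- function(table, mode = "sampled", n_permutations = 200,
                              seed = 1, split_fraction = 0.7, split_seed = 1,
                              lambda = 1) {
  parts <- table_parts(table)
  shap <- shap_values(table, emrr_factory(lambda = lambda), mode = mode,
                      n_permutations = n_permutations, seed = seed)
  ov <- overall_shap(shap)
  pc <- per_class_shap(shap)
  y_code <- as.integer(as_severity(table$label))
  pcc_lab <- vapply(parts$features,
                    function(f) as.numeric(pcc(parts$x[, f], y_code)),
                    numeric(1))
  acc <- vapply(parts$features, function(f)
    single_feature_accuracy(table, f, split_fraction, split_seed, lambda),
    numeric(1))
  out <- data.frame(feature = parts$features, overall_shap = as.numeric(ov),
                    shap_normal = pc[, "normal"], shap_mild = pc[, "mild"],
                    shap_severe = pc[, "severe"],
                    pcc_vs_label = pcc_lab, single_feature_acc = acc,
                    row.names = NULL, check.names = FALSE)
  structure(list(table = out, pcc_matrix = pcc_matrix(table), shap = shap),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report>\n")
  print(x$table[order(-x$table$overall_shap), ], digits = 3)
  invisible(x)
}

#' Write an importance report to CSV
#'
#' Writes the per-feature table (Name, SHAP, PCC, ACC columns plus the
#' per-class Shapley breakdown) and the correlation matrix to
#' \code{*_pcc_matrix.csv} alongside.
#'
#' @param report an [importance_report()].
#' @param path CSV path for the per-feature table.
#' @return Invisibly, \code{path}.
#' @export
write_importance_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  utils::write.csv(as.data.frame(report$pcc_matrix),
                   sub("\\.csv$", "_pcc_matrix.csv", path), row.names = TRUE)
  invisible(path)
}

#' Write a feature selection (and the rule that produced it) to JSON
#'
#' @param selected character vector of retained features.
#' @param rule the [selection_rule()] applied.
#' @param path JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_selection_json <- function(selected, rule, path) {
  jsonlite::write_json(
    list(selected = selected,
         rule = list(shap_floor = rule$shap_floor,
                     redundancy_threshold = rule$redundancy_threshold,
                     resolved_pairs = rule$resolved_pairs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
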