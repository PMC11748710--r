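#' Closed-form ridge regression fit
#'
#' Solves the L2-penalized least-squares problem
#' \deqn{\min_w \|Xw - Y\|_2^2 + \lambda \|w\|_2^2}
#' whose solution is \eqn{w = (X^T X + \lambda I)^{-1} X^T Y}. The design
#' matrix is expected to carry the intercept as its last (all-ones) column;
#' the intercept is penalized together with the slopes by default, matching
#' the objective as written, with \code{penalize_intercept = FALSE} for the
#' conventional unpenalized-intercept variant.
#'
#' @param X n x (M+1) design matrix, last column all ones.
#' @param Y numeric target vector (0/1 for one-vs-all classification).
#' @param lambda ridge penalty, >= 0.
#' @param penalize_intercept include the intercept in the penalty
#'   (default TRUE).
#' @return Weight vector of length M+1 (slopes then intercept).
#' @export
fit_rr <- function(X, Y, lambda, penalize_intercept = TRUE) {
  X <- as.matrix(X)
  stopifnot(length(Y) == nrow(X), lambda >= 0)
  p <- ncol(X)
  D <- diag(p)
  if (!penalize_intercept) D[p, p] <- 0
  A <- crossprod(X) + lambda * D
  b <- crossprod(X, Y)
  w <- tryCatch(solve(A, b), error = function(e)
    stop("singular design, set lambda > 0"))
  drop(w)
}

#' Fit the ensemble multi-class ridge regression (EMRR) classifier
#'
#' One ridge regression model per severity class in one-vs-all coding
#' (target 1 for the class, 0 otherwise), each fit in closed form with a
#' shared penalty \code{lambda}. At prediction time the per-class linear
#' scores are combined by softmax and the class with the largest probability
#' wins. Features are z-scored with training statistics by default, since
#' ridge shrinkage is scale-sensitive and the 27-feature catalog mixes bin
#' indices, boundary intensities and proportions.
#'
#' @param table feature table data.frame with a \code{label} column (see
#'   [extract_feature_table()]), or a numeric matrix.
#' @param labels severity labels, required when \code{table} is a matrix.
#' @param features character vector of feature columns to use (default: all
#'   non-id columns).
#' @param lambda ridge penalty (default 1).
#' @param standardize z-score features with training mean/sd (default TRUE).
#' @param penalize_intercept see [fit_rr()].
#' @return Object of class \code{emrr} with per-class weight vectors.
#' @export
fit_emrr <- function(table, labels = NULL, features = NULL, lambda = 1,
                     standardize = TRUE, penalize_intercept = TRUE) {
  if (is.data.frame(table)) {
    parts <- table_parts(table, features)
    x <- parts$x; y <- parts$y; features <- parts$features
  } else {
    x <- as.matrix(table)
    if (is.null(labels)) stop("labels required with a matrix input")
    y <- as_severity(labels)
    features <- colnames(x)
    if (is.null(features)) features <- paste0("f", seq_len(ncol(x)))
    colnames(x) <- features
  }
  classes <- severity_levels()
  present <- classes %in% y
  if (!all(present))
    stop("class absent from training data: ",
         paste(classes[!present], collapse = ", "))

  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1   # constant feature: leave as 0 after centering
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  } else {
    center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  }

  Xa <- cbind(x, 1)
  weights <- lapply(classes, function(cl)
    fit_rr(Xa, as.numeric(y == cl), lambda, penalize_intercept))
  names(weights) <- classes
  structure(
    list(classes = classes, weights = weights, lambda = lambda,
         feature_names = features,
         standardization = list(center = center, scale = scale),
         penalize_intercept = penalize_intercept),
    class = "emrr")
}

#' @export
print.emrr <- function(x, ...) {
  cat(sprintf("<emrr> %d one-vs-all ridge models, %d features, lambda = %g\n",
              length(x$classes), length(x$feature_names), x$lambda))
  invisible(x)
}

emrr_design <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(model$feature_names, names(newdata))
    if (length(missing) > 0)
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    x <- as.matrix(newdata[, model$feature_names, drop = FALSE])
  } else {
    x <- matrix(as.numeric(newdata), ncol = length(model$feature_names))
    if (!is.null(colnames(newdata)) && is.matrix(newdata)) {
      missing <- setdiff(model$feature_names, colnames(newdata))
      if (length(missing) > 0)
        stop("missing feature(s): ", paste(missing, collapse = ", "))
      x <- newdata[, model$feature_names, drop = FALSE]
    }
  }
  sweep(sweep(x, 2, model$standardization$center), 2,
        model$standardization$scale, "/")
}

#' Predict with an EMRR model
#'
#' @param object an [fit_emrr()] model.
#' @param newdata feature table, matrix or single named vector.
#' @param type \code{"class"} (default) for the argmax severity label,
#'   \code{"prob"} for softmax class probabilities, \code{"score"} for the
#'   raw per-class linear scores.
#' @param ... unused.
#' @return Factor of labels, or an n x 3 matrix of probabilities/scores.
#' @export
predict.emrr <- function(object, newdata, type = c("class", "prob", "score"),
                         ...) {
  type <- match.arg(type)
  if (is.numeric(newdata) && is.null(dim(newdata)) &&
      !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata), check.names = FALSE)
  x <- emrr_design(object, newdata)
  Xa <- cbind(x, 1)
  scores <- vapply(object$classes, function(cl) drop(Xa %*% object$weights[[cl]]),
                   numeric(nrow(Xa)))
  scores <- matrix(scores, nrow = nrow(Xa),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  probs <- softmax_rows(scores)
  if (type == "prob") return(probs)
  # ties resolve to the lowest severity code (normal < mild < severe)
  as_severity(object$classes[apply(probs, 1, which.max)])
}

#' Row-wise softmax with overflow protection
#' @keywords internal
softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Serialize / restore an EMRR model as JSON
#'
#' @param model an \code{emrr} model.
#' @param path JSON file path.
#' @return \code{write_emrr_json} invisibly returns \code{path};
#'   \code{read_emrr_json} returns the model.
#' @export
write_emrr_json <- function(model, path) {
  payload <- list(format = "octgrade-emrr-1", classes = model$classes,
                  feature_names = model$feature_names, lambda = model$lambda,
                  weights = model$weights,
                  standardization = model$standardization,
                  penalize_intercept = model$penalize_intercept)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emrr_json
#' @export
read_emrr_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "octgrade-emrr-1"))
    stop("unrecognized model format: ", p$format)
  structure(
    list(classes = p$classes,
         weights = lapply(stats::setNames(p$classes, p$classes),
                          function(cl) as.numeric(p$weights[[cl]])),
         lambda = p$lambda, feature_names = p$feature_names,
         standardization = list(
           center = stats::setNames(as.numeric(p$standardization$center),
                                    p$feature_names),
           scale = stats::setNames(as.numeric(p$standardization$scale),
                                   p$feature_names)),
         penalize_intercept = isTRUE(p$penalize_intercept)),
    class = "emrr")
}
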