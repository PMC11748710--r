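#' Confusion-matrix accounting
#'
#' Builds the C x C count matrix (rows = truth, columns = prediction, class
#' order normal/mild/severe) and the per-class one-vs-rest TP/FN/FP/TN
#' counts.
#'
#' @param truth,predicted severity labels of equal length.
#' @param classes class set (default the three severity levels).
#' @return Object of class \code{confusion_summary} with fields
#'   \code{matrix} and \code{counts} (one row per class).
#' @export
confusion <- function(truth, predicted, classes = severity_levels()) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted) || length(truth) < 1)
    stop("truth and predicted must be equal-length, nonempty")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  n <- sum(m)
  counts <- t(vapply(seq_along(classes), function(k) {
    tp <- m[k, k]
    fn <- sum(m[k, ]) - tp
    fp <- sum(m[, k]) - tp
    c(TP = tp, FN = fn, FP = fp, TN = n - tp - fn - fp)
  }, integer(4)))
  rownames(counts) <- classes
  structure(list(matrix = m, counts = counts, n = n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> rows = truth, columns = predicted\n")
  print(x$matrix)
  invisible(x)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Five evaluation metrics from a confusion summary
#'
#' Per class (one-vs-rest) and macro-averaged accuracy, precision,
#' sensitivity, specificity and F1:
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN),\quad PRE = TP/(TP+FP),}
#' \deqn{SEN = TP/(TP+FN),\quad SPE = TN/(TN+FP),\quad
#'       F1 = 2\,PRE\,SEN/(PRE+SEN).}
#' Macro values are unweighted means over classes. Cells with a zero
#' denominator are reported as 0 and flagged. \code{overall_accuracy} is the
#' plain multi-class accuracy (matrix trace over total), the quantity used
#' for held-out accuracy throughout the package.
#'
#' @param cm a [confusion()] result.
#' @return Object of class \code{metrics_report}: data.frame \code{per_class}
#'   (rows = classes + "macro"), \code{overall_accuracy}, and
#'   \code{zero_denominator} flags.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_summary"))
  k <- cm$counts
  pre <- safe_div(k[, "TP"], k[, "TP"] + k[, "FP"])
  sen <- safe_div(k[, "TP"], k[, "TP"] + k[, "FN"])
  per <- data.frame(
    ACC = (k[, "TP"] + k[, "TN"]) / cm$n,
    PRE = pre, SEN = sen,
    SPE = safe_div(k[, "TN"], k[, "TN"] + k[, "FP"]),
    F1 = safe_div(2 * pre * sen, pre + sen))
  flags <- c(PRE = any(k[, "TP"] + k[, "FP"] == 0),
             SEN = any(k[, "TP"] + k[, "FN"] == 0),
             SPE = any(k[, "TN"] + k[, "FP"] == 0),
             F1 = any(pre + sen == 0))
  per <- rbind(per, macro = colMeans(per))
  structure(list(per_class = per,
                 overall_accuracy = sum(diag(cm$matrix)) / cm$n,
                 zero_denominator = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> values in [0, 1]\n")
  print(round(x$per_class, 4))
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  invisible(x)
}

#' Write a metrics report and confusion matrix to CSV
#'
#' @param report a [compute_metrics()] result.
#' @param cm the matching [confusion()] summary (optional).
#' @param path metrics CSV path; the confusion matrix goes to
#'   \code{*_confusion.csv} next to it.
#' @return Invisibly, \code{path}.
#' @export
write_metrics_csv <- function(report, path, cm = NULL) {
  out <- cbind(class = rownames(report$per_class), report$per_class)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(cm)) {
    cpath <- sub("\\.csv$", "_confusion.csv", path)
    utils::write.csv(as.data.frame(cm$matrix), cpath, row.names = TRUE)
  }
  invisible(path)
}
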