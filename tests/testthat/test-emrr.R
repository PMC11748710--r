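make_design <- function(n, m, seed = 1) {
  set.seed(seed)
  cbind(matrix(rnorm(n * m), n, m), 1)
}

test_that("ridge at lambda = 0 recovers an exactly linear target", {
  X <- make_design(30, 3)
  beta <- c(2, -1, 0.5, 3)
  w <- fit_rr(X, drop(X %*% beta), lambda = 0)
  expect_equal(w, beta, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("any ridge fit satisfies its normal equations", {
  set.seed(3)
  for (lambda in c(0.01, 1, 50)) {
    X <- make_design(40, 5, seed = lambda * 100)
    Y <- rnorm(40)
    w <- fit_rr(X, Y, lambda)
    resid <- (crossprod(X) + lambda * diag(6)) %*% w - crossprod(X, Y)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("weight norm shrinks monotonically in lambda", {
  X <- make_design(50, 4, seed = 9)
  Y <- rnorm(50)
  norms <- vapply(c(0.01, 0.1, 1, 10, 100),
                  function(l) sqrt(sum(fit_rr(X, Y, l)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("singular designs demand a positive penalty", {
  X <- cbind(1:5, 2 * (1:5), 1)  # collinear columns
  expect_error(fit_rr(X, rnorm(5), lambda = 0), "singular design")
  expect_silent(fit_rr(X, rnorm(5), lambda = 0.1))
})

test_that("closed form matches the numeric minimizer of the penalized loss", {
  set.seed(17)
  for (k in 1:5) {
    X <- make_design(25, 3, seed = k)
    Y <- rnorm(25)
    lambda <- exp(runif(1, -2, 2))
    expect_equal(fit_rr(X, Y, lambda), oracle_ridge_minimize(X, Y, lambda),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("duplicating rows while doubling lambda leaves weights unchanged", {
  X <- make_design(20, 3, seed = 4)
  Y <- rnorm(20)
  w1 <- fit_rr(X, Y, lambda = 2)
  w2 <- fit_rr(rbind(X, X), c(Y, Y), lambda = 4)
  expect_equal(w1, w2, tolerance = 1e-10)
})

test_that("the ensemble separates well-separated Gaussian classes", {
  tab <- make_separable_table(n_per_class = 40, sep = 5, seed = 21)
  model <- fit_emrr(tab)
  expect_length(model$weights, 3)
  expect_length(model$weights$normal, 5)  # 4 slopes + intercept
  pred <- predict(model, tab)
  expect_gte(mean(pred == tab$label), 0.95)
})

test_that("fitting requires every class in the training data", {
  tab <- make_toy_table(10)
  expect_error(fit_emrr(tab[tab$label != "severe", ]),
               "class absent.*severe")
})

test_that("a single-feature model carries weight vectors of length two", {
  tab <- make_toy_table(10)
  model <- fit_emrr(tab, features = "f1")
  expect_length(model$weights$mild, 2)
})

test_that("softmax probabilities match closed forms and sum to one", {
  # hand-built model: zero slopes, intercepts = wanted scores
  mk <- function(intercepts) {
    structure(list(classes = severity_levels(),
                   weights = list(normal = c(0, intercepts[1]),
                                  mild = c(0, intercepts[2]),
                                  severe = c(0, intercepts[3])),
                   lambda = 1, feature_names = "f1",
                   standardization = list(center = 0, scale = 1),
                   penalize_intercept = TRUE),
              class = "emrr")
  }
  x <- data.frame(f1 = 0)
  expect_equal(drop(predict(mk(c(0, 0, 0)), x, type = "prob")),
               c(normal = 1 / 3, mild = 1 / 3, severe = 1 / 3))
  expect_equal(drop(predict(mk(c(0, 0, log(2))), x, type = "prob")),
               c(normal = 0.25, mild = 0.25, severe = 0.5))
  # softmax is invariant to adding a constant to every score
  expect_equal(predict(mk(c(1, 2, 3)), x, type = "prob"),
               predict(mk(c(1, 2, 3) + 7), x, type = "prob"),
               tolerance = 1e-12)
  # overflow safety at extreme scores
  p <- drop(predict(mk(c(1000, 0, -1000)), x, type = "prob"))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p[1]), 1, tolerance = 1e-12)
})

test_that("argmax decision follows the largest probability, ties to lowest code", {
  mk <- function(p) structure(
    list(classes = severity_levels(),
         weights = list(normal = c(0, log(p[1])), mild = c(0, log(p[2])),
                        severe = c(0, log(p[3]))),
         lambda = 1, feature_names = "f1",
         standardization = list(center = 0, scale = 1),
         penalize_intercept = TRUE),
    class = "emrr")
  x <- data.frame(f1 = 0)
  expect_equal(as.character(predict(mk(c(0.250, 0.225, 0.525)), x)), "severe")
  expect_equal(as.character(predict(mk(c(0.6, 0.3, 0.1)), x)), "normal")
  expect_equal(as.character(predict(mk(c(1, 1, 1) / 3), x)), "normal")
})

test_that("decisions agree whether taken on scores or probabilities", {
  tab <- make_toy_table(15, sep = 1.5, seed = 31)
  model <- fit_emrr(tab)
  sc <- predict(model, tab, type = "score")
  pr <- predict(model, tab, type = "prob")
  expect_equal(apply(sc, 1, which.max), apply(pr, 1, which.max))
})

test_that("score computation is the standardized linear form", {
  # weights (2, -1), intercept 0.5, x = (1, 3) -> score -0.5
  model <- structure(
    list(classes = severity_levels(),
         weights = list(normal = c(2, -1, 0.5), mild = c(0, 0, 0),
                        severe = c(0, 0, 0)),
         lambda = 1, feature_names = c("a", "b"),
         standardization = list(center = c(0, 0), scale = c(1, 1)),
         penalize_intercept = TRUE),
    class = "emrr")
  sc <- predict(model, data.frame(a = 1, b = 3), type = "score")
  expect_equal(unname(sc[1, "normal"]), -0.5)
  expect_equal(unname(sc[1, "mild"]), 0)
  expect_error(predict(model, data.frame(a = 1)), "missing feature.*b")
})

test_that("near-zero penalty matches the unpenalized fit on good data", {
  tab <- make_toy_table(25, sep = 2, seed = 41)
  p0 <- predict(fit_emrr(tab, lambda = 0), tab)
  p1 <- predict(fit_emrr(tab, lambda = 1e-8), tab)
  expect_identical(as.character(p0), as.character(p1))
})

test_that("models survive a JSON round-trip bit-for-bit in behavior", {
  dir <- withr::local_tempdir()
  tab <- make_toy_table(15, seed = 51)
  model <- fit_emrr(tab)
  path <- file.path(dir, "model.json")
  write_emrr_json(model, path)
  back <- read_emrr_json(path)
  expect_equal(predict(back, tab, type = "prob"),
               predict(model, tab, type = "prob"), tolerance = 1e-12)
})

test_that("intercept penalization is the default and the flag disables it", {
  X <- make_design(40, 2, seed = 61)
  Y <- rnorm(40) + 5          # large offset makes the intercept matter
  w_pen <- fit_rr(X, Y, lambda = 100)
  w_free <- fit_rr(X, Y, lambda = 100, penalize_intercept = FALSE)
  expect_lt(abs(w_pen[3]), abs(w_free[3]))
  expect_equal(w_free[3], mean(Y - X[, 1:2] %*% w_free[1:2]),
               tolerance = 0.2)
})
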