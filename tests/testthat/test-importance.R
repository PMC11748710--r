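test_that("pcc matches perfect linear relations and flags constants", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(as.numeric(pcc(x, 2 * x + 1)), 1)
  expect_equal(as.numeric(pcc(x, -x)), -1)
  const <- pcc(rep(2, 5), x)
  expect_equal(as.numeric(const), 0)
  expect_true(attr(const, "constant"))
  expect_error(pcc(1:3, 1:4), "equal length")
  expect_error(pcc(1, 1), "at least 2")
})

test_that("pcc matrix is symmetric with unit diagonal and zeroed constants", {
  set.seed(5)
  tab <- make_toy_table(20)
  tab$f4 <- tab$f1                      # duplicated column
  tab$f3 <- 7                           # constant column
  m <- pcc_matrix(tab)
  expect_identical(m, t(m))
  expect_equal(m["f1", "f4"], 1)
  expect_equal(unname(m["f3", ]), rep(0, 4))
  expect_equal(unname(diag(m)), c(1, 1, 0, 1))
})

test_that("independent columns show near-zero correlation at large n", {
  set.seed(6)
  x <- matrix(rnorm(10000 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(abs(pcc_matrix(x)["a", "b"]), 0.05)
})

test_that("a single-feature game collapses to one marginal", {
  tab <- make_toy_table(15, n_features = 1, seed = 8)
  s <- shap_values(tab, mode = "exact")
  expect_equal(s$phi[, 1, ], s$full - s$baseline, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("an additive value function is attributed exactly", {
  # custom trainer ignoring the data: f_S = sum of planted values over S
  v <- c(f1 = 0.3, f2 = -0.2)
  factory <- function(x, y) {
    val <- sum(v[colnames(x)])
    function(newx) matrix(val, nrow(newx), 3,
                          dimnames = list(NULL, severity_levels()))
  }
  tab <- make_toy_table(10, n_features = 2, seed = 12)
  s <- shap_values(tab, model_factory = factory, mode = "exact")
  expect_true(all(abs(s$phi[, "f1", ] - 0.3) < 1e-12))
  expect_true(all(abs(s$phi[, "f2", ] + 0.2) < 1e-12))
})

test_that("exact Shapley obeys efficiency, symmetry and the null axiom", {
  tab <- make_toy_table(15, n_features = 4, seed = 14)
  tab$f3 <- tab$f2                      # symmetric pair
  tab$f4 <- 1                           # null (constant) feature
  s <- shap_values(tab, mode = "exact")
  expect_lt(max(abs(apply(s$phi, c(1, 3), sum) - (s$full - s$baseline))),
            1e-8)
  expect_lt(max(abs(s$phi[, "f2", ] - s$phi[, "f3", ])), 1e-8)
  expect_lt(max(abs(s$phi[, "f4", ])), 1e-10)
})

test_that("exact mode refuses more than twelve features", {
  tab <- make_toy_table(4, n_features = 13, seed = 16)
  expect_error(shap_values(tab, mode = "exact"), "use sampled")
})

test_that("sampled Shapley converges to the exact values", {
  tab <- make_toy_table(12, n_features = 5, seed = 18)
  ex <- shap_values(tab, mode = "exact")
  mads <- vapply(c(100, 400, 1600), function(np)
    mean(abs(shap_values(tab, mode = "sampled", n_permutations = np,
                         seed = 99)$phi - ex$phi)),
    numeric(1))
  expect_true(all(diff(mads) < 0))
  expect_lt(mads[3], 0.02)
  # same seed, same estimate
  s1 <- shap_values(tab, mode = "sampled", n_permutations = 50, seed = 7)
  s2 <- shap_values(tab, mode = "sampled", n_permutations = 50, seed = 7)
  expect_identical(s1$phi, s2$phi)
})

test_that("overall and per-class aggregation are mean absolute values", {
  phi <- array(c(1, -1, 2, -2), dim = c(2, 1, 2),
               dimnames = list(NULL, "f1", c("a", "b")))
  expect_equal(unname(overall_shap(phi)), 1.5)
  expect_equal(unname(per_class_shap(phi)[1, ]), c(1, 2))

  tab <- make_toy_table(15, n_features = 2, sep = 4, seed = 22)
  s <- shap_values(tab, mode = "exact")
  ov <- overall_shap(s)
  expect_true(all(ov >= 0))
  expect_gt(ov[["f1"]], ov[["f2"]])     # only f1 carries class signal
})

test_that("single-feature accuracy tracks signal, chance and degeneracy", {
  tab <- make_toy_table(100, n_features = 2, sep = 6, seed = 24)
  expect_gt(single_feature_accuracy(tab, "f1"), 0.6)
  acc_noise <- single_feature_accuracy(tab, "f2")
  expect_lt(abs(acc_noise - 1 / 3), 0.1)
  tab$f2 <- 5
  acc_const <- single_feature_accuracy(tab, "f2")
  expect_lt(abs(acc_const - 1 / 3), 0.1)  # balanced classes: majority ~ 1/3
})

test_that("the selection rule reproduces the published subset on the fixture", {
  fix <- read.csv(system.file("extdata", "reference_importance.csv",
                              package = "octgrade"), check.names = FALSE)
  rule <- selection_rule(
    shap_floor = 0.015,
    resolved_pairs = list(c("G-Maximum", "GI-Maximum"),
                          c("G-Minimum", "GI-Minimum"),
                          c("D-Median", "I-Median")))
  sel <- select_features(fix, rule)
  expect_length(sel, 22)
  expect_setequal(setdiff(fix$feature, sel),
                  c("D-Minimum", "D-Uniformity", "G-Maximum",
                    "G-Minimum", "D-Median"))
  expect_identical(sel, fix$feature[fix$feature %in% sel])  # canonical order
})

test_that("a permissive rule is the identity and dropping all errors", {
  fix <- read.csv(system.file("extdata", "reference_importance.csv",
                              package = "octgrade"), check.names = FALSE)
  expect_identical(select_features(fix, selection_rule(shap_floor = 0)),
                   fix$feature)
  expect_error(select_features(fix, selection_rule(shap_floor = 10)),
               "empty selection")
})

test_that("redundant duplicated columns are resolved by lower importance", {
  df <- data.frame(feature = c("a", "b", "c"),
                   overall_shap = c(0.5, 0.2, 0.4))
  m <- diag(3); dimnames(m) <- list(df$feature, df$feature)
  m["a", "b"] <- m["b", "a"] <- 0.99
  sel <- select_features(df, selection_rule(shap_floor = 0,
                                            redundancy_threshold = 0.95),
                         pcc_mat = m)
  expect_identical(sel, c("a", "c"))
})

test_that("the full importance report carries every payload column", {
  tab <- make_toy_table(20, n_features = 3, seed = 28)
  rep_ <- importance_report(tab, n_permutations = 30, seed = 2)
  expect_s3_class(rep_, "importance_report")
  expect_identical(rep_$table$feature, c("f1", "f2", "f3"))
  expect_true(all(c("overall_shap", "shap_normal", "shap_mild",
                    "shap_severe", "pcc_vs_label", "single_feature_acc")
                  %in% names(rep_$table)))
  expect_true(all(rep_$table$overall_shap >= 0))
  expect_true(all(abs(rep_$table$pcc_vs_label) <= 1))
  expect_true(all(rep_$table$single_feature_acc >= 0 &
                    rep_$table$single_feature_acc <= 1))
  expect_equal(dim(rep_$pcc_matrix), c(3, 3))

  dir <- withr::local_tempdir()
  write_importance_csv(rep_, file.path(dir, "imp.csv"))
  expect_true(file.exists(file.path(dir, "imp.csv")))
  expect_true(file.exists(file.path(dir, "imp_pcc_matrix.csv")))
  write_selection_json(select_features(rep_, selection_rule(shap_floor = 0)),
                       selection_rule(shap_floor = 0),
                       file.path(dir, "sel.json"))
  got <- jsonlite::read_json(file.path(dir, "sel.json"),
                             simplifyVector = TRUE)
  expect_identical(got$selected, c("f1", "f2", "f3"))
})
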