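test_that("feature filter drops low-variance and redundant columns", {
  set.seed(20)
  a <- rbinom(1000, 1, 0.5)
  b <- rbinom(1000, 1, 0.5)
  x <- cbind(const = rep(1, 1000),        # variance 0
             rare = rbinom(1000, 1, 0.02), # variance < 0.1
             a = a, dup_a = a,             # |r| = 1
             b = b)
  mask <- feature_select(x)
  expect_equal(unname(mask), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  # invariant to row order
  expect_equal(feature_select(x[sample(1000), ]), mask)
  expect_error(feature_select(matrix(1, 5, 3)), "variance")
})

test_that("accuracy equals micro-averaged recall on any confusion matrix", {
  cm <- matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE)
  expect_equal(accuracy(cm), 0.7)
  expect_equal(micro_recall(cm), 0.7)
  expect_equal(accuracy(diag(c(4, 6, 2))), 1)
  set.seed(21)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    m <- random_cm(k)
    if (sum(m) == 0) next
    expect_equal(accuracy(m), micro_recall(m), tolerance = 1e-12)
  }
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("multiclass MCC generalizes the binary formula", {
  classical_mcc <- function(tp, fn, fp, tn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  set.seed(22)
  for (i in 1:200) {
    m <- random_cm(2)
    expect_equal(multiclass_mcc(m),
                 classical_mcc(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
  }
  # perfect classification and the degenerate single-column case
  expect_equal(multiclass_mcc(diag(c(3, 5, 7, 2))), 1)
  one_col <- cbind(c(5, 5), c(0, 0))
  expect_equal(multiclass_mcc(one_col), 0)
  # MCC = 1 iff off-diagonal mass is zero; always within [-1, 1]
  for (i in 1:100) {
    m <- random_cm(sample(2:5, 1))
    if (sum(m) == 0) next
    v <- multiclass_mcc(m)
    expect_gte(v, -1); expect_lte(v, 1)
    expect_equal(v == 1, sum(m) > 0 && sum(m - diag(diag(m))) == 0)
  }
})

test_that("binary collapse block-sums the 4-class matrix and scores chance", {
  cm4 <- diag(c(5, 6, 7, 8))
  cb <- collapse_binary(cm4)
  expect_equal(cb$q2, 1)
  expect_equal(unname(cb$matrix), matrix(c(11, 0, 0, 15), 2, 2))
  # perfectly balanced marginals give chance accuracy one half
  bal <- matrix(c(3, 2, 2, 3), 2, 2)
  cm4b <- rbind(cbind(bal, matrix(0, 2, 2)),
                cbind(matrix(0, 2, 2), bal))
  expect_equal(collapse_binary(cm4b)$q2_rnd, 0.5)
  cb2 <- collapse_binary(matrix(1:16, 4, 4))
  expect_equal(cb2$delta_q2, cb2$q2 - cb2$q2_rnd)
  expect_error(collapse_binary(diag(3)), "4-class")
})

test_that("the registry exposes twelve algorithms and flags the absent one", {
  expect_length(qsar_algorithms(), 12)
  expect_setequal(qsar_algorithms(),
                  c("DT", "ET", "RF", "GB", "LGBM", "XGB", "MLP", "LR",
                    "KNN", "SVM", "NB", "GP"))
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("a", "b"), 10))
  expect_error(train_model(model_config("LGBM"), x, y), "LGBM")
  expect_error(model_config("bogus"))
})

test_that("one-vs-rest training memorizes separable toy data deterministically", {
  set.seed(23)
  n <- 40
  y <- factor(rep(c("potent", "active", "intermediate", "inactive"),
                  each = n / 4),
              levels = c("potent", "active", "intermediate", "inactive"))
  x <- cbind(as.integer(y) %% 2, as.integer(y) %/% 3) +
    matrix(rnorm(2 * n, sd = 0.01), n, 2)
  for (alg in setdiff(qsar_algorithms(), "LGBM")) {
    cfg <- model_config(alg, seed = 42)
    fit <- train_model(cfg, x, y)
    p1 <- predict(fit, x)
    p2 <- predict(train_model(cfg, x, y), x)
    expect_identical(p1, p2)   # determinism under a fixed seed
    if (alg %in% c("DT", "ET", "XGB"))
      expect_equal(accuracy(confusion_matrix(y, p1)), 1)
  }
  expect_error(train_model(model_config("DT"), x, factor(rep("a", n))),
               "single class")
  expect_error(train_model(model_config("KNN", knn_k = 99), x, y), "KNN")
})

test_that("cross-validation predicts each sample exactly once", {
  set.seed(24)
  n <- 60
  y <- factor(rep(c("a", "b", "c"), each = 20))
  x <- cbind(as.integer(y), rnorm(n))
  cfg <- model_config("DT", seed = 42, cv_folds = 10)
  cv <- cross_validate(cfg, x, y)
  expect_equal(sum(cv$confusion), n)
  expect_equal(unname(rowSums(cv$confusion)), c(20, 20, 20))
  expect_equal(cv$accuracy, micro_recall(cv$confusion))
  expect_length(cv$fold_accuracy, 10)
  # a class smaller than the fold count shrinks the folds with a warning
  y2 <- factor(c(rep("a", 56), rep("b", 4)))
  expect_warning(cv2 <- cross_validate(cfg, x, y2), "folds")
  expect_equal(sum(cv2$confusion), n)
})

test_that("the model suite runs balance-split-filter-train-evaluate per group", {
  fx <- fixture_noisy()
  r <- fx$records
  fp <- fixture_ecfp4()
  st <- scaffold_table(r, scaffolds = fixture_scaffolds(),
                       skeletons = fixture_skeletons())
  grp <- group_by_skeleton(st)
  sizes <- vapply(grp, function(g) length(g$member_ids), integer(1))
  big <- grp[[which.max(sizes)]]
  expect_warning(
    reports <- run_model_suite(r, fp,
                               groups = list(big = big$member_ids,
                                             tiny = r$compound_id[1:6]),
                               algorithms = c("DT", "ET"), seed = 42),
    "skipped")
  expect_length(reports, 2)  # tiny group skipped
  summ <- suite_summary(reports)
  expect_equal(summ$group, c("big", "big"))
  expect_true(summ$best[1])
  expect_equal(summ$test_accuracy, sort(summ$test_accuracy,
                                        decreasing = TRUE))
  rep1 <- reports[[1]]
  # feature mask fitted on train only, applied unchanged to test
  expect_type(rep1$feature_mask, "logical")
  expect_equal(ncol(rep1$training$confusion), 4)
  expect_true(all(vapply(list(rep1$training, rep1$cv, rep1$test),
                         function(e) abs(e$accuracy -
                                         micro_recall(e$confusion)) < 1e-12,
                         logical(1))))
})

test_that("suite runs are reproducible for a fixed seed", {
  fx <- fixture_noisy()
  fp <- fixture_ecfp4()
  ids <- fx$records$compound_id[fx$records$category == "steroidal"]
  run <- function() suppressWarnings(
    run_model_suite(fx$records, fp, groups = list(s = ids),
                    algorithms = "DT", seed = 42, cv_folds = 5))
  r1 <- run(); r2 <- run()
  expect_identical(suite_summary(r1), suite_summary(r2))
})
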