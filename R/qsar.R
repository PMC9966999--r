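# Multiclass QSAR classification: variance/correlation feature filtering, a
# twelve-algorithm registry fitted one-vs-rest, stratified 10-fold
# cross-validation with a pooled confusion matrix, and the accuracy /
# micro-recall / multiclass-MCC metrics with binary collapse.

#' Variance and correlation feature filter
#'
#' Drops columns with variance below `min_variance`, then scans the
#' remaining columns in index order and drops any column whose absolute
#' Pearson correlation with an earlier retained column exceeds
#' `max_correlation` (the earlier-indexed column wins ties). The mask is
#' deterministic and invariant to row order.
#'
#' @param x numeric feature matrix (n >= 2 rows).
#' @param min_variance variance cut (default 0.1).
#' @param max_correlation correlation cut (default 0.90).
#' @return logical mask over the columns of `x`.
#' @export
feature_select <- function(x, min_variance = 0.1, max_correlation = 0.90) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows", call. = FALSE)
  v <- apply(x, 2, stats::var)
  mask <- v >= min_variance
  if (!any(mask)) stop("all features dropped by the variance filter",
                       call. = FALSE)
  idx <- which(mask)
  cm <- abs(suppressWarnings(stats::cor(x[, idx, drop = FALSE])))
  kept <- logical(length(idx))
  for (j in seq_along(idx)) {
    if (!any(kept)) { kept[j] <- TRUE; next }
    kept[j] <- all(cm[j, kept] <= max_correlation, na.rm = TRUE)
  }
  mask[idx] <- kept
  if (!any(mask)) stop("all features dropped", call. = FALSE)
  mask
}

#' The QSAR algorithm registry
#'
#' Twelve classification algorithms: DT (decision tree, rpart), ET (extra
#' trees, ranger), RF (random forest), GB (gradient-boosted trees), LGBM
#' (LightGBM; no backend in this installation), XGB (extreme gradient
#' boosting), MLP (single-hidden-layer perceptron, nnet), LR (ridge
#' logistic regression, glmnet), KNN (k-nearest neighbours), SVM (RBF
#' support vector machine), NB (Bernoulli naive Bayes), GP (Gaussian
#' process classifier, kernlab).
#'
#' @return character vector of the twelve algorithm codes.
#' @export
qsar_algorithms <- function() {
  c("DT", "ET", "RF", "GB", "LGBM", "XGB", "MLP", "LR", "KNN", "SVM",
    "NB", "GP")
}

#' QSAR model configuration
#'
#' @param algorithm one of [qsar_algorithms()].
#' @param fingerprint_scheme identifier recorded in reports.
#' @param seed integer seed (default 42).
#' @param cv_folds cross-validation folds (default 10).
#' @param test_fraction test-set fraction (default 0.2).
#' @param knn_k neighbours for KNN (default 5).
#' @return object of class `model_config`.
#' @export
model_config <- function(algorithm, fingerprint_scheme = "ecfp4",
                         seed = 42, cv_folds = 10, test_fraction = 0.2,
                         knn_k = 5L) {
  algorithm <- match.arg(algorithm, qsar_algorithms())
  structure(list(algorithm = algorithm,
                 fingerprint_scheme = fingerprint_scheme,
                 multiclass_strategy = "one-vs-rest", seed = seed,
                 cv_folds = cv_folds, test_fraction = test_fraction,
                 knn_k = knn_k), class = "model_config")
}

# Binary backends: each entry fits P(positive | x) for a 0/1 outcome and
# returns a closure predicting that probability. Library defaults are used
# unless noted; hyperparameters are echoed for auditability.
binary_backends <- list(
  DT = function(x, y, cfg) {
    # unpruned CART: grow to purity, as plain decision-tree classifiers do
    df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
    fit <- rpart::rpart(.y ~ ., df, method = "class",
                        control = rpart::rpart.control(minsplit = 2,
                                                       minbucket = 1,
                                                       cp = 0))
    function(newx) stats::predict(fit, data.frame(newx))[, "1"]
  },
  ET = function(x, y, cfg) {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          probability = TRUE, splitrule = "extratrees",
                          num.random.splits = 1, replace = FALSE,
                          sample.fraction = 1, num.trees = 500,
                          min.node.size = 1,
                          seed = cfg$seed, num.threads = 1)
    function(newx) stats::predict(fit, data = newx,
                                  num.threads = 1)$predictions[, "1"]
  },
  RF = function(x, y, cfg) {
    fit <- randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                      ntree = 500)
    function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
  },
  GB = function(x, y, cfg) {
    # classical gradient-boosted trees: shallow depth, shrinkage 0.1,
    # no regularization (the xgboost library in its plain-boosting setting)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, lambda = 0, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100)
    function(newx) stats::predict(fit, xgboost::xgb.DMatrix(newx))
  },
  LGBM = function(x, y, cfg) {
    stop("LGBM: no LightGBM backend is available in this installation; ",
         "choose another algorithm from qsar_algorithms()", call. = FALSE)
  },
  XGB = function(x, y, cfg) {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100)
    function(newx) stats::predict(fit, xgboost::xgb.DMatrix(newx))
  },
  MLP = function(x, y, cfg) {
    fit <- nnet::nnet(x = x, y = y, size = 8, decay = 1e-4, maxit = 200,
                      trace = FALSE, MaxNWts = 1e5, entropy = TRUE)
    function(newx) as.numeric(stats::predict(fit, newx))
  },
  LR = function(x, y, cfg) {
    fit <- glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                          family = "binomial", alpha = 0,
                          lambda = 1 / nrow(x))
    function(newx) as.numeric(stats::predict(fit, newx, type = "response"))
  },
  KNN = function(x, y, cfg) {
    if (cfg$knn_k > nrow(x))
      stop("KNN: k (", cfg$knn_k, ") exceeds the training size (",
           nrow(x), ")", call. = FALSE)
    cl <- factor(y, levels = c(0, 1))
    function(newx) {
      pred <- class::knn(x, newx, cl, k = cfg$knn_k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    }
  },
  SVM = function(x, y, cfg) {
    fit <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                      probability = TRUE)
    function(newx) {
      pr <- stats::predict(fit, newx, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }
  },
  NB = function(x, y, cfg) {
    df <- as.data.frame(lapply(as.data.frame(x), function(col)
      factor(col, levels = sort(unique(col)))))
    fit <- e1071::naiveBayes(df, factor(y, levels = c(0, 1)), laplace = 1)
    function(newx) {
      nd <- as.data.frame(newx)
      for (j in seq_along(nd))
        nd[[j]] <- factor(nd[[j]], levels = levels(df[[j]]))
      stats::predict(fit, nd, type = "raw")[, "1"]
    }
  },
  GP = function(x, y, cfg) {
    utils::capture.output(suppressMessages(
      fit <- kernlab::gausspr(x = x, y = factor(y, levels = c(0, 1)))))
    function(newx) kernlab::predict(fit, newx,
                                    type = "probabilities")[, "1"]
  }
)

#' Train a one-vs-rest multiclass classifier
#'
#' Fits one binary classifier per class (class vs rest) with seed-fixed
#' randomness; prediction takes the class with the highest positive-class
#' probability (ties go to the more potent class).
#'
#' @param config a [model_config()].
#' @param features numeric feature matrix.
#' @param labels factor of class labels (>= 2 classes present).
#' @return object of class `qsar_model`.
#' @export
train_model <- function(config, features, labels) {
  x <- as.matrix(features)
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  labels <- factor(labels)
  present <- levels(droplevels(labels))
  if (length(present) < 2L)
    stop("training data contains a single class", call. = FALSE)
  backend <- binary_backends[[config$algorithm]]
  fits <- lapply(present, function(cl) {
    with_seed(config$seed, backend(x, as.integer(labels == cl), config))
  })
  structure(list(config = config, classes = present,
                 class_levels = levels(labels), fits = fits,
                 n_features = ncol(x)),
            class = "qsar_model")
}

#' Predict classes with a fitted QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return factor of predicted classes with the training levels.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  stopifnot(ncol(x) == object$n_features)
  probs <- vapply(object$fits, function(f) as.numeric(f(x)),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1)
  pick <- apply(probs, 1, which.max)
  factor(object$classes[pick], levels = object$class_levels)
}

#' Confusion matrix with fixed label order
#'
#' @param true,predicted factors (or vectors) of class labels.
#' @param labels class order; defaults to the union of levels.
#' @return k x k integer matrix, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(true, predicted, labels = NULL) {
  if (is.null(labels)) labels <- union(levels(factor(true)),
                                       levels(factor(predicted)))
  t1 <- factor(true, levels = labels)
  t2 <- factor(predicted, levels = labels)
  unclass(table(true = t1, predicted = t2))
}

#' Accuracy of a confusion matrix
#'
#' Trace over total: the fraction of correct predictions.
#' @param cm confusion matrix.
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Micro-averaged recall of a confusion matrix
#'
#' The support-weighted mean of per-class recalls,
#' sum_i (TPi + FNi)/total * TPi/(TPi + FNi). For any multiclass confusion
#' matrix this equals the accuracy.
#'
#' @param cm confusion matrix.
#' @return micro-averaged recall in \[0, 1\].
#' @export
micro_recall <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  support <- rowSums(cm)
  recall_i <- ifelse(support > 0, diag(cm) / support, 0)
  sum(support / total * recall_i)
}

#' Multiclass Matthews correlation coefficient
#'
#' The Rk generalization: with c = trace, s = total, t = row sums (true
#' class counts) and p = column sums (predicted class counts),
#' MCC = (c s - sum(p t)) / sqrt((s^2 - sum(p^2)) (s^2 - sum(t^2))).
#' A zero denominator (all predictions or all truths in one class) yields 0
#' by convention. For k = 2 this reduces to the classical binary MCC.
#'
#' @param cm confusion matrix.
#' @return MCC in \[-1, 1\].
#' @export
multiclass_mcc <- function(cm) {
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t <- rowSums(cm)
  p <- colSums(cm)
  denom2 <- (s^2 - sum(p^2)) * (s^2 - sum(t^2))
  if (denom2 <= 0) return(0)
  (c0 * s - sum(p * t)) / sqrt(denom2)
}

#' Collapse a 4-class confusion matrix to binary
#'
#' The first two classes (potent, active) become the positive class and the
#' last two the negative class; the 4x4 matrix is block-summed into a 2x2
#' matrix. Also reports the binary accuracy Q2, the marginal chance
#' agreement Q2,rnd = sum_k row_k * col_k / total^2 (0.5 for perfectly
#' balanced marginals), and their difference.
#'
#' @param cm 4 x 4 confusion matrix (classes ordered most potent first).
#' @return list with `matrix` (2x2), `q2`, `q2_rnd`, `delta_q2`.
#' @export
collapse_binary <- function(cm) {
  if (!all(dim(cm) == c(4L, 4L)))
    stop("expected a 4-class confusion matrix", call. = FALSE)
  blocks <- list(pos = 1:2, neg = 3:4)
  m2 <- matrix(0, 2, 2, dimnames = list(true = names(blocks),
                                        predicted = names(blocks)))
  for (i in 1:2) for (j in 1:2)
    m2[i, j] <- sum(cm[blocks[[i]], blocks[[j]]])
  total <- sum(m2)
  q2 <- sum(diag(m2)) / total
  q2_rnd <- sum(rowSums(m2) * colSums(m2)) / total^2
  list(matrix = m2, q2 = q2, q2_rnd = q2_rnd, delta_q2 = q2 - q2_rnd)
}

#' Stratified cross-validation with a pooled confusion matrix
#'
#' Splits the data into `config$cv_folds` stratified folds (reduced with a
#' warning when the smallest class has fewer members than folds), trains on
#' all but one fold and predicts the held-out fold; out-of-fold predictions
#' are pooled into one confusion matrix. Per-fold accuracies are attached.
#'
#' @param config a [model_config()].
#' @param features feature matrix.
#' @param labels factor of class labels.
#' @return list with `confusion`, `accuracy`, `micro_recall`, `mcc`,
#'   `fold_accuracy`.
#' @export
cross_validate <- function(config, features, labels) {
  x <- as.matrix(features)
  labels <- droplevels(factor(labels))
  n <- nrow(x)
  folds <- config$cv_folds
  min_class <- min(table(labels))
  if (min_class < folds) {
    folds <- max(2L, min_class)
    warning("smallest class (", min_class, ") below cv_folds; using ",
            folds, " folds")
  }
  if (n < folds) stop("fewer rows than folds", call. = FALSE)
  fold_id <- integer(n)
  with_seed(config$seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- train_model(config, x[!hold, , drop = FALSE], labels[!hold])
    pred[hold] <- predict(fit, x[hold, , drop = FALSE])
  }
  cm <- confusion_matrix(labels, pred, labels = levels(labels))
  fold_acc <- vapply(seq_len(folds), function(f)
    mean(pred[fold_id == f] == labels[fold_id == f]), numeric(1))
  list(confusion = cm, accuracy = accuracy(cm),
       micro_recall = micro_recall(cm), mcc = multiclass_mcc(cm),
       fold_accuracy = fold_acc)
}

eval_split <- function(true, predicted, labels) {
  cm <- confusion_matrix(true, predicted, labels = labels)
  list(confusion = cm, accuracy = accuracy(cm),
       micro_recall = micro_recall(cm), mcc = multiclass_mcc(cm))
}

#' Run the QSAR modeling suite over scaffold groups
#'
#' For each group and algorithm: oversample to class balance, split
#' stratified train/test, fit the variance/correlation feature filter on
#' the training set only, train one-vs-rest, cross-validate within the
#' training set and evaluate on the test set. Groups smaller than
#' `min_group_size` are skipped with a warning. Reports within a group are
#' ranked by test accuracy and the best is flagged.
#'
#' @param records curated data.frame.
#' @param fingerprints fingerprint matrix with `compound_id` rownames.
#' @param groups optional list of compound-id vectors (e.g. from
#'   [group_by_skeleton()] members); default: one group with everything.
#' @param algorithms algorithm codes to try (default `"ET"`).
#' @param seed integer seed.
#' @param test_fraction test fraction (default 0.2).
#' @param cv_folds folds (default 10).
#' @param min_group_size smallest group worth modeling (default 20).
#' @return list of evaluation reports, one per group x algorithm; each has
#'   `group`, `config`, `n_records`, `feature_mask`, `training`, `cv`,
#'   `test` and `best_in_group`.
#' @export
run_model_suite <- function(records, fingerprints, groups = NULL,
                            algorithms = "ET", seed = 42,
                            test_fraction = 0.2, cv_folds = 10,
                            min_group_size = 20L) {
  if (is.null(groups))
    groups <- list(all = records$compound_id)
  if (is.null(names(groups)))
    names(groups) <- paste0("group_", seq_along(groups))
  fp <- as.matrix(fingerprints)
  reports <- list()
  for (gname in names(groups)) {
    recs <- records[records$compound_id %in% groups[[gname]], , drop = FALSE]
    if (nrow(recs) < min_group_size) {
      warning("group '", gname, "' skipped: ", nrow(recs),
              " compounds (< ", min_group_size, ")")
      next
    }
    balanced <- balance_by_oversampling(recs, seed = seed)
    split <- split_train_test(balanced, test_fraction = test_fraction,
                              seed = seed, stratify = TRUE)
    xtr <- fp[split$train$compound_id, , drop = FALSE]
    xte <- fp[split$test$compound_id, , drop = FALSE]
    mask <- feature_select(xtr)
    xtr <- xtr[, mask, drop = FALSE]
    xte <- xte[, mask, drop = FALSE]
    ytr <- droplevels(split$train$activity_class)
    yte <- factor(split$test$activity_class, levels = levels(ytr))
    group_reports <- lapply(algorithms, function(alg) {
      cfg <- model_config(alg, seed = seed, cv_folds = cv_folds,
                          test_fraction = test_fraction)
      fit <- train_model(cfg, xtr, ytr)
      list(group = gname, config = cfg, n_records = nrow(recs),
           n_balanced = nrow(balanced), feature_mask = mask,
           training = eval_split(ytr, predict(fit, xtr), levels(ytr)),
           cv = cross_validate(cfg, xtr, ytr),
           test = eval_split(yte, predict(fit, xte), levels(ytr)))
    })
    ord <- order(-vapply(group_reports, function(r) r$test$accuracy,
                         numeric(1)))
    group_reports <- group_reports[ord]
    group_reports[[1]]$best_in_group <- TRUE
    reports <- c(reports, group_reports)
  }
  reports
}

#' Summarize a model-suite run
#'
#' @param reports output of [run_model_suite()].
#' @return data.frame with one row per report: group, algorithm and the
#'   accuracy/MCC of the training, CV and test splits.
#' @export
suite_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) data.frame(
    group = r$group, algorithm = r$config$algorithm,
    n = r$n_records,
    train_accuracy = r$training$accuracy, cv_accuracy = r$cv$accuracy,
    test_accuracy = r$test$accuracy, train_mcc = r$training$mcc,
    cv_mcc = r$cv$mcc, test_mcc = r$test$mcc,
    best = isTRUE(r$best_in_group), stringsAsFactors = FALSE)))
}
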