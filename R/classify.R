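#' Confusion-matrix evaluation metrics
#'
#' PD is the positive class. Recall (sensitivity) `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, accuracy `(tp+tn)/n`, precision `tp/(tp+fp)` and F-measure
#' (harmonic mean of precision and recall). Undefined ratios are `NA`.
#'
#' @param cm Named vector or list with `tp`, `fp`, `tn`, `fn` counts.
#' @return Named numeric vector of the five metrics.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  if (any(c(tp, fp, tn, fn) < 0)) stopf("confusion counts must be >= 0")
  n <- tp + fp + tn + fn
  if (n == 0) stopf("empty confusion matrix")
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  recall <- ratio(tp, tp + fn)
  precision <- ratio(tp, tp + fp)
  f <- if (is.finite(recall) && is.finite(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(recall = recall, specificity = ratio(tn, tn + fp),
    accuracy = (tp + tn) / n, precision = precision, f_measure = f)
}

#' Stratified cross-validation folds
#'
#' Random partition into `k` folds with class proportions preserved
#' (within one subject); with the standard 80-subject cohort and `k = 10`,
#' every fold has exactly 8 subjects (4 per class). Reproducible from
#' `seed`.
#'
#' @param labels Factor of class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
make_folds <- function(labels, k = 10, seed = 1) {
  n <- length(labels)
  if (k < 2 || k > n) stopf("k must be in [2, n]")
  with_seed(seed, {
    fold <- integer(n)
    for (lv in levels(factor(labels))) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# rank-based AUC of scores for binary outcome (positive = TRUE)
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# inner hyperparameter selection -----------------------------------------

svm_grid <- function(kernel, p) {
  cost <- 10^seq(-3, 3)
  switch(kernel,
    linear = data.frame(cost = cost, gamma = 1 / p),
    radial = expand.grid(cost = cost, gamma = (1 / p) * 10^seq(-1, 1)),
    polynomial = data.frame(cost = cost, gamma = 1 / p))
}

fit_svm <- function(x, y, kernel, inner_k = 5, seed = 1) {
  grid <- svm_grid(kernel, ncol(x))
  if (nrow(grid) > 1) {
    fold <- make_folds(y, k = min(inner_k, min(table(y))), seed = seed)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L
      for (f in unique(fold)) {
        tr <- fold != f
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = kernel,
                          degree = 3, cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        correct <- correct + sum(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }
      correct / length(y)
    }, numeric(1))
    g <- which.max(acc)   # ties -> smallest cost (grid ordered by cost)
  } else g <- 1L
  e1071::svm(x, y, kernel = kernel, degree = 3, cost = grid$cost[g],
             gamma = grid$gamma[g], scale = FALSE)
}

fit_rf <- function(x, y, exponents = 1:12, auc_slack = 0.005, seed = 1) {
  # number of trees chosen as the smallest power of two whose out-of-bag
  # AUC is within `auc_slack` of the best, trading accuracy against
  # processing time
  with_seed(seed, {
    sizes <- 2^exponents
    aucs <- vapply(sizes, function(nt) {
      fit <- randomForest::randomForest(x, y, ntree = nt)
      rank_auc(fit$votes[, "PD"], y == "PD")
    }, numeric(1))
    best <- max(aucs, na.rm = TRUE)
    nt <- sizes[which(aucs >= best - auc_slack)[1]]
    randomForest::randomForest(x, y, ntree = nt)
  })
}

fit_nb <- function(x, y) {
  fit <- e1071::naiveBayes(x, y)
  # variance smoothing: floor each class SD at a small fraction of the
  # largest feature SD so a degenerate training column cannot blow up the
  # Gaussian likelihood
  eps <- 1e-9 * max(vapply(fit$tables, function(tb) max(tb[, 2]), numeric(1)), 1)
  fit$tables <- lapply(fit$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], eps); tb
  })
  fit
}

#' Cross-validated evaluation of one classifier on one feature set
#'
#' Stratified k-fold cross-validation: per fold, features are median-imputed
#' and z-scored on the training subjects only, the classifier is fitted
#' (with its inner hyperparameter search) and the held-out fold predicted.
#' Fold confusion counts are pooled into a single cohort-level matrix and
#' the metrics computed from it.
#'
#' @param x Numeric matrix, subjects x features.
#' @param y Factor with levels `HC`, `PD` (PD positive).
#' @param classifier One of `"RF"`, `"SVM_L"`, `"SVM_G"`, `"SVM_P"`, `"NB"`.
#' @param k Folds (default 10).
#' @param seed Integer seed controlling folds and classifier randomness.
#' @param folds Optional precomputed fold assignment (overrides `k`/`seed`
#'   for the partition).
#' @param rf_exponents Tree-count exponents searched for RF (default 1:12).
#' @return List with `confusion` (tp/fp/tn/fn), `metrics`, `folds`, `seed`.
#' @export
cross_validate <- function(x, y, classifier = c("RF", "SVM_L", "SVM_G",
                                                "SVM_P", "NB"),
                           k = 10, seed = 1, folds = NULL,
                           rf_exponents = 1:12) {
  classifier <- match.arg(classifier)
  y <- factor(y, levels = GROUPS)
  if (is.null(folds)) folds <- make_folds(y, k = k, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = GROUPS)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2)
      stopf("training folds must contain both classes")
    xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
    med <- apply(xtr, 2, median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(xtr))) {
      xtr[!is.finite(xtr[, j]), j] <- med[j]
      xte[!is.finite(xte[, j]), j] <- med[j]
    }
    mu <- colMeans(xtr); sg <- apply(xtr, 2, sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    xtr <- scale(xtr, mu, sg); xte <- scale(xte, mu, sg)
    fseed <- child_seed(seed, classifier, f)
    fit <- switch(classifier,
      RF = fit_rf(xtr, y[tr], exponents = rf_exponents, seed = fseed),
      SVM_L = fit_svm(xtr, y[tr], "linear", seed = fseed),
      SVM_G = fit_svm(xtr, y[tr], "radial", seed = fseed),
      SVM_P = fit_svm(xtr, y[tr], "polynomial", seed = fseed),
      NB = fit_nb(xtr, y[tr]))
    pr <- if (classifier == "NB")
      predict(fit, as.data.frame(xte)) else predict(fit, xte)
    pred[!tr] <- pr
  }
  cm <- c(tp = sum(pred == "PD" & y == "PD"),
          fp = sum(pred == "PD" & y == "HC"),
          tn = sum(pred == "HC" & y == "HC"),
          fn = sum(pred == "HC" & y == "PD"))
  list(confusion = cm, metrics = confusion_metrics(cm), folds = folds,
       seed = seed)
}

#' Benchmark all classifiers over all datasets and conditions
#'
#' Evaluates each classifier on each selected feature set (`PS`, `PS_B`,
#' `PC`, `PC_B`) under the FEET, HANDS and FULL conditions, reusing one
#' fold assignment across the whole grid for comparability.
#'
#' @param tab A `feature_table`.
#' @param selection A `selection_result` from [select_features()].
#' @param classifiers Classifiers to run (default all five).
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @param rf_exponents Tree-count exponents searched for RF.
#' @return An `evaluation_report`: list with `results` (data.frame of the
#'   grid metrics), `cells` (per-cell confusion/metrics), `folds`, `seed`.
#' @export
run_benchmark <- function(tab, selection,
                          classifiers = c("RF", "SVM_L", "SVM_G", "SVM_P", "NB"),
                          k = 10, seed = 1, rf_exponents = 1:12) {
  y <- tab$label
  folds <- make_folds(y, k = k, seed = seed)
  cells <- list()
  rows <- list()
  for (ds in names(selection$datasets)) {
    for (cond in c("FEET", "HANDS", "FULL")) {
      feats <- selection$datasets[[ds]][[cond]]
      for (cl in classifiers) {
        key <- paste(cl, ds, cond, sep = ".")
        if (!length(feats)) {
          cells[[key]] <- NULL
          rows[[key]] <- data.frame(classifier = cl, dataset = ds,
                                    condition = cond, n_features = 0L,
                                    recall = NA, specificity = NA,
                                    accuracy = NA, precision = NA,
                                    f_measure = NA)
          next
        }
        x <- tab$features[, feats, drop = FALSE]
        res <- cross_validate(x, y, cl, k = k, seed = seed, folds = folds,
                              rf_exponents = rf_exponents)
        cells[[key]] <- res
        rows[[key]] <- cbind(data.frame(classifier = cl, dataset = ds,
                                        condition = cond,
                                        n_features = length(feats)),
                             as.data.frame(as.list(res$metrics)))
      }
    }
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 cells = cells, folds = folds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d cells (seed %d)\n",
              nrow(x$results), x$seed))
  df <- x$results
  df[, 5:9] <- round(df[, 5:9], 3)
  print(df, row.names = FALSE)
  invisible(x)
}
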