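#' Balanced accuracy
#'
#' `bACC = (TP/(TP+FN) + TN/(TN+FP)) / 2`, the average of sensitivity and
#' specificity; malignant lesions are the positive class throughout.
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(tp, fn, tn, fp) {
  if (tp + fn == 0 || tn + fp == 0) {
    stop("balanced accuracy undefined: a class is empty")
  }
  0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

# confusion counts with malignant = positive
confusion <- function(truth, pred) {
  c(tp = sum(truth == "malignant" & pred == "malignant"),
    fn = sum(truth == "malignant" & pred == "benign"),
    tn = sum(truth == "benign" & pred == "benign"),
    fp = sum(truth == "benign" & pred == "malignant"))
}

# ACC / bACC / SENS / SPEC / AUC from malignant-class probabilities;
# prediction threshold 0.5, ties to malignant
fold_metrics <- function(truth, prob) {
  pred <- ifelse(prob >= 0.5, "malignant", "benign")
  cm <- confusion(truth, pred)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob,
    levels = c("benign", "malignant"), direction = "<", quiet = TRUE
  )))
  c(ACC = unname((cm["tp"] + cm["tn"]) / sum(cm)),
    bACC = balanced_accuracy(cm["tp"], cm["fn"], cm["tn"], cm["fp"]),
    SENS = unname(cm["tp"] / (cm["tp"] + cm["fn"])),
    SPEC = unname(cm["tn"] / (cm["tn"] + cm["fp"])),
    AUC = auc)
}

#' SMOTE + random undersampling of a training set
#'
#' Balances a training split the way the classification bench expects:
#' the minority class is oversampled by synthetic interpolation (SMOTE,
#' 5 nearest neighbors) up to `floor(smote_ratio * n_majority)` rows, and
#' the majority class is then randomly undersampled to
#' `floor(undersample_ratio * n_majority)` rows. Only training data may
#' ever be resampled; evaluation on synthetic rows would be
#' over-optimistic.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y factor of labels (`benign` / `malignant`).
#' @param smote_ratio target minority/majority ratio after oversampling
#'   (default 0.5).
#' @param undersample_ratio target majority size as a fraction of its
#'   original size (default 0.7).
#' @param k SMOTE neighbor count (default 5).
#' @param seed RNG seed; the output is deterministic given the seed.
#' @return list `X` (matrix), `y` (factor).
#' @export
resample_training <- function(X, y, smote_ratio = 0.5,
                              undersample_ratio = 0.7, k = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("benign", "malignant"))
  tab <- table(y)
  if (any(tab == 0)) stop("both classes must be present for resampling")
  min_cl <- names(tab)[which.min(tab)]
  maj_cl <- setdiff(levels(y), min_cl)
  n_min <- sum(y == min_cl); n_maj <- sum(y == maj_cl)
  target_min <- floor(smote_ratio * n_maj)
  target_maj <- floor(undersample_ratio * n_maj)
  with_local_seed(seed, {
    newX <- X; newy <- as.character(y)
    if (n_min < target_min) {
      if (n_min < k + 1) {
        stop(sprintf(
          "minority class too small for SMOTE: need >= %d, have %d",
          k + 1, n_min))
      }
      Xmin <- X[y == min_cl, , drop = FALSE]
      D <- as.matrix(dist(Xmin))
      diag(D) <- Inf
      n_new <- target_min - n_min
      base <- sample.int(n_min, n_new, replace = TRUE)
      synth <- t(vapply(base, function(i) {
        nb <- order(D[i, ])[seq_len(k)]
        j <- nb[sample.int(k, 1)]
        u <- runif(1)
        Xmin[i, ] + u * (Xmin[j, ] - Xmin[i, ])
      }, numeric(ncol(X))))
      newX <- rbind(newX, synth)
      newy <- c(newy, rep(min_cl, n_new))
    }
    maj_idx <- which(newy == maj_cl)
    if (length(maj_idx) > target_maj) {
      drop_idx <- maj_idx[-sample.int(length(maj_idx), target_maj)]
      if (length(drop_idx)) {
        newX <- newX[-drop_idx, , drop = FALSE]
        newy <- newy[-drop_idx]
      }
    }
    list(X = newX, y = factor(newy, levels = c("benign", "malignant")))
  })
}

# ---- model zoo -------------------------------------------------------------

#' L2-regularized logistic regression (IRLS)
#'
#' Direct iteratively reweighted least-squares fit of a ridge-penalized
#' logistic regression with unpenalized intercept, minimizing
#' `sum(nll) + ||w||^2 / (2 C)`; at cohort scale (tens of rows, tens of
#' columns) the closed-form normal-equation update keeps the bench's
#' many thousands of fits fast.
#'
#' @param X numeric feature matrix.
#' @param y01 0/1 response (1 = malignant).
#' @param C inverse regularization strength.
#' @param maxit,tol IRLS iteration controls.
#' @return coefficient vector (intercept first).
#' @export
ridge_logistic <- function(X, y01, C = 1, maxit = 50, tol = 1e-8) {
  X1 <- cbind(1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(c(0, rep(1 / C, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y01 - mu) / w
    xtw <- t(X1 * w)
    newb <- drop(solve(xtw %*% X1 + pen, xtw %*% z))
    if (max(abs(newb - beta)) < tol) {
      beta <- newb
      break
    }
    beta <- newb
  }
  beta
}

# probabilities must stay finite in [0, 1]; degenerate internal fits
# (e.g. a Platt calibration on a tiny fold) fall back to indifference
sanitize_prob <- function(p) {
  p[!is.finite(p)] <- 0.5
  pmin(pmax(p, 0), 1)
}

# Each model is a list(fit(X, y) -> obj, prob(obj, X) -> P(malignant)).
# Features are standardized by the caller; model seeds are set before
# stochastic fits.
make_model <- function(name, hyper, seed = 1L) {
  spec <- switch(name,
    lr = list(
      fit = function(X, y) {
        ridge_logistic(X, as.numeric(y == "malignant"), C = hyper$C)
      },
      prob = function(obj, X) {
        as.numeric(stats::plogis(cbind(1, as.matrix(X)) %*% obj))
      }
    ),
    svm = list(
      fit = function(X, y) {
        with_local_seed(seed, e1071::svm(
          x = as.matrix(X), y = y, kernel = hyper$kernel,
          cost = hyper$C,
          gamma = if (is.null(hyper$gamma)) 1 / ncol(X) else hyper$gamma,
          probability = TRUE, scale = FALSE
        ))
      },
      prob = function(obj, X) {
        pr <- attr(predict(obj, as.matrix(X), probability = TRUE),
                   "probabilities")
        as.numeric(pr[, "malignant"])
      }
    ),
    rf = list(
      fit = function(X, y) {
        p <- ncol(X)
        mtry <- if (identical(hyper$max_features, "sqrt")) {
          max(1, floor(sqrt(p)))
        } else {
          max(1, round(as.numeric(hyper$max_features) * p))
        }
        with_local_seed(seed, randomForest::randomForest(
          x = as.matrix(X), y = y, ntree = 150,
          nodesize = hyper$min_leaf, mtry = min(mtry, p)
        ))
      },
      prob = function(obj, X) {
        as.numeric(predict(obj, as.matrix(X), type = "prob")[, "malignant"])
      }
    ),
    knn = list(
      fit = function(X, y) {
        caret::knn3(as.matrix(X), y, k = min(hyper$k, nrow(X) - 1))
      },
      prob = function(obj, X) {
        as.numeric(predict(obj, as.matrix(X),
                           type = "prob")[, "malignant"])
      }
    ),
    stop("unknown model: ", name)
  )
  raw_prob <- spec$prob
  spec$prob <- function(obj, X) sanitize_prob(raw_prob(obj, X))
  spec
}

# hyperparameter grids; each contains the clinically optimized values
# (LR C = 0.5; SVM rbf C = 50 gamma = 0.001; RF min_leaf 1 max_features
# 0.2; kNN k = 5)
model_grid <- function(name) {
  switch(name,
    lr = lapply(c(0.1, 0.5, 1, 5, 10), function(C) list(C = C)),
    svm = c(
      do.call(c, lapply(c(1, 10, 50, 100), function(C) {
        lapply(c(1e-4, 1e-3, 1e-2), function(g) {
          list(kernel = "radial", C = C, gamma = g)
        })
      })),
      lapply(c(1, 10, 50, 100), function(C) {
        list(kernel = "linear", C = C)
      })
    ),
    rf = do.call(c, lapply(c(1, 2, 5), function(leaf) {
      lapply(list(0.2, 0.5, "sqrt"), function(mf) {
        list(min_leaf = leaf, max_features = mf)
      })
    })),
    knn = lapply(c(3, 5, 7, 9), function(k) list(k = k)),
    stop("unknown model: ", name)
  )
}

hyper_key <- function(hyper) {
  paste(vapply(hyper, function(v) paste(format(v), collapse = ""),
               character(1)), collapse = "|")
}

# stratified fold assignment; every fold must contain both classes
stratified_folds <- function(y, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    if (any(table(fold, y) == 0)) {
      stop("stratification error: a fold lost a class")
    }
    fold
  })
}

# mean cross-validated bACC of a model spec on (X, y)
cv_bacc <- function(name, hyper, X, y, k = 4, seed = 1L) {
  fold <- stratified_folds(y, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    mdl <- make_model(name, hyper, seed = seed + f)
    obj <- mdl$fit(X[tr, , drop = FALSE], y[tr])
    prob <- mdl$prob(obj, X[!tr, , drop = FALSE])
    pred <- ifelse(prob >= 0.5, "malignant", "benign")
    cm <- confusion(y[!tr], pred)
    if (cm["tp"] + cm["fn"] == 0 || cm["tn"] + cm["fp"] == 0) {
      return(NA_real_)
    }
    balanced_accuracy(cm["tp"], cm["fn"], cm["tn"], cm["fp"])
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Backward sequential feature selection
#'
#' Greedy backward elimination: starting from all columns, repeatedly
#' removes the feature whose removal gives the highest cross-validated
#' balanced accuracy, until `n_target` features remain. Score ties are
#' broken by dropping the lowest column index, so the procedure is
#' deterministic given the seed.
#'
#' @param name model name (`"lr"`, `"svm"`, `"rf"`, `"knn"`).
#' @param hyper hyperparameter list for the model.
#' @param X standardized feature matrix (training data only).
#' @param y labels.
#' @param n_target desired number of features (`<= ncol(X)`).
#' @param k inner CV folds for scoring (default 4).
#' @param seed RNG seed.
#' @return character vector of selected column names.
#' @export
backward_sfs <- function(name, hyper, X, y, n_target, k = 4, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(n_target >= 1, n_target <= ncol(X))
  cols <- colnames(X)
  if (is.null(cols)) cols <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  while (length(cols) > n_target) {
    scores <- vapply(seq_along(cols), function(ci) {
      cv_bacc(name, hyper, X[, cols[-ci], drop = FALSE], y, k, seed)
    }, numeric(1))
    cols <- cols[-which.max(scores)]  # first max = lowest index on ties
  }
  cols
}

#' Soft-voting probability combination
#'
#' Equal-weight average of the malignant-class probabilities of several
#' base models; the predicted class is the argmax, with probability ties
#' (0.5) resolved to malignant.
#'
#' @param prob_matrix samples x models matrix of malignant probabilities.
#' @return list `prob` (averaged probabilities) and `pred` (factor).
#' @export
soft_voting <- function(prob_matrix) {
  prob <- rowMeans(as.matrix(prob_matrix))
  pred <- factor(ifelse(prob >= 0.5, "malignant", "benign"),
                 levels = c("benign", "malignant"))
  list(prob = prob, pred = pred)
}

#' Permutation feature importance on a held-out fold
#'
#' Mean drop in a metric (balanced accuracy) when one feature of the test
#' set is randomly shuffled, averaged over `n_perm` shuffles; the
#' model-agnostic importance used to interpret the bench's classifiers.
#'
#' @param prob_fun function(X) returning malignant probabilities of the
#'   fitted model.
#' @param X_test,y_test held-out fold (never resampled).
#' @param features columns to assess (default all).
#' @param n_perm shuffles per feature (default 10).
#' @param seed RNG seed.
#' @return named numeric vector of mean bACC drops.
#' @export
permutation_importance <- function(prob_fun, X_test, y_test,
                                   features = colnames(X_test),
                                   n_perm = 10, seed = 1L) {
  X_test <- as.matrix(X_test)
  pred0 <- ifelse(prob_fun(X_test) >= 0.5, "malignant", "benign")
  cm0 <- confusion(y_test, pred0)
  base <- balanced_accuracy(cm0["tp"], cm0["fn"], cm0["tn"], cm0["fp"])
  with_local_seed(seed, {
    drops <- vapply(features, function(f) {
      mean(vapply(seq_len(n_perm), function(r) {
        Xp <- X_test
        Xp[, f] <- sample(Xp[, f])
        pred <- ifelse(prob_fun(Xp) >= 0.5, "malignant", "benign")
        cm <- confusion(y_test, pred)
        base - balanced_accuracy(cm["tp"], cm["fn"], cm["tn"], cm["fp"])
      }, numeric(1)))
    }, numeric(1))
    drops
  })
}

#' Corrected resampled t-test for cross-validated performance
#'
#' Compares two models' per-repetition performance with the
#' Nadeau-Bengio variance correction for repeated k-fold cross
#' validation, which inflates the naive variance of the mean difference
#' by the train/test overlap ratio:
#' `t = mean(p) / sqrt((1/n + rho) * var(p))` with `p = pA - pB`,
#' `var` the sample variance, and correction ratio `rho = n2/n1`
#' (test/train size) by default; `rho = 0` recovers the uncorrected
#' resampled t-test. The null distribution is t with `n - 1` degrees of
#' freedom; the null is rejected at confidence level `alpha` when
#' `|t| > t_{n-1, 1-alpha/2}`.
#'
#' @param pA,pB per-repetition metric values (equal length `n >= 2`).
#' @param n1,n2 training and test set sizes of each split.
#' @param alpha significance level (default 0.05).
#' @param rho correction ratio; default `n2 / n1`.
#' @return list `t`, `df`, `p_value`, `reject`, `mean_diff`,
#'   `degenerate` (TRUE when the difference variance is 0).
#' @export
corrected_t_test <- function(pA, pB, n1, n2, alpha = 0.05, rho = NULL) {
  n <- length(pA)
  stopifnot(length(pB) == n, n >= 2)
  if (is.null(rho)) rho <- n2 / n1
  p <- pA - pB
  pbar <- mean(p)
  s2 <- var(p)
  degenerate <- s2 == 0
  t_stat <- if (degenerate) {
    if (pbar == 0) 0 else sign(pbar) * Inf
  } else {
    pbar / sqrt((1 / n + rho) * s2)
  }
  df <- n - 1
  crit <- qt(1 - alpha / 2, df)
  p_value <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p_value = p_value,
       reject = abs(t_stat) > crit, mean_diff = pbar,
       degenerate = degenerate)
}

#' Cross-validation bench configuration
#'
#' @param outer_folds outer CV folds (default 4, so that a handful of
#'   benign lesions lands in every test fold).
#' @param repeats random re-splits of the outer folds (default 5; with 4
#'   outer folds this gives 20 performance evaluations).
#' @param inner_folds folds for grid search and SFS scoring (default 4).
#' @param smote_ratio,undersample_ratio resampling targets
#'   (see [resample_training()]).
#' @param sfs_target number of features kept by backward selection
#'   (default 12; selection is skipped when fewer features are
#'   available, or entirely when `NULL`).
#' @param n_perm permutation-importance shuffles per feature per fold.
#' @param correction `"test_train"` (Nadeau-Bengio default, rho = n2/n1)
#'   or `"train_test"` (rho = n1/n2) for the corrected t-test.
#' @param filter_in_folds when `TRUE`, the feature filtering
#'   ([correlation_prune()] + [adaptive_select()]) is re-fit on the
#'   training folds only (leak-free mode) instead of once on the full
#'   table beforehand (pooled mode, the default workflow).
#' @param seed master seed for the fold/resampling/model seed hierarchy.
#' @return a `cv_config` list.
#' @export
cv_config <- function(outer_folds = 4, repeats = 5, inner_folds = 4,
                      smote_ratio = 0.5, undersample_ratio = 0.7,
                      sfs_target = 12, n_perm = 10,
                      correction = c("test_train", "train_test"),
                      filter_in_folds = FALSE, seed = 42L) {
  structure(list(
    outer_folds = outer_folds, repeats = repeats,
    inner_folds = inner_folds, smote_ratio = smote_ratio,
    undersample_ratio = undersample_ratio, sfs_target = sfs_target,
    n_perm = n_perm, correction = match.arg(correction),
    filter_in_folds = isTRUE(filter_in_folds), seed = as.integer(seed)
  ), class = "cv_config")
}

# impute (train medians), optionally re-run the feature filtering on the
# training rows only (leak-free mode), resample the training rows, and
# standardize with the resampled-training statistics; the test rows are
# never resampled
prep_fold <- function(ft, train, test, config, seed) {
  X <- as.matrix(ft$features)
  y <- ft$labels
  if (isTRUE(config$filter_in_folds)) {
    ftr <- feature_table(ft$features[train, , drop = FALSE],
                         y[train], ft$sets)
    ftr <- adaptive_select(correlation_prune(ftr), seed = seed)
    X <- X[, names(ftr$features), drop = FALSE]
  }
  imp <- impute_median(as.data.frame(X[train, , drop = FALSE]))
  Xtr <- as.matrix(imp$features)
  Xte <- as.matrix(impute_median(as.data.frame(X[test, , drop = FALSE]),
                                 imp$medians)$features)
  rs <- resample_training(Xtr, y[train], config$smote_ratio,
                          config$undersample_ratio, seed = seed)
  mu <- colMeans(rs$X)
  sdv <- apply(rs$X, 2, sd)
  sdv[sdv == 0] <- 1
  list(
    Xtr = sweep(sweep(rs$X, 2, mu), 2, sdv, "/"), ytr = rs$y,
    Xte = sweep(sweep(Xte, 2, mu), 2, sdv, "/"), yte = y[test],
    n_train = sum(train), n_test = sum(test)
  )
}

#' Repeated nested cross-validation bench
#'
#' Trains and evaluates the four base classifiers (L2 logistic
#' regression, SVM, random forest, k-nearest neighbors) plus their
#' soft-voting combination and an all-malignant naive baseline, using
#' repeated stratified nested k-fold cross validation:
#'
#' 1. each repeat re-splits the lesions into `outer_folds` stratified
#'    folds; every fold serves once as the untouched test set;
#' 2. the training folds are SMOTE-oversampled and randomly undersampled
#'    ([resample_training()]), then backward feature selection
#'    ([backward_sfs()]) and an inner cross-validated grid search choose
#'    the feature subset and hyperparameters per fold;
#' 3. the most frequently chosen hyperparameters across all folds become
#'    the final ones, the procedure is re-run with them fixed, and ACC,
#'    bACC, SENS, SPEC and AUC are measured on each test fold;
#' 4. permutation feature importance and selection frequency are
#'    accumulated over all `repeats * outer_folds` evaluations, and all
#'    model pairs are compared on bACC with [corrected_t_test()].
#'
#' @param ft a `feature_table` (already filtered; see
#'   [correlation_prune()], [adaptive_select()]).
#' @param models base model names (default all four).
#' @param config a [cv_config()].
#' @return a `cv_report`: list with `metrics` (mean and sd data.frames),
#'   `per_fold` bACC matrix, `hyperparams`, `pfi`, `t_tests`, `config`.
#' @export
nested_cv <- function(ft, models = c("lr", "svm", "rf", "knn"),
                      config = cv_config()) {
  stopifnot(inherits(ft, "feature_table"))
  X <- as.matrix(ft$features)
  y <- ft$labels
  if (min(table(y)) < config$outer_folds) {
    stop("too few lesions in a class for stratified outer folds")
  }
  n_eval <- config$repeats * config$outer_folds
  all_models <- c(models, "svc", "naive")

  # fold layout and per-fold preprocessed data, shared by both passes
  preps <- vector("list", n_eval)
  e <- 0
  for (r in seq_len(config$repeats)) {
    fold <- stratified_folds(y, config$outer_folds, config$seed + r)
    for (f in seq_len(config$outer_folds)) {
      e <- e + 1
      preps[[e]] <- prep_fold(ft, fold != f, fold == f, config,
                              seed = config$seed + 1000L * r + f)
    }
  }

  # pass 1: per-fold SFS (default hyperparameters) + grid search
  message("nested_cv: hyperparameter pass (", n_eval, " folds)")
  keys <- list()
  for (m in models) {
    grid <- model_grid(m)
    keys[[m]] <- vapply(seq_len(n_eval), function(e) {
      pr <- preps[[e]]
      cols <- colnames(pr$Xtr)
      if (!is.null(config$sfs_target) &&
          length(cols) > config$sfs_target) {
        cols <- backward_sfs(m, grid[[1]], pr$Xtr, pr$ytr,
                             config$sfs_target, config$inner_folds,
                             seed = config$seed + e)
      }
      scores <- vapply(grid, function(h) {
        cv_bacc(m, h, pr$Xtr[, cols, drop = FALSE], pr$ytr,
                config$inner_folds, seed = config$seed + e)
      }, numeric(1))
      hyper_key(grid[[which.max(scores)]])
    }, character(1))
  }
  final_hyper <- lapply(models, function(m) {
    grid <- model_grid(m)
    tab <- table(keys[[m]])
    grid[[match(names(tab)[which.max(tab)],
                vapply(grid, hyper_key, character(1)))]]
  })
  names(final_hyper) <- models

  # pass 2: fixed hyperparameters; evaluate on the untouched test folds
  message("nested_cv: evaluation pass")
  metric_names <- c("ACC", "bACC", "SENS", "SPEC", "AUC")
  per_fold <- array(NA_real_,
                    dim = c(n_eval, length(all_models),
                            length(metric_names)),
                    dimnames = list(NULL, all_models, metric_names))
  pfi_acc <- lapply(setNames(nm = c(models, "svc")), function(m) {
    list(drop = setNames(numeric(ncol(X)), colnames(X)),
         count = setNames(numeric(ncol(X)), colnames(X)))
  })
  for (e in seq_len(n_eval)) {
    pr <- preps[[e]]
    prob_mat <- matrix(NA_real_, length(pr$yte), length(models),
                       dimnames = list(NULL, models))
    union_cols <- character(0)
    fits <- list()
    for (m in models) {
      cols <- colnames(pr$Xtr)
      if (!is.null(config$sfs_target) &&
          length(cols) > config$sfs_target) {
        cols <- backward_sfs(m, final_hyper[[m]], pr$Xtr, pr$ytr,
                             config$sfs_target, config$inner_folds,
                             seed = config$seed + e)
      }
      mdl <- make_model(m, final_hyper[[m]], seed = config$seed + e)
      obj <- mdl$fit(pr$Xtr[, cols, drop = FALSE], pr$ytr)
      prob <- mdl$prob(obj, pr$Xte[, cols, drop = FALSE])
      prob_mat[, m] <- prob
      per_fold[e, m, ] <- fold_metrics(pr$yte, prob)
      fits[[m]] <- list(obj = obj, mdl = mdl, cols = cols)
      union_cols <- union(union_cols, cols)
      pfi <- permutation_importance(
        function(Xp) mdl$prob(obj, Xp[, cols, drop = FALSE]),
        pr$Xte, pr$yte, features = cols, n_perm = config$n_perm,
        seed = config$seed + 7L * e
      )
      pfi_acc[[m]]$drop[cols] <- pfi_acc[[m]]$drop[cols] + pfi
      pfi_acc[[m]]$count[cols] <- pfi_acc[[m]]$count[cols] + 1
    }
    sv <- soft_voting(prob_mat)
    per_fold[e, "svc", ] <- fold_metrics(pr$yte, sv$prob)
    pfi_sv <- permutation_importance(
      function(Xp) {
        rowMeans(vapply(models, function(m) {
          fits[[m]]$mdl$prob(fits[[m]]$obj,
                             Xp[, fits[[m]]$cols, drop = FALSE])
        }, numeric(nrow(Xp))))
      },
      pr$Xte, pr$yte, features = union_cols, n_perm = config$n_perm,
      seed = config$seed + 7L * e
    )
    pfi_acc$svc$drop[union_cols] <- pfi_acc$svc$drop[union_cols] + pfi_sv
    pfi_acc$svc$count[union_cols] <- pfi_acc$svc$count[union_cols] + 1
    # naive all-malignant baseline
    cm <- confusion(pr$yte, rep("malignant", length(pr$yte)))
    per_fold[e, "naive", ] <- c(
      (cm["tp"] + cm["tn"]) / sum(cm),
      balanced_accuracy(cm["tp"], cm["fn"], cm["tn"], cm["fp"]),
      1, 0, NA_real_
    )
  }

  metrics_mean <- as.data.frame(t(apply(per_fold, c(2, 3), mean)))
  metrics_sd <- as.data.frame(t(apply(per_fold, c(2, 3), sd)))
  pfi <- lapply(pfi_acc, function(a) {
    sel <- a$count > 0
    mean_drop <- ifelse(sel, a$drop / pmax(a$count, 1), 0)
    top <- max(mean_drop)
    data.frame(
      feature = names(a$drop),
      norm_pfi = if (top > 0) mean_drop / top else mean_drop,
      selection_freq = a$count / n_eval,
      row.names = NULL
    )[order(-mean_drop), ]
  })
  n2 <- mean(vapply(preps, `[[`, numeric(1), "n_test"))
  n1 <- mean(vapply(preps, `[[`, numeric(1), "n_train"))
  rho <- if (config$correction == "test_train") n2 / n1 else n1 / n2
  cmp_models <- c(models, "svc")
  pairs <- t(combn(cmp_models, 2))
  t_tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    tt <- corrected_t_test(per_fold[, a, "bACC"], per_fold[, b, "bACC"],
                           n1, n2, rho = rho)
    data.frame(model_a = a, model_b = b, t = tt$t, df = tt$df,
               p_value = tt$p_value, reject = tt$reject)
  }))
  structure(list(
    metrics = list(mean = t(metrics_mean), sd = t(metrics_sd)),
    per_fold = per_fold, hyperparams = final_hyper, pfi = pfi,
    t_tests = t_tests, n_train = n1, n_test = n2, config = config
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> mean (sd) over",
      nrow(x$per_fold), "evaluations\n")
  m <- x$metrics$mean
  s <- x$metrics$sd
  for (r in rownames(m)) {
    cat(sprintf("  %-6s %s\n", r, paste(sprintf(
      "%s %.2f(%.2f)", colnames(m), m[r, ], s[r, ]), collapse = "  ")))
  }
  invisible(x)
}

#' Balanced-accuracy sweep over the number of selected features
#'
#' Re-runs the evaluation pass of the bench for a range of backward-SFS
#' target sizes and reports the mean bACC per target, reproducing the
#' feature-count optimization experiment on any cohort.
#'
#' @param ft a filtered `feature_table`.
#' @param model one base model name.
#' @param n_values integer vector of SFS targets (default 12 to the
#'   number of available features, capped at 41).
#' @param config a [cv_config()].
#' @return data.frame `n_features`, `mean_bacc`, `sd_bacc`.
#' @export
feature_count_sweep <- function(ft, model = "lr", n_values = NULL,
                                config = cv_config()) {
  p <- ncol(ft$features)
  if (is.null(n_values)) n_values <- seq(min(12, p), min(p, 41))
  res <- lapply(n_values, function(nf) {
    cfg <- config
    cfg$sfs_target <- nf
    rep <- nested_cv(ft, models = model, config = cfg)
    data.frame(n_features = nf,
               mean_bacc = rep$metrics$mean[model, "bACC"],
               sd_bacc = rep$metrics$sd[model, "bACC"])
  })
  do.call(rbind, res)
}
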