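test_that("balanced accuracy averages sensitivity and specificity", {
  expect_equal(balanced_accuracy(10, 0, 5, 0), 1)
  expect_equal(balanced_accuracy(3, 1, 1, 1), 0.625)
  # all-malignant prediction on an unbalanced cohort
  expect_equal(balanced_accuracy(74, 0, 0, 13), 0.5)
  expect_error(balanced_accuracy(0, 0, 5, 1), "empty")
})

test_that("training resampling follows the stated ratios", {
  set.seed(1)
  X <- matrix(rnorm(65 * 4), 65, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("benign", "malignant"), c(10, 55))
  rs <- resample_training(X, y, seed = 3)
  # floor(0.5 * 55) = 27 benign, floor(0.7 * 55) = 38 malignant
  expect_equal(unname(table(rs$y)["benign"]), 27L)
  expect_equal(unname(table(rs$y)["malignant"]), 38L)
  # deterministic under the seed
  rs2 <- resample_training(X, y, seed = 3)
  expect_identical(rs$X, rs2$X)
  # synthetic rows interpolate between real minority rows (convexity)
  rng <- apply(X[y == "benign", ], 2, range)
  synth <- rs$X[rs$y == "benign", ][-(1:10), ]
  expect_true(all(synth >= matrix(rng[1, ], nrow(synth), 4, TRUE) - 1e-9))
  expect_true(all(synth <= matrix(rng[2, ], nrow(synth), 4, TRUE) + 1e-9))
  # already balanced beyond the targets: only undersampling applies
  yb <- rep(c("benign", "malignant"), c(30, 40))
  Xb <- matrix(rnorm(70 * 4), 70, 4)
  rsb <- resample_training(Xb, yb, seed = 5)
  expect_equal(unname(table(rsb$y)["benign"]), 30L)
  expect_equal(unname(table(rsb$y)["malignant"]), 28L)
  # tiny minority class is refused with the required minimum
  expect_error(resample_training(X[c(1:3, 11:65), ],
                                 y[c(1:3, 11:65)], seed = 1),
               ">= 6")
})

test_that("ridge logistic regression matches glmnet on a fixture", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 80; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y01 <- rbinom(n, 1, plogis(X %*% c(1.5, -1, 0.5, 0, 0)))
  C <- 0.5
  beta <- ridge_logistic(X, y01, C = C)
  # glmnet penalizes lambda/2 * ||w||^2 * n on the mean log-likelihood
  fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                        lambda = 1 / (C * n), standardize = FALSE,
                        thresh = 1e-12)
  ref <- as.numeric(coef(fit))
  expect_equal(unname(beta), ref, tolerance = 0.02)
  p1 <- plogis(cbind(1, X) %*% beta)
  p2 <- as.numeric(predict(fit, X, type = "response"))
  expect_lt(max(abs(p1 - p2)), 0.01)
})

test_that("backward selection keeps the separating feature", {
  set.seed(11)
  n <- 48
  y <- factor(rep(c("benign", "malignant"), each = n / 2),
              levels = c("benign", "malignant"))
  X <- cbind(sep = rnorm(n) + (y == "malignant") * 4,
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  colnames(X)[1] <- "sep"
  kept <- backward_sfs("lr", list(C = 1), X, y, n_target = 1, seed = 2)
  expect_identical(kept, "sep")
  # n_target = n: identity
  expect_identical(backward_sfs("knn", list(k = 3), X, y, 6, seed = 2),
                   colnames(X))
  # duplicated informative feature: one copy may fall, the pair never
  X2 <- cbind(X[, "sep", drop = FALSE], dup = X[, "sep"],
              X[, 2:3])
  kept2 <- backward_sfs("lr", list(C = 1), X2, y, 2, seed = 2)
  expect_true("sep" %in% kept2 || "dup" %in% kept2)
})

test_that("soft voting averages probabilities and breaks ties malignant", {
  v <- soft_voting(cbind(c(0.9, 0.6, 0.9), c(0.9, 0.4, 0.2),
                         c(0.9, 0.5, 0.2)))
  expect_equal(v$prob[1], 0.9)
  expect_equal(as.character(v$pred[1]), "malignant")
  expect_equal(as.character(v$pred[2]), "malignant")  # 0.5 tie
  expect_equal(v$prob[3], mean(c(0.9, 0.2, 0.2)))
  expect_equal(as.character(v$pred[3]), "benign")
})

test_that("permutation importance isolates the used features", {
  set.seed(13)
  n <- 60
  y <- factor(rep(c("benign", "malignant"), each = n / 2),
              levels = c("benign", "malignant"))
  X <- cbind(sig = rnorm(n) + (y == "malignant") * 3,
             junk = rnorm(n))
  beta <- ridge_logistic(X[, "sig", drop = FALSE],
                         as.numeric(y == "malignant"), C = 10)
  prob_fun <- function(Xp) {
    plogis(cbind(1, Xp[, "sig", drop = FALSE]) %*% beta)
  }
  pfi <- permutation_importance(prob_fun, X, y, n_perm = 20, seed = 4)
  expect_equal(unname(pfi["junk"]), 0)       # never enters the model
  expect_gt(unname(pfi["sig"]), 0.2)
  # shared importance: exchangeable duplicates split the credit
  X3 <- cbind(a = X[, "sig"], b = X[, "sig"] + rnorm(n, 0, 0.01))
  beta2 <- ridge_logistic(X3, as.numeric(y == "malignant"), C = 10)
  prob2 <- function(Xp) plogis(cbind(1, Xp[, c("a", "b")]) %*% beta2)
  pfi2 <- permutation_importance(prob2, X3, y, n_perm = 20, seed = 4)
  expect_lt(unname(pfi2["a"]), unname(pfi["sig"]))
  expect_lt(unname(pfi2["b"]), unname(pfi["sig"]))
})

test_that("the corrected t-test reduces, flips and degenerates correctly", {
  set.seed(17)
  pA <- runif(20, 0.7, 0.9)
  # identical models: t = 0, never rejected
  tt <- corrected_t_test(pA, pA, n1 = 65, n2 = 22)
  expect_equal(tt$t, 0)
  expect_false(tt$reject)
  # antisymmetry
  pB <- runif(20, 0.6, 0.8)
  t_ab <- corrected_t_test(pA, pB, 65, 22)$t
  t_ba <- corrected_t_test(pB, pA, 65, 22)$t
  expect_equal(t_ab, -t_ba)
  # rho = 0 recovers the uncorrected resampled t
  p <- pA - pB
  t_unc <- mean(p) / sqrt(var(p) / 20)
  expect_equal(corrected_t_test(pA, pB, 65, 22, rho = 0)$t, t_unc)
  # constant nonzero difference: degenerate variance, flagged
  ttd <- corrected_t_test(pA, pA - 0.05, 65, 22)
  expect_true(ttd$degenerate)
  expect_true(is.infinite(ttd$t) && ttd$t > 0)
  expect_true(ttd$reject)
  # correction shrinks |t| relative to the uncorrected statistic
  expect_lt(abs(corrected_t_test(pA, pB, 65, 22)$t), abs(t_unc))
})

test_that("nested CV with backward selection runs end to end", {
  set.seed(23)
  n <- 48; p <- 6
  lab <- sample(rep(c("benign", "malignant"), c(16, 32)))
  X <- data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("Coherence_f", 1:p, "_median")
  X[, 1] <- X[, 1] + (lab == "malignant") * 3
  X[, 2] <- X[, 2] + (lab == "malignant") * 2
  ft <- feature_table(X, lab)
  cfg <- cv_config(repeats = 1, sfs_target = 4, n_perm = 3, seed = 9)
  rep1 <- nested_cv(ft, models = c("lr", "knn"), config = cfg)
  expect_equal(dim(rep1$per_fold), c(4L, 4L, 5L))
  # bACC identity holds on every evaluated fold and model
  for (m in c("lr", "knn", "svc", "naive")) {
    expect_equal(rep1$per_fold[, m, "bACC"],
                 (rep1$per_fold[, m, "SENS"] +
                    rep1$per_fold[, m, "SPEC"]) / 2)
  }
  # the informative features dominate the PFI ranking
  top <- rep1$pfi$lr$feature[1]
  expect_true(top %in% c("Coherence_f1_median", "Coherence_f2_median"))
  expect_true(all(rep1$pfi$lr$norm_pfi <= 1))
  # determinism of the whole report under the seed
  rep2 <- nested_cv(ft, models = c("lr", "knn"), config = cfg)
  expect_identical(rep1$per_fold, rep2$per_fold)
})

test_that("degenerate stratification is refused", {
  X <- data.frame(Coherence_a_median = rnorm(10))
  ft <- feature_table(X, rep(c("benign", "malignant"), c(2, 8)))
  expect_error(nested_cv(ft), "too few lesions")
})
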