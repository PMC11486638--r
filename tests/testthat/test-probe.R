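test_that("PCA reduction is orthonormal, complete on training rows, and caps at rank", {
  set.seed(10)
  X <- matrix(rnorm(20 * 50), 20, 50)
  red <- pca_reduce(X, n_components = 19)
  # orthonormal loadings
  g <- crossprod(red$rotation)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  # a full basis for the row space reconstructs training rows exactly
  xc <- sweep(X, 2, red$center)
  rec <- red$scores %*% t(red$rotation)
  expect_lt(max(abs(rec - xc)), 1e-8)
  # rank cap with warning
  Xlow <- matrix(rnorm(10 * 3), 10, 3) %*% matrix(rnorm(3 * 40), 3, 40)
  expect_warning(r2 <- pca_reduce(Xlow, n_components = 9), "rank")
  expect_lte(ncol(r2$rotation), 3L)
  expect_error(pca_reduce(X, n_components = 30), "exceeds")
})

test_that("a dominant axis is captured by the first component", {
  set.seed(2)
  n <- 40
  axis <- rnorm(n, 0, 10)
  X <- cbind(axis, rnorm(n, 0, 0.05)) %*% matrix(c(1, 0, 0, 1), 2, 2)
  red <- pca_reduce(X, 2)
  ev <- red$sdev^2 / sum(red$sdev^2)
  expect_gte(ev[1], 0.99)
})

probe_cohort <- function(n = 25, noise_sd = 0, jitter_sd = 0.01, seed = 31) {
  spec <- tiny_spec(noise_sd = noise_sd, subject_jitter_sd = jitter_sd,
                    atrophy_per_year = 0.006)
  coh <- generate_cohort(spec, n, effect = NULL, seed = seed)
  subs <- cohort_subjects(coh, "HS")
  list(volumes = lapply(subs, function(s) s$volume),
       ages = vapply(subs, function(s) s$age_years, numeric(1)),
       subject_ids = vapply(subs, function(s) s$subject_id, character(1)))
}

test_that("out-of-fold age prediction recovers a clean linear age signal", {
  # exactly linear: no noise, no jitter (the volume is template x age factor)
  st <- probe_cohort(n = 25, noise_sd = 0, jitter_sd = 0)
  pr <- predict_age_cv(st, k = 5, seed = 1)
  expect_lt(pr$mae, 0.5)
  # every subject predicted exactly once
  expect_equal(sort(pr$predictions$subject_id), sort(st$subject_ids))
  expect_false(any(is.na(pr$predictions$predicted_age)))
  # determinism
  pr2 <- predict_age_cv(st, k = 5, seed = 1)
  expect_identical(pr$predictions, pr2$predictions)
  expect_false(identical(
    predict_age_cv(st, k = 5, seed = 2)$predictions$fold_id,
    pr$predictions$fold_id))
})

test_that("permuted ages give chance-level prediction error", {
  st <- probe_cohort(n = 25, noise_sd = 0.01)
  baseline_mae <- predict_age_cv(st, k = 5, seed = 1)$mae
  st_perm <- st
  st_perm$ages <- st$ages[c(13:25, 1:12)]  # fixed derangement
  pr <- predict_age_cv(st_perm, k = 5, seed = 1)
  # null oracle: mean absolute deviation of the permuted age distribution
  mad0 <- mean(abs(st_perm$ages - mean(st_perm$ages)))
  expect_gt(pr$mae, 0.5 * mad0)
  expect_lt(baseline_mae, 0.5 * pr$mae)
})

test_that("PCA and regression fits never see the validation fold", {
  st <- probe_cohort(n = 20, noise_sd = 0.01)
  # shuffling ages of one fold's subjects must not change predictions for
  # the other folds (their training sets are disjoint from that fold only
  # through its ages... they do contain its volumes, so instead check:
  # perturbing a validation subject's volume changes only that subject's
  # prediction in its own fold round)
  pr <- predict_age_cv(st, k = 4, seed = 9)
  f1 <- which(pr$predictions$fold_id == 1)
  st2 <- st
  st2$ages[f1] <- st$ages[f1] + 100  # corrupt ages of fold-1 subjects
  # fold-1 ages enter every other fold's training set, so instead verify
  # the stronger contract directly: predictions for fold 1 do not depend on
  # fold-1 ages at all
  pr2 <- predict_age_cv(st2, k = 4, seed = 9)
  expect_equal(pr$predictions$predicted_age[f1],
               pr2$predictions$predicted_age[f1], tolerance = 1e-8)
})

test_that("paired comparison reproduces hand-computed effect sizes", {
  mk <- function(pred) {
    structure(list(predictions = data.frame(
      subject_id = paste0("s", 1:3), true_age = c(30, 40, 50),
      predicted_age = pred, fold_id = 1:3), mae = 0, state = "x", k = 3,
      seed = 1), class = "age_prediction")
  }
  a <- mk(c(10, 10, 10))
  b <- mk(c(10, 11, 12))  # diffs (0, 1, 2): mean 1, sd 1 -> d = 1
  cs <- compare_predictions_paired(a, b)
  expect_equal(cs$effect_size, 1)
  expect_equal(cs$statistic, sqrt(3), tolerance = 1e-12)
  # identical states: 0/1/0 conventions
  cs0 <- compare_predictions_paired(a, a)
  expect_equal(cs0$statistic, 0)
  expect_equal(cs0$p_value, 1)
  expect_equal(cs0$effect_size, 0)
  # antisymmetry
  expect_equal(compare_predictions_paired(b, a)$statistic, -cs$statistic)
  bad <- mk(c(1, 2, 3)); bad$predictions$true_age <- c(1, 2, 3)
  expect_error(compare_predictions_paired(a, bad), "aligned")
})

test_that("ANOVA across states matches oracles and the F = t^2 identity", {
  mk <- function(pred, state = "s") {
    structure(list(predictions = data.frame(
      subject_id = paste0("s", seq_along(pred)),
      true_age = seq_along(pred), predicted_age = pred,
      fold_id = 1), mae = 0, state = state, k = 2, seed = 1),
      class = "age_prediction")
  }
  # all states identical: F = 0, eta2p = 0
  a <- mk(c(1, 2, 3, 4))
  cs <- compare_predictions_anova(list(a, a, a))
  expect_equal(cs$statistic, 0)
  expect_equal(cs$effect_size, 0)

  # two states: F equals the two-sample t squared
  set.seed(8)
  x1 <- rnorm(12, 10); x2 <- rnorm(12, 11)
  cs2 <- compare_predictions_anova(list(mk(x1), mk(x2)))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(cs2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cs2$p_value, tt$p.value, tolerance = 1e-10)

  # brute-force sums of squares on a constructed design
  set.seed(9)
  g1 <- rnorm(30, 10, 1); g2 <- rnorm(30, 10, 1); g3 <- rnorm(30, 20, 1)
  cs3 <- compare_predictions_anova(list(mk(g1), mk(g2), mk(g3)))
  y <- c(g1, g2, g3); lab <- rep(1:3, each = 30)
  fit <- anova(lm(y ~ factor(lab)))
  expect_equal(cs3$statistic, fit$`F value`[1], tolerance = 1e-10)
  eta_oracle <- fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)
  expect_equal(cs3$effect_size, eta_oracle, tolerance = 1e-10)
  expect_gt(cs3$effect_size, 0.9)
  expect_error(compare_predictions_anova(list(a)), "at least 2")
})
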