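#' Principal-component reduction of a subjects-by-voxels matrix
#'
#' Centers the training matrix and projects onto its top components. The
#' number of retained components follows the sample-size rule (as many
#' components as training subjects), capped at the matrix rank; components
#' with negligible singular values are dropped with a warning when the
#' request exceeds the rank. Fitting uses training rows only; apply the fit
#' to held-out rows with [predict()] (no leakage).
#'
#' @param feature_matrix numeric matrix, subjects in rows, voxels in
#'   columns.
#' @param n_components requested number of components (default
#'   `nrow(feature_matrix)`).
#' @return A `pca_reduction`: list with `scores` (training projections),
#'   `rotation`, `center`, `sdev`.
#' @export
pca_reduce <- function(feature_matrix, n_components = nrow(feature_matrix)) {
  x <- as.matrix(feature_matrix)
  if (n_components < 1L) stop("`n_components` must be positive")
  if (n_components > min(dim(x)))
    stop("`n_components` exceeds min(n_subjects, n_voxels)")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  pc <- svd(xc, nu = 0, nv = min(nrow(x), ncol(x)))
  rank <- sum(pc$d > max(pc$d[1], 0) * 1e-8)
  if (rank == 0L) rank <- 1L
  if (n_components > rank) {
    warning("requested ", n_components, " components but the matrix rank is ",
            rank, "; truncating")
    n_components <- rank
  }
  rotation <- pc$v[, seq_len(n_components), drop = FALSE]
  structure(list(scores = xc %*% rotation, rotation = rotation, center = ctr,
                 sdev = pc$d[seq_len(n_components)] /
                   sqrt(max(1, nrow(x) - 1))),
            class = "pca_reduction")
}

#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2L, object$center) %*% object$rotation
}

#' Cross-validated brain-age prediction
#'
#' Out-of-fold age prediction by PCA + ordinary least squares: per fold, the
#' component basis and the regression are fitted on the training subjects
#' only and applied to the held-out fold, so every subject is predicted
#' exactly once by a model that never saw it. The component count follows
#' the sample-size rule (all `n_train` dimensions, capped at rank).
#'
#' @param cohort_state a `cohort`, a list of `subject_record`s, or a list
#'   with elements `volumes` (list of volumes) and `ages`.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param n_components optional fixed component count; default is the
#'   sample-size rule.
#' @param state label attached to the result (e.g. `"original"`,
#'   `"virtual"`, `"iteration-2"`).
#' @return An `age_prediction`: data frame `predictions`
#'   (`subject_id`, `true_age`, `predicted_age`, `fold_id`), plus `mae`
#'   (mean absolute error, years) and `state`.
#' @export
predict_age_cv <- function(cohort_state, k = 5L, seed = 1L,
                           n_components = NULL, state = "original") {
  xs <- probe_inputs(cohort_state)
  n <- length(xs$ages)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")")
  if (stats::sd(xs$ages) == 0)
    warning("constant ages: the regression fit is degenerate")
  X <- xs$mat
  folds <- with_seed(seed, {
    f <- rep(seq_len(k), length.out = n)
    sample(f)
  })
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    nc <- if (is.null(n_components)) length(tr) else n_components
    nc <- min(nc, length(tr) - 1L)
    red <- suppressWarnings(pca_reduce(X[tr, , drop = FALSE],
                                       n_components = nc))
    str_ <- red$scores
    sva <- predict(red, X[va, , drop = FALSE])
    fit <- stats::lm.fit(cbind(1, str_), xs$ages[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred[va] <- drop(cbind(1, sva) %*% beta)
  }
  out <- list(predictions = data.frame(subject_id = xs$ids,
                                       true_age = xs$ages,
                                       predicted_age = pred,
                                       fold_id = folds,
                                       stringsAsFactors = FALSE),
              mae = mean(abs(pred - xs$ages)), state = state, k = k,
              seed = seed)
  class(out) <- "age_prediction"
  out
}

probe_inputs <- function(x) {
  if (inherits(x, "cohort")) {
    vols <- cohort_volumes(x)
    ages <- cohort_ages(x)
    ids <- vapply(x$subjects, function(s) s$subject_id, character(1))
  } else if (is.list(x) && !is.null(x$volumes)) {
    vols <- x$volumes
    ages <- x$ages
    ids <- x$subject_ids %||% sprintf("sub-%03d", seq_along(vols))
  } else if (is.list(x) && length(x) && inherits(x[[1]], "subject_record")) {
    vols <- lapply(x, function(s) s$volume)
    ages <- vapply(x, function(s) s$age_years, numeric(1))
    ids <- vapply(x, function(s) s$subject_id, character(1))
  } else stop("unrecognized cohort-state input")
  if (length(vols) != length(ages)) stop("volumes and ages differ in length")
  list(mat = stack_volumes(vols)$mat, ages = as.numeric(ages), ids = ids)
}

#' @export
print.age_prediction <- function(x, ...) {
  cat(sprintf("<age_prediction> state '%s': %d subjects, %d folds, MAE %.2f years\n",
              x$state, nrow(x$predictions), x$k, x$mae))
  invisible(x)
}

#' Paired comparison of two sets of age predictions
#'
#' Paired t-test on predicted ages across two states of the same subjects,
#' with Cohen's d (`mean(diff) / sd(diff)`) as the effect size. Identical
#' predictions give statistic 0, p 1, and d 0 by convention.
#'
#' @param state_1,state_2 `age_prediction` objects over the same subjects in
#'   the same order.
#' @return A `comparison_stats`: list with `test = "paired-t"`, `statistic`,
#'   `p_value`, `effect_size` (Cohen's d), `dof`, `n`.
#' @export
compare_predictions_paired <- function(state_1, state_2) {
  stopifnot(inherits(state_1, "age_prediction"),
            inherits(state_2, "age_prediction"))
  p1 <- state_1$predictions; p2 <- state_2$predictions
  if (nrow(p1) != nrow(p2) ||
      !isTRUE(all.equal(p1$true_age, p2$true_age)) ||
      !identical(p1$subject_id, p2$subject_id))
    stop("prediction sets are not aligned on the same subjects")
  d <- p2$predicted_age - p1$predicted_age
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    stat <- 0; p <- 1; eff <- 0
  } else {
    stat <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(stat), df = n - 1)
    eff <- mean(d) / sdd
  }
  structure(list(test = "paired-t", statistic = stat, p_value = p,
                 effect_size = eff, effect_type = "cohens_d", dof = n - 1L,
                 n = n),
            class = "comparison_stats")
}

#' One-way ANOVA over age predictions across states
#'
#' Compares predicted ages across two or more transformation states with a
#' one-way analysis of variance on the state label, reporting partial
#' eta-squared `SS_effect / (SS_effect + SS_error)` as the effect size.
#'
#' @param states list of `age_prediction` objects (>= 2).
#' @return A `comparison_stats` with `test = "anova"`, `statistic` (F),
#'   `p_value`, `effect_size` (partial eta-squared), `dof` (numerator,
#'   denominator).
#' @export
compare_predictions_anova <- function(states) {
  if (!is.list(states) || length(states) < 2L)
    stop("need at least 2 states")
  vals <- lapply(states, function(s) {
    stopifnot(inherits(s, "age_prediction"))
    s$predictions$predicted_age
  })
  y <- unlist(vals)
  g <- rep(seq_along(vals), vapply(vals, length, integer(1)))
  kk <- length(vals)
  N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(split(y, g), function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(split(y, g), function(v) sum((v - mean(v))^2),
                    numeric(1)))
  df1 <- kk - 1L; df2 <- N - kk
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1; eta <- 0
  } else if (ssw == 0) {
    f <- Inf; p <- 0; eta <- 1
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    eta <- ssb / (ssb + ssw)
  }
  structure(list(test = "anova", statistic = f, p_value = p,
                 effect_size = eta, effect_type = "partial_eta_squared",
                 dof = c(df1, df2), n = N),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> %s: statistic = %.4g, p = %.4g, %s = %.4g\n",
              x$test, x$statistic, x$p_value, x$effect_type, x$effect_size))
  invisible(x)
}
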