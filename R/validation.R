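#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`; measures the
#' goodness of fit between actual and predicted PMI. Can be negative for
#' predictions worse than the mean.
#'
#' @param y Actual values, length >= 2, non-constant.
#' @param y_hat Predicted values, same length.
#' @return A single number.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R^2 undefined for a constant response", call. = FALSE)
  1 - sum((y - y_hat)^2) / sst
}

#' Root-mean-square error
#'
#' `sqrt(mean((y - y_hat)^2))`, in the units of the response (hours).
#'
#' @inheritParams r_squared
#' @return A single non-negative number.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (!length(y)) stop("need at least 1 observation", call. = FALSE)
  sqrt(mean((y - y_hat)^2))
}

#' Animal-wise k-fold split stratified by PMI group
#'
#' Partitions the calibration animals into k folds such that the animals of
#' each PMI group are spread across folds as evenly as possible (randomized
#' within group by `seed`). Under the reference design — 8 calibration
#' animals in each of 9 PMI groups, k = 8 — every fold receives exactly one
#' animal per group, i.e. 9 spectra covering all 9 PMI values. Keeping all
#' spectra of an animal in a single fold makes the cross-validation
#' animal-wise: a held-out animal never influences the model it is
#' predicted by.
#'
#' @param ds A [spectra_set]; rows with role `"calibration"` are used (all
#'   rows if no row carries that role).
#' @param k Number of folds, >= 2.
#' @param seed Optional integer seed for the within-group shuffle.
#' @param strict If `TRUE` (default), error when k exceeds the number of
#'   animals in some PMI group (a fold would miss that group).
#' @return Named integer vector mapping `animal_id` to fold in `1..k`, with
#'   attribute `"k"`.
#' @export
make_folds <- function(ds, k, seed = NULL, strict = TRUE) {
  validate_spectra_set(ds)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  idx <- if (any(ds$role == "calibration")) ds$role == "calibration"
         else rep(TRUE, length(ds$role))
  ids <- unique(ds$animal_id[idx])
  pmi_of <- ds$pmi_h[match(ids, ds$animal_id)]
  if (!is.null(seed)) set.seed(seed)
  assignment <- integer(length(ids))
  names(assignment) <- ids
  groups <- sort(unique(pmi_of))
  for (gi in seq_along(groups)) {
    members <- ids[pmi_of == groups[gi]]
    if (strict && length(members) < k)
      stop(sprintf(
        "PMI group %g h has %d animal(s) < k = %d folds (strict mode)",
        groups[gi], length(members), k), call. = FALSE)
    members <- sample(members)
    # rotate the starting fold per group so fold sizes stay balanced
    assignment[members] <-
      ((seq_along(members) - 1L + (gi - 1L)) %% k) + 1L
  }
  attr(assignment, "k") <- k
  assignment
}

# internal: fit a model described by a spec list on (X, y)
# spec: list(model = "pls", ncomp = 7) or
#       list(model = "svm", nu = , cost = , gamma = , pca_components = )
fit_model_spec <- function(spec, X, y) {
  if (is.null(spec$model) || !spec$model %in% c("pls", "svm"))
    stop("model_spec$model must be 'pls' or 'svm'", call. = FALSE)
  if (spec$model == "pls") {
    pls_fit(X, y, ncomp = if (is.null(spec$ncomp)) 7L else spec$ncomp)
  } else {
    svr_fit(X, y,
            nu = if (is.null(spec$nu)) 0.02 else spec$nu,
            cost = if (is.null(spec$cost)) 1 else spec$cost,
            gamma = spec$gamma,
            pca = spec$pca_components)
  }
}

#' Animal-wise k-fold cross-validation
#'
#' For each fold the model (and any PCA reduction inside it) is fitted on
#' the remaining k - 1 folds only and the held-out fold is predicted; R^2
#' and RMSECV are recorded per fold and summarized as mean and SD across
#' folds. Held-out rows never influence the fit.
#'
#' @param model_spec A list: `list(model = "pls", ncomp = 7)` or
#'   `list(model = "svm", nu = 0.02, cost = , gamma = ,
#'   pca_components = 8)`.
#' @param ds A [spectra_set] of (preprocessed) calibration spectra.
#' @param k Number of folds (default 8).
#' @param seed Optional seed for the fold split.
#' @param folds Optional precomputed [make_folds] assignment.
#' @return An object of class `"cv_result"`: `per_fold` (data.frame fold,
#'   r2, rmsecv), `summary` (means and SDs), `fold_assignment`,
#'   `model_spec`.
#' @export
cross_validate <- function(model_spec, ds, k = 8L, seed = NULL,
                           folds = NULL) {
  validate_spectra_set(ds)
  if (is.null(folds)) folds <- make_folds(ds, k, seed = seed)
  kk <- attr(folds, "k")
  fold_of_row <- unname(folds[ds$animal_id])
  use <- !is.na(fold_of_row)
  X <- ds$X[use, , drop = FALSE]
  y <- ds$pmi_h[use]
  fr <- fold_of_row[use]
  per <- lapply(sort(unique(fr)), function(f) {
    tr <- fr != f
    if (sum(!tr) < 2L)
      stop("a fold holds fewer than 2 samples; R^2 undefined", call. = FALSE)
    fit <- fit_model_spec(model_spec, X[tr, , drop = FALSE], y[tr])
    pred <- predict(fit, X[!tr, , drop = FALSE])
    data.frame(fold = f, r2 = r_squared(y[!tr], pred),
               rmsecv = rmse(y[!tr], pred))
  })
  per <- do.call(rbind, per)
  structure(
    list(per_fold = per,
         summary = list(r2_mean = mean(per$r2), r2_sd = stats::sd(per$r2),
                        rmsecv_mean = mean(per$rmsecv),
                        rmsecv_sd = stats::sd(per$rmsecv)),
         fold_assignment = folds, model_spec = model_spec, k = kk),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %d-fold cross-validation (%s model)\n",
              x$k, x$model_spec$model))
  cat(sprintf("  R^2    = %.4f +/- %.4f\n", s$r2_mean, s$r2_sd))
  cat(sprintf("  RMSECV = %.3f +/- %.3f h\n", s$rmsecv_mean, s$rmsecv_sd))
  invisible(x)
}

#' External validation of a fitted model
#'
#' Predicts an independent validation set and reports Q^2 (the
#' determination coefficient of those predictions) and RMSEP (the
#' root-mean-square error of prediction). The model must have been fitted
#' on calibration data only. With a single validation sample (or a
#' constant validation response) RMSEP is still defined but Q^2 is not; it
#' is returned as `NA` with a warning.
#'
#' @param model A fitted `"pmi_pls"` or `"pmi_svr"` model.
#' @param ds_val A non-empty [spectra_set] of validation spectra,
#'   preprocessed identically to the calibration set.
#' @return A list with `q2`, `rmsep`, `predicted`, `actual`.
#' @export
external_validate <- function(model, ds_val) {
  validate_spectra_set(ds_val)
  if (nrow(ds_val$X) == 0L) stop("validation set is empty", call. = FALSE)
  pred <- predict(model, ds_val$X)
  q2 <- tryCatch(r_squared(ds_val$pmi_h, pred), error = function(e) {
    warning("Q^2 undefined: ", conditionMessage(e), call. = FALSE)
    NA_real_
  })
  list(q2 = q2, rmsep = rmse(ds_val$pmi_h, pred),
       predicted = pred, actual = ds_val$pmi_h)
}

#' Compare two cross-validated models
#'
#' Two-sided unpaired (Welch) t-test on the per-fold R^2 and RMSECV of two
#' [cross_validate] results. When both sides have zero variance the t-test
#' degenerates: equal means give `t = 0, p = 1`; unequal means are treated
#' as the limit `|t| = Inf, p = 0`.
#'
#' @param cv_a,cv_b `"cv_result"` objects with equal fold counts.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return A data.frame with one row per metric: means, difference,
#'   t-statistic, p-value, significance flag.
#' @export
compare_models <- function(cv_a, cv_b, alpha = 0.05) {
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  if (nrow(cv_a$per_fold) != nrow(cv_b$per_fold))
    stop("fold counts differ", call. = FALSE)
  if (nrow(cv_a$per_fold) < 2L)
    stop("need at least 2 folds", call. = FALSE)
  one <- function(metric) {
    a <- cv_a$per_fold[[metric]]; b <- cv_b$per_fold[[metric]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(metric = metric, mean_a = mean(a), mean_b = mean(b),
               diff = mean(a) - mean(b), t = t, p = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  }
  rbind(one("r2"), one("rmsecv"))
}

# internal: pooled cross-validated Q^2 (predictions of every held-out fold
# pooled, then one determination coefficient)
cv_pooled_q2 <- function(spec, X, y, fold_of_row) {
  pred <- numeric(length(y))
  for (f in sort(unique(fold_of_row))) {
    tr <- fold_of_row != f
    fit <- fit_model_spec(spec, X[tr, , drop = FALSE], y[tr])
    pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  r_squared(y, pred)
}

#' Response-permutation test with the intercept criterion
#'
#' Diagnoses overfitting by refitting the model under randomly permuted
#' responses, keeping hyperparameters (latent-factor count, nu, cost,
#' gamma) frozen at their original values. For each permutation the
#' training R^2 and a cross-validated Q^2 (pooled held-out predictions over
#' the same animal-wise folds; optionally the external validation set) are
#' recorded together with the absolute correlation between permuted and
#' original responses. Straight lines of R^2 and Q^2 versus correlation are
#' fitted through the permuted points plus the unpermuted point at
#' correlation 1; a Q^2 intercept at or below zero (and an R^2 intercept
#' well below the original R^2) indicates a model whose apparent fit is not
#' an artifact of chance correlation.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (default 50).
#' @param q2_method `"cv"` (default) or `"external"`.
#' @param ds_val Validation [spectra_set], required for
#'   `q2_method = "external"`.
#' @return An object of class `"permutation_result"`: `permutations`
#'   (data.frame correlation, r2, q2), `original` (r2, q2 at correlation
#'   1), `intercepts` (named vector r2, q2), `n_perm`.
#' @export
permutation_test <- function(model_spec, ds, n_perm = 50L, k = 8L,
                             seed = NULL, q2_method = c("cv", "external"),
                             ds_val = NULL) {
  q2_method <- match.arg(q2_method)
  if (n_perm < 2L) stop("n_perm must be >= 2", call. = FALSE)
  if (q2_method == "external" && is.null(ds_val))
    stop("ds_val required for q2_method = 'external'", call. = FALSE)
  validate_spectra_set(ds)
  if (!is.null(seed)) set.seed(seed)
  folds <- make_folds(ds, k)
  fold_of_row <- unname(folds[ds$animal_id])
  use <- !is.na(fold_of_row)
  X <- ds$X[use, , drop = FALSE]
  y <- ds$pmi_h[use]
  fr <- fold_of_row[use]
  eval_once <- function(y_cur) {
    fit <- fit_model_spec(model_spec, X, y_cur)
    r2 <- r_squared(y_cur, predict(fit, X))
    q2 <- if (q2_method == "cv") {
      cv_pooled_q2(model_spec, X, y_cur, fr)
    } else {
      pred <- predict(fit, ds_val$X)
      r_squared(ds_val$pmi_h, pred)
    }
    c(r2 = r2, q2 = q2)
  }
  orig <- eval_once(y)
  perms <- t(vapply(seq_len(n_perm), function(i) {
    y_p <- sample(y)
    c(correlation = abs(stats::cor(y_p, y)), eval_once(y_p))
  }, numeric(3)))
  perms <- as.data.frame(perms)
  pts_r2 <- data.frame(x = c(perms$correlation, 1), y = c(perms$r2, orig["r2"]))
  pts_q2 <- data.frame(x = c(perms$correlation, 1), y = c(perms$q2, orig["q2"]))
  co_r2 <- unname(stats::coef(stats::lm(y ~ x, data = pts_r2)))
  co_q2 <- unname(stats::coef(stats::lm(y ~ x, data = pts_q2)))
  structure(
    list(permutations = perms,
         original = c(r2 = unname(orig["r2"]), q2 = unname(orig["q2"])),
         intercepts = c(r2 = co_r2[1], q2 = co_q2[1]),
         slopes = c(r2 = co_r2[2], q2 = co_q2[2]),
         n_perm = as.integer(n_perm),
         model_spec = model_spec, q2_method = q2_method),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations (%s model, Q^2 by %s)\n",
              x$n_perm, x$model_spec$model, x$q2_method))
  cat(sprintf("  original R^2 = %.4f, Q^2 = %.4f\n",
              x$original["r2"], x$original["q2"]))
  cat(sprintf("  intercepts:  R^2 = %.3f, Q^2 = %.3f\n",
              x$intercepts["r2"], x$intercepts["q2"]))
  invisible(x)
}

#' Permutation-test validation plot
#'
#' R^2 and Q^2 of permuted models against the absolute correlation of the
#' permuted response with the original one, with the fitted intercept
#' lines and the original model at correlation 1.
#'
#' @param x A `"permutation_result"`.
#' @param ... Unused.
#' @export
plot.permutation_result <- function(x, ...) {
  pm <- x$permutations
  ylim <- range(pm$r2, pm$q2, x$original, 0)
  graphics::plot(pm$correlation, pm$r2, pch = 1, xlim = c(0, 1), ylim = ylim,
                 xlab = "|correlation with original response|",
                 ylab = expression(R^2 ~ "/" ~ Q^2))
  graphics::points(pm$correlation, pm$q2, pch = 2)
  graphics::points(c(1, 1), x$original, pch = c(16, 17))
  graphics::abline(x$intercepts["r2"], x$slopes["r2"], lty = 1)
  graphics::abline(x$intercepts["q2"], x$slopes["q2"], lty = 2)
  graphics::legend("bottomright", pch = c(16, 17),
                   legend = c(expression(R^2), expression(Q^2)), bty = "n")
  invisible(x)
}
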