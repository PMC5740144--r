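#' nu-support-vector regression with RBF kernel
#'
#' Fits nu-SVR (libsvm via \pkg{e1071}) with the radial-basis-function
#' kernel `K(x, z) = exp(-gamma * ||x - z||^2)`. The parameter `nu` bounds
#' the fraction of margin errors from above and the fraction of support
#' vectors from below; only support vectors contribute to predictions. An
#' optional PCA reducer compresses the predictors first — it is fitted on
#' the training rows only and reused, unchanged, for prediction, so no
#' validation information leaks into the model.
#'
#' @param X Numeric `n x p` training matrix.
#' @param y Numeric response of length n (PMI in hours).
#' @param nu Fraction in (0, 1]; default 0.02.
#' @param cost,gamma Positive kernel/penalty parameters.
#' @param pca `NULL` (no reduction), an integer number of components, or a
#'   pre-fitted [pca_fit] reducer.
#' @param ... Further arguments passed to [e1071::svm] (e.g. `tolerance`).
#' @return An object of class `"pmi_svr"` with the libsvm fit, the reducer
#'   (or NULL), support-vector indices, dual coefficients and bias.
#' @note The libsvm convention is used: `cost` is the per-sample penalty
#'   bound, so `|dual_coefs| <= cost`, and duplicating every training point
#'   is equivalent to doubling `cost` rather than a no-op.
#' @export
svr_fit <- function(X, y, nu = 0.02, cost = 1,
                    gamma = NULL, pca = NULL, ...) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!(nu > 0 && nu <= 1)) stop("nu must lie in (0, 1]", call. = FALSE)
  if (cost <= 0) stop("cost must be > 0", call. = FALSE)
  reducer <- NULL
  if (!is.null(pca)) {
    reducer <- if (inherits(pca, "pca_reducer")) pca else pca_fit(X, pca)
    Z <- predict(reducer, X)
  } else {
    Z <- X
  }
  if (is.null(gamma)) gamma <- 1 / ncol(Z)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  fit <- e1071::svm(Z, y, type = "nu-regression", kernel = "radial",
                    nu = nu, cost = cost, gamma = gamma, scale = FALSE, ...)
  structure(
    list(fit = fit, reducer = reducer, nu = nu, cost = cost, gamma = gamma,
         sv_index = fit$index, dual_coefs = drop(fit$coefs),
         bias = -fit$rho, n_train = nrow(Z), y = y,
         fitted.values = unname(drop(stats::predict(fit, Z)))),
    class = "pmi_svr")
}

#' Predict from a fitted nu-SVR model
#'
#' @param object A `"pmi_svr"` model.
#' @param newdata Numeric matrix (or single-sample vector) in the original
#'   (pre-PCA) predictor space. Omitted: returns fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (hours).
#' @export
predict.pmi_svr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  Z <- if (!is.null(object$reducer)) predict(object$reducer, newdata)
       else newdata
  unname(drop(stats::predict(object$fit, Z)))
}

#' @export
print.pmi_svr <- function(x, ...) {
  cat(sprintf(
    "<pmi_svr> nu-SVR (RBF), nu = %g, cost = %g, gamma = %g\n",
    x$nu, x$cost, x$gamma))
  cat(sprintf("  %d support vectors out of %d training samples (%.1f%%)\n",
              length(x$sv_index), x$n_train,
              100 * length(x$sv_index) / x$n_train))
  if (!is.null(x$reducer))
    cat(sprintf("  inputs reduced to %d principal components\n",
                x$reducer$k))
  invisible(x)
}

#' @export
residuals.pmi_svr <- function(object, ...) object$y - object$fitted.values

#' @export
fitted.pmi_svr <- function(object, ...) object$fitted.values

#' Grid search for nu-SVR cost and gamma
#'
#' Exhaustive evaluation of cross-validated RMSE over a 2D `(cost, gamma)`
#' grid, returning the minimizing cell and the full error surface. Ties are
#' broken toward smaller cost, then smaller gamma. The optional PCA
#' reduction is refitted inside every training fold so the surface is free
#' of validation leakage; because the reduction does not depend on `(cost,
#' gamma)`, it is computed once per fold rather than once per cell.
#'
#' @param X,y Training data as in [svr_fit].
#' @param nu nu-SVR parameter (default 0.02).
#' @param cost_grid,gamma_grid Positive candidate values; defaults are the
#'   standard log2 lattices `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`.
#' @param folds Number of CV folds (default 8) when `fold_id` is not given.
#' @param seed Optional integer seed for the random fold split.
#' @param fold_id Optional integer vector assigning each row to a fold
#'   (e.g. an animal-wise split); overrides `folds`/`seed`.
#' @param pca `NULL` or an integer number of PCA components.
#' @return A list with `cost`, `gamma` (the argmin), `cv_rmse` (its error)
#'   and `surface` (a data.frame of cost, gamma, cv_rmse for every cell).
#' @export
svr_grid_search <- function(X, y, nu = 0.02,
                            cost_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            folds = 8L, seed = NULL, fold_id = NULL,
                            pca = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!length(cost_grid) || !length(gamma_grid))
    stop("cost_grid and gamma_grid must be non-empty", call. = FALSE)
  n <- nrow(X)
  if (is.null(fold_id)) {
    if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    fold_id <- sample(rep_len(seq_len(folds), n))
  }
  stopifnot(length(fold_id) == n)
  fold_levels <- sort(unique(fold_id))
  # per-fold projections, shared by all grid cells
  splits <- lapply(fold_levels, function(f) {
    tr <- fold_id != f
    if (!is.null(pca)) {
      red <- pca_fit(X[tr, , drop = FALSE], pca)
      list(Ztr = predict(red, X[tr, , drop = FALSE]),
           Zte = predict(red, X[!tr, , drop = FALSE]),
           ytr = y[tr], yte = y[!tr])
    } else {
      list(Ztr = X[tr, , drop = FALSE], Zte = X[!tr, , drop = FALSE],
           ytr = y[tr], yte = y[!tr])
    }
  })
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    err2 <- 0
    for (s in splits) {
      fit <- tryCatch(
        e1071::svm(s$Ztr, s$ytr, type = "nu-regression", kernel = "radial",
                   nu = nu, cost = grid$cost[i], gamma = grid$gamma[i],
                   scale = FALSE),
        error = function(e) stop(sprintf(
          "svm fit failed at cost = %g, gamma = %g: %s",
          grid$cost[i], grid$gamma[i], conditionMessage(e)), call. = FALSE))
      err2 <- err2 + sum((s$yte - stats::predict(fit, s$Zte))^2)
    }
    sqrt(err2 / n)
  }, numeric(1))
  ord <- order(grid$cv_rmse, grid$cost, grid$gamma)
  best <- grid[ord[1], ]
  list(cost = best$cost, gamma = best$gamma, cv_rmse = best$cv_rmse,
       surface = grid)
}
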