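#' Partial least squares regression (NIPALS)
#'
#' Fits a univariate-response PLS regression by sequential NIPALS
#' extraction: latent factors are chosen to covary maximally with the
#' response, making the method suitable for wide spectral matrices where
#' predictors hugely outnumber samples. X is deflated after each factor; the
#' response loading is recomputed per factor. Weight vectors are unit-norm
#' with the sign fixed so their first non-negligible element is positive,
#' which makes the fit fully deterministic.
#'
#' With `ncomp` equal to the rank of the centered predictor matrix the PLS
#' fit reproduces the ordinary least-squares solution. If the data's rank is
#' exhausted before `ncomp` factors, extraction stops with a warning and the
#' model is truncated.
#'
#' @param X Numeric `n x p` predictor matrix (spectra as rows).
#' @param y Numeric response of length n (PMI in hours); must not be
#'   constant.
#' @param ncomp Number of latent factors, `<= min(n - 1, p)`.
#' @return An object of class `"pmi_pls"` with weights `W` (`p x ncomp`),
#'   X-loadings `P`, response loadings `q`, scores `T`, centering vectors,
#'   the regression coefficient vector, and fitted values.
#' @seealso [vip_scores], [predict.pmi_pls]
#' @export
pls_fit <- function(X, y, ncomp = 7L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (stats::var(y) == 0) stop("response y has zero variance", call. = FALSE)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop(sprintf("ncomp must lie in [1, min(n - 1, p)] = [1, %d]",
                 min(n - 1L, p)), call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  scale0 <- sqrt(sum(E^2)) * sqrt(sum(yc^2))
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  A <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(scale0, 1)) break
    w <- w / nw
    j <- which(abs(w) > 1e-12)[1]
    if (!is.na(j) && w[j] < 0) w <- -w
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt <= 1e-24 * max(scale0, 1)) break
    P[, a] <- crossprod(E, t_a) / tt
    q[a] <- sum(yc * t_a) / tt
    W[, a] <- w; Tm[, a] <- t_a
    E <- E - tcrossprod(t_a, P[, a])
    A <- a
  }
  if (A < ncomp) {
    warning(sprintf(
      "rank exhausted after %d factor(s); model truncated from %d", A, ncomp))
    W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
    Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  }
  if (A == 0L) stop("no PLS factor could be extracted", call. = FALSE)
  # regression vector in original X coordinates
  R <- W %*% solve(crossprod(P, W))
  coefs <- drop(R %*% q)
  fitted <- drop(sweep(X, 2, x_mean) %*% coefs) + y_mean
  structure(
    list(n_factors = A, x_mean = x_mean, y_mean = y_mean,
         W = W, P = P, q = q, scores = Tm,
         coefficients = coefs, fitted.values = fitted,
         residuals = y - fitted, y = y,
         axis = colnames(X)),
    class = "pmi_pls")
}

#' Predict from a fitted PLS model
#'
#' @param object A `"pmi_pls"` model.
#' @param newdata Numeric matrix (or single-sample vector) with the training
#'   number of columns. Omitted: returns fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (hours).
#' @export
predict.pmi_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata column count does not match the training data",
         call. = FALSE)
  unname(drop(sweep(newdata, 2, object$x_mean) %*% object$coefficients) +
           object$y_mean)
}

#' @export
coef.pmi_pls <- function(object, ...) {
  c(`(Intercept)` = object$y_mean -
      sum(object$x_mean * object$coefficients),
    object$coefficients)
}

#' @export
residuals.pmi_pls <- function(object, ...) object$residuals

#' @export
fitted.pmi_pls <- function(object, ...) object$fitted.values

#' @export
print.pmi_pls <- function(x, ...) {
  cat(sprintf("<pmi_pls> PLS regression, %d latent factor(s), %d predictors\n",
              x$n_factors, nrow(x$W)))
  cat(sprintf("  training R^2 = %.4f, RMSE = %.3f h\n",
              r_squared(x$y, x$fitted.values), rmse(x$y, x$fitted.values)))
  invisible(x)
}

#' @export
summary.pmi_pls <- function(object, ...) {
  ss <- object$q^2 * colSums(object$scores^2)
  out <- list(
    n_factors = object$n_factors,
    r2_train = r_squared(object$y, object$fitted.values),
    rmse_train = rmse(object$y, object$fitted.values),
    y_variance_share = ss / sum((object$y - object$y_mean)^2))
  class(out) <- "summary.pmi_pls"
  out
}

#' @export
print.summary.pmi_pls <- function(x, ...) {
  cat(sprintf("PLS regression with %d latent factor(s)\n", x$n_factors))
  cat(sprintf("  training R^2 = %.4f, RMSE = %.3f h\n", x$r2_train,
              x$rmse_train))
  cat("  response variance captured per factor:\n")
  print(round(x$y_variance_share, 4))
  invisible(x)
}

#' Actual-versus-predicted plot for a PLS model
#'
#' @param x A `"pmi_pls"` model.
#' @param ... Passed to [graphics::plot].
#' @export
plot.pmi_pls <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values, xlab = "actual PMI (h)",
                 ylab = "predicted PMI (h)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' The VIP score of predictor j is the weighted contribution of its PLS
#' weights across factors, with each factor weighted by the response
#' variance it explains (`SS_a = q_a^2 * t_a' t_a`):
#' `VIP_j = sqrt(p * sum_a SS_a * w_ja^2 / sum_a SS_a)` (weights unit-norm).
#' The scores satisfy `sum(VIP^2) == p`, so a variable with VIP above 1
#' contributes more than an average variable.
#'
#' @param model A fitted `"pmi_pls"` model.
#' @return Numeric vector of length p.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pmi_pls"))
  ss <- model$q^2 * colSums(model$scores^2)
  p <- nrow(model$W)
  sqrt(p * drop(model$W^2 %*% ss) / sum(ss))
}

#' Influential variables by the VIP > threshold rule
#'
#' @param vip Numeric VIP vector (see [vip_scores]).
#' @param axis Wavenumber axis matching `vip`.
#' @param threshold Strict lower cut-off (default 1.0, the conventional
#'   influential-variable rule).
#' @return A data.frame with columns `wavenumber` and `vip`, sorted by VIP
#'   descending.
#' @export
influential_variables <- function(vip, axis, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  stopifnot(length(vip) == length(axis))
  keep <- which(vip > threshold)
  keep <- keep[order(vip[keep], decreasing = TRUE)]
  data.frame(wavenumber = axis[keep], vip = vip[keep])
}
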