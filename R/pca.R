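#' Fit a PCA dimension reducer
#'
#' Mean-centered principal component analysis used to compress preprocessed
#' spectra ahead of support-vector regression. The reducer stores the
#' training mean and loadings so new samples are always projected with
#' training-set statistics only.
#'
#' @param X Numeric `n x p` matrix.
#' @param k Number of components, `k <= min(n - 1, p)`.
#' @return An object of class `"pca_reducer"` with elements `mean`,
#'   `loadings` (`p x k`, orthonormal columns), `explained_variance_ratio`
#'   (share of total training variance per component, non-increasing) and
#'   `k`.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1L || k > min(nrow(X) - 1L, ncol(X)))
    stop(sprintf("k must lie in [1, min(n - 1, p)] = [1, %d]",
                 min(nrow(X) - 1L, ncol(X))), call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(mean = pc$center,
         loadings = pc$rotation[, seq_len(k), drop = FALSE],
         explained_variance_ratio = evr[seq_len(k)],
         k = k),
    class = "pca_reducer")
}

#' Project samples onto fitted principal axes
#'
#' @param object A `"pca_reducer"`.
#' @param newdata Numeric matrix (or vector for a single sample) with the
#'   training number of columns.
#' @param ... Unused.
#' @return An `n x k` score matrix.
#' @export
predict.pca_reducer <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean))
    stop("newdata column count does not match the training data",
         call. = FALSE)
  sweep(newdata, 2, object$mean) %*% object$loadings
}

#' @export
print.pca_reducer <- function(x, ...) {
  cat(sprintf("<pca_reducer> %d components, %.1f%% variance explained\n",
              x$k, 100 * sum(x$explained_variance_ratio)))
  invisible(x)
}
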