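#' Preprocessing configuration
#'
#' Collects the spectral preprocessing choices applied ahead of chemometric
#' modelling: the wavenumber window, the Savitzky-Golay smoothing window and
#' polynomial order for the second derivative, and the ordered list of steps.
#'
#' @param window_lo,window_hi Wavenumber window in cm^-1 (defaults 900, 1800).
#' @param sg_window Savitzky-Golay window length in points; odd,
#'   greater than `sg_polyorder` (default 25).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3, a common
#'   chemometric choice for second derivatives).
#' @param steps Character vector, ordered subset of
#'   `c("snv", "second_derivative")`; applied in the given order.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(window_lo = 900, window_hi = 1800,
                              sg_window = 25L, sg_polyorder = 3L,
                              steps = c("snv", "second_derivative")) {
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (window_lo >= window_hi) stop("window_lo must be < window_hi")
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (sg_window <= sg_polyorder) stop("sg_window must exceed sg_polyorder")
  bad <- setdiff(steps, c("snv", "second_derivative"))
  if (length(bad))
    stop("unknown preprocessing step(s): ", paste(bad, collapse = ", "))
  structure(list(window_lo = window_lo, window_hi = window_hi,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 steps = as.character(steps)),
            class = "preprocess_config")
}

#' Standard normal variate (SNV) normalization
#'
#' Centers and scales a single spectrum to mean 0 and sample standard
#' deviation 1 (denominator n - 1) across wavenumbers. SNV removes additive
#' offsets and multiplicative scatter: `snv(a * x + b) == snv(x)` for `a > 0`.
#'
#' @param x Numeric vector of absorbance values, length >= 2.
#' @return Normalized vector of the same length.
#' @export
snv <- function(x) {
  if (length(x) < 2L) stop("snv needs at least 2 points", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("snv undefined for a flat (zero-variance) spectrum", call. = FALSE)
  (x - mean(x)) / s
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Local least-squares polynomial differentiation with the given window and
#' polynomial order, scaled by the axis step so the output is in absorbance
#' units per cm^-2. The output has the same length as the input: at the
#' edges the fitted polynomial is re-evaluated off-center rather than the
#' series truncated, keeping the axis aligned across samples. Exact for
#' polynomial inputs up to the configured order: a quadratic
#' `a*nu^2 + b*nu + c` yields the constant `2a`.
#'
#' The axis must be uniformly spaced (relative tolerance 1e-6); resample
#' non-uniform data onto a regular grid first (see [read_spectra]).
#'
#' @param x Numeric absorbance vector, length >= `sg_window`.
#' @param axis Wavenumber vector in cm^-1, same length, uniformly spaced
#'   (ascending or descending).
#' @param sg_window,sg_polyorder See [preprocess_config].
#' @return Numeric vector of second-derivative values, same length as `x`.
#' @export
sg_second_derivative <- function(x, axis, sg_window = 25L, sg_polyorder = 3L) {
  sg_window <- as.integer(sg_window)
  if (length(x) != length(axis))
    stop("x and axis lengths differ", call. = FALSE)
  if (length(x) < sg_window)
    stop("spectrum shorter than the Savitzky-Golay window", call. = FALSE)
  h <- diff(axis)
  if (max(abs(h - mean(h))) > 1e-6 * abs(mean(h)))
    stop("axis is not uniformly spaced; interpolate onto a regular grid first",
         call. = FALSE)
  signal::sgolayfilt(x, p = sg_polyorder, n = sg_window, m = 2,
                     ts = abs(mean(h)))
}

#' Apply a preprocessing chain to a spectral dataset
#'
#' Restricts the dataset to the configured wavenumber window, then applies
#' the configured steps row-wise in order. The applied steps are recorded in
#' the `"steps"` attribute of the result so an analysis can always be traced
#' back to its preprocessing.
#'
#' @param ds A [spectra_set].
#' @param config A [preprocess_config].
#' @return A preprocessed [spectra_set].
#' @export
preprocess_spectra <- function(ds, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- restrict_window(ds, config$window_lo, config$window_hi)
  prov <- c(attr(ds, "steps"),
            sprintf("window[%g,%g]", config$window_lo, config$window_hi))
  for (step in config$steps) {
    out$X <- t(vapply(seq_len(nrow(out$X)), function(i) {
      tryCatch(
        switch(step,
          snv = snv(out$X[i, ]),
          second_derivative = sg_second_derivative(
            out$X[i, ], out$axis, config$sg_window, config$sg_polyorder)),
        error = function(e) {
          stop(sprintf("step '%s' failed on sample '%s': %s",
                       step, out$animal_id[i], conditionMessage(e)),
               call. = FALSE)
        })
    }, numeric(length(out$axis))))
    prov <- c(prov,
              if (step == "second_derivative")
                sprintf("second_derivative[n=%d,p=%d]",
                        config$sg_window, config$sg_polyorder)
              else step)
  }
  attr(out, "steps") <- prov
  out
}
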