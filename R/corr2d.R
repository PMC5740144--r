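#' Hilbert-Noda transformation matrix
#'
#' The discrete Hilbert transform used to construct the asynchronous
#' correlation map from perturbation-ordered spectra: `N[j, k] = 0` for
#' `j == k` and `1 / (pi * (k - j))` otherwise. The matrix is antisymmetric.
#'
#' @param m Number of perturbation points (here, PMI groups), >= 2.
#' @return An `m x m` numeric matrix.
#' @export
hilbert_noda_matrix <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("m must be an integer >= 2", call. = FALSE)
  d <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  N <- ifelse(d == 0L, 0, 1 / (pi * d))
  N
}

#' Dynamic spectra relative to a reference
#'
#' Subtracts a reference spectrum from each perturbation-ordered spectrum.
#' The default reference is the mean over the m group spectra, in which case
#' every column of the dynamic matrix sums to zero.
#'
#' @param x A [spectra_set] of group-average spectra ordered by ascending
#'   PMI, or an `m x p` numeric matrix (rows already in perturbation order).
#' @param reference `"mean"` (default) or a numeric vector of length p.
#' @return An `m x p` matrix of dynamic spectra with the reference attached
#'   as attribute `"reference"`.
#' @export
dynamic_spectra <- function(x, reference = "mean") {
  if (inherits(x, "spectra_set")) {
    if (is.unsorted(x$pmi_h, strictly = TRUE))
      stop("group spectra must be ordered by strictly ascending PMI",
           call. = FALSE)
    Y <- x$X
  } else {
    Y <- as.matrix(x)
  }
  if (nrow(Y) < 2L) stop("need at least 2 perturbation points", call. = FALSE)
  ref <- if (identical(reference, "mean")) colMeans(Y) else {
    reference <- as.numeric(reference)
    if (length(reference) != ncol(Y))
      stop("reference length must match the number of wavenumbers",
           call. = FALSE)
    reference
  }
  dyn <- sweep(Y, 2, ref)
  attr(dyn, "reference") <- ref
  dyn
}

#' Synchronous 2D correlation map
#'
#' `Phi = t(dyn) %*% dyn / (m - 1)`: the in-phase covariance of intensity
#' variations at every wavenumber pair. Symmetric with a non-negative
#' diagonal of auto-peaks.
#'
#' @param dyn `m x p` dynamic spectra matrix (see [dynamic_spectra]).
#' @return A `p x p` matrix.
#' @export
synchronous_2d <- function(dyn) {
  dyn <- as.matrix(dyn)
  if (nrow(dyn) < 2L) stop("need at least 2 perturbation points", call. = FALSE)
  crossprod(dyn) / (nrow(dyn) - 1)
}

#' Asynchronous 2D correlation map
#'
#' `Psi = t(dyn) %*% N %*% dyn / (m - 1)` with `N` the Hilbert-Noda matrix:
#' the out-of-phase component that reveals the sequential order of spectral
#' events. Antisymmetric with a zero diagonal.
#'
#' @inheritParams synchronous_2d
#' @return A `p x p` matrix.
#' @export
asynchronous_2d <- function(dyn) {
  dyn <- as.matrix(dyn)
  m <- nrow(dyn)
  if (m < 2L) stop("need at least 2 perturbation points", call. = FALSE)
  crossprod(dyn, hilbert_noda_matrix(m) %*% dyn) / (m - 1)
}

#' Generalized 2D correlation analysis
#'
#' Computes the synchronous and asynchronous correlation maps from
#' PMI-ordered group-average spectra. The perturbation here is postmortem
#' time: cross-peak sign patterns of the two maps, read under Noda's rules
#' (see [call_cross_peaks]), give the sequential order of the underlying
#' kinetic changes.
#'
#' @param ds A [spectra_set] of group-average spectra (one row per PMI
#'   group); rows are sorted by ascending PMI internally.
#' @param reference `"mean"` (default) or a numeric reference spectrum.
#' @return An object of class `"corr2d"` with elements `axis`, `phi`, `psi`,
#'   `reference`, `m`, and `pmi_h`.
#' @export
corr2d <- function(ds, reference = "mean") {
  stopifnot(inherits(ds, "spectra_set"))
  ord <- order(ds$pmi_h)
  ds <- subset_samples(ds, ord)
  dyn <- dynamic_spectra(ds, reference)
  structure(
    list(axis = ds$axis,
         phi = synchronous_2d(dyn),
         psi = asynchronous_2d(dyn),
         reference = attr(dyn, "reference"),
         m = nrow(ds$X), pmi_h = ds$pmi_h),
    class = "corr2d")
}

#' @export
print.corr2d <- function(x, ...) {
  cat(sprintf("<corr2d> %d x %d maps over %d perturbation points\n",
              nrow(x$phi), ncol(x$phi), x$m))
  ap <- autopeak_ranking(x, top_k = 3)
  if (nrow(ap))
    cat("  strongest auto-peaks (cm-1):",
        paste(sprintf("%g", ap$wavenumber), collapse = ", "), "\n")
  invisible(x)
}

#' Plot 2D correlation maps
#'
#' Filled contour images of the synchronous and/or asynchronous maps.
#'
#' @param x A `"corr2d"` object.
#' @param which `"phi"`, `"psi"`, or `"both"` (default).
#' @param ... Unused.
#' @export
plot.corr2d <- function(x, which = c("both", "phi", "psi"), ...) {
  which <- match.arg(which)
  maps <- switch(which, both = c("phi", "psi"), phi = "phi", psi = "psi")
  if (length(maps) == 2L) {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  }
  # orient axes so wavenumber decreases left-to-right, as in spectroscopy
  o <- order(x$axis)
  for (mp in maps) {
    M <- x[[mp]][o, o]
    graphics::image(x$axis[o], x$axis[o], M,
                    col = grDevices::hcl.colors(51, "RdBu", rev = TRUE),
                    xlim = rev(range(x$axis)), ylim = rev(range(x$axis)),
                    xlab = expression(nu[1] ~ (cm^-1)),
                    ylab = expression(nu[2] ~ (cm^-1)),
                    main = if (mp == "phi") "synchronous" else "asynchronous")
    graphics::contour(x$axis[o], x$axis[o], M, add = TRUE,
                      drawlabels = FALSE, nlevels = 8)
  }
  invisible(x)
}

#' Sequential-order verdict from cross-peak signs
#'
#' Encodes Noda's rules as used for time-ordered perturbations: with signs
#' `"+"`, `"-"` or `"n"` (no peak) for the synchronous (`phi_sign`) and
#' asynchronous (`psi_sign`) cross-peak at `(nu1, nu2)`,
#' * `phi == "n"` gives `"no_correlation"`;
#' * `psi == "n"` (with a synchronous peak) gives `"simultaneous"`;
#' * equal non-`"n"` signs mean the change at `nu1` occurs `"before"` that
#'   at `nu2`;
#' * opposite signs mean `"after"`.
#'
#' @param phi_sign,psi_sign Character vectors over `c("+", "-", "n")`.
#' @return Character vector of verdicts.
#' @export
noda_verdict <- function(phi_sign, psi_sign) {
  stopifnot(length(phi_sign) == length(psi_sign),
            all(phi_sign %in% c("+", "-", "n")),
            all(psi_sign %in% c("+", "-", "n")))
  mapply(function(a, b) {
    if (a == "n") "no_correlation"
    else if (b == "n") "simultaneous"
    else if (a == b) "before"
    else "after"
  }, phi_sign, psi_sign, USE.NAMES = FALSE)
}

#' Call cross-peaks and their sequential order
#'
#' Looks up each requested `(nu1, nu2)` band pair on the map axis (nearest
#' grid point within `tol_cm`), reads the synchronous and asynchronous
#' cross-peak signs, and applies [noda_verdict]. A sign is reported as `"n"`
#' when the cross-peak magnitude is below `epsilon` times the map's maximum
#' absolute value.
#'
#' @param obj A `"corr2d"` object.
#' @param band_pairs A two-column matrix/data.frame of `(nu1, nu2)` values in
#'   cm^-1, or a list of length-2 vectors.
#' @param epsilon Relative no-peak threshold in (0, 1); default 0.01.
#' @param tol_cm Maximum distance to the nearest grid point (default 4 cm^-1,
#'   a typical instrument resolution).
#' @return A data.frame with columns `nu1`, `nu2`, `phi_sign`, `psi_sign`,
#'   `verdict` and human-readable `order` (e.g. `"1517 > 1581"` when the
#'   change at 1517 precedes that at 1581).
#' @export
call_cross_peaks <- function(obj, band_pairs, epsilon = 0.01, tol_cm = 4) {
  stopifnot(inherits(obj, "corr2d"))
  if (!(epsilon > 0 && epsilon < 1))
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  if (is.list(band_pairs) && !is.data.frame(band_pairs))
    band_pairs <- do.call(rbind, band_pairs)
  band_pairs <- as.matrix(band_pairs)
  if (ncol(band_pairs) != 2L) stop("band_pairs must have two columns")
  lookup <- function(nu) {
    i <- which.min(abs(obj$axis - nu))
    if (abs(obj$axis[i] - nu) > tol_cm)
      stop(sprintf("band %g cm-1 is more than %g cm-1 from the axis",
                   nu, tol_cm), call. = FALSE)
    i
  }
  thr_phi <- epsilon * max(abs(obj$phi))
  thr_psi <- epsilon * max(abs(obj$psi))
  sign_of <- function(v, thr) if (abs(v) < thr) "n" else if (v > 0) "+" else "-"
  out <- lapply(seq_len(nrow(band_pairs)), function(r) {
    i1 <- lookup(band_pairs[r, 1]); i2 <- lookup(band_pairs[r, 2])
    ps <- sign_of(obj$phi[i1, i2], thr_phi)
    as_ <- sign_of(obj$psi[i1, i2], thr_psi)
    v <- noda_verdict(ps, as_)
    data.frame(nu1 = band_pairs[r, 1], nu2 = band_pairs[r, 2],
               phi_sign = ps, psi_sign = as_, verdict = v,
               order = switch(v,
                 before = sprintf("%g > %g", band_pairs[r, 1], band_pairs[r, 2]),
                 after = sprintf("%g < %g", band_pairs[r, 1], band_pairs[r, 2]),
                 simultaneous = sprintf("%g = %g",
                                        band_pairs[r, 1], band_pairs[r, 2]),
                 no_correlation = "no correlation"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank auto-peaks of the synchronous map
#'
#' Finds strict local maxima of the synchronous diagonal (the
#' autocorrelation of intensity variation at each wavenumber) and ranks them
#' by intensity, descending. The strongest auto-peaks mark the spectral
#' variables most susceptible to the perturbation.
#'
#' @param obj A `"corr2d"` object, or a `p x p` synchronous matrix (then
#'   supply `axis`).
#' @param top_k Maximum number of peaks to return (default all).
#' @param axis Wavenumber axis when `obj` is a plain matrix.
#' @return A data.frame with columns `wavenumber` and `intensity`.
#' @export
autopeak_ranking <- function(obj, top_k = Inf, axis = NULL) {
  if (inherits(obj, "corr2d")) {
    d <- diag(obj$phi); axis <- obj$axis
  } else {
    d <- diag(as.matrix(obj))
    if (is.null(axis)) stop("axis required when obj is a matrix")
  }
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  # plateau-aware local maxima: a maximal run of equal values is a peak
  # when it is strictly higher than both flanking values and does not
  # touch the boundary (so a flat diagonal has no peaks); when a band
  # center falls midway between grid points the two tied samples form a
  # run, represented by its middle index
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  idx <- integer(0)
  if (nr >= 3L) {
    for (j in 2:(nr - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        idx <- c(idx, starts[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  idx <- idx[order(d[idx], decreasing = TRUE)]
  idx <- utils::head(idx, top_k)
  data.frame(wavenumber = axis[idx], intensity = d[idx])
}
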