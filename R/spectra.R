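#' Construct a spectral dataset
#'
#' Bundles a sample-by-wavenumber absorbance matrix with its shared wavenumber
#' axis and per-sample metadata: animal identifier, postmortem interval (PMI)
#' in hours, replicate index, and the sample's role in the study
#' (typically `"calibration"` or `"validation"`).
#'
#' The wavenumber axis must be strictly monotone; by spectroscopy convention
#' it is usually stored descending (e.g. 1800 down to 900 cm^-1), but all
#' operations in the package are orientation-agnostic.
#'
#' @param axis Numeric vector of wavenumbers in cm^-1, strictly monotone.
#' @param X Numeric matrix, one row per sample, `length(axis)` columns.
#' @param pmi_h Numeric vector of PMI values in hours, one per sample,
#'   non-negative. Each animal must map to a single PMI (one sampling time
#'   point per animal).
#' @param animal_id Character vector of animal identifiers.
#' @param replicate Integer vector of replicate indices (>= 1). After
#'   replicate averaging this field holds the number of replicates averaged.
#' @param role Character vector of per-sample roles.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(axis, X, pmi_h, animal_id,
                        replicate = rep(1L, nrow(X)),
                        role = rep("calibration", nrow(X))) {
  X <- as.matrix(X)
  axis <- as.numeric(axis)
  ds <- structure(
    list(axis = axis, X = X, pmi_h = as.numeric(pmi_h),
         animal_id = as.character(animal_id),
         replicate = as.integer(replicate),
         role = as.character(role)),
    class = "spectra_set")
  validate_spectra_set(ds)
  ds
}

validate_spectra_set <- function(ds) {
  axis <- ds$axis
  X <- ds$X
  n <- nrow(X)
  if (length(axis) < 2L)
    stop("wavenumber axis must have at least 2 points", call. = FALSE)
  if (n < 1L)
    stop("dataset contains no samples", call. = FALSE)
  if (ncol(X) != length(axis))
    stop("number of matrix columns must equal the axis length", call. = FALSE)
  if (any(!is.finite(axis)) || any(!is.finite(X)))
    stop("axis and absorbance values must be finite (no NA/NaN/Inf)",
         call. = FALSE)
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone", call. = FALSE)
  for (field in c("pmi_h", "animal_id", "replicate", "role")) {
    if (length(ds[[field]]) != n)
      stop(sprintf("'%s' must have one entry per sample", field),
           call. = FALSE)
  }
  if (any(is.na(ds$pmi_h)) || any(ds$pmi_h < 0))
    stop("pmi_h must be non-negative and non-missing", call. = FALSE)
  if (any(is.na(ds$animal_id)) || any(!nzchar(ds$animal_id)))
    stop("animal_id must be non-empty", call. = FALSE)
  if (any(is.na(ds$replicate)) || any(ds$replicate < 1L))
    stop("replicate must be a positive integer", call. = FALSE)
  # one sampling time per animal
  pm <- tapply(ds$pmi_h, ds$animal_id, function(v) length(unique(v)))
  if (any(pm > 1L))
    stop("each animal_id must map to exactly one pmi_h; offending: ",
         paste(names(pm)[pm > 1L], collapse = ", "), call. = FALSE)
  invisible(ds)
}

#' @export
print.spectra_set <- function(x, ...) {
  rng <- range(x$axis)
  cat(sprintf(
    "<spectra_set> %d spectra x %d wavenumbers (%.6g-%.6g cm-1)\n",
    nrow(x$X), length(x$axis), rng[2], rng[1]))
  cat(sprintf("  PMI groups (h): %s\n",
              paste(sort(unique(x$pmi_h)), collapse = ", ")))
  tb <- table(x$role)
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  steps <- attr(x, "steps")
  if (!is.null(steps))
    cat(sprintf("  preprocessing: %s\n", paste(steps, collapse = " -> ")))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$X)

# internal row subsetter; keeps provenance attributes
subset_samples <- function(ds, idx) {
  out <- structure(
    list(axis = ds$axis, X = ds$X[idx, , drop = FALSE],
         pmi_h = ds$pmi_h[idx], animal_id = ds$animal_id[idx],
         replicate = ds$replicate[idx], role = ds$role[idx]),
    class = "spectra_set")
  attr(out, "steps") <- attr(ds, "steps")
  out
}

#' Read a spectral dataset from a CSV table
#'
#' Two dialects are supported. *Wide*: first column `wavenumber_cm-1`, one
#' column per sample, named `<animal_id>:<pmi_h>:<replicate>:<role>`. *Long*:
#' columns `animal_id, pmi_h, replicate, role, wavenumber_cm-1, absorbance`.
#' With `dialect = "auto"` the layout is detected from the header.
#'
#' In long format, samples recorded on non-identical wavenumber grids are
#' linearly interpolated onto the first sample's grid restricted to the
#' common overlap; no extrapolation is performed.
#'
#' @param path Path to a CSV file.
#' @param dialect One of `"auto"`, `"wide"`, `"long"`.
#' @return A [spectra_set].
#' @export
read_spectra <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("empty or unreadable spectra table: ", path,
                             call. = FALSE))
  if (nrow(tab) == 0L || ncol(tab) == 0L)
    stop("empty spectra table: ", path, call. = FALSE)
  long_cols <- c("animal_id", "pmi_h", "replicate", "role",
                 "wavenumber_cm-1", "absorbance")
  if (dialect == "auto") {
    dialect <- if (all(long_cols %in% names(tab))) "long" else "wide"
  }
  if (dialect == "long") {
    missing <- setdiff(long_cols, names(tab))
    if (length(missing))
      stop("long-format table lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    return(spectra_from_long(tab))
  }
  if (names(tab)[1] != "wavenumber_cm-1")
    stop("wide-format table must start with a 'wavenumber_cm-1' column",
         call. = FALSE)
  if (ncol(tab) < 2L)
    stop("wide-format table contains no sample columns", call. = FALSE)
  axis <- as.numeric(tab[[1]])
  meta <- strsplit(names(tab)[-1], ":", fixed = TRUE)
  bad <- vapply(meta, length, 1L) != 4L
  if (any(bad))
    stop("sample column names must be '<animal_id>:<pmi_h>:<replicate>:<role>'",
         call. = FALSE)
  meta <- do.call(rbind, meta)
  X <- t(as.matrix(tab[, -1, drop = FALSE]))
  dimnames(X) <- NULL
  spectra_set(axis, X,
              pmi_h = as.numeric(meta[, 2]), animal_id = meta[, 1],
              replicate = as.integer(meta[, 3]), role = meta[, 4])
}

spectra_from_long <- function(tab) {
  key <- interaction(tab$animal_id, tab$pmi_h, tab$replicate, tab$role,
                     drop = TRUE, lex.order = TRUE)
  # preserve file order of first appearance
  key <- factor(key, levels = unique(as.character(key)))
  pieces <- split(tab, key)
  first <- pieces[[1]]
  target <- as.numeric(first[["wavenumber_cm-1"]])
  d <- diff(target)
  if (length(target) < 2L || !(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone", call. = FALSE)
  # common overlap across all sample grids
  lo <- max(vapply(pieces, function(p) min(p[["wavenumber_cm-1"]]), 0))
  hi <- min(vapply(pieces, function(p) max(p[["wavenumber_cm-1"]]), 0))
  if (lo > hi) stop("sample wavenumber ranges do not overlap", call. = FALSE)
  axis <- target[target >= lo & target <= hi]
  if (length(axis) < 2L)
    stop("fewer than 2 wavenumbers in the common overlap", call. = FALSE)
  X <- t(vapply(pieces, function(p) {
    w <- as.numeric(p[["wavenumber_cm-1"]])
    dd <- diff(w)
    if (length(w) < 2L || !(all(dd > 0) || all(dd < 0)))
      stop("wavenumber axis must be strictly monotone", call. = FALSE)
    a <- as.numeric(p$absorbance)
    if (length(w) == length(axis) && all(w == axis)) return(a)
    stats::approx(w, a, xout = axis, rule = 1)$y
  }, numeric(length(axis))))
  dimnames(X) <- NULL
  meta <- do.call(rbind, lapply(pieces, function(p) p[1, , drop = FALSE]))
  spectra_set(axis, X, pmi_h = meta$pmi_h, animal_id = meta$animal_id,
              replicate = meta$replicate, role = meta$role)
}

#' Write a spectral dataset to CSV
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip reproduces the dataset to at least 12 significant digits.
#'
#' @param ds A [spectra_set].
#' @param path Output path.
#' @param dialect `"wide"` (default) or `"long"`; see [read_spectra].
#' @export
write_spectra <- function(ds, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  validate_spectra_set(ds)
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (dialect == "wide") {
    cols <- sprintf("%s:%s:%d:%s", ds$animal_id, fmt(ds$pmi_h),
                    ds$replicate, ds$role)
    out <- data.frame(fmt(ds$axis), apply(ds$X, 1, fmt),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(out) <- c("wavenumber_cm-1", cols)
  } else {
    n <- nrow(ds$X); p <- length(ds$axis)
    out <- data.frame(
      animal_id = rep(ds$animal_id, each = p),
      pmi_h = rep(fmt(ds$pmi_h), each = p),
      replicate = rep(ds$replicate, each = p),
      role = rep(ds$role, each = p),
      `wavenumber_cm-1` = rep(fmt(ds$axis), times = n),
      absorbance = fmt(as.vector(t(ds$X))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Average replicate spectra per animal
#'
#' Collapses the dataset to one spectrum per animal by taking the arithmetic
#' mean over that animal's replicates. The `replicate` field of the result
#' records the number of replicates averaged.
#'
#' @param ds A [spectra_set].
#' @return A [spectra_set] with one row per animal.
#' @export
average_replicates <- function(ds) {
  validate_spectra_set(ds)
  ids <- unique(ds$animal_id)
  rows <- lapply(ids, function(id) which(ds$animal_id == id))
  X <- t(vapply(rows, function(r) colMeans(ds$X[r, , drop = FALSE]),
                numeric(length(ds$axis))))
  first <- vapply(rows, `[`, 1L, 1L)
  roles <- vapply(rows, function(r) {
    u <- unique(ds$role[r])
    if (length(u) > 1L)
      stop("replicates of one animal carry different roles", call. = FALSE)
    u
  }, character(1))
  out <- spectra_set(ds$axis, X, pmi_h = ds$pmi_h[first], animal_id = ids,
                     replicate = vapply(rows, length, 1L), role = roles)
  attr(out, "steps") <- c(attr(ds, "steps"), "average_replicates")
  out
}

#' Average spectra within each PMI group
#'
#' Produces one mean spectrum per distinct PMI, ordered by ascending PMI —
#' the input expected by generalized 2D correlation analysis, where the PMI
#' groups form the ordered perturbation axis.
#'
#' @param ds A [spectra_set].
#' @return A [spectra_set] with one row per PMI group, role `"mean"`.
#' @export
group_average <- function(ds) {
  validate_spectra_set(ds)
  pmis <- sort(unique(ds$pmi_h))
  X <- t(vapply(pmis, function(t0) {
    colMeans(ds$X[ds$pmi_h == t0, , drop = FALSE])
  }, numeric(length(ds$axis))))
  counts <- vapply(pmis, function(t0) sum(ds$pmi_h == t0), 1L)
  out <- spectra_set(ds$axis, X, pmi_h = pmis,
                     animal_id = sprintf("group_%gh", pmis),
                     replicate = counts, role = rep("mean", length(pmis)))
  attr(out, "steps") <- c(attr(ds, "steps"), "group_average")
  out
}

#' Restrict a dataset to a wavenumber window
#'
#' Keeps only the columns with `lo <= wavenumber <= hi` (inclusive bounds).
#'
#' @param ds A [spectra_set].
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return A [spectra_set] on the restricted axis.
#' @export
restrict_window <- function(ds, lo, hi) {
  validate_spectra_set(ds)
  if (!(lo < hi)) stop("window requires lo < hi", call. = FALSE)
  keep <- ds$axis >= lo & ds$axis <= hi
  if (sum(keep) < 2L)
    stop(sprintf("window (%g, %g) overlaps fewer than 2 axis points", lo, hi),
         call. = FALSE)
  out <- spectra_set(ds$axis[keep], ds$X[, keep, drop = FALSE],
                     pmi_h = ds$pmi_h, animal_id = ds$animal_id,
                     replicate = ds$replicate, role = ds$role)
  attr(out, "steps") <- attr(ds, "steps")
  out
}
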