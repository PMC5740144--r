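#' Specify an absorption band with time-dependent intensity
#'
#' A Gaussian absorption band whose amplitude follows a kinetic profile in
#' postmortem time: `"sigmoid"` (logistic rise/fall around an onset hour),
#' `"linear"` (proportional drift across the study window), or
#' `"constant"`.
#'
#' @param center Band center in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1, > 0.
#' @param base_amplitude Baseline amplitude in absorbance units.
#' @param kinetic List with `type` (`"sigmoid"`, `"linear"` or
#'   `"constant"`), `delta` (total amplitude change, a.u.), `onset_h`
#'   (sigmoid midpoint, hours, >= 0) and `rate` (sigmoid steepness, 1/h).
#' @param assignment Free-text molecular assignment label.
#' @return An object of class `"band_spec"`.
#' @export
band_spec <- function(center, fwhm, base_amplitude,
                      kinetic = list(type = "constant", delta = 0,
                                     onset_h = 0, rate = 0.25),
                      assignment = "") {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  kinetic <- utils::modifyList(
    list(type = "constant", delta = 0, onset_h = 0, rate = 0.25), kinetic)
  if (!kinetic$type %in% c("sigmoid", "linear", "constant"))
    stop("kinetic$type must be sigmoid, linear or constant", call. = FALSE)
  if (kinetic$onset_h < 0) stop("onset_h must be >= 0", call. = FALSE)
  structure(list(center = center, fwhm = fwhm,
                 base_amplitude = base_amplitude, kinetic = kinetic,
                 assignment = assignment),
            class = "band_spec")
}

#' Band amplitude at a given postmortem time
#'
#' Evaluates a band's kinetic profile: sigmoid
#' `base + delta / (1 + exp(-rate * (t - onset)))` (half the change is
#' reached at the onset hour, saturating at `base + delta`); linear
#' `base + delta * t / pmi_max`; constant `base`.
#'
#' @param band A [band_spec].
#' @param t Time(s) in hours, >= 0.
#' @param pmi_max Study end point scaling the linear profile (default 48 h).
#' @return Amplitude(s) in absorbance units.
#' @export
band_amplitude <- function(band, t, pmi_max = 48) {
  stopifnot(inherits(band, "band_spec"), all(t >= 0))
  k <- band$kinetic
  switch(k$type,
    constant = rep(band$base_amplitude, length(t)),
    linear = band$base_amplitude + k$delta * t / pmi_max,
    sigmoid = band$base_amplitude +
      k$delta / (1 + exp(-k$rate * (t - k$onset_h))))
}

#' Define a synthetic study design
#'
#' Parameters of the emulated time-course biofluid study: 9 PMI groups at
#' 0-48 h in 6 h steps, 11 animals per group split 8 calibration / 3
#' validation, 9 instrument replicates averaged per animal, spectra on a
#' 1800-900 cm^-1 axis at 2 cm^-1 spacing.
#'
#' Noise defaults (absorbance units unless noted) represent a well-behaved
#' ATR-FTIR measurement of a centrifuged biofluid: `additive_sd` detector
#' noise per point; `scatter_slope_sd` / `scatter_offset_sd` multiplicative
#' and additive scatter per replicate (dimensionless / a.u.);
#' `baseline_curvature_sd` SD of the random quadratic baseline
#' coefficients; `animal_effect_sd` SD of the per-animal multiplicative
#' signal effect (dimensionless).
#'
#' @param pmi_points Sampling times in hours, ascending.
#' @param animals_per_point Animals sampled per time point.
#' @param n_calibration,n_validation Role split; must sum to
#'   `animals_per_point`.
#' @param replicates Instrument replicates averaged per animal.
#' @param axis_lo,axis_hi,axis_step Wavenumber axis in cm^-1.
#' @param noise Named list overriding any of the noise defaults.
#' @param seed Default seed used by [generate_study] when none is passed.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(pmi_points = seq(0, 48, by = 6),
                         animals_per_point = 11L,
                         n_calibration = 8L, n_validation = 3L,
                         replicates = 9L,
                         axis_lo = 900, axis_hi = 1800, axis_step = 2,
                         noise = list(), seed = 1L) {
  if (is.unsorted(pmi_points, strictly = TRUE))
    stop("pmi_points must be strictly ascending", call. = FALSE)
  if (n_calibration + n_validation != animals_per_point)
    stop("n_calibration + n_validation must equal animals_per_point",
         call. = FALSE)
  defaults <- list(additive_sd = 0.004, scatter_slope_sd = 0.05,
                   scatter_offset_sd = 0.02, baseline_curvature_sd = 0.01,
                   animal_effect_sd = 0.04)
  noise <- utils::modifyList(defaults, noise)
  structure(list(pmi_points = pmi_points,
                 animals_per_point = as.integer(animals_per_point),
                 n_calibration = as.integer(n_calibration),
                 n_validation = as.integer(n_validation),
                 replicates = as.integer(replicates),
                 axis_lo = axis_lo, axis_hi = axis_hi,
                 axis_step = axis_step, noise = noise,
                 seed = as.integer(seed)),
            class = "study_design")
}

design_axis <- function(design) {
  seq(design$axis_hi, design$axis_lo, by = -design$axis_step)
}

#' Generate one synthetic spectrum
#'
#' The noise-free signal is a sum of Gaussian bands evaluated at time `t`,
#' scaled by `(1 + animal_effect)`. Each replicate then receives a random
#' quadratic baseline, multiplicative scatter (a random slope applied to
#' the signal and an additive offset), and white noise; the `replicates`
#' are averaged unless `average = FALSE`. Uses the current RNG state — seed
#' before calling for reproducibility.
#'
#' @param design A [study_design].
#' @param bands List of [band_spec] objects.
#' @param t Postmortem time in hours.
#' @param animal_effect Per-animal multiplicative effect (dimensionless).
#' @param average Average the replicates (default) or return the replicate
#'   matrix.
#' @return A list with `wavenumbers` and `absorbance` (vector if averaged,
#'   otherwise a `replicates x p` matrix).
#' @export
generate_spectrum <- function(design, bands, t, animal_effect = 0,
                              average = TRUE) {
  axis <- design_axis(design)
  p <- length(axis)
  pmi_max <- max(design$pmi_points)
  signal <- rep(0, p)
  for (b in bands) {
    amp <- band_amplitude(b, t, pmi_max = pmi_max)
    signal <- signal + amp * exp(-4 * log(2) * (axis - b$center)^2 / b$fwhm^2)
  }
  signal <- signal * (1 + animal_effect)
  ns <- design$noise
  u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1  # [-1, 1]
  reps <- t(vapply(seq_len(design$replicates), function(r) {
    slope <- stats::rnorm(1, 0, ns$scatter_slope_sd)
    offset <- stats::rnorm(1, 0, ns$scatter_offset_sd)
    bl <- stats::rnorm(3, 0, ns$baseline_curvature_sd)
    baseline <- bl[1] + bl[2] * u + bl[3] * u^2
    (1 + slope) * signal + baseline + offset +
      stats::rnorm(p, 0, ns$additive_sd)
  }, numeric(p)))
  list(wavenumbers = axis,
       absorbance = if (average) colMeans(reps) else reps)
}

#' Generate a complete synthetic study
#'
#' Emulates the full sampling design: for each PMI group,
#' `animals_per_point` animals are drawn (each with its own random
#' multiplicative effect), measured in `replicates` averaged replicates,
#' and randomly split into calibration and validation roles. The returned
#' ground-truth record (band kinetics and per-animal effects) supports
#' recovery tests of every downstream stage.
#'
#' @param design A [study_design].
#' @param bands List of [band_spec]; default [default_scenario] bands.
#' @param seed Integer seed (default `design$seed`).
#' @return A list with elements `calibration` and `validation` (both
#'   [spectra_set]) and `truth` (list of `bands`, `animal_effects`,
#'   `design`, `seed`).
#' @export
generate_study <- function(design = study_design(), bands = NULL,
                           seed = design$seed) {
  if (is.null(bands)) bands <- default_scenario()$bands
  set.seed(seed)
  axis <- design_axis(design)
  n_groups <- length(design$pmi_points)
  apg <- design$animals_per_point
  rows <- vector("list", n_groups * apg)
  pmi <- numeric(0); ids <- character(0); roles <- character(0)
  effects <- numeric(0)
  i <- 0L
  for (g in seq_len(n_groups)) {
    t_g <- design$pmi_points[g]
    role_g <- sample(c(rep("calibration", design$n_calibration),
                       rep("validation", design$n_validation)))
    for (a in seq_len(apg)) {
      i <- i + 1L
      id <- sprintf("R%03d", i)
      eff <- stats::rnorm(1, 0, design$noise$animal_effect_sd)
      sp <- generate_spectrum(design, bands, t_g, animal_effect = eff)
      rows[[i]] <- sp$absorbance
      pmi <- c(pmi, t_g); ids <- c(ids, id); roles <- c(roles, role_g[a])
      effects <- c(effects, stats::setNames(eff, id))
    }
  }
  X <- do.call(rbind, rows)
  ds <- spectra_set(axis, X, pmi_h = pmi, animal_id = ids,
                    replicate = rep(design$replicates, length(ids)),
                    role = roles)
  cal <- subset_samples(ds, ds$role == "calibration")
  val <- subset_samples(ds, ds$role == "validation")
  list(calibration = cal, validation = val,
       truth = list(bands = bands, animal_effects = effects,
                    design = design, seed = seed))
}

#' Default synthetic scenario
#'
#' The reference band table: Gaussian bands at the canonical biofluid
#' positions (amide I 1650, amide II 1540, C-H bending 1453, COO- 1398,
#' amide III 1324, phosphate/saccharide 1078, glucose 1033, carbohydrate
#' 926 cm^-1) plus a protein band at 1581 cm^-1. Early postmortem kinetics
#' (sigmoid onset 6 h) drive the amide I/II/III bands — emulating protein
#' infiltration and degradation soon after death — while the 1581 and 1078
#' cm^-1 bands change late (onset 30 h), as for glycoprotein leakage after
#' barrier collapse; the remaining bands are constant. Amplitude changes
#' are largest in the amide region, so the amide bands dominate the
#' synchronous diagonal.
#'
#' @return A list with elements `design` (a [study_design]) and `bands`
#'   (list of [band_spec]).
#' @export
default_scenario <- function() {
  early <- function(delta) list(type = "sigmoid", delta = delta,
                                onset_h = 6, rate = 0.25)
  late <- function(delta) list(type = "sigmoid", delta = delta,
                               onset_h = 30, rate = 0.25)
  bands <- list(
    band_spec(1650, 40, 0.45, early(0.28), "amide I"),
    band_spec(1581, 25, 0.10, late(0.12), "protein (late stage)"),
    band_spec(1540, 35, 0.32, early(0.18), "amide II"),
    band_spec(1453, 25, 0.12, assignment = "C-H bending"),
    band_spec(1398, 25, 0.10, assignment = "COO- stretch"),
    band_spec(1324, 30, 0.08, early(0.10), "amide III"),
    band_spec(1078, 30, 0.15, late(0.09), "phosphate / saccharide"),
    band_spec(1033, 25, 0.18, assignment = "glucose"),
    band_spec(926, 20, 0.06, assignment = "carbohydrate"))
  list(design = study_design(), bands = bands)
}
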