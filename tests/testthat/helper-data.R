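# shared fixtures and independent oracles, built in code

# small dataset: n samples on a short descending axis
tiny_dataset <- function(n = 4, p = 6, seed = 42) {
  set.seed(seed)
  axis <- seq(1800, by = -2, length.out = p)
  X <- matrix(stats::rnorm(n * p, mean = 0.3, sd = 0.05), n, p)
  spectra_set(axis, X,
              pmi_h = rep(seq(0, by = 6, length.out = ceiling(n / 2)),
                          each = 2)[seq_len(n)],
              animal_id = sprintf("A%02d", rep(seq_len(ceiling(n / 2)),
                                               each = 2))[seq_len(n)],
              replicate = rep(1:2, length.out = n))
}

# loop-based 2D correlation oracles (independent of the matrix formulation)
phi_loop <- function(dyn) {
  m <- nrow(dyn); p <- ncol(dyn)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- 0
    for (k in seq_len(m)) s <- s + dyn[k, i] * dyn[k, j]
    out[i, j] <- s / (m - 1)
  }
  out
}

psi_loop <- function(dyn) {
  m <- nrow(dyn); p <- ncol(dyn)
  N <- matrix(0, m, m)
  for (j in seq_len(m)) for (k in seq_len(m))
    if (j != k) N[j, k] <- 1 / (pi * (k - j))
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- 0
    for (a in seq_len(m)) for (b in seq_len(m))
      s <- s + dyn[a, i] * N[a, b] * dyn[b, j]
    out[i, j] <- s / (m - 1)
  }
  out
}

# two-band group-average spectra with sigmoid kinetics at distinct onsets
two_band_groups <- function(onset_early = 6, onset_late = 30, rate = 0.25,
                            noise_sd = 0, seed = NULL,
                            times = seq(0, 48, by = 6)) {
  if (!is.null(seed)) set.seed(seed)
  axis <- seq(1800, 900, by = -4)
  profile <- function(onset, t) 1 / (1 + exp(-rate * (t - onset)))
  X <- t(vapply(times, function(t) {
    s <- profile(onset_early, t) *
      exp(-4 * log(2) * (axis - 1650)^2 / 40^2) +
      0.8 * profile(onset_late, t) *
      exp(-4 * log(2) * (axis - 1078)^2 / 30^2)
    s + stats::rnorm(length(axis), 0, noise_sd)
  }, numeric(length(axis))))
  spectra_set(axis, X, pmi_h = times,
              animal_id = sprintf("g%02d", seq_along(times)))
}

# small synthetic study for fast end-to-end tests
small_design <- function(...) {
  study_design(pmi_points = seq(0, 48, by = 12), animals_per_point = 4L,
               n_calibration = 3L, n_validation = 1L, replicates = 3L,
               axis_step = 4, ...)
}
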