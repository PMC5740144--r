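test_that("band kinetics follow the sigmoid/linear/constant profiles", {
  b_const <- band_spec(1453, 25, 0.12)
  expect_equal(band_amplitude(b_const, c(0, 17, 48)), rep(0.12, 3))
  b_sig <- band_spec(1650, 40, 0.4,
                     list(type = "sigmoid", delta = 0.3, onset_h = 12,
                          rate = 0.5))
  # midpoint identity at the onset
  expect_equal(band_amplitude(b_sig, 12), 0.4 + 0.15)
  # saturation
  expect_equal(band_amplitude(b_sig, 1e6), 0.7)
  expect_equal(band_amplitude(b_sig, 0), 0.4 + 0.3 / (1 + exp(6)))
  b_lin <- band_spec(1078, 30, 0.1,
                     list(type = "linear", delta = 0.24))
  expect_equal(band_amplitude(b_lin, c(0, 24, 48), pmi_max = 48),
               c(0.1, 0.22, 0.34))
  expect_error(band_spec(1650, -1, 1), "fwhm")
  expect_error(band_spec(1650, 1, 1, list(type = "voigt")), "kinetic")
})

test_that("a noise-free spectrum is the exact sum of Gaussian bands", {
  d <- study_design(noise = list(additive_sd = 0, scatter_slope_sd = 0,
                                 scatter_offset_sd = 0,
                                 baseline_curvature_sd = 0,
                                 animal_effect_sd = 0))
  b <- band_spec(1650, 40, 0.5,
                 list(type = "sigmoid", delta = 0.2, onset_h = 6,
                      rate = 0.25))
  sp <- generate_spectrum(d, list(b), t = 24)
  amp <- band_amplitude(b, 24)
  expected <- amp * exp(-4 * log(2) * (sp$wavenumbers - 1650)^2 / 40^2)
  expect_equal(sp$absorbance, expected, tolerance = 1e-12)
  expect_equal(max(sp$absorbance), amp, tolerance = 1e-6)
  expect_equal(sp$wavenumbers[which.max(sp$absorbance)], 1650)
})

test_that("SNV removes pure multiplicative scatter between replicates", {
  d <- study_design(replicates = 2,
                    noise = list(additive_sd = 0, scatter_slope_sd = 0.2,
                                 scatter_offset_sd = 0.3,
                                 baseline_curvature_sd = 0,
                                 animal_effect_sd = 0))
  set.seed(5)
  sp <- generate_spectrum(d, default_scenario()$bands, t = 12,
                          average = FALSE)
  expect_equal(snv(sp$absorbance[1, ]), snv(sp$absorbance[2, ]),
               tolerance = 1e-6)
})

test_that("generation is deterministic under a fixed seed", {
  d <- small_design()
  set.seed(99); s1 <- generate_spectrum(d, default_scenario()$bands, 12)
  set.seed(99); s2 <- generate_spectrum(d, default_scenario()$bands, 12)
  expect_identical(s1, s2)
  st1 <- generate_study(d, seed = 7)
  st2 <- generate_study(d, seed = 7)
  expect_identical(st1$calibration$X, st2$calibration$X)
  st3 <- generate_study(d, seed = 8)
  expect_false(identical(st1$calibration$X, st3$calibration$X))
  expect_identical(dim(st1$calibration$X), dim(st3$calibration$X))
})

test_that("the default study reproduces the sampling design", {
  st <- generate_study(seed = 2)
  expect_equal(nrow(st$calibration$X), 72L)
  expect_equal(nrow(st$validation$X), 27L)
  expect_equal(sort(unique(st$calibration$pmi_h)), seq(0, 48, 6))
  expect_true(all(table(st$calibration$pmi_h) == 8L))
  expect_true(all(table(st$validation$pmi_h) == 3L))
  expect_equal(length(st$truth$animal_effects), 99L)
  # degenerate design: single animal per point, no validation
  d1 <- study_design(animals_per_point = 1L, n_calibration = 1L,
                     n_validation = 0L, replicates = 1L)
  st1 <- generate_study(d1, seed = 3)
  expect_equal(nrow(st1$calibration$X), 9L)
  expect_equal(nrow(st1$validation$X), 0L)
  expect_error(study_design(animals_per_point = 5L, n_calibration = 3L,
                            n_validation = 1L), "equal")
})

test_that("increasing a band's kinetic delta increases its auto-peak", {
  mk <- function(delta) {
    d <- study_design(animals_per_point = 1L, n_calibration = 1L,
                      n_validation = 0L, replicates = 1L,
                      noise = list(additive_sd = 0, scatter_slope_sd = 0,
                                   scatter_offset_sd = 0,
                                   baseline_curvature_sd = 0,
                                   animal_effect_sd = 0))
    b <- list(band_spec(1650, 40, 0.4,
                        list(type = "sigmoid", delta = delta, onset_h = 12,
                             rate = 0.25)))
    st <- generate_study(d, b, seed = 1)
    co <- corr2d(group_average(st$calibration))
    diag(co$phi)[which.min(abs(co$axis - 1650))]
  }
  peaks <- vapply(c(0.1, 0.2, 0.4), mk, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("2D analysis of the noise-free default scenario recovers the kinetic order", {
  scen <- default_scenario()
  d <- scen$design
  d$noise <- lapply(d$noise, function(x) 0)
  d$animals_per_point <- 1L; d$n_calibration <- 1L; d$n_validation <- 0L
  d$replicates <- 1L
  st <- generate_study(d, scen$bands, seed = 1)
  co <- corr2d(group_average(st$calibration))
  # top auto-peak in the amide region
  top <- autopeak_ranking(co, top_k = 1)
  expect_true(top$wavenumber >= 1500 && top$wavenumber <= 1700)
  # every early/late pair reads 'before'
  early <- c(1650, 1540, 1324); late <- c(1581, 1078)
  pairs <- expand.grid(e = early, l = late)
  calls <- call_cross_peaks(co, as.matrix(pairs))
  expect_true(all(calls$verdict == "before"))
})

test_that("scenario designs round-trip through the YAML pipeline config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    seed = 11,
    input = list(
      mode = "simulate",
      design = list(pmi_points = seq(0, 48, 12), animals_per_point = 3,
                    n_calibration = 2, n_validation = 1, replicates = 2,
                    axis_step = 4),
      bands = list(list(center = 1650, fwhm = 40, base_amplitude = 0.4,
                        kinetic = list(type = "sigmoid", delta = 0.2,
                                       onset_h = 6, rate = 0.25)),
                   list(center = 1078, fwhm = 30, base_amplitude = 0.2)))),
    f)
  cfg <- read_pipeline_config(f)
  expect_s3_class(cfg$input$design, "study_design")
  expect_equal(cfg$input$design$pmi_points, seq(0, 48, 12))
  expect_s3_class(cfg$input$bands[[1]], "band_spec")
  expect_equal(cfg$input$bands[[1]]$kinetic$onset_h, 6)
  expect_equal(cfg$input$bands[[2]]$kinetic$type, "constant")
  expect_equal(cfg$seed, 11)
  # untouched blocks keep their defaults
  expect_equal(cfg$models$pls$factors, 7L)
})

test_that("models recover PMI and active bands across generator seeds", {
  d <- study_design(animals_per_point = 5L, n_calibration = 4L,
                    n_validation = 1L, replicates = 3L, axis_step = 4)
  active <- c(1650, 1581, 1540, 1324, 1078)
  r2_ok <- 0L; vip_ok <- 0L
  for (s in 1:20) {
    st <- generate_study(d, seed = 500 + s)
    pp <- preprocess_spectra(st$calibration, preprocess_config())
    cv <- cross_validate(list(model = "pls", ncomp = 7), pp, k = 4,
                         seed = s)
    r2_ok <- r2_ok + (cv$summary$r2_mean >= 0.9)
    fit <- pls_fit(pp$X, pp$pmi_h, 7)
    top <- pp$axis[order(vip_scores(fit), decreasing = TRUE)[1:10]]
    vip_ok <- vip_ok +
      any(vapply(top, function(w) any(abs(w - active) <= 10), logical(1)))
  }
  expect_gte(r2_ok, 18L)
  expect_gte(vip_ok, 18L)
})
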