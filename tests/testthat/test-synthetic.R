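test_that("concentration sampling is deterministic and respects bounds", {
  specs <- quick_specs()
  p1 <- sample_concentrations(specs, 50, seed = 42)
  p2 <- sample_concentrations(specs, 50, seed = 42)
  p3 <- sample_concentrations(specs, 50, seed = 43)
  expect_identical(unclass(p1), unclass(p2))
  expect_false(identical(unclass(p1), unclass(p3)))
  for (a in names(specs)) {
    expect_true(all(p1[, a] >= specs[[a]]$min & p1[, a] <= specs[[a]]$max))
  }
  expect_identical(dim(p1), c(50L, length(specs)))
})

test_that("degenerate sd = 0 yields a constant column at the mean", {
  sp <- analyte_spec("const", "u", mean = 5, sd = 0, min = 5, max = 5)
  v <- sample_concentrations(list(const = sp), 10, seed = 1)[, 1]
  expect_identical(unname(v), rep(5, 10))
})

test_that("invalid sampler inputs are rejected", {
  sp <- analyte_spec("x", "u", 1, 0.1, 0.5, 1.5)
  expect_error(sample_concentrations(list(x = sp), 1, seed = 1), "n must be")
  expect_error(analyte_spec("bad", "u", 1, -0.1, 0, 2), "nonnegative")
  expect_error(analyte_spec("bad", "u", 1, 0.1, 2, 3), "min <= mean <= max")
  expect_error(analyte_spec("bad", "u", 1, 0.1, 0, 2, log_transformed = TRUE),
               "min > 0")
})

test_that("heavily truncated sampling matches the quadrature oracle", {
  # symmetric truncation at one sd: sd target of 1 is unattainable on [-1, 1],
  # so the sampler must fall back to truncating the nominal N(0, 1)
  sp <- analyte_spec("t", "u", mean = 0, sd = 1, min = -1, max = 1)
  v <- sample_concentrations(list(t = sp), 1e5, seed = 3)[, 1]
  expect_identical(attr(sample_concentrations(list(t = sp), 10, seed = 1),
                        "parameterisation")[["t"]], "naive")
  om <- oracle_trunc_moments(0, 1, -1, 1)
  expect_equal(mean(v >= -1 & v <= 1), 1)
  expect_lt(abs(sd(v) - om["sd"]) / om["sd"], 0.01)
  expect_lt(abs(mean(v) - om["mean"]), 0.01)
  # rejection sampling draws from the same distribution
  vr <- sample_concentrations(list(t = sp), 2e4, seed = 4,
                              sampling = "rejection")[, 1]
  expect_lt(abs(sd(vr) - om["sd"]) / om["sd"], 0.02)
})

test_that("registry marginals reproduce their target moments", {
  specs <- analyte_registry()
  p <- sample_concentrations(specs, 1e4, seed = 7)
  used <- attr(p, "parameterisation")
  match_err <- attr(p, "match_rel_error")
  for (a in names(specs)) {
    sp <- specs[[a]]
    emp <- c(mean(p[, a]), sd(p[, a]))
    if (used[[a]] == "match") {
      # matched analytes: empirical moments within 2% of the published
      # targets, allowing the solver's own boundary-projection residual and
      # two standard errors of the respective moment estimator at n = 1e4
      se_mean <- 2 * (sp$sd / sp$mean) / sqrt(1e4)
      expect_lt(abs(emp[1] - sp$mean) / sp$mean,
                0.02 + match_err[[a]] + se_mean, label = a)
      expect_lt(abs(emp[2] - sp$sd) / sp$sd, 0.02 + match_err[[a]] + 0.015,
                label = a)
    } else {
      # infeasible targets (published SD exceeds the family's maximum on
      # the bounded range): sampler must still realise its own naive
      # truncated distribution faithfully
      np <- if (sp$log_transformed) {
        s2 <- log(1 + (sp$sd / sp$mean)^2)
        c(log(sp$mean) - s2 / 2, sqrt(s2))
      } else c(sp$mean, sp$sd)
      om <- oracle_trunc_moments(np[1], np[2], sp$min, sp$max,
                                 sp$log_transformed)
      expect_lt(abs(emp[1] - om["mean"]) / om["mean"], 0.02, label = a)
      expect_lt(abs(emp[2] - om["sd"]) / om["sd"], 0.04, label = a)
    }
  }
  # the two analytes whose printed SD is unattainable under truncation
  expect_identical(sort(names(used[used == "naive"])),
                   c("haptoglobin", "total_cholesterol"))
})

test_that("assay noise reproduces the between-run CVs", {
  specs <- analyte_registry(c("glucose", "haptoglobin"))
  base <- matrix(1, nrow = 1e4, ncol = 2,
                 dimnames = list(NULL, c("glucose", "haptoglobin")))
  ref <- make_reference_values(base, specs, seed = 9)
  rel_g <- ref[, "glucose"] / base[, "glucose"]
  rel_h <- ref[, "haptoglobin"] / base[, "haptoglobin"]
  expect_gt(100 * sd(rel_g), 1.4)   # glucose assay CV 1.50%
  expect_lt(100 * sd(rel_g), 1.6)
  expect_lt(abs(sd(rel_h) - 0.1354), 0.005)  # haptoglobin assay CV 13.54%
  # zero CV leaves values untouched
  sp0 <- analyte_spec("z", "u", 1, 0.1, 0.5, 1.5, assay_cv_percent = 0)
  base_z <- base[, 1, drop = FALSE]
  colnames(base_z) <- "z"
  expect_identical(make_reference_values(base_z, list(z = sp0), seed = 1)[, 1],
                   base[, 1])
  expect_error(make_reference_values(base, specs["glucose"], seed = 1),
               "no assay CV")
})

test_that("forward model: empty absorber transmits fully", {
  grid <- wavenumber_grid()
  cfg <- forward_model_config(grid, water_bands = matrix(numeric(0), 0, 3),
                              background_absorbance = 0,
                              baseline_drift_sd = 0, noise_sd = 0,
                              replicate_noise_sd = 0, seed = 5)
  panel <- matrix(0, 3, 1, dimnames = list(paste0("S", 1:3), "glucose"))
  comp <- list(glucose = pure_component("glucose", 2700, 10, 0.05))
  ds <- simulate_spectra(panel, comp, cfg)
  expect_equal(max(abs(ds$spectra$transmittance - 100)), 0)
})

test_that("forward model inverts and is linear in concentration", {
  grid <- wavenumber_grid()
  cfg <- forward_model_config(grid, water_bands = matrix(numeric(0), 0, 3),
                              background_absorbance = 0,
                              baseline_drift_sd = 0, noise_sd = 0,
                              replicate_noise_sd = 0, seed = 5)
  comp <- list(glucose = pure_component("glucose", c(2700, 1200), c(10, 14),
                                        c(0.05, 0.03)))
  panel1 <- matrix(2, 1, 1, dimnames = list("S1", "glucose"))
  panel2 <- matrix(4, 1, 1, dimnames = list("S1", "glucose"))
  a1 <- -log10(simulate_spectra(panel1, comp, cfg)$spectra$transmittance / 100)
  a2 <- -log10(simulate_spectra(panel2, comp, cfg)$spectra$transmittance / 100)
  i_center <- which(grid == 2700)
  expect_equal(a1[1, i_center], 2 * 0.05, tolerance = 1e-12)
  # doubling the concentration doubles absorbance at every wavenumber
  expect_equal(a2[1, ], 2 * a1[1, ], tolerance = 1e-10)
  expect_error(simulate_spectra(panel1, list(), cfg), "missing pure component")
})

test_that("replicate pairs differ only by replicate noise of the set size", {
  specs <- analyte_registry("glucose")
  grid <- wavenumber_grid()
  rep_sd <- 0.003
  cfg <- forward_model_config(grid, baseline_drift_sd = 0, noise_sd = 0,
                              replicate_noise_sd = rep_sd, seed = 8)
  panel <- sample_concentrations(specs, 20, seed = 8)
  ds <- simulate_spectra(panel, default_components(specs), cfg)
  expect_true(all(table(ds$spectra$sample_id) == 2))
  A <- -log10(ds$spectra$transmittance / 100)
  r1 <- A[ds$spectra$replicate == 1, ]
  r2 <- A[ds$spectra$replicate == 2, ]
  d <- as.numeric(r1 - r2)
  expect_lt(abs(sd(d) - rep_sd * sqrt(2)) / (rep_sd * sqrt(2)), 0.05)
})

test_that("synthetic study is reproducible end to end", {
  specs <- quick_specs()
  d1 <- synthetic_study(n = 6, specs = specs, seed = 21)
  d2 <- synthetic_study(n = 6, specs = specs, seed = 21)
  expect_identical(d1$spectra$transmittance, d2$spectra$transmittance)
  expect_identical(unclass(d1$reference_panel), unclass(d2$reference_panel))
  expect_identical(dim(d1$reference_panel), dim(d1$panel))
})

test_that("water bands are constrained to the water-absorption regions", {
  expect_error(forward_model_config(water_bands = cbind(2500, 50, 0.3)),
               "water-absorption regions")
  expect_error(forward_model_config(noise_sd = -1), ">= 0")
  expect_error(forward_model_config(grid = c(1, 3, 2)), "monotone")
})
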