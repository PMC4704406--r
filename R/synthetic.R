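# log(exp(la) - exp(lb)) for la > lb, without underflow.
.lse_sub <- function(la, lb) la + log1p(-exp(lb - la))
# log(exp(la) + exp(lb))
.lse_add <- function(la, lb) {
  m <- pmax(la, lb)
  m + log1p(exp(pmin(la, lb) - m))
}

# log of the truncation mass P(alpha < Z < beta) for a standard normal,
# stable deep in either tail.
.trunc_logmass <- function(alpha, beta) {
  if (beta <= 0) {
    .lse_sub(stats::pnorm(beta, log.p = TRUE), stats::pnorm(alpha, log.p = TRUE))
  } else if (alpha >= 0) {
    .lse_sub(stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE),
             stats::pnorm(beta, lower.tail = FALSE, log.p = TRUE))
  } else {
    log(stats::pnorm(beta) - stats::pnorm(alpha))
  }
}

# Mean and SD of a truncated normal / log-normal by numerical integration of
# the (log-stable) conditional density. Closed forms exist but cancel
# catastrophically in the heavily-truncated regimes the moment-matching
# search explores; quadrature is reliable everywhere on the finite [a, b].
.trunc_moments <- function(mu, sigma, a, b, lognormal) {
  if (lognormal) {
    lZ <- .trunc_logmass((log(a) - mu) / sigma, (log(b) - mu) / sigma)
    ldens <- function(x) stats::dlnorm(x, mu, sigma, log = TRUE) - lZ
  } else {
    lZ <- .trunc_logmass((a - mu) / sigma, (b - mu) / sigma)
    ldens <- function(x) stats::dnorm(x, mu, sigma, log = TRUE) - lZ
  }
  if (!is.finite(lZ)) return(c(mean = NA_real_, sd = NA_real_))
  m1 <- tryCatch(
    stats::integrate(function(x) exp(ldens(x)) * x, a, b,
                     rel.tol = 1e-10)$value,
    error = function(e) NA_real_)
  m2 <- tryCatch(
    stats::integrate(function(x) exp(ldens(x)) * x^2, a, b,
                     rel.tol = 1e-10)$value,
    error = function(e) NA_real_)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Naive underlying parameters: distribution whose UNtruncated moments equal
# the spec's mean/sd.
.naive_params <- function(spec) {
  if (spec$log_transformed) {
    s2 <- log(1 + (spec$sd / spec$mean)^2)
    list(mu = log(spec$mean) - s2 / 2, sigma = sqrt(s2))
  } else {
    list(mu = spec$mean, sigma = spec$sd)
  }
}

.match_cache <- new.env(parent = emptyenv())

# Solve for underlying (mu, sigma) so that the TRUNCATED distribution has the
# target mean/sd (multi-start Nelder-Mead on (mu, log sigma)). Returns NULL
# when the target is infeasible for the family (best relative error above
# tol), in which case the caller falls back to naive truncation.
.match_truncation <- function(spec, tol = 0.02) {
  if (spec$sd == 0) return(NULL)
  key <- paste(spec$mean, spec$sd, spec$min, spec$max, spec$log_transformed,
               sep = "|")
  if (!is.null(.match_cache[[key]])) {
    res <- .match_cache[[key]]
    return(if (identical(res, "infeasible")) NULL else res)
  }
  target <- c(spec$mean, spec$sd)
  denom <- pmax(abs(target), spec$sd)   # guards relative error at mean ~ 0
  la <- if (spec$log_transformed) log(spec$min) else spec$min
  lb <- if (spec$log_transformed) log(spec$max) else spec$max
  # search over the standardized truncation points (centre, log spread):
  # much better conditioned than (mu, sigma) in the heavily-truncated
  # regimes, where the family degenerates to exponential-tilt / power-law
  # shapes with extreme underlying parameters
  from_p <- function(p) {
    d <- exp(p[2])
    sigma <- (lb - la) / d
    list(mu = la - (p[1] - d / 2) * sigma, sigma = sigma)
  }
  obj <- function(p) {
    par <- from_p(p)
    m <- .trunc_moments(par$mu, par$sigma, spec$min, spec$max,
                        spec$log_transformed)
    if (any(!is.finite(m))) return(1e6)
    sum(((m - target) / denom)^2)
  }
  best <- NULL
  for (cc in c(0, -3, 3, -10, 10, -30, 30)) {
    for (ld in log(c(1, 0.1, 3))) {
      fit <- stats::optim(c(cc, ld), obj, method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-15))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (best$value < 1e-10) break
    }
    if (best$value < 1e-10) break
  }
  par <- from_p(best$par)
  mom <- .trunc_moments(par$mu, par$sigma, spec$min, spec$max,
                        spec$log_transformed)
  rel <- abs(mom - target) / denom
  res <- if (any(!is.finite(rel)) || any(rel > tol)) NULL
         else list(mu = par$mu, sigma = par$sigma,
                   rel_error = max(rel))
  .match_cache[[key]] <- if (is.null(res)) "infeasible" else res
  res
}

# Draw from a truncated normal / log-normal. The default inverse-CDF route is
# exact for any degree of truncation (probabilities handled on the log scale
# in either tail); the rejection route redraws out-of-range values with a
# retry cap and is only practical when the truncation mass is moderate.
.sample_truncated <- function(n, mu, sigma, a, b, lognormal,
                              method = c("inverse", "rejection"),
                              max_retry = 1000) {
  method <- match.arg(method)
  if (method == "rejection") {
    draw <- function(k) {
      if (lognormal) stats::rlnorm(k, mu, sigma)
      else stats::rnorm(k, mu, sigma)
    }
    x <- draw(n)
    bad <- which(x < a | x > b)
    tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > max_retry) {
        stop("rejection sampling failed to land in [", a, ", ", b,
             "] after ", max_retry, " retries", call. = FALSE)
      }
      x[bad] <- draw(length(bad))
      bad <- bad[x[bad] < a | x[bad] > b]
    }
    return(x)
  }
  la <- if (lognormal) log(a) else a
  lb <- if (lognormal) log(b) else b
  alpha <- (la - mu) / sigma
  beta <- (lb - mu) / sigma
  u <- stats::runif(n)
  if (beta <= 0) {            # both bounds in the lower tail: log-scale CDF
    lpa <- stats::pnorm(alpha, log.p = TRUE)
    lZ <- .trunc_logmass(alpha, beta)
    lp <- .lse_add(rep(lpa, n), log(u) + lZ)
    z <- stats::qnorm(lp, log.p = TRUE)
  } else if (alpha >= 0) {    # both bounds in the upper tail: mirror
    lpb <- stats::pnorm(beta, lower.tail = FALSE, log.p = TRUE)
    lZ <- .trunc_logmass(alpha, beta)
    lp <- .lse_add(rep(lpb, n), log(u) + lZ)
    z <- -stats::qnorm(lp, log.p = TRUE)
  } else {                    # straddles the centre: direct probabilities
    pa <- stats::pnorm(alpha)
    pb <- stats::pnorm(beta)
    z <- stats::qnorm(pa + u * (pb - pa))
  }
  x <- mu + sigma * z
  x <- pmin(pmax(x, la), lb)  # guard against last-ulp rounding
  if (lognormal) exp(x) else x
}

#' Draw a panel of true analyte concentrations
#'
#' Samples `n` animals from the marginal distribution of each analyte:
#' truncated normal, or truncated log-normal for right-skewed analytes.
#' By default the underlying parameters are moment-matched so that the
#' truncated distribution reproduces the specified mean and SD; when the
#' requested moments are not attainable within the family, the sampler falls
#' back to truncating the distribution parameterised directly by the
#' specified mean/SD (`parameterisation = "naive"` forces that behaviour).
#'
#' @param specs List of [analyte_spec] objects (see [analyte_registry()]).
#' @param n Number of samples (animals); at least 2.
#' @param seed Integer seed; fixed seed gives a bit-identical panel.
#' @param parameterisation `"match"` (default) or `"naive"`, see Details.
#' @param sampling `"inverse"` (inverse-CDF, exact for any truncation,
#'   default) or `"rejection"` (redraw out-of-range values, retry cap 1000).
#' @return A `concentration_panel`: numeric matrix `n x n_analytes` with
#'   sample ids as rownames and analyte names as colnames; attributes carry
#'   units and the parameterisation actually used per analyte.
#' @export
#' @examples
#' panel <- sample_concentrations(analyte_registry(), n = 35, seed = 1)
#' colMeans(panel)[1:4]
sample_concentrations <- function(specs, n, seed,
                                  parameterisation = c("match", "naive"),
                                  sampling = c("inverse", "rejection")) {
  specs <- .check_specs(specs)
  parameterisation <- match.arg(parameterisation)
  sampling <- match.arg(sampling)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("n must be an integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  used <- character(length(specs))
  match_err <- rep(NA_real_, length(specs))
  cols <- vector("list", length(specs))
  # resolve parameterisations before seeding so the cached/uncached state of
  # the moment-matching solver cannot influence the random stream
  pars <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (sp$sd == 0) { used[j] <- "degenerate"; next }
    par <- if (parameterisation == "match") .match_truncation(sp) else NULL
    if (is.null(par)) {
      used[j] <- "naive"
      par <- .naive_params(sp)
    } else {
      used[j] <- "match"
      match_err[j] <- par$rel_error
    }
    pars[[j]] <- par
  }
  set.seed(as.integer(seed))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (used[j] == "degenerate") {
      cols[[j]] <- rep(sp$mean, n)
      next
    }
    cols[[j]] <- .sample_truncated(n, pars[[j]]$mu, pars[[j]]$sigma,
                                   sp$min, sp$max, sp$log_transformed,
                                   method = sampling)
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(sprintf("S%02d", seq_len(n)), names(specs))
  structure(values,
            units = vapply(specs, `[[`, character(1), "unit"),
            parameterisation = stats::setNames(used, names(specs)),
            match_rel_error = stats::setNames(match_err, names(specs)),
            class = c("concentration_panel", "matrix", "array"))
}

#' Perturb true concentrations into reference-assay values
#'
#' Emulates the between-run imprecision of the wet-chemistry reference
#' methods: each true value is multiplied by `1 + e`, where `e` is Gaussian
#' with standard deviation `assay_cv_percent / 100` for that analyte. The
#' output plays the role of the "calibrating values" a clinical analyzer
#' would report.
#'
#' @param panel A `concentration_panel` of true values.
#' @param specs Specs providing `assay_cv_percent` for every panel column.
#' @param seed Integer seed.
#' @return A `concentration_panel` of the same shape.
#' @export
make_reference_values <- function(panel, specs, seed) {
  specs <- .check_specs(specs)
  missing <- setdiff(colnames(panel), names(specs))
  if (length(missing)) {
    stop("no assay CV available for analyte(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- unclass(panel)
  for (j in seq_len(ncol(out))) {
    cv <- specs[[colnames(out)[j]]]$assay_cv_percent / 100
    if (cv > 0) {
      out[, j] <- out[, j] * (1 + stats::rnorm(nrow(out), 0, cv))
    }
  }
  attributes(out) <- attributes(panel)
  out
}

#' Pure-component absorption spectrum of one analyte
#'
#' A synthetic molar-absorptivity profile: a sum of Gaussian bands, each with
#' a centre (cm^-1), a full width parameter (Gaussian sigma, cm^-1) and an
#' amplitude in absorbance units per unit concentration. These profiles stand
#' in for real plasma absorptivities, which are not tabulated; they make the
#' Beer-Lambert forward model fully known so recovery can be verified.
#'
#' @param analyte Analyte name.
#' @param centers,widths,amplitudes Equal-length numeric vectors describing
#'   the Gaussian bands; amplitudes must be nonnegative.
#' @return A `pure_component` object.
#' @export
pure_component <- function(analyte, centers, widths, amplitudes) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(amplitudes))
  if (any(amplitudes < 0)) stop("band amplitudes must be >= 0", call. = FALSE)
  if (any(widths <= 0)) stop("band widths must be > 0", call. = FALSE)
  structure(list(analyte = analyte, centers = centers, widths = widths,
                 amplitudes = amplitudes),
            class = "pure_component")
}

# Evaluate a pure component's absorptivity on a wavenumber grid.
.component_profile <- function(comp, grid) {
  prof <- numeric(length(grid))
  for (i in seq_along(comp$centers)) {
    prof <- prof + comp$amplitudes[i] *
      exp(-0.5 * ((grid - comp$centers[i]) / comp$widths[i])^2)
  }
  prof
}

#' Default wavenumber grid
#'
#' Descending grid over the instrument range 5012-926 cm^-1 at a 4 cm^-1
#' step (1022 points; the last ladder point at this step is 928 cm^-1).
#'
#' @param from,to,by Grid limits and step (cm^-1).
#' @return Numeric vector, strictly decreasing.
#' @export
wavenumber_grid <- function(from = 5012, to = 926, by = 4) {
  seq(from, to, by = -abs(by))
}

#' Configuration of the spectral forward model
#'
#' @param grid Wavenumber grid (strictly monotone), see [wavenumber_grid()].
#' @param water_bands Matrix-like with columns center, width, amplitude;
#'   centres must lie inside the two water-absorption regions
#'   (3626.5-2970.7 and 1716.8-1543.2 cm^-1).
#' @param background_absorbance Flat background absorbance of the aqueous
#'   matrix and measurement cell, added to every spectrum (absorbance
#'   units). Keeping it above the noise level prevents the %T ceiling at
#'   100 from truncating noise excursions.
#' @param baseline_drift_sd SD of the per-sample additive baseline offset
#'   (absorbance units).
#' @param noise_sd SD of per-sample spectral noise shared by both replicates
#'   (absorbance units).
#' @param replicate_noise_sd SD of independent per-replicate noise
#'   (absorbance units).
#' @param seed Integer seed used by [simulate_spectra()].
#' @return A `forward_model_config` object.
#' @export
forward_model_config <- function(grid = wavenumber_grid(),
                                 water_bands = default_water_bands(),
                                 background_absorbance = 0.05,
                                 baseline_drift_sd = 0.002,
                                 noise_sd = 0.001,
                                 replicate_noise_sd = 0.002,
                                 seed = 1L) {
  d <- diff(grid)
  if (!(all(d > 0) || all(d < 0))) {
    stop("grid must be strictly monotone", call. = FALSE)
  }
  if (baseline_drift_sd < 0 || noise_sd < 0 || replicate_noise_sd < 0 ||
      background_absorbance < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  water_bands <- as.matrix(water_bands)
  if (nrow(water_bands)) {
    colnames(water_bands) <- c("center", "width", "amplitude")
    in_water <- (water_bands[, 1] >= 2970.7 & water_bands[, 1] <= 3626.5) |
      (water_bands[, 1] >= 1543.2 & water_bands[, 1] <= 1716.8)
    if (!all(in_water)) {
      stop("water band centres must lie inside the water-absorption regions",
           call. = FALSE)
    }
  }
  structure(list(grid = grid, water_bands = water_bands,
                 background_absorbance = background_absorbance,
                 baseline_drift_sd = baseline_drift_sd, noise_sd = noise_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "forward_model_config")
}

#' @rdname forward_model_config
#' @export
default_water_bands <- function() {
  cbind(center = c(3310, 1640), width = c(160, 45),
        amplitude = c(0.45, 0.35))
}

#' Default pure-component library for a panel of analytes
#'
#' Places, for each analyte, one Gaussian band in each of the three retained
#' spectral windows, on a deterministic lattice so that primary bands of
#' different analytes do not coincide. Band amplitudes scale inversely with
#' the analyte's population mean, so each analyte contributes comparably to
#' total absorbance at its typical concentration. Within the fingerprint
#' window the lattice avoids the 1481-1492 cm^-1 reference band so that
#' reference-band normalisation is not confounded by analyte signal.
#'
#' @param specs List of [analyte_spec]; one component is built per spec.
#' @param peak_absorbance Target absorbance contribution of one analyte at
#'   its mean concentration at the primary band centre (default 0.2 AU).
#' @param null_analytes Analytes whose bands get amplitude 0: their
#'   concentrations leave no trace in the spectra (negative controls).
#' @return Named list of [pure_component] objects.
#' @export
default_components <- function(specs, peak_absorbance = 0.2,
                               null_analytes = character()) {
  specs <- .check_specs(specs)
  m <- length(specs)
  # usable sub-ranges of the retained windows, with margins for band tails
  win <- rbind(c(2455, 2950), c(1740, 2250), c(985, 1455))
  widths <- c(10, 14, 18)
  relamp <- c(1, 0.6, 0.8)
  comps <- vector("list", m)
  for (j in seq_len(m)) {
    sp <- specs[[j]]
    # rotate which window holds the primary (largest) band
    ord <- ((j - 1L + 0:2) %% 3L) + 1L
    centers <- numeric(3); w <- numeric(3); a <- numeric(3)
    for (b in 1:3) {
      wi <- ord[b]
      frac <- (j - 0.5) / m
      # second and third bands offset along the lattice to break collinearity
      frac <- (frac + (b - 1) * 0.37) %% 1
      centers[b] <- win[wi, 1] + frac * (win[wi, 2] - win[wi, 1])
      w[b] <- widths[wi]
      a[b] <- relamp[b] * peak_absorbance / sp$mean
    }
    if (sp$name %in% null_analytes) a[] <- 0
    comps[[j]] <- pure_component(sp$name, centers, w, a)
  }
  stats::setNames(comps, names(specs))
}

#' Simulate paired duplicate FT-MIR transmittance spectra
#'
#' Beer-Lambert forward model: for each sample the absorbance at wavenumber
#' v is `A(v) = sum_j c_j * eps_j(v) + water(v) + baseline + noise(v)`, with
#' Gaussian band shapes in each `eps_j`; transmittance is
#' `%T = 100 * 10^(-A)`, clipped to (0, 100]. Two replicates per sample are
#' produced that differ only by independent replicate noise.
#'
#' @param panel `concentration_panel` of true concentrations.
#' @param components Named list of [pure_component], one per panel column.
#' @param config A [forward_model_config()].
#' @return A `synthetic_dataset`: list with `panel`, `spectra` (a
#'   `spectra_set`), `components` and `config`. Use [make_reference_values()]
#'   to add assay-noised calibrating values.
#' @export
simulate_spectra <- function(panel, components, config = forward_model_config()) {
  stopifnot(inherits(config, "forward_model_config"))
  analytes <- colnames(panel)
  missing <- setdiff(analytes, names(components))
  if (length(missing)) {
    stop("missing pure component(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- config$grid
  n <- nrow(panel)
  p <- length(grid)
  E <- t(vapply(analytes,
                function(a) .component_profile(components[[a]], grid),
                numeric(p)))                     # analytes x grid
  A0 <- unclass(panel) %*% E                     # samples x grid
  water <- numeric(p)
  if (nrow(config$water_bands)) {
    for (i in seq_len(nrow(config$water_bands))) {
      wb <- config$water_bands[i, ]
      water <- water + wb[3] * exp(-0.5 * ((grid - wb[1]) / wb[2])^2)
    }
  }
  set.seed(config$seed)
  baseline <- stats::rnorm(n, 0, config$baseline_drift_sd)
  sample_noise <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  A_common <- A0 + rep(water, each = n) + config$background_absorbance +
    baseline + sample_noise
  reps <- vector("list", 2L)
  for (r in 1:2) {
    eps <- matrix(stats::rnorm(n * p, 0, config$replicate_noise_sd), n, p)
    A <- A_common + eps
    tr <- pmin(100 * 10^(-A), 100)
    reps[[r]] <- pmax(tr, 1e-12)
  }
  transmittance <- rbind(reps[[1]], reps[[2]])
  sample_id <- rep(rownames(panel), times = 2L)
  replicate <- rep(1:2, each = n)
  ord <- order(match(sample_id, rownames(panel)), replicate)
  spectra <- spectra_set(sample_id[ord], replicate[ord], grid,
                         transmittance[ord, , drop = FALSE])
  structure(list(panel = panel, spectra = spectra,
                 components = components, config = config),
            class = "synthetic_dataset")
}

#' Generate a complete synthetic calibration study
#'
#' Convenience wrapper reproducing the study design: `n` plasma samples with
#' true concentrations for every registry analyte, reference values with
#' assay noise, and two replicate transmittance spectra per sample.
#'
#' @param n Number of samples (default 35).
#' @param specs Analyte specs (default: full registry).
#' @param seed Integer seed driving panel, assay noise and spectra.
#' @param components Pure-component library (default [default_components()]).
#' @param config Forward-model configuration; its seed is derived from
#'   `seed` unless supplied.
#' @param ... Passed to [default_components()] (e.g. `null_analytes`).
#' @return A `synthetic_dataset` with an extra `reference_panel` element.
#' @export
#' @examples
#' ds <- synthetic_study(n = 8, specs = analyte_registry(c("glucose", "urea")),
#'                       seed = 42)
#' dim(ds$spectra$transmittance)
synthetic_study <- function(n = 35, specs = analyte_registry(), seed = 1L,
                            components = NULL, config = NULL, ...) {
  seed <- as.integer(seed)
  specs <- .check_specs(specs)
  if (is.null(components)) components <- default_components(specs, ...)
  if (is.null(config)) config <- forward_model_config(seed = seed + 2L)
  panel <- sample_concentrations(specs, n, seed = seed)
  refs <- make_reference_values(panel, specs, seed = seed + 1L)
  ds <- simulate_spectra(panel, components, config)
  ds$reference_panel <- refs
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples x %d analytes, %d spectra (%d grid points)\n",
              nrow(x$panel), ncol(x$panel),
              nrow(x$spectra$transmittance), length(x$spectra$wavenumbers)))
  invisible(x)
}
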