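#' Configuration of an end-to-end calibration run
#'
#' Every field defaults to the study's stated choices: the three retained
#' spectral windows with the 1492-1481 cm^-1 reference band, grouped
#' leave-one-sample-out cross-validation (both replicates of a sample leave
#' together), up to 15 candidate factors, Shapiro alpha 0.05, randomization
#' test at alpha 0.10 with 1000 sign-flip draws.
#'
#' Input is either a pair of CSV paths (`spectra_csv`, `analytes_csv`), or a
#' `synthetic` spec (list of arguments for [synthetic_study()]), or data
#' passed directly to [run_pipeline()].
#'
#' @param spectra_csv,analytes_csv Optional input file paths (see
#'   [read_spectra_csv()] for the formats).
#' @param synthetic Optional list of arguments for [synthetic_study()]
#'   (e.g. `list(n = 35)`); the run seed is injected.
#' @param windows A [spectral_windows()] definition.
#' @param cv_scheme `"loso"` or `"kfold"`.
#' @param k_folds Fold count for `"kfold"`.
#' @param max_factors Largest candidate factor count.
#' @param shapiro_alpha Significance level of the non-normality screen.
#' @param test_alpha Significance level of the factor-selection test.
#' @param n_permutations Sign-flip draws per model comparison.
#' @param model_log_scale If `TRUE` (default), analytes flagged by the
#'   transform screen are additionally calibrated on the natural-log scale,
#'   mirroring the paired raw/ln report rows of the study layout.
#' @param seed Integer master seed for the run.
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   the report there via [write_report()].
#' @return A `run_config` list.
#' @export
run_config <- function(spectra_csv = NULL, analytes_csv = NULL,
                       synthetic = NULL, windows = spectral_windows(),
                       cv_scheme = c("loso", "kfold"), k_folds = 10,
                       max_factors = 15, shapiro_alpha = 0.05,
                       test_alpha = 0.10, n_permutations = 1000,
                       model_log_scale = TRUE, seed = 1L,
                       output_dir = NULL) {
  cv_scheme <- match.arg(cv_scheme)
  structure(list(spectra_csv = spectra_csv, analytes_csv = analytes_csv,
                 synthetic = synthetic, windows = windows,
                 cv_scheme = cv_scheme, k_folds = k_folds,
                 max_factors = max_factors, shapiro_alpha = shapiro_alpha,
                 test_alpha = test_alpha, n_permutations = n_permutations,
                 model_log_scale = model_log_scale, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

.load_run_data <- function(config, data) {
  if (!is.null(data)) {
    stopifnot(inherits(data$spectra, "spectra_set"),
              is.matrix(data$reference) || inherits(data$reference,
                                                    "concentration_panel"))
    return(list(spectra = data$spectra,
                reference = unclass(data$reference)))
  }
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- config$seed
    ds <- do.call(synthetic_study, args)
    return(list(spectra = ds$spectra, reference = unclass(ds$reference_panel)))
  }
  if (is.null(config$spectra_csv) || is.null(config$analytes_csv)) {
    stop("run_config needs input CSVs, a synthetic spec, or direct data",
         call. = FALSE)
  }
  list(spectra = read_spectra_csv(config$spectra_csv),
       reference = read_analytes_csv(config$analytes_csv))
}

# Calibrate one response vector against the shared feature matrix.
.calibrate_one <- function(X, y_row, groups, config, seed) {
  trace <- cross_validate(X, y_row, groups,
                          max_factors = config$max_factors,
                          scheme = config$cv_scheme, k = config$k_folds,
                          seed = seed)
  sel <- select_factors(trace, alpha = config$test_alpha,
                        n_perm = config$n_permutations, seed = seed)
  model <- suppressWarnings(fit_pls(X, y_row, n_factors = sel$chosen_k))
  list(trace = trace, selection = sel, model = model)
}

#' Run the full calibration pipeline
#'
#' For every analyte: non-normality screen and transform decision, grouped
#' cross-validation of a PLS calibration against the preprocessed
#' absorbance features, factor-count selection by minimum PRESS plus
#' parsimony, refit at the chosen count, quality metrics (R2, RMSECV, RER,
#' RPD with interpretation classes) and duplicate-based repeatability.
#' Analytes flagged as non-normal are additionally calibrated on the
#' natural-log scale.
#'
#' @param config A [run_config()].
#' @param data Optional list with elements `spectra` (a `spectra_set`) and
#'   `reference` (sample x analyte matrix of calibrating values), bypassing
#'   file/synthetic input.
#' @return A `study_report`: `descriptive` and `quality` data.frames
#'   (population-statistics and calibration-statistics layouts),
#'   `transforms`, `scatter` (per-sample measured vs predicted), `models`,
#'   `config`, `log`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(synthetic = list(n = 12,
#'                   specs = analyte_registry(c("glucose", "total_protein"))),
#'                   max_factors = 6, n_permutations = 199, seed = 3)
#' rep <- run_pipeline(cfg)
#' rep$quality[, c("analyte", "scale", "extracted_factors", "r2", "rpd")]
#' }
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  inputs <- .load_run_data(config, data)
  spectra <- inputs$spectra
  reference <- inputs$reference
  missing <- setdiff(unique(spectra$sample_id), rownames(reference))
  if (length(missing)) {
    stop("analyte table lacks sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  reps_per_sample <- table(spectra$sample_id)
  has_duplicates <- all(reps_per_sample == 2)
  if (!has_duplicates) {
    note("not every sample has exactly 2 replicates; repeatability skipped")
  }
  feats <- preprocess_spectra(spectra, config$windows)
  note("retained %d of %d wavenumbers after window selection",
       length(feats$wavenumbers), length(spectra$wavenumbers))
  X <- feats$absorbance
  groups <- feats$sample_id
  y_all <- reference[groups, , drop = FALSE]
  analytes <- colnames(reference)

  desc_rows <- list(); qual_rows <- list(); trans_rows <- list()
  scatter_rows <- list(); models <- list()
  for (ai in seq_along(analytes)) {
    an <- analytes[ai]
    y_sample <- reference[, an]          # one value per sample
    dec <- decide_transform(y_sample, alpha = config$shapiro_alpha)
    trans_rows[[an]] <- data.frame(analyte = an, shapiro_p = dec$shapiro_p,
                                   transformed = dec$transformed,
                                   transform = dec$transform)
    note("%s: Shapiro p = %.3g -> %s", an, dec$shapiro_p, dec$transform)
    scales <- "raw"
    if (config$model_log_scale && dec$transformed &&
        dec$transform == "log") {
      scales <- c(scales, "ln")
    }
    for (sc in scales) {
      y_row <- if (sc == "ln") log(y_all[, an]) else y_all[, an]
      y_per_sample <- if (sc == "ln") log(y_sample) else y_sample
      stats_y <- descriptive_stats(y_per_sample)
      seed_a <- config$seed + 1000L * ai + ifelse(sc == "ln", 500L, 0L)
      cal <- .calibrate_one(X, y_row, groups, config, seed_a)
      kch <- cal$selection$chosen_k
      pred_cv <- cal$trace$predictions[, kch]
      rmsecv <- cal$trace$rmsecv[kch]
      r2 <- r_squared(y_row, pred_cv)
      rer_v <- rer(stats_y, rmsecv)
      rpd_v <- rpd(stats_y, rmsecv)
      cls <- classify_quality(r2, rer_v, rpd_v)
      note("%s [%s]: k = %d (min-PRESS %d), RMSECV = %.4g, R2 = %.3f",
           an, sc, kch, cal$selection$k_min_press, rmsecv, r2)
      if (has_duplicates) {
        pred_all <- predict(cal$model, X)
        ids <- unique(groups)
        p1 <- pred_all[match(paste(ids, 1), paste(groups, feats$replicate))]
        p2 <- pred_all[match(paste(ids, 2), paste(groups, feats$replicate))]
        rep_res <- repeatability(p1, p2)
      } else {
        rep_res <- list(s_r = NA_real_, rsd_r_percent = NA_real_)
      }
      label <- if (sc == "ln") paste0("ln_", an) else an
      desc_rows[[label]] <- data.frame(
        analyte = an, scale = sc, n = stats_y$n, mean = stats_y$mean,
        sd = stats_y$sd, cv_percent = stats_y$cv_percent, min = stats_y$min,
        max = stats_y$max, range = stats_y$range, median = stats_y$median,
        skewness = stats_y$skewness, kurtosis = stats_y$kurtosis)
      qual_rows[[label]] <- data.frame(
        analyte = an, scale = sc, extracted_factors = kch,
        k_min_press = cal$selection$k_min_press, r2 = r2, rmsecv = rmsecv,
        rer = rer_v, rpd = rpd_v,
        r2_class = as.character(cls$r2_class),
        rer_class = as.character(cls$rer_class),
        rpd_class = as.character(cls$rpd_class),
        s_r = rep_res$s_r, rsd_r_percent = rep_res$rsd_r_percent)
      ids <- unique(groups)
      pred_by_sample <- tapply(pred_cv, groups, mean)[ids]
      scatter_rows[[label]] <- data.frame(
        analyte = an, scale = sc, sample_id = ids,
        measured = y_per_sample[ids], predicted = as.numeric(pred_by_sample))
      models[[label]] <- list(model = cal$model, selection = cal$selection,
                              rmsecv_by_k = cal$trace$rmsecv,
                              press_by_k = cal$trace$press)
    }
  }
  report <- structure(
    list(descriptive = do.call(rbind, c(desc_rows, make.row.names = FALSE)),
         quality = do.call(rbind, c(qual_rows, make.row.names = FALSE)),
         transforms = do.call(rbind, c(trans_rows, make.row.names = FALSE)),
         scatter = do.call(rbind, c(scatter_rows, make.row.names = FALSE)),
         models = models, config = config, log = log_lines),
    class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d analyte model(s)\n", nrow(x$quality)))
  print(utils::head(display_quality(x), 10))
  invisible(x)
}

#' Display-rounded calibration table
#'
#' Applies the report's display rounding (factors as integers, R2 to 2
#' decimals, RMSECV and S_r to 4, RER/RPD to 1, CV and RSD_r to 2) without
#' altering the stored full-precision values.
#'
#' @param report A `study_report`.
#' @return A data.frame in the calibration-statistics layout.
#' @export
display_quality <- function(report) {
  q <- report$quality
  data.frame(analyte = q$analyte, scale = q$scale,
             extracted_factors = q$extracted_factors,
             r2 = round(q$r2, 2), rmsecv = round(q$rmsecv, 4),
             rer = round(q$rer, 1), rpd = round(q$rpd, 1),
             s_r = round(q$s_r, 4),
             rsd_r_percent = round(q$rsd_r_percent, 2))
}

#' Write a study report to disk
#'
#' Emits the full-precision tables as CSV, a display-rounded calibration
#' table, the whole report as JSON (full precision), the resolved
#' configuration as YAML and the run log.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_full(report$descriptive, file.path(dir, "descriptive.csv"))
  .write_csv_full(report$quality, file.path(dir, "quality.csv"))
  utils::write.csv(display_quality(report),
                   file.path(dir, "quality_display.csv"), row.names = FALSE)
  .write_csv_full(report$transforms, file.path(dir, "transforms.csv"))
  .write_csv_full(report$scatter, file.path(dir, "scatter.csv"))
  payload <- list(descriptive = report$descriptive,
                  quality = report$quality,
                  transforms = report$transforms,
                  scatter = report$scatter)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  cfg <- report$config
  cfg$windows <- list(retained = cfg$windows$retained,
                      reference_band = cfg$windows$reference_band,
                      reference_stat = cfg$windows$reference_stat)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "config.yaml"))
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Re-read a written report and check its internal metric identities
#'
#' Reloads `report.json` and verifies that `rpd * range == rer * sd` (both
#' equal `1/rmsecv` times range*sd/...) holds for every row, and returns
#' the reloaded tables.
#'
#' @param dir Directory written by [write_report()].
#' @param tol Numeric tolerance for the identity check.
#' @return List of tables with an added attribute `identity_ok`.
#' @export
read_report_json <- function(dir, tol = 1e-8) {
  payload <- jsonlite::read_json(file.path(dir, "report.json"),
                                 simplifyVector = TRUE)
  q <- payload$quality
  d <- payload$descriptive
  key <- paste(q$analyte, q$scale)
  dkey <- paste(d$analyte, d$scale)
  rng <- d$range[match(key, dkey)]
  sdv <- d$sd[match(key, dkey)]
  ok <- all(abs(q$rpd * rng - q$rer * sdv) <=
              tol * pmax(abs(q$rpd * rng), 1))
  attr(payload, "identity_ok") <- ok
  payload
}
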