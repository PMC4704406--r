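#' Distribution specification for one plasma analyte
#'
#' Bundles the marginal distribution of an analyte across clinically healthy
#' cows (mean, SD, observed min/max), whether the analyte is modelled on the
#' natural-log scale, and the between-run coefficient of variation of the
#' wet-chemistry reference assay used to measure it.
#'
#' @param name Analyte identifier (snake_case, e.g. `"total_protein"`).
#' @param unit Measurement unit as printed in clinical reports
#'   (e.g. `"g/L"`, `"mmol/L"`).
#' @param mean,sd Population mean and standard deviation, in `unit`.
#' @param min,max Truncation bounds: values outside `[min, max]` are never
#'   generated, mirroring the observed range of the study population.
#' @param log_transformed Logical; `TRUE` for right-skewed analytes that are
#'   simulated log-normally and calibrated on the natural-log scale.
#' @param assay_cv_percent Between-run CV (%) of the reference assay; used as
#'   the relative noise level when perturbing true values into reference
#'   values.
#' @param label Optional pretty display label (defaults to `name`).
#'
#' @return An object of class `analyte_spec`.
#' @export
#' @examples
#' analyte_spec("glucose", "mmol/L", mean = 4.02, sd = 0.67,
#'              min = 1.66, max = 6.20, assay_cv_percent = 1.50)
analyte_spec <- function(name, unit, mean, sd, min, max,
                         log_transformed = FALSE, assay_cv_percent = 0,
                         label = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(sd) || sd < 0) {
    stop("analyte '", name, "': sd must be a nonnegative number", call. = FALSE)
  }
  if (!is.numeric(assay_cv_percent) || assay_cv_percent < 0) {
    stop("analyte '", name, "': assay_cv_percent must be nonnegative",
         call. = FALSE)
  }
  if (min > mean || mean > max) {
    stop("analyte '", name, "': need min <= mean <= max", call. = FALSE)
  }
  if (log_transformed && min <= 0) {
    stop("analyte '", name, "': log-scale analytes need min > 0", call. = FALSE)
  }
  structure(
    list(name = name, unit = unit, mean = mean, sd = sd, min = min, max = max,
         log_transformed = log_transformed,
         assay_cv_percent = assay_cv_percent, label = label),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s [%s]: mean %.4g, sd %.4g, range [%.4g, %.4g]%s, assay CV %.4g%%\n",
              x$name, x$unit, x$mean, x$sd, x$min, x$max,
              if (x$log_transformed) ", log-scale" else "",
              x$assay_cv_percent))
  invisible(x)
}

# Registry rows: population statistics of the 22-item bovine plasma metabolic
# profile (35 clinically healthy Friesian cows) and the between-run CV of each
# reference assay. Zn and globulin have no published assay CV; 2.0% is the
# package default for an endpoint assay. Globulin is total protein minus
# albumin in practice but is carried as a first-class analyte here.
.analyte_table <- function() {
  tab <- rbind(
    # name               unit       mean    sd     min    max     log  cv
    c("glucose",          "mmol/L", 4.02,   0.67,  1.66,  6.20,   0, 1.50),
    c("total_cholesterol","mmol/L", 3.36,   1.59,  0.80,  5.87,   0, 2.10),
    c("nefa",             "mmol/L", 0.33,   0.29,  0.06,  1.18,   1, 1.50),
    c("bhba",             "mmol/L", 0.49,   0.13,  0.28,  0.85,   1, 5.25),
    c("urea",             "mmol/L", 4.21,   1.42,  1.50,  7.52,   0, 1.20),
    c("creatinine",       "umol/L", 99.54, 10.67, 83.62, 125.89,  0, 5.40),
    c("ca",               "mmol/L", 2.58,   0.12,  2.36,  2.86,   0, 1.40),
    c("p_inorganic",      "mmol/L", 1.81,   0.35,  1.19,  2.89,   0, 2.00),
    c("mg",               "mmol/L", 1.02,   0.10,  0.57,  1.12,   0, 1.40),
    c("na",               "mmol/L", 144.20, 3.44, 138.78, 151.78, 0, 0.90),
    c("k",                "mmol/L", 4.07,   0.20,  3.59,  4.57,   0, 1.30),
    c("cl",               "mmol/L", 107.51, 2.48, 102.27, 112.98, 0, 1.50),
    c("zn",               "umol/L", 11.43,  2.71,  5.17, 16.19,   0, 2.00),
    c("ceruloplasmin",    "umol/L", 3.24,   1.02,  1.99,  6.63,   0, 3.48),
    c("total_protein",    "g/L",    76.07,  6.27, 63.57, 86.89,   0, 1.20),
    c("albumin",          "g/L",    35.90,  2.65, 25.79, 39.55,   0, 1.80),
    c("globulin",         "g/L",    40.05,  6.33, 27.99, 52.08,   0, 2.00),
    c("total_bilirubin",  "umol/L", 3.98,   4.63,  0.29, 22.48,   1, 6.70),
    c("haptoglobin",      "g/L",    0.25,   0.27,  0.03,  0.91,   1, 13.54),
    c("ast",              "U/L",   106.67, 69.78, 49.98, 394.07,  1, 2.10),
    c("ggt",              "U/L",    28.78,  9.66, 16.27, 63.94,   1, 3.72),
    c("ap",               "U/L",    50.85, 22.75, 21.44, 103.73,  1, 1.70)
  )
  data.frame(
    name = tab[, 1], unit = tab[, 2],
    mean = as.numeric(tab[, 3]), sd = as.numeric(tab[, 4]),
    min = as.numeric(tab[, 5]), max = as.numeric(tab[, 6]),
    log_transformed = as.numeric(tab[, 7]) == 1,
    assay_cv_percent = as.numeric(tab[, 8]),
    stringsAsFactors = FALSE
  )
}

#' Built-in registry of plasma metabolic-profile analytes
#'
#' The default panel of 22 blood biochemistry analytes used for the dairy-cow
#' metabolic profile: energy metabolites (glucose, cholesterol, NEFA, BHBA),
#' protein metabolism (urea, creatinine, total protein, albumin, globulin),
#' minerals/electrolytes (Ca, P, Mg, Na, K, Cl, Zn), inflammation markers
#' (ceruloplasmin, haptoglobin, total bilirubin) and enzymes (AST, GGT, AP).
#' Right-skewed analytes (NEFA, BHBA, total bilirubin, haptoglobin, AST, GGT,
#' AP) carry `log_transformed = TRUE` and are simulated log-normally.
#'
#' @param names Optional character vector restricting (and ordering) the
#'   returned analytes.
#' @return A named list of [analyte_spec] objects.
#' @export
#' @examples
#' specs <- analyte_registry()
#' names(specs)
#' analyte_registry("glucose")[[1]]
analyte_registry <- function(names = NULL) {
  tab <- .analyte_table()
  if (!is.null(names)) {
    missing <- setdiff(names, tab$name)
    if (length(missing)) {
      stop("unknown analyte(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tab <- tab[match(names, tab$name), , drop = FALSE]
  }
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    with(tab[i, ], analyte_spec(name, unit, mean, sd, min, max,
                                log_transformed, assay_cv_percent))
  })
  stats::setNames(specs, tab$name)
}

.check_specs <- function(specs) {
  if (inherits(specs, "analyte_spec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "analyte_spec")
  if (!all(ok)) stop("specs must be a list of analyte_spec objects",
                     call. = FALSE)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  }
  specs
}
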