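#' Read and write spectra and analyte tables as CSV
#'
#' Spectra CSV is wide: columns `sample_id`, `replicate`, then one numeric
#' wavenumber label per column in monotone order. The analyte CSV holds
#' `sample_id` followed by one column per analyte. `read/write` round-trip
#' to full double precision (values are serialised with 17 significant
#' digits).
#'
#' @param path File path.
#' @return `read_spectra_csv()` returns a `spectra_set`;
#'   `read_analytes_csv()` a `concentration_panel`-style matrix with sample
#'   ids as rownames.
#' @name spectra_io
NULL

#' @rdname spectra_io
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(colnames(df)[1:2],
                                 c("sample_id", "replicate"))) {
    stop("spectra CSV must start with columns sample_id, replicate",
         call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(colnames(df)[-(1:2)]))
  if (any(is.na(wn))) {
    stop("non-numeric wavenumber label(s) in spectra CSV header",
         call. = FALSE)
  }
  d <- diff(wn)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber labels must be strictly monotone", call. = FALSE)
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(values) || anyNA(values)) {
    stop("non-numeric transmittance cell(s) in spectra CSV", call. = FALSE)
  }
  spectra_set(df$sample_id, df$replicate, wn, values)
}

#' @rdname spectra_io
#' @param x Object to write (a `spectra_set` / analyte matrix).
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_id, replicate = x$replicate,
                   check.names = FALSE)
  vals <- as.data.frame(x$transmittance)
  colnames(vals) <- format(x$wavenumbers, trim = TRUE, digits = 15)
  out <- cbind(df, vals)
  .write_csv_full(out, path)
  invisible(path)
}

#' @rdname spectra_io
#' @export
read_analytes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || colnames(df)[1] != "sample_id") {
    stop("analyte CSV must start with a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in analyte CSV", call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values) || anyNA(values)) {
    stop("non-numeric concentration cell(s) in analyte CSV", call. = FALSE)
  }
  rownames(values) <- df$sample_id
  values
}

#' @rdname spectra_io
#' @export
write_analytes_csv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(x), check.names = FALSE))
  .write_csv_full(df, path)
  invisible(path)
}

# CSV writer preserving full double precision.
.write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
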