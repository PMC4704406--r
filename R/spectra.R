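#' A set of transmittance spectra on a shared wavenumber grid
#'
#' Matrix-backed container: one row per (sample, replicate) spectrum, one
#' column per wavenumber. Transmittance is percent, in (0, 100].
#'
#' @param sample_id Character vector of sample identifiers (one per row).
#' @param replicate Integer replicate index per row.
#' @param wavenumbers Monotone numeric grid (cm^-1).
#' @param transmittance Numeric matrix, rows x wavenumbers.
#' @return A `spectra_set` object.
#' @export
spectra_set <- function(sample_id, replicate, wavenumbers, transmittance) {
  transmittance <- as.matrix(transmittance)
  if (length(sample_id) != nrow(transmittance) ||
      length(replicate) != nrow(transmittance)) {
    stop("sample_id/replicate must have one entry per spectrum", call. = FALSE)
  }
  if (length(wavenumbers) != ncol(transmittance)) {
    stop("wavenumbers must have one entry per column", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  }
  key <- paste(sample_id, replicate, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, replicate) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(transmittance)) || any(transmittance <= 0)) {
    stop("transmittance values must be finite and strictly positive",
         call. = FALSE)
  }
  dimnames(transmittance) <- list(key, format(wavenumbers, trim = TRUE))
  structure(list(sample_id = as.character(sample_id),
                 replicate = as.integer(replicate),
                 wavenumbers = as.numeric(wavenumbers),
                 transmittance = transmittance),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra (%d samples), %d wavenumbers in %.1f..%.1f cm^-1\n",
              nrow(x$transmittance), length(unique(x$sample_id)),
              length(x$wavenumbers), max(x$wavenumbers), min(x$wavenumbers)))
  invisible(x)
}

#' Extract one spectrum from a set
#'
#' @param x A `spectra_set`.
#' @param sample_id,replicate Key of the spectrum.
#' @return A list with `sample_id`, `replicate`, `wavenumbers`,
#'   `transmittance` (vector).
#' @export
get_spectrum <- function(x, sample_id, replicate = 1L) {
  i <- which(x$sample_id == sample_id & x$replicate == replicate)
  if (length(i) != 1L) {
    stop("no spectrum for (", sample_id, ", ", replicate, ")", call. = FALSE)
  }
  list(sample_id = sample_id, replicate = as.integer(replicate),
       wavenumbers = x$wavenumbers, transmittance = x$transmittance[i, ])
}
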