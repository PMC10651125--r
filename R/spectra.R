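#' Construct a single Raman spectrum
#'
#' A spectrum is the atomic unit of every pipeline stage: one strictly
#' increasing wavenumber axis (cm^-1) plus an intensity series of the same
#' length, with free-form metadata (sample id, class label, map position).
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`.
#' @param meta Named list of metadata (e.g. `sample_id`, `class`, `x`, `y`).
#' @return An object of class `"raman_spectrum"`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least 2 channels", call. = FALSE)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity lengths differ (",
         length(wavenumber), " vs ", length(intensity), ")", call. = FALSE)
  if (any(!is.finite(wavenumber)) || any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be finite and strictly increasing",
         call. = FALSE)
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 meta = as.list(meta)),
            class = "raman_spectrum")
}

#' Construct a spectral map
#'
#' A spectral map is an ordered collection of spectra sharing one wavenumber
#' axis — typically the Raman surface map of a single tissue sample. Stored
#' column-wise: one column per spectrum.
#'
#' @param wavenumber Shared wavenumber axis (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, `length(wavenumber)` rows, one column
#'   per spectrum.
#' @param meta Data frame with one row per spectrum (may carry `sample_id`,
#'   `class`, and map positions `x`, `y`). Optional.
#' @return An object of class `"spectral_map"`.
#' @export
spectral_map <- function(wavenumber, intensities, meta = NULL) {
  wavenumber <- as.numeric(wavenumber)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) < 1L) stop("empty spectral map", call. = FALSE)
  if (nrow(intensities) != length(wavenumber))
    stop("intensity matrix must have one row per wavenumber", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(ncol(intensities)))
  if (nrow(meta) != ncol(intensities))
    stop("meta must have one row per spectrum", call. = FALSE)
  structure(list(wavenumber = wavenumber, intensities = intensities,
                 meta = meta),
            class = "spectral_map")
}

#' Number of spectra in a map
#' @param map A `spectral_map`.
#' @return Integer count.
#' @export
n_spectra <- function(map) ncol(map$intensities)

#' Extract one spectrum from a map
#' @param map A `spectral_map`.
#' @param i Column index.
#' @return A `raman_spectrum`.
#' @export
map_spectrum <- function(map, i) {
  raman_spectrum(map$wavenumber, map$intensities[, i],
                 meta = as.list(map$meta[i, , drop = FALSE]))
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat("Raman spectrum: ", length(x$wavenumber), " channels, ",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1\n", sep = "")
  if (length(x$meta))
    cat("  meta: ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.spectral_map <- function(x, ...) {
  cat("Spectral map: ", n_spectra(x), " spectra x ",
      length(x$wavenumber), " channels (",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm^-1)\n", sep = "")
  invisible(x)
}

# trapezoidal integral over the spectral axis
trapz_integral <- function(wavenumber, intensity) {
  pracma::trapz(wavenumber, intensity)
}

# evaluate an expression under a temporary RNG seed, restoring session state;
# seed = NULL consumes the session stream as usual
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-stage seed below 2^31 from a global seed and a stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}
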