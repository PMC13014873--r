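#' Senescence class labels
#'
#' The six visual senescence classes, ordered from healthy to fully
#' senesced: HOL (healthy), MinSOL-H and ModSOL-H (visually green tissue on
#' partly senesced leaves), MinSOL and ModSOL (minimal / moderate
#' yellowing-browning) and SOL (fully browned, pre-abscission).
#'
#' @return character vector of the six class labels in senescence order
#' @export
senescence_classes <- function() {
  c("HOL", "MinSOL-H", "ModSOL-H", "MinSOL", "ModSOL", "SOL")
}

#' Construct a single Raman spectrum
#'
#' A spectrum is a strictly increasing wavenumber grid (cm^-1) with one
#' intensity (a.u.) per grid point plus acquisition metadata.
#'
#' @param wavenumber numeric vector, strictly increasing, cm^-1
#' @param intensity numeric vector, same length, a.u.
#' @param sample_id,map_id,class optional metadata
#' @return object of class `raman_spectrum`
#' @export
spectrum <- function(wavenumber, intensity, sample_id = NA_character_,
                     map_id = NA_character_, class = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  if (!all(is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         meta = list(sample_id = sample_id, map_id = map_id, class = class)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm^-1", length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (!is.na(x$meta$sample_id)) cat(" [", x$meta$sample_id, "]", sep = "")
  if (!is.na(x$meta$class)) cat(" class =", x$meta$class)
  cat("\n")
  invisible(x)
}

#' Construct a labelled collection of spectra on a common grid
#'
#' @param wavenumbers common grid, strictly increasing, cm^-1
#' @param intensities numeric matrix, one row per spectrum (a.u.)
#' @param meta data.frame with columns `sample_id`, `map_id`, `class`
#' @return object of class `raman_dataset`
#' @export
spectral_dataset <- function(wavenumbers, intensities, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers))
    stop("intensity columns must match the wavenumber grid", call. = FALSE)
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "map_id", "class")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("meta lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != nrow(intensities))
    stop("meta rows must match spectra", call. = FALSE)
  rownames(intensities) <- meta$sample_id
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta),
            class = "raman_dataset")
}

#' @export
print.raman_dataset <- function(x, ...) {
  cat(sprintf("<raman_dataset> %d spectra x %d points, %.0f-%.0f cm^-1\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (!all(is.na(x$meta$class)))
    print(table(x$meta$class))
  invisible(x)
}

#' Number of spectra in a dataset
#' @param ds a `raman_dataset`
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Extract one spectrum from a dataset
#' @param ds a `raman_dataset`
#' @param i row index or sample_id
#' @export
get_spectrum <- function(ds, i) {
  if (is.character(i)) i <- match(i, ds$meta$sample_id)
  if (is.na(i) || i < 1L || i > n_spectra(ds))
    stop("no such spectrum", call. = FALSE)
  spectrum(ds$wavenumbers, ds$intensities[i, ],
           sample_id = ds$meta$sample_id[i], map_id = ds$meta$map_id[i],
           class = ds$meta$class[i])
}

#' Apply a per-spectrum transformation across a dataset
#' @param ds a `raman_dataset`
#' @param f function taking and returning a `raman_spectrum`
#' @param ... passed to `f`
#' @return transformed `raman_dataset` (grid taken from the first result)
#' @export
map_spectra <- function(ds, f, ...) {
  out <- lapply(seq_len(n_spectra(ds)), function(i) f(get_spectrum(ds, i), ...))
  wn <- out[[1L]]$wavenumber
  mat <- do.call(rbind, lapply(out, function(s) s$intensity))
  spectral_dataset(wn, mat, ds$meta)
}
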