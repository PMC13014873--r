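# Dataset input/output
#
# Two on-disk formats are supported:
#  * "long": a single TSV with columns sample_id, map_id, class,
#    wavenumber_cm1, intensity_au
#  * "csvdir": a directory of per-spectrum two-column CSVs
#    (wavenumber_cm1, intensity_au) plus a manifest.tsv carrying metadata

#' Write a spectral dataset to disk
#'
#' @param ds a `raman_dataset`
#' @param path output file (long TSV) or directory (per-spectrum CSVs)
#' @param format `"long"` or `"csvdir"`
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path, format = c("long", "csvdir")) {
  format <- match.arg(format)
  if (format == "long") {
    n <- n_spectra(ds)
    p <- length(ds$wavenumbers)
    dt <- data.table::data.table(
      sample_id = rep(ds$meta$sample_id, each = p),
      map_id = rep(ds$meta$map_id, each = p),
      class = rep(ds$meta$class, each = p),
      wavenumber_cm1 = rep(ds$wavenumbers, n),
      intensity_au = as.vector(t(ds$intensities)))
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ds$meta$sample_id), ".csv")
    for (i in seq_len(n_spectra(ds))) {
      data.table::fwrite(
        data.table::data.table(wavenumber_cm1 = ds$wavenumbers,
                               intensity_au = ds$intensities[i, ]),
        file.path(path, files[i]))
    }
    mf <- data.frame(sample_id = ds$meta$sample_id, map_id = ds$meta$map_id,
                     class = ds$meta$class, file = files,
                     stringsAsFactors = FALSE)
    data.table::fwrite(mf, file.path(path, "manifest.tsv"), sep = "\t")
  }
  invisible(path)
}

check_numeric_column <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric %s at data line %d of %s: '%s'",
                 col, bad[1L], path, x[bad[1L]]), call. = FALSE)
  v
}

#' Read a spectral dataset from disk
#'
#' Spectra must share a common strictly increasing grid unless
#' `resample = TRUE`, in which case all spectra are linearly interpolated
#' onto the union grid.
#'
#' @param path long-format TSV file or per-spectrum CSV directory
#' @param format `"long"` or `"csvdir"`
#' @param resample allow mixed grids (union grid + linear interpolation)
#' @return a `raman_dataset`
#' @export
read_dataset <- function(path, format = c("long", "csvdir"),
                         resample = FALSE) {
  format <- match.arg(format)
  if (format == "long") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    dt <- data.table::fread(path, sep = "\t", colClasses = "character")
    need <- c("sample_id", "map_id", "class", "wavenumber_cm1",
              "intensity_au")
    missing_cols <- setdiff(need, names(dt))
    if (length(missing_cols))
      stop("malformed dataset, missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    wn <- check_numeric_column(dt$wavenumber_cm1, "wavenumber", path)
    it <- check_numeric_column(dt$intensity_au, "intensity", path)
    ids <- unique(dt$sample_id)
    specs <- lapply(ids, function(id) {
      sel <- dt$sample_id == id
      list(w = wn[sel], y = it[sel],
           map_id = dt$map_id[sel][1L], class = dt$class[sel][1L])
    })
  } else {
    mfp <- file.path(path, "manifest.tsv")
    if (!file.exists(mfp)) stop("no manifest.tsv in ", path, call. = FALSE)
    mf <- data.table::fread(mfp, sep = "\t", colClasses = "character")
    ids <- mf$sample_id
    specs <- lapply(seq_len(nrow(mf)), function(i) {
      f <- file.path(path, mf$file[i])
      d <- data.table::fread(f, colClasses = "character")
      list(w = check_numeric_column(d$wavenumber_cm1, "wavenumber", f),
           y = check_numeric_column(d$intensity_au, "intensity", f),
           map_id = mf$map_id[i], class = mf$class[i])
    })
  }
  for (i in seq_along(specs))
    if (any(diff(specs[[i]]$w) <= 0))
      stop("non-monotone wavenumber grid in record '", ids[i], "'",
           call. = FALSE)
  grids <- lapply(specs, `[[`, "w")
  same <- all(vapply(grids, function(g)
    identical(length(g), length(grids[[1L]])) && all(g == grids[[1L]]),
    logical(1)))
  if (same) {
    wn <- grids[[1L]]
    mat <- do.call(rbind, lapply(specs, `[[`, "y"))
  } else if (!resample) {
    j <- which(!vapply(grids, function(g)
      identical(length(g), length(grids[[1L]])) && all(g == grids[[1L]]),
      logical(1)))[1L]
    stop("record '", ids[j], "' is on a different grid; ",
         "pass resample = TRUE to interpolate onto the union grid",
         call. = FALSE)
  } else {
    wn <- sort(unique(unlist(grids)))
    mat <- do.call(rbind, lapply(specs, function(s)
      stats::approx(s$w, s$y, xout = wn, rule = 2)$y))
  }
  meta <- data.frame(
    sample_id = ids,
    map_id = vapply(specs, `[[`, character(1), "map_id"),
    class = vapply(specs, `[[`, character(1), "class"),
    stringsAsFactors = FALSE)
  spectral_dataset(wn, mat, meta)
}

#' Write an RGB patch as a plain-text PPM (P3) image
#'
#' PPM is used instead of PNG because it is a plain-text raster format
#' requiring no compression codec.
#'
#' @param patch an `rgb_patch` (integer array h x w x 3 in \[0, 255\])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ppm <- function(patch, path) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L)
    stop("patch must be an h x w x 3 array", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  # one pixel row per line, R G B triples left to right
  for (i in seq_len(d[1])) {
    trip <- rbind(patch[i, , 1], patch[i, , 2], patch[i, , 3])
    writeLines(paste(as.vector(trip), collapse = " "), con)
  }
  invisible(path)
}

#' Read a plain-text PPM (P3) image written by [write_ppm()]
#' @param path PPM file
#' @return integer array h x w x 3
#' @export
read_ppm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1L], collapse = " "), quiet = TRUE)
  w <- tok[1L]; h <- tok[2L]
  vals <- tok[-(1:3)]
  px <- array(0L, dim = c(h, w, 3))
  m <- matrix(as.integer(vals), nrow = 3)
  k <- 1L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    px[i, j, ] <- m[, k]; k <- k + 1L
  }
  structure(px, class = "rgb_patch")
}
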