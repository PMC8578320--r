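#' Construct a plate of absorbance spectra
#'
#' A `spectra_plate` holds one absorbance spectrum per well on a shared,
#' strictly increasing wavelength grid (typically 220-700 nm at 1 nm steps).
#'
#' @param wavelengths numeric vector of wavelengths, nm, strictly increasing.
#' @param absorbance numeric matrix, one row per well, columns matching
#'   `wavelengths`.
#' @param wells character vector of unique well ids (row names).
#' @param metadata optional named list (instrument, temperature, timestamp).
#' @return object of class `"spectra_plate"`.
#' @export
spectra_plate <- function(wavelengths, absorbance, wells, metadata = list()) {
  absorbance <- as.matrix(absorbance)
  if (length(wavelengths) != ncol(absorbance)) {
    stop("absorbance must have one column per wavelength")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (anyDuplicated(wells)) stop("well ids must be unique")
  if (length(wells) != nrow(absorbance)) {
    stop("need one well id per spectrum")
  }
  if (!all(is.finite(absorbance))) stop("absorbance values must be finite")
  dimnames(absorbance) <- list(wells, NULL)
  structure(list(wavelengths = as.numeric(wavelengths), absorbance = absorbance,
                 metadata = metadata),
            class = "spectra_plate")
}

#' @export
print.spectra_plate <- function(x, ...) {
  cat(sprintf("spectra_plate: %d wells, %d wavelengths (%g-%g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$layout)) {
    cat(sprintf("  annotated: %d sample, %d blank wells\n",
                sum(x$layout$role == "sample"), sum(x$layout$role == "blank")))
  }
  invisible(x)
}

wells_of <- function(plate) rownames(plate$absorbance)

#' Extract one well's spectrum
#' @param plate a [spectra_plate()].
#' @param well well id.
#' @return list of class `"spectrum_read"` with `well`, `wavelengths`,
#'   `absorbance`.
#' @export
get_read <- function(plate, well) {
  if (!well %in% wells_of(plate)) stop("well ", well, " not on the plate")
  structure(list(well = well, wavelengths = plate$wavelengths,
                 absorbance = as.numeric(plate$absorbance[well, ])),
            class = "spectrum_read")
}

#' Parse a plate-reader spectral export
#'
#' Two interchange dialects are supported. `"long"`: rows
#' `well,wavelength_nm,absorbance`. `"wide"`: a `well` column followed by
#' one column per wavelength (numeric column names). All wells must share
#' the same wavelength grid; the grid may be any strictly increasing set of
#' wavelengths.
#'
#' @param path CSV file path (lines starting with `#` are ignored).
#' @param dialect `"long"` or `"wide"`.
#' @return a [spectra_plate()].
#' @export
read_spectra <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
    needed <- c("well", "wavelength_nm", "absorbance")
    if (!all(needed %in% names(df))) {
      stop("long-format spectra need columns well,wavelength_nm,absorbance")
    }
    abs_num <- suppressWarnings(as.numeric(df$absorbance))
    if (anyNA(abs_num)) {
      stop("non-numeric absorbance at data row(s) ",
           paste(utils::head(which(is.na(abs_num)), 5), collapse = ", "))
    }
    wl_num <- suppressWarnings(as.numeric(df$wavelength_nm))
    if (anyNA(wl_num)) {
      stop("non-numeric wavelength at data row(s) ",
           paste(utils::head(which(is.na(wl_num)), 5), collapse = ", "))
    }
    wells <- unique(df$well)
    grids <- split(wl_num, factor(df$well, levels = wells))
    ref <- grids[[1]]
    bad <- names(grids)[!vapply(grids, function(g) identical(length(g), length(ref)) && all(g == ref), logical(1))]
    if (length(bad)) {
      stop("ragged wavelength grids; offending wells: ", paste(bad, collapse = ", "))
    }
    ord <- order(ref)
    A <- do.call(rbind, lapply(split(abs_num, factor(df$well, levels = wells)),
                               function(a) a[ord]))
    spectra_plate(ref[ord], A, wells)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
    if (!"well" %in% names(df)) stop("wide-format spectra need a 'well' column")
    wl <- suppressWarnings(as.numeric(setdiff(names(df), "well")))
    if (anyNA(wl)) stop("wide-format column names must be wavelengths in nm")
    A <- as.matrix(df[, setdiff(names(df), "well"), drop = FALSE])
    if (!is.numeric(A)) stop("non-numeric absorbance values in wide-format file")
    ord <- order(wl)
    spectra_plate(wl[ord], A[, ord, drop = FALSE], df$well)
  }
}

#' Write a plate back to disk
#'
#' @param plate a [spectra_plate()].
#' @param path output CSV path.
#' @param dialect `"long"` or `"wide"` (see [read_spectra()]).
#' @param header optional comment line (without the leading `#`) written at
#'   the top of the file, e.g. a seed/config stamp.
#' @export
write_spectra <- function(plate, path, dialect = c("long", "wide"), header = NULL) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (dialect == "long") {
    df <- data.frame(
      well = rep(wells_of(plate), each = length(plate$wavelengths)),
      wavelength_nm = rep(plate$wavelengths, times = nrow(plate$absorbance)),
      absorbance = as.vector(t(plate$absorbance)))
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(well = wells_of(plate), plate$absorbance,
                     check.names = FALSE)
    colnames(df) <- c("well", plate$wavelengths)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Savitzky-Golay smoothing of all spectra on a plate
#'
#' Applies a Savitzky-Golay filter along the wavelength axis of every well.
#' Edges are handled by mirror padding, so the filter exactly preserves
#' polynomials up to `polyorder` away from the spectrum ends. The wavelength
#' grid is unchanged.
#'
#' @param plate a [spectra_plate()].
#' @param window filter window length in grid points; odd, larger than
#'   `polyorder`, at most the spectrum length. Default 11.
#' @param polyorder polynomial order of the local fit. Default 3.
#' @return a smoothed [spectra_plate()] (layout annotation, if any, is kept).
#' @export
smooth_spectra <- function(plate, window = 11L, polyorder = 3L) {
  n <- length(plate$wavelengths)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > n) stop("window exceeds spectrum length")
  k <- (window - 1L) %/% 2L
  sm <- t(apply(plate$absorbance, 1L, function(y) {
    padded <- c(y[(k + 1L):2L], y, y[(n - 1L):(n - k)])
    signal::sgolayfilt(padded, p = polyorder, n = window)[(k + 1L):(k + n)]
  }))
  out <- plate
  out$absorbance <- sm
  rownames(out$absorbance) <- wells_of(plate)
  out
}

#' Attach a plate layout to measured spectra
#'
#' Joins the layout table (see [write_layout()]) onto the spectra. Wells on
#' the plate but absent from the layout are dropped with a warning; a layout
#' row referencing a well that was not measured is an error.
#'
#' @param plate a [spectra_plate()].
#' @param layout a layout data frame or the path to a layout CSV.
#' @return the plate with a `$layout` data frame, class
#'   `c("annotated_plate", "spectra_plate")`.
#' @export
annotate_layout <- function(plate, layout) {
  if (is.character(layout)) layout <- read_layout(layout)
  missing_wells <- setdiff(layout$well, wells_of(plate))
  if (length(missing_wells)) {
    stop("layout references wells absent from the plate: ",
         paste(missing_wells, collapse = ", "))
  }
  extra <- setdiff(wells_of(plate), layout$well)
  if (length(extra)) {
    warning(length(extra), " measured well(s) not in the layout were dropped")
    plate$absorbance <- plate$absorbance[layout$well, , drop = FALSE]
  }
  if (!all(layout$role %in% c("sample", "blank"))) {
    stop("layout roles must be 'sample' or 'blank'")
  }
  plate$layout <- layout[match(wells_of(plate), layout$well), , drop = FALSE]
  rownames(plate$layout) <- NULL
  class(plate) <- unique(c("annotated_plate", class(plate)))
  plate
}
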