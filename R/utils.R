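# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate plate well coordinates in row-major order
#'
#' @param n number of wells needed.
#' @param nrow,ncol plate geometry; defaults are a 384-well plate (16 x 24).
#' @return character vector of coordinates like `"A1"`, `"A2"`, ...
#' @keywords internal
#' @noRd
well_ids <- function(n, nrow = 16L, ncol = 24L) {
  if (n > nrow * ncol) {
    stop("plate capacity exceeded: need ", n, " wells, plate holds ", nrow * ncol)
  }
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% ncol + 1L], i %% ncol + 1L)
}

# Index of a wavelength on a grid; exact to within `tol` nm.
wl_index <- function(wavelengths, target, tol = 0.5) {
  i <- which.min(abs(wavelengths - target))
  if (abs(wavelengths[i] - target) > tol) {
    stop("wavelength grid does not contain ", target, " nm")
  }
  i
}

# Indices of grid points within an inclusive band.
wl_band <- function(wavelengths, lo, hi) {
  idx <- which(wavelengths >= lo & wavelengths <= hi)
  if (length(idx) == 0L) {
    stop("wavelength grid does not cover the ", lo, "-", hi, " nm band")
  }
  idx
}

# FNV-1a hash of an R object (via its serialization) as 8 hex chars; used to
# stamp output files so identical config + inputs give identical stamps.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep within int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Format volumes at worklist precision (0.001 uL).
fmt_vol <- function(v) formatC(round(v, 3), format = "f", digits = 3)
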