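#' Electrode array geometry
#'
#' Describes the recording grid of a CMOS multielectrode array. The default
#' corresponds to a 4096-electrode chip: a 64 x 64 grid of 21 x 21 um
#' electrodes at 42 um pitch. Electrodes are indexed 0-based and row-major,
#' so electrode `row * n_cols + col` sits at grid position `(row, col)`.
#'
#' @param n_rows,n_cols Grid dimensions (electrodes).
#' @param pitch_um Centre-to-centre electrode spacing in micrometres.
#' @param electrode_size_um Electrode side length in micrometres.
#' @return An object of class `array_geometry`.
#' @examples
#' g <- array_geometry()
#' n_electrodes(g)
#' @export
array_geometry <- function(n_rows = 64L, n_cols = 64L, pitch_um = 42,
                           electrode_size_um = 21) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L) stop("n_rows must be >= 1")
  if (is.na(n_cols) || n_cols < 1L) stop("n_cols must be >= 1")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
         electrode_size_um = electrode_size_um),
    class = "array_geometry"
  )
}

#' Number of electrodes in a geometry
#' @param geometry An [array_geometry()].
#' @return Integer electrode count.
#' @export
n_electrodes <- function(geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  geometry$n_rows * geometry$n_cols
}

#' Convert between electrode index and grid position
#'
#' Indices are 0-based and row-major: electrode `row * n_cols + col` for
#' 0-based `row`, `col`.
#'
#' @param row,col 0-based grid coordinates (vectorised).
#' @param index 0-based electrode indices (vectorised).
#' @param geometry An [array_geometry()].
#' @return `electrode_index()` returns integer indices;
#'   `electrode_position()` returns a data frame with columns `row`, `col`.
#' @export
electrode_index <- function(row, col, geometry = array_geometry()) {
  if (any(row < 0 | row >= geometry$n_rows) ||
      any(col < 0 | col >= geometry$n_cols)) {
    stop("row/col out of range for geometry")
  }
  as.integer(row) * geometry$n_cols + as.integer(col)
}

#' @rdname electrode_index
#' @export
electrode_position <- function(index, geometry = array_geometry()) {
  index <- as.integer(index)
  if (any(index < 0L | index >= n_electrodes(geometry))) {
    stop("electrode index out of range for geometry")
  }
  data.frame(row = index %/% geometry$n_cols,
             col = index %% geometry$n_cols)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("Array geometry: %d x %d electrodes (%g um pitch, %g um size)\n",
              x$n_rows, x$n_cols, x$pitch_um, x$electrode_size_um))
  invisible(x)
}
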