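#' Build a one-dimensional sediment grid
#'
#' Discretizes a sediment column into uniform finite-volume cells.  Depth is
#' measured in cm, positive downward from the sediment--water interface at
#' `x = 0`.
#'
#' @param depth_max total column depth (cm), `> 0`.
#' @param n_cells number of cells, at least 4.
#' @param porosity porewater volume fraction, either a scalar applied to all
#'   cells or a vector of length `n_cells`; every value must lie strictly
#'   between 0 and 1.
#' @return An object of class `"sediment_grid"`: a list with `cell_centers`,
#'   `cell_widths`, `porosity`, `depth_max` and `n_cells`.
#' @examples
#' g <- build_grid(40, 80, 0.4)
#' head(g$cell_centers)
#' @export
build_grid <- function(depth_max, n_cells, porosity) {
  if (!is.numeric(depth_max) || length(depth_max) != 1L || !is.finite(depth_max) ||
      depth_max <= 0)
    stop_invalid("`depth_max` must be a single positive number (cm)")
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells != round(n_cells) ||
      n_cells < 4)
    stop_invalid("`n_cells` must be an integer >= 4")
  n_cells <- as.integer(n_cells)
  if (!is.numeric(porosity) || !(length(porosity) %in% c(1L, n_cells)))
    stop_invalid("`porosity` must be a scalar or a vector of length `n_cells`")
  if (any(!is.finite(porosity)) || any(porosity <= 0) || any(porosity >= 1))
    stop_invalid("`porosity` must lie strictly between 0 and 1")
  h <- depth_max / n_cells
  g <- structure(
    list(cell_centers = (seq_len(n_cells) - 0.5) * h,
         cell_widths  = rep(h, n_cells),
         porosity     = rep_len(as.double(porosity), n_cells),
         depth_max    = as.double(depth_max),
         n_cells      = n_cells),
    class = "sediment_grid")
  validate_grid(g)
  g
}

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "sediment_grid"))
  x <- grid$cell_centers
  w <- grid$cell_widths
  if (any(diff(x) <= 0) || x[1] <= 0 || x[length(x)] > grid$depth_max)
    stop_invalid("grid cell centers must be strictly increasing within (0, depth_max]")
  if (any(w <= 0) || abs(sum(w) - grid$depth_max) > 1e-9 * grid$depth_max)
    stop_invalid("grid cell widths must be positive and sum to depth_max")
  if (any(grid$porosity <= 0) || any(grid$porosity >= 1))
    stop_invalid("porosity must lie strictly in (0, 1)")
  invisible(grid)
}

#' @export
print.sediment_grid <- function(x, ...) {
  cat(sprintf("sediment_grid: %d cells, 0-%g cm (width %g cm), porosity %s\n",
              x$n_cells, x$depth_max, x$cell_widths[1],
              if (length(unique(x$porosity)) == 1L)
                format(x$porosity[1]) else "depth-varying"))
  invisible(x)
}
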