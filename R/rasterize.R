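#' Rasterize a simulation onto the shared occupancy grid
#'
#' All three models are projected onto one binary raster so that downstream
#' statistics and filtrations see identical substrates. The grid has
#' `resolution` cells per side, cell `k` centred on `k * cs`
#' (`cs = L / (resolution - 1)`), so with the default
#' `resolution = lattice_resolution` the lattice model's trail sites map to
#' cells one-to-one. Off-lattice polylines are traced with a supercover line
#' walk: consecutive trail points occupy a 4-connected chain of cells.
#'
#' @param sim An [simulate_vessels()] result, or a data frame of trail
#'   points with columns `x`, `y` and (for polylines) `tip`.
#' @param resolution Cells per side (>= 8); defaults to the simulation's
#'   lattice resolution.
#' @param side_length Domain side; taken from `sim` when available.
#' @return An object of class `occupancy_grid`: list with logical matrix
#'   `cells` (`[ix, iy]`, 1-based), `resolution`, `cell_size`,
#'   `side_length`.
#' @export
rasterize <- function(sim, resolution = NULL, side_length = NULL) {
  if (inherits(sim, "angio_sim")) {
    trail <- sim$trail
    resolution <- resolution %||% sim$config$lattice_resolution
    side_length <- side_length %||% sim$config$side_length
    group <- trail$tip
  } else {
    trail <- tibble::as_tibble(sim)
    stopifnot(!is.null(resolution), all(c("x", "y") %in% names(trail)))
    side_length <- side_length %||% 1
    group <- if ("tip" %in% names(trail)) trail$tip else seq_len(nrow(trail))
  }
  if (nrow(trail) == 0) stop("empty trail: nothing to rasterize", call. = FALSE)
  resolution <- as.integer(resolution)
  if (resolution < 8) stop("`resolution` must be at least 8", call. = FALSE)
  cs <- side_length / (resolution - 1)
  ij <- supercover_cells(trail$x, trail$y, as.integer(group), cs, resolution)
  cells <- matrix(FALSE, resolution, resolution)
  cells[ij + 1L] <- TRUE
  structure(
    list(cells = cells, resolution = resolution, cell_size = cs,
         side_length = side_length),
    class = "occupancy_grid"
  )
}

#' Coordinates of occupied cell centres
#'
#' @param grid An [rasterize()] result.
#' @return A tibble with columns `x`, `y` (one row per occupied cell).
#' @export
occupied_centers <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  idx <- which(grid$cells, arr.ind = TRUE)
  tibble::tibble(x = unname((idx[, 1] - 1) * grid$cell_size),
                 y = unname((idx[, 2] - 1) * grid$cell_size))
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> %dx%d, %d occupied cells\n",
              x$resolution, x$resolution, sum(x$cells)))
  invisible(x)
}

#' Spatially-averaged summary statistics of a vascular network
#'
#' Computes, over the multiset of occupied-cell centre coordinates, the
#' mean, standard deviation, minimum, maximum, range, and the 10th, 25th,
#' 75th and 90th percentiles of the `x` and `y` coordinates (18 statistics).
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), fixed so the values are bit-stable across
#' the pipeline.
#'
#' @param grid An [rasterize()] result (non-empty).
#' @return A one-row tibble with columns `sx_mean`, `sx_std`, `sx_min`,
#'   `sx_max`, `sx_range`, `sx_p10`, `sx_p25`, `sx_p75`, `sx_p90` and the
#'   `sy_` equivalents.
#' @export
spatial_statistics <- function(grid) {
  pts <- occupied_centers(grid)
  if (nrow(pts) == 0) stop("empty occupancy grid", call. = FALSE)
  one <- function(v, prefix) {
    q <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
    out <- c(mean(v), pop_or_zero_sd(v), min(v), max(v), max(v) - min(v), q)
    names(out) <- paste0(prefix, c("mean", "std", "min", "max", "range",
                                   "p10", "p25", "p75", "p90"))
    out
  }
  tibble::as_tibble(as.list(c(one(pts$x, "sx_"), one(pts$y, "sy_"))))
}

# sd() is NA for a single observation; a one-cell network has spread 0.
pop_or_zero_sd <- function(v) {
  if (length(v) < 2) return(0)
  stats::sd(v)
}
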