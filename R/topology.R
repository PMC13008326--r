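#' Sweeping-plane filtration of an occupancy grid
#'
#' Builds a cubical complex on the occupied cells (one vertex per occupied
#' cell, an edge between 4-adjacent occupied cells, a square for every fully
#' occupied 2x2 block) filtered by a coordinate height function: the value
#' of a vertex is its cell-centre `y` (vertical sweep, from the parent
#' vessel towards the tumour) or `x` (horizontal sweep); edges and squares
#' enter at the maximum of their vertices (lower-star extension). The
#' sublevel complex at threshold `k` therefore contains exactly the cells a
#' distance `k` or less along the sweep axis.
#'
#' @param grid An [rasterize()] result (non-empty).
#' @param direction `"vertical"` (sweep in `y`) or `"horizontal"` (in `x`).
#' @return An object of class `angio_filtration`.
#' @export
build_filtration <- function(grid, direction = c("vertical", "horizontal")) {
  direction <- match.arg(direction)
  cx <- build_complex(grid)
  if (cx$n_vertices == 0) stop("empty occupancy grid", call. = FALSE)
  values <- if (direction == "vertical") cx$vertex_xy[, 2] else cx$vertex_xy[, 1]
  structure(
    list(complex = cx, values = values, direction = direction,
         side_length = grid$side_length),
    class = "angio_filtration"
  )
}

# Cubical complex of an occupancy grid (V-construction on occupied cells).
build_complex <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  occ <- grid$cells
  R <- grid$resolution
  cs <- grid$cell_size
  vid <- matrix(0L, R, R)
  idx <- which(occ, arr.ind = TRUE)
  V <- nrow(idx)
  vid[idx] <- seq_len(V)
  vertex_xy <- cbind(x = (idx[, 1] - 1) * cs, y = (idx[, 2] - 1) * cs)
  # horizontal edges (x-neighbours) and vertical edges (y-neighbours)
  hpair <- which(occ[-R, , drop = FALSE] & occ[-1, , drop = FALSE],
                 arr.ind = TRUE)
  vpair <- which(occ[, -R, drop = FALSE] & occ[, -1, drop = FALSE],
                 arr.ind = TRUE)
  edges <- rbind(
    cbind(vid[hpair], vid[cbind(hpair[, 1] + 1L, hpair[, 2])]),
    cbind(vid[vpair], vid[cbind(vpair[, 1], vpair[, 2] + 1L)])
  )
  sq <- which(occ[-R, -R, drop = FALSE] & occ[-1, -R, drop = FALSE] &
                occ[-R, -1, drop = FALSE] & occ[-1, -1, drop = FALSE],
              arr.ind = TRUE)
  squares <- cbind(
    vid[sq],
    vid[cbind(sq[, 1] + 1L, sq[, 2])],
    vid[cbind(sq[, 1], sq[, 2] + 1L)],
    vid[cbind(sq[, 1] + 1L, sq[, 2] + 1L)]
  )
  if (nrow(edges) > 0) {
    ekey <- pmin(edges[, 1], edges[, 2]) * (V + 1) + pmax(edges[, 1], edges[, 2])
  } else {
    ekey <- numeric(0)
  }
  # the four boundary edges of each square, as row indices into `edges`
  square_edges <- NULL
  if (nrow(squares) > 0) {
    pair_id <- function(a, b) pmin(a, b) * (V + 1) + pmax(a, b)
    square_edges <- cbind(
      match(pair_id(squares[, 1], squares[, 2]), ekey),
      match(pair_id(squares[, 3], squares[, 4]), ekey),
      match(pair_id(squares[, 1], squares[, 3]), ekey),
      match(pair_id(squares[, 2], squares[, 4]), ekey)
    )
  }
  list(n_vertices = V, vertex_xy = vertex_xy, edges = edges,
       squares = squares, square_edges = square_edges, vid = vid)
}

#' Vertices of the sublevel complex at a threshold
#'
#' @param filtration An [build_filtration()] object.
#' @param k Threshold along the sweep axis.
#' @return Integer vertex ids whose filtration value is `<= k`.
#' @export
sublevel_vertices <- function(filtration, k) {
  which(filtration$values <= k)
}

#' Extended persistent homology of a sweeping-plane filtration
#'
#' Computes the extended persistence diagram of the lower-star filtration by
#' matrix reduction over `Z/2Z` of the coned complex: a cone vertex first,
#' the cells of the complex in ascending filtration order, then the coned
#' cells in descending order of their minimum vertex value. Pairs with both
#' cells in the ascending part are Ordinary, pairs spanning the two parts
#' are Extended (plus if `death >= birth`, minus otherwise), and pairs
#' inside the coned part are Relative. Every feature receives a finite
#' death; in particular each connected component yields one ExtendedPlus
#' dimension-0 point (min height, max height) and each independent loop one
#' ExtendedMinus dimension-1 point. Zero-persistence Ordinary and Relative
#' points are discarded; only dimensions 0 and 1 are reported.
#'
#' @param filtration An [build_filtration()] object.
#' @return A tibble with columns `birth`, `death`, `dim` (0 or 1), `cls`
#'   (`"Ordinary"`, `"Relative"`, `"ExtendedPlus"`, `"ExtendedMinus"`), and
#'   the filtration direction as attribute `direction`.
#' @export
extended_persistence <- function(filtration) {
  stopifnot(inherits(filtration, "angio_filtration"))
  cx <- filtration$complex
  cells <- enumerate_cells(filtration)
  N <- nrow(cells)
  asc_pos <- integer(N)
  asc_pos[order(cells$value, cells$dim)] <- seq_len(N)
  asc_pos <- asc_pos + 1L                      # cone vertex occupies column 1
  desc_pos <- integer(N)
  desc_pos[order(-cells$minv, cells$dim)] <- seq_len(N)
  desc_pos <- desc_pos + N + 1L
  pairs <- eph_reduce(cx$n_vertices, cx$edges, cx$square_edges %||%
                        matrix(0L, 0, 4), asc_pos, desc_pos, TRUE)
  pos2cell <- integer(2L * N + 1L)
  pos2cell[asc_pos] <- seq_len(N)
  pos2cell[desc_pos] <- seq_len(N)
  b <- pairs[, 1]
  d <- pairs[, 2]
  bc <- pos2cell[b]
  dc <- pos2cell[d]
  split_at <- N + 1L
  kind <- ifelse(d <= split_at, "ord", ifelse(b <= split_at, "ext", "rel"))
  birth <- ifelse(kind == "rel", cells$minv[bc], cells$value[bc])
  death <- ifelse(kind == "ord", cells$value[dc], cells$minv[dc])
  dim <- cells$dim[bc] + (kind == "rel")
  cls <- dplyr::case_when(
    kind == "ord" ~ "Ordinary",
    kind == "rel" ~ "Relative",
    death >= birth ~ "ExtendedPlus",
    TRUE ~ "ExtendedMinus"
  )
  keep <- dim <= 1 & (kind == "ext" | birth != death)
  out <- tibble::tibble(birth = birth[keep], death = death[keep],
                        dim = as.integer(dim[keep]), cls = cls[keep])
  stopifnot(all(is.finite(out$birth)), all(is.finite(out$death)))
  attr(out, "direction") <- filtration$direction
  out
}

#' Ordinary persistent homology of the same filtration
#'
#' The ascending (sublevel) persistence alone: finite pairs plus essential
#' classes with infinite death. Used to contrast with
#' [extended_persistence()], whose Ordinary points coincide with the finite
#' pairs here while every essential class is replaced by a finite Extended
#' point.
#'
#' @inheritParams extended_persistence
#' @return A tibble with columns `birth`, `death` (possibly `Inf`), `dim`.
#' @export
ordinary_persistence <- function(filtration) {
  stopifnot(inherits(filtration, "angio_filtration"))
  cx <- filtration$complex
  cells <- enumerate_cells(filtration)
  N <- nrow(cells)
  asc_pos <- integer(N)
  asc_pos[order(cells$value, cells$dim)] <- seq_len(N)
  pairs <- eph_reduce(cx$n_vertices, cx$edges, cx$square_edges %||%
                        matrix(0L, 0, 4), asc_pos, integer(N), FALSE)
  pos2cell <- integer(N)
  pos2cell[asc_pos] <- seq_len(N)
  bc <- pos2cell[pairs[, 1]]
  dc <- pos2cell[pairs[, 2]]
  fin <- tibble::tibble(birth = cells$value[bc], death = cells$value[dc],
                        dim = cells$dim[bc])
  fin <- fin[fin$birth != fin$death, ]
  ess_cells <- pos2cell[attr(pairs, "essential")]
  ess <- tibble::tibble(birth = cells$value[ess_cells], death = Inf,
                        dim = cells$dim[ess_cells])
  out <- dplyr::bind_rows(fin, ess)
  out <- out[out$dim <= 1, ]
  attr(out, "direction") <- filtration$direction
  out
}

# Flat cell table of a filtration: dimension, lower-star value (max over
# vertices) and min vertex value, in cell order (vertices, edges, squares).
enumerate_cells <- function(filtration) {
  cx <- filtration$complex
  v <- filtration$values
  V <- cx$n_vertices
  E <- nrow(cx$edges)
  S <- if (is.null(cx$squares)) 0L else nrow(cx$squares)
  dim <- c(rep(0L, V), rep(1L, E), rep(2L, S))
  value <- c(v,
             if (E > 0) pmax(v[cx$edges[, 1]], v[cx$edges[, 2]]) else numeric(0),
             if (S > 0) do.call(pmax, lapply(1:4, function(k) v[cx$squares[, k]]))
             else numeric(0))
  minv <- c(v,
            if (E > 0) pmin(v[cx$edges[, 1]], v[cx$edges[, 2]]) else numeric(0),
            if (S > 0) do.call(pmin, lapply(1:4, function(k) v[cx$squares[, k]]))
            else numeric(0))
  tibble::tibble(dim = dim, value = value, minv = minv)
}
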