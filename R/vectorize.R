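#' Vectorization settings for the topological summary statistics
#'
#' @param image_resolution Pixels per side of each persistence image.
#' @param bandwidth Gaussian bandwidth of the persistence image; default
#'   1/20 of the filtration range (the domain side).
#' @param weight Point weighting of the persistence image:
#'   `"persistence"` (linear in persistence, weight 0 at persistence 0)
#'   or `"constant"`.
#' @return A list of class `topo_config`.
#' @export
topo_config <- function(image_resolution = 5, bandwidth = NULL,
                        weight = c("persistence", "constant")) {
  weight <- match.arg(weight)
  if (!is.null(bandwidth) && bandwidth <= 0) {
    stop("`bandwidth` must be positive", call. = FALSE)
  }
  structure(list(image_resolution = as.integer(image_resolution),
                 bandwidth = bandwidth, weight = weight),
            class = "topo_config")
}

#' Persistence image of one diagram stratum
#'
#' Maps diagram points to (birth, persistence) coordinates with
#' `persistence = |death - birth|` and sums weighted Gaussian bumps on a
#' fixed pixel grid over `[0, L] x [0, L]` (the filtration values are
#' confined to the domain, so the image support is data-independent). The
#' weight is linear in persistence (0 at 0) by default.
#'
#' @param diagram A tibble with columns `birth`, `death` (a single
#'   (direction, dimension, class) stratum). An empty diagram gives the
#'   zero vector.
#' @param side_length Filtration range `L`.
#' @param config A [topo_config()].
#' @return Numeric vector of length `image_resolution^2`, pixel order:
#'   birth index fastest (column-major in (birth, persistence)).
#' @export
persistence_image <- function(diagram, side_length = 1,
                              config = topo_config()) {
  res <- config$image_resolution
  bw <- config$bandwidth %||% (side_length / 20)
  if (bw <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  centers <- (seq_len(res) - 0.5) * side_length / res
  if (is.null(diagram) || nrow(diagram) == 0) {
    return(numeric(res * res))
  }
  b <- diagram$birth
  p <- abs(diagram$death - diagram$birth)
  w <- switch(config$weight,
              persistence = p / side_length,
              constant = rep(1, length(b)))
  # kernel factorizes: image = (Gb * diag(w)) %*% t(Gp) summed over points
  gb <- stats::dnorm(outer(centers, b, "-"), sd = bw)      # res x npts
  gp <- stats::dnorm(outer(centers, p, "-"), sd = bw)
  img <- gb %*% (w * t(gp))                                # birth x persistence
  as.vector(img)
}

#' Persistence statistics of one diagram stratum
#'
#' Summarizes the four derived samples of a diagram stratum — births,
#' deaths, midpoints `(b + d)/2` and lifespans `|d - b|` — by mean,
#' standard deviation (population convention, so a one-point stratum has
#' spread 0), median, interquartile range and the 10th/25th/75th/90th
#' percentiles, plus the persistent entropy of the normalized lifespans,
#' the number of points in the stratum and the total lifespan. An empty
#' stratum returns an all-zero block (documented sentinel so that
#' downstream forests and distances always see fixed-length numeric input).
#'
#' @inheritParams persistence_image
#' @return A named numeric vector of length 35.
#' @export
persistence_statistics <- function(diagram) {
  stats_names <- c("mean", "std", "median", "iqr", "p10", "p25", "p75", "p90")
  blocks <- c("birth", "death", "mid", "life")
  nm <- c(paste(rep(blocks, each = length(stats_names)), stats_names,
                sep = "_"), "entropy", "count", "life_total")
  if (is.null(diagram) || nrow(diagram) == 0) {
    return(stats::setNames(numeric(length(nm)), nm))
  }
  b <- diagram$birth
  d <- diagram$death
  samples <- list(b, d, (b + d) / 2, abs(d - b))
  one <- function(v) {
    q <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
    c(mean(v), sqrt(mean((v - mean(v))^2)), stats::median(v), q[3] - q[2],
      q[1], q[2], q[3], q[4])
  }
  life <- abs(d - b)
  total <- sum(life)
  ent <- if (total <= 0) 0 else {
    p <- life[life > 0] / total
    -sum(p * log(p))
  }
  stats::setNames(c(unlist(lapply(samples, one)), ent, nrow(diagram), total),
                  nm)
}

# The fixed stratum list shared by images, statistics and column naming.
topo_strata <- function() {
  tibble::tribble(
    ~code,     ~dim, ~cls,
    "d0ord",   0L,   "Ordinary",
    "d0ext",   0L,   "ExtendedPlus",
    "d1ord",   1L,   "Ordinary",
    "d1ext",   1L,   "ExtendedMinus",
    "d1rel",   1L,   "Relative"
  )
}

#' Topological summary statistics of an occupancy grid
#'
#' Computes extended persistence under the vertical and horizontal
#' sweeping-plane filtrations, splits each diagram into the five strata
#' that occur in this data — dimension 0 Ordinary and ExtendedPlus,
#' dimension 1 Ordinary, ExtendedMinus and Relative — and concatenates, in
#' a fixed documented order, the persistence images of every stratum
#' followed by the persistence-statistics blocks. Column order: all images
#' (vertical strata then horizontal strata, pixels in [persistence_image()]
#' order), then all statistics blocks in the same stratum order. Column
#' names carry the direction (`t_y_`/`t_x_`) and stratum code.
#'
#' @param grid An [rasterize()] result.
#' @param config A [topo_config()].
#' @return A one-row tibble of `2 * 5 * (image_resolution^2 + 35)` numeric
#'   columns.
#' @export
topo_features <- function(grid, config = topo_config()) {
  stopifnot(inherits(grid, "occupancy_grid"))
  strata <- topo_strata()
  L <- grid$side_length
  diags <- list(
    y = extended_persistence(build_filtration(grid, "vertical")),
    x = extended_persistence(build_filtration(grid, "horizontal"))
  )
  imgs <- list()
  stat_blocks <- list()
  for (dir in c("y", "x")) {
    dg <- diags[[dir]]
    for (s in seq_len(nrow(strata))) {
      sl <- dg[dg$dim == strata$dim[s] & dg$cls == strata$cls[s], ]
      key <- paste0("t_", dir, "_", strata$code[s])
      iv <- persistence_image(sl, side_length = L, config = config)
      names(iv) <- sprintf("%s_i%03d", key, seq_along(iv))
      imgs[[key]] <- iv
      sv <- persistence_statistics(sl)
      names(sv) <- paste0(key, "_", names(sv))
      stat_blocks[[key]] <- sv
    }
  }
  vec <- c(unlist(unname(imgs)), unlist(unname(stat_blocks)))
  tibble::as_tibble(as.list(vec))
}

#' Full feature vector of one simulation
#'
#' Rasterizes the trail and concatenates the 18 spatially-averaged
#' statistics with the topological summary statistics.
#'
#' @param sim An [simulate_vessels()] result.
#' @param resolution Raster resolution; defaults to the lattice resolution.
#' @param config A [topo_config()].
#' @return A one-row tibble (`sx_*`, `sy_*`, `t_*` columns).
#' @export
featurize <- function(sim, resolution = NULL, config = topo_config()) {
  grid <- rasterize(sim, resolution = resolution)
  dplyr::bind_cols(spatial_statistics(grid), topo_features(grid, config))
}

#' Metadata of feature-vector columns
#'
#' Classifies feature names by type (spatially-averaged vs topological) and
#' coordinate direction, the bookkeeping used to report what kinds of
#' statistics the selection step keeps.
#'
#' @param features Character vector of feature column names.
#' @return A tibble with columns `feature`, `type` (`"spatial"`/
#'   `"topological"`), `direction` (`"x"`/`"y"`).
#' @export
feature_metadata <- function(features) {
  tibble::tibble(
    feature = features,
    type = ifelse(grepl("^t_", features), "topological", "spatial"),
    direction = dplyr::case_when(
      grepl("^sx_|^t_x_", features) ~ "x",
      grepl("^sy_|^t_y_", features) ~ "y",
      TRUE ~ NA_character_
    )
  )
}
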