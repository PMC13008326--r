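# Independent oracles for the topology module, coded in plain R with
# different algorithms than the package (flood fill / union-find / dense
# GF(2) reduction) so they can serve as cross-checks.

# Wrap a logical occupancy matrix as an occupancy_grid on [0, 1]^2.
mk_grid <- function(occ) {
  structure(list(cells = occ, resolution = nrow(occ),
                 cell_size = 1 / (nrow(occ) - 1), side_length = 1),
            class = "occupancy_grid")
}

random_occupancy <- function(R, p = 0.55) {
  occ <- matrix(stats::runif(R * R) < p, R, R)
  if (!any(occ)) occ[sample(R, 1), sample(R, 1)] <- TRUE
  occ
}

# Connected components of occupied cells (4-connectivity) by flood fill.
flood_components <- function(occ) {
  R <- nrow(occ)
  C <- ncol(occ)
  lab <- matrix(0L, R, C)
  nc <- 0L
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      if (!occ[i, j] || lab[i, j] != 0L) next
      nc <- nc + 1L
      stack <- list(c(i, j))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > R || p[2] < 1 || p[2] > C) next
        if (!occ[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- nc
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  list(n = nc, labels = lab)
}

# First Betti number from the Euler characteristic of the cubical complex:
# beta1 = components - V + E - F.
betti1_oracle <- function(occ) {
  R <- nrow(occ)
  V <- sum(occ)
  E <- sum(occ[-R, , drop = FALSE] & occ[-1, , drop = FALSE]) +
    sum(occ[, -R, drop = FALSE] & occ[, -1, drop = FALSE])
  F <- sum(occ[-R, -R, drop = FALSE] & occ[-1, -R, drop = FALSE] &
             occ[-R, -1, drop = FALSE] & occ[-1, -1, drop = FALSE])
  flood_components(occ)$n - V + E - F
}

# Ordinary sublevel persistence of the sweeping-plane filtration, coded
# independently: explicit cell enumeration and dense GF(2) column reduction.
ord_ph_oracle <- function(occ, dir) {
  R <- nrow(occ)
  cs <- 1 / (R - 1)
  idx <- which(occ, arr.ind = TRUE)
  V <- nrow(idx)
  vid <- matrix(0L, R, R)
  vid[idx] <- seq_len(V)
  coord <- if (dir == "vertical") (idx[, 2] - 1) * cs else (idx[, 1] - 1) * cs
  edges <- NULL
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (!occ[i, j]) next
      if (i < R && occ[i + 1, j]) edges <- rbind(edges, c(vid[i, j], vid[i + 1, j]))
      if (j < R && occ[i, j + 1]) edges <- rbind(edges, c(vid[i, j], vid[i, j + 1]))
    }
  }
  sqs <- NULL
  for (i in seq_len(R - 1)) {
    for (j in seq_len(R - 1)) {
      if (occ[i, j] && occ[i + 1, j] && occ[i, j + 1] && occ[i + 1, j + 1]) {
        sqs <- rbind(sqs, c(vid[i, j], vid[i + 1, j], vid[i, j + 1],
                            vid[i + 1, j + 1]))
      }
    }
  }
  E <- if (is.null(edges)) 0L else nrow(edges)
  S <- if (is.null(sqs)) 0L else nrow(sqs)
  N <- V + E + S
  dims <- c(rep(0L, V), rep(1L, E), rep(2L, S))
  vals <- c(coord,
            if (E > 0) pmax(coord[edges[, 1]], coord[edges[, 2]]),
            if (S > 0) apply(matrix(coord[sqs], ncol = 4), 1, max))
  pos <- integer(N)
  pos[order(vals, dims)] <- seq_len(N)
  B <- matrix(FALSE, N, N)
  if (E > 0) {
    for (e in seq_len(E)) {
      B[pos[edges[e, 1]], pos[V + e]] <- TRUE
      B[pos[edges[e, 2]], pos[V + e]] <- TRUE
    }
  }
  if (S > 0) {
    pairkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ekeys <- pairkey(edges[, 1], edges[, 2])
    for (s in seq_len(S)) {
      vs <- sqs[s, ]
      es <- match(c(pairkey(vs[1], vs[2]), pairkey(vs[3], vs[4]),
                    pairkey(vs[1], vs[3]), pairkey(vs[2], vs[4])), ekeys)
      for (e in es) B[pos[V + e], pos[V + E + s]] <- TRUE
    }
  }
  lowf <- function(col) {
    w <- which(col)
    if (length(w)) max(w) else 0L
  }
  pivots <- integer(N)
  pairs <- NULL
  for (j in seq_len(N)) {
    repeat {
      l <- lowf(B[, j])
      if (l == 0L) break
      k <- pivots[l]
      if (k == 0L) break
      B[, j] <- xor(B[, j], B[, k])
    }
    l <- lowf(B[, j])
    if (l > 0L) {
      pivots[l] <- j
      pairs <- rbind(pairs, c(l, j))
    }
  }
  cell_of <- integer(N)
  cell_of[pos] <- seq_len(N)
  if (is.null(pairs)) {
    fin <- data.frame(birth = numeric(0), death = numeric(0), dim = integer(0))
    paired <- integer(0)
  } else {
    fin <- data.frame(birth = vals[cell_of[pairs[, 1]]],
                      death = vals[cell_of[pairs[, 2]]],
                      dim = dims[cell_of[pairs[, 1]]])
    fin <- fin[fin$birth != fin$death, , drop = FALSE]
    paired <- c(pairs)
  }
  ess <- setdiff(seq_len(N), paired)
  essd <- data.frame(birth = vals[cell_of[ess]], death = Inf,
                     dim = dims[cell_of[ess]])
  out <- rbind(fin, essd)
  out[out$dim <= 1, , drop = FALSE]
}

sort_pairs <- function(d) d[order(d$dim, d$birth, d$death), , drop = FALSE]

# The Fig-2-style fixture: a stem with a lower branch merging into it and
# one loop higher up (on a 9x9 grid over [0,1]^2, cell size 0.125).
y_with_loop <- function() {
  occ <- matrix(FALSE, 9, 9)
  occ[5, 1:3] <- TRUE        # stem at x = 0.5, y = 0 .. 0.25
  occ[4:6, 3] <- TRUE        # loop bottom, y = 0.25
  occ[4, 3:6] <- TRUE        # loop left side
  occ[6, 3:6] <- TRUE        # loop right side
  occ[4:6, 6] <- TRUE        # loop top, y = 0.625
  occ[3, 1] <- TRUE          # lower branch rooted at y = 0
  occ[3, 2] <- TRUE
  occ[4, 2] <- TRUE          # merges into the stem at y = 0.125
  occ
}
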