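test_that("filtration sublevel sets realize the sweeping plane", {
  occ <- matrix(FALSE, 9, 9)
  occ[4, 6] <- TRUE
  filt <- build_filtration(mk_grid(occ), "vertical")
  expect_equal(filt$values, 5 / 8)          # single vertex at its height
  expect_length(sublevel_vertices(filt, 0.5), 0)
  expect_length(sublevel_vertices(filt, 5 / 8), 1)
  # a full occupied column is connected at every threshold once entered
  occ <- matrix(FALSE, 9, 9)
  occ[5, ] <- TRUE
  filt <- build_filtration(mk_grid(occ), "vertical")
  for (k in c(0, 0.25, 0.5, 1)) {
    vs <- sublevel_vertices(filt, k)
    expect_equal(length(vs), sum((0:8) / 8 <= k))
  }
  # nesting
  set.seed(31)
  occ <- random_occupancy(8)
  filt <- build_filtration(mk_grid(occ), "horizontal")
  ks <- sort(runif(5))
  for (i in 1:4) {
    expect_true(all(sublevel_vertices(filt, ks[i]) %in%
                      sublevel_vertices(filt, ks[i + 1])))
  }
})

test_that("sublevel component counts match flood fill at multiple thresholds", {
  set.seed(32)
  for (rep in 1:10) {
    occ <- random_occupancy(8)
    g <- mk_grid(occ)
    filt <- build_filtration(g, "vertical")
    for (k in seq(0, 1, length.out = 5)) {
      sub <- occ
      ycoord <- matrix(rep((0:7) / 7, each = 8), 8)
      sub[ycoord > k] <- FALSE
      dg <- extended_persistence(filt)
      # components alive at threshold k in the sweep equal flood fill of
      # the thresholded raster
      alive <- sum(dg$dim == 0 &
                     ((dg$cls == "Ordinary" & dg$birth <= k & dg$death > k) |
                        (dg$cls == "ExtendedPlus" & dg$birth <= k)))
      expect_equal(alive, flood_components(sub)$n)
    }
  }
})

test_that("extended persistence of a rasterized ring is exactly one component and one loop", {
  occ <- matrix(TRUE, 3, 3)
  occ[2, 2] <- FALSE
  d <- extended_persistence(build_filtration(mk_grid(occ), "vertical"))
  expect_equal(nrow(d), 2)
  comp <- d[d$dim == 0, ]
  loop <- d[d$dim == 1, ]
  expect_equal(comp$cls, "ExtendedPlus")
  expect_equal(c(comp$birth, comp$death), c(0, 1))   # (min, max) height
  expect_equal(loop$cls, "ExtendedMinus")
  expect_equal(c(loop$birth, loop$death), c(1, 0))   # (max, min) height
})

test_that("two disjoint bars give two extended components and no loops", {
  occ <- matrix(FALSE, 9, 9)
  occ[2, 2:6] <- TRUE
  occ[7, 3:8] <- TRUE
  d <- extended_persistence(build_filtration(mk_grid(occ), "vertical"))
  expect_equal(sum(d$dim == 0 & d$cls == "ExtendedPlus"), 2)
  expect_equal(sum(d$dim == 1 & d$cls != "Relative"), 0)
})

test_that("the Y-with-loop vessel reproduces the worked comparison of PH and EPH", {
  occ <- y_with_loop()
  filt <- build_filtration(mk_grid(occ), "vertical")
  ph <- ordinary_persistence(filt)
  # ordinary PH: one essential component and one essential loop (death Inf)
  ess <- ph[!is.finite(ph$death), ]
  expect_equal(sum(ess$dim == 0), 1)
  expect_equal(sum(ess$dim == 1), 1)
  expect_equal(ess$birth[ess$dim == 0], 0)            # rooted at y = 0
  expect_equal(ess$birth[ess$dim == 1], 0.625)        # loop closes at its top
  # the lower branch is a finite ordinary pair (0, 0.125)
  fin <- ph[is.finite(ph$death), ]
  expect_true(any(fin$dim == 0 & fin$birth == 0 & fin$death == 0.125))
  # EPH: both essential classes become finite at the features' extreme
  # heights, and all finite ordinary pairs are preserved
  eph <- extended_persistence(filt)
  expect_true(all(is.finite(eph$birth) & is.finite(eph$death)))
  comp <- eph[eph$dim == 0 & eph$cls == "ExtendedPlus", ]
  expect_equal(nrow(comp), 1)
  expect_equal(c(comp$birth, comp$death), c(0, 0.625))
  loop <- eph[eph$dim == 1 & eph$cls == "ExtendedMinus", ]
  expect_equal(nrow(loop), 1)
  expect_equal(c(loop$birth, loop$death), c(0.625, 0.25))
  ord <- eph[eph$cls == "Ordinary", ]
  expect_equal(sort_pairs(ord)[, c("birth", "death", "dim")],
               sort_pairs(fin)[, c("birth", "death", "dim")],
               ignore_attr = TRUE)
})

test_that("extended diagrams match flood-fill, Euler and independent PH oracles on random grids", {
  set.seed(33)
  for (rep in 1:25) {
    occ <- random_occupancy(sample(5:10, 1), runif(1, 0.3, 0.75))
    g <- mk_grid(occ)
    for (dir in c("vertical", "horizontal")) {
      filt <- build_filtration(g, dir)
      eph <- extended_persistence(filt)
      expect_true(all(is.finite(c(eph$birth, eph$death))))
      expect_equal(sum(eph$dim == 0 & eph$cls == "ExtendedPlus"),
                   flood_components(occ)$n)
      expect_equal(sum(eph$dim == 1 & eph$cls == "ExtendedMinus"),
                   betti1_oracle(occ))
      oracle <- ord_ph_oracle(occ, dir)
      mine <- ordinary_persistence(filt)
      expect_equal(sort_pairs(as.data.frame(mine)), sort_pairs(oracle),
                   ignore_attr = TRUE)
      fin <- oracle[is.finite(oracle$death), ]
      ords <- eph[eph$cls == "Ordinary", ]
      expect_equal(sort_pairs(as.data.frame(ords))[, c("birth", "death", "dim")],
                   sort_pairs(fin), ignore_attr = TRUE)
    }
  }
})

test_that("persistence images obey the closed-form Gaussian oracle and linearity", {
  cfgv <- topo_config(image_resolution = 8, bandwidth = 0.07)
  expect_equal(persistence_image(tibble::tibble(birth = numeric(0),
                                                death = numeric(0)),
                                 1, cfgv),
               numeric(64))
  one <- tibble::tibble(birth = 0.3, death = 0.8)
  img <- persistence_image(one, 1, topo_config(8, 0.07, weight = "constant"))
  centers <- (seq_len(8) - 0.5) / 8
  expected <- as.vector(outer(dnorm(centers, 0.3, 0.07),
                              dnorm(centers, 0.5, 0.07)))
  expect_equal(img, expected, tolerance = 1e-12)
  # linear persistence weight scales the bump
  imgw <- persistence_image(one, 1, cfgv)
  expect_equal(imgw, 0.5 * expected, tolerance = 1e-12)
  # two identical points double the image
  two <- dplyr::bind_rows(one, one)
  expect_equal(persistence_image(two, 1, cfgv), 2 * imgw, tolerance = 1e-12)
  expect_true(all(persistence_image(two, 1, cfgv) >= 0))
  expect_error(topo_config(bandwidth = -1), "bandwidth")
})

test_that("persistence statistics match direct computation and entropy conventions", {
  empty <- persistence_statistics(tibble::tibble(birth = numeric(0),
                                                 death = numeric(0)))
  expect_length(empty, 35)
  expect_true(all(empty == 0))
  one <- persistence_statistics(tibble::tibble(birth = 0.2, death = 0.7))
  expect_equal(unname(one["life_mean"]), 0.5)
  expect_equal(unname(one["life_std"]), 0)
  expect_equal(unname(one["mid_mean"]), 0.45)
  expect_equal(unname(one["entropy"]), 0)
  # n equal lifespans: entropy log n
  n <- 7
  eq <- tibble::tibble(birth = seq(0, 0.6, length.out = n),
                       death = seq(0, 0.6, length.out = n) + 0.2)
  expect_equal(unname(persistence_statistics(eq)["entropy"]), log(n),
               tolerance = 1e-12)
  # random diagram against independently coded formulas
  set.seed(34)
  d <- tibble::tibble(birth = runif(10), death = runif(10))
  s <- persistence_statistics(d)
  life <- abs(d$death - d$birth)
  expect_equal(unname(s["birth_mean"]), mean(d$birth))
  expect_equal(unname(s["death_p75"]), unname(quantile(d$death, 0.75)))
  expect_equal(unname(s["mid_median"]), median((d$birth + d$death) / 2))
  expect_equal(unname(s["life_iqr"]),
               unname(diff(quantile(life, c(0.25, 0.75)))))
  expect_equal(unname(s["birth_std"]),
               sqrt(mean((d$birth - mean(d$birth))^2)))
  p <- life / sum(life)
  expect_equal(unname(s["entropy"]), -sum(p * log(p)))
})

test_that("topological feature vectors are deterministic with documented length", {
  set.seed(35)
  g <- mk_grid(random_occupancy(9, 0.6))
  cfgv <- topo_config(image_resolution = 6)
  f1 <- topo_features(g, cfgv)
  f2 <- topo_features(g, cfgv)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 2 * 5 * (36 + 35))
  expect_true(all(grepl("^t_[xy]_d[01](ord|ext|rel)_", names(f1))))
  img_cols <- grep("_i\\d+$", names(f1), value = TRUE)
  expect_true(all(as.matrix(f1[, img_cols]) >= 0))
})

test_that("mirroring the grid left-right preserves vertical blocks and maps horizontal ones", {
  set.seed(36)
  occ <- random_occupancy(8, 0.55)
  gm <- mk_grid(occ[rev(seq_len(8)), ])
  g <- mk_grid(occ)
  dv <- extended_persistence(build_filtration(g, "vertical"))
  dvm <- extended_persistence(build_filtration(gm, "vertical"))
  expect_equal(sort_pairs(as.data.frame(dv)), sort_pairs(as.data.frame(dvm)),
               ignore_attr = TRUE)
  # the horizontal sweep of the mirror is the reversed filtration: Extended
  # points map by value -> L - value, and the Ordinary dim-0 / Relative
  # dim-1 strata swap roles (up-branches become down-branches)
  dh <- extended_persistence(build_filtration(g, "horizontal"))
  dhm <- extended_persistence(build_filtration(gm, "horizontal"))
  L <- 1
  for (cls in c("ExtendedPlus", "ExtendedMinus")) {
    a <- dh[dh$cls == cls, ]
    b <- dhm[dhm$cls == cls, ]
    a2 <- data.frame(birth = L - a$death, death = L - a$birth, dim = a$dim)
    # reversal also swaps the roles of birth/death within extended pairs
    expect_equal(sort_pairs(a2),
                 sort_pairs(as.data.frame(b[, c("birth", "death", "dim")])),
                 ignore_attr = TRUE)
  }
  expect_equal(sum(dhm$cls == "Ordinary" & dhm$dim == 0),
               sum(dh$cls == "Relative" & dh$dim == 1))
  expect_equal(sum(dhm$cls == "Relative" & dhm$dim == 1),
               sum(dh$cls == "Ordinary" & dh$dim == 0))
})

test_that("a one-pixel perturbation changes the persistence image boundedly", {
  set.seed(37)
  occ <- random_occupancy(10, 0.6)
  occ2 <- occ
  ij <- which(!occ2, arr.ind = TRUE)[1, ]
  occ2[ij[1], ij[2]] <- TRUE
  cfgv <- topo_config(image_resolution = 8)
  f1 <- as.numeric(topo_features(mk_grid(occ), cfgv))
  f2 <- as.numeric(topo_features(mk_grid(occ2), cfgv))
  expect_true(all(is.finite(f1)) && all(is.finite(f2)))
  img_idx <- seq_len(2 * 5 * 64)
  expect_lt(max(abs(f1[img_idx] - f2[img_idx])), 50)
})
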