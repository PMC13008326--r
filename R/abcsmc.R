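#' Scaled summary-statistic distance to observed replicates
#'
#' Builds the ABC distance: each selected summary statistic is scaled by
#' its largest absolute value in the training data (so scaled training
#' features lie in `[-1, 1]` and no statistic dominates by units), and the
#' distance of a candidate feature vector is the mean over observed
#' replicates of the Euclidean norm of the scaled difference. Features
#' whose training maximum absolute value is zero carry no information and
#' are dropped with a warning.
#'
#' @param train An [build_training_set()] tibble (or any data frame
#'   containing the selected columns).
#' @param selected Character vector of selected feature names.
#' @param observed Data frame of observed replicate feature vectors (one
#'   row per replicate; must contain the selected columns).
#' @return An object of class `abc_distance`.
#' @export
make_distance <- function(train, selected, observed) {
  observed <- tibble::as_tibble(observed)
  stopifnot(nrow(observed) >= 1)
  missing <- setdiff(selected, names(train))
  if (length(missing) > 0) {
    stop("selected features absent from training data: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  scales <- vapply(selected, function(f) max(abs(train[[f]])), numeric(1))
  zero <- scales == 0
  if (any(zero)) {
    warning(sum(zero), " feature(s) with zero training scale dropped",
            call. = FALSE)
    selected <- selected[!zero]
    scales <- scales[!zero]
  }
  if (length(selected) == 0) stop("no usable features", call. = FALSE)
  obs <- as.matrix(observed[, selected, drop = FALSE])
  obs_scaled <- sweep(obs, 2, scales, "/")
  structure(
    list(features = selected, scales = scales, obs_scaled = obs_scaled),
    class = "abc_distance"
  )
}

#' Evaluate an [make_distance()] distance on candidate feature vectors
#'
#' @param distance An `abc_distance` object.
#' @param x A data frame or matrix of feature vectors (rows).
#' @return Numeric vector of distances (mean over observed replicates of
#'   the scaled Euclidean distance).
#' @export
abc_distance_to <- function(distance, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, distance$features, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x[distance$features], nrow = 1)
  xs <- sweep(x[, distance$features, drop = FALSE], 2, distance$scales, "/")
  obs <- distance$obs_scaled
  d <- matrix(0, nrow(xs), nrow(obs))
  for (j in seq_len(nrow(obs))) {
    d[, j] <- sqrt(rowSums(sweep(xs, 2, obs[j, ], "-")^2))
  }
  rowMeans(d)
}

#' Feature-space simulator for one angiogenesis model
#'
#' Wraps [simulate_vessels()] + [featurize()] as a `function(theta, seed)`
#' returning a one-row feature tibble, the interface the ABC samplers use
#' (and which toy models can mimic in tests).
#'
#' @param model One of `"ac"`, `"sl"`, `"ps"`.
#' @param config A [domain_config()].
#' @param resolution,topo Passed to [featurize()].
#' @return A function `(theta, seed) -> one-row tibble`.
#' @export
angio_simulator <- function(model, config = domain_config(),
                            resolution = NULL, topo = topo_config()) {
  fields <- make_environment(config)
  function(theta, seed) {
    p <- do.call(model_params, c(list(model = model), as.list(theta)))
    sim <- simulate_vessels(p, config, seed = seed, fields = fields)
    featurize(sim, resolution = resolution, config = topo)
  }
}

#' Plain ABC rejection sampling
#'
#' Draws parameters from the prior, simulates, and accepts every draw whose
#' distance to the observed summaries is below `epsilon`.
#'
#' @param sim_fun A `function(theta, seed)` returning a feature row, e.g.
#'   from [angio_simulator()].
#' @param prior A prior tibble ([default_prior()] style).
#' @param distance An [make_distance()] object.
#' @param epsilon Acceptance tolerance (> 0; `Inf` accepts everything).
#' @param n_draws Number of prior draws.
#' @param seed Master seed (parameter draws and per-simulation seeds).
#' @return A list with `accepted` (tibble of accepted parameters and their
#'   distances) and `acceptance_rate`.
#' @export
abc_rejection <- function(sim_fun, prior, distance, epsilon, n_draws,
                          seed = 1L) {
  stopifnot(epsilon > 0, n_draws >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  thetas <- sample_prior(prior, n_draws)
  seeds <- sample.int(.Machine$integer.max, n_draws)
  dists <- vapply(seq_len(n_draws), function(i) {
    abc_distance_to(distance, sim_fun(thetas[i, ], seeds[i]))
  }, numeric(1))
  acc <- dists < epsilon
  if (!any(acc)) {
    stop("no draws accepted at epsilon = ", epsilon,
         "; increase the tolerance", call. = FALSE)
  }
  accepted <- dplyr::bind_cols(thetas[acc, ], tibble::tibble(distance = dists[acc]))
  list(accepted = accepted, acceptance_rate = mean(acc))
}

#' ABC sequential Monte Carlo
#'
#' Sequential importance sampling through a decreasing tolerance schedule.
#' Generation 1 draws from the prior at tolerance `eps1` (default `Inf`,
#' i.e. the prior predictive); each later generation resamples the previous
#' particles by weight, perturbs them with a component-wise Gaussian kernel
#' whose variance is twice the weighted empirical variance of the previous
#' generation, rejects proposals outside the prior support, and accepts at
#' the next tolerance, set adaptively to the `alpha` quantile (default the
#' median) of the previous generation's accepted distances. Importance
#' weights follow the standard sequential scheme
#' `w_i` proportional to `pi(theta_i) / sum_j w_j K(theta_i | theta_j)`.
#' If a generation cannot reach `n_particles` acceptances within
#' `max_attempts` proposals the algorithm stops and returns the completed
#' generations with status `"stopped_early"`.
#'
#' @inheritParams abc_rejection
#' @param n_particles Particles per generation (>= 50).
#' @param n_generations Number of generations.
#' @param eps1 Generation-1 tolerance.
#' @param alpha Quantile of accepted distances used for the next tolerance.
#' @param max_attempts Proposal budget per generation (default `50 *
#'   n_particles`).
#' @return An object of class `abc_smc`: list with `populations` (one
#'   tibble per generation: parameter columns, `weight`, `distance`),
#'   `epsilons`, `acceptance_rates`, `status`, `prior`.
#' @export
abc_smc <- function(sim_fun, prior, distance, n_particles = 200,
                    n_generations = 5, seed = 1L, eps1 = Inf, alpha = 0.5,
                    max_attempts = NULL) {
  stopifnot(n_particles >= 50, n_generations >= 1)
  max_attempts <- max_attempts %||% (50L * n_particles)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pnames <- prior$param
  npar <- length(pnames)
  populations <- list()
  epsilons <- numeric(0)
  rates <- numeric(0)
  status <- "ok"
  prev <- NULL
  eps <- eps1
  for (gen in seq_len(n_generations)) {
    if (gen > 1) {
      new_eps <- stats::quantile(prev$distance, alpha, names = FALSE)
      # keep the schedule strictly decreasing even under distance ties
      eps <- if (new_eps < eps) new_eps else eps * 0.95
      kmean <- as.matrix(prev[, pnames])
      ksd <- vapply(seq_len(npar), function(d) {
        mu <- sum(prev$weight * kmean[, d])
        sqrt(2 * sum(prev$weight * (kmean[, d] - mu)^2))
      }, numeric(1))
      ksd <- pmax(ksd, 1e-9 * (prior$upper - prior$lower))
    }
    acc_theta <- matrix(NA_real_, n_particles, npar)
    acc_dist <- numeric(n_particles)
    n_acc <- 0L
    attempts <- 0L
    while (n_acc < n_particles && attempts < max_attempts) {
      attempts <- attempts + 1L
      if (gen == 1) {
        theta <- vapply(seq_len(npar), function(d) {
          stats::runif(1, prior$lower[d], prior$upper[d])
        }, numeric(1))
      } else {
        j <- sample.int(n_particles, 1, prob = prev$weight)
        theta <- kmean[j, ] + stats::rnorm(npar, 0, ksd)
        if (any(theta < prior$lower | theta > prior$upper)) next
      }
      names(theta) <- pnames
      sim_seed <- sample.int(.Machine$integer.max, 1)
      d <- abc_distance_to(distance, sim_fun(theta, sim_seed))
      if (d < eps) {
        n_acc <- n_acc + 1L
        acc_theta[n_acc, ] <- theta
        acc_dist[n_acc] <- d
      }
    }
    if (n_acc < n_particles) {
      status <- "stopped_early"
      break
    }
    if (gen == 1) {
      w <- rep(1 / n_particles, n_particles)
    } else {
      w <- vapply(seq_len(n_particles), function(i) {
        kd <- rep(1, n_particles)
        for (d in seq_len(npar)) {
          kd <- kd * stats::dnorm(acc_theta[i, d], kmean[, d], ksd[d])
        }
        pd <- prod(stats::dunif(acc_theta[i, ], prior$lower, prior$upper))
        pd / sum(prev$weight * kd)
      }, numeric(1))
      w <- w / sum(w)
    }
    pop <- tibble::as_tibble(as.data.frame(acc_theta))
    names(pop) <- pnames
    pop$weight <- w
    pop$distance <- acc_dist
    populations[[gen]] <- pop
    epsilons[gen] <- eps
    rates[gen] <- n_particles / attempts
    prev <- pop
  }
  structure(
    list(populations = populations, epsilons = epsilons,
         acceptance_rates = rates, status = status,
         n_particles = n_particles, prior = prior, seed = seed),
    class = "abc_smc"
  )
}

#' @export
print.abc_smc <- function(x, ...) {
  cat(sprintf("<abc_smc> %d generation(s), N = %d, status = %s\n",
              length(x$populations), x$n_particles, x$status))
  if (length(x$epsilons) > 0) {
    cat("  epsilons:", paste(signif(x$epsilons, 4), collapse = " > "), "\n")
    cat("  acceptance:", paste(signif(x$acceptance_rates, 3), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Weighted Gaussian kernel density of an ABC posterior sample
#'
#' Fits a diagonal-bandwidth weighted Gaussian KDE to the final particle
#' population (bandwidths by Silverman's rule on weighted moments, with the
#' effective sample size in place of n). Supports density evaluation and
#' highest-posterior-density membership queries.
#'
#' @param x An [abc_smc()] object or a population tibble with parameter
#'   columns and a `weight` column.
#' @param params Optional character vector naming the parameter columns.
#' @return An object of class `angio_kde`.
#' @export
posterior_density <- function(x, params = NULL) {
  pop <- if (inherits(x, "abc_smc")) {
    params <- params %||% x$prior$param
    x$populations[[length(x$populations)]]
  } else {
    tibble::as_tibble(x)
  }
  params <- params %||% setdiff(names(pop), c("weight", "distance"))
  pts <- as.matrix(pop[, params, drop = FALSE])
  w <- if ("weight" %in% names(pop)) pop$weight else rep(1 / nrow(pts), nrow(pts))
  w <- w / sum(w)
  if (nrow(unique(pts)) < 2) {
    stop("need at least 2 distinct particles for a density estimate",
         call. = FALSE)
  }
  neff <- 1 / sum(w^2)
  d <- ncol(pts)
  # multivariate Silverman rule with the effective sample size
  fac <- (4 / (d + 2))^(1 / (d + 4)) * neff^(-1 / (d + 4))
  bw <- vapply(seq_len(d), function(j) {
    mu <- sum(w * pts[, j])
    sd_w <- sqrt(sum(w * (pts[, j] - mu)^2))
    h <- fac * sd_w
    if (h <= 0) h <- max(1e-9, 1e-3 * max(abs(pts[, j]), 1))
    h
  }, numeric(1))
  structure(list(particles = pts, weights = w, bandwidth = bw,
                 params = params),
            class = "angio_kde")
}

#' Evaluate an [posterior_density()] estimate
#'
#' @param kde An `angio_kde` object.
#' @param x Named vector, matrix or data frame of evaluation points.
#' @return Numeric vector of density values.
#' @export
kde_density <- function(kde, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, kde$params, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x[kde$params], nrow = 1,
                                   dimnames = list(NULL, kde$params))
  pts <- kde$particles
  bw <- kde$bandwidth
  vapply(seq_len(nrow(x)), function(i) {
    k <- rep(1, nrow(pts))
    for (d in seq_len(ncol(pts))) {
      k <- k * stats::dnorm(x[i, d], pts[, d], bw[d])
    }
    sum(kde$weights * k)
  }, numeric(1))
}

#' Membership in the highest-posterior-density region
#'
#' A point is inside the `level` HPD region when its KDE density is at
#' least the weighted `(1 - level)` quantile of the density evaluated at
#' the particles themselves (the standard sample-based HPD cut).
#'
#' @param kde An `angio_kde` object.
#' @param theta Named parameter vector (or data frame rows).
#' @param level HPD mass (default 0.95).
#' @return Logical vector.
#' @export
hpd_contains <- function(kde, theta, level = 0.95) {
  f_particles <- kde_density(kde, kde$particles)
  cut <- weighted_quantile(f_particles, kde$weights, 1 - level)
  kde_density(kde, theta) >= cut
}

weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= p)[1]]
}
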