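# Toy models and synthetic designs shared across inference tests.

# Conjugate Gaussian toy: one observation x = mu + N(0, 1), uniform prior.
# As the tolerance shrinks the ABC posterior approaches the truncated
# normal N(x_obs, 1) restricted to the prior support.
gaussian_toy <- function(x_obs = 0.8, half_width = 5) {
  list(
    prior = tibble::tibble(param = "mu", lower = -half_width,
                           upper = half_width),
    sim_fun = function(theta, seed) {
      set.seed(seed)
      tibble::tibble(xbar = theta[["mu"]] + stats::rnorm(1))
    },
    observed = tibble::tibble(xbar = x_obs),
    x_obs = x_obs
  )
}

# A flat reference table so max-abs scaling of the toy summary is fixed.
gaussian_toy_train <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(xbar = stats::runif(n, -6, 6))
}

# Three Gaussian blobs in 5 features, separation controls class overlap.
blob_training <- function(n_per_class = 120, sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  rows <- lapply(1:3, function(k) {
    x <- matrix(stats::rnorm(n_per_class * 5, sd = sd), n_per_class, 5)
    x[, 1] <- x[, 1] + centers[k, 1]
    x[, 2] <- x[, 2] + centers[k, 2]
    colnames(x) <- paste0("t_y_f", 1:5)
    dplyr::bind_cols(tibble::tibble(model = c("ac", "sl", "ps")[k]),
                     tibble::as_tibble(x))
  })
  dplyr::bind_rows(rows)
}

# Feature table with one planted informative column among pure noise.
planted_training <- function(n = 200, n_noise = 29, seed = 1,
                             signal = "sx_mean") {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  colnames(x) <- sprintf("t_y_n%02d", seq_len(n_noise))
  tab <- tibble::as_tibble(x)
  tab[[signal]] <- stats::rnorm(n)
  tab$theta <- 3 * tab[[signal]] + stats::rnorm(n, 0, 0.3)
  dplyr::bind_cols(tibble::tibble(model = "toy", sim_seed = seq_len(n)), tab)
}

# Small shared simulation config for fast tests.
fast_config <- function(n_timesteps = 120, ...) {
  domain_config(n_timesteps = n_timesteps, ...)
}
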