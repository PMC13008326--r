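#' Model parameters for the three angiogenesis models
#'
#' Each model exposes exactly four inferred parameters:
#' \describe{
#'   \item{ac}{`chi` (chemotaxis), `rho` (haptotaxis), `a_br`, `c_br`.}
#'   \item{sl}{`kappa` (chemotactic drift), `sigma` (velocity noise),
#'     `a_br`, `c_br`.}
#'   \item{ps}{`d_c` (chemotactic turn bias), `D_r` (turning rate),
#'     `a_br`, `c_br`.}
#' }
#' `a_br` is the minimum tip age before branching (time units) and `c_br` the
#' VEGF concentration threshold for branching; both gates must be exceeded
#' for a tip to be eligible to bifurcate.
#'
#' @param model One of `"ac"`, `"sl"`, `"ps"`.
#' @param ... The four named parameter values for that model.
#' @return An object of class `angio_params`: list with `model` and the named
#'   numeric vector `theta`.
#' @export
#' @examples
#' model_params("ac", chi = 1, rho = 0.5, a_br = 20, c_br = 0.3)
model_params <- function(model = c("ac", "sl", "ps"), ...) {
  model <- match.arg(model)
  theta <- c(...)
  expected <- param_names(model)
  if (!setequal(names(theta), expected)) {
    stop(sprintf("model '%s' needs exactly the parameters: %s", model,
                 paste(expected, collapse = ", ")), call. = FALSE)
  }
  theta <- theta[expected]
  if (any(theta < 0)) stop("parameters must be non-negative", call. = FALSE)
  if (theta[["c_br"]] > 1) stop("`c_br` must lie in [0, 1]", call. = FALSE)
  structure(list(model = model, theta = theta), class = "angio_params")
}

#' @rdname model_params
#' @export
param_names <- function(model = c("ac", "sl", "ps")) {
  switch(match.arg(model),
    ac = c("chi", "rho", "a_br", "c_br"),
    sl = c("kappa", "sigma", "a_br", "c_br"),
    ps = c("d_c", "D_r", "a_br", "c_br")
  )
}

#' Independent uniform priors over model parameters
#'
#' Ranges span each model's qualitative regimes on the default dimensionless
#' domain (side length 1, `dt = 1`, 300 steps): chemotaxis/haptotaxis weights
#' from unbiased to strongly biased walks, branching age up to a third of the
#' simulation, and the VEGF branching threshold across the domain height.
#'
#' @param model One of `"ac"`, `"sl"`, `"ps"`.
#' @return A tibble of class `angio_prior` with columns `param`, `lower`,
#'   `upper` and attribute `model`.
#' @export
default_prior <- function(model = c("ac", "sl", "ps")) {
  model <- match.arg(model)
  tab <- switch(model,
    ac = tibble::tribble(
      ~param, ~lower, ~upper,
      "chi",  0,      2,
      "rho",  0,      2,
      "a_br", 0,      100,
      "c_br", 0,      0.9
    ),
    sl = tibble::tribble(
      ~param, ~lower, ~upper,
      "kappa", 0,     0.04,
      "sigma", 0,     0.02,
      "a_br",  0,     100,
      "c_br",  0,     0.9
    ),
    ps = tibble::tribble(
      ~param, ~lower, ~upper,
      "d_c",  0,      1,
      "D_r",  0,      0.3,
      "a_br", 0,      100,
      "c_br", 0,      0.9
    )
  )
  structure(tab, model = model, class = c("angio_prior", class(tab)))
}

#' Sample from / evaluate a uniform prior
#'
#' @param prior An `angio_prior` tibble (columns `param`, `lower`, `upper`).
#' @param n Number of draws.
#' @return `sample_prior()`: a tibble with one column per parameter;
#'   `prior_density()`: numeric vector of joint densities (0 outside support).
#' @export
sample_prior <- function(prior, n) {
  stopifnot(all(prior$lower < prior$upper))
  draws <- purrr::map(seq_len(nrow(prior)), function(i) {
    stats::runif(n, prior$lower[i], prior$upper[i])
  })
  names(draws) <- prior$param
  tibble::as_tibble(draws)
}

#' @rdname sample_prior
#' @param theta A named numeric vector or data frame of parameter values.
#' @export
prior_density <- function(prior, theta) {
  m <- as.matrix(as.data.frame(theta)[, prior$param, drop = FALSE])
  dens <- rep(1, nrow(m))
  for (i in seq_len(nrow(prior))) {
    dens <- dens * stats::dunif(m[, i], prior$lower[i], prior$upper[i])
  }
  dens
}
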