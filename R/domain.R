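#' Configure the simulation domain
#'
#' All three angiogenesis models share a square domain `[0, L] x [0, L]`
#' (dimensionless) with the parent vessel along the bottom edge (`y = 0`) and
#' the tumour beyond the top edge (`y = L`). The Anderson-Chaplain model moves
#' on a lattice of `lattice_resolution` nodes per side (spacing
#' `h = L / (lattice_resolution - 1)`); the same grid is used to rasterize the
#' off-lattice models so that all models feed identical downstream statistics.
#'
#' @param side_length Domain side length `L` (dimensionless). Default 1.
#' @param lattice_resolution Number of lattice nodes per side (>= 8).
#' @param n_initial_tips Number of tip cells seeded along the bottom (>= 2).
#' @param n_timesteps Number of time steps to simulate.
#' @param dt Time-step size (model time units).
#' @param control Nuisance coefficients, see [angio_control()].
#' @return An object of class `angio_domain`.
#' @export
domain_config <- function(side_length = 1, lattice_resolution = 51,
                          n_initial_tips = 7, n_timesteps = 300, dt = 1,
                          control = angio_control()) {
  stopifnot(side_length > 0, dt > 0, n_timesteps >= 1)
  if (lattice_resolution < 8) {
    stop("`lattice_resolution` must be at least 8", call. = FALSE)
  }
  if (n_initial_tips < 2) {
    stop("`n_initial_tips` must be at least 2 (multiple distinct tips seed the bottom edge)",
         call. = FALSE)
  }
  structure(
    list(
      side_length = side_length,
      lattice_resolution = as.integer(lattice_resolution),
      n_initial_tips = as.integer(n_initial_tips),
      n_timesteps = as.integer(n_timesteps),
      dt = dt,
      h = side_length / (lattice_resolution - 1),
      control = control
    ),
    class = "angio_domain"
  )
}

#' Nuisance coefficients for the angiogenesis simulators
#'
#' The four inferred parameters per model live in [model_params()]; everything
#' else about the movement rules is a nuisance coefficient fixed here and
#' exposed rather than hard-coded.
#'
#' @param ac_diffusion Baseline (unbiased) move weight of the lattice walk.
#' @param stay_weight Weight of the stay-in-place move `P0` (default 0: the
#'   tip moves every step unless all four move weights clamp to zero).
#' @param branch_rate Per-step Bernoulli probability that an *eligible* tip
#'   (age > `a_br` and VEGF > `c_br`) bifurcates.
#' @param max_tips Hard cap on simultaneously tracked tips.
#' @param sl_drag Velocity relaxation (drag) coefficient `beta` of the
#'   Stokes-Lauffenburger velocity SDE.
#' @param sl_v0 Initial upward speed of Stokes-Lauffenburger tips.
#' @param ps_speed Constant Plank-Sleeman tip speed; default `h / dt` (one
#'   lattice spacing per step).
#' @param ps_dphi Plank-Sleeman angular increment `phi_hat` (radians).
#' @param fusion_radius Anastomosis fusion radius for off-lattice models;
#'   default one lattice spacing `h`.
#' @param vegf_profile One of `"linear"` or `"exponential"`.
#' @param vegf_decay Decay constant `k` of the exponential VEGF profile.
#' @param fib_init Initial uniform fibronectin level.
#' @param fib_production,fib_uptake Production / uptake rates of fibronectin
#'   at sites occupied by tip cells (Anderson-Chaplain only).
#' @param fib_dynamic Logical; evolve fibronectin under the tips (default) or
#'   keep it static.
#' @return A named list of class `angio_control`.
#' @export
angio_control <- function(ac_diffusion = 1, stay_weight = 0,
                          branch_rate = 0.05, max_tips = 256,
                          sl_drag = 0.5, sl_v0 = 0.01,
                          ps_speed = NULL, ps_dphi = pi / 6,
                          fusion_radius = NULL,
                          vegf_profile = "linear", vegf_decay = 5,
                          fib_init = 0.25, fib_production = 0.02,
                          fib_uptake = 0.01, fib_dynamic = TRUE) {
  stopifnot(ac_diffusion >= 0, stay_weight >= 0, branch_rate >= 0,
            branch_rate <= 1, max_tips >= 2, sl_drag >= 0, ps_dphi > 0)
  structure(
    list(
      ac_diffusion = ac_diffusion, stay_weight = stay_weight,
      branch_rate = branch_rate, max_tips = as.integer(max_tips),
      sl_drag = sl_drag, sl_v0 = sl_v0,
      ps_speed = ps_speed, ps_dphi = ps_dphi,
      fusion_radius = fusion_radius,
      vegf_profile = vegf_profile, vegf_decay = vegf_decay,
      fib_init = fib_init, fib_production = fib_production,
      fib_uptake = fib_uptake, fib_dynamic = fib_dynamic
    ),
    class = "angio_control"
  )
}

#' Build the VEGF and fibronectin fields
#'
#' VEGF is a static, nondimensional concentration `c(x, y)` in `[0, 1]` that
#' increases from the bottom of the domain towards the tumour at the top.
#' Two profiles are supported:
#' \describe{
#'   \item{linear}{`c(x, y) = y / L`.}
#'   \item{exponential}{`c(x, y) = exp(-k (L - y) / L)` with decay `k`.}
#' }
#' Fibronectin starts uniform at `control$fib_init` and is produced/consumed
#' under tip cells during Anderson-Chaplain simulations.
#'
#' @param config An [domain_config()] object.
#' @param profile Overrides `config$control$vegf_profile` if given.
#' @param decay Overrides `config$control$vegf_decay` if given.
#' @return An object of class `angio_fields` with matrices `vegf` and
#'   `fibronectin` indexed `[ix, iy]` over lattice nodes, node `i` at
#'   coordinate `(i - 1) * h`.
#' @export
make_environment <- function(config, profile = NULL, decay = NULL) {
  stopifnot(inherits(config, "angio_domain"))
  profile <- profile %||% config$control$vegf_profile
  decay <- decay %||% config$control$vegf_decay
  R <- config$lattice_resolution
  L <- config$side_length
  yy <- seq(0, L, length.out = R)
  cy <- switch(profile,
    linear = yy / L,
    exponential = exp(-decay * (L - yy) / L),
    stop("unknown VEGF profile: ", profile, call. = FALSE)
  )
  vegf <- matrix(rep(cy, each = R), nrow = R)  # [ix, iy]
  fib <- matrix(config$control$fib_init, R, R)
  structure(
    list(vegf = vegf, fibronectin = fib, config = config, profile = profile),
    class = "angio_fields"
  )
}

# Bilinear interpolation of a node field at continuous coordinates.
field_at <- function(mat, x, y, config) {
  h <- config$h
  R <- config$lattice_resolution
  fx <- pmin(pmax(x / h, 0), R - 1)
  fy <- pmin(pmax(y / h, 0), R - 1)
  i0 <- pmin(floor(fx), R - 2)
  j0 <- pmin(floor(fy), R - 2)
  tx <- fx - i0
  ty <- fy - j0
  i0 <- i0 + 1L  # to 1-based
  j0 <- j0 + 1L
  v00 <- mat[cbind(i0, j0)]
  v10 <- mat[cbind(i0 + 1L, j0)]
  v01 <- mat[cbind(i0, j0 + 1L)]
  v11 <- mat[cbind(i0 + 1L, j0 + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

# Central-difference gradient matrices of a node field (one-sided at edges).
field_gradient <- function(mat, config) {
  h <- config$h
  R <- config$lattice_resolution
  gx <- matrix(0, R, R)
  gy <- matrix(0, R, R)
  gx[2:(R - 1), ] <- (mat[3:R, ] - mat[1:(R - 2), ]) / (2 * h)
  gx[1, ] <- (mat[2, ] - mat[1, ]) / h
  gx[R, ] <- (mat[R, ] - mat[R - 1, ]) / h
  gy[, 2:(R - 1)] <- (mat[, 3:R] - mat[, 1:(R - 2)]) / (2 * h)
  gy[, 1] <- (mat[, 2] - mat[, 1]) / h
  gy[, R] <- (mat[, R] - mat[, R - 1]) / h
  list(gx = gx, gy = gy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
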