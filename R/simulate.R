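#' Lattice move probabilities of the Anderson-Chaplain model
#'
#' A tip cell on the lattice makes one of five moves each step (stay, right,
#' left, up, down) with probabilities `P0..P4` obtained by normalizing
#' non-negative move weights. The weight of a move towards a neighbouring
#' node is the baseline diffusion weight plus chemotactic and haptotactic
#' biases proportional to the VEGF and fibronectin differences per lattice
#' spacing:
#' \deqn{w_d = \max(0,\; D + \chi (c_d - c_0)/h + \rho (f_d - f_0)/h)}
#' Moves off the lattice get weight 0; if every weight (including the stay
#' weight) is 0 the tip stays in place (`P0 = 1`). Negative weights under
#' strong gradients are clamped to 0 before normalization, preserving the
#' probability simplex.
#'
#' @param tip A list with `position` (length-2, domain coordinates; snapped
#'   to the nearest lattice node).
#' @param fields An [make_environment()] object.
#' @param params An [model_params()] object with `model = "ac"`.
#' @param config The [domain_config()].
#' @return Named numeric of length 5: `P0` (stay), `P1` (right), `P2` (left),
#'   `P3` (up), `P4` (down); non-negative, summing to 1.
#' @export
ac_move_probabilities <- function(tip, fields, params, config) {
  stopifnot(params$model == "ac")
  h <- config$h
  ix <- as.integer(round(tip$position[1] / h))
  iy <- as.integer(round(tip$position[2] / h))
  w <- ac_move_weights(ix, iy, fields$vegf, fields$fibronectin,
                       params$theta[["chi"]], params$theta[["rho"]], config)
  p <- ac_weights_to_probs(w)
  c(P0 = p$p0[1], P1 = p$p1[1], P2 = p$p2[1], P3 = p$p3[1], P4 = p$p4[1])
}

# Vectorized move weights for 0-based lattice indices (ix, iy).
ac_move_weights <- function(ix, iy, vegf, fib, chi, rho, config) {
  R <- config$lattice_resolution
  h <- config$h
  D <- config$control$ac_diffusion
  i1 <- ix + 1L
  j1 <- iy + 1L
  c0 <- vegf[cbind(i1, j1)]
  f0 <- fib[cbind(i1, j1)]
  wdir <- function(di, dj) {
    ok <- (ix + di) >= 0L & (ix + di) <= (R - 1L) &
      (iy + dj) >= 0L & (iy + dj) <= (R - 1L)
    w <- numeric(length(ix))
    if (any(ok)) {
      idx <- cbind(i1[ok] + di, j1[ok] + dj)
      w[ok] <- pmax(0, D + chi * (vegf[idx] - c0[ok]) / h +
                      rho * (fib[idx] - f0[ok]) / h)
    }
    w
  }
  list(right = wdir(1L, 0L), left = wdir(-1L, 0L),
       up = wdir(0L, 1L), down = wdir(0L, -1L),
       stay = rep(config$control$stay_weight, length(ix)))
}

ac_weights_to_probs <- function(w) {
  s <- w$stay + w$right + w$left + w$up + w$down
  zero <- s <= 0
  s[zero] <- 1
  p0 <- w$stay / s
  p0[zero] <- 1
  list(p0 = p0, p1 = w$right / s, p2 = w$left / s, p3 = w$up / s,
       p4 = w$down / s)
}

#' One Euler-Maruyama step of the Stokes-Lauffenburger velocity SDE
#'
#' Tip velocity follows an Ornstein-Uhlenbeck process with additive
#' chemotactic drift along the VEGF gradient:
#' \deqn{dw = (-\beta w + \kappa \nabla c)\,dt + \sigma\,dW}
#' discretized by Euler-Maruyama; the position advances by `w * dt`. Side and
#' bottom walls reflect (position and the normal velocity component); the top
#' boundary absorbs (the tip reaches the tumour and is deactivated by the
#' caller). Consumes two standard-normal draws from the current RNG stream.
#'
#' @inheritParams ac_move_probabilities
#' @param dt Time-step size.
#' @return List with updated `position`, `velocity`, and `absorbed` flag.
#' @export
sl_velocity_step <- function(tip, fields, params, config, dt = config$dt) {
  stopifnot(params$model == "sl", dt > 0)
  grad <- fields$gradients %||% field_gradient(fields$vegf, fields$config)
  st <- sl_step_core(tip$position[1], tip$position[2],
                     tip$velocity[1], tip$velocity[2],
                     grad, params$theta[["kappa"]], params$theta[["sigma"]],
                     fields$config, dt,
                     xi1 = stats::rnorm(1), xi2 = stats::rnorm(1))
  if (!all(is.finite(c(st$vx, st$vy)))) {
    stop("non-finite velocity in SL step", call. = FALSE)
  }
  list(position = c(st$x, st$y), velocity = c(st$vx, st$vy),
       absorbed = st$absorbed)
}

sl_step_core <- function(x, y, vx, vy, grad, kappa, sigma, config, dt,
                         xi1, xi2) {
  beta <- config$control$sl_drag
  gx <- field_at(grad$gx, x, y, config)
  gy <- field_at(grad$gy, x, y, config)
  vx <- vx + (-beta * vx + kappa * gx) * dt + sigma * sqrt(dt) * xi1
  vy <- vy + (-beta * vy + kappa * gy) * dt + sigma * sqrt(dt) * xi2
  x <- x + vx * dt
  y <- y + vy * dt
  L <- config$side_length
  # reflecting side and bottom walls
  refl <- x < 0
  x[refl] <- -x[refl]
  vx[refl] <- -vx[refl]
  refl <- x > L
  x[refl] <- 2 * L - x[refl]
  vx[refl] <- -vx[refl]
  refl <- y < 0
  y[refl] <- -y[refl]
  vy[refl] <- -vy[refl]
  absorbed <- y >= L
  y[absorbed] <- L
  x <- pmin(pmax(x, 0), L)
  list(x = x, y = y, vx = vx, vy = vy, absorbed = absorbed)
}

#' One turning step of the Plank-Sleeman discrete-angle model
#'
#' The tip moves at constant speed; its heading, measured as the angle
#' `phi` from the vertical (counter-clockwise positive), turns by `+phi_hat`
#' with probability `tau_plus`, by `-phi_hat` with probability `tau_minus`,
#' and otherwise stays:
#' \deqn{\tau_\pm = D_r\,dt\,\exp\{d_c\,(\cos(\phi \pm \hat\phi) - \cos\phi)\}}
#' so the turning rate scales with `D_r` and, when `d_c > 0`, the turn that
#' increases alignment with the upward (tumour) direction has the larger
#' rate; `d_c = 0` gives symmetric turning. Consumes one uniform draw.
#'
#' @inheritParams sl_velocity_step
#' @return List with updated `position`, `heading` (radians from vertical),
#'   `speed`, and `absorbed` flag.
#' @export
ps_turn_step <- function(tip, fields, params, config, dt = config$dt) {
  stopifnot(params$model == "ps", dt > 0)
  ps_check_rates(params, config, dt)
  speed <- tip$speed %||% config$control$ps_speed %||% (config$h / config$dt)
  st <- ps_step_core(tip$position[1], tip$position[2], tip$heading,
                     params$theta[["D_r"]], params$theta[["d_c"]],
                     config, dt, speed, u = stats::runif(1))
  list(position = c(st$x, st$y), heading = st$phi, speed = speed,
       absorbed = st$absorbed)
}

ps_turn_rates <- function(phi, D_r, d_c, dphi, dt) {
  base <- D_r * dt
  list(plus = base * exp(d_c * (cos(phi + dphi) - cos(phi))),
       minus = base * exp(d_c * (cos(phi - dphi) - cos(phi))))
}

ps_check_rates <- function(params, config, dt) {
  dphi <- config$control$ps_dphi
  phis <- seq(-pi, pi, length.out = 181)
  r <- ps_turn_rates(phis, params$theta[["D_r"]], params$theta[["d_c"]],
                     dphi, dt)
  if (max(r$plus + r$minus) > 1) {
    stop("PS turning probabilities exceed 1 for these (D_r, d_c); ",
         "use a smaller dt", call. = FALSE)
  }
  invisible(TRUE)
}

ps_step_core <- function(x, y, phi, D_r, d_c, config, dt, speed, u) {
  dphi <- config$control$ps_dphi
  r <- ps_turn_rates(phi, D_r, d_c, dphi, dt)
  phi <- phi + dphi * (u < r$plus) - dphi * (u >= r$plus & u < r$plus + r$minus)
  # heading phi from vertical, ccw positive: direction (-sin phi, cos phi)
  x <- x - speed * dt * sin(phi)
  y <- y + speed * dt * cos(phi)
  L <- config$side_length
  refl <- x < 0
  x[refl] <- -x[refl]
  phi[refl] <- -phi[refl]
  refl <- x > L
  x[refl] <- 2 * L - x[refl]
  phi[refl] <- -phi[refl]
  refl <- y < 0
  y[refl] <- -y[refl]
  phi[refl] <- pi - phi[refl]  # reflect heading about horizontal
  absorbed <- y >= L
  y[absorbed] <- L
  list(x = x, y = y, phi = phi, absorbed = absorbed)
}

#' Branching gate
#'
#' A tip may bifurcate into two independently moving tips only if its age
#' exceeds `a_br` *and* the VEGF concentration at its location exceeds
#' `c_br`; an eligible tip then fires with per-step probability
#' `control$branch_rate`. On branching both parent and daughter ages reset
#' to 0 and the daughter inherits the parent's lineage.
#'
#' @inheritParams ac_move_probabilities
#' @return `NULL` (no branch) or a daughter tip list with `position`,
#'   `age = 0`, and the parent's lineage.
#' @export
branch_check <- function(tip, fields, params, config) {
  cpos <- field_at(fields$vegf, tip$position[1], tip$position[2],
                   fields$config)
  eligible <- tip$age > params$theta[["a_br"]] && cpos > params$theta[["c_br"]]
  if (!eligible) return(NULL)
  if (stats::runif(1) >= config$control$branch_rate) return(NULL)
  list(position = tip$position, age = 0, lineage = tip$lineage %||% 1L)
}

#' Anastomosis test against existing trails
#'
#' A tip fuses (and is deactivated) when its location meets a trail laid by
#' a *different* lineage: same lattice cell for the lattice model, within the
#' fusion radius (default one lattice spacing) for the off-lattice models.
#'
#' @param tip A list with `position` and `lineage`.
#' @param trail A data frame of trail points with columns `x`, `y`,
#'   `lineage`.
#' @param config The [domain_config()].
#' @return Logical: `TRUE` if the tip fuses.
#' @export
anastomosis_check <- function(tip, trail, config) {
  if (is.null(trail) || nrow(trail) == 0) return(FALSE)
  other <- trail$lineage != (tip$lineage %||% 1L)
  if (!any(other)) return(FALSE)
  r <- config$control$fusion_radius %||% config$h
  d2 <- (trail$x[other] - tip$position[1])^2 +
    (trail$y[other] - tip$position[2])^2
  any(d2 <= r^2 + 1e-15)
}

#' Simulate a vascular network with one of the three snail-trail models
#'
#' Runs the chosen model for `config$n_timesteps` steps (or until every tip
#' is inactive). Tips are seeded evenly along the bottom edge, move by the
#' model's movement rule, deposit a stalk-cell trail behind them, may branch
#' (gate: age > `a_br` and VEGF > `c_br`), fuse with trails of other
#' lineages (anastomosis), and are absorbed at the top boundary (tumour).
#' The run is deterministic given `(model, params, config, seed)`: a single
#' RNG stream is seeded with `seed` and consumed in a fixed order (movement
#' draws for all active tips, then branching draws, each step).
#'
#' @param params An [model_params()] object (fixes the model).
#' @param config An [domain_config()].
#' @param seed Integer seed for the simulation's RNG stream.
#' @param fields Optional pre-built [make_environment()] fields.
#' @return An object of class `angio_sim`: list with `model`, `params`,
#'   `config`, `seed`, tibble `trail` (`x`, `y`, `tip`, `lineage`, `t`),
#'   `n_tips_final`, `n_branches`, `n_anastomoses`, `n_absorbed`.
#' @export
#' @examples
#' cfg <- domain_config(n_timesteps = 50)
#' sim <- simulate_vessels(model_params("ac", chi = 1, rho = 0, a_br = 5,
#'                                      c_br = 0.1), cfg, seed = 1)
#' sim$n_branches
simulate_vessels <- function(params, config = domain_config(), seed = 1L,
                             fields = NULL) {
  stopifnot(inherits(params, "angio_params"), inherits(config, "angio_domain"))
  model <- params$model
  fields <- fields %||% make_environment(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sim <- switch(model,
    ac = simulate_ac(params, config, fields),
    sl = simulate_offlattice(params, config, fields, "sl"),
    ps = simulate_offlattice(params, config, fields, "ps")
  )
  structure(
    c(list(model = model, params = params, config = config, seed = seed),
      sim),
    class = "angio_sim"
  )
}

initial_tip_x <- function(config) {
  n <- config$n_initial_tips
  config$side_length * seq_len(n) / (n + 1)
}

# --- Anderson-Chaplain lattice walk --------------------------------------

simulate_ac <- function(params, config, fields) {
  R <- config$lattice_resolution
  h <- config$h
  ctl <- config$control
  theta <- params$theta
  vegf <- fields$vegf
  fib <- fields$fibronectin

  ix <- as.integer(round(initial_tip_x(config) / h))
  n0 <- length(ix)
  iy <- rep(0L, n0)
  age <- rep(0, n0)
  active <- rep(TRUE, n0)
  lineage <- seq_len(n0)
  owner <- matrix(0L, R, R)
  owner[cbind(ix + 1L, iy + 1L)] <- lineage
  n_branch <- 0L
  n_anast <- 0L
  n_absorbed <- 0L
  tx <- list(ix)
  ty <- list(iy)
  tl <- list(lineage)
  tid <- list(seq_len(n0))
  tt <- list(rep(0L, n0))
  id <- seq_len(n0)
  next_id <- n0 + 1L

  for (step in seq_len(config$n_timesteps)) {
    act <- which(active)
    if (length(act) == 0) break
    w <- ac_move_weights(ix[act], iy[act], vegf, fib,
                         theta[["chi"]], theta[["rho"]], config)
    p <- ac_weights_to_probs(w)
    u <- stats::runif(length(act))
    c1 <- p$p0
    c2 <- c1 + p$p1
    c3 <- c2 + p$p2
    c4 <- c3 + p$p3
    dxs <- ifelse(u < c1, 0L, ifelse(u < c2, 1L, ifelse(u < c3, -1L, 0L)))
    dys <- ifelse(u < c3, 0L, ifelse(u < c4, 1L, -1L))
    nix <- ix[act] + dxs
    niy <- iy[act] + dys
    moved <- dxs != 0L | dys != 0L
    # anastomosis: entering a cell owned by a different lineage fuses
    own <- owner[cbind(nix + 1L, niy + 1L)]
    cellid <- nix * R + niy
    firstlin <- lineage[act][match(cellid, cellid)]
    fuse <- moved & ((own != 0L & own != lineage[act]) |
                       (own == 0L & firstlin != lineage[act]))
    stamp <- own == 0L & !fuse
    owner[cbind(nix + 1L, niy + 1L)[stamp, , drop = FALSE]] <-
      lineage[act][stamp]
    ix[act] <- nix
    iy[act] <- niy
    n_anast <- n_anast + sum(fuse)
    active[act[fuse]] <- FALSE
    # absorbing top boundary: tip reaches the tumour
    top <- niy == (R - 1L) & !fuse
    n_absorbed <- n_absorbed + sum(top)
    active[act[top]] <- FALSE
    # record trail sites
    tx <- c(tx, list(nix))
    ty <- c(ty, list(niy))
    tl <- c(tl, list(lineage[act]))
    tid <- c(tid, list(id[act]))
    tt <- c(tt, list(rep(step, length(act))))
    # fibronectin dynamics under the tips
    if (ctl$fib_dynamic) {
      cells <- cbind(nix + 1L, niy + 1L)
      f <- fib[cells]
      fib[cells] <- pmin(1, pmax(0, f + config$dt *
        (ctl$fib_production * (1 - f) - ctl$fib_uptake * f)))
    }
    # ageing then branching
    age[active] <- age[active] + config$dt
    act <- which(active)
    if (length(act) > 0 && length(ix) < ctl$max_tips) {
      cpos <- vegf[cbind(ix[act] + 1L, iy[act] + 1L)]
      eligible <- age[act] > theta[["a_br"]] & cpos > theta[["c_br"]]
      fire <- eligible & stats::runif(length(act)) < ctl$branch_rate
      fire_idx <- act[fire]
      room <- ctl$max_tips - length(ix)
      if (length(fire_idx) > room) fire_idx <- fire_idx[seq_len(room)]
      if (length(fire_idx) > 0) {
        n_new <- length(fire_idx)
        ix <- c(ix, ix[fire_idx])
        iy <- c(iy, iy[fire_idx])
        age[fire_idx] <- 0
        age <- c(age, rep(0, n_new))
        active <- c(active, rep(TRUE, n_new))
        lineage <- c(lineage, lineage[fire_idx])
        id <- c(id, next_id + seq_len(n_new) - 1L)
        next_id <- next_id + n_new
        n_branch <- n_branch + n_new
      }
    }
  }
  trail <- tibble::tibble(
    x = unlist(tx) * h, y = unlist(ty) * h,
    tip = unlist(tid), lineage = unlist(tl), t = unlist(tt)
  )
  list(trail = trail, fields = list(fibronectin = fib),
       n_tips_final = length(ix), n_branches = n_branch,
       n_anastomoses = n_anast, n_absorbed = n_absorbed,
       n_active_final = sum(active))
}

# --- Off-lattice models (SL velocity SDE, PS discrete-angle walk) ---------

simulate_offlattice <- function(params, config, fields, model) {
  R <- config$lattice_resolution
  h <- config$h
  L <- config$side_length
  ctl <- config$control
  theta <- params$theta
  if (model == "ps") ps_check_rates(params, config, config$dt)
  grad <- field_gradient(fields$vegf, config)
  speed <- ctl$ps_speed %||% (h / config$dt)

  x <- initial_tip_x(config)
  n0 <- length(x)
  y <- rep(0, n0)
  vx <- rep(0, n0)
  vy <- rep(ctl$sl_v0, n0)
  phi <- rep(0, n0)  # vertical heading
  age <- rep(0, n0)
  active <- rep(TRUE, n0)
  lineage <- seq_len(n0)
  id <- seq_len(n0)
  next_id <- n0 + 1L
  owner <- matrix(0L, R, R)
  ci <- as.integer(round(x / h))
  owner[cbind(ci + 1L, rep(1L, n0))] <- lineage
  n_branch <- 0L
  n_anast <- 0L
  n_absorbed <- 0L
  px <- list(x)
  py <- list(y)
  pl <- list(lineage)
  pid <- list(id)
  pt <- list(rep(0L, n0))

  for (step in seq_len(config$n_timesteps)) {
    act <- which(active)
    if (length(act) == 0) break
    if (model == "sl") {
      st <- sl_step_core(x[act], y[act], vx[act], vy[act], grad,
                         theta[["kappa"]], theta[["sigma"]], config,
                         config$dt,
                         xi1 = stats::rnorm(length(act)),
                         xi2 = stats::rnorm(length(act)))
      if (!all(is.finite(c(st$vx, st$vy)))) {
        stop(sprintf("non-finite SL velocity at step %d", step),
             call. = FALSE)
      }
      vx[act] <- st$vx
      vy[act] <- st$vy
    } else {
      st <- ps_step_core(x[act], y[act], phi[act], theta[["D_r"]],
                         theta[["d_c"]], config, config$dt, speed,
                         u = stats::runif(length(act)))
      phi[act] <- st$phi
    }
    x[act] <- st$x
    y[act] <- st$y
    # fusion at lattice-cell resolution (radius = one lattice spacing)
    nix <- as.integer(round(st$x / h))
    niy <- as.integer(round(st$y / h))
    own <- owner[cbind(nix + 1L, niy + 1L)]
    cellid <- nix * R + niy
    firstlin <- lineage[act][match(cellid, cellid)]
    fuse <- (own != 0L & own != lineage[act]) |
      (own == 0L & firstlin != lineage[act])
    stamp <- own == 0L & !fuse
    owner[cbind(nix + 1L, niy + 1L)[stamp, , drop = FALSE]] <-
      lineage[act][stamp]
    n_anast <- n_anast + sum(fuse)
    active[act[fuse]] <- FALSE
    absorbed <- st$absorbed & !fuse
    n_absorbed <- n_absorbed + sum(absorbed)
    active[act[absorbed]] <- FALSE
    px <- c(px, list(st$x))
    py <- c(py, list(st$y))
    pl <- c(pl, list(lineage[act]))
    pid <- c(pid, list(id[act]))
    pt <- c(pt, list(rep(step, length(act))))
    # ageing then branching
    age[active] <- age[active] + config$dt
    act <- which(active)
    if (length(act) > 0 && length(x) < ctl$max_tips) {
      cpos <- field_at(fields$vegf, x[act], y[act], config)
      eligible <- age[act] > theta[["a_br"]] & cpos > theta[["c_br"]]
      fire <- eligible & stats::runif(length(act)) < ctl$branch_rate
      fire_idx <- act[fire]
      room <- ctl$max_tips - length(x)
      if (length(fire_idx) > room) fire_idx <- fire_idx[seq_len(room)]
      if (length(fire_idx) > 0) {
        n_new <- length(fire_idx)
        x <- c(x, x[fire_idx])
        y <- c(y, y[fire_idx])
        if (model == "sl") {
          # split: parent and daughter velocities rotated +/- 45 degrees
          a <- pi / 4
          dvx <- vx[fire_idx] * cos(a) - vy[fire_idx] * sin(a)
          dvy <- vx[fire_idx] * sin(a) + vy[fire_idx] * cos(a)
          nvx <- vx[fire_idx] * cos(a) + vy[fire_idx] * sin(a)
          nvy <- -vx[fire_idx] * sin(a) + vy[fire_idx] * cos(a)
          vx[fire_idx] <- nvx
          vy[fire_idx] <- nvy
          vx <- c(vx, dvx)
          vy <- c(vy, dvy)
          phi <- c(phi, phi[fire_idx])
        } else {
          dphi <- ctl$ps_dphi
          dphi_new <- phi[fire_idx] + dphi
          phi[fire_idx] <- phi[fire_idx] - dphi
          phi <- c(phi, dphi_new)
          vx <- c(vx, vx[fire_idx])
          vy <- c(vy, vy[fire_idx])
        }
        age[fire_idx] <- 0
        age <- c(age, rep(0, n_new))
        active <- c(active, rep(TRUE, n_new))
        lineage <- c(lineage, lineage[fire_idx])
        id <- c(id, next_id + seq_len(n_new) - 1L)
        next_id <- next_id + n_new
        n_branch <- n_branch + n_new
      }
    }
  }
  trail <- tibble::tibble(
    x = unlist(px), y = unlist(py),
    tip = unlist(pid), lineage = unlist(pl), t = unlist(pt)
  )
  trail <- trail[order(trail$tip, trail$t), ]
  list(trail = trail, fields = NULL,
       n_tips_final = length(x), n_branches = n_branch,
       n_anastomoses = n_anast, n_absorbed = n_absorbed,
       n_active_final = sum(active))
}

#' @export
print.angio_sim <- function(x, ...) {
  cat(sprintf(
    "<angio_sim> model=%s seed=%d tips=%d branches=%d anastomoses=%d trail points=%d\n",
    x$model, x$seed, x$n_tips_final, x$n_branches, x$n_anastomoses,
    nrow(x$trail)))
  invisible(x)
}
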