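#' Tidy an ABC-SMC fit
#'
#' @param x An [abc_smc()] object.
#' @param generation Which generation to return (default: final).
#' @param ... Unused.
#' @return A tibble: one row per particle with parameter columns, `weight`,
#'   `distance` and `generation`.
#' @exportS3Method generics::tidy
tidy.abc_smc <- function(x, generation = NULL, ...) {
  gens <- if (is.null(generation)) length(x$populations) else generation
  dplyr::bind_rows(lapply(gens, function(g) {
    dplyr::mutate(x$populations[[g]], generation = g)
  }))
}

#' @rdname tidy.abc_smc
#' @return `glance()`: one row per generation with `epsilon`,
#'   `acceptance_rate`, `status`.
#' @exportS3Method generics::glance
glance.abc_smc <- function(x, ...) {
  tibble::tibble(
    generation = seq_along(x$epsilons),
    epsilon = x$epsilons,
    acceptance_rate = x$acceptance_rates,
    n_particles = x$n_particles,
    status = x$status
  )
}

#' Tidy a model-posterior estimate
#'
#' @param x A [model_posterior()] object.
#' @param ... Unused.
#' @return `tidy()`: per-replicate predictions; `glance()`: one-row summary.
#' @exportS3Method generics::tidy
tidy.model_posterior <- function(x, ...) {
  dplyr::mutate(x$replicates, replicate = dplyr::row_number(),
                .before = 1)
}

#' @rdname tidy.model_posterior
#' @exportS3Method generics::glance
glance.model_posterior <- function(x, ...) {
  tibble::tibble(predicted_model = x$predicted_model,
                 posterior_prob = x$posterior_prob,
                 oob_error = x$oob_error,
                 n_replicates = nrow(x$replicates))
}

#' Tidy a simulation result
#'
#' @param x An [simulate_vessels()] object.
#' @param ... Unused.
#' @return `tidy()`: the trail tibble; `glance()`: one-row counters.
#' @exportS3Method generics::tidy
tidy.angio_sim <- function(x, ...) {
  x$trail
}

#' @rdname tidy.angio_sim
#' @exportS3Method generics::glance
glance.angio_sim <- function(x, ...) {
  tibble::tibble(model = x$model, seed = x$seed,
                 n_tips_final = x$n_tips_final,
                 n_branches = x$n_branches,
                 n_anastomoses = x$n_anastomoses,
                 n_absorbed = x$n_absorbed,
                 n_trail_points = nrow(x$trail))
}
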