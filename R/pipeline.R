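#' Generate a synthetic observed test-case
#'
#' Simulates one model `r` times (default 10) at known parameters to stand
#' in for observed data with known ground truth: all replicates share the
#' true parameter vector and differ only by seed (seeds derived from the
#' master seed via the RNG stream).
#'
#' @param model One of `"ac"`, `"sl"`, `"ps"`.
#' @param theta Named true parameter vector for the model.
#' @param r Number of replicates.
#' @param config A [domain_config()].
#' @param seed Master seed.
#' @param resolution,topo Passed to [featurize()].
#' @return An object of class `angio_testcase`: list with `model`,
#'   `theta`, `sims` (list of [simulate_vessels()] results), `features`
#'   (tibble, one row per replicate), `seed`.
#' @export
make_testcase <- function(model, theta, r = 10, config = domain_config(),
                          seed = 1L, resolution = NULL,
                          topo = topo_config()) {
  stopifnot(r >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, r)
  fields <- make_environment(config)
  p <- do.call(model_params, c(list(model = model), as.list(theta)))
  sims <- lapply(seeds, function(s) {
    simulate_vessels(p, config, seed = s, fields = fields)
  })
  features <- dplyr::bind_rows(lapply(sims, featurize,
                                      resolution = resolution, config = topo))
  structure(
    list(model = model, theta = p$theta, r = r, sims = sims,
         features = features, seed = seed, config = config),
    class = "angio_testcase"
  )
}

#' Run the three-step inference pipeline on one test-case
#'
#' Executes, against a synthetic (or user-supplied) observed test-case:
#' step 1 — per-parameter regression-forest ranking and round-robin
#' selection of `ns` summary statistics per model; step 2 — ABC-SMC
#' approximation of each requested model's parameter posterior under the
#' scaled selected-statistic distance; step 3 — model-posterior estimation
#' from the classification forest and its out-of-bag error regressor on
#' the cross-model common statistics.
#'
#' @param testcase An [make_testcase()] object (or a list with `features`).
#' @param training Named list of [build_training_set()] tibbles, one per
#'   model (`ac`, `sl`, `ps`).
#' @param ns Number of selected statistics per model.
#' @param fit_models Models whose parameter posterior to fit by ABC-SMC
#'   (default: the test-case's generating model; use all three to
#'   reproduce full fits).
#' @param n_particles,n_generations,seed ABC-SMC settings.
#' @param num_trees Trees per random forest.
#' @param config,resolution,topo Simulation and featurization settings for
#'   the ABC simulators (defaults from the test-case).
#' @return A list of class `angio_pipeline_fit`: `selected` (per model),
#'   `common`, `posteriors` (named list of [abc_smc()] fits),
#'   `model_posterior`, `rankings`.
#' @export
run_pipeline <- function(testcase, training, ns = 100,
                         fit_models = testcase$model,
                         n_particles = 200, n_generations = 5, seed = 1L,
                         num_trees = 500, config = testcase$config,
                         resolution = NULL, topo = topo_config()) {
  stopifnot(all(c("ac", "sl", "ps") %in% names(training)))
  observed <- testcase$features
  # step 1: rank and select per model
  rankings <- lapply(training, function(tr) {
    prior <- attr(tr, "prior")
    lapply(stats::setNames(prior$param, prior$param), function(p) {
      rank_features(tr, p, num_trees = num_trees, seed = seed)
    })
  })
  selected <- lapply(rankings, select_top_features, ns = ns)
  # step 2: ABC-SMC per requested model
  posteriors <- lapply(stats::setNames(fit_models, fit_models), function(m) {
    dist <- make_distance(training[[m]], selected[[m]], observed)
    abc_smc(angio_simulator(m, config, resolution, topo),
            attr(training[[m]], "prior"), dist,
            n_particles = n_particles, n_generations = n_generations,
            seed = seed)
  })
  # step 3: model posterior on the common (unscaled) statistics
  common <- common_features(selected)
  pooled <- dplyr::bind_rows(lapply(training, function(tr) {
    tr[, c("model", common)]
  }))
  classifier <- train_classifier(pooled, common, num_trees = num_trees,
                                 seed = seed)
  regressor <- train_error_regressor(pooled, classifier,
                                     num_trees = num_trees, seed = seed + 1L)
  mp <- model_posterior(observed, classifier, regressor)
  structure(
    list(selected = selected, common = common, posteriors = posteriors,
         model_posterior = mp, rankings = rankings,
         classifier = classifier, regressor = regressor),
    class = "angio_pipeline_fit"
  )
}

#' @export
print.angio_pipeline_fit <- function(x, ...) {
  cat("<angio_pipeline_fit>\n")
  cat("  common features:", length(x$common), "\n")
  cat("  fitted posteriors:", paste(names(x$posteriors), collapse = ", "), "\n")
  print(x$model_posterior)
  invisible(x)
}
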