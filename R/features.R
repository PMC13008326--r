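#' Build a training set of prior draws, simulations and summary statistics
#'
#' Draws `n` parameter vectors from the prior, simulates the model once per
#' draw, and computes the full feature vector of each simulation. Fully
#' reproducible: `seed` seeds one RNG stream from which the parameter draws
#' and the per-simulation seeds are taken in a fixed order. Simulations
#' that fail are skipped with a warning; the number skipped is recorded in
#' the `n_failed` attribute.
#'
#' @param model One of `"ac"`, `"sl"`, `"ps"`.
#' @param prior An [default_prior()]-style tibble.
#' @param n Number of prior draws.
#' @param config A [domain_config()].
#' @param seed Master seed.
#' @param resolution,topo Passed to [featurize()].
#' @return A tibble of class `angio_train`: columns `model`, `sim_seed`,
#'   the parameter columns, then the feature columns.
#' @export
build_training_set <- function(model, prior = default_prior(model), n,
                               config = domain_config(), seed = 1L,
                               resolution = NULL, topo = topo_config()) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  thetas <- sample_prior(prior, n)
  sim_seeds <- sample.int(.Machine$integer.max, n)
  fields <- make_environment(config)
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      p <- do.call(model_params, c(list(model = model), as.list(thetas[i, ])))
      sim <- simulate_vessels(p, config, seed = sim_seeds[i], fields = fields)
      dplyr::bind_cols(
        tibble::tibble(model = model, sim_seed = sim_seeds[i]),
        thetas[i, ],
        featurize(sim, resolution = resolution, config = topo)
      )
    }, error = function(e) {
      warning(sprintf("simulation %d (seed %d) failed: %s", i, sim_seeds[i],
                      conditionMessage(e)), call. = FALSE)
      n_failed <<- n_failed + 1L
      NULL
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- n_failed
  attr(out, "prior") <- prior
  class(out) <- c("angio_train", class(out))
  out
}

feature_columns <- function(train) {
  grep("^s[xy]_|^t_", names(train), value = TRUE)
}

#' Rank summary statistics by random-forest importance for one parameter
#'
#' Fits a regression random forest (impurity importance, 500 trees by
#' default) of one model parameter on all summary statistics and returns
#' the features ranked by importance, normalized to sum to one.
#' Importance ties are broken by feature name so the ranking is
#' deterministic given the training table. The forest's out-of-bag R^2 is
#' attached for diagnostics.
#'
#' @param train An [build_training_set()] tibble.
#' @param param Name of the parameter column to predict.
#' @param num_trees Number of trees.
#' @param seed Forest seed.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return A tibble of class `angio_ranking` with columns `rank`,
#'   `feature`, `importance` (non-increasing), attributes `param` and
#'   `oob_r2`.
#' @export
rank_features <- function(train, param, num_trees = 500, seed = 1L,
                          importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  if (nrow(train) < 50) {
    stop("need at least 50 training records to rank features", call. = FALSE)
  }
  y <- train[[param]]
  if (is.null(y)) stop("unknown parameter column: ", param, call. = FALSE)
  if (stats::var(y) == 0) {
    stop("constant response: parameter ", param, " does not vary", call. = FALSE)
  }
  feats <- feature_columns(train)
  x <- as.data.frame(train[, feats])
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        importance = importance, seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  out <- tibble::tibble(rank = seq_along(imp), feature = names(imp)[ord],
                        importance = unname(imp[ord]))
  attr(out, "param") <- param
  attr(out, "oob_r2") <- fit$r.squared
  class(out) <- c("angio_ranking", class(out))
  out
}

#' Round-robin selection of the top `ns` summary statistics for one model
#'
#' Walks the per-parameter importance rankings in round-robin order, taking
#' the next not-yet-selected feature from each list in turn, until `ns`
#' distinct feature names are collected — an equal number from each
#' parameter's ranking up to overlap. Deterministic given the rankings.
#'
#' @param rankings A list of [rank_features()] tibbles (one per parameter).
#' @param ns Total number of statistics to select (divisible by the number
#'   of rankings; the headline choice is `ns = 100` over 4 parameters).
#' @return Character vector of `ns` distinct feature names.
#' @export
select_top_features <- function(rankings, ns = 100) {
  k <- length(rankings)
  stopifnot(k >= 1)
  if (ns %% k != 0) {
    stop("`ns` must be divisible by the number of rankings (", k, ")",
         call. = FALSE)
  }
  lists <- lapply(rankings, function(r) r$feature)
  n_distinct <- length(unique(unlist(lists)))
  if (n_distinct < ns) {
    stop("only ", n_distinct, " distinct features exist; cannot select ", ns,
         call. = FALSE)
  }
  selected <- character(0)
  ptr <- rep(1L, k)
  while (length(selected) < ns) {
    for (j in seq_len(k)) {
      if (length(selected) >= ns) break
      lst <- lists[[j]]
      while (ptr[j] <= length(lst) && lst[ptr[j]] %in% selected) {
        ptr[j] <- ptr[j] + 1L
      }
      if (ptr[j] <= length(lst)) {
        selected <- c(selected, lst[ptr[j]])
        ptr[j] <- ptr[j] + 1L
      }
    }
  }
  selected
}

#' Tabulate a selection by statistic type and direction
#'
#' @param selected Character vector of selected feature names.
#' @return A tibble with the 2x2 counts of (spatial/topological) x (x/y),
#'   summing to `length(selected)`.
#' @export
summarize_selection <- function(selected) {
  stopifnot(length(selected) > 0)
  md <- feature_metadata(selected)
  tidyr::complete(
    dplyr::count(md, .data$type, .data$direction),
    type = c("spatial", "topological"), direction = c("x", "y"),
    fill = list(n = 0L)
  )
}
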