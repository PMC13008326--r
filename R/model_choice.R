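#' Cross-model common feature set
#'
#' The model-choice forests only use summary statistics that appear among
#' the selected top-`ns` statistics of *every* model. The intersection is
#' taken deterministically, keeping the order of the first selection.
#'
#' @param selections A named list of character vectors (one per model).
#' @return Character vector of common feature names.
#' @export
common_features <- function(selections) {
  stopifnot(length(selections) >= 2)
  common <- Reduce(intersect, selections)
  if (length(common) == 0) {
    stop("no summary statistic is selected for all models; ",
         "enlarge ns so that some informative statistics are shared",
         call. = FALSE)
  }
  common
}

#' Train the model-choice classification forest
#'
#' Fits a probability random forest of the model label on the *unscaled*
#' common summary statistics of the pooled training tables, and records,
#' for every training record, the out-of-bag predicted class and the 0/1
#' misclassification indicator that the error regressor is trained on.
#'
#' @param train Pooled training tibble (rows from all models; `model`
#'   column plus feature columns).
#' @param features Character vector of common feature names.
#' @param num_trees Number of trees.
#' @param seed Forest seed.
#' @return An object of class `angio_classifier`: list with the fitted
#'   forest, `features`, `oob` (tibble: `model`, `oob_pred`, `miss`), and
#'   `oob_error`.
#' @export
train_classifier <- function(train, features, num_trees = 500, seed = 1L) {
  y <- factor(train$model)
  counts <- table(y)
  if (length(counts) < 2 || any(counts < 50)) {
    stop("need at least 50 records per model class", call. = FALSE)
  }
  x <- as.data.frame(train[, features, drop = FALSE])
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        probability = TRUE, seed = seed, num.threads = 1)
  oob_prob <- fit$predictions            # out-of-bag class probabilities
  oob_pred <- colnames(oob_prob)[max.col(oob_prob, ties.method = "first")]
  miss <- as.integer(oob_pred != as.character(y))
  structure(
    list(forest = fit, features = features,
         oob = tibble::tibble(model = as.character(y), oob_pred = oob_pred,
                              miss = miss),
         oob_error = mean(miss), classes = levels(y)),
    class = "angio_classifier"
  )
}

#' Train the regression forest on out-of-bag misclassification
#'
#' Learns the relationship between the summary statistics and the
#' classifier's out-of-bag misclassification indicator, giving a pointwise
#' estimate of the probability that the predicted model index is wrong.
#' Predictions are clamped to `[0, 1]`.
#'
#' @param train The pooled training tibble used for [train_classifier()].
#' @param classifier The fitted [train_classifier()] object.
#' @param num_trees Number of trees.
#' @param seed Forest seed.
#' @return An object of class `angio_error_regressor`.
#' @export
train_error_regressor <- function(train, classifier, num_trees = 500,
                                  seed = 2L) {
  stopifnot(inherits(classifier, "angio_classifier"))
  x <- as.data.frame(train[, classifier$features, drop = FALSE])
  fit <- ranger::ranger(x = x, y = classifier$oob$miss,
                        num.trees = num_trees, seed = seed, num.threads = 1)
  structure(list(forest = fit, features = classifier$features),
            class = "angio_error_regressor")
}

#' Estimate the model posterior for observed data
#'
#' Each observed replicate is classified separately; the reported model is
#' the majority vote and the posterior probability estimate is the mean
#' over replicates of `1 - predicted misclassification probability`.
#'
#' @param observed Data frame of observed replicate feature vectors.
#' @param classifier An [train_classifier()] object.
#' @param regressor An [train_error_regressor()] object.
#' @return An object of class `model_posterior`: list with
#'   `predicted_model`, `posterior_prob`, tibble `replicates`
#'   (`predicted`, `p_hat`, per-class vote fractions), and `oob_error`.
#' @export
model_posterior <- function(observed, classifier, regressor) {
  missing <- setdiff(classifier$features, names(observed))
  if (length(missing) > 0) {
    stop("observed data lacks feature column(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(observed[, classifier$features, drop = FALSE])
  prob <- stats::predict(classifier$forest, data = x)$predictions
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  err <- stats::predict(regressor$forest, data = x)$predictions
  p_hat <- 1 - pmin(pmax(err, 0), 1)
  votes <- table(factor(pred, levels = classifier$classes))
  winner <- names(votes)[which.max(votes)]
  reps <- dplyr::bind_cols(
    tibble::tibble(predicted = pred, p_hat = p_hat),
    tibble::as_tibble(as.data.frame.matrix(prob))
  )
  structure(
    list(predicted_model = winner,
         posterior_prob = mean(p_hat[pred == winner]),
         replicates = reps, oob_error = classifier$oob_error),
    class = "model_posterior"
  )
}

#' @export
print.model_posterior <- function(x, ...) {
  cat(sprintf("<model_posterior> predicted = %s, p = %.3f (%d replicate(s))\n",
              x$predicted_model, x$posterior_prob, nrow(x$replicates)))
  invisible(x)
}
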