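# Accuracy and bias metrics, fold aggregation and cross-model comparison.

.checkPairs <- function(y, yhat, min_n = 3) {
  stopifnot(length(y) == length(yhat))
  if (length(y) < min_n) stop("need at least ", min_n, " paired values")
}

#' Pearson prediction accuracy r = cor(y*, y-hat*)
#' @param y_star adjusted phenotypes.
#' @param y_hat predicted adjusted phenotypes.
#' @return correlation coefficient.
#' @export
accuracyPearson <- function(y_star, y_hat) {
  .checkPairs(y_star, y_hat)
  if (sd(y_star) == 0 || sd(y_hat) == 0)
    stop("constant vector: correlation undefined")
  cor(y_star, y_hat)
}

#' Spearman rank accuracy
#' @inheritParams accuracyPearson
#' @export
accuracySpearman <- function(y_star, y_hat) {
  .checkPairs(y_star, y_hat)
  if (sd(y_star) == 0 || sd(y_hat) == 0)
    stop("constant vector: correlation undefined")
  cor(y_star, y_hat, method = "spearman")
}

#' Predictive root mean squared error
#'
#' sqrt(sum((y-hat* - y*)^2) / n).
#' @inheritParams accuracyPearson
#' @export
rmse <- function(y_star, y_hat) {
  .checkPairs(y_star, y_hat, min_n = 1)
  sqrt(mean((y_hat - y_star)^2))
}

#' Slope of the regression of y* on y-hat* (1 = empirically unbiased)
#' @inheritParams accuracyPearson
#' @export
slopeBias <- function(y_star, y_hat) {
  .checkPairs(y_star, y_hat)
  if (var(y_hat) == 0) stop("zero-variance predictions: slope undefined")
  cov(y_star, y_hat) / var(y_hat)
}

#' Relative difference in prediction accuracy (percent)
#'
#' RD = (r_m1 - r_m2) / r_m2 x 100, with the GBLUP accuracy as the baseline
#' r_m2 by convention.
#' @param r_m1 accuracy of the comparison model.
#' @param r_m2 accuracy of the baseline model (nonzero).
#' @export
relativeDifference <- function(r_m1, r_m2) {
  if (any(r_m2 == 0)) stop("zero baseline accuracy")
  (r_m1 - r_m2) / r_m2 * 100
}

#' Per-fold metrics of a prediction result
#'
#' @param result a \code{PredictionResult} from \code{\link{runCV}}.
#' @return data.frame with one row per (model, design, rep, fold) and
#'   columns \code{pearson}, \code{spearman}, \code{rmse}, \code{slope},
#'   \code{n}.
#' @export
foldMetrics <- function(result) {
  sp <- split(result, interaction(result$model, result$design, result$rep,
                                  result$fold, drop = TRUE))
  rows <- lapply(sp, function(d) {
    data.frame(model = d$model[1], design = d$design[1], rep = d$rep[1],
               fold = d$fold[1],
               pearson = accuracyPearson(d$y_star, d$y_hat),
               spearman = accuracySpearman(d$y_star, d$y_hat),
               rmse = rmse(d$y_star, d$y_hat),
               slope = slopeBias(d$y_star, d$y_hat),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-fold metrics to mean and standard error
#'
#' Metrics are computed per fold and then averaged (not pooled); the SE is
#' across folds/repeats.
#'
#' @param metrics output of \code{\link{foldMetrics}} (>= 2 folds per
#'   group).
#' @return data.frame with mean and SE per (model, design) and metric.
#' @export
aggregateFolds <- function(metrics) {
  sp <- split(metrics, interaction(metrics$model, metrics$design,
                                   drop = TRUE))
  rows <- lapply(sp, function(d) {
    se <- function(x) sd(x) / sqrt(length(x))
    data.frame(model = d$model[1], design = d$design[1],
               n_folds = nrow(d),
               pearson_mean = mean(d$pearson), pearson_se = se(d$pearson),
               spearman_mean = mean(d$spearman), spearman_se = se(d$spearman),
               rmse_mean = mean(d$rmse), rmse_se = se(d$rmse),
               slope_mean = mean(d$slope), slope_se = se(d$slope),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Comparison table with relative differences against a baseline model
#'
#' @param metrics output of \code{\link{foldMetrics}}.
#' @param baseline baseline model label (default \code{"GBLUP"}).
#' @return the \code{\link{aggregateFolds}} table with an \code{rd} column:
#'   RD of each model's mean Pearson accuracy against the baseline's.
#' @export
comparisonTable <- function(metrics, baseline = "GBLUP") {
  agg <- aggregateFolds(metrics)
  out <- do.call(rbind, lapply(split(agg, agg$design), function(d) {
    if (!baseline %in% d$model)
      stop("baseline model ", baseline, " absent from results")
    r_base <- d$pearson_mean[d$model == baseline]
    d$rd <- relativeDifference(d$pearson_mean, r_base)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Coefficient of determination of accuracy regressed on heritability
#'
#' Least-squares line of per-trait prediction accuracy on per-trait
#' heritability, across a suite of traits.
#'
#' @param accuracy per-trait accuracies (>= 3).
#' @param h2 matching heritability estimates.
#' @return R-squared of the fit.
#' @export
accuracyVsH2Fit <- function(accuracy, h2) {
  stopifnot(length(accuracy) == length(h2))
  if (length(accuracy) < 3) stop("need at least 3 traits")
  fit <- lm(accuracy ~ h2)
  summary(fit)$r.squared
}
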