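# Two-step SNP preselection: rank markers by gradient-boosting relative
# influence on the training fold, keep the top k, and refit a predictor on
# the reduced panel — per cross-validation fold, so the validation set never
# informs the selection.

#' Rank markers by gradient-boosting relative influence
#'
#' Trains a GBM on the training data (random search per \code{cfg}, or the
#' fixed parameters in \code{params}) and ranks all markers by relative
#' influence (percent of total split-gain, summing to 100). Ties — in
#' particular the zero-influence markers — are broken by genome order
#' (chromosome, position), then marker id.
#'
#' @param y_train adjusted phenotypes of the training individuals.
#' @param M_train their dosage matrix (marker ids as colnames).
#' @param cfg a \code{\link{gbmConfig}} used when \code{params} is NULL.
#' @param params optional list(ntree, lr, depth, node) to skip the search.
#' @param marker_order optional data.frame with rownames = marker ids and
#'   columns \code{chrom}, \code{pos} for the tie rule; colname order is
#'   used when absent.
#' @return data.frame of class \code{ImportanceRanking}: \code{marker_id},
#'   \code{influence}, sorted by decreasing influence.
#' @export
rankSnps <- function(y_train, M_train, cfg = gbmConfig(), params = NULL,
                     marker_order = NULL) {
  if (is.null(params)) {
    fit <- fitGbm(y_train, M_train, M_train[0, , drop = FALSE], cfg)
    infl <- fit$influence
  } else {
    bst <- gbmTrain(y_train, M_train, params$ntree, params$lr, params$depth,
                    params$node)
    infl <- .gbmInfluence(bst, colnames(M_train))
  }
  if (sum(infl) == 0)
    stop("no informative marker: the boosting model made no split; ",
         "loosen the GBM configuration")
  ids <- names(infl)
  if (!is.null(marker_order)) {
    ord <- order(-infl,
                 as.character(marker_order[ids, "chrom"]),
                 marker_order[ids, "pos"], ids)
  } else {
    ord <- order(-infl, match(ids, colnames(M_train)), ids)
  }
  out <- data.frame(marker_id = ids[ord], influence = unname(infl[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ImportanceRanking", "data.frame")
  out
}

#' Select the top-k markers of an importance ranking
#'
#' @param ranking an \code{ImportanceRanking} from \code{\link{rankSnps}}.
#' @param k number of markers to keep (cohort default 1500).
#' @return character vector of marker ids.
#' @export
selectTop <- function(ranking, k = 1500) {
  stopifnot(inherits(ranking, "ImportanceRanking"))
  if (k > nrow(ranking))
    stop("k exceeds the number of ranked markers")
  ranking$marker_id[seq_len(k)]
}

#' Refit a predictor on GBM-preselected markers, per fold
#'
#' For every fold of an existing all-marker run: rank markers on the
#' training side, keep the top k, rebuild the predictor's inputs from the
#' subset (VanRaden denominators recomputed from the selected markers), fit
#' and predict the validation side. BayesB is rejected here — it performs
#' its own variable selection, so preselection is not applied to it.
#'
#' @param model one of \code{"GBLUP"}, \code{"ENET"}, \code{"GBM"},
#'   \code{"Stack"}.
#' @param y_star named adjusted phenotypes.
#' @param M dosage matrix (rownames = sample ids).
#' @param folds fold object as in \code{\link{runCV}}.
#' @param k markers to preselect (default 1500).
#' @param rank_cfg GBM configuration for the ranking step.
#' @param rank_params optional fixed GBM parameters for the ranking step.
#' @param spec_args extra arguments passed to the model's spec constructor.
#' @param all_marker_result optional all-marker \code{PredictionResult} on
#'   the same folds; when given, per-model relative gain (RD of subset vs
#'   all-marker accuracy) is attached as attribute \code{relative_gain}.
#' @return a \code{PredictionResult} for the subset run, with attribute
#'   \code{selected} (list of per-fold marker id sets).
#' @export
refitWithSubset <- function(model, y_star, M, folds, k = 1500,
                            rank_cfg = gbmConfig(), rank_params = NULL,
                            spec_args = list(),
                            all_marker_result = NULL) {
  if (toupper(model) == "BAYESB")
    stop("BayesB is excluded from preselection: it is itself a variable ",
         "selection method, so preselected SNPs are not fed to it")
  spec_fun <- switch(toupper(model),
                     GBLUP = gblupSpec, ENET = enetSpec, GBM = gbmSpec,
                     STACK = stackSpec,
                     stop("unknown model: ", model))
  base_spec <- do.call(spec_fun, spec_args)

  ids <- names(y_star)
  selected <- list()
  sel_spec <- .mkSpec(base_spec$label, function(y_tr, M_tr, M_val) {
    rk <- rankSnps(y_tr, M_tr, cfg = rank_cfg, params = rank_params)
    keep <- selectTop(rk, min(k, nrow(rk)))
    selected[[length(selected) + 1]] <<- keep
    base_spec$fit(y_tr, M_tr[, keep, drop = FALSE],
                  M_val[, keep, drop = FALSE])
  })
  res <- runCV(sel_spec, y_star, M, folds)
  attr(res, "selected") <- selected
  if (!is.null(all_marker_result)) {
    r_sub <- accuracyPearson(res$y_star, res$y_hat)
    base <- all_marker_result[all_marker_result$model == base_spec$label, ]
    r_all <- accuracyPearson(base$y_star, base$y_hat)
    attr(res, "relative_gain") <- relativeDifference(r_sub, r_all)
  }
  res
}

#' Selection-frequency table across folds
#' @param selected list of per-fold marker id sets (attribute of
#'   \code{\link{refitWithSubset}} output).
#' @return data.frame of marker id and the number of folds selecting it.
#' @export
selectionFrequency <- function(selected) {
  tab <- sort(table(unlist(selected)), decreasing = TRUE)
  data.frame(marker_id = names(tab), n_folds = as.integer(tab),
             stringsAsFactors = FALSE)
}
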