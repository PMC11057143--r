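# Cross-validation designs (genomic-distance tenfold; leave-batch-out) and
# the engine that runs any predictor through them.

#' Genomic-distance folds
#'
#' Individuals are grouped by Ward hierarchical clustering of the genomic
#' distance matrix, then balanced to sizes floor(n/k) / ceiling(n/k) by
#' greedily moving, from each oversized fold, the individual whose average
#' distance to the receiving (undersized) fold is smallest. Related
#' individuals therefore stay within folds, reducing the dependence between
#' training and validation sets.
#'
#' @param dist square symmetric genomic distance matrix (see
#'   \code{\link{genomicDistance}}).
#' @param k number of folds (default 10).
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic given the distance matrix.
#' @return data.frame of class \code{FoldAssignment}: \code{sample_id},
#'   \code{fold}, with attributes \code{design = "genomic_tenfold"}.
#' @export
genomicFolds <- function(dist, k = 10, seed = 1L) {
  stopifnot(nrow(dist) == ncol(dist))
  n <- nrow(dist)
  if (k > n) stop("k exceeds the number of individuals")
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  hc <- hclust(as.dist(dist), method = "ward.D2")
  fold <- cutree(hc, k = k)

  lo <- floor(n / k); hi <- ceiling(n / k)
  n_hi <- n - lo * k  # number of folds of size hi
  target <- rep(lo, k); if (n_hi > 0) target[seq_len(n_hi)] <- hi
  # assign larger targets to the currently largest folds (less movement)
  ord <- order(tabulate(fold, k), decreasing = TRUE)
  tgt <- integer(k); tgt[ord] <- sort(target, decreasing = TRUE)

  repeat {
    sizes <- tabulate(fold, k)
    over <- which(sizes > tgt); under <- which(sizes < tgt)
    if (!length(over)) break
    best <- NULL
    for (f_from in over) {
      members <- which(fold == f_from)
      for (f_to in under) {
        recv <- which(fold == f_to)
        avg <- if (length(recv))
          rowMeans(dist[members, recv, drop = FALSE]) else rep(0, length(members))
        j <- which.min(avg)
        if (is.null(best) || avg[j] < best$d) {
          best <- list(i = members[j], to = f_to, d = avg[j])
        }
      }
    }
    fold[best$i] <- best$to
  }
  out <- data.frame(sample_id = ids, fold = as.integer(fold),
                    stringsAsFactors = FALSE)
  attr(out, "design") <- "genomic_tenfold"
  attr(out, "k") <- k
  class(out) <- c("FoldAssignment", "data.frame")
  out
}

#' Leave-batch-out splits
#'
#' Per repeat, floor(train_frac * B) batches form the training set and the
#' remainder the validation set; all records of a batch travel together.
#' Repeats draw disjoint validation batch sets while unused batches remain,
#' then top up from already-used batches (logged via a message).
#'
#' @param batch vector of batch labels, one per individual.
#' @param train_frac fraction of batches assigned to training (default 0.8).
#' @param repeats number of repeats (default 5).
#' @param seed RNG seed.
#' @return list of data.frames (\code{sample_id} omitted; columns
#'   \code{index}, \code{role}) — one per repeat, each of class
#'   \code{FoldAssignment} with attribute \code{val_batches}.
#' @export
batchOutSplits <- function(batch, train_frac = 0.8, repeats = 5, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie in (0, 1)")
  batch <- as.character(batch)
  levels <- unique(batch)
  B <- length(levels)
  if (B < 2) stop("at least two distinct batches required")
  n_train <- floor(train_frac * B)
  n_val <- B - n_train
  set.seed(seed)
  unused <- levels
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    if (length(unused) >= n_val) {
      val <- sample(unused, n_val)
    } else {
      extra <- sample(setdiff(levels, unused), n_val - length(unused))
      if (length(unused) < n_val)
        message("repeat ", r, ": validation batches partially reused")
      val <- c(unused, extra)
    }
    unused <- setdiff(unused, val)
    role <- ifelse(batch %in% val, "validation", "training")
    df <- data.frame(index = seq_along(batch), role = role,
                     stringsAsFactors = FALSE)
    attr(df, "design") <- "batch_out"
    attr(df, "repeat") <- r
    attr(df, "val_batches") <- val
    attr(df, "train_batches") <- setdiff(levels, val)
    class(df) <- c("FoldAssignment", "data.frame")
    out[[r]] <- df
  }
  out
}

# ---- model specs: a uniform fit/predict contract --------------------------

#' Model specifications for the cross-validation engine
#'
#' Each spec wraps one predictor behind a common contract: given the
#' adjusted phenotypes and raw dosages of the training individuals plus the
#' dosages of the validation individuals, return validation predictions.
#'
#' @param variances optional fixed list(sigma2_g, sigma2_e) for GBLUP
#'   (REML on the training fold when NULL).
#' @param cfg,enet_cfg,gbm_cfg predictor configurations.
#' @param inner_folds,seed stacking out-of-fold construction.
#' @return list of class \code{ModelSpec} with \code{label} and \code{fit}.
#' @name modelSpecs
NULL

.mkSpec <- function(label, fit) {
  structure(list(label = label, fit = fit), class = "ModelSpec")
}

#' @rdname modelSpecs
#' @export
gblupSpec <- function(variances = NULL)
  .mkSpec("GBLUP", function(y_tr, M_tr, M_val)
    fitGblup(y_tr, M_tr, M_val, variances = variances)$pred)

#' @rdname modelSpecs
#' @export
bayesbSpec <- function(cfg = bayesbConfig())
  .mkSpec("BayesB", function(y_tr, M_tr, M_val)
    fitBayesB(y_tr, M_tr, M_val, cfg)$pred)

#' @rdname modelSpecs
#' @export
enetSpec <- function(cfg = enetConfig())
  .mkSpec("ENET", function(y_tr, M_tr, M_val)
    fitEnet(y_tr, M_tr, M_val, cfg)$pred)

#' @rdname modelSpecs
#' @export
gbmSpec <- function(cfg = gbmConfig())
  .mkSpec("GBM", function(y_tr, M_tr, M_val)
    fitGbm(y_tr, M_tr, M_val, cfg)$pred)

#' @rdname modelSpecs
#' @export
stackSpec <- function(enet_cfg = enetConfig(), gbm_cfg = gbmConfig(),
                      inner_folds = 5, seed = 1L)
  .mkSpec("Stack", function(y_tr, M_tr, M_val)
    fitStack(y_tr, M_tr, M_val, enet_cfg, gbm_cfg, inner_folds, seed)$pred)

#' Run a predictor through a cross-validation design
#'
#' For each fold (or repeat), the model is fit strictly on the training side
#' — including any inner hyperparameter search and marker centering — and
#' predicts the validation side once. Model failure on a fold is recorded
#' and the run continues.
#'
#' @param spec a \code{ModelSpec} (see \link{modelSpecs}).
#' @param y_star named numeric vector of adjusted phenotypes (names =
#'   sample ids).
#' @param M dosage matrix with matching rownames.
#' @param folds either a \code{FoldAssignment} from
#'   \code{\link{genomicFolds}} or the list returned by
#'   \code{\link{batchOutSplits}}.
#' @return data.frame of class \code{PredictionResult}: \code{sample_id},
#'   \code{model}, \code{design}, \code{rep}, \code{fold}, \code{y_star},
#'   \code{y_hat}; failed folds listed in attribute \code{failures}.
#' @export
runCV <- function(spec, y_star, M, folds) {
  stopifnot(inherits(spec, "ModelSpec"))
  ids <- names(y_star)
  stopifnot(!is.null(ids), identical(ids, rownames(M)))
  tasks <- list()
  if (inherits(folds, "FoldAssignment") &&
      identical(attr(folds, "design"), "genomic_tenfold")) {
    stopifnot(identical(sort(folds$sample_id), sort(ids)))
    for (f in sort(unique(folds$fold))) {
      val_ids <- folds$sample_id[folds$fold == f]
      tasks[[length(tasks) + 1]] <-
        list(rep = 1L, fold = f, val = match(val_ids, ids))
    }
    design <- "genomic_tenfold"
  } else if (is.list(folds) && all(vapply(folds, inherits, TRUE,
                                          "FoldAssignment"))) {
    for (r in seq_along(folds)) {
      fa <- folds[[r]]
      tasks[[length(tasks) + 1]] <-
        list(rep = r, fold = 1L, val = fa$index[fa$role == "validation"])
    }
    design <- "batch_out"
  } else stop("unrecognized fold object")

  rows <- list(); failures <- character()
  for (t in tasks) {
    val <- t$val; tr <- setdiff(seq_along(ids), val)
    pred <- tryCatch(
      spec$fit(y_star[tr], M[tr, , drop = FALSE], M[val, , drop = FALSE]),
      error = function(e) {
        failures <<- c(failures, paste0(spec$label, " rep ", t$rep,
                                        " fold ", t$fold, ": ",
                                        conditionMessage(e)))
        NULL
      })
    if (is.null(pred)) next
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = ids[val], model = spec$label, design = design,
      rep = t$rep, fold = t$fold, y_star = unname(y_star[val]),
      y_hat = unname(pred), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  class(out) <- c("PredictionResult", "data.frame")
  out
}
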