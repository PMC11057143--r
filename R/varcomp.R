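# Bayesian animal model: Gibbs-sampling variance components with batch and
# additive / dominance / additive-by-additive kernels, Geweke convergence
# diagnostics, posterior ratio summaries and phenotype adjustment.

#' Gibbs chain configuration
#'
#' @param n_iter total Gibbs cycles (cohort default 500,000).
#' @param burn_in discarded initial cycles (default 50,000).
#' @param thin sampling interval (default 10). The retained-sample count is
#'   \code{(n_iter - burn_in) / thin}.
#' @param prior_df degrees of freedom of the scaled inverse chi-square
#'   variance priors (default 5).
#' @param seed RNG seed.
#' @return list of class \code{GibbsConfig} with an \code{n_retained} field.
#' @export
gibbsConfig <- function(n_iter = 500000, burn_in = 50000, thin = 10,
                        prior_df = 5, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, prior_df > 0)
  cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin), prior_df = prior_df,
              seed = as.integer(seed),
              n_retained = as.integer((n_iter - burn_in) / thin))
  class(cfg) <- "GibbsConfig"
  cfg
}

.designFromTraits <- function(traits, pc_scores = NULL) {
  stopifnot(all(c("y", "dim_class", "parity_class", "batch") %in%
                  names(traits)))
  df <- data.frame(dim_class = droplevels(factor(traits$dim_class)),
                   parity_class = droplevels(factor(traits$parity_class)))
  # first level of each factor dropped (reference-level identifiability)
  X <- stats::model.matrix(~ dim_class + parity_class, data = df)
  if (!is.null(pc_scores)) {
    pc <- as.matrix(pc_scores)
    colnames(pc) <- paste0("PC", seq_len(ncol(pc)))
    X <- cbind(X, pc)
  }
  # drop rank-deficient columns, reported
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    message("dropping rank-deficient fixed-effect columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(X = X, batch = factor(traits$batch))
}

.checkKernel <- function(K, ids) {
  stopifnot(is(K, "RelationshipMatrix"))
  v <- kernelValues(K)
  if (!all(ids %in% rownames(v)))
    stop("kernel does not cover all phenotyped individuals")
  v <- v[ids, ids]
  ev <- eigen(v, symmetric = TRUE)
  tol <- 1e-8 * sum(diag(v)) / nrow(v)
  if (min(ev$values) < -max(tol, 1e-8))
    stop("kernel of kind ", kernelKind(K), " is not positive semi-definite")
  ev$values[ev$values < 0] <- 0
  ev
}

#' Fit the Bayesian animal model by Gibbs sampling
#'
#' Model: y = Xb + Wh + (sum of correlated genetic effects) + e, with flat
#' priors on fixed effects (days-in-milk class, parity class, PC
#' covariates), i.i.d. normal batch effects, genetic effects with
#' covariance proportional to the supplied kernels, and scaled inverse
#' chi-square variance priors whose scales split the phenotypic variance
#' equally across fitted variance components. Correlated effects are
#' sampled in each kernel's eigenbasis (one spectral decomposition per
#' kernel), giving exact O(n) conditional draws.
#'
#' @param traits a \code{TraitTable} (one record per individual).
#' @param kernels named list of \linkS4class{RelationshipMatrix} objects;
#'   names among \code{additive}, \code{dominance}, \code{epistatic}.
#' @param cfg a \code{\link{gibbsConfig}}.
#' @param pc_scores optional matrix of PC covariates (rows follow
#'   \code{traits}).
#' @param fit_batch include the random batch effect (default TRUE).
#' @return A \code{PosteriorChain}: retained variance samples (columns
#'   \code{sigma2_additive}, ..., \code{sigma2_batch}, \code{sigma2_e}),
#'   fixed-effect samples, posterior-mean solutions for fixed, batch and
#'   each genetic effect, and bookkeeping.
#' @export
fitAnimalModel <- function(traits, kernels, cfg = gibbsConfig(),
                           pc_scores = NULL, fit_batch = TRUE) {
  stopifnot(inherits(cfg, "GibbsConfig"), length(kernels) >= 1)
  kn <- names(kernels)
  if (is.null(kn) || any(!nzchar(kn)))
    stop("kernels must be a named list")
  ids <- as.character(traits$sample_id)
  des <- .designFromTraits(traits, pc_scores)
  eig <- lapply(kernels, .checkKernel, ids = ids)

  vy <- var(traits$y)
  n_comp <- length(kernels) + as.integer(fit_batch) + 1L
  scale0 <- vy / n_comp * (cfg$prior_df - 2) / cfg$prior_df
  if (scale0 <= 0) scale0 <- vy / n_comp

  batch_i <- if (fit_batch) as.integer(des$batch) else integer(nrow(traits))
  n_batch <- if (fit_batch) nlevels(des$batch) else 0L

  set.seed(cfg$seed)
  res <- .gibbs_animal_cpp(
    traits$y, des$X,
    if (fit_batch) batch_i else rep(0L, nrow(traits)),
    n_batch,
    lapply(eig, `[[`, "vectors"), lapply(eig, `[[`, "values"),
    cfg$prior_df, rep(scale0, length(kernels)), scale0, scale0,
    cfg$n_iter, cfg$burn_in, cfg$thin)

  vs <- res$var_samples
  colnames(vs) <- c(paste0("sigma2_", kn), "sigma2_batch", "sigma2_e")
  if (!fit_batch) vs <- vs[, colnames(vs) != "sigma2_batch", drop = FALSE]
  bs <- res$b_samples
  colnames(bs) <- colnames(des$X)

  eff <- res$effect_means[, seq_along(kernels), drop = FALSE]
  colnames(eff) <- kn
  rownames(eff) <- ids

  chain <- list(
    var_samples = vs, b_samples = bs,
    b_hat = setNames(drop(res$b_mean), colnames(des$X)),
    h_hat = if (fit_batch)
      setNames(drop(res$h_mean), levels(des$batch)) else NULL,
    effect_means = eff,
    n_retained = res$n_retained,
    sample_ids = ids,
    design = list(X = des$X, batch = if (fit_batch) des$batch else NULL),
    cfg = cfg
  )
  class(chain) <- "PosteriorChain"
  chain
}

#' @export
print.PosteriorChain <- function(x, ...) {
  cat("PosteriorChain:", x$n_retained, "retained samples;",
      "components:", paste(colnames(x$var_samples), collapse = ", "), "\n")
  print(round(colMeans(x$var_samples), 4))
  invisible(x)
}

#' Posterior variance-fraction summaries
#'
#' Ratios are computed per retained sample and then averaged (posterior
#' mean of the ratio). Heritability and the batch fraction use all fitted
#' variances including batch; the dominance and epistatic fractions include
#' the batch variance in their denominator when \code{include_batch} is
#' TRUE (the supplementary-definition form) and omit it otherwise (the
#' main-text form).
#'
#' @param chain a \code{PosteriorChain}.
#' @param include_batch include sigma2_batch in the d2/ep2/h2 denominators.
#' @return list of class \code{VarianceComponents}: posterior means and SDs
#'   of the variances and of h2, h2_batch, and (when fitted) d2, ep2.
#' @export
summarizeRatios <- function(chain, include_batch = TRUE) {
  vs <- chain$var_samples
  if (nrow(vs) == 0) stop("empty posterior chain")
  gen_cols <- setdiff(colnames(vs), c("sigma2_batch", "sigma2_e"))
  has_batch <- "sigma2_batch" %in% colnames(vs)
  total_all <- rowSums(vs)
  if (any(total_all <= 0)) stop("zero total variance sample")
  denom <- if (include_batch || !has_batch) total_all else
    total_all - vs[, "sigma2_batch"]

  ratios <- list()
  if ("sigma2_additive" %in% gen_cols)
    ratios$h2 <- vs[, "sigma2_additive"] / denom
  if (has_batch)
    ratios$h2_batch <- vs[, "sigma2_batch"] / total_all
  if ("sigma2_dominance" %in% gen_cols)
    ratios$d2 <- vs[, "sigma2_dominance"] / denom
  if ("sigma2_epistatic" %in% gen_cols)
    ratios$ep2 <- vs[, "sigma2_epistatic"] / denom

  out <- list(
    variance_mean = colMeans(vs),
    variance_sd = apply(vs, 2, sd),
    ratio_mean = vapply(ratios, mean, numeric(1)),
    ratio_sd = vapply(ratios, sd, numeric(1)),
    include_batch = include_batch
  )
  class(out) <- "VarianceComponents"
  out
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("Variance fractions (posterior mean +/- SD):\n")
  for (nm in names(x$ratio_mean))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", nm, x$ratio_mean[nm],
                x$ratio_sd[nm]))
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first \code{frac1} of a chain against the last
#' \code{frac2}, with the variance of each segment mean estimated from the
#' spectral density at frequency zero (AR fit), giving a z-statistic and
#' two-sided p-value.
#'
#' @param x numeric chain (length >= 100, non-constant).
#' @param frac1,frac2 early and late window fractions (defaults 0.1, 0.5).
#' @return list with \code{z} and \code{p}.
#' @export
gewekeTest <- function(x, frac1 = 0.1, frac2 = 0.5) {
  x <- as.numeric(x)
  if (length(x) < 100) stop("chain too short for the Geweke diagnostic")
  if (stats::sd(x) == 0) stop("constant chain: diagnostic undefined")
  n <- length(x)
  a <- x[seq_len(floor(frac1 * n))]
  b <- x[seq.int(n - floor(frac2 * n) + 1, n)]
  s0 <- function(seg) {
    if (stats::sd(seg) == 0) return(0)
    fit <- try(ar(seg, aic = TRUE, order.max = min(20, length(seg) %/% 5)),
               silent = TRUE)
    if (inherits(fit, "try-error") || length(fit$ar) == 0)
      return(var(seg))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  v <- s0(a) / length(a) + s0(b) / length(b)
  if (v <= 0) stop("zero spectral variance estimate")
  z <- (mean(a) - mean(b)) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Convergence report for a posterior chain
#'
#' Runs \code{\link{gewekeTest}} on every stored variance component.
#' @param chain a \code{PosteriorChain}.
#' @param alpha significance level for the pass/fail flag (default 0.10).
#' @return data.frame with parameter, z, p and pass.
#' @export
convergenceReport <- function(chain, alpha = 0.10) {
  vs <- chain$var_samples
  res <- lapply(colnames(vs), function(nm) {
    g <- gewekeTest(vs[, nm])
    data.frame(parameter = nm, z = g$z, p = g$p, pass = g$p > alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Adjust phenotypes for fixed and batch effects
#'
#' y* = y - X b-hat - W h-hat with the posterior means from a fitted chain;
#' the genetic and residual signal is retained in y*.
#'
#' @param traits the \code{TraitTable} the chain was fitted on.
#' @param chain the fitted \code{PosteriorChain}.
#' @return data.frame (class \code{AdjustedPhenotypes}) with
#'   \code{sample_id} and \code{y_star}.
#' @export
adjustPhenotypes <- function(traits, chain) {
  ids <- as.character(traits$sample_id)
  if (!identical(ids, chain$sample_ids))
    stop("record set differs from the one the chain was fitted on")
  fitted_fx <- drop(chain$design$X %*% chain$b_hat)
  if (!is.null(chain$design$batch))
    fitted_fx <- fitted_fx +
      unname(chain$h_hat[as.integer(chain$design$batch)])
  out <- data.frame(sample_id = ids, y_star = traits$y - fitted_fx,
                    stringsAsFactors = FALSE)
  class(out) <- c("AdjustedPhenotypes", "data.frame")
  out
}
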