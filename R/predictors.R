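# The five whole-genome predictors: GBLUP, BayesB, elastic net, gradient
# boosting and a stacking ensemble. All are trained on adjusted phenotypes
# y* from the training side only; marker centering statistics always come
# from the training data.

# ---- GBLUP ----------------------------------------------------------------

# Eigen-based REML for y = 1*mu + g + e, g ~ N(0, sigma2_g * K).
# Profiles mu and sigma2_e out and optimizes the variance ratio on the
# eigenvalue scale; O(n) per candidate ratio after one decomposition.
.remlKernel <- function(y, K) {
  n <- length(y)
  ev <- eigen(K, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  T <- drop(crossprod(ev$vectors, y))
  xt <- drop(crossprod(ev$vectors, rep(1, n)))
  negll <- function(loglambda) {
    r <- exp(loglambda)
    D <- r * lam + 1
    xDx <- sum(xt^2 / D)
    mu <- sum(xt * T / D) / xDx
    rss <- sum((T - xt * mu)^2 / D)
    0.5 * ((n - 1) * log(rss) + sum(log(D)) + log(xDx))
  }
  opt <- optimize(negll, c(log(1e-6), log(1e6)))
  r <- exp(opt$minimum)
  D <- r * lam + 1
  xDx <- sum(xt^2 / D)
  mu <- sum(xt * T / D) / xDx
  rss <- sum((T - xt * mu)^2 / D)
  sigma2_e <- rss / (n - 1)
  list(sigma2_g = r * sigma2_e, sigma2_e = sigma2_e, mu = mu)
}

#' Fit GBLUP and predict validation individuals
#'
#' Mixed model y* = 1 mu + g + e with g ~ N(0, G sigma2_g). Variances are
#' estimated on the training data by eigen-based REML unless supplied.
#' Training solutions are the usual BLUP shrinkage of centered phenotypes;
#' validation predictions are the conditional expectation
#' G_vt G_tt^{-1} g-hat.
#'
#' @param y_train named numeric vector of adjusted phenotypes (training).
#' @param M_train,M_val raw dosage matrices (0/1/2) for training and
#'   validation individuals over the same markers; centering and the
#'   VanRaden denominator use training allele frequencies.
#' @param variances optional list(sigma2_g, sigma2_e) to skip REML.
#' @return list of class \code{GblupModel}: \code{mu}, \code{g_hat} (training
#'   solutions), \code{pred} (validation predictions), \code{fitted}
#'   (training fitted values), variances used.
#' @export
fitGblup <- function(y_train, M_train, M_val, variances = NULL) {
  p <- colMeans(M_train) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all training markers monomorphic")
  Zt <- sweep(M_train, 2, 2 * p)
  Zv <- sweep(M_val, 2, 2 * p)
  Gtt <- tcrossprod(Zt) / denom
  Gvt <- tcrossprod(Zv, Zt) / denom

  if (is.null(variances)) variances <- .remlKernel(y_train, Gtt)
  s2g <- variances$sigma2_g; s2e <- variances$sigma2_e
  n <- length(y_train)
  if (s2g <= 1e-12 * s2e) {
    mu <- mean(y_train)
    return(structure(list(mu = mu, g_hat = rep(0, n),
                          pred = rep(mu, nrow(M_val)),
                          fitted = rep(mu, n),
                          sigma2_g = s2g, sigma2_e = s2e),
                     class = "GblupModel"))
  }
  V <- s2g * Gtt + diag(s2e, n)
  Vi <- tryCatch(solve(V), error = function(e) {
    jit <- 1e-8 * sum(diag(V)) / n
    message("singular training system; adding jitter ", signif(jit, 3))
    solve(V + diag(jit, n))
  })
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% y_train) / crossprod(one, Vi %*% one))
  alpha <- Vi %*% (y_train - mu)
  g_hat <- drop(s2g * Gtt %*% alpha)
  # conditional expectation for validation: G_vt G_tt^{-1} g_hat, evaluated
  # in the numerically stable form s2g * G_vt V^{-1} (y - mu) (identical
  # because g_hat = s2g G_tt V^{-1} (y - mu))
  g_val <- drop(s2g * Gvt %*% alpha)
  structure(list(mu = mu, g_hat = g_hat, pred = mu + g_val,
                 fitted = mu + g_hat, sigma2_g = s2g, sigma2_e = s2e),
            class = "GblupModel")
}

# ---- BayesB ---------------------------------------------------------------

#' BayesB configuration
#'
#' Mixture prior on marker effects: point mass at zero with probability
#' \code{pi}, otherwise a scaled t with \code{df} degrees of freedom and
#' scale \code{s_b}. When \code{s_b} is NULL it is solved so the prior
#' attributes half of var(y*) to the markers:
#' (1 - pi) E[var(u)] 2 sum p(1-p) = var(y*)/2.
#'
#' @param pi prior null probability (default 0.95).
#' @param df t degrees of freedom (default 5).
#' @param s_b t scale parameter; NULL to solve from the data.
#' @param n_iter,burn_in,thin Gibbs chain (defaults 200,000 / 50,000 / 10,
#'   giving 15,000 retained samples).
#' @param seed RNG seed.
#' @export
bayesbConfig <- function(pi = 0.95, df = 5, s_b = NULL, n_iter = 200000,
                         burn_in = 50000, thin = 10, seed = 1L) {
  stopifnot(pi >= 0, pi <= 1, df > 0, burn_in < n_iter, thin >= 1)
  cfg <- list(pi = pi, df = df, s_b = s_b, n_iter = as.integer(n_iter),
              burn_in = as.integer(burn_in), thin = as.integer(thin),
              seed = as.integer(seed),
              n_retained = as.integer((n_iter - burn_in) / thin))
  class(cfg) <- "BayesBConfig"
  cfg
}

#' Fit BayesB and predict validation individuals
#'
#' Gibbs sampler with a per-marker inclusion indicator and hierarchical
#' scaled-inverse-chi-square marker variances (marginally the scaled-t slab).
#' Markers are column-centered with training means; predictions are
#' mu-hat + M_val u-hat with posterior-mean effects.
#'
#' @inheritParams fitGblup
#' @param cfg a \code{\link{bayesbConfig}}.
#' @param intercept fit the intercept (default TRUE).
#' @param sigma_e fix the residual variance at this value instead of
#'   sampling it (used by calibration oracles).
#' @return list of class \code{BayesBModel}: posterior means \code{mu},
#'   \code{u_hat}, validation \code{pred}, retained-sample bookkeeping.
#' @export
fitBayesB <- function(y_train, M_train, M_val, cfg = bayesbConfig(),
                      intercept = TRUE, sigma_e = NULL) {
  stopifnot(inherits(cfg, "BayesBConfig"))
  ctr <- colMeans(M_train)
  Mt <- sweep(M_train, 2, ctr)
  Mv <- sweep(M_val, 2, ctr)
  vy <- var(y_train)
  s_b <- cfg$s_b
  if (is.null(s_b)) {
    p <- colMeans(M_train) / 2
    sumpq <- 2 * sum(p * (1 - p))
    if (cfg$pi >= 1 || sumpq <= 0) s_b <- vy  # degenerate, unused when pi=1
    else s_b <- (vy / 2) * (cfg$df - 2) / (cfg$df * (1 - cfg$pi) * sumpq)
    s_b <- max(s_b, 1e-12)
  }
  if (cfg$pi >= 1)
    warning("pi = 1: all marker effects null; intercept-only model")
  set.seed(cfg$seed)
  res <- .bayesb_cpp(y_train, Mt, cfg$pi, cfg$df, s_b,
                     cfg$n_iter, cfg$burn_in, cfg$thin,
                     intercept,
                     if (is.null(sigma_e)) -1 else sigma_e,
                     5, vy / 2)
  structure(list(mu = res$mu_mean, u_hat = drop(res$u_mean),
                 pred = drop(res$mu_mean + Mv %*% res$u_mean),
                 fitted = drop(res$mu_mean + Mt %*% res$u_mean),
                 n_retained = res$n_retained, s_b = s_b,
                 sig2e_samples = drop(res$sig2e_samples),
                 u_samples = res$u_samples),
            class = "BayesBModel")
}

# ---- Elastic net ----------------------------------------------------------

#' Elastic-net configuration
#'
#' The loss is (1/2N) sum (y - b0 - x'b)^2 + lambda((1-alpha)||b||_2^2 +
#' alpha ||b||_1), with the un-halved ridge term. The alpha grid is 0.0-1.0
#' in steps of 0.1; the lambda grid is log-spaced from lambda_max (smallest
#' lambda zeroing all coefficients at alpha = 1) down to
#' \code{lambda_min_ratio} times lambda_max, or a raw 0-1 step 0.1 grid when
#' \code{raw_lambda_grid} is set.
#'
#' @param alpha_grid mixing-parameter grid.
#' @param n_lambda number of log-spaced lambda values (default 50).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @param raw_lambda_grid use lambda in \{0, 0.1, ..., 1\} instead.
#' @param inner_folds folds of the inner grid-search CV (default 5).
#' @param seed RNG seed for the inner folds.
#' @export
enetConfig <- function(alpha_grid = seq(0, 1, by = 0.1), n_lambda = 50,
                       lambda_min_ratio = 1e-4, raw_lambda_grid = FALSE,
                       inner_folds = 5, seed = 1L) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1), inner_folds >= 2)
  cfg <- list(alpha_grid = alpha_grid, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio,
              raw_lambda_grid = isTRUE(raw_lambda_grid),
              inner_folds = as.integer(inner_folds), seed = as.integer(seed))
  class(cfg) <- "EnetConfig"
  cfg
}

# The loss minimized here is (1/2N) RSS + lambda((1-alpha)||b||_2^2 +
# alpha ||b||_1): an un-halved ridge term. glmnet minimizes (1/2N) RSS +
# lam_g(alpha_g ||b||_1 + (1-alpha_g)/2 ||b||_2^2) after internally
# standardizing y, which multiplies the effective ridge weight by
# 1/sd_n(y). Matching both penalty weights gives, with s = sd_n(y) and
# k = alpha + 2 s (1 - alpha): lam_g = lambda k, alpha_g = alpha / k.
.enetMap <- function(alpha, y) {
  s <- sqrt(mean((y - mean(y))^2))
  k <- alpha + 2 * s * (1 - alpha)
  list(k = k, alpha_g = if (k > 0) alpha / k else 1)
}

#' Elastic net at a fixed penalty
#'
#' Solves min (1/2N) sum(y - b0 - x'b)^2 + lambda((1-alpha) ||b||_2^2 +
#' alpha ||b||_1) by coordinate descent (glmnet with a reparameterised
#' penalty).
#'
#' @param y response vector
#' @param M predictor matrix
#' @param alpha mixing parameter in [0, 1]
#' @param lambda penalty strength (the loss above)
#' @param thresh glmnet convergence threshold
#' @return list(beta0, beta)
#' @export
enetFit <- function(y, M, alpha, lambda, thresh = 1e-12) {
  mp <- .enetMap(alpha, y)
  lg <- lambda * mp$k
  lmax <- max(abs(crossprod(M, y - mean(y)))) / length(y)
  lgmax <- if (mp$alpha_g > 0) lmax / mp$alpha_g else lmax * 1e3
  hi <- max(lgmax, lg * 2, 1e-8)
  lseq <- sort(unique(c(exp(seq(log(hi), log(max(lg, hi * 1e-8, 1e-10)),
                                length.out = 30)), lg)),
               decreasing = TRUE)
  # drop near-duplicate knots (they trip the coef() interpolator)
  keep <- c(TRUE, -diff(lseq) / lseq[-length(lseq)] > 1e-9)
  lseq <- lseq[keep]
  fit <- glmnet::glmnet(M, y, alpha = mp$alpha_g, lambda = lseq,
                        standardize = FALSE, thresh = thresh)
  i <- which.min(abs(lseq - lg))  # lg is on the path: exact
  cf <- as.matrix(coef(fit, s = lseq[i]))
  list(beta0 = cf[1, 1], beta = cf[-1, 1])
}

#' Fit the elastic net with inner-CV grid search and predict validation
#'
#' Grid-searches (alpha, lambda) by K-fold cross-validation inside the
#' training set; the winner maximizes out-of-fold accuracy, breaking ties
#' by lower MSE, then smaller lambda, then smaller alpha; it is then refit
#' on the full training set.
#'
#' @inheritParams fitGblup
#' @param cfg an \code{\link{enetConfig}}.
#' @return list of class \code{EnetModel}: \code{beta0}, \code{beta},
#'   winning \code{alpha}, \code{lambda}, validation \code{pred}.
#' @export
fitEnet <- function(y_train, M_train, M_val, cfg = enetConfig()) {
  stopifnot(inherits(cfg, "EnetConfig"))
  ctr <- colMeans(M_train)
  Mt <- sweep(M_train, 2, ctr)
  Mv <- sweep(M_val, 2, ctr)
  n <- length(y_train)
  lmax <- max(abs(crossprod(Mt, y_train - mean(y_train)))) / n
  lgrid <- if (cfg$raw_lambda_grid) seq(0, 1, by = 0.1) else
    exp(seq(log(lmax), log(lmax * cfg$lambda_min_ratio),
            length.out = cfg$n_lambda))
  set.seed(cfg$seed)
  fold <- sample(rep_len(seq_len(cfg$inner_folds), n))

  lgrid <- sort(lgrid, decreasing = TRUE)
  best <- NULL
  for (alpha in cfg$alpha_grid) {
    oof <- matrix(NA_real_, n, length(lgrid))
    for (f in seq_len(cfg$inner_folds)) {
      tr <- fold != f
      mp <- .enetMap(alpha, y_train[tr])
      lgseq <- pmax(lgrid * mp$k, 1e-10)
      fit <- glmnet::glmnet(Mt[tr, , drop = FALSE], y_train[tr],
                            alpha = mp$alpha_g, lambda = lgseq,
                            standardize = FALSE)
      pr <- stats::predict(fit, newx = Mt[!tr, , drop = FALSE], s = lgseq)
      oof[!tr, ] <- as.matrix(pr)
    }
    for (j in seq_along(lgrid)) {
      pj <- oof[, j]
      acc <- if (sd(pj) == 0) -Inf else cor(pj, y_train)
      mse <- mean((pj - y_train)^2)
      lam_printed <- lgrid[j]
      cand <- list(alpha = alpha, lambda = lam_printed, acc = acc, mse = mse)
      if (is.null(best) ||
          acc > best$acc + 1e-12 ||
          (abs(acc - best$acc) <= 1e-12 &&
           (mse < best$mse - 1e-12 ||
            (abs(mse - best$mse) <= 1e-12 &&
             (lam_printed < best$lambda - 1e-12 ||
              (abs(lam_printed - best$lambda) <= 1e-12 &&
               alpha < best$alpha))))))
        best <- cand
    }
  }
  fin <- enetFit(y_train, Mt, best$alpha, best$lambda)
  structure(list(beta0 = fin$beta0, beta = fin$beta,
                 alpha = best$alpha, lambda = best$lambda,
                 inner_acc = best$acc, inner_mse = best$mse,
                 pred = drop(fin$beta0 + Mv %*% fin$beta),
                 fitted = drop(fin$beta0 + Mt %*% fin$beta)),
            class = "EnetModel")
}

# ---- Gradient boosting ----------------------------------------------------

#' Gradient-boosting configuration
#'
#' Hyperparameter grids as used for the cohort: trees
#' \{100, 200, 300, 500, 750, 1000, 1250, 1500, 2000, 2500, 3000\}, learning
#' rate 0.01-1 step 0.05, maximum depth 0-50 step 5 (0 = no depth limit),
#' minimum observations per leaf 5-50 step 15. Hyperparameters are chosen by
#' random search (\code{n_draws} draws) scored by inner K-fold MSE.
#'
#' @param ntree_grid,lr_grid,depth_grid,node_grid the search grids.
#' @param n_draws random-search budget (default 36).
#' @param inner_folds folds of the inner CV (default 5).
#' @param seed RNG seed.
#' @export
gbmConfig <- function(ntree_grid = c(100, 200, 300, 500, 750, 1000, 1250,
                                     1500, 2000, 2500, 3000),
                      lr_grid = seq(0.01, 1, by = 0.05),
                      depth_grid = seq(0, 50, by = 5),
                      node_grid = seq(5, 50, by = 15),
                      n_draws = 36, inner_folds = 5, seed = 1L) {
  stopifnot(n_draws >= 1, inner_folds >= 2)
  cfg <- list(ntree_grid = ntree_grid, lr_grid = lr_grid,
              depth_grid = depth_grid, node_grid = node_grid,
              n_draws = as.integer(n_draws),
              inner_folds = as.integer(inner_folds), seed = as.integer(seed))
  class(cfg) <- "GbmConfig"
  cfg
}

.xgbParams <- function(lr, depth, node_size) {
  p <- list(objective = "reg:squarederror", eta = lr,
            min_child_weight = node_size, lambda = 0, alpha = 0,
            tree_method = "hist", nthread = 1, max_depth = depth)
  if (depth == 0) {  # depth 0 in the grid means no depth limit
    p$grow_policy <- "lossguide"
    p$max_leaves <- 256
  }
  p
}

#' Train a single gradient-boosting model
#'
#' Squared-error boosting of regression trees with shrinkage \code{lr},
#' depth limit \code{depth} (0 = unlimited) and minimum leaf size
#' \code{node_size}.
#'
#' @param y response vector.
#' @param M predictor matrix (markers as columns, named).
#' @param ntree boosting rounds.
#' @param lr learning rate.
#' @param depth maximum tree depth (0 = no limit).
#' @param node_size minimum observations per leaf.
#' @return an xgboost booster with the training base value attached.
#' @export
gbmTrain <- function(y, M, ntree, lr, depth, node_size) {
  if (ntree == 0)  # zero boosting steps: the constant training-mean model
    return(structure(list(base = mean(y)), class = "gbmConstModel"))
  dtrain <- xgboost::xgb.DMatrix(M, label = y)
  params <- .xgbParams(lr, depth, node_size)
  params$base_score <- mean(y)
  bst <- xgboost::xgb.train(params = params, data = dtrain, nrounds = ntree,
                            verbose = 0)
  attr(bst, "feature_names") <- colnames(M)
  bst
}

#' @rdname gbmTrain
#' @param model trained booster.
#' @param M_new matrix to predict.
#' @export
gbmPredict <- function(model, M_new) {
  if (inherits(model, "gbmConstModel")) return(rep(model$base, nrow(M_new)))
  drop(stats::predict(model, xgboost::xgb.DMatrix(M_new)))
}

# Relative influence on the percentage scale over ALL markers: normalized
# sum of squared-error reductions (gain) across all splits.
.gbmInfluence <- function(model, marker_ids) {
  imp <- xgboost::xgb.importance(model = model)
  infl <- setNames(rep(0, length(marker_ids)), marker_ids)
  if (!is.null(imp) && nrow(imp) > 0)
    infl[imp$Feature] <- imp$Gain * 100
  infl
}

#' Fit a gradient-boosting machine with random hyperparameter search
#'
#' @inheritParams fitGblup
#' @param cfg a \code{\link{gbmConfig}}.
#' @return list of class \code{GbmModel}: the winning hyperparameters,
#'   validation \code{pred}, and per-marker \code{influence} (relative
#'   influence, percent, summing to 100 when at least one split occurred).
#' @export
fitGbm <- function(y_train, M_train, M_val, cfg = gbmConfig()) {
  stopifnot(inherits(cfg, "GbmConfig"))
  if (length(y_train) == 0) stop("empty training set")
  set.seed(cfg$seed)
  draws <- unique(data.frame(
    ntree = sample(cfg$ntree_grid, cfg$n_draws, replace = TRUE),
    lr = sample(cfg$lr_grid, cfg$n_draws, replace = TRUE),
    depth = sample(cfg$depth_grid, cfg$n_draws, replace = TRUE),
    node = sample(cfg$node_grid, cfg$n_draws, replace = TRUE)))
  n <- length(y_train)
  fold <- sample(rep_len(seq_len(cfg$inner_folds), n))
  score <- numeric(nrow(draws))
  if (nrow(draws) == 1) score <- NA_real_  # nothing to select between
  for (i in seq_len(if (nrow(draws) > 1) nrow(draws) else 0)) {
    mse <- 0
    for (f in seq_len(cfg$inner_folds)) {
      tr <- fold != f
      bst <- gbmTrain(y_train[tr], M_train[tr, , drop = FALSE],
                      draws$ntree[i], draws$lr[i], draws$depth[i],
                      draws$node[i])
      pr <- gbmPredict(bst, M_train[!tr, , drop = FALSE])
      mse <- mse + mean((pr - y_train[!tr])^2)
    }
    score[i] <- mse / cfg$inner_folds
  }
  w <- if (nrow(draws) > 1) which.min(score) else 1L
  bst <- gbmTrain(y_train, M_train, draws$ntree[w], draws$lr[w],
                  draws$depth[w], draws$node[w])
  structure(list(model = bst,
                 params = as.list(draws[w, ]),
                 inner_mse = score[w],
                 pred = gbmPredict(bst, M_val),
                 fitted = gbmPredict(bst, M_train),
                 influence = .gbmInfluence(bst, colnames(M_train))),
            class = "GbmModel")
}

# ---- Stacking ensemble ----------------------------------------------------

# Non-negative least squares with intercept for two base learners: exact
# active-set enumeration over which weights are clamped to zero.
.nnlsMeta <- function(y, F) {
  stopifnot(ncol(F) >= 1)
  k <- ncol(F)
  best <- NULL
  subsets <- lapply(0:(2^k - 1), function(b) which(bitwAnd(b, 2^(0:(k - 1))) > 0))
  for (S in subsets) {
    X <- cbind(1, F[, S, drop = FALSE])
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    wS <- cf[-1]
    if (length(wS) && any(wS < -1e-10)) next
    w <- rep(0, k); w[S] <- pmax(wS, 0)
    rss <- sum((y - cf[1] - F %*% w)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(intercept = cf[1], w = w, rss = rss)
  }
  best
}

#' Fit a stacking ensemble of elastic net and GBM base learners
#'
#' Step 1 trains the base learners with K-fold cross-validation inside the
#' training set so every training individual has an out-of-fold base
#' prediction; step 2 fits the meta-learner, a linear model with
#' non-negative weights and an intercept, on those out-of-fold predictions.
#' The final prediction applies the meta-weights to base-learner
#' predictions from models refit on the full training set.
#'
#' @inheritParams fitGblup
#' @param enet_cfg,gbm_cfg base-learner configurations.
#' @param inner_folds folds for the out-of-fold base predictions.
#' @param seed RNG seed for the fold split.
#' @return list of class \code{StackModel}: meta \code{intercept} and
#'   non-negative \code{weights} (named enet, gbm), validation \code{pred}.
#' @export
fitStack <- function(y_train, M_train, M_val, enet_cfg = enetConfig(),
                     gbm_cfg = gbmConfig(), inner_folds = 5, seed = 1L) {
  n <- length(y_train)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(inner_folds), n))
  oof <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("enet", "gbm")))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    fe <- fitEnet(y_train[tr], M_train[tr, , drop = FALSE],
                  M_train[!tr, , drop = FALSE], enet_cfg)
    fg <- fitGbm(y_train[tr], M_train[tr, , drop = FALSE],
                 M_train[!tr, , drop = FALSE], gbm_cfg)
    oof[!tr, "enet"] <- fe$pred
    oof[!tr, "gbm"] <- fg$pred
  }
  meta <- .nnlsMeta(y_train, oof)
  if (all(meta$w == 0)) {
    # the non-negativity constraint emptied the ensemble; fall back to the
    # base learner with the lowest out-of-fold MSE rather than predicting a
    # constant
    j <- which.min(colMeans((oof - y_train)^2))
    meta$w[j] <- 1
    meta$intercept <- mean(y_train - oof[, j])
  }
  fe <- fitEnet(y_train, M_train, M_val, enet_cfg)
  fg <- fitGbm(y_train, M_train, M_val, gbm_cfg)
  base_val <- cbind(enet = fe$pred, gbm = fg$pred)
  structure(list(intercept = meta$intercept,
                 weights = setNames(meta$w, c("enet", "gbm")),
                 base_models = list(enet = fe, gbm = fg),
                 oof = oof,
                 pred = drop(meta$intercept + base_val %*% meta$w),
                 fitted = drop(meta$intercept + oof %*% meta$w)),
            class = "StackModel")
}
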