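# The five predictors and their oracle equivalences.

test_that("GBLUP equals matched-penalty marker ridge on random fixtures", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 60; m <- 120
    M <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), n, m, byrow = TRUE)
    dimnames(M) <- list(sprintf("i%02d", 1:n), sprintf("s%03d", 1:m))
    y <- rnorm(n)
    tr <- 1:45; val <- 46:60
    vv <- list(sigma2_g = 0.6, sigma2_e = 0.4)
    fb <- fitGblup(y[tr], M[tr, ], M[val, ], variances = vv)
    p <- colMeans(M[tr, ]) / 2
    c2 <- 2 * sum(p * (1 - p))
    Zt <- sweep(M[tr, ], 2, 2 * p); Zv <- sweep(M[val, ], 2, 2 * p)
    lam <- vv$sigma2_e / (vv$sigma2_g / c2)
    beta <- solve(crossprod(Zt) + diag(lam, m), crossprod(Zt, y[tr] - fb$mu))
    pr <- fb$mu + drop(Zv %*% beta)
    expect_gte(cor(pr, fb$pred), 1 - 1e-8)
  }
})

test_that("GBLUP limits behave: no signal and duplicated individuals", {
  set.seed(21)
  n <- 50; m <- 80
  M <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("i%02d", 1:n), sprintf("s%02d", 1:m)))
  y <- rnorm(n)
  f0 <- fitGblup(y[1:40], M[1:40, ], M[41:50, ],
                 variances = list(sigma2_g = 1e-14, sigma2_e = 1))
  expect_equal(f0$pred, rep(mean(y[1:40]), 10))
  # validation duplicate of a training individual predicts its fitted value
  Mdup <- M[c(41:49, 5), ]
  fd <- fitGblup(y[1:40], M[1:40, ], Mdup,
                 variances = list(sigma2_g = 0.5, sigma2_e = 0.5))
  expect_equal(fd$pred[10], fd$fitted[5], tolerance = 1e-8)
})

test_that("BayesB bookkeeping and degenerate priors", {
  expect_equal(bayesbConfig()$n_retained, 15000L)
  expect_equal(bayesbConfig(n_iter = 200000, burn_in = 50000,
                            thin = 10)$n_retained, 15000L)
  set.seed(22)
  M <- matrix(rbinom(200, 2, 0.4), 40, 5,
              dimnames = list(sprintf("i%02d", 1:40), paste0("s", 1:5)))
  y <- rnorm(40)
  expect_warning(
    fb <- fitBayesB(y[1:30], M[1:30, ], M[31:40, ],
                    bayesbConfig(pi = 1, n_iter = 600, burn_in = 100,
                                 thin = 1, seed = 1)),
    "pi = 1")
  expect_true(all(fb$u_hat == 0))
  expect_equal(sd(fb$pred), 0)
})

test_that("BayesB single-marker posterior mean matches 1-D quadrature", {
  set.seed(23)
  n <- 50
  x <- rbinom(n, 2, 0.4); x <- x - mean(x)
  u_true <- 0.4
  s2e <- 0.6
  y <- x * u_true + rnorm(n, 0, sqrt(s2e))
  pi0 <- 0.6; df <- 5; S <- 0.05
  M <- matrix(x + mean(x), n, 1, dimnames = list(sprintf("i%02d", 1:n), "s1"))
  fb <- fitBayesB(y, M, M[0, , drop = FALSE],
                  bayesbConfig(pi = pi0, df = df, s_b = S, n_iter = 200000,
                               burn_in = 20000, thin = 10, seed = 2),
                  intercept = FALSE, sigma_e = s2e)
  oracle <- bayesb_quadrature_mean(y, x, pi0, df, S, s2e)
  us <- drop(fb$u_samples)
  rho <- acf(us, plot = FALSE, lag.max = 100)$acf[-1]
  ess <- length(us) / (1 + 2 * sum(pmax(rho, 0)))
  mcse <- sd(us) / sqrt(max(ess, 10))
  expect_lt(abs(fb$u_hat - oracle), 3 * mcse + 1e-3)
})

test_that("elastic net recovers OLS, closed-form ridge and full shrinkage", {
  set.seed(24)
  n <- 20; X <- matrix(rnorm(n * 3), n, 3,
                       dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n, 0, 0.3)
  # lambda = 0: OLS
  f0 <- enetFit(y, X, alpha = 0.5, lambda = 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(c(f0$beta0, f0$beta) - ols)), 1e-6)
  # alpha = 0, lambda = 1: closed-form ridge of the un-halved loss
  f1 <- enetFit(y, X, alpha = 0, lambda = 1)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  bref <- solve(crossprod(Xc) / n + diag(2, 3), crossprod(Xc, yc) / n)
  expect_lt(max(abs(f1$beta - drop(bref))), 1e-6)
  # alpha = 1 with a huge lambda: intercept-only
  f2 <- enetFit(y, X, alpha = 1, lambda = 100)
  expect_true(all(f2$beta == 0))
  expect_equal(f2$beta0, mean(y), tolerance = 1e-8)
})

test_that("elastic-net solutions satisfy the subgradient conditions of the loss", {
  set.seed(25)
  n <- 40; m <- 15
  M <- matrix(rbinom(n * m, 2, 0.35), n, m,
              dimnames = list(NULL, paste0("s", 1:m)))
  y <- drop(scale(M, scale = FALSE) %*% rnorm(m, 0, 0.3)) + rnorm(n)
  for (par in list(c(0.3, 0.05), c(0.7, 0.02), c(1, 0.05), c(0, 0.1))) {
    a <- par[1]; l <- par[2]
    f <- enetFit(y, M, a, l)
    r <- y - f$beta0 - drop(M %*% f$beta)
    grad <- -drop(crossprod(M, r)) / n
    act <- which(f$beta != 0)
    if (length(act))
      expect_lt(max(abs(grad[act] + l * (2 * (1 - a) * f$beta[act] +
                                           a * sign(f$beta[act])))), 1e-6)
    inact <- which(f$beta == 0)
    if (length(inact) && a > 0)
      expect_lte(max(abs(grad[inact])), l * a + 1e-6)
    expect_lt(abs(mean(r)), 1e-8)  # intercept optimality
  }
})

test_that("elastic-net grid search selects by accuracy, then MSE, then size", {
  set.seed(26)
  co <- quick_cohort(n = 120, m = 100, seed = 26,
                     n_qtl_additive = 15, n_qtl_dominance = 0,
                     n_qtl_epistatic_pairs = 0,
                     target_h2 = 0.5, target_d2 = 0, target_ep2 = 0,
                     target_batch2 = 0)
  tr <- 1:90; val <- 91:120
  fe <- fitEnet(co$y[tr], co$M[tr, ], co$M[val, ],
                enetConfig(alpha_grid = c(0, 0.5, 1), n_lambda = 15,
                           inner_folds = 3, seed = 1))
  expect_true(fe$alpha %in% c(0, 0.5, 1))
  expect_gt(fe$lambda, 0)
  expect_length(fe$pred, 30)
  expect_gt(cor(fe$pred, co$y[val]), 0)
})

test_that("GBM depth-1 single trees match exhaustive split search", {
  # the canonical separable fixture
  y4 <- c(0, 0, 10, 10)
  M4 <- cbind(snpA = c(0, 0, 2, 2), snpB = c(1, 0, 1, 0))
  b1 <- gbmTrain(y4, M4, ntree = 1, lr = 1, depth = 1, node_size = 1)
  expect_equal(gbmPredict(b1, M4), c(0, 0, 10, 10))
  # random fixtures against the brute-force stump
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 30; m <- 6
    M <- matrix(rbinom(n * m, 2, 0.4), n, m,
                dimnames = list(NULL, paste0("s", 1:m)))
    y <- rnorm(n)
    b <- gbmTrain(y, M, ntree = 1, lr = 1, depth = 1, node_size = 1)
    expect_equal(gbmPredict(b, M), best_stump(y, M), tolerance = 1e-6)
  }
})

test_that("GBM zero rounds and relative-influence normalization", {
  set.seed(27)
  M <- matrix(rbinom(300, 2, 0.4), 60, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  y <- M[, 2] * 1.5 + rnorm(60, 0, 0.5)
  b0 <- gbmTrain(y, M, ntree = 0, lr = 0.1, depth = 3, node_size = 5)
  expect_equal(gbmPredict(b0, M), rep(mean(y), 60))
  fg <- fitGbm(y[1:45], M[1:45, ], M[46:60, ],
               gbmConfig(ntree_grid = 100, lr_grid = 0.1, depth_grid = c(0, 3),
                         node_grid = 5, n_draws = 2, inner_folds = 3,
                         seed = 1))
  expect_equal(sum(fg$influence), 100, tolerance = 1e-6)
  expect_true(all(fg$influence >= 0))
  expect_equal(names(which.max(fg$influence)), "s2")
})

test_that("GBM hyperparameter grids follow the printed search space", {
  cfg <- gbmConfig()
  expect_equal(cfg$ntree_grid,
               c(100, 200, 300, 500, 750, 1000, 1250, 1500, 2000, 2500, 3000))
  expect_equal(cfg$lr_grid, seq(0.01, 1, by = 0.05))
  expect_equal(cfg$depth_grid, seq(0, 50, by = 5))
  expect_equal(cfg$node_grid, seq(5, 50, by = 15))
  expect_equal(cfg$n_draws, 36L)
})

test_that("stacking meta-learner is non-negative and sane", {
  nnls <- MetaboGP:::.nnlsMeta
  # identical base predictions collapse to that prediction
  set.seed(28)
  f <- rnorm(50)
  m <- nnls(f, cbind(enet = f, gbm = f))
  pred <- m$intercept + drop(cbind(f, f) %*% m$w)
  expect_lt(max(abs(pred - f)), 1e-8)
  expect_true(all(m$w >= 0))
  # truth vs pure noise: the noise learner is down-weighted
  bad <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    truth <- rnorm(80)
    y <- truth + rnorm(80, 0, 0.1)
    noise <- rnorm(80)
    m <- nnls(y, cbind(truth = truth, noise = noise))
    if (m$w[2] > 0.1) bad <- bad + 1
    expect_true(all(m$w >= 0))
  }
  expect_lte(bad, 2)
})

test_that("the full stack tracks its best base learner on simulated data", {
  co <- quick_cohort(n = 160, m = 120, seed = 29,
                     n_qtl_additive = 20, n_qtl_dominance = 0,
                     n_qtl_epistatic_pairs = 0, target_h2 = 0.55,
                     target_d2 = 0, target_ep2 = 0, target_batch2 = 0)
  tr <- 1:120; val <- 121:160
  ec <- enetConfig(alpha_grid = c(0, 1), n_lambda = 10, inner_folds = 3,
                   seed = 1)
  gcfg <- gbmConfig(ntree_grid = 100, lr_grid = 0.1, depth_grid = 3,
                    node_grid = 5, n_draws = 1, inner_folds = 3, seed = 1)
  fs <- fitStack(co$y[tr], co$M[tr, ], co$M[val, ], ec, gcfg,
                 inner_folds = 3, seed = 1)
  expect_true(all(fs$weights >= 0))
  r_stack <- cor(fs$pred, co$y[val])
  r_base <- max(cor(fs$base_models$enet$pred, co$y[val]),
                cor(fs$base_models$gbm$pred, co$y[val]))
  expect_gt(r_stack, 0.8 * r_base)
})

test_that("no predictor sees validation phenotypes", {
  co <- quick_cohort(n = 100, m = 60, seed = 30, n_qtl_additive = 15,
                     n_qtl_dominance = 0, n_qtl_epistatic_pairs = 0,
                     target_h2 = 0.5, target_d2 = 0, target_ep2 = 0,
                     target_batch2 = 0)
  tr <- 1:80; val <- 81:100
  ec <- enetConfig(alpha_grid = c(0.5), n_lambda = 8, inner_folds = 3,
                   seed = 1)
  gcfg <- gbmConfig(ntree_grid = 50, lr_grid = 0.2, depth_grid = 3,
                    node_grid = 5, n_draws = 1, inner_folds = 3, seed = 1)
  fits <- function() list(
    gblup = fitGblup(co$y[tr], co$M[tr, ], co$M[val, ])$pred,
    bayesb = fitBayesB(co$y[tr], co$M[tr, ], co$M[val, ],
                       bayesbConfig(n_iter = 500, burn_in = 100, thin = 1,
                                    seed = 3))$pred,
    enet = fitEnet(co$y[tr], co$M[tr, ], co$M[val, ], ec)$pred,
    gbm = fitGbm(co$y[tr], co$M[tr, ], co$M[val, ], gcfg)$pred,
    stack = fitStack(co$y[tr], co$M[tr, ], co$M[val, ], ec, gcfg,
                     inner_folds = 3, seed = 4)$pred)
  a <- fits()
  co$y[val] <- rnorm(20, 100, 5)  # scramble validation labels
  b <- fits()
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
})
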