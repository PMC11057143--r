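# Bayesian animal model: bookkeeping, ratio summaries, convergence
# diagnostics, phenotype adjustment, parameter recovery, and agreement with
# independent estimators.

test_that("retention bookkeeping is exact for all chain configs", {
  expect_equal(gibbsConfig(500000, 50000, 10)$n_retained, 45000L)
  for (cfg in list(c(20000, 5000, 5), c(1000, 100, 1), c(9000, 3000, 3))) {
    gc <- gibbsConfig(cfg[1], cfg[2], cfg[3])
    expect_equal(gc$n_retained, as.integer((cfg[1] - cfg[2]) / cfg[3]))
  }
  expect_error(gibbsConfig(1000, 2000, 10))
  expect_error(gibbsConfig(1000, 100, 0))
})

test_that("posterior ratios average per-sample ratios, not ratio of means", {
  mk_chain <- function(vs) {
    structure(list(var_samples = vs, n_retained = nrow(vs)),
              class = "PosteriorChain")
  }
  vs <- cbind(sigma2_additive = rep(0.3, 5), sigma2_batch = rep(0.2, 5),
              sigma2_e = rep(0.5, 5))
  vc <- summarizeRatios(mk_chain(vs))
  expect_equal(unname(vc$ratio_mean["h2"]), 0.30)
  expect_equal(unname(vc$ratio_mean["h2_batch"]), 0.20)
  # equal split over a, d, ep, e with batch excluded
  vs2 <- cbind(sigma2_additive = rep(0.25, 4), sigma2_dominance = rep(0.25, 4),
               sigma2_epistatic = rep(0.25, 4), sigma2_e = rep(0.25, 4))
  vc2 <- summarizeRatios(mk_chain(vs2))
  expect_equal(unname(vc2$ratio_mean["d2"]), 0.25)
  expect_equal(unname(vc2$ratio_mean["ep2"]), 0.25)
  # random chains match brute-force per-sample averaging
  set.seed(2)
  vs3 <- cbind(sigma2_additive = rexp(200), sigma2_dominance = rexp(200),
               sigma2_epistatic = rexp(200), sigma2_batch = rexp(200),
               sigma2_e = rexp(200))
  vc3 <- summarizeRatios(mk_chain(vs3), include_batch = TRUE)
  tot <- rowSums(vs3)
  expect_equal(unname(vc3$ratio_mean["h2"]),
               mean(vs3[, 1] / tot), tolerance = 1e-12)
  expect_equal(unname(vc3$ratio_mean["ep2"]),
               mean(vs3[, 3] / tot), tolerance = 1e-12)
  # main-text form: batch excluded from the d2/ep2/h2 denominator
  vc4 <- summarizeRatios(mk_chain(vs3), include_batch = FALSE)
  expect_equal(unname(vc4$ratio_mean["d2"]),
               mean(vs3[, 2] / (tot - vs3[, 4])), tolerance = 1e-12)
  expect_gt(unname(vc4$ratio_mean["d2"]), unname(vc3$ratio_mean["d2"]))
})

test_that("Geweke diagnostic is calibrated on stationary chains", {
  set.seed(3)
  z <- replicate(200, gewekeTest(rnorm(10000))$z)
  expect_gte(mean(abs(z) < 3), 0.99)
  # power: a 3-SD linear drift is flagged
  set.seed(4)
  drift <- rnorm(5000) + seq(0, 3, length.out = 5000)
  expect_lt(gewekeTest(drift)$p, 0.01)
  expect_error(gewekeTest(rep(1, 5000)), "constant")
  expect_error(gewekeTest(rnorm(50)), "short")
})

test_that("phenotype adjustment removes exactly the fitted fixed+batch part", {
  co <- quick_cohort(n = 150, m = 150, seed = 5, remove_batch = FALSE)
  G <- vanRadenG(co$genotypes)
  ch <- fitAnimalModel(co$cohort$phenotypes, list(additive = G),
                       cfg = gibbsConfig(1500, 500, 5, seed = 6))
  ys <- adjustPhenotypes(co$cohort$phenotypes, ch)
  # identity when the estimated effects are zeroed
  ch0 <- ch
  ch0$b_hat[] <- 0
  ch0$h_hat[] <- 0
  ys0 <- adjustPhenotypes(co$cohort$phenotypes, ch0)
  expect_equal(ys0$y_star, co$cohort$phenotypes$y)
  # y* removes X b-hat + W h-hat and nothing else
  fitted <- drop(ch$design$X %*% ch$b_hat) +
    unname(ch$h_hat[as.integer(ch$design$batch)])
  expect_equal(ys$y_star, unname(co$cohort$phenotypes$y - fitted),
               tolerance = 1e-12)
  # mismatched record sets rejected
  ph2 <- co$cohort$phenotypes[-1, ]
  expect_error(adjustPhenotypes(ph2, ch), "record")
})

test_that("adjusted phenotypes retain the genetic signal", {
  # near-noiseless additive trait: y* correlates strongly with truth
  cfg <- simConfig(n_individuals = 250, n_markers = 300, n_chromosomes = 3,
                   n_qtl_additive = 50, n_qtl_dominance = 0,
                   n_qtl_epistatic_pairs = 0, target_h2 = 0.9, target_d2 = 0,
                   target_ep2 = 0, target_batch2 = 0.05, n_batches = 6,
                   seed = 7)
  coh <- simulateCohort(cfg)
  g <- imputeMissingMean(coh$genotypes)
  G <- vanRadenG(g)
  ch <- fitAnimalModel(coh$phenotypes, list(additive = G),
                       cfg = gibbsConfig(2000, 500, 5, seed = 8))
  ys <- adjustPhenotypes(coh$phenotypes, ch)
  expect_gt(cor(ys$y_star, coh$architecture$true_genetic_value$additive),
            0.95)
})

test_that("model-1 Gibbs recovers simulated variance fractions", {
  cfg <- simConfig(n_individuals = 300, n_markers = 1000, n_chromosomes = 5,
                   n_qtl_additive = 80, n_qtl_dominance = 0,
                   n_qtl_epistatic_pairs = 0, target_h2 = 0.30,
                   target_d2 = 0, target_ep2 = 0, target_batch2 = 0.20,
                   n_batches = 10, seed = 9)
  coh <- simulateCohort(cfg)
  g <- imputeMissingMean(coh$genotypes)
  G <- vanRadenG(g)
  pca <- genotypePca(g, 2)
  ch <- fitAnimalModel(coh$phenotypes, list(additive = G),
                       cfg = gibbsConfig(8000, 2000, 5, seed = 10),
                       pc_scores = pca$scores)
  vc <- summarizeRatios(ch)
  expect_lt(abs(vc$ratio_mean["h2"] - 0.30), 0.10)
  expect_lt(abs(vc$ratio_mean["h2_batch"] - 0.20), 0.10)
  # Geweke convergence report runs on every component
  cr <- convergenceReport(ch)
  expect_equal(nrow(cr), 3)
  expect_true(all(cr$p >= 0 & cr$p <= 1))
})

test_that("posterior mean h2 agrees with dense REML on the same data", {
  cfg <- simConfig(n_individuals = 250, n_markers = 800, n_chromosomes = 4,
                   n_qtl_additive = 80, n_qtl_dominance = 0,
                   n_qtl_epistatic_pairs = 0, target_h2 = 0.35, target_d2 = 0,
                   target_ep2 = 0, target_batch2 = 0.15, n_batches = 8,
                   seed = 11)
  coh <- simulateCohort(cfg)
  g <- imputeMissingMean(coh$genotypes)
  G <- vanRadenG(g)
  ch <- fitAnimalModel(coh$phenotypes, list(additive = G),
                       cfg = gibbsConfig(8000, 2000, 5, seed = 12))
  h2_gibbs <- summarizeRatios(ch)$ratio_mean["h2"]
  des <- list(
    X = model.matrix(~ dim_class + parity_class, coh$phenotypes),
    W = model.matrix(~ 0 + batch, coh$phenotypes))
  s <- reml_dense(coh$phenotypes$y, des$X,
                  list(kernelValues(G), tcrossprod(des$W)))
  h2_reml <- s[1] / sum(s)
  expect_lt(abs(h2_gibbs - h2_reml), 0.05)
})

test_that("with an identity kernel the sampler matches a brute-force i.i.d. sampler", {
  set.seed(13)
  n <- 50
  ph <- data.frame(sample_id = sprintf("i%02d", 1:n),
                   y = rnorm(n, 2, 1),
                   dim_class = factor(sample(1:3, n, TRUE)),
                   parity_class = factor(sample(1:2, n, TRUE)),
                   batch = factor(rep(1, n)))
  In <- diag(n); dimnames(In) <- list(ph$sample_id, ph$sample_id)
  K <- RelationshipMatrix(In, "G_additive")
  ch <- fitAnimalModel(ph, list(additive = K),
                       cfg = gibbsConfig(20000, 5000, 5, seed = 14),
                       fit_batch = FALSE)
  X <- model.matrix(~ dim_class + parity_class, ph)
  scale0 <- var(ph$y) / 2 * 3 / 5
  ref <- gibbs_iid_bruteforce(ph$y, X, 20000, 5000, 5, scale0, seed = 15)
  m1 <- colMeans(ch$var_samples)
  m2 <- colMeans(ref)
  expect_lt(abs(m1["sigma2_additive"] - m2["s2a"]), 0.12)
  expect_lt(abs(m1["sigma2_e"] - m2["s2e"]), 0.12)
  r1 <- mean(ch$var_samples[, 1] / rowSums(ch$var_samples))
  r2 <- mean(ref[, 1] / rowSums(ref))
  expect_lt(abs(r1 - r2), 0.06)
})

test_that("non-PSD kernels are rejected", {
  set.seed(16)
  n <- 20
  ph <- data.frame(sample_id = sprintf("i%02d", 1:n), y = rnorm(n),
                   dim_class = factor(rep(1:2, 10)),
                   parity_class = factor(rep(1:2, each = 10)),
                   batch = factor(rep(1:2, 10)))
  bad <- diag(n); bad[1, 2] <- bad[2, 1] <- 2  # indefinite
  dimnames(bad) <- list(ph$sample_id, ph$sample_id)
  expect_error(
    fitAnimalModel(ph, list(additive = RelationshipMatrix(bad, "G_additive")),
                   cfg = gibbsConfig(500, 100, 2, seed = 1)),
    "positive semi-definite")
})

test_that("noiseless limit reproduces the true genetic values", {
  # response is (almost) pure additive genetic value: solutions track truth
  set.seed(17)
  cfg <- simConfig(n_individuals = 300, n_markers = 400, n_chromosomes = 2,
                   n_qtl_additive = 50, n_qtl_dominance = 0,
                   n_qtl_epistatic_pairs = 0, target_h2 = 0.99, target_d2 = 0,
                   target_ep2 = 0, target_batch2 = 0, n_batches = 4,
                   seed = 17)
  g <- simulateGenotypes(cfg)
  arch <- simulateArchitecture(cfg, g)
  tg <- arch$true_genetic_value
  ph <- data.frame(sample_id = tg$sample_id,
                   y = tg$additive + rnorm(300, 0, 0.02),
                   dim_class = factor(sample(1:2, 300, TRUE)),
                   parity_class = factor(sample(1:2, 300, TRUE)),
                   batch = factor(rep(1:4, 75)))
  G <- vanRadenG(imputeMissingMean(g))
  ch <- fitAnimalModel(ph, list(additive = G),
                       cfg = gibbsConfig(4000, 1000, 5, seed = 18),
                       fit_batch = FALSE)
  expect_gt(cor(ch$effect_means[, "additive"], tg$additive), 0.99)
})
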