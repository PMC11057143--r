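# Shared fixtures: small cohorts and genotype matrices built in code.

# random genotype matrix with named dims
rand_geno <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(d) <- list(sprintf("i%04d", seq_len(n)), sprintf("s%04d", seq_len(m)))
  GenotypeMatrix(d)
}

# small complete cohort with the trait response adjusted for the TRUE fixed
# and (optionally) batch effects — used where the varcomp stage is not under
# test itself
quick_cohort <- function(n = 300, m = 400, seed = 1, remove_batch = TRUE, ...) {
  args <- list(n_individuals = n, n_markers = m, n_chromosomes = 4,
               n_batches = 8, seed = seed,
               n_qtl_additive = max(5, round(m / 8)),
               n_qtl_dominance = max(2, round(m / 20)),
               n_qtl_epistatic_pairs = max(2, round(m / 20)))
  args <- utils::modifyList(args, list(...))
  cfg <- do.call(simConfig, args)
  coh <- simulateCohort(cfg)
  g <- imputeMissingMean(coh$genotypes)
  fx <- coh$architecture$fixed_effect_values
  y <- coh$phenotypes$y -
    fx$dim[as.integer(coh$phenotypes$dim_class)] -
    fx$parity[as.integer(coh$phenotypes$parity_class)]
  if (remove_batch) y <- y - attr(coh$phenotypes, "true_batch_effect")
  names(y) <- coh$phenotypes$sample_id
  list(cfg = cfg, cohort = coh, genotypes = g, M = dosages(g), y = y)
}
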