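# Synthetic cohort generator: genotypes with subpopulation and LD structure,
# a true genetic architecture (additive / dominance / additive-by-additive
# QTL), and phenotypes with batch and fixed (days-in-milk, parity) effects.

#' Simulate biallelic SNP genotypes with subpopulations and block LD
#'
#' Ancestral counted-allele frequencies are drawn uniformly on the configured
#' MAF range (random strand so frequencies sit on either side of 0.5);
#' per-subpopulation frequencies follow a Balding-Nichols Beta draw at the
#' configured Fst, truncated to the MAF range. Haplotypes are produced by
#' thresholding block-equicorrelated latent Gaussians at the Hardy-Weinberg
#' quantile of each subpopulation frequency, so within-block LD is
#' controlled by \code{ld_rho} and genotypes are in HWE within
#' subpopulations.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypeMatrix} with a \code{subpop} attribute
#'   giving each individual's subpopulation label.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  p <- config@params
  set.seed(p$seed)
  n <- p$n_individuals; m <- p$n_markers
  # ancestral frequencies of the counted allele
  maf <- runif(m, p$maf_range[1], p$maf_range[2])
  anc <- ifelse(runif(m) < 0.5, maf, 1 - maf)
  lo <- p$maf_range[1]; hi <- 1 - p$maf_range[1]
  # Balding-Nichols subpopulation frequencies, truncated to the MAF range
  pf <- matrix(anc, nrow = p$n_subpops, ncol = m, byrow = TRUE)
  if (p$fst > 0) {
    a <- anc * (1 - p$fst) / p$fst
    b <- (1 - anc) * (1 - p$fst) / p$fst
    for (s in seq_len(p$n_subpops)) pf[s, ] <- rbeta(m, a, b)
    pf <- pmin(pmax(pf, lo), hi)
  }
  subpop <- sort(rep_len(seq_len(p$n_subpops), n))
  # batch assignment (herd/date): Dirichlet(5) sizes, optionally nested
  # within subpopulations
  alpha <- 5
  w <- rgamma(p$n_batches, alpha, 1); w <- w / sum(w)
  batch <- integer(n)
  bsub <- rep_len(seq_len(p$n_subpops), p$n_batches)  # batch -> subpop
  if (p$batch_by_subpop && p$n_subpops > 1) {
    for (s in seq_len(p$n_subpops)) {
      ids <- which(subpop == s); bs <- which(bsub == s)
      batch[ids] <- sample(bs, length(ids), replace = TRUE,
                           prob = w[bs] / sum(w[bs]))
    }
  } else {
    batch <- sample.int(p$n_batches, n, replace = TRUE, prob = w)
  }
  empty <- setdiff(seq_len(p$n_batches), unique(batch))
  for (b in empty) {
    cand <- if (p$batch_by_subpop && p$n_subpops > 1)
      which(subpop == bsub[b]) else seq_len(n)
    batch[sample(cand, 1)] <- b
  }
  # optional herd-lineage drift: per-batch frequencies around the batch's
  # subpopulation frequencies, making batch-mates genetic relatives
  if (p$fst_batch > 0) {
    pb <- matrix(NA_real_, p$n_batches, m)
    fb <- p$fst_batch
    for (b in seq_len(p$n_batches)) {
      base <- if (p$batch_by_subpop && p$n_subpops > 1)
        pf[bsub[b], ] else pf[1 + (b - 1) %% p$n_subpops, ]
      pb[b, ] <- rbeta(m, base * (1 - fb) / fb, (1 - base) * (1 - fb) / fb)
    }
    pb <- pmin(pmax(pb, lo), hi)
    freq_row <- batch
    freq_mat <- pb
  } else {
    freq_row <- subpop
    freq_mat <- pf
  }
  # chromosome assignment: contiguous, near-equal marker counts
  chrom <- rep(seq_len(p$n_chromosomes), each = ceiling(m / p$n_chromosomes),
               length.out = m)
  # LD blocks never straddle chromosomes
  block <- integer(m); bid <- 0L
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    nb <- ceiling(length(idx) / p$ld_block_size)
    block[idx] <- bid + rep(seq_len(nb), each = p$ld_block_size,
                            length.out = length(idx))
    bid <- bid + nb
  }
  rho <- p$ld_rho
  dos <- matrix(0, n, m)
  blocks <- split(seq_len(m), block)
  for (idx in blocks) {
    bsz <- length(idx)
    for (h in 1:2) {
      shared <- rnorm(n)
      z <- sqrt(rho) * matrix(shared, n, bsz) +
        sqrt(1 - rho) * matrix(rnorm(n * bsz), n, bsz)
      thr <- qnorm(freq_mat[, idx, drop = FALSE])  # groups x bsz
      dos[, idx] <- dos[, idx] + (z < thr[freq_row, , drop = FALSE])
    }
  }
  rownames(dos) <- sprintf("ind_%04d", seq_len(n))
  colnames(dos) <- sprintf("snp_%05d", seq_len(m))
  mi <- data.frame(chrom = as.character(chrom),
                   pos = stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L,
                   a1 = "A", a2 = "B", row.names = colnames(dos),
                   stringsAsFactors = FALSE)
  g <- GenotypeMatrix(dos, markerInfo = mi)
  attr(g, "subpop") <- subpop
  attr(g, "batch") <- batch
  g
}

#' Simulate a true genetic architecture on a genotype matrix
#'
#' Additive QTL act on allele-frequency-centered dosages, dominance QTL on
#' centered heterozygosity indicators, and epistatic QTL pairs on products
#' of centered dosages. Raw standard-normal effects are rescaled so the
#' realized variance of each component on this cohort equals its target
#' fraction of a unit phenotypic variance (residual takes the remainder).
#'
#' @param config a \code{\link{simConfig}}.
#' @param genotypes the \linkS4class{GenotypeMatrix} the architecture acts on.
#' @return A list of class \code{TrueArchitecture} with the QTL effect maps,
#'   per-class fixed-effect values, per-batch effects, and the per-individual
#'   additive, dominance and epistatic true genetic values.
#' @export
simulateArchitecture <- function(config, genotypes) {
  stopifnot(is(config, "SimConfig"), is(genotypes, "GenotypeMatrix"))
  p <- config@params
  d <- dosages(genotypes)
  m <- ncol(d)
  stopifnot(p$n_qtl_additive <= m, p$n_qtl_dominance <= m)
  if (p$n_qtl_epistatic_pairs > 0 && m < 2)
    stop("epistatic pairs require at least two markers")
  set.seed(p$seed + 1L)
  af <- alleleFreq(genotypes)
  centered <- sweep(d, 2, 2 * af)

  rescale <- function(val, target) {
    v <- var(val)
    if (target <= 0 || v == 0) return(list(val = rep(0, length(val)), k = 0))
    k <- sqrt(target / v)
    list(val = val * k, k = k)
  }

  add_idx <- sort(sample.int(m, p$n_qtl_additive))
  a_raw <- rnorm(p$n_qtl_additive)
  ga <- drop(centered[, add_idx, drop = FALSE] %*% a_raw)
  sa <- rescale(ga, p$target_h2)
  additive <- setNames(a_raw * sa$k, colnames(d)[add_idx])

  dominance <- numeric(0); gd <- rep(0, nrow(d))
  if (p$n_qtl_dominance > 0) {
    dom_idx <- sort(sample.int(m, p$n_qtl_dominance))
    het <- (d[, dom_idx, drop = FALSE] == 1) * 1
    hetc <- sweep(het, 2, colMeans(het))
    d_raw <- rnorm(p$n_qtl_dominance)
    gd0 <- drop(hetc %*% d_raw)
    sd_ <- rescale(gd0, p$target_d2)
    gd <- sd_$val
    dominance <- setNames(d_raw * sd_$k, colnames(d)[dom_idx])
  }

  epistatic <- data.frame(marker1 = character(), marker2 = character(),
                          effect = numeric(), stringsAsFactors = FALSE)
  gep <- rep(0, nrow(d))
  if (p$n_qtl_epistatic_pairs > 0) {
    # partners are adjacent markers (same LD block where possible): cis
    # interactions carry a marginal (quadratic) signal through the LD
    # correlation, as interacting loci do in real data
    pr <- matrix(NA_integer_, p$n_qtl_epistatic_pairs, 2)
    first <- sample.int(m - 1, p$n_qtl_epistatic_pairs,
                        replace = p$n_qtl_epistatic_pairs > m - 1)
    pr[, 1] <- first
    pr[, 2] <- first + 1L
    e_raw <- rnorm(p$n_qtl_epistatic_pairs)
    gep0 <- rep(0, nrow(d))
    for (i in seq_len(nrow(pr)))
      gep0 <- gep0 + e_raw[i] * centered[, pr[i, 1]] * centered[, pr[i, 2]]
    se <- rescale(gep0, p$target_ep2)
    gep <- se$val
    epistatic <- data.frame(marker1 = colnames(d)[pr[, 1]],
                            marker2 = colnames(d)[pr[, 2]],
                            effect = e_raw * se$k, stringsAsFactors = FALSE)
  }

  batch_eff <- if (p$target_batch2 > 0) rnorm(p$n_batches) else
    rep(0, p$n_batches)
  arch <- list(
    additive_effects = additive,
    dominance_effects = dominance,
    epistatic_pairs = epistatic,
    fixed_effect_values = list(
      dim = rnorm(p$n_dim_classes, 0, 0.5),
      parity = rnorm(p$n_parity_classes, 0, 0.5)
    ),
    batch_effects = batch_eff,
    true_genetic_value = data.frame(
      sample_id = rownames(d),
      additive = sa$val, dominance = gd, epistatic = gep,
      stringsAsFactors = FALSE
    )
  )
  class(arch) <- "TrueArchitecture"
  arch
}

#' Simulate phenotype records for a cohort
#'
#' One record per individual: trait value, days-in-milk class, parity class,
#' batch id and subpopulation label. The batch assignment (Dirichlet(5)
#' sizes, optionally nested in subpopulations, optionally with herd-lineage
#' drift) comes from \code{\link{simulateGenotypes}}. Batch effects are
#' rescaled so the batch component realizes its target variance fraction;
#' the residual is independent Gaussian with the leftover fraction.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} from
#'   \code{\link{simulateGenotypes}}.
#' @param arch the matching \code{TrueArchitecture}.
#' @param config the \code{\link{simConfig}} used for both.
#' @return A \code{data.frame} (class \code{TraitTable}) with columns
#'   \code{sample_id}, \code{y}, \code{dim_class}, \code{parity_class},
#'   \code{batch}, \code{subpop}.
#' @export
simulatePhenotypes <- function(genotypes, arch, config) {
  stopifnot(is(genotypes, "GenotypeMatrix"),
            inherits(arch, "TrueArchitecture"))
  p <- config@params
  n <- nrow(dosages(genotypes))
  stopifnot(nrow(arch$true_genetic_value) == n)
  set.seed(p$seed + 2L)
  subpop <- attr(genotypes, "subpop")
  if (is.null(subpop)) subpop <- rep(1L, n)
  batch <- attr(genotypes, "batch")
  if (is.null(batch)) batch <- rep_len(seq_len(p$n_batches), n)

  dim_class <- sample.int(p$n_dim_classes, n, replace = TRUE)
  parity_class <- sample.int(p$n_parity_classes, n, replace = TRUE)

  be <- arch$batch_effects[batch]
  if (p$target_batch2 > 0 && var(be) > 0)
    be <- be * sqrt(p$target_batch2 / var(be))
  res_frac <- 1 - p$target_h2 - p$target_d2 - p$target_ep2 - p$target_batch2
  e <- rnorm(n, 0, sqrt(res_frac))
  tg <- arch$true_genetic_value
  y <- arch$fixed_effect_values$dim[dim_class] +
    arch$fixed_effect_values$parity[parity_class] +
    be + tg$additive + tg$dominance + tg$epistatic + e

  tt <- data.frame(sample_id = rownames(dosages(genotypes)), y = y,
                   dim_class = factor(dim_class,
                                      levels = seq_len(p$n_dim_classes)),
                   parity_class = factor(parity_class,
                                         levels = seq_len(p$n_parity_classes)),
                   batch = factor(batch, levels = seq_len(p$n_batches)),
                   subpop = subpop, stringsAsFactors = FALSE)
  attr(tt, "true_batch_effect") <- be
  attr(tt, "true_residual") <- e
  class(tt) <- c("TraitTable", "data.frame")
  tt
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper running \code{\link{simulateGenotypes}},
#' \code{\link{simulateArchitecture}} and \code{\link{simulatePhenotypes}}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{genotypes}, \code{architecture},
#'   \code{phenotypes}.
#' @export
simulateCohort <- function(config) {
  g <- simulateGenotypes(config)
  arch <- simulateArchitecture(config, g)
  ph <- simulatePhenotypes(g, arch, config)
  list(genotypes = g, architecture = arch, phenotypes = ph)
}

#' Write simulated cohort tables to TSV
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohortTsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genotypes.tsv")
  writeGenotypesTsv(cohort$genotypes, gp)
  pp <- file.path(dir, "phenotypes.tsv")
  write.table(cohort$phenotypes, pp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ap <- file.path(dir, "architecture_true_values.tsv")
  write.table(cohort$architecture$true_genetic_value, ap, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(gp, pp, ap))
}
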