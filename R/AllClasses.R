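#' @import methods
#' @importFrom stats var cor sd rnorm runif rbeta qnorm rchisq rgamma quantile
#'   prcomp hclust cutree ar pnorm pchisq lm coef optim optimize integrate
#'   dt setNames aggregate as.dist cov model.matrix predict qr.coef
#' @importFrom utils read.table write.table head
#' @useDynLib MetaboGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenotypeMatrix: biallelic SNP dosages with marker metadata
#'
#' Individuals x markers dosage codes counted on the second (ALT) allele,
#' 0/1/2 with NA for missing calls, plus per-marker metadata (chromosome,
#' position, alleles) and per-marker counted-allele frequencies.
#'
#' @slot dosages numeric matrix, individuals in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids); hard calls are 0/1/2 with
#'   NA for missing, mean-imputed entries are expected dosages in [0, 2].
#' @slot markerInfo data.frame with one row per marker: \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2} (the counted allele).
#' @slot alleleFreq numeric vector, frequency of the counted allele per
#'   marker, computed from observed calls.
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    dosages = "matrix",
    markerInfo = "data.frame",
    alleleFreq = "numeric"
  )
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "sample ids (rownames) must be present and unique")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    msg <- c(msg, "marker ids (colnames) must be present and unique")
  bad <- d[!is.na(d)]
  # hard calls are 0/1/2; mean-imputed entries are expected dosages in [0, 2]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  if (nrow(object@markerInfo) != ncol(d))
    msg <- c(msg, "markerInfo must have one row per marker")
  if (length(object@alleleFreq) != ncol(d))
    msg <- c(msg, "alleleFreq must have one entry per marker")
  af <- object@alleleFreq[!is.na(object@alleleFreq)]
  if (length(af) && (any(af < 0) || any(af > 1)))
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of 0/1/2/NA dosages with rownames (sample
#'   ids) and colnames (marker ids).
#' @param markerInfo optional data.frame of per-marker metadata with columns
#'   \code{chrom}, \code{pos}, \code{a1}, \code{a2}; a single-chromosome
#'   placeholder is built when omitted.
#' @param alleleFreq optional counted-allele frequencies; recomputed from
#'   observed calls when omitted.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosages, markerInfo = NULL, alleleFreq = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind_", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp_", seq_len(ncol(dosages)))
  if (is.null(markerInfo)) {
    markerInfo <- data.frame(
      chrom = rep("1", ncol(dosages)),
      pos = seq_len(ncol(dosages)),
      a1 = "A", a2 = "B",
      row.names = colnames(dosages),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(alleleFreq)) alleleFreq <- .afFromDosages(dosages)
  new("GenotypeMatrix", dosages = dosages, markerInfo = markerInfo,
      alleleFreq = alleleFreq)
}

.afFromDosages <- function(d) {
  nobs <- colSums(!is.na(d))
  colSums(d, na.rm = TRUE) / (2 * pmax(nobs, 1L)) + ifelse(nobs == 0, NA, 0)
}

#' RelationshipMatrix: a genomic kernel over individuals
#'
#' @slot values symmetric numeric matrix with sample ids as dimnames.
#' @slot kind one of \code{"G_additive"}, \code{"D_dominance"},
#'   \code{"GG_epistatic"}.
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", kind = "character")
)

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "kernel must be square")
  else if (max(abs(v - t(v))) > 1e-10 * max(1, max(abs(v))))
    msg <- c(msg, "kernel must be symmetric within 1e-10")
  if (!object@kind %in% c("G_additive", "D_dominance", "GG_epistatic"))
    msg <- c(msg, "kind must be G_additive, D_dominance or GG_epistatic")
  if (is.null(rownames(v))) msg <- c(msg, "sample ids required as dimnames")
  if (length(msg)) msg else TRUE
})

RelationshipMatrix <- function(values, kind) {
  values <- (values + t(values)) / 2
  new("RelationshipMatrix", values = values, kind = kind)
}

#' SimConfig: synthetic cohort configuration
#'
#' Holds the cohort dimensions, allele-frequency and LD structure, the
#' experimental design (batches, days-in-milk and parity classes) and the
#' target variance fractions of the simulated genetic architecture. The
#' defaults emulate a dairy cohort: two genetic subpopulations, 21 herd/date
#' batches, six days-in-milk classes and four parity classes.
#'
#' @slot params named list of configuration values; see \code{\link{simConfig}}.
#' @export
setClass("SimConfig", representation(params = "list"))

setValidity("SimConfig", function(object) {
  p <- object@params
  msg <- character()
  cnt <- c("n_individuals", "n_markers", "n_chromosomes", "ld_block_size",
           "n_subpops", "n_batches", "n_dim_classes", "n_parity_classes",
           "n_qtl_additive")
  for (nm in cnt) if (p[[nm]] < 1) msg <- c(msg, paste(nm, "must be positive"))
  if (p$n_qtl_dominance < 0 || p$n_qtl_epistatic_pairs < 0)
    msg <- c(msg, "QTL counts must be non-negative")
  mr <- p$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    msg <- c(msg, "maf_range must lie within (0, 0.5]")
  if (p$ld_block_size > p$n_markers)
    msg <- c(msg, "ld_block_size cannot exceed n_markers")
  if (p$ld_rho < 0 || p$ld_rho >= 1) msg <- c(msg, "ld_rho must be in [0, 1)")
  if (p$fst < 0 || p$fst >= 0.5) msg <- c(msg, "fst must be in [0, 0.5)")
  if (p$fst_batch < 0 || p$fst_batch >= 0.5)
    msg <- c(msg, "fst_batch must be in [0, 0.5)")
  tf <- c(p$target_h2, p$target_d2, p$target_ep2, p$target_batch2)
  if (any(tf < 0)) msg <- c(msg, "target variance fractions must be >= 0")
  if (sum(tf) >= 1)
    msg <- c(msg, "target variance fractions must sum to < 1")
  if (length(msg)) msg else TRUE
})

#' Build a synthetic-cohort configuration
#'
#' @param n_individuals,n_markers,n_chromosomes cohort dimensions.
#' @param maf_range range of ancestral counted-allele minor frequencies,
#'   within (0, 0.5].
#' @param ld_block_size markers per equicorrelated LD block.
#' @param ld_rho latent haplotype correlation within a block, in [0, 1).
#' @param n_subpops number of genetic subpopulations (default 2).
#' @param fst Balding-Nichols divergence of subpopulation allele
#'   frequencies, in [0, 0.5).
#' @param fst_batch additional Balding-Nichols drift of per-batch allele
#'   frequencies around their subpopulation frequencies (herd-lineage
#'   relatedness: batch-mates become genetic relatives); 0 disables.
#' @param n_batches herd/date sampling batches (default 21).
#' @param n_dim_classes days-in-milk classes (6 in the cohort design).
#' @param n_parity_classes parity classes (4 in the cohort design).
#' @param n_qtl_additive,n_qtl_dominance,n_qtl_epistatic_pairs QTL counts.
#' @param target_h2,target_d2,target_ep2,target_batch2 target fractions of
#'   phenotypic variance for the additive, dominance, additive-by-additive
#'   epistatic and batch components; must sum to < 1 (remainder residual).
#' @param batch_by_subpop when TRUE each batch samples a single
#'   subpopulation (herd/date batches are genetically coherent), confounding
#'   batch with genetic structure; default FALSE (batches cut across the
#'   population).
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(n_individuals = 1353, n_markers = 61226,
                      n_chromosomes = 29, maf_range = c(0.05, 0.5),
                      ld_block_size = 20, ld_rho = 0.5,
                      n_subpops = 2, fst = 0.05, fst_batch = 0,
                      n_batches = 21, n_dim_classes = 6,
                      n_parity_classes = 4,
                      n_qtl_additive = 300, n_qtl_dominance = 100,
                      n_qtl_epistatic_pairs = 100,
                      target_h2 = 0.25, target_d2 = 0.10,
                      target_ep2 = 0.20, target_batch2 = 0.20,
                      batch_by_subpop = FALSE, seed = 1L) {
  p <- list(n_individuals = n_individuals, n_markers = n_markers,
            n_chromosomes = n_chromosomes, maf_range = maf_range,
            ld_block_size = ld_block_size, ld_rho = ld_rho,
            n_subpops = n_subpops, fst = fst, fst_batch = fst_batch,
            n_batches = n_batches,
            n_dim_classes = n_dim_classes,
            n_parity_classes = n_parity_classes,
            n_qtl_additive = n_qtl_additive,
            n_qtl_dominance = n_qtl_dominance,
            n_qtl_epistatic_pairs = n_qtl_epistatic_pairs,
            target_h2 = target_h2, target_d2 = target_d2,
            target_ep2 = target_ep2, target_batch2 = target_batch2,
            batch_by_subpop = isTRUE(batch_by_subpop),
            seed = as.integer(seed))
  new("SimConfig", params = p)
}

# ---- generics -------------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param x,object a GenotypeMatrix
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markerInfo)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("alleleFreq", "GenotypeMatrix", function(x) x@alleleFreq)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname RelationshipMatrix-class
#' @export
setMethod("sampleIds", "RelationshipMatrix", function(x) rownames(x@values))

#' @rdname RelationshipMatrix-class
#' @param x,object a RelationshipMatrix
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))
#' @rdname RelationshipMatrix-class
#' @export
setMethod("kernelValues", "RelationshipMatrix", function(x) x@values)

#' @rdname RelationshipMatrix-class
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))
#' @rdname RelationshipMatrix-class
#' @export
setMethod("kernelKind", "RelationshipMatrix", function(x) x@kind)

#' Subset a GenotypeMatrix by individuals and/or markers
#' @param x a GenotypeMatrix
#' @param i individual index/ids
#' @param j marker index/ids
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  d <- x@dosages[i, j, drop = FALSE]
  GenotypeMatrix(d, markerInfo = x@markerInfo[j, , drop = FALSE],
                 alleleFreq = NULL)
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  cat("GenotypeMatrix:", nrow(d), "individuals x", ncol(d), "markers\n")
  nm <- sum(is.na(d))
  cat("  missing calls:", nm,
      sprintf("(%.2f%%)", 100 * nm / length(d)), "\n")
  cat("  chromosomes:", length(unique(object@markerInfo$chrom)), "\n")
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix (", object@kind, "): ",
      nrow(object@values), " individuals, mean diagonal ",
      sprintf("%.3f", mean(diag(object@values))), "\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$n_individuals, "individuals x", p$n_markers,
      "markers,", p$n_subpops, "subpops (fst", p$fst, "),",
      p$n_batches, "batches\n")
  cat("  targets: h2 =", p$target_h2, " d2 =", p$target_d2,
      " ep2 =", p$target_ep2, " batch2 =", p$target_batch2, "\n")
})
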