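# Genomic relationship kernels (VanRaden additive, Vitezica dominance,
# Hadamard additive-by-additive), genotype PCA and kernel-induced genomic
# distances.

.requireComplete <- function(g) {
  if (anyNA(dosages(g)))
    stop("missing dosages present; run imputeMissingMean() first")
}

#' VanRaden additive genomic relationship matrix
#'
#' G = MM' / (2 sum p_j (1 - p_j)) with M the dosage matrix centered by
#' twice the counted-allele frequency per marker.
#'
#' @param g a complete (no missing calls) \linkS4class{GenotypeMatrix}.
#' @param freq optional allele frequencies to center with; defaults to the
#'   frequencies observed in \code{g}.
#' @return A \linkS4class{RelationshipMatrix} of kind \code{G_additive}.
#' @export
vanRadenG <- function(g, freq = NULL) {
  .requireComplete(g)
  d <- dosages(g)
  p <- if (is.null(freq)) computeAlleleFreq(g) else freq
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero VanRaden denominator")
  M <- sweep(d, 2, 2 * p)
  G <- tcrossprod(M) / denom
  RelationshipMatrix(G, "G_additive")
}

#' Vitezica dominance relationship matrix
#'
#' Dominance covariate per marker: genotype 0 -> -2p^2, 1 -> 2pq,
#' 2 -> -2q^2 (q = 1 - p, p the counted-allele frequency);
#' D = WW' / sum (2 p_j q_j)^2. The coding is HWE-centered, and D is
#' invariant to swapping which allele is counted.
#'
#' @inheritParams vanRadenG
#' @return A \linkS4class{RelationshipMatrix} of kind \code{D_dominance}.
#' @export
vitezicaD <- function(g, freq = NULL) {
  .requireComplete(g)
  d <- dosages(g)
  p <- if (is.null(freq)) computeAlleleFreq(g) else freq
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  if (denom <= 0) stop("all markers monomorphic: zero Vitezica denominator")
  W <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (code in 0:2) {
    val <- switch(code + 1L, -2 * p^2, 2 * p * q, -2 * q^2)
    idx <- d == code
    W[idx] <- matrix(val, nrow(d), ncol(d), byrow = TRUE)[idx]
  }
  D <- tcrossprod(W) / denom
  RelationshipMatrix(D, "D_dominance")
}

#' Additive-by-additive epistatic kernel by Hadamard product
#'
#' GG_ij = G_ij * G_ij, the element-wise product of the additive kernel with
#' itself (positive semi-definite by the Schur product theorem). Not
#' rescaled by default; \code{normalize} divides by mean(diag) for
#' comparability.
#'
#' @param G a \linkS4class{RelationshipMatrix} of kind \code{G_additive}.
#' @param normalize rescale so the mean diagonal is 1 (default FALSE).
#' @return A \linkS4class{RelationshipMatrix} of kind \code{GG_epistatic}.
#' @export
hadamardGG <- function(G, normalize = FALSE) {
  stopifnot(is(G, "RelationshipMatrix"))
  if (kernelKind(G) != "G_additive")
    stop("hadamardGG expects the additive kernel, got ", kernelKind(G))
  GG <- kernelValues(G) * kernelValues(G)
  if (normalize) GG <- GG / mean(diag(GG))
  RelationshipMatrix(GG, "GG_epistatic")
}

#' Genotype principal component analysis
#'
#' PCA of the column-centered (optionally column-standardized) dosage
#' matrix, used to describe population substructure and to supply PC-score
#' covariates to the animal model.
#'
#' @param g a complete GenotypeMatrix.
#' @param n_components number of components to retain.
#' @param standardize divide centered columns by their SD (default FALSE,
#'   VanRaden-consistent).
#' @return list of class \code{PcaResult}: \code{scores} (individuals x
#'   components), \code{variance_explained} (per-component fraction of the
#'   total dosage variance).
#' @export
genotypePca <- function(g, n_components = 2, standardize = FALSE) {
  .requireComplete(g)
  d <- dosages(g)
  if (n_components > min(dim(d)))
    stop("n_components exceeds min(n individuals, n markers)")
  pc <- prcomp(d, center = TRUE, scale. = standardize, rank. = n_components)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(scores = pc$x[, seq_len(n_components), drop = FALSE],
              variance_explained = ve[seq_len(n_components)],
              loadings = pc$rotation)
  class(out) <- "PcaResult"
  out
}

#' Kernel-induced genomic distance
#'
#' d_ij = sqrt(max(0, G_ii + G_jj - 2 G_ij)), the Euclidean distance in the
#' feature space of the additive kernel; zero diagonal, symmetric.
#'
#' @param G a \linkS4class{RelationshipMatrix} of kind \code{G_additive}.
#' @return symmetric numeric distance matrix with sample-id dimnames.
#' @export
genomicDistance <- function(G) {
  stopifnot(is(G, "RelationshipMatrix"))
  if (kernelKind(G) != "G_additive")
    stop("genomicDistance expects the additive kernel")
  v <- kernelValues(G)
  dg <- diag(v)
  d2 <- outer(dg, dg, "+") - 2 * v
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' Write a symmetric matrix as TSV with a sample-id header
#' @param mat matrix with dimnames
#' @param path output path
#' @export
writeMatrixTsv <- function(mat, path) {
  out <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
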