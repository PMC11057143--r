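# Genotype input (VCF / PLINK text / native TSV) and chip-style quality
# control: autosome restriction, call-rate, MAF and Hardy-Weinberg filters.

#' Read genotypes from VCF, PLINK text or native TSV
#'
#' Dosage is counted on the alternate (VCF) / second (PLINK) allele; missing
#' calls are kept as NA; marker order follows the file.
#'
#' @param path file path (.vcf; .ped with a sibling .map; or .tsv).
#' @param format one of \code{"vcf"}, \code{"plink_text"}, \code{"tsv"}.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, format = c("vcf", "plink_text", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = .readVcf(path),
         plink_text = .readPlinkText(path),
         tsv = .readTsv(path))
}

.readVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic records not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles per call; "./." and friends -> NA
  cnt <- function(x) {
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "." | a == ""))
        return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  }
  d <- t(apply(gt, 1, cnt))
  dimnames(d) <- dimnames(gt)
  d <- t(d)  # individuals x markers
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(d) <- ids
  mi <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                   a1 = fix[, "REF"], a2 = fix[, "ALT"], row.names = ids,
                   stringsAsFactors = FALSE)
  GenotypeMatrix(d, markerInfo = mi)
}

.readPlinkText <- function(path) {
  map_path <- sub("\\.ped$", ".map", path)
  if (!file.exists(map_path)) stop("missing .map file: ", map_path)
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  colnames(map)[1:4] <- c("chrom", "id", "cm", "pos")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- nrow(map)
  n <- length(lines)
  A1 <- matrix("0", n, m); A2 <- A1
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("malformed .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, got ", length(f))
    sample_ids[i] <- f[2]
    A1[i, ] <- f[seq(7, by = 2, length.out = m)]
    A2[i, ] <- f[seq(8, by = 2, length.out = m)]
  }
  # second allele = lexicographically larger of the two observed alleles
  dos <- matrix(NA_real_, n, m)
  alleles1 <- character(m); alleles2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(A1[, j], A2[, j]); obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2) stop("more than two alleles at marker ", map$id[j])
    alleles1[j] <- if (length(obs)) obs[1] else "0"
    alleles2[j] <- if (length(obs) == 2) obs[2] else alleles1[j]
    miss <- A1[, j] == "0" | A2[, j] == "0"
    dos[, j] <- (A1[, j] == alleles2[j]) + (A2[, j] == alleles2[j])
    dos[miss, j] <- NA_real_
  }
  rownames(dos) <- make.unique(sample_ids)
  colnames(dos) <- map$id
  mi <- data.frame(chrom = as.character(map$chrom), pos = map$pos,
                   a1 = alleles1, a2 = alleles2, row.names = map$id,
                   stringsAsFactors = FALSE)
  GenotypeMatrix(dos, markerInfo = mi)
}

.readTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- tab[[1]]
  GenotypeMatrix(d)
}

#' Write a GenotypeMatrix to the native TSV dosage format
#'
#' Header row of marker ids, first column \code{sample_id}, cells 0/1/2/NA.
#' @param g a GenotypeMatrix
#' @param path output path
#' @export
writeGenotypesTsv <- function(g, path) {
  d <- dosages(g)
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GenotypeMatrix as a minimal VCF 4.2 (GT only, unphased)
#' @param g a GenotypeMatrix (no missing dosages are required; NA becomes ./.)
#' @param path output path
#' @export
writeGenotypesVcf <- function(g, path) {
  d <- dosages(g); mi <- markerInfo(g)
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    gj <- d[, j]
    gt <- ifelse(is.na(gj), "./.", gtcode[gj + 1])
    writeLines(paste(c(mi$chrom[j], mi$pos[j], colnames(d)[j],
                       mi$a1[j], mi$a2[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  close(con)
  invisible(path)
}

#' Counted-allele frequency per marker
#'
#' p_j = (sum of observed dosages) / (2 x observed calls).
#' @param g a GenotypeMatrix
#' @return named numeric vector of frequencies.
#' @export
computeAlleleFreq <- function(g) {
  d <- dosages(g)
  nobs <- colSums(!is.na(d))
  if (any(nobs == 0))
    stop("all calls missing for marker(s): ",
         paste(colnames(d)[nobs == 0], collapse = ", "))
  setNames(colSums(d, na.rm = TRUE) / (2 * nobs), colnames(d))
}

#' One-degree-of-freedom Hardy-Weinberg chi-square p-value
#'
#' Observed genotype counts against HWE expectations at the observed allele
#' frequency.
#' @param n0,n1,n2 counts of dosage-0, 1 and 2 genotypes.
#' @return two-sided chi-square p-value (1 df); 1 for monomorphic markers.
#' @export
hweChisqP <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (n1 + 2 * n2) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Chip-style genotype quality control
#'
#' Filter order: drop non-autosomal markers, then samples with call rate
#' below \code{callrate_min}, then markers with call rate below
#' \code{callrate_min}, then markers with MAF strictly below \code{maf_min},
#' then markers with HWE chi-square p <= \code{hwe_p}. MAF is
#' \code{min(p, 1-p)} of the counted allele on observed calls.
#'
#' @param g a GenotypeMatrix
#' @param maf_min minimum minor allele frequency (strict: MAF < maf_min is
#'   removed, MAF == maf_min retained).
#' @param hwe_p HWE chi-square p-value threshold (p <= hwe_p removed).
#' @param callrate_min minimum fraction of non-missing calls for samples and
#'   markers.
#' @param autosomes_only drop markers whose chromosome is X, Y, MT or 0.
#' @return list with elements \code{genotypes} (filtered GenotypeMatrix) and
#'   \code{report} (a \code{QCReport} list of counts, id lists and
#'   thresholds).
#' @export
qcFilter <- function(g, maf_min = 0.05, hwe_p = 1e-5, callrate_min = 0.95,
                     autosomes_only = TRUE) {
  d <- dosages(g)
  if (nrow(d) == 0 || ncol(d) == 0) stop("empty genotype matrix")
  mi <- markerInfo(g)
  n_markers_in <- ncol(d); n_samples_in <- nrow(d)

  removed_nonautosomal <- character(0)
  if (autosomes_only) {
    nonauto <- toupper(mi$chrom) %in% c("X", "Y", "MT", "M", "XY", "0")
    removed_nonautosomal <- colnames(d)[nonauto]
    d <- d[, !nonauto, drop = FALSE]; mi <- mi[!nonauto, , drop = FALSE]
  }

  scr <- rowMeans(!is.na(d))
  removed_sample <- rownames(d)[scr < callrate_min]
  d <- d[scr >= callrate_min, , drop = FALSE]

  mcr <- colMeans(!is.na(d))
  removed_mcall <- colnames(d)[mcr < callrate_min]
  keep <- mcr >= callrate_min
  d <- d[, keep, drop = FALSE]; mi <- mi[keep, , drop = FALSE]

  nobs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(nobs, 1L))
  maf <- pmin(p, 1 - p)
  removed_maf <- colnames(d)[maf < maf_min | nobs == 0]
  keep <- maf >= maf_min & nobs > 0
  d <- d[, keep, drop = FALSE]; mi <- mi[keep, , drop = FALSE]

  hwe <- vapply(seq_len(ncol(d)), function(j) {
    gj <- d[, j]
    hweChisqP(sum(gj == 0, na.rm = TRUE), sum(gj == 1, na.rm = TRUE),
              sum(gj == 2, na.rm = TRUE))
  }, numeric(1))
  removed_hwe <- colnames(d)[hwe <= hwe_p]
  keep <- hwe > hwe_p
  d <- d[, keep, drop = FALSE]; mi <- mi[keep, , drop = FALSE]

  if (ncol(d) == 0 || nrow(d) == 0)
    stop("quality control removed all markers or samples")

  report <- list(
    n_markers_in = n_markers_in, n_markers_out = ncol(d),
    n_samples_in = n_samples_in, n_samples_out = nrow(d),
    removed_nonautosomal = removed_nonautosomal,
    removed_by_sample_callrate = removed_sample,
    removed_by_marker_callrate = removed_mcall,
    removed_by_maf = removed_maf,
    removed_by_hwe = removed_hwe,
    thresholds = list(maf_min = maf_min, hwe_p = hwe_p,
                      callrate_min = callrate_min,
                      autosomes_only = autosomes_only)
  )
  class(report) <- "QCReport"
  list(genotypes = GenotypeMatrix(d, markerInfo = mi), report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report:", x$n_samples_in, "->", x$n_samples_out, "samples;",
      x$n_markers_in, "->", x$n_markers_out, "markers\n")
  cat("  non-autosomal:", length(x$removed_nonautosomal),
      "| sample call rate:", length(x$removed_by_sample_callrate),
      "| marker call rate:", length(x$removed_by_marker_callrate),
      "| MAF:", length(x$removed_by_maf),
      "| HWE:", length(x$removed_by_hwe), "\n")
  invisible(x)
}

#' Mean-impute missing dosages
#'
#' Each missing call is replaced by 2 p_j, the expected dosage at the
#' marker's observed counted-allele frequency; column means are preserved.
#'
#' @param g a GenotypeMatrix
#' @return a GenotypeMatrix with no missing entries.
#' @export
imputeMissingMean <- function(g) {
  d <- dosages(g)
  nobs <- colSums(!is.na(d))
  if (any(nobs == 0))
    stop("cannot impute marker(s) with no observed calls: ",
         paste(colnames(d)[nobs == 0], collapse = ", "))
  if (!anyNA(d)) return(g)
  p <- colSums(d, na.rm = TRUE) / (2 * nobs)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  GenotypeMatrix(d, markerInfo = markerInfo(g), alleleFreq = p)
}
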