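#' PCA of genotype data with Hardy-Weinberg normalisation
#'
#' Principal component analysis of alternate-allele dosages under an
#' additive model. Per SNP the allele frequency p is estimated from the
#' called samples, SNPs fixed in the sample (p of 0 or 1) are dropped,
#' missing calls are imputed with the mean dosage 2p, and entries are
#' normalised by the theoretical standard deviation under
#' Hardy-Weinberg equilibrium, (g - 2p) / sqrt(2p(1 - p)). Components
#' come from the eigendecomposition of the sample-by-sample covariance
#' of the normalised matrix (efficient when samples are far fewer than
#' SNPs). The sign of each component is fixed so that its
#' largest-magnitude score is positive.
#'
#' @param geno A [geno_matrix()].
#' @param n_components Number of components to return.
#' @param autosomes_only Drop ChrZ/ChrW SNPs first (default `TRUE`).
#' @param samples Optional keep-list of sample ids (e.g. an unrelated
#'   subset).
#' @return A `snp_pca` object: list with `scores` (tibble sample, line,
#'   PC1..PCk), `explained` (fraction of variance per component),
#'   `snps_used`.
#' @export
pca_genotypes <- function(geno, n_components = 10, autosomes_only = TRUE,
                          samples = NULL) {
  calls <- geno$calls
  info <- geno$samples
  if (!is.null(samples)) {
    calls <- calls[samples, , drop = FALSE]
    info <- info[match(samples, info$sample), ]
  }
  if (nrow(calls) < 2) pf_abort("PCA requires at least 2 samples")
  if (autosomes_only && !all(is.na(geno$snps$chrom))) {
    calls <- calls[, !geno$snps$chrom %in% c("ChrZ", "ChrW", "Z", "W"),
                   drop = FALSE]
  }
  z <- normalize_dosages(calls)
  if (!ncol(z)) pf_abort("all SNPs are monomorphic in the sample")
  n_components <- min(n_components, nrow(calls) - 1L, ncol(z))
  # eigendecomposition in sample space; scores equal the U %*% D factor
  # of the SVD of z, so they match an SNP-space formulation exactly
  eg <- eigen(tcrossprod(z), symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  scores <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_components)]), n_components)
  for (k in seq_len(n_components)) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    scores = bind_cols(info[c("sample", "line")], as_tibble(scores)),
    explained = pos[seq_len(n_components)] / sum(pos),
    snps_used = ncol(z)
  ), class = "snp_pca")
}

# centre/normalise a dosage matrix under HWE; drops fixed SNPs,
# imputes missing with the mean dosage (2p), columns end up mean 0
normalize_dosages <- function(calls) {
  p <- colMeans(calls, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  calls <- calls[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(calls, 2, 2 * p)
  z[is.na(z)] <- 0
  sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
}

#' @export
print.snp_pca <- function(x, ...) {
  cat("<snp_pca> ", nrow(x$scores), " samples, ", x$snps_used,
      " SNPs; PC1-", length(x$explained), " explain ",
      format(round(100 * sum(x$explained), 1)), "% of variance\n", sep = "")
  invisible(x)
}

#' @export
tidy.snp_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score")
}

#' @export
glance.snp_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), snps_used = x$snps_used,
         pc1_frac = x$explained[1],
         pc2_frac = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Linkage disequilibrium between adjacent panel SNPs
#'
#' Squared Pearson correlation of genotype dosages for each consecutive
#' SNP pair in panel order within a chromosome, over samples called at
#' both SNPs. Pairs spanning a chromosome boundary emit no value; pairs
#' with a monomorphic member give `NA`.
#'
#' @param geno A [geno_matrix()]; SNP order and chromosomes are taken
#'   from `geno$snps`.
#' @return A tibble: `snp_id_1`, `snp_id_2`, `chrom`, `r2`.
#' @export
adjacent_ld <- function(geno) {
  snps <- geno$snps
  calls <- geno$calls
  n <- nrow(snps)
  if (n < 2) {
    return(tibble(snp_id_1 = character(), snp_id_2 = character(),
                  chrom = character(), r2 = numeric()))
  }
  i <- seq_len(n - 1)
  same <- snps$chrom[i] == snps$chrom[i + 1]
  i <- i[same | is.na(same)]
  r2 <- vapply(i, function(j) {
    g1 <- calls[, j]
    g2 <- calls[, j + 1]
    ok <- !is.na(g1) & !is.na(g2)
    if (sum(ok) < 2 || var(g1[ok]) == 0 || var(g2[ok]) == 0) return(NA_real_)
    cor(g1[ok], g2[ok])^2
  }, numeric(1))
  tibble(snp_id_1 = snps$snp_id[i], snp_id_2 = snps$snp_id[i + 1],
         chrom = snps$chrom[i], r2 = r2)
}
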