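#' Genotype matrices
#'
#' Validation genotypes are held as a samples-by-SNPs integer matrix of
#' alternate-allele dosages (0, 1, 2, `NA` for a missing call), with a
#' sample table (`sample`, `line`) and a SNP table (`snp_id`, `chrom`,
#' `pos`).
#'
#' @param calls Integer matrix, samples in rows, SNPs in columns, values
#'   in \{0, 1, 2, NA\}; dimnames give sample ids and SNP ids.
#' @param samples Tibble with columns `sample`, `line` (one row per
#'   matrix row).
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (one row per
#'   matrix column).
#' @return A list with class `geno_matrix`.
#' @export
geno_matrix <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    pf_abort("genotype calls must be 0, 1, 2 or NA")
  }
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps)) {
    pf_abort("genotype matrix dimensions do not match sample/SNP tables")
  }
  rownames(calls) <- samples$sample
  colnames(calls) <- snps$snp_id
  structure(list(calls = calls, samples = as_tibble(samples),
                 snps = as_tibble(snps)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs (", format(round(100 * mean(is.na(x$calls)), 2)),
      "% missing)\n", sep = "")
  invisible(x)
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @export
tidy.geno_matrix <- function(x, ...) {
  as_tibble(x$calls, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "snp_id",
                        values_to = "dosage") |>
    left_join(x$samples, by = "sample")
}

#' Read and write genotype matrices
#'
#' TSV layout: first column `sample`, second `line`, then one column per
#' SNP with values 0/1/2/NA. SNP coordinates are carried in a `#snp`
#' header block (`snp_id`, `chrom`, `pos` lines prefixed with `##`) when
#' written by the package, or supplied via `snps`.
#'
#' @param path TSV path.
#' @param snps Optional SNP table (`snp_id`, `chrom`, `pos`); if `NULL`,
#'   recovered from the `##` header lines.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, snps = NULL) {
  if (!file.exists(path)) pf_abort(paste0("no such genotype file: ", path))
  all_lines <- readr::read_lines(path)
  hdr <- grep("^##", all_lines, value = TRUE)
  if (is.null(snps) && length(hdr)) {
    parts <- strsplit(sub("^##", "", hdr), "\t", fixed = TRUE)
    snps <- tibble(snp_id = map_chr(parts, 1), chrom = map_chr(parts, 2),
                   pos = as.numeric(map_chr(parts, 3)))
  }
  x <- readr::read_tsv(I(all_lines[!startsWith(all_lines, "##")]),
                       col_types = readr::cols(
                         sample = readr::col_character(),
                         line = readr::col_character(),
                         .default = readr::col_integer()),
                       na = c("NA", "."), progress = FALSE)
  calls <- as.matrix(x[setdiff(names(x), c("sample", "line"))])
  if (is.null(snps)) {
    snps <- tibble(snp_id = colnames(calls), chrom = NA_character_,
                   pos = NA_real_)
  }
  geno_matrix(calls, x[c("sample", "line")], snps)
}

#' @rdname read_genotypes
#' @param geno A [geno_matrix()].
#' @export
write_genotypes <- function(geno, path) {
  hdr <- paste0("##", geno$snps$snp_id, "\t", geno$snps$chrom, "\t",
                geno$snps$pos)
  body <- bind_cols(geno$samples[c("sample", "line")],
                    as_tibble(geno$calls))
  readr::write_lines(hdr, path)
  readr::write_tsv(body, path, na = "NA", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Import genotypes from VCF
#'
#' Parses the GT field of a VCF into alternate-allele dosages. Sample
#' line labels may be given as a named vector; unknown samples get
#' `NA` line.
#'
#' @param path VCF path.
#' @param line_labels Optional named character vector `sample -> line`.
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path, line_labels = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    pf_abort("package 'vcfR' is required for VCF genotype import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           vapply(strsplit(g, "/", fixed = TRUE),
                  function(a) sum(a == "1"), integer(1)))
  }
  calls <- t(apply(gt, 1, dosage))
  calls <- matrix(as.integer(calls), nrow = ncol(gt), ncol = nrow(gt),
                  byrow = TRUE, dimnames = list(colnames(gt), rownames(gt)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snps <- tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.numeric(fix$POS))
  samples <- tibble(sample = colnames(gt),
                    line = if (is.null(line_labels)) NA_character_ else
                      unname(line_labels[colnames(gt)]))
  geno_matrix(calls, samples, snps)
}

#' Classify assay conversion
#'
#' Per-SNP conversion outcome on the array: `failed` if the genotype
#' call rate falls below `call_rate_min`; otherwise
#' `monomorphic_low_allele_count` if the minor-allele count over all
#' called genotypes is below `min_minor_count`; otherwise `polymorphic`.
#'
#' @param geno A [geno_matrix()].
#' @param call_rate_min Minimum fraction of called samples (default 0.98,
#'   matching the "high call rate" criterion).
#' @param min_minor_count Minimum minor-allele count (default 2).
#' @return A tibble: `snp_id`, `call_rate`, `minor_count`, `class`.
#' @export
classify_conversion <- function(geno, call_rate_min = 0.98,
                                min_minor_count = 2) {
  calls <- geno$calls
  called <- colSums(!is.na(calls))
  call_rate <- called / nrow(calls)
  alt <- colSums(calls, na.rm = TRUE)
  minor <- pmin(alt, 2 * called - alt)
  cls <- ifelse(call_rate < call_rate_min, "failed",
                ifelse(minor < min_minor_count,
                       "monomorphic_low_allele_count", "polymorphic"))
  tibble(snp_id = colnames(calls), call_rate = unname(call_rate),
         minor_count = unname(minor), class = unname(cls))
}

#' Mendelian trio consistency
#'
#' A trio is inconsistent at a SNP iff the offspring genotype cannot be
#' formed from one allele of each parent under biallelic inheritance
#' (e.g. homozygous parents 0 x 0 force offspring 0; 0 x 2 force the
#' obligate heterozygote; a parent homozygous for one allele excludes an
#' offspring homozygous for the other). Any missing genotype within the
#' trio yields no evidence (consistent). Sex chromosomes (ChrZ, ChrW)
#' are excluded by default because of hemizygosity.
#'
#' @param geno A [geno_matrix()].
#' @param trios Tibble with columns `sire`, `dam`, `offspring` (sample
#'   ids present in `geno`).
#' @param autosomes_only Drop ChrZ/ChrW SNPs (default `TRUE`).
#' @return A tibble: `snp_id`, `n_inconsistent` (trios), `fails`
#'   (inconsistent in >= 1 trio).
#' @export
mendelian_check <- function(geno, trios, autosomes_only = TRUE) {
  calls <- geno$calls
  unknown <- setdiff(unlist(trios[c("sire", "dam", "offspring")]),
                     rownames(calls))
  if (length(unknown)) {
    pf_abort(paste0("trio sample(s) not in genotype matrix: ",
                    paste(unknown, collapse = ", ")))
  }
  keep <- rep(TRUE, ncol(calls))
  if (autosomes_only) {
    keep <- !geno$snps$chrom %in% c("ChrZ", "ChrW", "Z", "W")
  }
  n_bad <- integer(ncol(calls))
  for (i in seq_len(nrow(trios))) {
    f <- calls[trios$sire[i], ]
    m <- calls[trios$dam[i], ]
    o <- calls[trios$offspring[i], ]
    bad <- (f == 0 & o == 2) | (f == 2 & o == 0) |
      (m == 0 & o == 2) | (m == 2 & o == 0) |
      (f == 0 & m == 0 & o != 0) | (f == 2 & m == 2 & o != 2) |
      (((f == 0 & m == 2) | (f == 2 & m == 0)) & o != 1)
    # any missing genotype in the trio gives no evidence at that SNP
    bad[is.na(f) | is.na(m) | is.na(o)] <- FALSE
    n_bad <- n_bad + bad
  }
  n_bad[!keep] <- 0L
  tibble(snp_id = colnames(calls), n_inconsistent = n_bad,
         fails = n_bad > 0L & keep)
}

#' Exact Hardy-Weinberg test
#'
#' Conditional exact test: given the sample size and the minor-allele
#' count, every feasible heterozygote count of matching parity is
#' weighted by the number of genotype configurations producing it,
#' n! / (n_AA! n_AB! n_BB!) * 2^n_AB. The p-value is the total
#' probability of outcomes no more probable than the observed one
#' (two-sided by probability ordering), so p is in (0, 1]. `midp = TRUE`
#' counts only half of the observed outcome's probability.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (>= 0, total >= 1).
#' @param midp Use the mid-p variant (default `FALSE`).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, midp = FALSE) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) pf_abort("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) pf_abort("at least one genotype is required")
  minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  hets <- seq(minor %% 2, minor, by = 2)
  log_w <- function(ab) {
    aa <- (minor - ab) / 2
    bb <- n - aa - ab
    # counts derived for the minor-allele orientation; symmetric in p
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(ab + 1) - lgamma(bb + 1) +
      ab * log(2)
  }
  lw <- vapply(hets, log_w, numeric(1))
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) pf_abort("heterozygote count incompatible with allele count")
  p <- sum(pr[pr <= obs * (1 + 1e-12)])
  if (midp) p <- p - obs / 2
  min(1, p)
}

#' @rdname hwe_exact_test
#' @param geno A [geno_matrix()].
#' @param samples Optional subset of sample ids.
#' @return `hwe_test_all()`: a tibble `snp_id`, `p_hwe`.
#' @export
hwe_test_all <- function(geno, samples = NULL, midp = FALSE) {
  calls <- geno$calls
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  p <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2), midp = midp)
  }, numeric(1))
  tibble(snp_id = colnames(calls), p_hwe = p)
}

#' Estimate minor allele frequency from genotypes
#'
#' Folded allele frequency min(p, 1-p) with p the alternate-allele
#' frequency over called genotypes.
#'
#' @param geno A [geno_matrix()].
#' @param lines Optional subset of line labels to restrict samples.
#' @return A tibble: `snp_id`, `maf` (`NA` where all calls are missing).
#' @export
estimate_maf <- function(geno, lines = NULL) {
  calls <- geno$calls
  if (!is.null(lines)) {
    calls <- calls[geno$samples$line %in% lines, , drop = FALSE]
  }
  called <- colSums(!is.na(calls))
  p <- ifelse(called > 0, colSums(calls, na.rm = TRUE) / (2 * called), NA)
  tibble(snp_id = colnames(calls), maf = unname(pmin(p, 1 - p)))
}
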