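#' Filter policy
#'
#' Thresholds for the candidate-reduction cascade that shrinks a raw
#' multi-line SNP catalog to an array-designable subset. Defaults follow
#' the chicken 600K design: SNP quality score >= 60 with minor allele
#' frequency >= 0.05 (rescuing prior-panel SNPs and exempting Chr16 and
#' ChrZ), a spacing screen requiring >= 10 SNP-free bases on one side and
#' >= 4 on the other, array design scores of 16-mer count <= 100 with
#' p-convert >= 0.2 on at least one probe strand, exclusion of records
#' whose read coverage exceeds the per-line mean by more than 3 standard
#' deviations, and post-genotyping removal of SNPs with extreme
#' Hardy-Weinberg departure (P < 1e-5).
#'
#' @param min_quality Minimum phred-like SNP quality score.
#' @param min_maf Minimum minor allele frequency.
#' @param exempt_chroms Chromosomes exempt from the quality/MAF and
#'   proximity screens (poorly assembled or low-diversity chromosomes
#'   whose candidates are retained regardless).
#' @param near_gap,far_gap Required SNP-free bases on the two sides
#'   (`near_gap <= far_gap`).
#' @param max_kmer16 Maximum 16-mer count of the probe flank.
#' @param min_pconvert Minimum predicted conversion probability.
#' @param coverage_sd_k Coverage-outlier multiplier (mean + k * SD).
#' @param hwe_alpha Hardy-Weinberg exclusion threshold (strict `<`).
#' @return A list with class `filter_policy`.
#' @export
filter_policy <- function(min_quality = 60, min_maf = 0.05,
                          exempt_chroms = c("Chr16", "ChrZ"),
                          near_gap = 4, far_gap = 10,
                          max_kmer16 = 100, min_pconvert = 0.2,
                          coverage_sd_k = 3, hwe_alpha = 1e-5) {
  if (near_gap > far_gap) pf_abort("near_gap must be <= far_gap")
  vals <- c(min_quality, min_maf, near_gap, far_gap, max_kmer16,
            min_pconvert, coverage_sd_k, hwe_alpha)
  if (any(vals < 0)) pf_abort("filter thresholds must be >= 0")
  structure(list(min_quality = min_quality, min_maf = min_maf,
                 exempt_chroms = exempt_chroms, near_gap = near_gap,
                 far_gap = far_gap, max_kmer16 = max_kmer16,
                 min_pconvert = min_pconvert, coverage_sd_k = coverage_sd_k,
                 hwe_alpha = hwe_alpha),
            class = "filter_policy")
}

#' Quality and minor-allele-frequency screen
#'
#' Keeps a record iff its chromosome is exempt, or some single line shows
#' quality >= `min_quality` together with MAF >= `min_maf`, or the global
#' (all-lines-combined) analysis does, or the SNP was present in a prior
#' panel. Missing evidence never satisfies a threshold.
#'
#' @param catalog A sorted [snp_catalog()].
#' @param policy A [filter_policy()].
#' @return The filtered catalog (rows only ever removed, never altered).
#' @export
filter_quality_maf <- function(catalog, policy = filter_policy()) {
  lines <- catalog_lines(catalog)
  line_pass <- rep(FALSE, nrow(catalog))
  for (ln in lines$name) {
    q <- catalog[[paste0(ln, "_qual")]]
    m <- catalog[[paste0(ln, "_maf")]]
    line_pass <- line_pass |
      (!is.na(q) & q >= policy$min_quality & !is.na(m) & m >= policy$min_maf)
  }
  gq <- catalog$global_quality
  gm <- catalog$global_maf
  global_pass <- !is.na(gq) & gq >= policy$min_quality &
    !is.na(gm) & gm >= policy$min_maf
  keep <- catalog$chrom %in% policy$exempt_chroms | line_pass | global_pass |
    (!is.na(catalog$in_prior_panel) & catalog$in_prior_panel)
  restore_catalog(catalog[keep, ], catalog)
}

#' Proximity (spacing) screen
#'
#' A single pass over the original SNP configuration: for each record the
#' gap to a neighbour is the count of intervening SNP-free bases
#' (`pos_next - pos_prev - 1`); chromosome-terminal sides count as
#' infinite. A record is kept iff one side has >= `far_gap` SNP-free
#' bases and the other >= `near_gap`. Exempt chromosomes bypass the
#' screen. With `iterative = TRUE` the screen is re-applied to its own
#' output until a fixed point, for sensitivity work; the default single
#' pass targets the cluster itself rather than eroding its flanks.
#'
#' @inheritParams filter_quality_maf
#' @param iterative Re-apply until a fixed point (default `FALSE`).
#' @export
filter_proximity <- function(catalog, policy = filter_policy(),
                             iterative = FALSE) {
  one_pass <- function(cat) {
    if (!nrow(cat)) return(cat)
    pos <- cat$pos
    chrom <- cat$chrom
    same_prev <- c(FALSE, chrom[-1] == chrom[-length(chrom)])
    left <- ifelse(same_prev, pos - c(NA, pos[-length(pos)]) - 1, Inf)
    same_next <- c(chrom[-1] == chrom[-length(chrom)], FALSE)
    right <- ifelse(same_next, c(pos[-1], NA) - pos - 1, Inf)
    keep <- (left >= policy$far_gap & right >= policy$near_gap) |
      (left >= policy$near_gap & right >= policy$far_gap) |
      chrom %in% policy$exempt_chroms
    restore_catalog(cat[keep, ], cat)
  }
  out <- one_pass(catalog)
  while (iterative && nrow(out) < nrow(catalog)) {
    catalog <- out
    out <- one_pass(catalog)
  }
  out
}

#' Array design-score screen
#'
#' Keeps a record iff at least one probe strand satisfies both
#' manufacturability thresholds: 16-mer count <= `max_kmer16` and
#' p-convert >= `min_pconvert` (inclusive comparisons). Records with no
#' design scores on either strand are removed and their count reported.
#'
#' @inheritParams filter_quality_maf
#' @export
filter_design_scores <- function(catalog, policy = filter_policy()) {
  strand_pass <- function(k, p) {
    !is.na(k) & !is.na(p) & k <= policy$max_kmer16 & p >= policy$min_pconvert
  }
  no_scores <- (is.na(catalog$fwd_16mer) | is.na(catalog$fwd_pconvert)) &
    (is.na(catalog$rev_16mer) | is.na(catalog$rev_pconvert))
  if (any(no_scores)) {
    inform(paste0(sum(no_scores),
                  " record(s) had no design scores on either strand; removed"))
  }
  keep <- strand_pass(catalog$fwd_16mer, catalog$fwd_pconvert) |
    strand_pass(catalog$rev_16mer, catalog$rev_pconvert)
  restore_catalog(catalog[keep, ], catalog)
}

#' Coverage-outlier exclusion
#'
#' Guards against false positives from collapsed duplications: per line,
#' the mean and sample standard deviation of read coverage are computed
#' over that line's segregating records, and a record is removed if in
#' any line where it segregates its coverage strictly exceeds
#' mean + `coverage_sd_k` * SD. Lines with fewer than two segregating
#' records contribute no exclusions (warning).
#'
#' @inheritParams filter_quality_maf
#' @export
filter_coverage_outliers <- function(catalog, policy = filter_policy()) {
  lines <- catalog_lines(catalog)
  drop <- rep(FALSE, nrow(catalog))
  for (ln in lines$name) {
    seg <- catalog[[paste0(ln, "_seg")]]
    seg <- !is.na(seg) & seg
    cov <- catalog[[paste0(ln, "_cov")]]
    idx <- seg & !is.na(cov)
    if (sum(idx) < 2L) {
      if (any(seg)) {
        warn(paste0("line ", ln, " has < 2 segregating records with ",
                    "coverage; no coverage-outlier exclusion applied"))
      }
      next
    }
    thr <- mean(cov[idx]) + policy$coverage_sd_k * sd(cov[idx])
    drop <- drop | (idx & cov > thr)
  }
  restore_catalog(catalog[!drop, ], catalog)
}

#' Hardy-Weinberg extreme-departure exclusion
#'
#' Applied after validation genotyping: records whose exact
#' Hardy-Weinberg test p-value is strictly below `hwe_alpha` are removed
#' (extreme departure suggests genotyping error, copy-number overlap or a
#' lethal recessive rather than selection). Records without a p-value are
#' kept.
#'
#' @inheritParams filter_quality_maf
#' @param hwe_pvalues Named numeric vector, `snp_id -> p`.
#' @export
filter_hwe_extreme <- function(catalog, hwe_pvalues,
                               policy = filter_policy()) {
  if (length(hwe_pvalues) &&
      (any(hwe_pvalues < 0, na.rm = TRUE) || any(hwe_pvalues > 1, na.rm = TRUE))) {
    pf_abort("HWE p-values must lie in [0, 1]")
  }
  p <- unname(hwe_pvalues[match(catalog$snp_id, names(hwe_pvalues))])
  keep <- is.na(p) | p >= policy$hwe_alpha
  restore_catalog(catalog[keep, ], catalog)
}

#' Run the pre-genotyping filter cascade
#'
#' Applies quality/MAF, proximity, design-score and coverage-outlier
#' screens in order and records a per-stage count ledger mirroring the
#' design flow diagram.
#'
#' @inheritParams filter_quality_maf
#' @return A list with elements `catalog` (the filtered catalog) and
#'   `ledger` (a tibble of stage, n_in, n_out, n_removed).
#' @export
filter_cascade <- function(catalog, policy = filter_policy()) {
  stages <- list(
    quality_maf = function(c) filter_quality_maf(c, policy),
    proximity = function(c) filter_proximity(c, policy),
    design_scores = function(c) filter_design_scores(c, policy),
    coverage_outliers = function(c) filter_coverage_outliers(c, policy)
  )
  ledger <- tibble(stage = character(), n_in = integer(),
                   n_out = integer(), n_removed = integer())
  for (nm in names(stages)) {
    n_in <- nrow(catalog)
    catalog <- stages[[nm]](catalog)
    ledger <- add_row(ledger, stage = nm, n_in = n_in, n_out = nrow(catalog),
                      n_removed = n_in - nrow(catalog))
  }
  list(catalog = catalog, ledger = ledger)
}
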