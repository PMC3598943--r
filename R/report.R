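#' Validation summary
#'
#' Summary arithmetic of a validation campaign: counts of polymorphic,
#' monomorphic (low allele count) and failed-to-convert SNPs, trio count
#' and Mendelian failures, with percentages of the validated total
#' rounded half-up to 2 decimals so the printed table recomputes exactly
#' from its counts.
#'
#' @param total_validated,polymorphic,monomorphic,failed,mendel_fail
#'   Counts; the three conversion classes must sum to `total_validated`.
#' @param trios Number of trios checked.
#' @return A tibble with one row per summary line (`metric`, `count`,
#'   `percent`).
#' @export
validation_summary <- function(total_validated, polymorphic, monomorphic,
                               failed, trios = NA_integer_,
                               mendel_fail = NA_integer_) {
  counts <- c(total_validated, polymorphic, monomorphic, failed)
  if (any(counts < 0, na.rm = TRUE)) pf_abort("counts must be >= 0")
  if (polymorphic + monomorphic + failed != total_validated) {
    pf_abort("conversion class counts must sum to total_validated")
  }
  pct <- function(x) round_half_up(100 * x / total_validated, 2)
  tibble(
    metric = c("total_validated", "polymorphic",
               "monomorphic_low_allele_count", "failed", "trios_checked",
               "mendel_fail"),
    count = c(total_validated, polymorphic, monomorphic, failed, trios,
              mendel_fail),
    percent = c(NA, pct(polymorphic), pct(monomorphic), pct(failed), NA,
                pct(mendel_fail))
  )
}

annotation_categories <- c(
  "intergenic", "intronic", "non-synonymous", "synonymous",
  "stopgain_stoploss", "upstream1kb", "downstream1kb", "utr3", "utr5",
  "splicing", "ncRNA")

#' Annotation summary
#'
#' Counts and percentages of predicted genomic effects for a panel.
#' Category percentages are of the annotated subset; the annotated
#' percentage is of the whole panel. Accepts either a panel catalog
#' (tibble with an `annotation` column, `NA` for unannotated records) or
#' a named vector of per-category counts together with `total_panel`.
#'
#' @param x A data frame with an `annotation` column, or a named numeric
#'   vector of category counts.
#' @param total_panel Total panel size (required when `x` is a count
#'   vector).
#' @return A tibble: `category`, `count`, `percent`.
#' @export
annotation_summary <- function(x, total_panel = NULL) {
  if (is.data.frame(x)) {
    total_panel <- total_panel %||% nrow(x)
    ann <- x$annotation[!is.na(x$annotation)]
    counts <- table(factor(ann, levels = annotation_categories))
    unknown <- setdiff(unique(ann), annotation_categories)
  } else {
    if (is.null(total_panel)) pf_abort("total_panel is required")
    unknown <- setdiff(names(x), annotation_categories)
    counts <- setNames(rep(0, length(annotation_categories)),
                       annotation_categories)
    counts[names(x)[names(x) %in% annotation_categories]] <-
      x[names(x) %in% annotation_categories]
  }
  if (length(unknown)) {
    pf_abort(paste0("unknown annotation categor(ies): ",
                    paste(unknown, collapse = ", ")))
  }
  annotated <- sum(counts)
  pct_of <- function(num, den) {
    if (den == 0) 0 else round_half_up(100 * num / den, 2)
  }
  tibble(
    category = c("total_panel", "annotated", annotation_categories),
    count = c(total_panel, annotated, as.numeric(counts)),
    percent = c(NA, pct_of(annotated, total_panel),
                vapply(as.numeric(counts), pct_of, numeric(1),
                       den = annotated))
  )
}

#' Inter-marker spacing statistics
#'
#' Gap lengths of a panel: distances between consecutive SNPs within a
#' chromosome plus, per chromosome, the distances from the chromosome
#' ends to the nearest SNP (so the gap multiset tiles each chromosome;
#' a chromosome with no SNP contributes its whole length as one gap,
#' with a warning). The inter-SNP gap here is the plain position
#' difference — distinct from the proximity filter's intervening-base
#' count.
#'
#' @param panel Tibble with `chrom`, `pos` (a `panel_selection` works).
#' @param chrom_lengths Named numeric vector, chromosome -> length in
#'   bases (must cover every panel position).
#' @return A list: `mean_gap`, `sd_gap`, `n_gaps`, and `cumulative`, a
#'   tibble of gap size `g`, fraction of gaps <= g (`snp_fraction`) and
#'   fraction of the genome in gaps <= g (`genome_coverage`).
#' @export
spacing_stats <- function(panel, chrom_lengths) {
  gaps <- numeric(0)
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    pos <- sort(panel$pos[panel$chrom == chr])
    if (length(pos) && max(pos) > len) {
      pf_abort(paste0("panel position beyond length of ", chr))
    }
    if (!length(pos)) {
      warn(paste0("chromosome ", chr, " has no panel SNP; ",
                  "whole length counted as one gap"))
      gaps <- c(gaps, len)
      next
    }
    gaps <- c(gaps, pos[1], diff(pos), len - pos[length(pos)])
  }
  g_sorted <- sort(unique(gaps))
  cum_snp <- vapply(g_sorted, function(g) mean(gaps <= g), numeric(1))
  genome <- sum(chrom_lengths)
  coverage <- vapply(g_sorted, function(g) 1 - sum(gaps[gaps > g]) / genome,
                     numeric(1))
  list(mean_gap = mean(gaps), sd_gap = sd(gaps), n_gaps = length(gaps),
       gaps = gaps,
       cumulative = tibble(g = g_sorted, snp_fraction = cum_snp,
                           genome_coverage = coverage))
}

#' Per-chromosome SNP density
#'
#' SNPs per megabase (physical) and per centimorgan (genetic), the two
#' panels of the density comparison: an evenly-distributed-in-cM panel
#' shows near-constant SNPs/cM while SNPs/Mb tracks the cM/Mb rate.
#'
#' @param panel Tibble with `chrom`, `pos`.
#' @param map A [genetic_map()].
#' @param chrom_lengths Named numeric vector of physical lengths (bases);
#'   defaults to the last map anchor per chromosome.
#' @return A tibble: `chrom`, `n_snps`, `snps_per_mb`, `snps_per_cm`.
#' @export
density_by_chromosome <- function(panel, map, chrom_lengths = NULL) {
  chroms <- unique(map$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(
      map_dbl(chroms, function(ch) max(map_chrom(map, ch)$pos_bp)), chroms)
  }
  out <- lapply(chroms, function(ch) {
    n <- sum(panel$chrom == ch)
    mb <- chrom_lengths[[ch]] / 1e6
    cm <- map_length_cm(map, ch)
    if (mb == 0 || cm == 0) {
      warn(paste0("chromosome ", ch, " has zero physical or map length"))
    }
    tibble(chrom = ch, n_snps = n,
           snps_per_mb = if (mb > 0) n / mb else NA_real_,
           snps_per_cm = if (cm > 0) n / cm else NA_real_)
  })
  list_rbind(out)
}

#' Three-group sharing counts
#'
#' For a three-set Venn partition, counts SNPs segregating in at least
#' one line of exactly each group combination. SNPs segregating only in
#' ungrouped lines are excluded.
#'
#' @param catalog A [snp_catalog()].
#' @param grouping Named character vector, line -> group label; exactly
#'   three distinct group labels.
#' @return A tibble: `groups` (e.g. `"broiler&WEL"`), `count`, one row
#'   per non-empty combination of the 7 Venn regions.
#' @export
group_sharing <- function(catalog, grouping) {
  gnames <- unique(unname(grouping))
  if (length(gnames) != 3) pf_abort("grouping must define exactly 3 groups")
  seg <- segregation_matrix(catalog)
  in_group <- sapply(gnames, function(g) {
    members <- intersect(names(grouping)[grouping == g], colnames(seg))
    if (!length(members)) return(rep(FALSE, nrow(seg)))
    rowSums(seg[, members, drop = FALSE]) > 0
  })
  in_group <- matrix(in_group, ncol = 3, dimnames = list(NULL, gnames))
  combos <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                        c = c(FALSE, TRUE))[-1, ]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- unlist(combos[i, ])
    tibble(groups = paste(gnames[mask], collapse = "&"),
           count = sum(in_group[, 1] == mask[1] & in_group[, 2] == mask[2] &
                         in_group[, 3] == mask[3]))
  })
  list_rbind(out)
}

#' Per-group mean SNP counts
#'
#' Arithmetic mean of per-line SNP counts within each group, reported in
#' millions to 1 decimal (half-up), the precision of the published
#' per-group averages.
#'
#' @param per_line_counts Named numeric vector, line -> SNP count.
#' @param grouping Named character vector, line -> group.
#' @return A tibble: `group`, `n_lines`, `mean_count`, `mean_millions`.
#' @export
group_mean_counts <- function(per_line_counts, grouping) {
  if (any(per_line_counts < 0)) pf_abort("counts must be >= 0")
  groups <- unique(unname(grouping[names(per_line_counts)]))
  out <- lapply(groups, function(g) {
    members <- names(grouping)[grouping == g]
    vals <- per_line_counts[intersect(members, names(per_line_counts))]
    tibble(group = g, n_lines = length(vals),
           mean_count = if (length(vals)) mean(vals) else NA_real_,
           mean_millions = if (length(vals)) {
             round_half_up(mean(vals) / 1e6, 1)
           } else NA_real_)
  })
  list_rbind(out)
}

#' Minor allele frequency histogram
#'
#' Counts per bin of width `binwidth` over (0, 0.5]; a MAF of exactly 0
#' falls in the first bin. One histogram per group when `groups` is
#' given.
#'
#' @param maf Numeric vector of folded frequencies in \[0, 0.5\].
#' @param binwidth Bin width (default 0.05).
#' @param groups Optional grouping vector parallel to `maf`.
#' @return A tibble: `group` (if any), `bin_low`, `bin_high`, `count`.
#' @export
maf_distribution <- function(maf, binwidth = 0.05, groups = NULL) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    pf_abort("MAF values must lie in [0, 0.5]")
  }
  breaks <- seq(0, 0.5, by = binwidth)
  one <- function(v) {
    h <- table(cut(v, breaks, include.lowest = TRUE))
    tibble(bin_low = head(breaks, -1), bin_high = breaks[-1],
           count = as.integer(h))
  }
  if (is.null(groups)) return(one(maf[!is.na(maf)]))
  out <- lapply(unique(groups), function(g) {
    mutate(one(maf[groups == g & !is.na(maf)]), group = g, .before = 1)
  })
  list_rbind(out)
}
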