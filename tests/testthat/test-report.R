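test_that("validation summary reproduces the published percentages from counts", {
  vs <- validation_summary(total_validated = 1829290, polymorphic = 1187482,
                           monomorphic = 313000, failed = 328808,
                           trios = 32, mendel_fail = 10674)
  pct <- setNames(vs$percent, vs$metric)
  expect_equal(unname(pct["polymorphic"]), 64.91)
  expect_equal(unname(pct["monomorphic_low_allele_count"]), 17.11)
  expect_equal(unname(pct["failed"]), 17.97)
  expect_equal(unname(pct["mendel_fail"]), 0.58)

  vs2 <- validation_summary(100, 100, 0, 0)
  expect_equal(vs2$percent[vs2$metric == "polymorphic"], 100)
  expect_error(validation_summary(100, 50, 10, 10), "sum")
})

test_that("annotation summary reproduces the published panel percentages", {
  counts <- c(intergenic = 266636, intronic = 189128,
              "non-synonymous" = 9345, synonymous = 12069,
              stopgain_stoploss = 120, upstream1kb = 5892,
              downstream1kb = 6456, utr3 = 2497, utr5 = 302,
              splicing = 83, ncRNA = 44)
  as1 <- annotation_summary(counts, total_panel = 580954)
  val <- setNames(as1$percent, as1$category)
  expect_equal(as1$count[as1$category == "annotated"], 492572)
  expect_equal(unname(val["annotated"]), 84.79)
  expect_equal(unname(val["intergenic"]), 54.13)
  expect_equal(unname(val["intronic"]), 38.40)
  expect_equal(unname(val["non-synonymous"]), 1.90)

  # from a panel catalog, and degenerate cases
  df <- tibble::tibble(annotation = c("intergenic", NA))
  as2 <- annotation_summary(df)
  expect_equal(as2$percent[as2$category == "annotated"], 50)
  expect_equal(as2$percent[as2$category == "intergenic"], 100)
  as3 <- annotation_summary(tibble::tibble(annotation = NA_character_))
  expect_equal(as3$count[as3$category == "annotated"], 0)
  expect_true(all(as3$percent[-1] == 0))
  expect_error(annotation_summary(tibble::tibble(annotation = "exotic")),
               "unknown annotation")
})

test_that("spacing gaps include chromosome-terminal distances", {
  panel <- tibble::tibble(chrom = "Chr1", pos = c(10, 30, 90))
  sp <- spacing_stats(panel, c(Chr1 = 100))
  expect_setequal(sp$gaps, c(10, 20, 60, 10))
  expect_equal(sp$mean_gap, 25)
  expect_equal(sum(sp$gaps), 100)  # gaps tile the chromosome
  # cumulative curves are monotone and end at 1
  expect_true(all(diff(sp$cumulative$snp_fraction) >= 0))
  expect_equal(dplyr::last(sp$cumulative$snp_fraction), 1)
  expect_equal(dplyr::last(sp$cumulative$genome_coverage), 1)

  dense <- tibble::tibble(chrom = "Chr1", pos = 1:5)
  expect_true(all(spacing_stats(dense, c(Chr1 = 5))$gaps <= 1))

  expect_warning(sp3 <- spacing_stats(tibble::tibble(chrom = character(),
                                                     pos = numeric()),
                                      c(Chr1 = 50)), "no panel SNP")
  expect_equal(sp3$gaps, 50)
  expect_error(spacing_stats(panel, c(Chr1 = 80)), "beyond")
})

test_that("density per chromosome uses physical and map lengths", {
  map <- test_map(length_bp = 1e6, length_cm = 3)
  panel <- tibble::tibble(chrom = "Chr1", pos = seq(5000, 995000, length.out = 100))
  d <- density_by_chromosome(panel, map, c(Chr1 = 1e6))
  expect_equal(d$snps_per_mb, 100)
  expect_equal(round(d$snps_per_cm, 2), 33.33)
  # empty chromosome yields zero densities
  map2 <- test_map(chrom = c("Chr1", "Chr2"), length_bp = 1e6, length_cm = 3)
  d2 <- density_by_chromosome(panel, map2, c(Chr1 = 1e6, Chr2 = 1e6))
  expect_equal(d2$n_snps[d2$chrom == "Chr2"], 0)
  expect_equal(d2$snps_per_cm[d2$chrom == "Chr2"], 0)
})

test_that("cM-based selection flattens SNPs/cM while SNPs/Mb tracks recombination rate", {
  # one line, candidates on a 2 kb grid so per-cM supply exceeds demand on
  # both a macro-like (2.5 cM/Mb) and a micro-like (12 cM/Mb) chromosome
  lines <- test_lines(names = "B1", fill = "B1")
  pos1 <- seq(2000, 10e6, by = 2000)
  pos2 <- seq(2000, 2e6, by = 2000)
  cat_g <- test_catalog(pos = c(pos1, pos2),
                        chrom = rep(c("Chr1", "Chr25"),
                                    c(length(pos1), length(pos2))),
                        lines = lines)
  map <- genetic_map(tibble::tibble(
    chrom = c("Chr1", "Chr1", "Chr25", "Chr25"),
    pos_bp = c(1, 10e6, 1, 2e6), pos_cM = c(0, 25, 0, 24)))
  panel <- select_panel(cat_g, selection_config(t = 200000,
                                                densities = c(B1 = 5)), map)
  d <- density_by_chromosome(panel, map, c(Chr1 = 10e6, Chr25 = 2e6))
  spread <- function(v) max(v) / min(v)
  expect_gt(spread(d$snps_per_mb), 2)            # follows cM/Mb contrast
  expect_lt(spread(d$snps_per_cm), 1.5)          # roughly flat per cM
  expect_lt(spread(d$snps_per_cm), spread(d$snps_per_mb) / 2)
})

test_that("three-group sharing partitions segregating SNPs into Venn regions", {
  lines <- test_lines()
  grouping <- c(B1 = "broiler", B2 = "broiler", WEL1 = "WEL", WEL2 = "WEL",
                BEL1 = "BEL")
  cat5 <- test_catalog(pos = c(100, 200, 300, 400, 500),
                       seg = list(c("B1", "WEL1"),
                                  "I1",          # ungrouped only: excluded
                                  "B2",
                                  "WEL2",
                                  "BEL1"))
  gs <- group_sharing(cat5, grouping)
  expect_equal(gs$count[gs$groups == "broiler&WEL"], 1)
  expect_equal(gs$count[gs$groups == "broiler"], 1)
  expect_equal(gs$count[gs$groups == "WEL"], 1)
  expect_equal(gs$count[gs$groups == "BEL"], 1)
  expect_equal(sum(gs$count), 4)  # the I1-only SNP is not counted
  expect_error(group_sharing(cat5, c(B1 = "x", B2 = "y")), "3 groups")
})

test_that("per-group means reproduce the published per-line averages", {
  lp <- chicken_line_panel()
  counts <- setNames(lp$n_snps_detected, lp$name)
  grouping <- setNames(ifelse(lp$group == "broiler", "broiler",
                              ifelse(lp$group == "inbred", "inbred", "layer")),
                       lp$name)
  gm <- group_mean_counts(counts, grouping)
  means <- setNames(gm$mean_millions, gm$group)
  expect_equal(unname(means["broiler"]), 10.0)
  expect_equal(unname(means["layer"]), 7.7)
  expect_equal(unname(means["inbred"]), 1.0)
  expect_equal(gm$n_lines, c(4, 12, 8))
})

test_that("MAF histograms bin (0, 0.5] in 0.05 steps", {
  d <- maf_distribution(rep(0.25, 7))
  expect_equal(sum(d$count), 7)
  expect_equal(d$count[d$bin_low == 0.2], 7)
  expect_equal(nrow(d), 10)
  expect_error(maf_distribution(0.6), "0, 0.5")
  expect_equal(sum(maf_distribution(numeric(0))$count), 0)

  # uniform draws: each bin within 3 sigma of n/bins
  set.seed(3)
  v <- runif(10000, 0, 0.5)
  d2 <- maf_distribution(v)
  expected <- 1000
  sigma <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(d2$count - expected) <= 3 * sigma))

  # per-group histograms
  d3 <- maf_distribution(c(0.1, 0.4), groups = c("a", "b"))
  expect_equal(sum(d3$count[d3$group == "a"]), 1)
})

test_that("round_half_up rounds .5 away from zero at any precision", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(17.105, 2), 17.11)
  expect_equal(round_half_up(0.585, 2), 0.59)
})
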