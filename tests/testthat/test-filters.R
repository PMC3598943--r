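test_that("quality/MAF screen applies per-line, global, prior and exemption rules", {
  lines <- test_lines()
  cat5 <- test_catalog(
    pos = c(100, 200, 300, 400, 500),
    chrom = c("Chr1", "Chr16", "Chr1", "Chr1", "Chr1"),
    seg = rep(list("B1"), 5),
    qual = c(59, 20, 30, 80, 61),
    maf = c(0.2, 0.01, 0.2, 0.04, 0.05),
    in_prior_panel = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- filter_quality_maf(cat5)
  # quality 59 fails; Chr16 exempt; prior rescued; maf 0.04 fails; 61/0.05 passes
  expect_setequal(out$snp_id, c("s2", "s3", "s5"))

  # global evidence alone can rescue a record
  cat1 <- test_catalog(pos = 100, seg = list("B1"), qual = 10, maf = 0.2,
                       global_quality = 90, global_maf = 0.3)
  expect_equal(nrow(filter_quality_maf(cat1)), 1)
  # missing is not zero, and not a pass
  cat2 <- test_catalog(pos = 100, seg = list("B1"), qual = NA, maf = NA)
  expect_equal(nrow(filter_quality_maf(cat2)), 0)
})

test_that("proximity screen keeps the documented spacing patterns", {
  keep_ids <- function(pos, chrom = "Chr1") {
    filter_proximity(test_catalog(pos = pos, chrom = chrom))$pos
  }
  # gaps 4 and 14 with infinite terminal sides: all three survive
  expect_equal(keep_ids(c(100, 105, 120)), c(100, 105, 120))
  # shared gap of 2 SNP-free bases kills both
  expect_equal(keep_ids(c(100, 103)), numeric(0))
  expect_equal(keep_ids(500), 500)
  # exempt chromosomes bypass the screen entirely
  expect_equal(keep_ids(c(100, 101, 102), chrom = "Chr16"), c(100, 101, 102))

  # per-chromosome independence: a crowded Chr2 cannot affect Chr1
  both <- test_catalog(pos = c(100, 105, 120, 100, 103),
                       chrom = c(rep("Chr1", 3), rep("Chr2", 2)))
  out <- filter_proximity(both)
  expect_equal(out$pos[out$chrom == "Chr1"], c(100, 105, 120))
  expect_equal(sum(out$chrom == "Chr2"), 0)

  # iterative mode reaches a fixed point and removes at least as much
  it <- filter_proximity(both, iterative = TRUE)
  expect_lte(nrow(it), nrow(out))
})

test_that("design-score screen requires one strand to pass both thresholds", {
  cat3 <- test_catalog(pos = c(100, 200, 300),
                       fwd_16mer = c(101, 101, 100),
                       fwd_pconvert = c(0.9, 0.1, 0.2),
                       rev_16mer = c(50, 50, 2000),
                       rev_pconvert = c(0.19, 0.5, 0.01))
  out <- filter_design_scores(cat3)
  # row 1: neither strand passes both; row 2: reverse passes; row 3:
  # forward exactly at the inclusive thresholds
  expect_setequal(out$snp_id, c("s2", "s3"))
  no_scores <- test_catalog(pos = 100, fwd_16mer = NA, fwd_pconvert = NA,
                            rev_16mer = NA, rev_pconvert = NA)
  expect_message(out2 <- filter_design_scores(no_scores), "no design scores")
  expect_equal(nrow(out2), 0)
})

test_that("coverage outliers are removed per line with sample SD and strict inequality", {
  lines <- test_lines()
  cov <- c(rep(10, 19), 200)
  cat20 <- test_catalog(pos = seq(1000, 20000, by = 1000),
                        seg = rep(list("B1"), 20), cov = cov)
  out <- filter_coverage_outliers(cat20)
  expect_equal(nrow(out), 19)
  expect_false("s20" %in% out$snp_id)
  # the implied threshold: mean + 3 * sample SD
  expect_gt(200, mean(cov) + 3 * sd(cov))

  # all-equal coverage: SD is 0 and nothing strictly exceeds the mean
  flat <- test_catalog(pos = c(100, 200, 300), seg = rep(list("B1"), 3),
                       cov = 7)
  expect_equal(nrow(filter_coverage_outliers(flat)), 3)

  # strictness at the boundary, isolated with coverage_sd_k = 0:
  # a value equal to the mean stays, values above it go
  tri <- test_catalog(pos = c(100, 200, 300), seg = rep(list("B1"), 3),
                      cov = c(10, 20, 30))
  out3 <- filter_coverage_outliers(tri, filter_policy(coverage_sd_k = 0))
  expect_equal(out3$B1_cov, c(10, 20))

  # a line with a single segregating record contributes no exclusions
  one <- test_catalog(pos = c(100, 200), seg = list("B1", "B2"),
                      cov = c(1000, 10))
  w <- testthat::capture_warnings(out4 <- filter_coverage_outliers(one))
  expect_true(any(grepl("< 2 segregating", w)))
  expect_equal(nrow(out4), 2)
})

test_that("extreme HWE departures are removed strictly below the threshold", {
  cat3 <- test_catalog(pos = c(100, 200, 300))
  pv <- c(s1 = 0.000009, s2 = 0.00001)
  out <- filter_hwe_extreme(cat3, pv)
  # 9e-6 removed; exactly 1e-5 kept (strict <); no p-value kept
  expect_setequal(out$snp_id, c("s2", "s3"))
  expect_error(filter_hwe_extreme(cat3, c(s1 = 1.2)), "\\[0, 1\\]")
})

test_that("filters are idempotent, only remove records, and preserve order", {
  set.seed(11)
  lines <- test_lines()
  n <- 200
  cat_r <- test_catalog(
    pos = sort(sample(1:5000, n)),
    seg = lapply(1:n, function(i) sample(lines$name, sample(0:4, 1))),
    qual = runif(n, 0, 120), maf = runif(n, 0, 0.5),
    cov = rpois(n, 10),
    fwd_16mer = sample(0:300, n, replace = TRUE),
    fwd_pconvert = runif(n),
    rev_16mer = sample(0:300, n, replace = TRUE),
    rev_pconvert = runif(n))
  filters <- list(
    function(c) filter_quality_maf(c),
    function(c) filter_proximity(c),
    function(c) filter_design_scores(c),
    function(c) filter_coverage_outliers(c))
  for (f in filters) {
    once <- suppressMessages(suppressWarnings(f(cat_r)))
    twice <- suppressMessages(suppressWarnings(f(once)))
    expect_equal(as.data.frame(twice), as.data.frame(once))
    # survivors are untouched rows of the input, in sorted order
    expect_true(all(once$snp_id %in% cat_r$snp_id))
    expect_equal(as.data.frame(once),
                 as.data.frame(cat_r[match(once$snp_id, cat_r$snp_id), ]),
                 ignore_attr = TRUE)
    expect_equal(order(match(once$chrom, unique(once$chrom)), once$pos),
                 seq_len(nrow(once)))
  }
  led <- suppressMessages(suppressWarnings(filter_cascade(cat_r)))$ledger
  expect_true(all(led$n_out <= led$n_in))
})
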