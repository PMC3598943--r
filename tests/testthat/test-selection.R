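test_that("backbone pass is a greedy left-to-right scan with strict > t spacing", {
  lines <- test_lines(names = "B1", fill = "B1")
  cat5 <- test_catalog(pos = c(1000, 2000, 4000, 7000, 8000), lines = lines)
  st <- build_backbones(cat5, selection_config(t = 2000), test_map())
  bb <- st$panel[st$panel$provenance == "backbone_all", ]
  expect_equal(bb$pos, c(1000, 4000, 7000))
  expect_equal(st$counters$N, 3)
  # spacing invariant across the whole backbone
  expect_true(all(diff(sort(st$panel$pos)) > 0))
})

test_that("later backbone passes fill when no SNP segregates in all lines", {
  lines <- test_lines()
  # nothing segregates in the inbred lines, so N = I = 0
  cat4 <- test_catalog(pos = c(1000, 5000, 9000, 13000),
                       seg = list(c("WEL1", "WEL2", "BEL1"),
                                  c("WEL1", "WEL2", "BEL1", "B1", "B2"),
                                  c("B1", "B2"),
                                  c("WEL1", "WEL2", "BEL1", "B1", "B2")))
  st <- build_backbones(cat4, selection_config(t = 2000), test_map())
  expect_equal(st$counters$N, 0)
  expect_equal(st$counters$I, 0)
  expect_equal(st$counters$L, 3)   # layer backbone: rows 1, 2, 4
  expect_equal(st$counters$B, 1)   # row 3 still > 2 kb from 1000/5000? no: 9000-5000>2000 -> accepted
  expect_equal(st$counters$X, 4)
  # L_u: layer-backbone SNPs segregating in no broiler line
  expect_equal(st$counters$L_u, 1)
})

test_that("inbred backbone counters distinguish SNPs unique to inbred lines", {
  lines <- test_lines()
  inb <- c("I1", "I2")
  cat3 <- test_catalog(pos = c(1000, 5000, 9000),
                       seg = list(inb, c(inb, "B1"), lines$name))
  st <- build_backbones(cat3, selection_config(t = 2000), test_map())
  expect_equal(st$counters$N, 1)    # row 3 segregates everywhere
  expect_equal(st$counters$I, 2)    # rows 1 and 2
  expect_equal(st$counters$I_u, 1)  # row 1 only: no commercial line
})

test_that("coding SNPs join the final backbone regardless of spacing", {
  lines <- test_lines(names = "B1", fill = "B1")
  cat3 <- test_catalog(pos = c(1000, 1003, 9000), lines = lines,
                       coding = c(FALSE, TRUE, FALSE))
  cfg <- selection_config(t = 2000, coding_ids = "s2")
  st_pre <- build_backbones(cat3, cfg, test_map(), mode = "prescreen")
  expect_false("s2" %in% st_pre$panel$snp_id)
  st_fin <- build_backbones(cat3, cfg, test_map(), mode = "final")
  expect_true("s2" %in% st_fin$panel$snp_id)
  expect_equal(st_fin$counters$C, 1)
  expect_equal(st_fin$panel$provenance[st_fin$panel$snp_id == "s2"], "coding")
})

test_that("segments per chromosome are line-segregating panel SNPs plus one", {
  lines <- test_lines()
  # backbone SNPs at 250k/500k segregate everywhere except B2
  not_b2 <- setdiff(lines$name, "B2")
  cat5 <- test_catalog(pos = c(250000, 400000, 500000, 600000, 700000),
                       seg = list(not_b2, c("WEL1", "B1"), not_b2,
                                  c("WEL1"), c("B1")))
  map <- test_map(length_bp = 1e6, length_cm = 10)
  st <- build_backbones(cat5, selection_config(t = 2000), map)
  expect_setequal(st$panel$snp_id, c("s1", "s3"))  # inbred-backbone pass
  segs <- segments_for_line(st, "WEL1", cat5, map)
  expect_equal(nrow(segs), 3)  # 2 boundary SNPs -> 3 segments
  # candidates: rows 2 and 4 (segregating, unselected, strictly inside)
  expect_setequal(unlist(segs$candidates), which(cat5$snp_id %in% c("s2", "s4")))
  # a line with no segregating panel SNPs gets one whole-map segment
  segs_b <- segments_for_line(st, "B2", cat5, map)
  expect_equal(nrow(segs_b), 1)
  expect_equal(segs_b$right_cm - segs_b$left_cm, 10)
})

test_that("candidates exactly at a boundary cM are excluded from segments", {
  lines <- test_lines(names = c("B1", "B2"), fill = c("B1", "B2"))
  # two SNPs at the same bp cannot exist, but two different alt alleles can
  df_pos <- c(250000, 250000, 750000)
  cat3 <- test_catalog(pos = c(250000, 750000), lines = lines)
  extra <- as.data.frame(cat3)[1, ]
  extra$snp_id <- "dup"
  extra$alt <- "T"
  extra$B1_seg <- TRUE
  cat3 <- snp_catalog(rbind(as.data.frame(cat3), extra), lines)
  map <- test_map(length_bp = 1e6, length_cm = 10)
  st <- build_backbones(cat3, selection_config(t = 2000), map)
  # the duplicate-position candidate sits exactly on the boundary cM
  segs <- segments_for_line(st, "B1", cat3, map)
  expect_false(any(vapply(segs$candidates,
                          function(ix) "dup" %in% cat3$snp_id[ix],
                          logical(1))))
})

test_that("segment quotas follow the small-gap rule and rounding rule", {
  expect_equal(compute_segment_quota(0.4, 1), 0L)      # gap below 1/d
  expect_equal(compute_segment_quota(3.7, 2), 7L)      # round(7.4)
  expect_equal(compute_segment_quota(1, 1), 1L)        # exactly 1/d
  expect_equal(compute_segment_quota(0.5, 2), 1L)      # boundary again
  expect_equal(compute_segment_quota(1.25, 2, "floor"), 2L)
  expect_equal(compute_segment_quota(1.25, 2, "ceiling"), 3L)
  expect_equal(compute_segment_quota(2.5, 1), 3L)      # half rounds up
  expect_error(compute_segment_quota(1, 0), "> 0")
})

test_that("segment filling minimises the squared-gap objective", {
  x <- c(1, 2, 5, 8, 9)
  expect_equal(fill_segment(x, 0, 10, 1), 3L)  # x = 5, the midpoint
  # n = 2: {2,5} ties with {5,8} at cost 38; lexicographic tie-break
  expect_equal(fill_segment(x, 0, 10, 2), c(2L, 3L))
  expect_equal(fill_segment(x, 0, 10, 5), 1:5)  # saturation
  expect_equal(fill_segment(x, 0, 10, 0), integer(0))
  expect_equal(fill_segment(numeric(0), 0, 10, 3), integer(0))
})

test_that("DP filling equals exhaustive enumeration on random instances", {
  for (seed in 1:60) {
    set.seed(seed)
    m <- sample(1:12, 1)
    n <- sample(1:5, 1)
    x <- sort(runif(m, 0, 10))
    got <- fill_segment(x, 0, 10, n)
    want <- fill_segment_oracle(x, 0, 10, n)
    expect_equal(got, as.integer(want), info = paste("seed", seed))
  }
})

test_that("panel selection is deterministic and respects the line order", {
  lines <- test_lines()
  set.seed(5)
  n <- 400
  cat_r <- test_catalog(
    pos = sort(sample(1:1000000, n)),
    seg = lapply(1:n, function(i) {
      sample(lines$name, sample(2:6, 1))
    }))
  map <- test_map(length_bp = 1e6, length_cm = 20)
  cfg <- selection_config(t = 2000, densities = setNames(
    rep(1, 5), c("WEL1", "WEL2", "BEL1", "B1", "B2")))
  p1 <- select_panel(cat_r, cfg, map)
  p2 <- select_panel(cat_r, cfg, map)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  rep1 <- selection_report(p1)
  expect_equal(rep1$line, c("WEL1", "WEL2", "BEL1", "B1", "B2"))
  expect_true(all(diff(rep1$X_after) >= 0))
  expect_equal(rep1$X_after[5], nrow(p1))
  # F_i counts panel SNPs not segregating in the line at processing time
  seg1 <- !is.na(cat_r$WEL1_seg) & cat_r$WEL1_seg
  bb <- attr(p1, "state")$counters$X
  expect_equal(rep1$F_i[1],
               sum(!seg1[match(p1$snp_id, cat_r$snp_id)][
                 p1$provenance %in% c("backbone_all", "backbone_inbred",
                                      "backbone_layer", "backbone_broiler")]))
})

test_that("an empty line order leaves the backbones as the panel", {
  lines <- test_lines()
  cat3 <- test_catalog(pos = c(1000, 50000, 99000))
  cfg <- selection_config(t = 2000, line_order = character(),
                          densities = numeric())
  p <- select_panel(cat3, cfg, test_map())
  expect_setequal(p$provenance, "backbone_all")
  expect_equal(nrow(selection_report(p)), 0)
})

test_that("an already-covered identical line receives far fewer new SNPs", {
  lines <- test_lines(names = c("WEL1", "WEL2"), fill = c("WEL1", "WEL2"))
  set.seed(9)
  pos <- sort(sample(1:1000000, 300))
  cat_r <- test_catalog(pos = pos, lines = lines)  # both lines everywhere
  map <- test_map(length_bp = 1e6, length_cm = 30)
  cfg <- selection_config(t = 1e9,  # suppress backbones: force pure filling
                          densities = c(WEL1 = 2, WEL2 = 2))
  p <- select_panel(cat_r, cfg, map)
  rep1 <- selection_report(p)
  # the first line's placements mostly satisfy the second's density:
  # only segments left at or slightly above the target spacing refill
  expect_gt(rep1$S_i[1], 20)
  expect_lte(rep1$S_i[2], 0.5 * rep1$S_i[1])
})

test_that("budget calibration hits the band, doubles sensibly and saturates", {
  lines <- test_lines()
  set.seed(21)
  n <- 1200
  cat_r <- test_catalog(
    pos = sort(sample(1:2000000, n)),
    seg = lapply(1:n, function(i) sample(lines$name, sample(2:7, 1))))
  map <- test_map(length_bp = 2e6, length_cm = 40)
  base <- selection_config(budget = 400, t = 5000,
                           group_ratio = c(broiler = 1, WEL = 1, BEL = 1))
  p <- select_panel(cat_r, base, map)
  expect_gte(nrow(p), 400 * 0.98)
  expect_lte(nrow(p), 400 * 1.02)

  # doubling the budget in the unsaturated regime roughly doubles the panel
  dbl <- base
  dbl$budget <- 800
  p2 <- select_panel(cat_r, dbl, map)
  expect_gt(nrow(p2), nrow(p) * 1.7)
  expect_lt(nrow(p2), nrow(p) * 2.3)

  # budget beyond the candidate pool: saturate with a warning
  sat <- base
  sat$budget <- 5000
  w <- testthat::capture_warnings(p3 <- select_panel(cat_r, sat, map))
  expect_true(any(grepl("saturat|exceeds", w)))
  expect_gt(nrow(p3), 0.9 * n)
})

test_that("group ratio steers placed counts on a symmetric catalog", {
  lines <- test_lines(names = c("B1", "WEL1"), fill = c("WEL1", "B1"))
  set.seed(33)
  pos <- sort(sample(1:2000000, 2000))
  cat_r <- test_catalog(pos = pos, lines = lines)  # fully symmetric lines
  map <- test_map(length_bp = 2e6, length_cm = 50)
  cfg <- selection_config(budget = 500, t = 1e9,
                          group_ratio = c(broiler = 3, WEL = 2))
  p <- select_panel(cat_r, cfg, map)
  rep1 <- selection_report(p)
  placed <- setNames(rep1$S_i, rep1$line)
  # WEL fills first; broiler density is 1.5x, so placed counts approach 3:2
  expect_gt(placed[["B1"]] / placed[["WEL1"]], 1.2)
  expect_lt(placed[["B1"]] / placed[["WEL1"]], 1.9)
})
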