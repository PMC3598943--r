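#' Simulation configuration
#'
#' Parameters of the synthetic multi-line catalog generator. The
#' defaults emulate the study conditions behind the chicken 600K design
#' at desk scale: a 24-line panel (4 broiler, 6 WEL, 5 BEL, 8 inbred,
#' 1 experimental layer line) with pooled evidence from 10 diploid
#' samples per line, Balding-Nichols drift between groups (F = 0.1, the
#' level that reproduces tight per-line PCA clusters) and within groups
#' (F = 0.05), near-fixed inbred lines (F = 0.9, mirroring their ~1 M
#' versus ~10 M segregating counts), and a scaled-down genome mixing
#' macro- and micro-chromosomes with contrasting cM/Mb rates.
#'
#' @param seed Integer seed; all generator functions are deterministic
#'   given the seed.
#' @param lines A [line_info()] registry.
#' @param chromosomes Tibble `name`, `length_bp`, `cm_per_mb`.
#' @param n_snps Total candidate SNPs to draw.
#' @param f_group,f_line,f_inbred Balding-Nichols drift coefficients
#'   (ancestral to group, group to commercial line, group to inbred
#'   line).
#' @param pool_size Diploid individuals per sequencing pool; a line
#'   segregates when both alleles appear among its 2 * pool_size allele
#'   draws.
#' @param quality_mean,quality_sd Distribution of the per-SNP base
#'   quality score, shared across lines up to line-level noise and
#'   truncated at 0 (so a genuinely poor site fails in every line, as
#'   real mapping artefacts do).
#' @param global_rate Probability that the combined all-lines analysis
#'   contributes evidence for a SNP (the global pass is consulted where
#'   per-line coverage is thin, not everywhere).
#' @param coverage_mean Mean per-line read coverage (Poisson).
#' @param design_pass_rate Per-strand probability that a probe draws
#'   passing design scores; the default makes roughly two thirds of
#'   SNPs designable on at least one strand.
#' @param prior_panel_rate,coding_rate,annotated_rate Bernoulli rates
#'   for prior-panel membership, coding status and annotatability.
#' @param genotype_error_rate,missing_rate Validation-genotype error
#'   and missingness rates.
#' @param mendel_error_rate Trio injection rate for incompatible
#'   offspring genotypes.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lines = default_sim_lines(),
                       chromosomes = default_sim_chromosomes(),
                       n_snps = 20000L,
                       f_group = 0.1, f_line = 0.05, f_inbred = 0.9,
                       pool_size = 10L,
                       quality_mean = 75, quality_sd = 30,
                       global_rate = 0.3,
                       coverage_mean = 12,
                       design_pass_rate = 0.417,
                       prior_panel_rate = 0.01, coding_rate = 0.02,
                       annotated_rate = 0.85,
                       genotype_error_rate = 0.001, missing_rate = 0.005,
                       mendel_error_rate = 0) {
  rates <- c(f_group, f_line, f_inbred, design_pass_rate, prior_panel_rate,
             coding_rate, annotated_rate, genotype_error_rate, missing_rate,
             mendel_error_rate)
  if (any(rates < 0 | rates > 1)) pf_abort("rates must lie in [0, 1]")
  if (any(chromosomes$length_bp <= 0)) pf_abort("chromosome lengths must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_lines <- function() {
  nm <- c(paste0("B", 1:4), paste0("WEL", 1:6), paste0("BEL", 1:5),
          "RIJ", paste0("I", 1:8))
  grp <- c(rep("broiler", 4), rep("WEL", 6), rep("BEL", 5), "experimental",
           rep("inbred", 8))
  fill <- grp %in% c("broiler", "WEL", "BEL")
  # filling order follows decreasing LD: white layers, brown layers,
  # then broilers
  rank <- rep(NA_integer_, length(nm))
  ordered <- c(grep("^WEL", nm), grep("^BEL", nm), grep("^B[0-9]", nm))
  rank[ordered] <- seq_along(ordered)
  line_info(nm, grp, selection_rank = rank,
            target_density = ifelse(fill, 1, NA))
}

#' @rdname sim_config
#' @export
default_sim_chromosomes <- function() {
  tibble(name = c("Chr1", "Chr2", "Chr5", "Chr20", "Chr25"),
         length_bp = c(4e7, 3e7, 2e7, 8e6, 2e6),
         cm_per_mb = c(2.5, 3, 4, 7, 12))
}

#' Simulate a genetic map
#'
#' Piecewise-linear map per chromosome: anchors evenly spaced in bp from
#' 1 to the chromosome length, with per-interval cM/Mb rates jittered
#' multiplicatively around the chromosome's nominal rate to create
#' local recombination-rate variation.
#'
#' @param config A [sim_config()].
#' @param n_anchors Anchors per chromosome (>= 2).
#' @param rate_jitter_sd SD of the log-normal rate jitter (0 for exactly
#'   linear maps).
#' @return A [genetic_map()].
#' @export
simulate_map <- function(config, n_anchors = 6, rate_jitter_sd = 0.3) {
  set.seed(config$seed + 1009L)
  out <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
    chr <- config$chromosomes[i, ]
    bp <- round(seq(1, chr$length_bp, length.out = n_anchors))
    seg_mb <- diff(bp) / 1e6
    rates <- chr$cm_per_mb * exp(rnorm(n_anchors - 1, 0, rate_jitter_sd))
    tibble(chrom = chr$name, pos_bp = bp, pos_cM = c(0, cumsum(seg_mb * rates)))
  })
  genetic_map(list_rbind(out))
}

bn_freq <- function(p, f) {
  if (f <= 0) return(p)
  if (f >= 1) return(ifelse(runif(length(p)) < p, 1, 0))
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a multi-line SNP catalog
#'
#' Candidate positions are uniform per chromosome (sorted,
#' deduplicated, allocated proportionally to length); each SNP gets an
#' ancestral frequency ~ U(0.05, 0.95), group frequencies by
#' Balding-Nichols drift from the ancestral, and line frequencies by
#' further drift from the group (inbred lines use the high inbred
#' coefficient and end up mostly fixed). A line segregates when both
#' alleles appear in a simulated pool of 2 * pool_size allele draws;
#' per-line MAF is the folded line frequency. Quality, coverage and
#' design scores are drawn per the configuration. The latent
#' frequencies are returned as the truth record.
#'
#' @param config A [sim_config()].
#' @return A list: `catalog` (a [snp_catalog()]), `truth` (list with
#'   `ancestral`, `group_freq`, `line_freq` matrices).
#' @export
simulate_catalog <- function(config) {
  set.seed(config$seed)
  lines <- config$lines
  chroms <- config$chromosomes
  n_per <- round(config$n_snps * chroms$length_bp / sum(chroms$length_bp))
  pos_list <- lapply(seq_len(nrow(chroms)), function(i) {
    sort(unique(ceiling(runif(n_per[i], 0, chroms$length_bp[i]))))
  })
  chrom <- rep(chroms$name, lengths(pos_list))
  pos <- unlist(pos_list)
  n <- length(pos)
  if (!n) {
    return(list(catalog = snp_catalog(empty_catalog_frame(lines), lines),
                truth = list(ancestral = numeric(0),
                             group_freq = matrix(0, 0, 0),
                             line_freq = matrix(0, 0, 0))))
  }
  anc <- runif(n, 0.05, 0.95)
  groups <- unique(lines$group)
  group_freq <- matrix(vapply(groups, function(g) bn_freq(anc, config$f_group),
                              numeric(n)),
                       nrow = n, dimnames = list(NULL, groups))
  line_freq <- matrix(vapply(seq_len(nrow(lines)), function(i) {
    f <- if (lines$group[i] == "inbred") config$f_inbred else config$f_line
    bn_freq(group_freq[, lines$group[i]], f)
  }, numeric(n)), nrow = n, dimnames = list(NULL, lines$name))

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))

  base_q <- rnorm(n, config$quality_mean, config$quality_sd)
  has_global <- runif(n) < config$global_rate
  cat_df <- tibble(
    snp_id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
    ref = unname(ref), alt = unname(alt),
    global_quality = ifelse(has_global, pmax(0, base_q + rnorm(n, 0, 10)), NA),
    global_maf = ifelse(has_global, pmin(anc, 1 - anc), NA),
    in_prior_panel = runif(n) < config$prior_panel_rate,
    coding = runif(n) < config$coding_rate,
    annotation = ifelse(runif(n) < config$annotated_rate,
                        sample(annotation_categories, n, replace = TRUE,
                               prob = c(54, 38, 1.9, 2.5, 0.02, 1.2, 1.3,
                                        0.5, 0.06, 0.02, 0.01)),
                        NA_character_)
  )
  draw_design <- function() {
    pass <- runif(n) < config$design_pass_rate
    k16 <- ifelse(pass, sample(0:100, n, replace = TRUE),
                  ifelse(runif(n) < 0.5, sample(101:2000, n, replace = TRUE),
                         sample(0:100, n, replace = TRUE)))
    pc <- ifelse(pass, runif(n, 0.2, 1),
                 ifelse(k16 > 100, runif(n), runif(n, 0, 0.2)))
    list(k16 = k16, pc = pc)
  }
  fwd <- draw_design()
  rev <- draw_design()
  cat_df$fwd_16mer <- fwd$k16
  cat_df$fwd_pconvert <- fwd$pc
  cat_df$rev_16mer <- rev$k16
  cat_df$rev_pconvert <- rev$pc
  cat_df$coding[is.na(cat_df$annotation)] <- FALSE
  cat_df$coding <- cat_df$coding |
    cat_df$annotation %in% c("non-synonymous", "synonymous",
                             "stopgain_stoploss")

  for (i in seq_len(nrow(lines))) {
    ln <- lines$name[i]
    f <- line_freq[, i]
    nalt <- rbinom(n, 2L * config$pool_size, f)
    seg <- nalt > 0L & nalt < 2L * config$pool_size
    cat_df[[paste0(ln, "_seg")]] <- seg
    cat_df[[paste0(ln, "_maf")]] <- ifelse(seg, pmin(f, 1 - f), NA)
    cat_df[[paste0(ln, "_qual")]] <- ifelse(seg, pmax(0, base_q +
                                                        rnorm(n, 0, 10)), NA)
    cat_df[[paste0(ln, "_cov")]] <- ifelse(seg, rpois(n, config$coverage_mean),
                                           NA)
  }
  list(catalog = snp_catalog(cat_df, lines),
       truth = list(snp_id = cat_df$snp_id, chrom = chrom, pos = pos,
                    ancestral = anc, group_freq = group_freq,
                    line_freq = line_freq))
}

empty_catalog_frame <- function(lines) {
  base <- tibble(snp_id = character(), chrom = character(), pos = numeric(),
                 ref = character(), alt = character(),
                 global_quality = numeric(), global_maf = numeric(),
                 in_prior_panel = logical(), coding = logical(),
                 annotation = character(), fwd_16mer = numeric(),
                 fwd_pconvert = numeric(), rev_16mer = numeric(),
                 rev_pconvert = numeric())
  for (ln in lines$name) {
    base[[paste0(ln, "_seg")]] <- logical()
    base[[paste0(ln, "_maf")]] <- numeric()
    base[[paste0(ln, "_qual")]] <- numeric()
    base[[paste0(ln, "_cov")]] <- numeric()
  }
  base
}

#' Simulate validation genotypes
#'
#' Draws Hardy-Weinberg genotypes at each line's latent allele
#' frequency, then applies genotyping error (a call is replaced by one
#' of the other two states) and missingness at the configured rates.
#'
#' @param truth Truth record from [simulate_catalog()].
#' @param line_samples Named integer vector, line -> number of samples.
#' @param config A [sim_config()].
#' @param snp_ids Optional subset of SNPs (default: all).
#' @param seed_offset Offset added to the config seed (so genotype and
#'   trio draws are independent streams).
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(truth, line_samples, config,
                               snp_ids = NULL, seed_offset = 2003L) {
  set.seed(config$seed + seed_offset)
  idx <- if (is.null(snp_ids)) seq_along(truth$snp_id) else
    match(snp_ids, truth$snp_id)
  if (anyNA(idx)) pf_abort("unknown snp_id(s) in truth record")
  snps <- tibble(snp_id = truth$snp_id[idx], chrom = truth$chrom[idx],
                 pos = truth$pos[idx])
  rows <- list()
  ids <- character(0)
  labs <- character(0)
  for (ln in names(line_samples)) {
    if (!ln %in% colnames(truth$line_freq)) {
      pf_abort(paste0("line not in truth record: ", ln))
    }
    f <- truth$line_freq[idx, ln]
    ns <- line_samples[[ln]]
    g <- matrix(rbinom(ns * length(idx), 2L, rep(f, each = ns)),
                nrow = ns)
    rows[[ln]] <- g
    ids <- c(ids, paste0(ln, "_s", seq_len(ns)))
    labs <- c(labs, rep(ln, ns))
  }
  calls <- do.call(rbind, rows)
  e <- config$genotype_error_rate
  if (e > 0) {
    flip <- which(runif(length(calls)) < e)
    calls[flip] <- (calls[flip] + sample(1:2, length(flip), replace = TRUE)) %% 3L
  }
  if (config$missing_rate > 0) {
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
  }
  geno_matrix(calls, tibble(sample = ids, line = labs), snps)
}

#' Simulate trios with optional Mendelian-error injection
#'
#' Parents are drawn under Hardy-Weinberg at the line's latent
#' frequency; each offspring receives one allele from each parent. At
#' the configured injection rate an offspring call is replaced by a
#' genotype incompatible with its parents, and the replacement is
#' recorded in a ledger (trios where every genotype is compatible with
#' the parents — both parents heterozygous — cannot be injected and are
#' skipped).
#'
#' @inheritParams simulate_genotypes
#' @param line Line name.
#' @param n_trios Number of sire/dam/offspring triples.
#' @return A list: `geno` (a [geno_matrix()] of 3 * n_trios samples),
#'   `trios` (tibble `sire`, `dam`, `offspring`), `ledger` (tibble
#'   `snp_id`, `trio`, `original`, `injected`).
#' @export
simulate_trios <- function(truth, line, n_trios, config,
                           snp_ids = NULL, seed_offset = 3001L) {
  if (n_trios < 1) pf_abort("n_trios must be >= 1")
  set.seed(config$seed + seed_offset)
  idx <- if (is.null(snp_ids)) seq_along(truth$snp_id) else
    match(snp_ids, truth$snp_id)
  snps <- tibble(snp_id = truth$snp_id[idx], chrom = truth$chrom[idx],
                 pos = truth$pos[idx])
  f <- truth$line_freq[idx, line]
  m <- length(idx)
  sire <- matrix(rbinom(n_trios * m, 2L, rep(f, each = n_trios)), n_trios)
  dam <- matrix(rbinom(n_trios * m, 2L, rep(f, each = n_trios)), n_trios)
  transmit <- function(g) rbinom(length(g), 1L, g / 2)
  off <- matrix(transmit(sire) + transmit(dam), n_trios)
  ledger <- list()
  if (config$mendel_error_rate > 0) {
    hit <- which(matrix(runif(n_trios * m), n_trios) <
                   config$mendel_error_rate, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      ti <- hit[r, 1]
      sj <- hit[r, 2]
      compat <- compatible_offspring(sire[ti, sj], dam[ti, sj])
      incompat <- setdiff(0:2, compat)
      if (!length(incompat)) next
      orig <- off[ti, sj]
      inj <- if (length(incompat) == 1) incompat else sample(incompat, 1)
      off[ti, sj] <- inj
      ledger[[length(ledger) + 1L]] <-
        tibble(snp_id = snps$snp_id[sj], trio = ti, original = orig,
               injected = inj)
    }
  }
  ledger <- if (length(ledger)) list_rbind(ledger) else
    tibble(snp_id = character(), trio = integer(), original = integer(),
           injected = integer())
  ids <- c(paste0(line, "_sire", seq_len(n_trios)),
           paste0(line, "_dam", seq_len(n_trios)),
           paste0(line, "_off", seq_len(n_trios)))
  calls <- rbind(sire, dam, off)
  geno <- geno_matrix(calls,
                      tibble(sample = ids, line = line),
                      snps)
  trios <- tibble(sire = ids[seq_len(n_trios)],
                  dam = ids[n_trios + seq_len(n_trios)],
                  offspring = ids[2L * n_trios + seq_len(n_trios)])
  list(geno = geno, trios = trios, ledger = ledger)
}

# offspring dosages consistent with two parent dosages
compatible_offspring <- function(f, m) {
  fa <- if (f == 0) 0 else if (f == 2) 1 else c(0, 1)
  ma <- if (m == 0) 0 else if (m == 2) 1 else c(0, 1)
  sort(unique(as.vector(outer(fa, ma, `+`))))
}
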