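# in-code fixtures: small line registries, catalogs, maps and genotype
# matrices built deterministically for the unit tests

test_lines <- function(names = c("B1", "B2", "WEL1", "WEL2", "BEL1",
                                 "I1", "I2"),
                       fill = c("WEL1", "WEL2", "BEL1", "B1", "B2"),
                       density = 1) {
  grp <- dplyr::case_when(
    grepl("^WEL", names) ~ "WEL",
    grepl("^BEL", names) ~ "BEL",
    grepl("^I", names) ~ "inbred",
    grepl("^B[0-9]", names) ~ "broiler",
    TRUE ~ "experimental")
  rank <- match(names, fill)
  line_info(names, grp, selection_rank = rank,
            target_density = ifelse(is.na(rank), NA, density))
}

# wide catalog frame with sensible defaults; seg is a character vector
# (same lines segregate everywhere) or a list of character vectors per row
test_catalog <- function(pos, chrom = "Chr1", lines = test_lines(),
                         seg = lines$name, maf = 0.25, qual = 100,
                         cov = 10, ...) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  df <- tibble::tibble(
    snp_id = paste0("s", seq_len(n)), chrom = chrom, pos = pos,
    ref = rep("A", n), alt = rep("G", n),
    global_quality = rep(NA_real_, n), global_maf = rep(NA_real_, n),
    in_prior_panel = rep(FALSE, n), coding = rep(FALSE, n),
    annotation = rep(NA_character_, n),
    fwd_16mer = rep(10, n), fwd_pconvert = rep(0.9, n),
    rev_16mer = rep(10, n), rev_pconvert = rep(0.9, n))
  if (!is.list(seg)) seg <- rep(list(seg), n)
  maf <- rep_len(maf, n)
  qual <- rep_len(qual, n)
  cov <- rep_len(cov, n)
  for (ln in lines$name) {
    s <- vapply(seg, function(v) ln %in% v, logical(1))
    df[[paste0(ln, "_seg")]] <- s
    df[[paste0(ln, "_maf")]] <- as.numeric(ifelse(s, maf, NA))
    df[[paste0(ln, "_qual")]] <- as.numeric(ifelse(s, qual, NA))
    df[[paste0(ln, "_cov")]] <- as.numeric(ifelse(s, cov, NA))
  }
  overrides <- list(...)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  snp_catalog(df, lines)
}

# linear one- or multi-chromosome map
test_map <- function(chrom = "Chr1", length_bp = 1e6, length_cm = 3) {
  length_bp <- rep_len(length_bp, length(chrom))
  length_cm <- rep_len(length_cm, length(chrom))
  anchors <- lapply(seq_along(chrom), function(i) {
    tibble::tibble(chrom = chrom[i], pos_bp = c(1, length_bp[i]),
                   pos_cM = c(0, length_cm[i]))
  })
  genetic_map(dplyr::bind_rows(anchors))
}

# genotype matrix from per-sample dosage vectors (one column per SNP)
test_geno <- function(..., line = "L1", chrom = "Chr1") {
  cols <- list(...)
  calls <- do.call(cbind, cols)
  n_snp <- ncol(calls)
  geno_matrix(
    calls,
    tibble::tibble(sample = paste0("s", seq_len(nrow(calls))),
                   line = rep_len(line, nrow(calls))),
    tibble::tibble(snp_id = names(cols) %||% paste0("snp", seq_len(n_snp)),
                   chrom = rep_len(chrom, n_snp), pos = seq_len(n_snp) * 100))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# exhaustive subset search for the segment-filling objective, with the
# same lexicographic tie-break
fill_segment_oracle <- function(x, a, b, n) {
  m <- length(x)
  if (n <= 0 || m == 0) return(integer(0))
  if (n >= m) return(seq_len(m))
  combos <- utils::combn(m, n)
  costs <- apply(combos, 2, function(idx) {
    pts <- c(a, x[idx], b)
    sum(diff(pts)^2)
  })
  best <- which(costs <= min(costs) + 1e-12)
  # lexicographically smallest position tuple among optima
  key <- apply(combos[, best, drop = FALSE], 2, paste, collapse = ",")
  ord <- do.call(order, as.data.frame(t(combos[, best, drop = FALSE])))
  combos[, best[ord[1]]]
}

# exact HWE p-value by enumerating equally likely allele-slot
# configurations: the minor alleles occupy C(2n, n_minor) slot subsets,
# consecutive slots pair into genotypes
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  slots <- 2 * n
  if (minor == 0) return(1)
  cfgs <- utils::combn(slots, minor)
  het_of <- apply(cfgs, 2, function(idx) {
    v <- integer(slots)
    v[idx] <- 1L
    g <- v[seq(1, slots, 2)] + v[seq(2, slots, 2)]
    sum(g == 1L)
  })
  tab <- table(het_of) / ncol(cfgs)
  obs <- tab[as.character(n_ab)]
  sum(tab[tab <= obs + 1e-12])
}

# dictionary k-mer counter + interval masker, written independently of
# the implementation's vectorised substring scan
kmer_mask_oracle <- function(seqs, k, max_occ) {
  counts <- new.env()
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) < k) next
    for (i in 1:(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("N", km, fixed = TRUE)) next
      counts[[km]] <- (counts[[km]] %||% 0) + 1
    }
  }
  lapply(seqs, function(s) {
    su <- toupper(s)
    mask <- logical(nchar(su))
    if (nchar(su) >= k) {
      for (i in 1:(nchar(su) - k + 1)) {
        km <- substr(su, i, i + k - 1)
        if (grepl("N", km, fixed = TRUE)) next
        if ((counts[[km]] %||% 0) > max_occ) mask[i:(i + k - 1)] <- TRUE
      }
    }
    mask
  })
}

# gap CV of a set of positions (cM) within chromosomes, including the
# distances to the map ends
gap_cv <- function(cm, chrom, map) {
  gaps <- numeric(0)
  for (ch in unique(map$chrom)) {
    a <- map[map$chrom == ch, ]
    x <- sort(cm[chrom == ch])
    gaps <- c(gaps, diff(c(a$pos_cM[1], x, a$pos_cM[nrow(a)])))
  }
  stats::sd(gaps) / mean(gaps)
}
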