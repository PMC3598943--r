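#' Selection configuration
#'
#' Parameters of the backbone-plus-gap-filling panel selection. `t` is
#' the minimum spacing between backbone SNPs in bases; the default 2 kb
#' corresponds to the expected density of a 600K panel on a ~1 Gb genome.
#' `group_ratio` weights per-line target densities by line group (e.g.
#' broiler 3, layer 2 for the final panel; 1:1 for a pre-screening
#' panel). `line_order` fixes the order of per-line filling — white egg
#' layers first, then brown, then broilers, following the decreasing
#' extent of linkage disequilibrium, so that the lines needing the most
#' markers fill last against an already-dense backbone.
#'
#' @param budget Target total panel size (used by [calibrate_densities()]).
#' @param t Minimum backbone spacing in bases (strict `> t` rule).
#' @param group_ratio Named numeric weights per line group.
#' @param line_order Character vector of lines to fill, in order; if
#'   `NULL`, derived from the registry's `selection_rank`.
#' @param densities Named numeric, SNPs/cM per filled line; if `NULL`,
#'   calibrated against `budget`.
#' @param coding_ids SNP ids force-included in final-panel mode
#'   (validated coding variants; added without any spacing constraint).
#' @param quota_rule Rounding rule mapping segment length x density to a
#'   SNP count: `"half_up"` (default), `"floor"` or `"ceiling"`.
#' @param budget_tolerance Acceptable relative deviation from `budget`
#'   during calibration.
#' @return A list with class `selection_config`.
#' @export
selection_config <- function(budget = NULL, t = 2000,
                             group_ratio = c(broiler = 1, WEL = 1, BEL = 1),
                             line_order = NULL, densities = NULL,
                             coding_ids = character(),
                             quota_rule = c("half_up", "floor", "ceiling"),
                             budget_tolerance = 0.02) {
  if (t < 0) pf_abort("t must be >= 0")
  if (!is.null(budget) && budget <= 0) pf_abort("budget must be > 0")
  if (any(group_ratio <= 0)) pf_abort("group_ratio weights must be > 0")
  structure(list(budget = budget, t = t, group_ratio = group_ratio,
                 line_order = line_order, densities = densities,
                 coding_ids = coding_ids,
                 quota_rule = match.arg(quota_rule),
                 budget_tolerance = budget_tolerance),
            class = "selection_config")
}

# greedy left-to-right scan: accept candidates > t bases from every
# already-accepted position (existing must be sorted)
greedy_accept <- function(cand_pos, existing, t) {
  accept <- logical(length(cand_pos))
  ne <- length(existing)
  iL <- if (ne) findInterval(cand_pos, existing) else rep(0L, length(cand_pos))
  last <- -Inf
  for (i in seq_along(cand_pos)) {
    p <- cand_pos[i]
    left <- if (iL[i] >= 1L) max(existing[iL[i]], last) else last
    right <- if (iL[i] < ne) existing[iL[i] + 1L] else Inf
    if (p - left > t && right - p > t) {
      accept[i] <- TRUE
      last <- p
    }
  }
  accept
}

#' Build the backbone panels
#'
#' Four greedy passes seed the panel with SNPs shared across groups of
#' lines, partitioning every chromosome into short segments for the
#' per-line filling step: (1) SNPs segregating in all lines, (2) in all
#' inbred lines, (3) in all layer lines (WEL and BEL), (4) in all
#' broiler lines. Each pass scans positions left to right and accepts a
#' candidate iff it lies more than `t` bases from every already-accepted
#' SNP on that chromosome. In final-panel mode, validated coding SNPs
#' not already present are then added with no spacing constraint.
#'
#' Counters follow the design bookkeeping: `N`, `I`, `L`, `B` are the
#' per-pass acceptance counts, `I_u` the accepted inbred-backbone SNPs
#' segregating in no commercial line, `L_u` the accepted layer-backbone
#' SNPs segregating in no broiler line, `C` the coding additions, and
#' `X` the backbone total.
#'
#' @param catalog A filtered, sorted [snp_catalog()].
#' @param config A [selection_config()].
#' @param map A [genetic_map()] covering all catalog chromosomes.
#' @param mode `"prescreen"` or `"final"`; coding force-inclusion applies
#'   only in final mode.
#' @return A `selection_state` list: `panel` (tibble snp_id, chrom, pos,
#'   provenance), `counters`, `selected` (logical over catalog rows).
#' @export
build_backbones <- function(catalog, config, map,
                            mode = c("prescreen", "final")) {
  mode <- match.arg(mode)
  lines <- catalog_lines(catalog)
  if (!nrow(catalog)) {
    warn("empty catalog; backbone state is empty")
    return(list(panel = tibble(snp_id = character(), chrom = character(),
                               pos = numeric(), provenance = character()),
                counters = list(N = 0L, I = 0L, I_u = 0L, L = 0L, L_u = 0L,
                                B = 0L, C = 0L, X = 0L),
                selected = logical(0)))
  }
  missing_chr <- setdiff(unique(catalog$chrom), unique(map$chrom))
  if (length(missing_chr)) {
    pf_abort(paste0("genetic map lacks chromosome(s): ",
                    paste(missing_chr, collapse = ", ")))
  }
  seg <- segregation_matrix(catalog)
  grp <- function(g) lines$name[lines$group %in% g]
  seg_all_of <- function(members) {
    if (!length(members)) return(rep(FALSE, nrow(catalog)))
    rowSums(seg[, members, drop = FALSE]) == length(members)
  }
  passes <- list(
    backbone_all = seg_all_of(lines$name),
    backbone_inbred = seg_all_of(grp("inbred")),
    backbone_layer = seg_all_of(grp(c("WEL", "BEL"))),
    backbone_broiler = seg_all_of(grp("broiler"))
  )
  n <- nrow(catalog)
  selected <- logical(n)
  provenance <- character(n)
  counts <- integer(4)
  names(counts) <- names(passes)
  chroms <- catalog$chrom
  for (pi in seq_along(passes)) {
    eligible <- passes[[pi]] & !selected
    for (chr in unique(chroms[eligible])) {
      idx <- which(eligible & chroms == chr)
      existing <- sort(catalog$pos[selected & chroms == chr])
      acc <- greedy_accept(catalog$pos[idx], existing, config$t)
      sel_idx <- idx[acc]
      selected[sel_idx] <- TRUE
      provenance[sel_idx] <- names(passes)[pi]
      counts[pi] <- counts[pi] + length(sel_idx)
    }
  }
  commercial <- lines$name[lines$commercial]
  broilers <- grp("broiler")
  inbred_acc <- provenance == "backbone_inbred"
  I_u <- sum(inbred_acc & rowSums(seg[, commercial, drop = FALSE]) == 0)
  layer_acc <- provenance == "backbone_layer"
  L_u <- if (length(broilers)) {
    sum(layer_acc & rowSums(seg[, broilers, drop = FALSE]) == 0)
  } else sum(layer_acc)
  C <- 0L
  if (mode == "final" && length(config$coding_ids)) {
    add <- !selected & catalog$snp_id %in% config$coding_ids
    selected[add] <- TRUE
    provenance[add] <- "coding"
    C <- sum(add)
  }
  counters <- list(N = unname(counts[1]), I = unname(counts[2]),
                   I_u = as.integer(I_u), L = unname(counts[3]),
                   L_u = as.integer(L_u), B = unname(counts[4]), C = C,
                   X = sum(selected))
  panel <- tibble(snp_id = catalog$snp_id[selected],
                  chrom = catalog$chrom[selected],
                  pos = catalog$pos[selected],
                  provenance = provenance[selected])
  list(panel = panel, counters = counters, selected = selected)
}

#' Segments for a line
#'
#' Partitions each chromosome into the intervals between panel SNPs
#' segregating in the given line (converted to cM), bounded by the
#' chromosome's map ends; with k such SNPs on a chromosome there are
#' k + 1 segments. Candidates are the line-segregating, not-yet-selected
#' catalog SNPs strictly inside a segment (a candidate exactly at a
#' boundary position belongs to no segment).
#'
#' @param state A `selection_state` from [build_backbones()].
#' @param line Line name.
#' @inheritParams build_backbones
#' @return A tibble of segments: `chrom`, `left_cm`, `right_cm`,
#'   `candidates` (list column of catalog row indices), `candidate_cm`
#'   (list column).
#' @export
segments_for_line <- function(state, line, catalog, map) {
  seg_col <- catalog[[paste0(line, "_seg")]]
  seg_col <- !is.na(seg_col) & seg_col
  cm <- record_cm(catalog, map)
  out <- list()
  for (chr in unique(map$chrom)) {
    a <- map_chrom(map, chr)
    start_cm <- a$pos_cM[1]
    end_cm <- a$pos_cM[nrow(a)]
    on_chr <- catalog$chrom == chr
    bnd <- sort(cm[on_chr & state$selected & seg_col])
    bounds <- c(start_cm, bnd, end_cm)
    cand <- which(on_chr & seg_col & !state$selected)
    cand <- cand[order(cm[cand], catalog$snp_id[cand])]
    ccm <- cm[cand]
    k <- length(bounds) - 1L
    iv <- findInterval(ccm, bounds)
    inside <- iv >= 1L & iv <= k & ccm > bounds[pmax(iv, 1L)] &
      ccm < bounds[pmin(iv + 1L, k + 1L)]
    out[[chr]] <- tibble(
      chrom = chr,
      left_cm = bounds[seq_len(k)],
      right_cm = bounds[seq_len(k) + 1L],
      candidates = lapply(seq_len(k), function(s) cand[inside & iv == s]),
      candidate_cm = lapply(seq_len(k), function(s) ccm[inside & iv == s])
    )
  }
  list_rbind(out)
}

# cM of every catalog record (cached computation)
record_cm <- function(catalog, map) {
  cm <- numeric(nrow(catalog))
  for (chr in unique(catalog$chrom)) {
    idx <- catalog$chrom == chr
    cm[idx] <- interpolate_cm(map, chr, catalog$pos[idx])
  }
  cm
}

#' Segment quota
#'
#' Number of SNPs to place in a segment: 0 when the segment is shorter
#' than the inter-marker interval implied by the target density (a gap
#' "too small" receives no SNP), otherwise `length_cm * density` rounded
#' under the quota rule (default round half up).
#'
#' @param length_cm Segment length in cM (>= 0).
#' @param density Target density in SNPs/cM (> 0).
#' @param quota_rule `"half_up"`, `"floor"` or `"ceiling"`.
#' @return Integer count >= 0.
#' @export
compute_segment_quota <- function(length_cm, density,
                                  quota_rule = c("half_up", "floor",
                                                 "ceiling")) {
  quota_rule <- match.arg(quota_rule)
  if (density <= 0) pf_abort("density must be > 0")
  quota_n(length_cm, density, quota_rule)
}

# quota computation without argument matching, for the per-segment hot loop
quota_n <- function(length_cm, density, quota_rule) {
  raw <- length_cm * density
  n <- switch(quota_rule,
              half_up = round_half_up(raw),
              floor = floor(raw),
              ceiling = ceiling(raw))
  as.integer(ifelse(length_cm < 1 / density, 0L, n))
}

#' Fill a segment with evenly spaced SNPs
#'
#' Chooses the size-n subset of candidate positions minimising the sum of
#' squared distances between consecutive SNPs, with the segment bounds
#' included as fixed endpoints: for chosen positions x_1 < ... < x_n and
#' bounds x_0, x_(n+1), the cost is sum over j of (x_(j+1) - x_j)^2.
#' Computed by dynamic programming over (candidate, count) in O(m^2 n);
#' ties are broken by the lexicographically smallest position tuple. If
#' `n` is at least the number of candidates, all candidates are returned.
#'
#' @param candidate_cm Sorted numeric vector of candidate positions (cM),
#'   strictly inside the bounds.
#' @param left_cm,right_cm Segment bounds.
#' @param n Number of SNPs to place (>= 0).
#' @return Integer indices into `candidate_cm` of the chosen positions.
#' @export
fill_segment <- function(candidate_cm, left_cm, right_cm, n) {
  m <- length(candidate_cm)
  if (n <= 0L || m == 0L) return(integer(0))
  if (n >= m) return(seq_len(m))
  x <- candidate_cm
  # h[j, k]: min cost from x[j] (chosen) to the right bound using k
  # chosen SNPs in x[j..m]
  h <- matrix(Inf, m, n)
  h[, 1] <- (right_cm - x)^2
  if (n > 1) {
    for (k in 2:n) {
      for (j in (m - k + 1L):1L) {
        l <- (j + 1L):(m - k + 2L)
        h[j, k] <- min((x[l] - x[j])^2 + h[l, k - 1L])
      }
    }
  }
  total <- (x - left_cm)^2 + h[, n]
  chosen <- integer(n)
  j <- which.min(total[seq_len(m - n + 1L)])
  chosen[1] <- j
  k <- n
  while (k > 1L) {
    l <- (j + 1L):(m - k + 2L)
    vals <- (x[l] - x[j])^2 + h[l, k - 1L]
    j <- l[which.min(vals)]
    k <- k - 1L
    chosen[n - k + 1L] <- j
  }
  chosen
}

#' Select a marker panel
#'
#' The full iterative selection: backbone construction
#' ([build_backbones()]), then per-line gap filling in `line_order`. For
#' each line the chromosomes are partitioned into segments bounded by
#' panel SNPs segregating in that line ([segments_for_line()]), each
#' segment receives a quota from the line's target density
#' ([compute_segment_quota()]), and the quota is met by the candidates
#' closest to ideal even spacing ([fill_segment()]). Placed SNPs join the
#' panel before the next line is processed, so later lines fill around
#' them. Deterministic for identical inputs.
#'
#' @inheritParams build_backbones
#' @return A `panel_selection`: a tibble (`snp_id`, `chrom`, `pos`,
#'   `provenance`) sorted by position, with the selection state
#'   (counters, per-line `F_i`/`S_i` bookkeeping) in attribute `"state"`.
#' @export
select_panel <- function(catalog, config, map,
                         mode = c("prescreen", "final")) {
  mode <- match.arg(mode)
  lines <- catalog_lines(catalog)
  state <- build_backbones(catalog, config, map, mode = mode)
  line_order <- config$line_order
  if (is.null(line_order)) {
    if (!is.null(config$densities)) {
      # explicit densities name the lines to fill; keep registry rank order
      filled <- lines[lines$name %in% names(config$densities), ]
    } else {
      filled <- lines[!is.na(lines$target_density) |
                        !is.na(lines$selection_rank), ]
    }
    line_order <- filled$name[order(filled$selection_rank)]
  }
  densities <- config$densities
  if (is.null(densities) && length(line_order)) {
    if (is.null(config$budget)) {
      pf_abort("either densities or a budget (for calibration) is required")
    }
    densities <- calibrate_densities(catalog, config, map, mode = mode,
                                     line_order = line_order)
  }
  if (!is.null(config$budget) && config$budget > nrow(catalog)) {
    warn("budget exceeds the number of candidates; panel saturates")
  }
  per_line <- tibble(line = character(), F_i = integer(), S_i = integer(),
                     X_after = integer())
  if (nrow(catalog)) {
    seg_m <- segregation_matrix(catalog)
    cm <- record_cm(catalog, map)
    prov <- character(nrow(catalog))
    prov[state$selected] <- state$panel$provenance[
      match(catalog$snp_id[state$selected], state$panel$snp_id)]
    for (ln in line_order) {
      d <- densities[[ln]]
      seg_col <- seg_m[, ln]
      F_i <- sum(state$selected & !seg_col)
      placed <- 0L
      for (chr in unique(map$chrom)) {
        on_chr <- catalog$chrom == chr
        a <- map_chrom(map, chr)
        bounds <- c(a$pos_cM[1],
                    sort(cm[on_chr & state$selected & seg_col]),
                    a$pos_cM[nrow(a)])
        cand <- which(on_chr & seg_col & !state$selected)
        if (!length(cand)) next
        cand <- cand[order(cm[cand], catalog$snp_id[cand])]
        ccm <- cm[cand]
        k <- length(bounds) - 1L
        iv <- findInterval(ccm, bounds)
        inside <- iv >= 1L & iv <= k & ccm > bounds[pmax(iv, 1L)] &
          ccm < bounds[pmin(iv + 1L, k + 1L)]
        for (s in unique(iv[inside])) {
          len <- bounds[s + 1L] - bounds[s]
          nq <- quota_n(len, d, config$quota_rule)
          if (nq == 0L) next
          in_s <- inside & iv == s
          pick <- fill_segment(ccm[in_s], bounds[s], bounds[s + 1L], nq)
          sel <- cand[in_s][pick]
          state$selected[sel] <- TRUE
          prov[sel] <- paste0("line:", ln)
          placed <- placed + length(sel)
        }
      }
      per_line <- add_row(per_line, line = ln, F_i = as.integer(F_i),
                          S_i = placed, X_after = sum(state$selected))
    }
    panel <- tibble(snp_id = catalog$snp_id[state$selected],
                    chrom = catalog$chrom[state$selected],
                    pos = catalog$pos[state$selected],
                    provenance = prov[state$selected])
  } else {
    panel <- state$panel
  }
  state$counters$X_final <- nrow(panel)
  structure(panel,
            state = list(counters = state$counters, per_line = per_line,
                         densities = densities, mode = mode),
            class = c("panel_selection", class(panel)))
}

#' Calibrate per-line densities against a budget
#'
#' Target densities are proportional to the group weights:
#' `d_i = s * w_g(i) / (n_filled_in_group * total_map_length_cm)`, with
#' the scalar `s` found by monotone bisection so that the realised panel
#' size falls within `budget * (1 +/- budget_tolerance)`. Panel size is
#' non-decreasing in `s`. If even saturating densities cannot reach the
#' budget (fewer candidates than budget) all candidates end up selected,
#' with a warning.
#'
#' @inheritParams build_backbones
#' @param line_order Lines to fill (defaults to the registry order).
#' @return Named numeric vector of densities (SNPs/cM) per filled line.
#' @export
calibrate_densities <- function(catalog, config, map,
                                mode = c("prescreen", "final"),
                                line_order = NULL) {
  mode <- match.arg(mode)
  lines <- catalog_lines(catalog)
  if (is.null(config$budget)) pf_abort("calibration requires a budget")
  if (is.null(line_order)) {
    filled <- lines[!is.na(lines$selection_rank), ]
    line_order <- filled$name[order(filled$selection_rank)]
  }
  grp <- lines$group[match(line_order, lines$name)]
  w <- config$group_ratio[grp]
  if (any(is.na(w))) {
    pf_abort(paste0("group_ratio lacks weight(s) for group(s): ",
                    paste(unique(grp[is.na(w)]), collapse = ", ")))
  }
  n_in_group <- table(grp)[grp]
  total_cm <- sum(map_dbl(unique(map$chrom), function(ch) map_length_cm(map, ch)))
  unit <- setNames(as.numeric(w / (as.numeric(n_in_group) * total_cm)),
                   line_order)
  size_at <- function(s) {
    cfg <- config
    cfg$densities <- pmax(unit * s, .Machine$double.eps)
    cfg$budget <- NULL
    nrow(select_panel(catalog, cfg, map, mode = mode))
  }
  budget <- config$budget
  tol <- config$budget_tolerance
  lo <- 0
  size_lo <- size_at(.Machine$double.eps)
  if (size_lo >= budget * (1 - tol)) {
    if (size_lo > budget * (1 + tol)) {
      pf_abort(paste0("backbone alone (", size_lo,
                      " SNPs) exceeds the budget band; reduce t or budget"))
    }
    return(unit * .Machine$double.eps)
  }
  hi <- budget
  size_hi <- size_at(hi)
  it <- 0
  while (size_hi < budget * (1 - tol) && it < 30) {
    hi2 <- hi * 2
    size_hi2 <- size_at(hi2)
    if (size_hi2 == size_hi) {
      warn(paste0("panel saturates at ", size_hi,
                  " SNPs, below the budget of ", budget,
                  "; selecting all reachable candidates"))
      return(unit * hi2)
    }
    hi <- hi2
    size_hi <- size_hi2
    it <- it + 1
  }
  trace <- tibble(s = c(lo, hi), size = c(size_lo, size_hi))
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    size_mid <- size_at(mid)
    trace <- add_row(trace, s = mid, size = size_mid)
    if (size_mid >= budget * (1 - tol) && size_mid <= budget * (1 + tol)) {
      return(unit * mid)
    }
    if (size_mid < budget) lo <- mid else hi <- mid
  }
  pf_abort(paste0("density calibration failed to land inside the budget ",
                  "band; trace: ",
                  paste(sprintf("s=%.4g:%d", trace$s, trace$size),
                        collapse = ", ")))
}

#' @export
glance.panel_selection <- function(x, ...) {
  st <- attr(x, "state")
  as_tibble(c(st$counters, list(n_lines_filled = nrow(st$per_line),
                                mode = st$mode)))
}

#' @export
tidy.panel_selection <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "state") <- NULL
  out
}

#' Per-line selection bookkeeping
#'
#' @param panel A `panel_selection`.
#' @return Tibble with, per filled line, the panel SNPs not segregating
#'   in it at processing time (`F_i`), the SNPs placed for it (`S_i`)
#'   and the running panel size (`X_after`).
#' @export
selection_report <- function(panel) attr(panel, "state")$per_line
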