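#' Genetic maps
#'
#' A genetic map is a tibble of anchors (`chrom`, `pos_bp`, `pos_cM`),
#' strictly increasing in both coordinates within each chromosome. It is
#' the coordinate system in which panel evenness is measured: distributing
#' markers per centimorgan rather than per megabase equalises coverage
#' between macro-chromosomes and the highly recombining micro-chromosomes.
#'
#' @param x A data frame with columns `chrom`, `pos_bp`, `pos_cM`.
#' @return `x` with class `genetic_map`, anchors sorted within chromosome.
#' @export
genetic_map <- function(x) {
  x <- as_tibble(x)[c("chrom", "pos_bp", "pos_cM")]
  x <- x[catalog_order(x$chrom, x$pos_bp), ]
  for (chr in unique(x$chrom)) {
    a <- x[x$chrom == chr, ]
    if (nrow(a) == 1L) {
      warn(paste0("chromosome ", chr, " has a single map anchor; ",
                  "its map length is 0"))
      next
    }
    if (any(diff(a$pos_bp) <= 0) || any(diff(a$pos_cM) <= 0)) {
      pf_abort(paste0("map anchors for ", chr,
                      " are not strictly increasing in both coordinates"))
    }
  }
  class(x) <- unique(c("genetic_map", class(x)))
  x
}

#' @rdname genetic_map
#' @param path Path to a map TSV with columns `chrom`, `pos_bp`, `pos_cM`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) pf_abort(paste0("no such map file: ", path))
  genetic_map(readr::read_tsv(
    path, col_types = readr::cols(chrom = readr::col_character(),
                                  pos_bp = readr::col_double(),
                                  pos_cM = readr::col_double()),
    progress = FALSE))
}

#' @rdname genetic_map
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path, progress = FALSE)
  invisible(path)
}

map_chrom <- function(map, chrom) {
  a <- map[map$chrom == chrom, ]
  if (!nrow(a)) pf_abort(paste0("chromosome not in genetic map: ", chrom))
  a
}

#' Convert physical to genetic-map position
#'
#' Linear interpolation between the bracketing anchors; beyond the anchor
#' range, linear extrapolation at the terminal interval's cM/Mb rate,
#' floored at 0 cM so map positions stay non-negative. Exactly at an
#' anchor, the anchor's cM is returned. The result is monotone
#' non-decreasing (strictly increasing inside the non-floored range), so
#' distinct physical positions keep a strict ordering in cM.
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome name (must be present in the map).
#' @param pos Vector of 1-based physical positions.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, pos) {
  a <- map_chrom(map, chrom)
  if (nrow(a) == 1L) return(rep(a$pos_cM, length(pos)))
  bp <- a$pos_bp
  cm <- a$pos_cM
  out <- approx(bp, cm, xout = pos, rule = 2)$y
  lo <- pos < bp[1]
  if (any(lo)) {
    rate <- (cm[2] - cm[1]) / (bp[2] - bp[1])
    out[lo] <- pmax(0, cm[1] + (pos[lo] - bp[1]) * rate)
  }
  n <- length(bp)
  hi <- pos > bp[n]
  if (any(hi)) {
    rate <- (cm[n] - cm[n - 1]) / (bp[n] - bp[n - 1])
    out[hi] <- cm[n] + (pos[hi] - bp[n]) * rate
  }
  out
}

#' Genetic length of a chromosome
#'
#' @inheritParams interpolate_cm
#' @return Last anchor cM minus first anchor cM (0 for a degenerate
#'   single-anchor chromosome, with a warning at map construction).
#' @export
map_length_cm <- function(map, chrom) {
  a <- map_chrom(map, chrom)
  a$pos_cM[nrow(a)] - a$pos_cM[1]
}

#' Summarise per-interval recombination rates
#'
#' Reports cM/Mb for every anchor interval; used by the map-check entry
#' point to validate monotonicity and flag implausible rates.
#'
#' @param map A [genetic_map()].
#' @return A tibble with one row per anchor interval.
#' @export
map_rates <- function(map) {
  as_tibble(map) |>
    group_by(.data$chrom) |>
    reframe(start_bp = head(.data$pos_bp, -1), end_bp = tail(.data$pos_bp, -1),
            start_cM = head(.data$pos_cM, -1), end_cM = tail(.data$pos_cM, -1)) |>
    mutate(cm_per_mb = (.data$end_cM - .data$start_cM) /
             ((.data$end_bp - .data$start_bp) / 1e6))
}
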