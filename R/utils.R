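#' Round half away from zero
#'
#' Decimal rounding with the half-up rule used throughout the package's
#' report arithmetic, so that printed percentages recompute exactly from
#' their counts. Base R's `round()` rounds half to even, which differs on
#' exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half up (half away from zero for
#'   negative input).
#' @examples
#' round_half_up(2.5)   # 3, where round(2.5) == 2
#' round_half_up(38.395, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# stop with a classed panelforge error
pf_abort <- function(msg, class = "panelforge_error") {
  abort(msg, class = class)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# order chromosomes as they first appear, positions numerically within
catalog_order <- function(chrom, pos) order(match(chrom, unique(chrom)), pos)
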