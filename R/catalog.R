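#' SNP catalogs
#'
#' A SNP catalog is a tibble with one row per candidate variant and class
#' `snp_catalog`. Fixed columns are `snp_id`, `chrom`, `pos` (1-based,
#' VCF convention), `ref`, `alt`, `global_quality`, `global_maf`,
#' `in_prior_panel`, `coding`, `annotation`, and the array design scores
#' `fwd_16mer`, `fwd_pconvert`, `rev_16mer`, `rev_pconvert`. Each
#' registered line contributes four columns `<line>_seg` (logical:
#' segregating in that line), `<line>_maf`, `<line>_qual`, `<line>_cov`.
#' Missing numeric evidence is `NA` (encoded `"."` on disk); missing is
#' never conflated with zero. Rows are kept sorted by (`chrom`, `pos`)
#' with chromosomes in first-appearance order; every operation in the
#' package preserves that order. The line registry travels in the
#' `"lines"` attribute.
#'
#' @param x A data frame with the columns described above.
#' @param lines A [line_info()] registry naming every line whose
#'   `<line>_seg` columns appear in `x`.
#' @return `x` sorted and validated, with class `snp_catalog`.
#' @export
snp_catalog <- function(x, lines) {
  x <- as_tibble(x)
  fixed <- c("snp_id", "chrom", "pos", "ref", "alt", "global_quality",
             "global_maf", "in_prior_panel", "coding", "annotation",
             "fwd_16mer", "fwd_pconvert", "rev_16mer", "rev_pconvert")
  missing_cols <- setdiff(fixed, names(x))
  if (length(missing_cols)) {
    pf_abort(paste0("catalog is missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  seg_cols <- grep("_seg$", names(x), value = TRUE)
  seg_lines <- sub("_seg$", "", seg_cols)
  unknown <- setdiff(seg_lines, lines$name)
  if (length(unknown)) {
    pf_abort(paste0("catalog references unregistered line(s): ",
                    paste(unknown, collapse = ", ")))
  }
  if (nrow(x)) {
    if (any(is.na(x$pos)) || any(x$pos < 1)) {
      pf_abort("catalog positions must be >= 1 (1-based convention)")
    }
    mafs <- c(x$global_maf, unlist(x[paste0(seg_lines, "_maf")], use.names = FALSE))
    if (any(mafs > 0.5 + 1e-12, na.rm = TRUE)) {
      pf_abort("minor allele frequencies must lie in [0, 0.5]")
    }
    if (anyDuplicated(x[c("chrom", "pos", "alt")])) {
      pf_abort("duplicate (chrom, pos, alt) records in catalog")
    }
    x <- x[catalog_order(x$chrom, x$pos), ]
  }
  attr(x, "lines") <- lines
  class(x) <- unique(c("snp_catalog", class(x)))
  x
}

#' @rdname snp_catalog
#' @export
catalog_lines <- function(x) attr(x, "lines")

# re-assert class/attributes after dplyr verbs strip them
restore_catalog <- function(x, template) {
  attr(x, "lines") <- catalog_lines(template)
  class(x) <- unique(c("snp_catalog", class(x)))
  x
}

catalog_column_order <- function(lines) {
  c("snp_id", "chrom", "pos", "ref", "alt", "global_quality", "global_maf",
    "in_prior_panel", "coding", "annotation",
    "fwd_16mer", "fwd_pconvert", "rev_16mer", "rev_pconvert",
    as.vector(t(outer(lines$name, c("_seg", "_maf", "_qual", "_cov"), paste0))))
}

#' Read and write SNP catalogs
#'
#' The canonical on-disk dialect is a tab-separated file with one header
#' line and the column layout described in [snp_catalog()]; missing values
#' are encoded `"."`. `write_catalog()` / `read_catalog()` round-trip a
#' catalog field-for-field, and a write-read-write cycle is
#' byte-identical.
#'
#' @param path Path to a catalog TSV.
#' @param lines A [line_info()] registry; the file's `<line>_seg` columns
#'   must all name registered lines.
#' @return `read_catalog()` returns a sorted [snp_catalog()];
#'   `write_catalog()` invisibly returns `path`.
#' @export
read_catalog <- function(path, lines) {
  if (!file.exists(path)) pf_abort(paste0("no such catalog file: ", path))
  spec <- readr::cols(
    snp_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double(), ref = readr::col_character(),
    alt = readr::col_character(), global_quality = readr::col_double(),
    global_maf = readr::col_double(), in_prior_panel = readr::col_logical(),
    coding = readr::col_logical(), annotation = readr::col_character(),
    .default = readr::col_double()
  )
  hdr <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1]]
  for (col in grep("_seg$", hdr, value = TRUE)) {
    spec$cols[[col]] <- readr::col_logical()
  }
  # unknown non-evidence columns are dropped later; parse them as text so
  # they cannot trigger spurious numeric-parse errors first
  foreign <- setdiff(hdr, c(names(spec$cols), "fwd_16mer", "fwd_pconvert",
                            "rev_16mer", "rev_pconvert"))
  foreign <- foreign[!grepl("_(seg|maf|qual|cov)$", foreign)]
  for (col in foreign) spec$cols[[col]] <- readr::col_character()
  # parse problems are promoted to errors below; silence vroom's advisory
  x <- suppressWarnings(
    readr::read_tsv(path, col_types = spec, na = ".", progress = FALSE))
  probs <- readr::problems(x)
  if (nrow(probs)) {
    pf_abort(paste0("malformed catalog row at file line ", probs$row[1] + 1L,
                    ": ", probs$expected[1], " vs '", probs$actual[1], "'"))
  }
  expected <- catalog_column_order(lines)
  extra <- setdiff(names(x), expected)
  extra <- extra[!grepl("_(seg|maf|qual|cov)$", extra)]
  if (length(extra)) {
    warn(paste0("ignoring unknown catalog column(s): ",
                paste(extra, collapse = ", ")))
    x <- x[setdiff(names(x), extra)]
  }
  snp_catalog(x, lines)
}

#' @rdname read_catalog
#' @param catalog A [snp_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  lines <- catalog_lines(catalog)
  cols <- intersect(catalog_column_order(lines), names(catalog))
  readr::write_tsv(as_tibble(catalog)[cols], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Lines in which a SNP segregates
#'
#' @param catalog A [snp_catalog()].
#' @param snp_id Optional single SNP id; if omitted, a named list over all
#'   records is returned.
#' @return A character vector of line names (or a named list of them).
#' @export
segregation_set <- function(catalog, snp_id = NULL) {
  m <- segregation_matrix(catalog)
  if (!is.null(snp_id)) {
    if (!snp_id %in% rownames(m)) pf_abort(paste0("unknown snp_id: ", snp_id))
    return(colnames(m)[m[snp_id, ]])
  }
  apply(m, 1L, function(row) colnames(m)[row], simplify = FALSE)
}

# records x lines logical matrix of segregation status (NA -> FALSE)
segregation_matrix <- function(catalog) {
  lines <- catalog_lines(catalog)
  m <- sapply(paste0(lines$name, "_seg"),
              function(col) !is.na(catalog[[col]]) & catalog[[col]])
  m <- matrix(m, nrow = nrow(catalog), ncol = nrow(lines),
              dimnames = list(catalog$snp_id, lines$name))
  m
}

#' Write a selected panel
#'
#' Panels are written either as a TSV (`snp_id`, `chrom`, `pos`,
#' `provenance`; 1-based positions) or as BED (0-based half-open) for
#' genome-browser use.
#'
#' @param panel A `panel_selection` tibble as returned by [select_panel()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_panel <- function(panel, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(panel)[c("snp_id", "chrom", "pos", "provenance")],
                     path, na = ".", progress = FALSE)
  } else {
    bed <- tibble(chrom = panel$chrom, start = panel$pos - 1L, end = panel$pos,
                  name = panel$snp_id)
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Import a catalog from VCF
#'
#' Reads a VCF 4.x file whose INFO field carries the per-line evidence
#' under keys `SEG_<line>` (flag), `MAF_<line>`, `QUAL_<line>`,
#' `COV_<line>`, plus optional `GQUAL`, `GMAF`, `PRIOR`, `CODING`,
#' `ANNO`, `K16F`, `PCF`, `K16R`, `PCR`. The TSV dialect remains the
#' source of truth; this is an import convenience.
#'
#' @inheritParams read_catalog
#' @return A [snp_catalog()].
#' @export
read_catalog_vcf <- function(path, lines) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    pf_abort("package 'vcfR' is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  get_num <- function(key) {
    val <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", info)
    suppressWarnings(as.numeric(ifelse(grepl(paste0("(^|;)", key, "="), info),
                                       val, NA)))
  }
  get_chr <- function(key) {
    val <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", info)
    ifelse(grepl(paste0("(^|;)", key, "="), info), val, NA_character_)
  }
  has_flag <- function(key) grepl(paste0("(^|;)", key, "(;|$)"), info)
  x <- tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    global_quality = get_num("GQUAL"), global_maf = get_num("GMAF"),
    in_prior_panel = has_flag("PRIOR"), coding = has_flag("CODING"),
    annotation = get_chr("ANNO"),
    fwd_16mer = get_num("K16F"), fwd_pconvert = get_num("PCF"),
    rev_16mer = get_num("K16R"), rev_pconvert = get_num("PCR")
  )
  for (ln in lines$name) {
    x[[paste0(ln, "_seg")]] <- has_flag(paste0("SEG_", ln))
    x[[paste0(ln, "_maf")]] <- get_num(paste0("MAF_", ln))
    x[[paste0(ln, "_qual")]] <- get_num(paste0("QUAL_", ln))
    x[[paste0(ln, "_cov")]] <- get_num(paste0("COV_", ln))
  }
  snp_catalog(x, lines)
}
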