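#' Construct a line registry
#'
#' A line registry describes the populations ("lines") contributing
#' evidence to a SNP catalog: its group (meat-type broiler, white or brown
#' egg layer, inbred, or experimental), whether it is a commercial line,
#' the order in which per-line gap filling visits it, and its target
#' marker density in SNPs per centimorgan (`NA` for lines that are not
#' filled, e.g. inbred lines covered only by the backbone passes).
#'
#' @param name Character vector of unique line names.
#' @param group Character vector, each one of `"broiler"`, `"WEL"`,
#'   `"BEL"`, `"inbred"`, `"experimental"`.
#' @param commercial Logical vector; defaults to `TRUE` for broiler/WEL/BEL.
#' @param selection_rank Integer order of per-line filling (`NA` for lines
#'   never filled); must be unique among lines with a non-missing
#'   `target_density`.
#' @param target_density SNPs per cM for filled lines (`NA` otherwise).
#' @return A tibble with class `line_info`.
#' @export
line_info <- function(name, group,
                      commercial = group %in% c("broiler", "WEL", "BEL"),
                      selection_rank = NA_integer_,
                      target_density = NA_real_) {
  groups <- c("broiler", "WEL", "BEL", "inbred", "experimental")
  if (anyDuplicated(name)) pf_abort("line names must be unique")
  if (!all(group %in% groups)) {
    pf_abort(paste0("unknown line group(s): ",
                    paste(setdiff(group, groups), collapse = ", ")))
  }
  out <- tibble(
    name = as.character(name),
    group = as.character(group),
    commercial = rep_len(as.logical(commercial), length(name)),
    selection_rank = rep_len(as.integer(selection_rank), length(name)),
    target_density = rep_len(as.numeric(target_density), length(name))
  )
  ranked <- out$selection_rank[!is.na(out$target_density)]
  if (anyDuplicated(ranked[!is.na(ranked)])) {
    pf_abort("selection_rank must be unique among filled lines")
  }
  class(out) <- c("line_info", class(out))
  out
}

#' The 24-line chicken resequencing panel
#'
#' The line panel used to build the chicken 600K array candidate catalog:
#' four commercial broiler lines, six white egg layer (WEL) lines, five
#' brown egg layer (BEL) lines, eight highly inbred experimental layers
#' and one unselected experimental layer line, together with the number of
#' segregating SNPs detected per line (quality score >= 20) from pooled
#' resequencing. Used by the report helpers to reproduce the published
#' per-group mean SNP counts.
#'
#' @return A tibble with columns `name`, `group`, `commercial`,
#'   `n_snps_detected`.
#' @examples
#' lines <- chicken_line_panel()
#' group_mean_counts(
#'   setNames(lines$n_snps_detected, lines$name),
#'   grouping = setNames(ifelse(lines$group == "broiler", "broiler",
#'     ifelse(lines$group == "inbred", "inbred", "layer")), lines$name)
#' )
#' @export
chicken_line_panel <- function() {
  tibble(
    name = c("B1", "B2", "B3", "B4",
             "WEL1", "WEL2", "WEL3", "WEL4", "WEL5", "WEL6",
             "BEL1", "BEL2", "BEL3", "BEL4", "BEL5",
             "RI-J",
             paste0("I", 1:8)),
    group = c(rep("broiler", 4), rep("WEL", 6), rep("BEL", 5),
              "experimental", rep("inbred", 8)),
    commercial = c(rep(TRUE, 15), rep(FALSE, 9)),
    n_snps_detected = c(
      9525306, 10760626, 9305545, 10422420,
      8605672, 9900302, 7340262, 7951423, 11139255, 2630343,
      8182562, 7876558, 11593980, 3236749, 3751628,
      10358702,
      447683, 1816948, 1109100, 1055257, 801052, 1395679, 803892, 603338
    )
  )
}
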