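#' Pipeline configuration
#'
#' Bundles the file paths and stage parameters for a full design run.
#' All paths are checked up front so a misconfigured run fails before
#' any computation.
#'
#' @param catalog,map Paths to the catalog and genetic-map TSVs.
#' @param lines A [line_info()] registry.
#' @param genotypes,trios Optional paths to a validation genotype TSV
#'   and a trio TSV (`sire`, `dam`, `offspring`); without genotypes the
#'   run stops after the pre-screening panel.
#' @param policy A [filter_policy()].
#' @param prescreen,final [selection_config()]s for the two selection
#'   passes (final-mode coding force-inclusion is derived from the
#'   catalog's `coding` flag).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in every output header.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(catalog, map, lines, genotypes = NULL,
                            trios = NULL, policy = filter_policy(),
                            prescreen = selection_config(),
                            final = selection_config(
                              group_ratio = c(broiler = 3, WEL = 2, BEL = 2)),
                            out_dir = ".", seed = 1L) {
  for (p in c(catalog, map, genotypes, trios)) {
    if (!file.exists(p)) pf_abort(paste0("configured file does not exist: ", p))
  }
  structure(list(catalog = catalog, map = map, lines = lines,
                 genotypes = genotypes, trios = trios, policy = policy,
                 prescreen = prescreen, final = final, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

output_header <- function(config) {
  h <- rlang::hash(config[setdiff(names(config), "out_dir")])
  paste0("# panelforge ",
         as.character(utils::packageVersion("panelforge")),
         " config=", h, " seed=", config$seed)
}

write_output <- function(df, path, header) {
  readr::write_lines(header, path)
  readr::write_tsv(df, path, na = ".", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full design pipeline
#'
#' Stage order mirrors the array-design workflow: quality/MAF screen,
#' proximity screen, design-score screen, coverage-outlier exclusion,
#' pre-screening panel selection, validation analytics (conversion
#' classification, Mendelian trio check, exact Hardy-Weinberg test,
#' MAF estimation), extreme-HWE exclusion, final panel selection with
#' coding force-inclusion, and summary reports. Every output file
#' carries a header comment with the tool version, a configuration hash
#' and the seed; reruns with an identical configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage-count `ledger`, the
#'   `prescreen` and `final` panels and the validation tables.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(config)
  out <- function(name) file.path(config$out_dir, name)
  set.seed(config$seed)

  catalog <- read_catalog(config$catalog, config$lines)
  map <- read_genetic_map(config$map)
  ledger <- tibble(stage = "catalog", n_snps = nrow(catalog))

  fc <- filter_cascade(catalog, config$policy)
  ledger <- bind_rows(ledger,
                      tibble(stage = fc$ledger$stage, n_snps = fc$ledger$n_out))
  filtered <- fc$catalog

  prescreen <- select_panel(filtered, config$prescreen, map,
                            mode = "prescreen")
  write_panel_output(prescreen, out("prescreen_panel.tsv"), hdr)
  ledger <- add_row(ledger, stage = "prescreen_panel", n_snps = nrow(prescreen))

  final <- NULL
  validation <- NULL
  if (!is.null(config$genotypes)) {
    geno <- read_genotypes(config$genotypes)
    keep <- geno$snps$snp_id %in% prescreen$snp_id
    geno <- geno_matrix(geno$calls[, keep, drop = FALSE],
                        geno$samples, geno$snps[keep, ])
    conv <- classify_conversion(geno)
    mendel <- if (!is.null(config$trios)) {
      trios <- readr::read_tsv(config$trios,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
      mendelian_check(geno, trios)
    } else {
      tibble(snp_id = conv$snp_id, n_inconsistent = 0L, fails = FALSE)
    }
    # test HWE within lines (pooling drifted lines would reject nearly
    # everything through the Wahlund effect); a SNP is extreme if it is
    # extreme in any line with enough samples
    hwe_lines <- names(which(table(geno$samples$line) >= 10))
    if (length(hwe_lines)) {
      pmat <- vapply(hwe_lines, function(ln) {
        ids <- geno$samples$sample[geno$samples$line == ln]
        hwe_test_all(geno, samples = ids)$p_hwe
      }, numeric(ncol(geno$calls)))
      pmat <- matrix(pmat, ncol = length(hwe_lines))
      p_min <- apply(pmat, 1, function(v) {
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
      })
      hwe <- tibble(snp_id = colnames(geno$calls), p_hwe = p_min)
    } else {
      hwe <- hwe_test_all(geno)
    }
    maf <- estimate_maf(geno)
    validation <- conv |>
      left_join(mendel, by = "snp_id") |>
      left_join(hwe, by = "snp_id") |>
      left_join(maf, by = "snp_id")
    write_output(validation, out("validation.tsv"), hdr)

    vs <- validation_summary(
      total_validated = nrow(validation),
      polymorphic = sum(validation$class == "polymorphic"),
      monomorphic = sum(validation$class == "monomorphic_low_allele_count"),
      failed = sum(validation$class == "failed"),
      trios = if (!is.null(config$trios)) nrow(trios) else NA_integer_,
      mendel_fail = sum(validation$fails & validation$class == "polymorphic"))
    write_output(vs, out("validation_summary.tsv"), hdr)

    ok_ids <- validation$snp_id[validation$class == "polymorphic" &
                                  !validation$fails]
    ledger <- add_row(ledger, stage = "validated_polymorphic",
                      n_snps = length(ok_ids))
    candidates <- filtered[filtered$snp_id %in% ok_ids, ]
    candidates <- restore_catalog(candidates, filtered)
    pv <- setNames(validation$p_hwe, validation$snp_id)
    candidates <- filter_hwe_extreme(candidates, pv, config$policy)
    ledger <- add_row(ledger, stage = "hwe_pass", n_snps = nrow(candidates))

    final_cfg <- config$final
    final_cfg$coding_ids <- candidates$snp_id[candidates$coding]
    final <- select_panel(candidates, final_cfg, map, mode = "final")
    write_panel_output(final, out("final_panel.tsv"), hdr)
    ledger <- add_row(ledger, stage = "final_panel", n_snps = nrow(final))

    chrom_lengths <- setNames(
      map_dbl(unique(map$chrom),
              function(ch) max(map_chrom(map, ch)$pos_bp)),
      unique(map$chrom))
    sp <- spacing_stats(final, chrom_lengths)
    write_output(tibble(metric = c("mean_gap", "sd_gap", "n_gaps"),
                        value = c(sp$mean_gap, sp$sd_gap, sp$n_gaps)),
                 out("spacing_summary.tsv"), hdr)
    write_output(density_by_chromosome(final, map, chrom_lengths),
                 out("density_by_chromosome.tsv"), hdr)
    panel_maf <- maf$maf[maf$snp_id %in% final$snp_id]
    write_output(maf_distribution(panel_maf[!is.na(panel_maf)]),
                 out("maf_distribution.tsv"), hdr)
    write_output(annotation_summary(as_tibble(final) |>
                                      left_join(as_tibble(catalog)[
                                        c("snp_id", "annotation")],
                                        by = "snp_id")),
                 out("annotation_summary.tsv"), hdr)
  }

  state <- attr(prescreen, "state")
  prov <- bind_rows(
    tibble(stage = paste0("prescreen_", names(state$counters)),
           count = as.integer(unlist(state$counters))),
    if (!is.null(final)) {
      fstate <- attr(final, "state")
      tibble(stage = paste0("final_", names(fstate$counters)),
             count = as.integer(unlist(fstate$counters)))
    })
  write_output(prov, out("provenance_counts.tsv"), hdr)
  write_output(ledger, out("stage_ledger.tsv"), hdr)
  invisible(list(ledger = ledger, prescreen = prescreen, final = final,
                 validation = validation))
}

write_panel_output <- function(panel, path, header) {
  write_output(as_tibble(panel)[c("snp_id", "chrom", "pos", "provenance")],
               path, header)
}
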