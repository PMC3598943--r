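# build a small but complete on-disk study: catalog, map, validation
# genotypes for every catalog SNP, and trios
make_pipeline_fixture <- function(dir, seed = 404, n_snps = 1200) {
  cfg <- sim_config(seed = seed, n_snps = n_snps,
                    chromosomes = tibble::tibble(
                      name = c("Chr1", "Chr20"), length_bp = c(6e6, 2e6),
                      cm_per_mb = c(3, 8)))
  sim <- simulate_catalog(cfg)
  map <- simulate_map(cfg)
  write_catalog(sim$catalog, file.path(dir, "catalog.tsv"))
  write_genetic_map(map, file.path(dir, "map.tsv"))
  geno <- simulate_genotypes(
    sim$truth, c(WEL1 = 25, WEL2 = 25, BEL1 = 25, B1 = 25, B2 = 25), cfg)
  tr <- simulate_trios(sim$truth, "B1", n_trios = 4, cfg)
  merged <- geno_matrix(rbind(geno$calls, tr$geno$calls),
                        dplyr::bind_rows(geno$samples, tr$geno$samples),
                        geno$snps)
  write_genotypes(merged, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(tr$trios, file.path(dir, "trios.tsv"))
  dens <- setNames(rep(1.2, 5), c("WEL1", "WEL2", "BEL1", "B1", "B2"))
  pipeline_config(
    catalog = file.path(dir, "catalog.tsv"),
    map = file.path(dir, "map.tsv"),
    lines = cfg$lines,
    genotypes = file.path(dir, "genotypes.tsv"),
    trios = file.path(dir, "trios.tsv"),
    prescreen = selection_config(t = 2000, densities = dens),
    final = selection_config(t = 2000, densities = dens * 0.7),
    out_dir = file.path(dir, "out"), seed = seed)
}
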