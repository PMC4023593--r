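# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A small noise-free or noisy simulated HD screen.
make_screen <- function(n_strains = 50, seed = 1, n_responders = 0,
                        delta = 1 / 3, n_rd = 0, sigma_log = 0,
                        affinity_sdlog = 0, carbon_sources = c("YPD", "YPE",
                                                               "YPG", "YPL"),
                        replicates = 3, frac_single_tag = 0.02, ...) {
  design <- pool_design(n_strains, carbon_sources = carbon_sources,
                        replicates = replicates,
                        frac_single_tag = frac_single_tag, seed = seed)
  map <- make_strain_map(design)
  truth <- make_truth(map, design, n_responders = n_responders, delta = delta,
                      n_rd = n_rd, affinity_sdlog = affinity_sdlog, ...)
  sim <- simulate_pool(design, map, truth, noise_model(sigma_log = sigma_log))
  list(design = design, map = map, truth = truth, table = sim$table,
       samples = sim$samples)
}

# A bare tag_table built from an explicit matrix, for normalization tests.
# One pool, all uptags, one strain per tag.
toy_table <- function(values, scale = "log2", pool = "HD",
                      tag_group = "uptag") {
  n <- nrow(values)
  k <- ncol(values)
  tags <- data.frame(tag_id = sprintf("t%03d", seq_len(n)),
                     strain = sprintf("s%03d", seq_len(n)),
                     tag_group = tag_group, pool = pool,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("smp%02d", seq_len(k)),
                        pool = pool, carbon_source = "YPE",
                        treatment = rep(c("none", "Cu"), length.out = k),
                        replicate = seq_len(k), stringsAsFactors = FALSE)
  dimnames(values) <- list(tags$tag_id, samples$sample_id)
  tag_table(values, tags, samples, scale = scale)
}

# Write a simulated screen to TSV files in a fresh temp dir; returns paths.
write_screen_fixture <- function(screen, dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  paths <- list(
    intensities = file.path(dir, "intensities.tsv"),
    samplesheet = file.path(dir, "samplesheet.tsv"),
    strainmap = file.path(dir, "strainmap.tsv"),
    dir = dir)
  write_intensities(screen$table, paths$intensities)
  write_sample_sheet(screen$samples, paths$samplesheet)
  write_strain_map(screen$map, paths$strainmap)
  paths
}
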