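# The reference synthetic study: the conditions under which the spatial
# claim is evaluated. 2000 genes on five 13 Mb chromosomes (>= 30 kb TSS
# spacing needs ~12 Mb for 400 genes), 20 tracks, 5 kb contact resolution,
# half the genes with planted distal loops, equal linear and spatial effect
# sizes, noise SD 0.5. Ten repeated trainings per arm; boosting uses 100
# rounds at learning rate 0.1 (the package default capacity at half the
# cost, chosen for desk-scale runtimes).
study_synth_config <- function(beta_sp, seed = 2024) {
  synth_config(n_genes = 2000,
               chrom_lengths = c(chr1 = 13e6, chr2 = 13e6, chr3 = 13e6,
                                 chr5 = 13e6, chr8 = 13e6),
               n_tracks = 20, resolution = 5000, loop_prob = 0.5,
               beta_lin = 1, beta_sp = beta_sp, noise_sd = 0.5, seed = seed)
}

run_study <- function(beta_sp, n_runs = 10, seed = 2024, base_seed = 100) {
  cfg <- study_synth_config(beta_sp, seed = seed)
  ds <- synth_generate(cfg)
  archive <- suppressMessages(build_tensor_archive(
    ds$genes, ds$contact_set, track_predictor(ds$store), decay_basis(),
    verbose = FALSE))
  sp <- chromosome_split(ds$genes)
  y <- transform_target(ds$expression[ds$genes$gene_id, 1], cfg$pseudocount)
  names(y) <- ds$genes$gene_id
  mcfg <- model_config(n_rounds = 100, learning_rate = 0.1)
  arm <- function(spatial) {
    ftr <- feature_matrix(archive, sp$train_ids, spatial = spatial)
    fte <- feature_matrix(archive, sp$test_ids, spatial = spatial)
    repeated_runs(ftr, y[sp$train_ids], fte, y[sp$test_ids], mcfg,
                  n_runs = n_runs, base_seed = base_seed)
  }
  list(ds = ds, archive = archive, split = sp, y = y,
       spatial = arm(TRUE), baseline = arm(FALSE))
}

cached_study <- function(beta_sp) {
  key <- paste0("study", beta_sp)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_study(beta_sp)
  .fixture_cache[[key]]
}
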