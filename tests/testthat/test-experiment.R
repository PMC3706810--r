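small_cfg <- function(...) {
  args <- utils::modifyList(
    list(scheme = "backcross", pool_sizes = 5, coverages = 10,
         replicates = 2, seed = 71, n_mutations = 60,
         markers_per_chrom = 25),
    list(...)
  )
  do.call(sweep_config, args)
}

test_that("replicates are deterministic given the seed", {
  cfg <- small_cfg()
  ctx <- prepare_context(cfg)
  r1 <- run_replicate(cfg, 3, ctx)
  r2 <- run_replicate(cfg, 3, ctx)
  expect_identical(r1, r2)
  r3 <- run_replicate(cfg, 4, ctx)
  expect_false(identical(r1$cam_count, r3$cam_count) &&
                 identical(r1$causal_inside, r3$causal_inside) &&
                 identical(r1, r3))
})

test_that("sweeps aggregate replicate records per cell", {
  cfg <- small_cfg()
  sw <- run_sweep(cfg)
  expect_equal(nrow(sw$summary), 1)
  expect_equal(sw$summary$replicates, 2)
  expect_equal(nrow(sw$replicates), 2)
  expect_true(all(c("mean_cams", "sd_cams", "frac_causal_inside") %in%
                    names(sw$summary)))

  # a single replicate leaves the SD undefined
  cfg1 <- small_cfg(replicates = 1)
  sw1 <- run_sweep(cfg1)
  expect_true(is.na(sw1$summary$sd_cams))

  # summary plot renders without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_invisible(plot(sw))
})

test_that("outcross replicates report intervals that contain the causal
          locus most of the time", {
  cfg <- sweep_config(scheme = "outcross", pool_sizes = 30, coverages = 25,
                      replicates = 1, seed = 77, n_mutations = 200,
                      markers_per_chrom = 60)
  ctx <- prepare_context(cfg)
  recs <- do.call(rbind, lapply(1:5, function(i) run_replicate(cfg, i, ctx)))
  expect_true(all(recs$length_bp > 0))
  expect_gte(mean(recs$causal_inside), 0.8)
  expect_true(all(recs$cam_count >= 0))
})

test_that("direct scheme forces a pool of one", {
  cfg <- sweep_config(scheme = "direct", pool_sizes = 99, coverages = 30,
                      replicates = 1, seed = 79, n_mutations = 100,
                      markers_per_chrom = 25, backcross_rounds = 2)
  expect_equal(cfg$pool_sizes, 1)
  ctx <- prepare_context(cfg)
  rec <- run_replicate(cfg, 1, ctx)
  expect_gte(rec$cam_count, 1)
  expect_true(rec$causal_inside)
})

test_that("YAML configs load with aliases and reject unknown keys", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scheme: backcross", "pool_size: [5, 10]", "coverage: 20",
               "generations: 2", "replicates: 3", "seed: 5",
               "n_mutations: 80"), p)
  cfg <- load_sweep_config(p)
  expect_equal(cfg$pool_sizes, c(5, 10))
  expect_equal(cfg$coverages, 20)
  expect_equal(cfg$backcross_rounds, 2)

  # total_reads overrides the coverage target for sequencing depth
  writeLines(c("scheme: backcross", "pool_sizes: 5", "coverages: 10",
               "total_reads: 1234", "replicates: 1", "n_mutations: 40",
               "markers_per_chrom: 15", "seed: 4"), p)
  cfgt <- load_sweep_config(p)
  ctxt <- prepare_context(cfgt)
  set.seed(1)
  ctxt$mutations <- mutagenize(ctxt$genome, 40)
  pop <- breed_population("backcross", 40, ctxt$plan,
                          mutations = ctxt$mutations)
  pool <- select_pool(pop, ctxt$mutations, 5, 0)
  cts <- sequence_pool(pool, NULL, ctxt$mutations,
                       seq_params(coverage = 10,
                                  total_reads = cfgt$total_reads))
  expect_identical(sum(cts$cov), 1234L)

  writeLines(c("scheme: outcross", "frobnicate: 1"), p)
  expect_error(load_sweep_config(p), "unknown config keys")
  expect_error(load_sweep_config("/nope.yaml"), "no such config")
})

test_that("the CLI runs sweeps reproducibly and fails cleanly", {
  cfgp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scheme: backcross", "pool_sizes: 4", "coverages: 8",
               "replicates: 2", "n_mutations: 50",
               "markers_per_chrom: 20"), cfgp)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  expect_equal(psim_cli(c("sweep", "--config", cfgp, "--seed", "7",
                          "--out-dir", d1)), 0L)
  expect_equal(psim_cli(c("sweep", "--config", cfgp, "--seed", "7",
                          "--out-dir", d2)), 0L)
  expect_identical(readLines(file.path(d1, "summary.tsv")),
                   readLines(file.path(d2, "summary.tsv")))
  expect_identical(readLines(file.path(d1, "replicates.tsv")),
                   readLines(file.path(d2, "replicates.tsv")))

  expect_equal(psim_cli(c("sweep", "--config", "/missing.yaml",
                          "--out-dir", d1)), 2L)
  expect_equal(psim_cli("no-such-command"), 2L)
  expect_equal(psim_cli(c("sweep", "--config")), 2L)

  # filter-markers end to end
  mp <- withr::local_tempfile()
  write_markers(marker_map("c1", c(100, 130, 400), quality = c(30, 30, 10)),
                mp)
  out <- withr::local_tempfile()
  expect_equal(psim_cli(c("filter-markers", "--markers", mp,
                          "--out", out)), 0L)
  kept <- utils::read.table(out, header = TRUE, sep = "\t")
  expect_equal(kept$pos, 100)
})
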