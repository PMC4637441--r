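# The synthetic cohort generator: determinism, band-limited content,
# record-layout compatibility, and configuration validation.

test_that("band signals are deterministic and band-limited", {
  set.seed(1)
  a <- generate_band_signal(c(8, 13), 4, fs = 128, amplitude_uv = c(20, 200))
  set.seed(1)
  b <- generate_band_signal(c(8, 13), 4, fs = 128, amplitude_uv = c(20, 200))
  expect_identical(a, b)
  expect_length(a, 512)

  # Fourier oracle: energy concentrated inside the requested band
  set.seed(2)
  for (edges in list(c(0.5, 3.5), c(4, 7), c(8, 13), c(14, 30))) {
    s <- generate_band_signal(edges, 8, fs = 128)
    expect_gt(fft_band_fraction(s, 128, max(edges[1] - 1, 0), edges[2] + 1),
              0.95)
  }
  # the delta example: dominant content below 4 Hz
  set.seed(3)
  d <- generate_band_signal(c(0.5, 3.5), 4, fs = 128)
  expect_gt(fft_band_fraction(d, 128, 0, 4), 0.9)

  expect_error(generate_band_signal(c(8, 13), 0), "duration")
  expect_error(generate_band_signal(c(13, 8), 4), "edges")
  expect_error(generate_band_signal(c(8, 70), 4), "edges")
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(n_trained = 13), "n_trained")
  expect_error(generator_config(noise_fraction = 1), "noise_fraction")
  expect_error(generator_config(isi_range_ms = c(2000, 1000)), "isi")
  expect_error(
    generator_config(band_fractions = c(delta = 0.5, theta = 0.5,
                                        alpha = 0.2, beta = 0.2)),
    "sum to 1")
  expect_error(
    generator_config(band_edges = list(delta = c(0.1, 3.5), theta = c(4, 7),
                                       alpha = c(8, 13), beta = c(14, 30))),
    "acquisition band")
  # a single fraction vector is replicated over tasks
  cfg <- generator_config(band_fractions = c(delta = 0.25, theta = 0.25,
                                             alpha = 0.25, beta = 0.25))
  expect_setequal(names(cfg$band_fractions), unique(default_task_map()))
})

test_that("recordings have the configured event structure and gaps", {
  cfg <- generator_config(n_subjects = 1, epoch_duration_s = 2, seed = 4)
  rec <- generate_recording(cfg, 1)
  ids <- rec$event_ids
  expect_setequal(ids[ids > 0], 1:9)
  runs <- rle(ids)
  expect_identical(runs$values[runs$values > 0], 1:9)
  # gaps precede every event and last 1000-2000 ms at 128 Hz
  gap_lens <- runs$lengths[runs$values == 0]
  expect_length(gap_lens, 9)
  expect_true(all(gap_lens >= 128 & gap_lens <= 256))
  # event epochs have the configured duration
  expect_true(all(runs$lengths[runs$values > 0] == 256))
  # timestamps n/fs; baseline column is the channel average
  expect_equal(rec$time_s, (seq_along(ids) - 1) / 128)
  expect_equal(rec$baseline, rowMeans(rec$voltages), tolerance = 1e-12)
})

test_that("the same seed reproduces a cohort bit for bit, including files", {
  cfg <- tiny_preset(seed = 6)
  d1 <- tempfile()
  d2 <- tempfile()
  sim1 <- simulate_cohort(cfg, dir = d1)
  sim2 <- simulate_cohort(cfg, dir = d2)
  expect_identical(sim1$recordings[[1]]$voltages,
                   sim2$recordings[[1]]$voltages)
  f1 <- list.files(d1, pattern = "tsv$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "tsv$", full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  # sidecar records the seed
  side <- jsonlite::read_json(file.path(d1, "generator_config.json"))
  expect_equal(side$seed, 6)
})

test_that("cohorts have 12 subjects with 4 flagged trained by default", {
  cfg <- generator_config(epoch_duration_s = 0.25, n_events = 1,
                          isi_range_ms = c(10, 20))
  sim <- simulate_cohort(cfg)
  expect_length(sim$recordings, 12)
  expect_identical(unname(table(sim$groups)["trained"]), 4L)
  expect_true(attr(sim$recordings[["1"]], "trained"))
  expect_false(attr(sim$recordings[["12"]], "trained"))
})

test_that("generated files are accepted unchanged by the reader", {
  cfg <- generator_config(n_subjects = 1, n_events = 3,
                          epoch_duration_s = 2, seed = 8)
  dir <- tempfile()
  sim <- simulate_cohort(cfg, dir = dir)
  path <- list.files(dir, pattern = "tsv$", full.names = TRUE)
  back <- read_records(path)[[1]]
  expect_equal(back$voltages, sim$recordings[[1]]$voltages,
               tolerance = 1e-5)
  expect_identical(back$event_ids, sim$recordings[[1]]$event_ids)
  expect_true(validate_sampling(back)$pass)
})

test_that("headline preset encodes the three directional effects", {
  cfg <- headline_preset(seed = 1)
  for (bf in cfg$band_fractions) {
    expect_identical(names(which.min(bf)), "alpha")
  }
  expect_gt(cfg$left_beta_boost, 1)
  expect_gt(cfg$task1_beta_boost, 1)
  expect_gt(cfg$trained_beta_boost, 1)
  expect_identical(cfg$n_subjects, 12L)
  expect_identical(cfg$n_trained, 4L)
})

test_that("requested band fractions are recovered by the pipeline", {
  fr <- c(delta = 0.50, theta = 0.20, alpha = 0.08, beta = 0.22)
  cfg <- generator_config(n_subjects = 1, n_events = 9,
                          epoch_duration_s = 4, band_fractions = fr,
                          noise_fraction = 0.05, seed = 12)
  sim <- simulate_cohort(cfg)
  res <- run_pipeline(sim$recordings, task_map = cfg$task_map)
  tb <- res$features
  # per-channel estimate: mean ratio over the subject's epochs/tasks
  agg <- aggregate(energy_ratio ~ channel + band, data = tb, FUN = mean)
  dev <- abs(agg$energy_ratio - fr[as.character(agg$band)])
  expect_true(all(dev <= 0.05),
              info = sprintf("max per-channel dev %.3f", max(dev)))
})

test_that("null configuration (no boosts) centres contrasts on zero", {
  diffs <- vapply(1:4, function(s) {
    cfg <- generator_config(n_subjects = 1, n_events = 4,
                            epoch_duration_s = 2,
                            band_fractions = c(delta = 0.5, theta = 0.2,
                                               alpha = 0.08, beta = 0.22),
                            seed = 100 + s)
    sim <- simulate_cohort(cfg)
    res <- run_pipeline(sim$recordings, task_map = cfg$task_map)
    hc <- res$contrasts$hemisphere
    hc$group_means[["left"]] - hc$group_means[["right"]]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})
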