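# Record-table parsing, montage metadata, sampling validation, epoching
# and feature-table round trips.

test_that("the montage partitions channels by hemisphere and region", {
  m <- default_montage()
  expect_setequal(m$channel,
                  c("Fp1", "Fp2", "T3", "T4", "C3", "C4", "O1", "O2"))
  left <- m$channel[m$hemisphere == "left"]
  right <- m$channel[m$hemisphere == "right"]
  expect_setequal(left, c("Fp1", "T3", "C3", "O1"))
  expect_setequal(right, c("Fp2", "T4", "C4", "O2"))
  expect_length(intersect(left, right), 0)
  expect_setequal(m$channel[m$region == "frontal"], c("Fp1", "Fp2"))
  expect_setequal(m$channel[m$region == "parietal"],
                  c("T3", "T4", "C3", "C4"))
  expect_setequal(m$channel[m$region == "occipital"], c("O1", "O2"))
  p <- montage_pairs(m)
  expect_equal(nrow(p), 4)
})

test_that("the printed sample rows parse with exact values", {
  path <- write_sample_records()
  recs <- read_records(path)
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_equal(rec$tester_id, 1) # "Number 01" normalized
  expect_equal(rec$time_s[1], 210.633)
  expect_equal(unname(rec$voltages[1, "Fp1"]), 33.925)
  expect_equal(unname(rec$voltages[1, "O2"]), -135.587)
  expect_equal(rec$baseline[1], -738.123)
  expect_identical(unique(rec$event_ids), 1L)
})

test_that("comma-separated dialect is sniffed from the header", {
  path <- write_sample_records(tempfile(fileext = ".csv"), delim = ",")
  rec <- read_records(path)[[1]]
  expect_equal(unname(rec$voltages[2, "Fp1"]), 25.359)
})

test_that("malformed record files fail with informative errors", {
  # 12 columns: baseline missing
  lines <- sample_record_lines()
  broken <- vapply(lines, function(l) sub("\t[^\t]*$", "", l), "")
  p <- tempfile()
  writeLines(broken, p)
  expect_error(read_records(p), "Baseline")

  # non-numeric voltage names the row
  lines2 <- sample_record_lines()
  lines2[3] <- sub("25.359", "oops", lines2[3], fixed = TRUE)
  p2 <- tempfile()
  writeLines(lines2, p2)
  expect_error(read_records(p2), "row 2")

  p3 <- tempfile()
  writeLines(character(0), p3)
  expect_error(read_records(p3), "empty")
  expect_error(read_records(tempfile()), "not found")
})

test_that("recordings survive a write-read round trip", {
  set.seed(7)
  rec <- eeg_recording(3, matrix(rnorm(40 * 8, sd = 50), 40), fs = 128,
                       event_ids = rep(c(1L, 2L), each = 20),
                       baseline = rnorm(40))
  path <- tempfile(fileext = ".tsv")
  write_records(rec, path)
  back <- read_records(path)[[1]]
  expect_equal(back$tester_id, 3)
  expect_equal(back$voltages, rec$voltages, tolerance = 1e-5)
  expect_equal(back$time_s, rec$time_s, tolerance = 1e-5)
  expect_equal(back$baseline, rec$baseline, tolerance = 1e-5)
  expect_identical(back$event_ids, rec$event_ids)
})

test_that("sampling validation accepts a 128 Hz grid and flags bad grids", {
  path <- write_sample_records()
  rec <- read_records(path)[[1]]
  report <- validate_sampling(rec)
  expect_true(report$pass)
  expect_equal(report$median_interval_s, 1 / 128, tolerance = 0.05)

  # generator time axis is n/fs by construction
  g <- generate_recording(generator_config(n_subjects = 1, n_events = 2,
                                           epoch_duration_s = 1), 1)
  expect_true(validate_sampling(g)$pass)

  # degenerate flat time axis (forced past the constructor)
  bad <- rec
  bad$time_s <- rep(1, length(bad$time_s))
  expect_false(validate_sampling(bad)$pass)
  expect_match(validate_sampling(bad)$message, "zero")

  one <- rec
  one$time_s <- one$time_s[1]
  expect_error(validate_sampling(one), "at least 2")

  # off-frequency grid fails the 5% band
  slow <- rec
  slow$time_s <- (seq_along(slow$time_s) - 1) / 100
  expect_false(validate_sampling(slow)$pass)
})

test_that("epoching splits contiguous runs and drops sub-minimum ones", {
  v <- matrix(rnorm(9 * 20 * 8), ncol = 8)
  rec <- eeg_recording(1, v, event_ids = rep(1:9, each = 20))
  eps <- epoch_by_event(rec)
  expect_length(eps, 9)
  expect_identical(vapply(eps, function(e) e$event_id, 1L), 1:9)
  expect_equal(sum(vapply(eps, function(e) nrow(e$voltages), 1L)), nrow(v))
  expect_identical(eps[[1]]$task_label, "online payment")
  expect_identical(eps[[2]]$task_label, "online chat")

  single <- eeg_recording(1, v, event_ids = rep(1L, nrow(v)))
  expect_length(epoch_by_event(single), 1)
  expect_equal(epoch_by_event(single)[[1]]$voltages, single$voltages,
               ignore_attr = TRUE)

  short <- eeg_recording(1, matrix(rnorm(30 * 8), 30),
                         event_ids = rep(c(1L, 2L), c(10, 20)))
  expect_warning(eps2 <- epoch_by_event(short), "below the 16-sample")
  expect_length(eps2, 1)

  inter <- eeg_recording(1, matrix(rnorm(60 * 8), 60),
                         event_ids = rep(c(1L, 2L, 1L), each = 20))
  expect_error(epoch_by_event(inter), "contiguous")

  # gap samples (id 0) are background, never epochs
  gappy <- eeg_recording(1, matrix(rnorm(60 * 8), 60),
                         event_ids = rep(c(0L, 5L, 0L), each = 20))
  eps3 <- epoch_by_event(gappy)
  expect_length(eps3, 1)
  expect_identical(eps3[[1]]$event_id, 5L)
})

test_that("feature tables round trip through CSV", {
  ref <- reference_feature_table()
  path <- tempfile(fileext = ".csv")
  write_features(ref, path)
  back <- read_features(path)
  expect_equal(nrow(back), 64) # 8 channels x 4 bands x 2 tasks
  merged <- merge(as.data.frame(ref), as.data.frame(back),
                  by = c("tester", "task", "channel", "band"))
  expect_equal(merged$rhythm_energy.x, merged$rhythm_energy.y,
               tolerance = 1e-9)
  expect_equal(merged$energy_ratio.x, merged$energy_ratio.y,
               tolerance = 1e-9)
  # channel-major ordering with bands low to high within channel
  expect_identical(back$channel[1:8],
                   rep(c("Fp1"), 8))
  expect_error(write_features(ref[0, ], path), "nrow")
  expect_error(read_features(path = tempfile()), "not found")
})
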