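# Reading, validating, epoching and writing record tables in the
# 13-column layout (tester, event, minutes, seconds, 8 channel voltages
# in microvolts, baseline), plus electrode montage metadata.

CHANNELS <- c("Fp1", "Fp2", "T3", "T4", "C3", "C4", "O1", "O2")

RECORD_COLUMNS <- c("Tester", "Event", "Minutes", "Seconds",
                    paste("Channel", 1:8), "Baseline")

#' Eight-electrode 10-20 montage
#'
#' The fixed montage used throughout: Fp1/Fp2 (frontal), T3/T4/C3/C4
#' (parietal), O1/O2 (occipital); odd labels form the left hemisphere,
#' even labels the right.
#'
#' @return A tibble of class `eeg_montage` with columns `channel`,
#'   `hemisphere` (`"left"`/`"right"`), `region`
#'   (`"frontal"`/`"parietal"`/`"occipital"`).
#' @examples
#' default_montage()
#' @export
default_montage <- function() {
  m <- tibble::tibble(
    channel = CHANNELS,
    hemisphere = rep(c("left", "right"), 4),
    region = c("frontal", "frontal", "parietal", "parietal",
               "parietal", "parietal", "occipital", "occipital"))
  class(m) <- c("eeg_montage", class(m))
  m
}

#' Homologous left-right electrode pairs of the montage
#' @param montage An `eeg_montage`.
#' @return Tibble with columns `left`, `right` (four pairs).
#' @export
montage_pairs <- function(montage = default_montage()) {
  tibble::tibble(
    left = montage$channel[montage$hemisphere == "left"],
    right = montage$channel[montage$hemisphere == "right"])
}

#' Multichannel EEG recording container
#'
#' One tester's continuous 8-channel voltage trace with per-sample event
#' labels and timestamps.
#'
#' @param tester_id Subject identifier (integer or string).
#' @param voltages Numeric samples x 8 matrix of channel voltages in
#'   microvolts; columns are taken in montage order.
#' @param fs Sampling frequency in Hz.
#' @param event_ids Integer per-sample event label, 0 (inter-stimulus
#'   gap) to 9.
#' @param time_s Per-sample timestamps in seconds; defaults to
#'   `(0:(n-1))/fs`.
#' @param baseline Per-sample baseline-electrode voltage (stored
#'   opaquely; not used by the pipeline, which re-references to the
#'   channel average). Defaults to 0.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(tester_id, voltages, fs = 128, event_ids,
                          time_s = NULL, baseline = NULL) {
  voltages <- as.matrix(voltages)
  n <- nrow(voltages)
  if (n == 0L) stop("recording has no samples", call. = FALSE)
  if (ncol(voltages) != 8L) {
    stop("expected 8 channels, got ", ncol(voltages), call. = FALSE)
  }
  dimnames(voltages) <- list(NULL, CHANNELS)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1L) / fs
  if (is.null(baseline)) baseline <- numeric(n)
  event_ids <- as.integer(event_ids)
  stopifnot(length(event_ids) == n, length(time_s) == n,
            length(baseline) == n)
  if (any(event_ids < 0L | event_ids > 9L)) {
    stop("event ids must lie in 0..9 (0 = inter-stimulus gap)",
         call. = FALSE)
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(
    list(tester_id = tester_id, event_ids = event_ids, time_s = time_s,
         voltages = voltages, baseline = baseline, fs = fs),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> tester %s: %d samples x 8 channels @ %g Hz, events %s\n",
              x$tester_id, nrow(x$voltages), x$fs,
              paste(sort(unique(x$event_ids[x$event_ids > 0L])),
                    collapse = ",")))
  invisible(x)
}

#' One epoch (event scene) of an EEG recording
#'
#' @param tester_id,event_id Identifiers.
#' @param task_label Task the event belongs to (free text, e.g.
#'   `"online payment"`).
#' @param voltages Samples x 8 matrix, microvolts.
#' @param fs Sampling frequency, Hz.
#' @return Object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(tester_id, event_id, task_label, voltages, fs = 128) {
  voltages <- as.matrix(voltages)
  stopifnot(ncol(voltages) == 8L)
  colnames(voltages) <- CHANNELS
  structure(
    list(tester_id = tester_id, event_id = as.integer(event_id),
         task_label = task_label, voltages = voltages, fs = fs),
    class = "eeg_epoch")
}

parse_tester_id <- function(x) {
  # "Number 01" -> 1; bare integers pass through; other strings verbatim
  x <- trimws(as.character(x))
  stripped <- sub("^[Nn]umber\\s*", "", x)
  num <- suppressWarnings(as.integer(stripped))
  ifelse(is.na(num), x, num)
}

sniff_delim <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read record tables
#'
#' Parses a delimited text file in the 13-column record layout
#' (`Tester, Event, Minutes, Seconds, Channel 1..8, Baseline`),
#' tab- or comma-separated (sniffed from the header line), and returns
#' one recording per tester. The `Seconds` column is treated as
#' authoritative absolute time; `Minutes` is checked for consistency
#' (within 1 s) and otherwise ignored.
#'
#' @param path Path to the record table.
#' @param fs Sampling frequency in Hz the file is declared at.
#' @return Named list of [eeg_recording()] objects, one per tester.
#' @export
read_records <- function(path, fs = 128) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty record file: ", path, call. = FALSE)
  delim <- sniff_delim(header)
  df <- read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) stop("record file has no data rows: ", path,
                           call. = FALSE)
  if (ncol(df) != 13L) {
    have <- names(df)
    missing <- setdiff(RECORD_COLUMNS, have)
    stop("expected the 13-column record layout (",
         paste(RECORD_COLUMNS, collapse = ", "), "); got ", ncol(df),
         " columns",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  names(df) <- RECORD_COLUMNS

  num_cols <- RECORD_COLUMNS[3:13]
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(gsub("−", "-", df[[cn]])))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad)) {
      stop("non-numeric value in column '", cn, "' at data row ", bad[1L],
           ": '", df[[cn]][bad[1L]], "'", call. = FALSE)
    }
    df[[cn]] <- v
  }
  df$Event <- as.integer(round(as.numeric(df$Event)))

  mismatch <- abs(df$Minutes * 60 - df$Seconds) > 1
  if (any(mismatch)) {
    warning(sum(mismatch), " rows where Minutes*60 and Seconds disagree ",
            "by more than 1 s; using Seconds", call. = FALSE)
  }

  tester <- parse_tester_id(df$Tester)
  out <- lapply(split(seq_len(nrow(df)), factor(tester, unique(tester))),
                function(ix) {
    eeg_recording(
      tester_id = tester[ix[1L]],
      voltages = as.matrix(df[ix, 5:12]),
      fs = fs,
      event_ids = df$Event[ix],
      time_s = df$Seconds[ix],
      baseline = df$Baseline[ix])
  })
  names(out) <- vapply(out, function(r) as.character(r$tester_id), "")
  out
}

#' Write recordings as a record table
#'
#' Inverse of [read_records()]: writes one or more recordings in the
#' 13-column layout. Voltages and seconds are printed with 6 decimals so
#' a write-read round trip is lossless to at least 6 significant digits.
#'
#' @param recordings A single `eeg_recording` or a list of them.
#' @param path Output path.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_records <- function(recordings, path, delim = "\t") {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  rows <- lapply(recordings, function(r) {
    id <- r$tester_id
    label <- if (is.numeric(id) || grepl("^[0-9]+$", id)) {
      sprintf("Number %02d", as.integer(id))
    } else as.character(id)
    data.frame(
      Tester = label,
      Event = r$event_ids,
      Minutes = sprintf("%.5f", r$time_s / 60),
      Seconds = sprintf("%.6f", r$time_s),
      V = matrix(sprintf("%.6f", r$voltages), nrow = nrow(r$voltages)),
      Baseline = sprintf("%.6f", r$baseline),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- RECORD_COLUMNS
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(RECORD_COLUMNS, collapse = delim), con)
  write.table(df, con, sep = delim, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Check the sampling grid of a recording
#'
#' Reports the median inter-sample interval and whether it is within
#' `tol` (default 5%) of the declared `1/fs`.
#'
#' @param rec An `eeg_recording`.
#' @param tol Relative tolerance on the median interval.
#' @return List of class `sampling_report`: `median_interval_s`,
#'   `expected_interval_s`, `pass`, `message`.
#' @export
validate_sampling <- function(rec, tol = 0.05) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$time_s) < 2L) {
    stop("need at least 2 samples to assess the sampling grid",
         call. = FALSE)
  }
  dt <- diff(rec$time_s)
  med <- median(dt)
  expected <- 1 / rec$fs
  if (med <= 0) {
    rep <- list(median_interval_s = med, expected_interval_s = expected,
                pass = FALSE,
                message = "zero or negative median inter-sample interval")
  } else {
    ok <- abs(med - expected) / expected <= tol
    rep <- list(
      median_interval_s = med, expected_interval_s = expected, pass = ok,
      message = sprintf(
        "median interval %.6f s vs expected %.6f s (%s %g%% tolerance)",
        med, expected, if (ok) "within" else "outside", 100 * tol))
  }
  structure(rep, class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf("<sampling_report> %s: %s\n",
              if (x$pass) "PASS" else "FAIL", x$message))
  invisible(x)
}

#' Split a recording into per-event epochs
#'
#' Cuts the recording at changes of the event label. Each non-gap event
#' id must form a single contiguous run. Runs shorter than `min_samples`
#' (default 16, the minimum for a four-level dyadic decomposition) are
#' dropped with a warning, as are gap runs (id 0) and events absent from
#' `task_map`.
#'
#' @param rec An `eeg_recording`.
#' @param task_map Named character vector mapping event id to task
#'   label, e.g. `c("1" = "online payment", "2" = "online chat")`.
#' @param min_samples Minimum epoch length in samples.
#' @return List of [eeg_epoch()] objects, in temporal order.
#' @export
epoch_by_event <- function(rec, task_map = default_task_map(),
                           min_samples = 16L) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$event_ids
  r <- rle(ev)
  nonzero <- r$values[r$values != 0L]
  if (anyDuplicated(nonzero)) {
    dup <- nonzero[duplicated(nonzero)][1L]
    stop("event ", dup, " appears in more than one run: event samples ",
         "must be contiguous", call. = FALSE)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    id <- r$values[i]
    if (id == 0L) next
    if (!as.character(id) %in% names(task_map)) next
    len <- r$lengths[i]
    if (len < min_samples) {
      warning("dropping event ", id, " of tester ", rec$tester_id, ": run of ",
              len, " samples is below the ", min_samples, "-sample minimum",
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- eeg_epoch(
      tester_id = rec$tester_id, event_id = id,
      task_label = unname(task_map[as.character(id)]),
      voltages = rec$voltages[starts[i]:ends[i], , drop = FALSE],
      fs = rec$fs)
  }
  out
}

#' Default event-to-task assignment
#'
#' Nine event scenes split between the two test tasks: odd scenes are
#' the visual online-payment task, even scenes the aural online-chat
#' task.
#'
#' @return Named character vector of length 9.
#' @export
default_task_map <- function() {
  stats::setNames(
    ifelse(seq_len(9) %% 2 == 1, "online payment", "online chat"),
    as.character(1:9))
}

FEATURE_COLUMNS <- c("tester", "task", "channel", "band",
                     "rhythm_energy", "energy_ratio")

#' Write / read a feature table
#'
#' CSV with columns `tester, task, channel, band, rhythm_energy,
#' energy_ratio` (plus `n_epochs` when present), ordered channel-major
#' with bands in delta, theta, alpha, beta order within each channel.
#'
#' @param table A feature table (see [compute_feature_table()]).
#' @param path Output path.
#' @return `path` invisibly (`write_features`); a tibble
#'   (`read_features`).
#' @export
write_features <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  missing <- setdiff(FEATURE_COLUMNS, names(table))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tb <- as.data.frame(table)
  tb <- tb[order(match(tb$tester, unique(tb$tester)),
                 match(tb$channel, CHANNELS),
                 match(tb$band, BAND_LEVELS),
                 tb$task), , drop = FALSE]
  tb$band <- as.character(tb$band)
  utils::write.csv(tb, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing)) {
    stop("not a feature table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$band <- factor(df$band, levels = BAND_LEVELS)
  tibble::as_tibble(df)
}
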