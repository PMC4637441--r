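# Rhythm energy and energy ratio features per channel, band and task.

#' Raw band energies of a packet tree
#'
#' Sums squared leaf coefficients over each band's frequency-ordered
#' leaf set. Because the transform is orthogonal (periodized), the sum
#' over all 16 leaves equals the signal energy.
#'
#' @param tree A `packet_tree` from [wpt_decompose()].
#' @param map A [band_map()].
#' @return List with `bands` (named numeric, microvolt^2 x samples) and
#'   `total` (energy over all leaves).
#' @export
band_energies <- function(tree, map = band_map(tree$fs, tree$levels)) {
  stopifnot(inherits(tree, "packet_tree"))
  leaves <- tree$coeffs[[tree$levels + 1L]]
  if (length(leaves) == 0L) stop("empty packet tree", call. = FALSE)
  leaf_energy <- vapply(leaves, function(z) sum(z^2), numeric(1))
  bands <- vapply(map, function(freq_idx) {
    sum(leaf_energy[natural_order(tree$levels, freq_idx) + 1L])
  }, numeric(1))
  list(bands = bands, total = sum(leaf_energy))
}

#' Normalized rhythm energy
#'
#' Each band's energy as a fraction of the total energy over all 16
#' subbands. The four values sum to less than 1 whenever the signal has
#' content in subbands outside the four rhythm bands.
#'
#' @param band_energy Named numeric of raw band energies (the `bands`
#'   element of [band_energies()]).
#' @param total_energy Total energy over all leaves.
#' @return Named numeric of fractions in `[0, 1]`.
#' @export
rhythm_energy <- function(band_energy, total_energy) {
  if (!is.finite(total_energy) || total_energy <= 0) {
    stop("degenerate signal: total energy is not positive", call. = FALSE)
  }
  band_energy / total_energy
}

#' Energy ratio across the four rhythm bands
#'
#' Each band's share of the summed energy of the four rhythm bands;
#' the ratios sum to exactly 1 and are invariant to amplifier gain.
#'
#' @param rhythm_energies Named numeric of the four per-band energies
#'   (raw or normalized; the ratio is the same).
#' @return Named numeric summing to 1.
#' @export
energy_ratio <- function(rhythm_energies) {
  s <- sum(rhythm_energies)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate signal: all band energies are zero", call. = FALSE)
  }
  rhythm_energies / s
}

#' Per-channel band features for a set of epochs
#'
#' For every preprocessed epoch and channel: packet-decompose, take band
#' energies, normalize to rhythm energy (share of all 16 subbands) and
#' energy ratio (share of the four rhythm bands), then average the
#' per-epoch values with an unweighted mean across epochs of the same
#' (tester, task).
#'
#' @param epochs List of preprocessed epochs ([preprocess_epoch()]);
#'   raw `eeg_epoch` objects are accepted but should normally be
#'   preprocessed first.
#' @param montage An `eeg_montage` (used to order channels).
#' @param spec A [wavelet_spec()].
#' @param map A [band_map()].
#' @return Tibble of class `feature_table` with columns `tester`,
#'   `task`, `channel`, `band` (ordered factor), `rhythm_energy`,
#'   `energy_ratio`, `n_epochs`.
#' @export
compute_feature_table <- function(epochs, montage = default_montage(),
                                  spec = wavelet_spec(),
                                  map = NULL) {
  if (length(epochs) == 0L) stop("no epochs to compute features from",
                                 call. = FALSE)
  per_epoch <- lapply(epochs, function(ep) {
    stopifnot(inherits(ep, "eeg_epoch"))
    m <- if (is.null(map)) band_map(ep$fs, spec$levels) else map
    rows <- lapply(montage$channel, function(ch) {
      tree <- wpt_decompose(ep$voltages[, ch], spec = spec, fs = ep$fs)
      be <- band_energies(tree, m)
      re <- rhythm_energy(be$bands, be$total)
      er <- energy_ratio(be$bands)
      tibble::tibble(
        tester = as.character(ep$tester_id), task = ep$task_label,
        channel = ch, band = names(m),
        rhythm_energy = unname(re), energy_ratio = unname(er))
    })
    dplyr::bind_rows(rows)
  })
  tb <- dplyr::bind_rows(per_epoch)
  tb <- dplyr::summarise(
    dplyr::group_by(tb, .data$tester, .data$task, .data$channel, .data$band),
    rhythm_energy = mean(.data$rhythm_energy),
    energy_ratio = mean(.data$energy_ratio),
    n_epochs = dplyr::n(), .groups = "drop")
  tb$band <- factor(tb$band, levels = BAND_LEVELS)
  tb <- dplyr::arrange(tb, .data$tester, .data$task,
                       match(.data$channel, CHANNELS), .data$band)
  class(tb) <- c("feature_table", class(tb))
  tb
}

#' Internal consistency of a printed feature table
#'
#' Recomputes each band's energy ratio from the rhythm-energy column
#' (band energy divided by the four-band sum, per channel and task) and
#' reports the largest absolute deviation from the tabulated ratio.
#' Useful to audit published rhythm-energy tables, where rounding or
#' transcription can break the ratio identity.
#'
#' @param table A feature table with `rhythm_energy` and `energy_ratio`
#'   columns.
#' @return Tibble with one row per (tester, task, channel) group:
#'   `max_abs_dev` of recomputed vs tabulated ratios.
#' @export
ratio_consistency <- function(table) {
  stopifnot(is.data.frame(table))
  grp <- dplyr::group_by(table, dplyr::across(dplyr::any_of("tester")),
                         .data$task, .data$channel)
  dplyr::summarise(
    grp,
    max_abs_dev = max(abs(
      .data$rhythm_energy / sum(.data$rhythm_energy) - .data$energy_ratio)),
    .groups = "drop")
}
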