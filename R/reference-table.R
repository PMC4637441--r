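# Published sample of rhythm energies and energy ratios from an
# 8-channel EEG study of information-security awareness, for two test
# tasks (task 1 = online payment, visual; task 2 = online chat, aural).
# Bundled as a reference for auditing the ratio identity
# energy_ratio = rhythm_energy / sum(four rhythm energies) and for
# shaping synthetic defaults.

# per channel: delta, theta, alpha, beta rows;
# columns: energy task1, energy task2, ratio task1, ratio task2
REFERENCE_VALUES <- c(
  # Fp1
  0.3266, 0.4593, 0.4801, 0.5872,
  0.1386, 0.1528, 0.2037, 0.1923,
  0.0555, 0.0396, 0.0817, 0.0517,
  0.1595, 0.1305, 0.2345, 0.1688,
  # Fp2
  0.3436, 0.4734, 0.5021, 0.5903,
  0.1525, 0.1609, 0.2229, 0.2007,
  0.0444, 0.0364, 0.0649, 0.0454,
  0.1437, 0.1312, 0.2101, 0.1636,
  # T3
  0.3304, 0.4834, 0.4740, 0.5988,
  0.1388, 0.1490, 0.1991, 0.1845,
  0.0559, 0.0388, 0.0802, 0.0472,
  0.1720, 0.1361, 0.2467, 0.1695,
  # T4
  0.3278, 0.4956, 0.4927, 0.6129,
  0.1385, 0.1523, 0.2081, 0.1884,
  0.0490, 0.0337, 0.0737, 0.0417,
  0.1501, 0.1270, 0.2255, 0.1570,
  # C3
  0.3174, 0.4906, 0.4572, 0.6088,
  0.1402, 0.1465, 0.2020, 0.1818,
  0.0569, 0.0390, 0.0820, 0.0384,
  0.1797, 0.1297, 0.2588, 0.1710,
  # C4
  0.3370, 0.4873, 0.5072, 0.6102,
  0.1307, 0.1536, 0.1968, 0.1923,
  0.0476, 0.0330, 0.0717, 0.0414,
  0.1490, 0.1247, 0.2243, 0.1561,
  # O1
  0.3126, 0.4733, 0.4833, 0.6001,
  0.1350, 0.1472, 0.2001, 0.1866,
  0.0573, 0.0378, 0.0849, 0.0479,
  0.1698, 0.1304, 0.2317, 0.1654,
  # O2
  0.3720, 0.5257, 0.5014, 0.6224,
  0.1482, 0.1534, 0.1998, 0.1816,
  0.0592, 0.0377, 0.0799, 0.0447,
  0.1624, 0.1278, 0.2189, 0.1513)

#' Published reference table of rhythm energies and energy ratios
#'
#' A tabulated per-channel sample of normalized rhythm energies and
#' energy ratios for the two online test tasks, as printed in the study
#' the pipeline reproduces. Used to audit the ratio identity (see
#' [ratio_consistency()]) and to choose realistic synthetic defaults.
#' Note the known internal inconsistencies of the printed source: the
#' O1 task-1 ratios and most task-2 ratio columns do not satisfy the
#' ratio identity from their printed energies, so consistency checks
#' restrict to the task-1 columns of the other seven channels.
#'
#' @return A tibble of class `feature_table` with 64 rows (8 channels x
#'   4 bands x 2 tasks): `tester` (`"reference"`), `task`, `channel`,
#'   `band`, `rhythm_energy`, `energy_ratio`.
#' @examples
#' ref <- reference_feature_table()
#' subset(ref, channel == "Fp1" & task == "online payment")
#' @export
reference_feature_table <- function() {
  m <- matrix(REFERENCE_VALUES, ncol = 4, byrow = TRUE)
  base <- tibble::tibble(
    channel = rep(CHANNELS, each = 4),
    band = rep(BAND_LEVELS, times = 8))
  tb <- dplyr::bind_rows(
    dplyr::mutate(base, tester = "reference", task = "online payment",
                  rhythm_energy = m[, 1], energy_ratio = m[, 3]),
    dplyr::mutate(base, tester = "reference", task = "online chat",
                  rhythm_energy = m[, 2], energy_ratio = m[, 4]))
  tb$band <- factor(tb$band, levels = BAND_LEVELS)
  tb <- tb[, c("tester", "task", "channel", "band",
               "rhythm_energy", "energy_ratio")]
  class(tb) <- c("feature_table", class(tb))
  tb
}

#' Channels whose printed task-1 columns satisfy the ratio identity
#' @return Character vector of seven channel labels (O1 excluded).
#' @export
reference_consistent_channels <- function() {
  setdiff(CHANNELS, "O1")
}
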