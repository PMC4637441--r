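# Descriptive contrasts of relative band power: hemispheric asymmetry,
# task differences, training-group differences, region summaries. No
# inferential statistics are attached: the contrasts are directional
# observations on mean energy ratios.

contrast_report <- function(band, grouping, group_means, detail, n) {
  dir <- NA_character_
  if (length(group_means) == 2L) {
    dir <- names(group_means)[which.max(group_means)]
  }
  structure(
    list(band = band, grouping = grouping, group_means = group_means,
         detail = detail, direction = dir, n = n),
    class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("<contrast_report> band %s by %s\n", x$band, x$grouping))
  means <- paste(sprintf("%s = %.4f", names(x$group_means), x$group_means),
                 collapse = ", ")
  cat("  group means:", means, "\n")
  if (!is.na(x$direction)) cat("  larger group:", x$direction, "\n")
  print(x$detail)
  invisible(x)
}

# mean ratio per channel for one band, optionally restricted to tasks
channel_means <- function(table, band, tasks = NULL) {
  tb <- table[as.character(table$band) == band, , drop = FALSE]
  if (!is.null(tasks)) tb <- tb[tb$task %in% tasks, , drop = FALSE]
  if (nrow(tb) == 0L) stop("no rows for band '", band, "'", call. = FALSE)
  dplyr::summarise(dplyr::group_by(tb, .data$channel),
                   energy_ratio = mean(.data$energy_ratio),
                   .groups = "drop")
}

#' Left-right hemispheric contrast of a band's energy ratio
#'
#' Compares homologous electrode pairs (Fp1-Fp2, T3-T4, C3-C4, O1-O2):
#' reports each left-minus-right difference of the mean energy ratio and
#' the hemisphere means.
#'
#' @param table A feature table ([compute_feature_table()]); ratios are
#'   averaged over testers and tasks (or the subset in `tasks`).
#' @param band Band name, default `"beta"` (the activity marker).
#' @param tasks Optional task labels to restrict to.
#' @param montage An `eeg_montage`.
#' @return A `contrast_report` whose `detail` lists the four pairwise
#'   differences.
#' @export
hemispheric_contrast <- function(table, band = "beta", tasks = NULL,
                                 montage = default_montage()) {
  cm <- channel_means(table, band, tasks)
  missing <- setdiff(montage$channel, cm$channel)
  if (length(missing)) {
    stop("feature table lacks channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs <- montage_pairs(montage)
  val <- stats::setNames(cm$energy_ratio, cm$channel)
  detail <- tibble::tibble(
    left = pairs$left, right = pairs$right,
    left_ratio = unname(val[pairs$left]),
    right_ratio = unname(val[pairs$right]),
    difference = unname(val[pairs$left] - val[pairs$right]))
  means <- c(left = mean(detail$left_ratio),
             right = mean(detail$right_ratio))
  contrast_report(band, "hemisphere", means, detail,
                  n = nrow(table[as.character(table$band) == band, ]))
}

#' Task contrast of a band's energy ratio
#'
#' Per-channel difference of mean energy ratio between two tasks, plus
#' the count of channels on which `task_a` exceeds `task_b`.
#'
#' @inheritParams hemispheric_contrast
#' @param task_a,task_b Task labels to compare (a minus b).
#' @return A `contrast_report`; `detail` holds per-channel differences
#'   and `n_channels_a_higher` is attached to the report.
#' @export
task_contrast <- function(table, band = "beta",
                          task_a = "online payment",
                          task_b = "online chat") {
  for (tk in c(task_a, task_b)) {
    if (!tk %in% table$task) stop("task '", tk, "' absent from the table",
                                  call. = FALSE)
  }
  ca <- channel_means(table, band, task_a)
  cb <- channel_means(table, band, task_b)
  common <- intersect(ca$channel, cb$channel)
  if (length(common) == 0L) stop("tasks share no channels", call. = FALSE)
  va <- stats::setNames(ca$energy_ratio, ca$channel)[common]
  vb <- stats::setNames(cb$energy_ratio, cb$channel)[common]
  detail <- tibble::tibble(channel = common,
                           ratio_a = unname(va), ratio_b = unname(vb),
                           difference = unname(va - vb))
  detail <- detail[order(match(detail$channel, CHANNELS)), ]
  means <- stats::setNames(c(mean(va), mean(vb)), c(task_a, task_b))
  rep <- contrast_report(band, "task", means, detail,
                         n = length(common))
  rep$n_channels_a_higher <- sum(detail$difference > 0)
  rep
}

#' Training-group contrast of a band's energy ratio
#'
#' Compares subjects who received information-security awareness
#' training with untrained subjects, using each subject's mean band
#' energy ratio (over channels and tasks) as the per-subject value.
#' Higher beta ratio is read as "more active".
#'
#' @inheritParams hemispheric_contrast
#' @param groups Named character vector mapping tester id to
#'   `"trained"` / `"untrained"`.
#' @return A `contrast_report`; `detail` lists per-subject values.
#' @export
group_contrast <- function(table, groups, band = "beta") {
  tb <- table[as.character(table$band) == band, , drop = FALSE]
  tb$group <- unname(groups[as.character(tb$tester)])
  if (any(is.na(tb$group))) {
    stop("testers without a group assignment: ",
         paste(unique(tb$tester[is.na(tb$group)]), collapse = ", "),
         call. = FALSE)
  }
  per_subject <- dplyr::summarise(
    dplyr::group_by(tb, .data$group, .data$tester),
    energy_ratio = mean(.data$energy_ratio), .groups = "drop")
  for (g in c("trained", "untrained")) {
    if (!g %in% per_subject$group) stop("group '", g, "' is empty",
                                        call. = FALSE)
  }
  means <- vapply(split(per_subject$energy_ratio, per_subject$group),
                  mean, numeric(1))
  contrast_report(band, "training", means[c("trained", "untrained")],
                  per_subject, n = nrow(per_subject))
}

#' Region summary of a band's energy ratio
#'
#' Mean ratio over the frontal, parietal and occipital channel sets,
#' with the left-parietal pair (T3, C3) reported separately.
#'
#' @inheritParams hemispheric_contrast
#' @return A `contrast_report`; `group_means` holds the three region
#'   means and `left_parietal` the T3/C3 mean.
#' @export
region_summary <- function(table, band = "beta", tasks = NULL,
                           montage = default_montage()) {
  cm <- channel_means(table, band, tasks)
  val <- stats::setNames(cm$energy_ratio, cm$channel)
  regions <- split(montage$channel, montage$region)
  means <- vapply(regions, function(ch) mean(val[ch], na.rm = TRUE),
                  numeric(1))
  detail <- tibble::tibble(channel = cm$channel,
                           energy_ratio = cm$energy_ratio)
  rep <- contrast_report(band, "region", means, detail, n = nrow(cm))
  rep$left_parietal <- mean(val[c("T3", "C3")])
  rep
}

#' Bar chart of a band's energy ratio per channel and task
#'
#' @param table A feature table.
#' @param band Band to plot.
#' @return A ggplot object (channels on x, one bar per task).
#' @export
plot_band_ratio <- function(table, band = "beta") {
  tb <- table[as.character(table$band) == band, , drop = FALSE]
  tb <- dplyr::summarise(
    dplyr::group_by(tb, .data$channel, .data$task),
    energy_ratio = mean(.data$energy_ratio), .groups = "drop")
  tb$channel <- factor(tb$channel, levels = CHANNELS)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$channel,
                                   y = .data$energy_ratio,
                                   fill = .data$task)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("%s energy ratio", band),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
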