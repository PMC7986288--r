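#' Per-chamber distance to the control group at one time point
#'
#' The screen's distance readout at a single time point: for a treated
#' chamber, the mean distance to all control chambers; for a control
#' chamber, the mean distance to the *other* control chambers (self
#' excluded). Including the controls' own self-distance is what later
#' allows expressing every chamber relative to a control level of 1.
#'
#' @param d An `"mbra_dist"` matrix over the samples of one time point.
#' @param metadata Metadata tibble covering those samples (`sample_id`,
#'   `chamber_id`, `treatment`).
#' @param control Treatment label of the untreated chambers.
#' @return Tibble with columns `chamber_id`, `treatment`, `value`.
#' @export
per_chamber_control_distance <- function(d, metadata, control = "control") {
  ids <- rownames(d)
  meta <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort("Distance matrix contains samples missing from metadata.")
  }
  is_ctrl <- meta$treatment == control
  if (sum(is_ctrl) < 2) {
    abort("Need >= 2 control chambers at every time point.")
  }
  value <- vapply(seq_along(ids), function(i) {
    others <- is_ctrl
    if (is_ctrl[i]) others[i] <- FALSE
    mean(d[i, others])
  }, numeric(1))
  tibble(chamber_id = meta$chamber_id, treatment = meta$treatment,
         value = value)
}

#' Distance-to-control trajectory for every chamber
#'
#' Builds the raw distance readout series: at each sampling time, computes
#' the pairwise distance matrix among that time point's samples and reduces
#' it with [per_chamber_control_distance()].
#'
#' @param ft A [feature_table()] holding all samples of one experiment.
#' @param metadata Metadata tibble for those samples.
#' @param metric,tree,normalized Passed to [distance_matrix()].
#' @param control Treatment label of the untreated chambers.
#' @return Series tibble: `chamber_id`, `treatment`, `time_h`, `value`.
#' @export
distance_to_control_series <- function(ft, metadata,
                                       metric = "jaccard", tree = NULL,
                                       normalized = TRUE,
                                       control = "control") {
  counts <- ft_counts(ft)
  meta <- metadata[metadata$sample_id %in% rownames(counts), ]
  purrr::map_dfr(sort(unique(meta$time_h)), function(t) {
    sub <- meta[meta$time_h == t, ]
    m <- counts[sub$sample_id, , drop = FALSE]
    d <- distance_matrix(feature_table(m), metric = metric, tree = tree,
                         normalized = normalized)
    dplyr::mutate(per_chamber_control_distance(d, sub, control = control),
                  time_h = t, .after = "treatment")
  })
}

#' Normalize a readout series to the control group
#'
#' First normalization stage: every chamber's value at time `t` is divided
#' by the mean of the control chambers' values at `t`, so the control group
#' averages exactly 1 at every time point and day-to-day drift common to
#' all chambers cancels.
#'
#' @param series Tibble with columns `chamber_id`, `treatment`, `time_h`,
#'   `value`.
#' @param control Treatment label of the untreated chambers.
#' @return The series with `value` rescaled.
#' @export
normalize_to_control <- function(series, control = "control") {
  ctrl <- series |>
    dplyr::filter(.data$treatment == control) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(.ctrl_mean = mean(.data$value), .groups = "drop")
  if (nrow(ctrl) == 0) abort("No control chambers in series.")
  bad <- ctrl$time_h[!is.finite(ctrl$.ctrl_mean) | ctrl$.ctrl_mean <= 0]
  if (length(bad) > 0) {
    abort(paste0("Control mean is not positive at t = ", bad[1], " h."))
  }
  missing <- setdiff(unique(series$time_h), ctrl$time_h)
  if (length(missing) > 0) {
    abort(paste0("No control values at t = ", missing[1], " h."))
  }
  series |>
    dplyr::left_join(ctrl, by = "time_h") |>
    dplyr::mutate(value = .data$value / .data$.ctrl_mean) |>
    dplyr::select(-".ctrl_mean")
}

#' Normalize a readout series to its pre-treatment baseline
#'
#' Second normalization stage, applied after [normalize_to_control()]:
#' every chamber's whole trajectory is divided by its *treatment group's*
#' mean value at the baseline time (24 h), so each group averages exactly 1
#' at baseline and pre-existing between-group offsets cancel. The control
#' group, already at mean 1 everywhere, is unchanged.
#'
#' @param series Control-normalized series tibble.
#' @param baseline_time Baseline sampling time in hours (default 24).
#' @return The series with `value` rescaled.
#' @export
normalize_to_baseline <- function(series, baseline_time = 24) {
  base <- series |>
    dplyr::filter(.data$time_h == baseline_time) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(.base_mean = mean(.data$value), .groups = "drop")
  missing <- setdiff(unique(series$treatment), base$treatment)
  if (length(missing) > 0) {
    abort(paste0("Treatment '", missing[1], "' has no sample at the ",
                 baseline_time, "-h baseline."))
  }
  if (any(!is.finite(base$.base_mean) | base$.base_mean <= 0)) {
    abort("Baseline group mean must be positive.")
  }
  series |>
    dplyr::left_join(base, by = "treatment") |>
    dplyr::mutate(value = .data$value / .data$.base_mean) |>
    dplyr::select(-".base_mean")
}

#' Trapezoid area under a trajectory over a phase window
#'
#' Integrates the piecewise-linear trajectory over `[t_start, t_end]` by
#' the trapezoidal rule, in value-hours. The trajectory must contain
#' points at both window boundaries: the boundary samples anchor both
#' adjacent phases, which makes AUCs additive across the shared boundary.
#'
#' @param time_h,value Numeric vectors describing one chamber's trajectory.
#' @param window Numeric `c(t_start, t_end)` in hours.
#' @return AUC in value-hours.
#' @export
#' @examples
#' trapezoid_auc(c(72, 120, 216), c(1, 1, 1), c(72, 216))  # 144
trapezoid_auc <- function(time_h, value, window) {
  seg <- window_segment(time_h, value, window)
  sum(diff(seg$t) * (head(seg$y, -1) + seg$y[-1]) / 2)
}

#' Above- and below-baseline AUC over a phase window
#'
#' Decomposes the deviation from baseline into the area above
#' (`max(y - baseline, 0)`) and below (`max(baseline - y, 0)`) the
#' baseline, splitting piecewise-linear segments exactly at baseline
#' crossings before integrating, so `auc_above - auc_below` equals the
#' trapezoid AUC of `y - baseline` to machine precision. Used for readouts
#' that can move in either direction (density, alpha diversity, bioassays).
#'
#' @inheritParams trapezoid_auc
#' @param baseline Baseline level (1 = the control level after
#'   normalization).
#' @return Named numeric `c(auc_above, auc_below)`, both >= 0, value-hours.
#' @export
#' @examples
#' phase_auc_above_below(c(72, 216), c(0.5, 1.5), c(72, 216))  # 18, 18
phase_auc_above_below <- function(time_h, value, window, baseline = 1) {
  seg <- window_segment(time_h, value, window)
  t <- seg$t
  y <- seg$y - baseline
  # insert exact crossing points where consecutive deviations change sign
  tt <- t[1]
  yy <- y[1]
  for (i in seq_len(length(t) - 1)) {
    if (y[i] * y[i + 1] < 0) {
      tc <- t[i] + (t[i + 1] - t[i]) * y[i] / (y[i] - y[i + 1])
      tt <- c(tt, tc)
      yy <- c(yy, 0)
    }
    tt <- c(tt, t[i + 1])
    yy <- c(yy, y[i + 1])
  }
  dt <- diff(tt)
  above <- sum(dt * (pmax(head(yy, -1), 0) + pmax(yy[-1], 0)) / 2)
  below <- sum(dt * (pmax(-head(yy, -1), 0) + pmax(-yy[-1], 0)) / 2)
  c(auc_above = above, auc_below = below)
}

window_segment <- function(time_h, value, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(t_start, t_end) with t_start < t_end.")
  }
  o <- order(time_h)
  time_h <- time_h[o]
  value <- value[o]
  if (anyDuplicated(time_h)) abort("Trajectory times must be strictly increasing.")
  if (any(!is.finite(value))) abort("Trajectory values must be finite.")
  keep <- time_h >= window[1] & time_h <= window[2]
  t <- time_h[keep]
  if (length(t) == 0 || abs(t[1] - window[1]) > 1e-9 ||
      abs(t[length(t)] - window[2]) > 1e-9) {
    abort(paste0("Trajectory lacks a sample at a window boundary (",
                 window[1], " or ", window[2], " h)."))
  }
  list(t = t, y = value[keep])
}

#' Score one readout into per-chamber phase AUCs
#'
#' The full scoring composition for one readout: control normalization,
#' baseline normalization, then per-chamber trapezoid AUC plus
#' above/below-baseline decomposition over each phase window. Distance
#' readouts should enter as raw per-chamber distance-to-control series
#' (from [distance_to_control_series()]); scalar readouts (density, alpha
#' diversity, bioassay levels) as raw per-chamber values.
#'
#' @param series Raw series tibble: `chamber_id`, `treatment`, `time_h`,
#'   `value`.
#' @param readout Readout name recorded in the output.
#' @param windows Named list of phase windows (default [phase_windows()]).
#' @param baseline_time Baseline time passed to [normalize_to_baseline()].
#' @param control Treatment label of the untreated chambers.
#' @return Tibble of class `mbra_auc`: `chamber_id`, `treatment`,
#'   `readout`, `phase`, `auc`, `auc_above`, `auc_below`.
#' @export
score_readout <- function(series, readout, windows = phase_windows(),
                          baseline_time = 24, control = "control") {
  norm <- series |>
    normalize_to_control(control = control) |>
    normalize_to_baseline(baseline_time = baseline_time)
  out <- purrr::map_dfr(names(windows), function(ph) {
    w <- windows[[ph]]
    norm |>
      dplyr::group_by(.data$chamber_id, .data$treatment) |>
      dplyr::summarise(
        phase = ph,
        auc = trapezoid_auc(.data$time_h, .data$value, w),
        auc_above = phase_auc_above_below(.data$time_h, .data$value,
                                          w)[["auc_above"]],
        auc_below = phase_auc_above_below(.data$time_h, .data$value,
                                          w)[["auc_below"]],
        .groups = "drop")
  })
  out <- dplyr::mutate(out, readout = readout, .after = "treatment")
  class(out) <- c("mbra_auc", class(out))
  out
}
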