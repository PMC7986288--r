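#' Raw per-chamber readout series of an experiment
#'
#' Extracts, for one simulated or assembled experiment, the raw trajectory
#' of a readout per chamber: qPCR-derived relative density, per-sample
#' alpha diversity (Pielou evenness or observed features),
#' distance-to-control for the composition metrics, or reporter-assay
#' analyte levels.
#'
#' @param experiment An `mbra_experiment` from [generate_experiment()].
#' @param readout One of `"density"`, `"evenness"`, `"observed"`,
#'   `"jaccard"`, `"unweighted_unifrac"`, `"weighted_unifrac"`, `"lps"`,
#'   `"flic"`.
#' @return Series tibble: `chamber_id`, `treatment`, `time_h`, `value`.
#' @export
readout_series <- function(experiment,
                           readout = c("density", "evenness", "observed",
                                       "jaccard", "unweighted_unifrac",
                                       "weighted_unifrac", "lps", "flic")) {
  readout <- match.arg(readout)
  meta <- experiment$metadata
  if (readout %in% c("jaccard", "unweighted_unifrac", "weighted_unifrac")) {
    return(distance_to_control_series(
      experiment$feature_table, meta, metric = readout,
      tree = experiment$tree))
  }
  if (readout == "density") {
    curve <- fit_qpcr_standard_curve(experiment$qpcr_standards)
    vals <- tibble(sample_id = experiment$cq$sample_id,
                   value = quantify_density(experiment$cq$cq, curve))
  } else if (readout %in% c("evenness", "observed")) {
    m <- ft_counts(experiment$feature_table)
    fun <- if (readout == "evenness") pielou_evenness else observed_features
    vals <- tibble(sample_id = rownames(m),
                   value = apply(m, 1, fun))
  } else {
    an <- c(lps = "LPS", flic = "FliC")[[readout]]
    q <- quantify_bioactive_table(
      dplyr::filter(experiment$plate_readings, .data$analyte == an),
      experiment$reporter_standards)
    vals <- tibble(sample_id = q$sample_id, value = q$concentration)
  }
  meta |>
    dplyr::inner_join(vals, by = "sample_id") |>
    dplyr::select("chamber_id", "treatment", "time_h", "value")
}

#' Score all readouts of an experiment into phase AUCs
#'
#' Runs the full scoring chain ([normalize_to_control()],
#' [normalize_to_baseline()], phase AUCs) for each requested readout, and
#' appends the single-time-point transcriptome distance-to-control (tested
#' as a plain value in the treatment phase, since it is measured only at
#' 120 h) when `"transcriptome"` is requested.
#'
#' @param experiment An `mbra_experiment`.
#' @param readouts Character vector of readout names (see
#'   [readout_series()]; may also include `"transcriptome"`).
#' @param windows Phase windows (default [phase_windows()]).
#' @param baseline_time Baseline normalization time (default 24 h).
#' @return An `mbra_auc` tibble covering all requested readouts.
#' @export
score_experiment <- function(experiment,
                             readouts = c("density", "jaccard",
                                          "weighted_unifrac", "evenness",
                                          "lps", "flic"),
                             windows = phase_windows(),
                             baseline_time = 24) {
  plain <- setdiff(readouts, "transcriptome")
  out <- purrr::map_dfr(plain, function(rd) {
    score_readout(readout_series(experiment, rd), readout = rd,
                  windows = windows, baseline_time = baseline_time)
  })
  if ("transcriptome" %in% readouts) {
    tr <- transcript_distance_to_control(
      experiment$transcripts,
      experiment$metadata) |>
      dplyr::mutate(readout = "transcriptome", phase = "treatment",
                    auc = .data$value, auc_above = NA_real_,
                    auc_below = NA_real_) |>
      dplyr::select("chamber_id", "treatment", "readout", "phase",
                    "auc", "auc_above", "auc_below")
    out <- dplyr::bind_rows(out, tr)
  }
  class(out) <- c("mbra_auc", class(out))
  out
}

#' Run the full synthetic screen end to end
#'
#' Simulates each configured experiment, scores every requested readout
#' into phase AUCs, compares each treatment to its own experiment's
#' controls (treatments are never compared across experiments), pools the
#' comparison grids, and builds the impact summary and ranking. With
#' `out_dir` set, every stage's table is written as TSV together with a
#' JSON manifest recording the parameters and output file checksums.
#'
#' @param configs A [simulation_config()] or list of them (one per
#'   independent experiment; give each a distinct `experiment_id` and
#'   seed).
#' @param readouts Readouts to score (see [score_experiment()]).
#' @param alpha Significance level (default 0.05).
#' @param windows Phase windows.
#' @param out_dir Optional output directory for TSV artifacts + manifest.
#' @return List of class `mbra_screen`: `experiments`, `auc`,
#'   `comparisons` (`mbra_comparisons`), `impact` (`mbra_impact`).
#' @export
run_pipeline <- function(configs,
                         readouts = c("density", "jaccard",
                                      "weighted_unifrac", "evenness",
                                      "lps", "flic", "transcriptome"),
                         alpha = 0.05, windows = phase_windows(),
                         out_dir = NULL) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  experiments <- lapply(configs, generate_experiment)
  auc <- purrr::map_dfr(experiments, function(ex) {
    dplyr::mutate(score_experiment(ex, readouts = readouts,
                                   windows = windows),
                  experiment_id = ex$config$experiment_id)
  })
  comparisons <- purrr::map_dfr(experiments, function(ex) {
    a <- auc[auc$experiment_id == ex$config$experiment_id, ]
    if (length(unique(a$treatment)) < 2) return(NULL)
    tidy(compare_to_control(a, alpha = alpha))
  })
  class(comparisons) <- c("mbra_comparisons", class(comparisons))
  attr(comparisons, "alpha") <- alpha
  impact <- build_impact_summary(comparisons)
  res <- structure(list(experiments = experiments, auc = auc,
                        comparisons = comparisons, impact = impact),
                   class = "mbra_screen")
  if (!is.null(out_dir)) write_screen(res, out_dir, alpha = alpha)
  res
}

write_screen <- function(res, out_dir, alpha) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(auc = file.path(out_dir, "auc.tsv"),
             comparisons = file.path(out_dir, "comparisons.tsv"),
             impact_classes = file.path(out_dir, "impact_classes.tsv"),
             impact_ranking = file.path(out_dir, "impact_ranking.tsv"))
  readr::write_tsv(res$auc, paths[["auc"]])
  readr::write_tsv(tidy(res$comparisons), paths[["comparisons"]])
  readr::write_tsv(res$impact$classes, paths[["impact_classes"]])
  readr::write_tsv(res$impact$ranking, paths[["impact_ranking"]])
  for (ex in res$experiments) {
    id <- ex$config$experiment_id
    p <- file.path(out_dir, paste0(id, "_feature_table.tsv"))
    write_feature_table(ex$feature_table, p)
    m <- file.path(out_dir, paste0(id, "_metadata.tsv"))
    write_metadata(ex$metadata, m)
    tw <- file.path(out_dir, paste0(id, "_tree.nwk"))
    ape::write.tree(ex$tree, tw)
    paths <- c(paths, setNames(c(p, m, tw),
                               paste0(id, c("_table", "_meta", "_tree"))))
  }
  manifest <- list(
    stage = "run_pipeline",
    parameters = list(
      alpha = alpha,
      seeds = vapply(res$experiments,
                     function(ex) ex$config$seed, numeric(1)),
      experiment_ids = vapply(res$experiments,
                              function(ex) ex$config$experiment_id, ""),
      phase_windows = phase_windows(),
      baseline_time_h = 24),
    outputs = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mbra_screen <- function(x, ...) {
  cat("MBRA screen:", length(x$experiments), "experiment(s),",
      length(unique(x$auc$readout)), "readouts\n")
  print(x$impact)
  invisible(x)
}
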