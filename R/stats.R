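#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within variance
#' decomposition) via [stats::lm()]/[stats::anova()], returning the F
#' statistic and its p value. Requires at least two groups of at least two
#' values each and non-degenerate within-group variance.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (coerced to factor), same length.
#' @return List with `f`, `p`, `df_between`, `df_within`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$f  # 13.5
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) abort("Need >= 2 groups.")
  if (any(table(group) < 2)) abort("Every group needs >= 2 values.")
  if (var(values) == 0) {
    abort("Degenerate input: total variance is zero.")
  }
  tab <- anova(lm(values ~ group))
  if (tab$`Mean Sq`[2] == 0) {
    abort("Degenerate input: zero within-group variance everywhere.")
  }
  list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Compare every treatment to control with Bonferroni correction
#'
#' Within each readout x phase family: an omnibus one-way ANOVA across all
#' groups, then pairwise treatment-versus-control t tests using the pooled
#' within-group variance (the ANOVA mean square error), with each raw p
#' multiplied by the number of treatments (Bonferroni) and capped at 1 —
#' the standard "ANOVA with Bonferroni's multiple comparisons" many-to-one
#' procedure. Corrections are applied within each readout x phase family
#' only, never across readouts.
#'
#' @param auc An `mbra_auc` tibble from [score_readout()] (or any tibble
#'   with columns `treatment`, `readout`, `phase` and the value column).
#' @param value Name of the value column to test (default `"auc"`).
#' @param alpha Significance level (default 0.05).
#' @param control Treatment label of the untreated chambers.
#' @return Object of class `mbra_comparisons`: a tibble with one row per
#'   treatment x readout x phase carrying group means, SEMs, the omnibus F,
#'   raw and Bonferroni-adjusted p values, and a `significant` flag.
#' @export
compare_to_control <- function(auc, value = "auc", alpha = 0.05,
                               control = "control") {
  stopifnot(value %in% names(auc))
  out <- auc |>
    dplyr::group_by(.data$readout, .data$phase) |>
    dplyr::group_modify(function(df, key) {
      if (!control %in% df$treatment) {
        abort(paste0("No control group for readout ", key$readout,
                     ", phase ", key$phase, "."))
      }
      compare_family(df$treatment, df[[value]], control)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_adjusted <= alpha) |>
    dplyr::relocate("treatment")
  attr(out, "alpha") <- alpha
  attr(out, "control") <- control
  class(out) <- c("mbra_comparisons", class(out))
  out
}

compare_family <- function(group, values, control) {
  group <- factor(group)
  treatments <- setdiff(levels(group), control)
  fit <- anova(lm(values ~ group))
  mse <- fit$`Mean Sq`[2]
  df_within <- fit$Df[2]
  n <- table(group)
  mu <- tapply(values, group, mean)
  sem <- tapply(values, group, function(v) sd(v) / sqrt(length(v)))
  k <- length(treatments)
  purrr::map_dfr(treatments, function(tr) {
    se <- sqrt(mse * (1 / n[[tr]] + 1 / n[[control]]))
    tstat <- if (se == 0) 0 else (mu[[tr]] - mu[[control]]) / se
    p_raw <- if (se == 0) 1 else 2 * pt(-abs(tstat), df_within)
    mean_tr <- mu[[tr]]
    sem_tr <- sem[[tr]]
    mean_ctrl <- mu[[control]]
    sem_ctrl <- sem[[control]]
    tibble(treatment = tr,
           mean = mean_tr, sem = sem_tr,
           control_mean = mean_ctrl, control_sem = sem_ctrl,
           f_statistic = fit$`F value`[1],
           p_omnibus = fit$`Pr(>F)`[1],
           t_statistic = tstat,
           p_raw = p_raw,
           p_adjusted = min(1, p_raw * k))
  })
}

#' Classify the reversibility of a treatment effect
#'
#' From the two phase-level significance flags of one treatment x readout:
#' no significant phase is `"none"`; significant during exposure only is
#' `"reversible"`; significant in the post phase — whether carried over
#' from the exposure phase or late-emerging — is `"non_reversible"`,
#' because the effect outlives the exposure either way.
#'
#' @param sig_treatment,sig_post Logical flags (vectorized).
#' @return Factor with levels `none`, `reversible`, `non_reversible`.
#' @export
#' @examples
#' classify_reversibility(TRUE, FALSE)  # reversible
classify_reversibility <- function(sig_treatment, sig_post) {
  cls <- dplyr::case_when(
    !sig_treatment & !sig_post ~ "none",
    sig_treatment & !sig_post ~ "reversible",
    .default = "non_reversible")
  factor(cls, levels = c("none", "reversible", "non_reversible"))
}

#' Summarize a comparison grid into impact classes and ranking
#'
#' Collapses a full treatment x readout x phase comparison grid into one
#' reversibility class per treatment x readout, an impact score per
#' treatment (the count of significant readout x phase cells), and a rank
#' ordering from lowest to highest impact (ties broken alphabetically).
#' Readouts measured in only one phase (e.g. a single-time-point
#' transcriptome distance) are classified with the missing phase treated
#' as not significant.
#'
#' @param comparisons An `mbra_comparisons` tibble from
#'   [compare_to_control()].
#' @return Object of class `mbra_impact`: list with `classes` (tibble:
#'   `treatment`, `readout`, `sig_treatment`, `sig_post`, `class`) and
#'   `ranking` (tibble: `treatment`, `impact_score`, `rank`).
#' @export
build_impact_summary <- function(comparisons) {
  classes <- comparisons |>
    dplyr::group_by(.data$treatment, .data$readout) |>
    dplyr::summarise(
      sig_treatment = any(.data$significant[.data$phase == "treatment"]),
      sig_post = any(.data$significant[.data$phase == "post"]),
      .groups = "drop") |>
    dplyr::mutate(
      sig_treatment = dplyr::coalesce(.data$sig_treatment, FALSE),
      sig_post = dplyr::coalesce(.data$sig_post, FALSE),
      class = classify_reversibility(.data$sig_treatment, .data$sig_post))
  ranking <- comparisons |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(impact_score = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::arrange(.data$impact_score, .data$treatment) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(classes = classes, ranking = ranking),
            class = "mbra_impact")
}

#' @export
print.mbra_impact <- function(x, ...) {
  cat("MBRA impact summary:", nrow(x$ranking), "treatments,",
      length(unique(x$classes$readout)), "readouts\n")
  print(x$ranking)
  invisible(x)
}

#' Tidy methods for screen result objects
#'
#' `tidy()` on an `mbra_comparisons` returns the comparison grid as a plain
#' tibble; on an `mbra_impact` it returns the per-cell class table.
#' `glance()` gives one-row summaries.
#'
#' @param x An `mbra_comparisons` or `mbra_impact` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mbra_comparisons <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mbra_comparisons")
  as_tibble(out)
}

#' @rdname tidy.mbra_comparisons
#' @export
glance.mbra_comparisons <- function(x, ...) {
  tibble(n_comparisons = nrow(x),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha") %||% NA_real_,
         n_treatments = length(unique(x$treatment)),
         n_readouts = length(unique(x$readout)))
}

#' @rdname tidy.mbra_comparisons
#' @export
tidy.mbra_impact <- function(x, ...) {
  dplyr::left_join(x$classes, x$ranking, by = "treatment")
}

#' @rdname tidy.mbra_comparisons
#' @export
glance.mbra_impact <- function(x, ...) {
  tibble(n_treatments = nrow(x$ranking),
         n_affected = sum(x$ranking$impact_score > 0),
         max_impact_score = max(c(0, x$ranking$impact_score)))
}
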