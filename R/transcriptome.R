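#' Quality-filter sequencing reads
#'
#' Keeps a read if and only if the fraction of bases with Phred quality at
#' or above `min_q` is at least `min_percent` percent of its length
#' (inclusive at the boundary: a 10-base read with exactly 8 bases >= Q28
#' passes the default 80% rule). Read order is preserved; empty reads are
#' dropped with a warning. Filtering is idempotent.
#'
#' @param reads Tibble with columns `id`, `sequence`, `quality` (Phred+33),
#'   as from [read_fastq()].
#' @param min_q Minimum per-base quality score (default 28).
#' @param min_percent Minimum percentage of qualifying bases (default 80).
#' @return The kept reads, same columns, original order.
#' @export
quality_filter <- function(reads, min_q = 28, min_percent = 80) {
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$quality)
  if (any(len == 0)) {
    warn(paste0("Dropping ", sum(len == 0), " empty read(s)."))
  }
  frac <- vapply(phred_scores(reads$quality), function(q) {
    if (length(q) == 0) return(-1)
    sum(q >= min_q) / length(q)
  }, numeric(1))
  reads[frac * 100 >= min_percent & len > 0, ]
}

#' Transcript distance to control at a single time point
#'
#' Bray-Curtis distance separating each chamber's transcript profile from
#' the untreated chambers, at the one sampling time where transcriptomes
#' are collected (mid-exposure, 120 h). A single time point yields one
#' value per chamber rather than an AUC.
#'
#' @param transcripts A [feature_table()] of per-sample transcript (gene
#'   family) relative abundances at one time point.
#' @param metadata Metadata tibble covering those samples.
#' @param control Treatment label of the untreated chambers.
#' @return Tibble: `chamber_id`, `treatment`, `value` (Bray-Curtis
#'   distance to control).
#' @export
transcript_distance_to_control <- function(transcripts, metadata,
                                           control = "control") {
  d <- distance_matrix(transcripts, metric = "bray_curtis")
  meta <- metadata[metadata$sample_id %in% rownames(d), ]
  per_chamber_control_distance(d, meta, control = control)
}

#' Volcano classification of gene families
#'
#' For each gene family, the log2 fold change of the treated group mean
#' over the control group mean (both offset by a pseudocount equal to half
#' the smallest positive abundance in either table), a two-sided Welch t
#' test on the per-replicate relative abundances, and Benjamini-Hochberg q
#' values across families. A family is `up` when `log2fc >= lfc_threshold`
#' (inclusive — "at least" a 16-fold change at the default of 4) and
#' `q < q_threshold` (strict); `down` symmetrically; otherwise `ns`.
#'
#' @param treated,control_tbl [feature_table()]s of relative abundances
#'   with >= 2 replicate samples each, over the same families.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 4).
#' @param q_threshold BH q-value threshold (default 0.1).
#' @return Tibble of class `mbra_volcano`: `family_id`, `log2fc`, `p`,
#'   `q`, `class` (factor `up`/`down`/`ns`).
#' @export
volcano <- function(treated, control_tbl, lfc_threshold = 4,
                    q_threshold = 0.1) {
  mt <- ft_counts(treated)
  mc <- ft_counts(control_tbl)
  if (!setequal(colnames(mt), colnames(mc))) {
    abort("Treated and control tables cover different families.")
  }
  mc <- mc[, colnames(mt), drop = FALSE]
  if (nrow(mt) < 2 || nrow(mc) < 2) {
    abort("Volcano needs >= 2 replicates per group.")
  }
  pos <- c(mt[mt > 0], mc[mc > 0])
  if (length(pos) == 0) abort("All abundances are zero.")
  eps <- min(pos) / 2
  stats_per_family <- purrr::map_dfr(colnames(mt), function(f) {
    a <- mt[, f]
    b <- mc[, f]
    lfc <- log2((mean(a) + eps) / (mean(b) + eps))
    p <- if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      t.test(a, b)$p.value          # Welch by default
    }
    tibble(family_id = f, log2fc = lfc, p = p)
  })
  out <- stats_per_family |>
    dplyr::mutate(
      q = p.adjust(.data$p, method = "BH"),
      class = classify_volcano(.data$log2fc, .data$q, lfc_threshold,
                               q_threshold))
  class(out) <- c("mbra_volcano", class(out))
  out
}

#' Volcano class from fold change and q value
#'
#' The classification rule on its own: `up` needs `log2fc >= lfc_threshold`
#' (inclusive, "at least" a 16-fold change at the default threshold of 4)
#' and `q < q_threshold` (strict); `down` is symmetric; anything else is
#' `ns`.
#'
#' @param log2fc,q Numeric vectors.
#' @param lfc_threshold,q_threshold Thresholds (defaults 4 and 0.1).
#' @return Factor with levels `up`, `down`, `ns`.
#' @export
#' @examples
#' classify_volcano(c(4, 5, -4), c(0.05, 0.1, 0.099))  # up, ns, down
classify_volcano <- function(log2fc, q, lfc_threshold = 4,
                             q_threshold = 0.1) {
  factor(dplyr::case_when(
    log2fc >= lfc_threshold & q < q_threshold ~ "up",
    log2fc <= -lfc_threshold & q < q_threshold ~ "down",
    .default = "ns"), levels = c("up", "down", "ns"))
}
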