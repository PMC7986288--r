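#' Fit a qPCR standard curve
#'
#' Least-squares line `Cq = slope * log10(quantity) + intercept` through
#' standards of known template quantity. Amplification efficiency is
#' `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope -3.3219
#' and efficiency 1. Slopes must be negative (more template, earlier Cq)
#' and the implied efficiency must lie in (0, 1.2].
#'
#' @param standards Data frame with columns `log10_quantity` and `cq`
#'   (e.g. the standard rows of [read_cq_table()]).
#' @return An object of class `qpcr_curve` with elements `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `n`.
#' @export
#' @examples
#' s <- tibble::tibble(log10_quantity = 0:4, cq = 30 - 3.3219 * (0:4))
#' fit_qpcr_standard_curve(s)$efficiency
fit_qpcr_standard_curve <- function(standards) {
  ok <- is.finite(standards$log10_quantity) & is.finite(standards$cq)
  standards <- standards[ok, ]
  if (length(unique(standards$log10_quantity)) < 3) {
    abort("Need standards at >= 3 distinct quantities to fit a curve.")
  }
  fit <- lm(cq ~ log10_quantity, data = standards)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    abort("Invalid standards: qPCR slope must be negative.")
  }
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.2) {
    abort(sprintf("Implied efficiency %.3f outside (0, 1.2].", eff))
  }
  sst <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = eff,
                 r_squared = r2,
                 n = nrow(standards)),
            class = "qpcr_curve")
}

#' Quantify relative 16S copies from Cq values
#'
#' Inverts the standard curve: `quantity = 10^((cq - intercept) / slope)`.
#' Units are arbitrary; downstream use is always the ratio to control
#' chambers, so they cancel.
#'
#' @param cq Numeric vector of quantification cycles.
#' @param curve A `qpcr_curve` from [fit_qpcr_standard_curve()].
#' @return Numeric vector of relative template quantities.
#' @export
quantify_density <- function(cq, curve) {
  stopifnot(inherits(curve, "qpcr_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Build a reporter-assay standard curve
#'
#' Monotone piecewise-linear interpolant of OD620 against log10
#' concentration over the declared linear range of purified-standard
#' readings. Interpolation (rather than a parametric 4PL fit) is
#' assumption-free and exact at the knots.
#'
#' @param concentration Known standard concentrations (positive, strictly
#'   increasing once sorted).
#' @param od Matching OD620 readings; must be strictly increasing with
#'   concentration.
#' @param analyte Label, e.g. `"LPS"` or `"FliC"`.
#' @return Object of class `reporter_curve`.
#' @export
reporter_standard_curve <- function(concentration, od, analyte = "LPS") {
  o <- order(concentration)
  concentration <- concentration[o]
  od <- od[o]
  if (any(concentration <= 0)) abort("Standard concentrations must be positive.")
  if (anyDuplicated(concentration)) abort("Duplicate standard concentration.")
  if (any(diff(od) <= 0)) {
    abort("Reporter OD must increase strictly with concentration in the linear range.")
  }
  structure(list(log10_conc = log10(concentration), od = od,
                 analyte = analyte),
            class = "reporter_curve")
}

#' Quantify a bioactive analyte from a dilution series
#'
#' Picks the least-diluted reading whose OD falls inside the standard
#' curve's linear range, inverts the monotone interpolant to a
#' concentration, and multiplies by the dilution factor. With noise-free
#' readings any in-range dilution gives the same answer; using the least
#' diluted one maximizes signal over background.
#'
#' @param readings Data frame for one sample x analyte with columns
#'   `dilution_factor` and `od620`.
#' @param curve A `reporter_curve`.
#' @return Concentration equivalent (same units as the standards).
#' @export
quantify_bioactive <- function(readings, curve) {
  stopifnot(inherits(curve, "reporter_curve"))
  o <- order(readings$dilution_factor)
  dil <- readings$dilution_factor[o]
  od <- readings$od620[o]
  lo <- min(curve$od)
  hi <- max(curve$od)
  in_range <- od >= lo & od <= hi
  if (!any(in_range)) {
    if (all(od > hi)) {
      abort("All readings saturated above the linear range; dilute further.")
    }
    abort("All readings below the detection range of the standard curve.")
  }
  k <- which(in_range)[1]       # least-diluted in-range reading
  logc <- approx(curve$od, curve$log10_conc, xout = od[k], ties = "ordered")$y
  10^logc * dil[k]
}

#' Quantify bioactive analytes for a whole plate-readings table
#'
#' @param readings Tibble from [read_plate_readings()] (columns
#'   `sample_id`, `analyte`, `dilution_factor`, `od620`).
#' @param curves Named list of `reporter_curve` objects keyed by analyte.
#' @return Tibble with columns `sample_id`, `analyte`, `concentration`.
#' @export
quantify_bioactive_table <- function(readings, curves) {
  purrr::map_dfr(unique(readings$analyte), function(an) {
    curve <- curves[[an]]
    if (is.null(curve)) abort(paste0("No standard curve for ", an))
    lo <- min(curve$od)
    hi <- max(curve$od)
    sub <- readings[readings$analyte == an, ] |>
      dplyr::arrange(.data$sample_id, .data$dilution_factor) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(.in_range = .data$od620 >= lo & .data$od620 <= hi,
                    .pick = .data$.in_range &
                      cumsum(.data$.in_range) == 1) |>
      dplyr::ungroup()
    bad <- sub |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(none = !any(.data$.in_range),
                       high = all(.data$od620 > hi), .groups = "drop") |>
      dplyr::filter(.data$none)
    if (nrow(bad) > 0) {
      if (bad$high[1]) {
        abort(paste0("Sample ", bad$sample_id[1], " (", an,
                     "): all readings saturated above the linear range."))
      }
      abort(paste0("Sample ", bad$sample_id[1], " (", an,
                   "): all readings below the detection range."))
    }
    picked <- sub[sub$.pick, ]
    logc <- approx(curve$od, curve$log10_conc, xout = picked$od620,
                   ties = "ordered")$y
    tibble(sample_id = picked$sample_id, analyte = an,
           concentration = 10^logc * picked$dilution_factor)
  })
}
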