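#' The standard MBRA sampling schedule
#'
#' Seventeen sampling times (hours post-inoculation) covering a 274-h
#' minibioreactor run with a compound exposure window from 72 h to 216 h:
#' sparse daily sampling before and after exposure and denser sampling
#' immediately after the switch to compound-supplemented medium.
#'
#' @return Numeric vector of 17 sampling times in hours.
#' @export
#' @examples
#' mbra_schedule()
mbra_schedule <- function() {
  c(0, 24, 48, 72, 74, 77, 80, 96, 108, 120, 144, 168, 192, 216,
    240, 264, 274)
}

#' Default phase windows
#'
#' The treatment phase spans the exposure window (72-216 h) and the
#' post-treatment phase runs from the end of exposure to the end of the run
#' (216-274 h). The 72-h and 216-h samples anchor both adjacent phases: the
#' 72-h sample is drawn just before compound-supplemented medium is
#' connected and the 216-h sample just before it is disconnected.
#'
#' @return Named list with numeric `c(start, end)` windows (hours) for
#'   `treatment` and `post`.
#' @export
phase_windows <- function() {
  list(treatment = c(72, 216), post = c(216, 274))
}

#' Assign experiment phase from sampling time
#'
#' Phase is a pure function of time given the exposure window: `pre` for
#' `t <= start`, `treatment` for `start < t <= end`, `post` for `t > end`.
#' Boundary samples belong to the earlier phase because they are drawn
#' before the medium switch takes effect. Over the standard 17-point
#' schedule this yields 4 pre, 10 treatment and 3 post samples.
#'
#' @param time_h Numeric vector of sampling times in hours.
#' @param window Numeric `c(start, end)` exposure window in hours.
#' @return Factor with levels `pre`, `treatment`, `post`.
#' @export
#' @examples
#' table(assign_phase(mbra_schedule()))
assign_phase <- function(time_h, window = phase_windows()$treatment) {
  if (!is.numeric(time_h) || anyNA(time_h)) {
    abort("`time_h` must be numeric with no missing values.")
  }
  phase <- ifelse(time_h <= window[1], "pre",
                  ifelse(time_h <= window[2], "treatment", "post"))
  factor(phase, levels = c("pre", "treatment", "post"))
}

#' Catalog of screened emulsifying agents
#'
#' The twenty food additives with emulsifying properties covered by the
#' screen, with their E numbers and manufacturers, shipped as a plain TSV
#' inside the package.
#'
#' @return Tibble with columns `emulsifier`, `e_number`, `manufacturer`.
#' @export
#' @examples
#' nrow(emulsifier_catalog())
emulsifier_catalog <- function() {
  path <- system.file("extdata", "emulsifiers.tsv", package = "mbrascreen",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}
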