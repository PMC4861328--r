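#' Default daily poverty line for a sector
#'
#' Rs 32.4/day for rural and Rs 46.9/day for urban India (expert-group
#' recommended thresholds), at 30 days/month.
#'
#' @param sector `"rural"` or `"urban"`.
#' @return A [poverty_line()].
#' @export
poverty_line_default <- function(sector = c("rural", "urban")) {
  sector <- match.arg(sector)
  poverty_line(if (sector == "rural") 32.4 else 46.9, sector)
}

#' Run the full impoverishment analysis for one sector
#'
#' Convenience wrapper chaining the whole pipeline with the shipped
#' defaults: drug catalog -> step-up regimens -> expenditure curve from
#' the sector's bracket table -> poverty before/after each regimen ->
#' population allocation through the risk cascade -> burden table.
#'
#' @param sector `"rural"` or `"urban"`.
#' @param method interpolation method for the expenditure curve.
#' @param uptake fraction of eligible people purchasing out of pocket.
#' @return List of class `"cvd_burden_analysis"` with components
#'   `regimens`, `curve`, `line`, `poverty`, `allocation`, `burden`.
#' @export
#' @examples
#' ana <- cvd_burden_analysis("rural")
#' ana$poverty
#' attr(ana$burden, "totals")
cvd_burden_analysis <- function(sector = c("rural", "urban"),
                                method = c("monotone", "hyman", "linear"),
                                uptake = 1) {
  sector <- match.arg(sector)
  method <- match.arg(method)
  regimens <- build_step_regimens(drug_catalog())
  line <- poverty_line_default(sector)
  curve <- expenditure_curve(mpce_brackets(sector), method = method)
  poverty <- impoverishment_table(curve, line, regimens)
  alloc <- allocate(cascade_params_default(sector))
  ctx <- population_context_default(sector)
  ctx$uptake_fraction <- uptake
  burden <- burden_table(alloc, poverty, ctx)
  structure(list(regimens = regimens, curve = curve, line = line,
                 poverty = poverty, allocation = alloc, burden = burden,
                 sector = sector),
            class = "cvd_burden_analysis")
}

#' @export
print.cvd_burden_analysis <- function(x, ...) {
  cat("== Impoverishment from out-of-pocket cardiovascular medicines ==\n\n")
  print(x$regimens); cat("\n")
  print(x$poverty); cat("\n")
  print(x$allocation); cat("\n")
  print(x$burden)
  invisible(x)
}
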