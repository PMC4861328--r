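#' Poverty line
#'
#' A daily per-capita expenditure threshold, converted to a monthly
#' value with `days_per_month` (default 30, the factor under which the
#' daily thresholds and monthly bracket data are commensurate).
#'
#' @param daily_value rupees/day, positive.
#' @param sector_label label carried along for display.
#' @param days_per_month days used for the monthly conversion.
#' @return Object of class `"poverty_line"`.
#' @export
#' @examples
#' poverty_line(32.4, "rural")  # Rs 972/month
poverty_line <- function(daily_value, sector_label = "", days_per_month = 30) {
  if (!is.numeric(daily_value) || length(daily_value) != 1L ||
      is.na(daily_value) || daily_value <= 0)
    stop_invalid("daily_value must be a single positive number")
  structure(list(daily_value = daily_value,
                 days_per_month = days_per_month,
                 sector_label = sector_label),
            class = "poverty_line")
}

#' Monthly value of a poverty line
#' @param line a `"poverty_line"`.
#' @return rupees/month.
#' @export
monthly_value <- function(line) {
  stopifnot(inherits(line, "poverty_line"))
  line$daily_value * line$days_per_month
}

#' @export
print.poverty_line <- function(x, ...) {
  cat(sprintf("Poverty line%s: Rs %.1f/day = Rs %.1f/month (%d days)\n",
              if (nzchar(x$sector_label)) paste0(" (", x$sector_label, ")") else "",
              x$daily_value, monthly_value(x), x$days_per_month))
  invisible(x)
}

#' Poverty headcount ratio
#'
#' Percentage of the population whose (shifted) expenditure falls below
#' the poverty line: 100 times the population fraction at which the
#' expenditure curve intersects the line. Lines below the curve minimum
#' give 0; lines above the curve's value at the end of its domain are
#' clamped to the domain maximum with a warning and a `clamped`
#' attribute (the open top bracket is never extrapolated).
#'
#' @param curve an `"expenditure_curve"`.
#' @param line a `"poverty_line"`.
#' @return Headcount as a percentage of the population.
#' @export
#' @examples
#' headcount(expenditure_curve(mpce_brackets("rural"), method = "linear"),
#'           poverty_line(32.4))  # 30.80...
headcount <- function(curve, line) {
  stopifnot(inherits(curve, "expenditure_curve"), inherits(line, "poverty_line"))
  p <- invert_curve(curve, monthly_value(line), on_exceed = "clamp")
  if (isTRUE(attr(p, "clamped")))
    warning("poverty line exceeds the curve on its domain; headcount clamped to ",
            format(100 * curve$p_max), "%")
  h <- 100 * as.numeric(p)
  attr(h, "clamped") <- isTRUE(attr(p, "clamped"))
  h
}

#' Poverty gap index
#'
#' Mean shortfall below the poverty line as a fraction of the line,
#' averaged over the whole population: geometrically, the area between
#' the line and the expenditure curve up to the headcount point,
#' normalised by the line,
#' `PGI = 100 / z * integral_0^H (z - E(p)) dp`.
#' Piecewise-linear curves use the exact trapezoid sum; cubic curves use
#' adaptive quadrature (absolute tolerance 1e-6). When the shift exceeds
#' the anchor the integrand is negative-valued at small p (resources
#' fully exhausted); set `floor_at_zero = TRUE` to floor shifted
#' expenditure at zero instead.
#'
#' @inheritParams headcount
#' @param floor_at_zero floor shifted expenditures at 0 in the gap
#'   integrand (default `FALSE`).
#' @return PGI as a percentage; never exceeds the headcount when
#'   expenditures are non-negative over the poor segment.
#' @export
poverty_gap_index <- function(curve, line, floor_at_zero = FALSE) {
  stopifnot(inherits(curve, "expenditure_curve"), inherits(line, "poverty_line"))
  z <- monthly_value(line)
  H <- headcount(curve, line) / 100
  if (H <= 0) return(0)
  ev <- function(p) {
    e <- curve$.fun(p) - curve$shift
    if (floor_at_zero) e <- pmax(e, 0)
    z - e
  }
  gap <- if (curve$kind == "piecewise_linear" && !floor_at_zero) {
    kn <- curve$knots
    pp <- c(kn$p[kn$p < H], H)
    ee <- z - (curve$.fun(pp) - curve$shift)
    sum(diff(pp) * (utils::head(ee, -1) + utils::tail(ee, -1)) / 2)
  } else {
    stats::integrate(ev, 0, H, abs.tol = 1e-6, rel.tol = 1e-9,
                     subdivisions = 400L)$value
  }
  100 * gap / z
}

#' Poverty before and after medicine purchase
#'
#' Computes gross and net poverty headcount ratios and poverty gap
#' indices for a baseline curve and after deducting each regimen's
#' monthly cost (daily cost times `days_per_month` of the line). Gross
#' values are measured on the shifted curve; net values are gross minus
#' baseline -- the impoverishment attributable to the purchase.
#'
#' @param curve baseline `"expenditure_curve"` (unshifted).
#' @param line a `"poverty_line"`.
#' @param regimens a `"regimen_set"` (or list of `"regimen"`).
#' @param floor_at_zero passed to [poverty_gap_index()].
#' @return data.frame of class `"impoverishment_table"`: one baseline
#'   row plus one row per regimen, columns `regimen`, `daily_cost`,
#'   `headcount_pct`, `net_headcount_pct`, `pgi_pct`, `net_pgi_pct`.
#'   Unrounded; the print method displays 2 decimals.
#' @export
#' @examples
#' cv <- expenditure_curve(mpce_brackets("rural"))
#' impoverishment_table(cv, poverty_line(32.4, "rural"),
#'                      build_step_regimens(drug_catalog()))
impoverishment_table <- function(curve, line, regimens, floor_at_zero = FALSE) {
  stopifnot(inherits(curve, "expenditure_curve"))
  if (length(regimens) == 0L) stop_invalid("regimens must be non-empty")
  if (curve$shift != 0)
    warning("baseline curve already carries a shift; regimen costs add to it")
  rows <- vector("list", length(regimens) + 1L)
  h0 <- as.numeric(headcount(curve, line))
  g0 <- poverty_gap_index(curve, line, floor_at_zero)
  rows[[1]] <- data.frame(regimen = "Baseline", daily_cost = 0,
                          headcount_pct = h0, net_headcount_pct = 0,
                          pgi_pct = g0, net_pgi_pct = 0)
  for (k in seq_along(regimens)) {
    r <- regimens[[k]]
    cost <- regimen_cost(r, NA)
    cv <- shift_curve(curve, cost * line$days_per_month)
    h <- as.numeric(headcount(cv, line))
    g <- poverty_gap_index(cv, line, floor_at_zero)
    rows[[k + 1L]] <- data.frame(regimen = r$step_label, daily_cost = cost,
                                 headcount_pct = h, net_headcount_pct = h - h0,
                                 pgi_pct = g, net_pgi_pct = g - g0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sector_label") <- line$sector_label
  class(out) <- c("impoverishment_table", "data.frame")
  out
}

#' @export
print.impoverishment_table <- function(x, ...) {
  lab <- attr(x, "sector_label")
  cat(sprintf("Poverty before/after medicine purchase%s\n",
              if (nzchar(lab %||% "")) paste0(" (", lab, ")") else ""))
  d <- data.frame(
    regimen = x$regimen,
    `Rs/day` = sprintf("%.2f", x$daily_cost),
    `headcount %` = sprintf("%.2f", round_half_up(x$headcount_pct, 2)),
    `net %` = sprintf("%+.2f", round_half_up(x$net_headcount_pct, 2)),
    `PGI %` = sprintf("%.2f", round_half_up(x$pgi_pct, 2)),
    `net PGI %` = sprintf("%+.2f", round_half_up(x$net_pgi_pct, 2)),
    check.names = FALSE
  )
  print(d, row.names = FALSE)
  invisible(x)
}
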