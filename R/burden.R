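#' Population context for burden estimates
#'
#' @param adult_population number of adults (above 20 years).
#' @param uptake_fraction fraction of people needing a regimen who
#'   actually buy it out of pocket (default 1).
#' @param sector_label label for display.
#' @return Object of class `"population_context"`.
#' @export
population_context <- function(adult_population, uptake_fraction = 1,
                               sector_label = "") {
  if (!is.numeric(adult_population) || length(adult_population) != 1L ||
      is.na(adult_population) || adult_population <= 0)
    stop_invalid("adult_population must be positive")
  check_fraction(uptake_fraction, "uptake_fraction")
  structure(list(adult_population = adult_population,
                 uptake_fraction = uptake_fraction,
                 sector_label = sector_label),
            class = "population_context")
}

#' @rdname population_context
#' @param sector `"rural"` (545 million adults) or `"urban"`
#'   (238 million adults).
#' @export
population_context_default <- function(sector = c("rural", "urban")) {
  sector <- match.arg(sector)
  population_context(if (sector == "rural") 545e6 else 238e6,
                     sector_label = sector)
}

match_poverty_rows <- function(alloc, poverty) {
  idx <- match(names(alloc), poverty$regimen)
  if (anyNA(idx))
    stop_invalid("poverty table is missing rows for: ",
                 paste(names(alloc)[is.na(idx)], collapse = ", "))
  poverty[idx, , drop = FALSE]
}

#' Population financially burdened or impoverished by regimen
#'
#' Combines regimen population shares, per-regimen poverty results, and
#' the adult population into person counts: for each step,
#' `burdened = share x gross headcount x adults x uptake` (people for
#' whom the regimen is unaffordable) and
#' `impoverished = share x net headcount x adults x uptake` (people
#' pushed below the poverty line by the purchase). The expenditure
#' distribution within each regimen subgroup is assumed identical to
#' the general population, so sector-level poverty percentages apply
#' unchanged to every step's subgroup. All intermediates are unrounded;
#' totals are sums of unrounded per-step contributions.
#'
#' @param alloc a `"regimen_allocation"`.
#' @param poverty an `"impoverishment_table"` containing a row for every
#'   step in `alloc`.
#' @param ctx a `"population_context"`.
#' @return data.frame of class `"burden_table"` with one row per step,
#'   columns `step_label`, `share_pct`, `unaffordable_pct`,
#'   `impoverished_pct`, `pop_impoverished_pct_of_adults`,
#'   `pgi_increase_pct`, `actual_pgi_increase_pct`, `burdened_millions`,
#'   `impoverished_millions`; totals in `attr(, "totals")`.
#' @export
#' @examples
#' cv <- expenditure_curve(mpce_brackets("rural"))
#' pov <- impoverishment_table(cv, poverty_line(32.4, "rural"),
#'                             build_step_regimens(drug_catalog()))
#' burden_table(allocate(cascade_params_default("rural")), pov,
#'              population_context_default("rural"))
burden_table <- function(alloc, poverty, ctx) {
  stopifnot(inherits(alloc, "regimen_allocation"),
            inherits(ctx, "population_context"))
  pv <- match_poverty_rows(alloc, poverty)
  share <- as.numeric(alloc)
  persons <- ctx$adult_population * ctx$uptake_fraction / 1e6
  out <- data.frame(
    step_label = names(alloc),
    share_pct = 100 * share,
    unaffordable_pct = pv$headcount_pct,
    impoverished_pct = pv$net_headcount_pct,
    pop_impoverished_pct_of_adults = share * pv$net_headcount_pct,
    pgi_increase_pct = pv$net_pgi_pct,
    actual_pgi_increase_pct = share * pv$net_pgi_pct,
    burdened_millions = share * pv$headcount_pct / 100 * persons,
    impoverished_millions = share * pv$net_headcount_pct / 100 * persons,
    row.names = NULL
  )
  totals <- c(share_pct = sum(out$share_pct),
              pop_impoverished_pct_of_adults = sum(out$pop_impoverished_pct_of_adults),
              actual_pgi_increase_pct = sum(out$actual_pgi_increase_pct),
              burdened_millions = sum(out$burdened_millions),
              impoverished_millions = sum(out$impoverished_millions))
  attr(out, "totals") <- totals
  attr(out, "context") <- ctx
  class(out) <- c("burden_table", "data.frame")
  out
}

#' @export
print.burden_table <- function(x, ...) {
  ctx <- attr(x, "context")
  cat(sprintf("Population burdened/impoverished%s (adults: %.0f M, uptake %.0f%%)\n",
              if (nzchar(ctx$sector_label)) paste0(" (", ctx$sector_label, ")") else "",
              ctx$adult_population / 1e6, 100 * ctx$uptake_fraction))
  d <- data.frame(
    step = x$step_label,
    `share %` = sprintf("%.2f", round_half_up(x$share_pct, 2)),
    `unafford %` = sprintf("%.2f", round_half_up(x$unaffordable_pct, 2)),
    `impov %` = sprintf("%.2f", round_half_up(x$impoverished_pct, 2)),
    `burdened M` = sprintf("%.2f", round_half_up(x$burdened_millions, 2)),
    `impov M` = sprintf("%.2f", round_half_up(x$impoverished_millions, 2)),
    check.names = FALSE
  )
  print(d, row.names = FALSE)
  t <- attr(x, "totals")
  cat(sprintf("  Total: share %.2f%%, burdened %.2f M, impoverished %.2f M\n",
              round_half_up(t[["share_pct"]], 2),
              round_half_up(t[["burdened_millions"]], 2),
              round_half_up(t[["impoverished_millions"]], 2)))
  invisible(x)
}

#' Scale a burden table by an uptake fraction
#'
#' All person counts scale linearly with the fraction of eligible people
#' who actually purchase out of pocket; percentages of the adult
#' population are unchanged.
#'
#' @param table a `"burden_table"`.
#' @param uptake fraction in `[0, 1]`, applied multiplicatively to the
#'   table's current uptake.
#' @return The rescaled `"burden_table"`.
#' @export
uptake_scenario <- function(table, uptake) {
  stopifnot(inherits(table, "burden_table"))
  check_fraction(uptake, "uptake")
  ctx <- attr(table, "context")
  ctx$uptake_fraction <- ctx$uptake_fraction * uptake
  for (col in c("burdened_millions", "impoverished_millions"))
    table[[col]] <- table[[col]] * uptake
  t <- attr(table, "totals")
  t[c("burdened_millions", "impoverished_millions")] <-
    t[c("burdened_millions", "impoverished_millions")] * uptake
  attr(table, "totals") <- t
  attr(table, "context") <- ctx
  table
}

#' Univariate (tornado) sensitivity of impoverishment counts
#'
#' Recomputes the total number of people impoverished while perturbing
#' one cascade parameter at a time by `+/- rel_delta` (relative). Only
#' the population shares respond to the perturbation; the per-regimen
#' poverty percentages are held fixed. Rows are ordered by decreasing
#' output range, the tornado convention.
#'
#' @param params a `"cascade_params"`.
#' @param poverty an `"impoverishment_table"` for the same sector.
#' @param ctx a `"population_context"`.
#' @param rel_delta relative perturbation (default 0.10).
#' @return data.frame of class `"tornado_sensitivity"` with columns
#'   `param`, `low_millions`, `high_millions`, `range_millions`;
#'   baseline total in `attr(, "baseline_millions")`.
#' @export
univariate_sensitivity <- function(params, poverty, ctx, rel_delta = 0.10) {
  stopifnot(inherits(params, "cascade_params"))
  if (!is.numeric(rel_delta) || length(rel_delta) != 1L || rel_delta < 0)
    stop_invalid("rel_delta must be non-negative")
  total <- function(p) {
    bt <- burden_table(allocate(p), poverty, ctx)
    attr(bt, "totals")[["impoverished_millions"]]
  }
  fields <- setdiff(names(unclass(params)), "sector_label")
  lo <- hi <- numeric(length(fields))
  for (i in seq_along(fields)) {
    a <- total(perturb(params, fields[i], -rel_delta))
    b <- total(perturb(params, fields[i], +rel_delta))
    lo[i] <- min(a, b); hi[i] <- max(a, b)
  }
  out <- data.frame(param = fields, low_millions = lo, high_millions = hi,
                    range_millions = hi - lo)
  out <- out[order(-out$range_millions), ]
  rownames(out) <- NULL
  attr(out, "baseline_millions") <- total(params)
  attr(out, "sector_label") <- params$sector_label
  class(out) <- c("tornado_sensitivity", "data.frame")
  out
}

#' @export
print.tornado_sensitivity <- function(x, ...) {
  cat(sprintf("Tornado sensitivity of impoverished millions%s (baseline %.2f M)\n",
              if (nzchar(attr(x, "sector_label") %||% ""))
                paste0(" (", attr(x, "sector_label"), ")") else "",
              attr(x, "baseline_millions")))
  d <- data.frame(param = x$param,
                  low = sprintf("%.2f", x$low_millions),
                  high = sprintf("%.2f", x$high_millions),
                  range = sprintf("%.2f", x$range_millions))
  print(d, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tornado_sensitivity <- function(x, ...) {
  base <- attr(x, "baseline_millions")
  n <- nrow(x)
  ord <- rev(seq_len(n)) # widest bar on top
  graphics::plot(NULL, xlim = range(c(x$low_millions, x$high_millions)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Adults impoverished (millions)", ylab = "",
                 main = paste("Tornado sensitivity", attr(x, "sector_label")), ...)
  graphics::rect(x$low_millions[ord], seq_len(n) - 0.35,
                 x$high_millions[ord], seq_len(n) + 0.35, col = "grey80")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(n), labels = x$param[ord], las = 1, cex.axis = 0.7)
  invisible(x)
}
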