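table1_cut_fractions <- function() c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50,
                                     0.60, 0.70, 0.80, 0.90, 0.95)

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulate per-capita monthly expenditure microdata
#'
#' Draws a right-skewed positive expenditure sample emulating
#' household-survey microdata. The default single lognormal is
#' calibrated so its decile bounds resemble the shipped rural bracket
#' table (median `exp(meanlog)` = 1270 Rs/month, between the printed
#' 40-50% and 50-60% bracket bounds). A two-component lognormal mixture
#' is available for stress tests. The seed is a mandatory argument:
#' draws are reproducible and the global random state is restored.
#'
#' @param n sample size, at least 100.
#' @param seed integer seed (required).
#' @param meanlog,sdlog lognormal parameters (defaults `log(1270)`, 0.55).
#' @param dist `"lognormal"` or `"mixture"`.
#' @param mix_weight,meanlog2,sdlog2 mixture: weight of the first
#'   component and parameters of the second.
#' @param weights optional non-negative sampling weights.
#' @return Object of class `"micro_sample"`: list with `expenditures`,
#'   `weights`, `seed`, `params`.
#' @export
#' @examples
#' s <- simulate_expenditure(1000, seed = 42)
#' median(s$expenditures)
simulate_expenditure <- function(n, seed, meanlog = log(1270), sdlog = 0.55,
                                 dist = c("lognormal", "mixture"),
                                 mix_weight = 0.8, meanlog2 = log(3200),
                                 sdlog2 = 0.40, weights = NULL) {
  dist <- match.arg(dist)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 100)
    stop_invalid("n must be at least 100")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("a single integer seed is required")
  if (sdlog <= 0 || (dist == "mixture" && sdlog2 <= 0))
    stop_invalid("scale parameters must be positive")
  n <- as.integer(n)
  x <- with_seed(seed, {
    if (dist == "lognormal") {
      stats::rlnorm(n, meanlog, sdlog)
    } else {
      check_fraction(mix_weight, "mix_weight")
      comp <- stats::rbinom(n, 1L, mix_weight)
      ifelse(comp == 1L, stats::rlnorm(n, meanlog, sdlog),
             stats::rlnorm(n, meanlog2, sdlog2))
    }
  })
  if (!is.null(weights)) {
    if (length(weights) != n || anyNA(weights) || any(weights < 0) ||
        sum(weights) == 0)
      stop_invalid("weights must be non-negative, length n, not all zero")
  }
  structure(list(expenditures = x, weights = weights, seed = seed,
                 params = list(dist = dist, meanlog = meanlog, sdlog = sdlog,
                               mix_weight = mix_weight, meanlog2 = meanlog2,
                               sdlog2 = sdlog2)),
            class = "micro_sample")
}

#' @export
print.micro_sample <- function(x, ...) {
  cat(sprintf("Synthetic expenditure microdata: n = %d, %s, seed = %s\n",
              length(x$expenditures), x$params$dist, format(x$seed)))
  print(summary(x$expenditures))
  invisible(x)
}

#' Aggregate microdata into NSS-style expenditure brackets
#'
#' Collapses a micro sample to a grouped table: for each cumulative cut
#' fraction the bracket upper bound is the type-1 (inverse-CDF) weighted
#' quantile -- the smallest observed value whose cumulative normalized
#' weight reaches the cut. When the last cut is below 1, an open top
#' bracket with an absent bound is appended, mirroring published
#' summary-report layouts.
#'
#' @param sample a `"micro_sample"`.
#' @param cut_fractions strictly increasing fractions in (0, 1];
#'   default is the 11-cut layout of the shipped bracket tables.
#' @return data.frame of class `"mpce_brackets"` (not validated for
#'   strict monotonicity: a degenerate sample yields tied bounds, which
#'   [expenditure_curve()] will refuse).
#' @export
aggregate_to_brackets <- function(sample, cut_fractions = table1_cut_fractions()) {
  stopifnot(inherits(sample, "micro_sample"))
  x <- sample$expenditures
  if (length(x) == 0L) stop_invalid("empty sample")
  q <- cut_fractions
  if (length(q) == 0L || anyNA(q) || any(q <= 0) || any(q > 1) ||
      is.unsorted(q, strictly = TRUE))
    stop_invalid("cut_fractions must be strictly increasing in (0, 1]")
  w <- sample$weights %||% rep(1, length(x))
  o <- order(x)
  xs <- x[o]
  Fw <- cumsum(w[o]) / sum(w)
  tiny <- sqrt(.Machine$double.eps)
  bounds <- vapply(q, function(qq) xs[which(Fw >= qq - tiny)[1]], numeric(1))
  out <- data.frame(cum_fraction_upper = q, mpce_upper = bounds)
  if (q[length(q)] < 1)
    out <- rbind(out, data.frame(cum_fraction_upper = 1, mpce_upper = NA_real_))
  attr(out, "sector_label") <- "synthetic"
  class(out) <- c("mpce_brackets", "data.frame")
  out
}

#' Validate the aggregate-data poverty method against microdata
#'
#' The central methodological check: poverty headcounts computed from
#' the full microdata (empirical quantile curve) are compared with
#' headcounts computed after first collapsing the same sample to
#' grouped brackets and interpolating -- the only computation possible
#' when just a summary table is published. Reported for the baseline
#' and after deducting each regimen's monthly cost.
#'
#' @param sample a `"micro_sample"`.
#' @param line a `"poverty_line"`.
#' @param regimens a `"regimen_set"`.
#' @param cut_fractions bracket cuts (default the 11-cut layout).
#' @param method interpolation method for the aggregated curve.
#' @return data.frame of class `"aggregate_validation"` with columns
#'   `regimen`, `micro_pct`, `aggregate_pct`, `difference_pp`
#'   (aggregate minus micro, percentage points).
#' @export
#' @examples
#' s <- simulate_expenditure(20000, seed = 7)
#' validate_aggregate_method(s, poverty_line(32.4, "rural"),
#'                           build_step_regimens(drug_catalog()))
validate_aggregate_method <- function(sample, line, regimens,
                                      cut_fractions = table1_cut_fractions(),
                                      method = c("monotone", "hyman", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "micro_sample"), inherits(line, "poverty_line"))
  micro <- expenditure_curve(sample$expenditures, weights = sample$weights,
                             sector_label = "micro")
  agg <- expenditure_curve(aggregate_to_brackets(sample, cut_fractions),
                           anchor_E0 = 0, method = method,
                           sector_label = "aggregate")
  costs <- c(0, vapply(regimens, function(r) regimen_cost(r, NA), numeric(1)))
  labels <- c("Baseline", vapply(regimens, function(r) r$step_label, character(1)))
  hm <- ha <- numeric(length(costs))
  for (i in seq_along(costs)) {
    shift <- costs[i] * line$days_per_month
    hm[i] <- suppressWarnings(as.numeric(headcount(shift_curve(micro, shift), line)))
    ha[i] <- suppressWarnings(as.numeric(headcount(shift_curve(agg, shift), line)))
  }
  out <- data.frame(regimen = labels, micro_pct = hm, aggregate_pct = ha,
                    difference_pp = ha - hm)
  class(out) <- c("aggregate_validation", "data.frame")
  out
}

#' @export
print.aggregate_validation <- function(x, ...) {
  cat("Aggregate-data vs micro-data poverty headcounts (%)\n")
  d <- data.frame(regimen = x$regimen,
                  micro = sprintf("%.2f", x$micro_pct),
                  aggregate = sprintf("%.2f", x$aggregate_pct),
                  diff = sprintf("%+.2f", x$difference_pp))
  print(d, row.names = FALSE)
  invisible(x)
}
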