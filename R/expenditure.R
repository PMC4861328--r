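#' Read aggregated MPCE brackets
#'
#' Reads a grouped expenditure table: cumulative population fractions
#' with the monthly per-capita expenditure (MPCE) upper bound of each
#' bracket, as published in NSS summary reports. An empty `mpce_upper`
#' cell denotes the open top bracket, which has no finite bound.
#'
#' @param path CSV with columns `cum_fraction_upper`, `mpce_upper`.
#' @param sector_label label ("rural"/"urban") carried along for display.
#' @return data.frame of class `"mpce_brackets"`.
#' @export
read_mpce_brackets <- function(path, sector_label = "") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cum_fraction_upper", "mpce_upper") %in% names(x)))
    stop_invalid("bracket table must have columns cum_fraction_upper, mpce_upper")
  out <- data.frame(cum_fraction_upper = as.numeric(x$cum_fraction_upper),
                    mpce_upper = as.numeric(x$mpce_upper))
  attr(out, "sector_label") <- sector_label
  class(out) <- c("mpce_brackets", "data.frame")
  validate_brackets(out)
  out
}

#' Shipped NSS-68 style MPCE brackets for rural and urban India
#'
#' @param sector `"rural"` or `"urban"`.
#' @return data.frame of class `"mpce_brackets"` with eleven closed
#'   brackets (cumulative fractions 0.05-0.95) and an open top bracket.
#' @export
#' @examples
#' mpce_brackets("rural")
mpce_brackets <- function(sector = c("rural", "urban")) {
  sector <- match.arg(sector)
  read_mpce_brackets(cvd_extdata(paste0("mpce_", sector, ".csv")), sector)
}

validate_brackets <- function(x) {
  p <- x$cum_fraction_upper
  e <- x$mpce_upper
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop_invalid("cumulative fractions must lie in (0, 1]")
  bad_p <- which(diff(p) <= 0)
  open <- is.na(e)
  if (any(open[-length(open)]))
    stop_invalid("only the last bracket may be open (missing mpce_upper)")
  ec <- e[!open]
  bad_e <- which(diff(ec) <= 0)
  if (any(ec <= 0)) bad_e <- union(bad_e, which(ec <= 0) - 1L)
  if (length(bad_p) || length(bad_e))
    stop_invalid("bracket table is not strictly increasing; offending rows: ",
                 paste(sort(unique(c(bad_p + 1L, bad_e + 1L))), collapse = ", "))
  invisible(x)
}

#' Fit a monotone expenditure quantile curve
#'
#' Reconstructs the continuous mapping E(p) from population fraction
#' p (poorest fraction of the population) to monthly per-capita
#' expenditure. Two kinds of input are supported:
#'
#' * a bracket table (`"mpce_brackets"` or plain data.frame with columns
#'   `cum_fraction_upper`, `mpce_upper`): the closed bracket bounds become
#'   interpolation knots together with an anchor at `(0, anchor_E0)`;
#'   the open top bracket is excluded and the curve's domain ends at the
#'   last closed cumulative fraction (no extrapolation);
#' * a numeric vector of per-capita monthly expenditures (microdata,
#'   optionally weighted): the empirical weighted quantile function is
#'   built as a piecewise-linear curve through midpoint plotting
#'   positions `(cumw_i - w_i/2) / W`, anchored at `(0, min(x))`.
#'
#' Interpolation methods for bracket input: `"monotone"` (default) is
#' the Fritsch-Carlson monotonicity-preserving cubic Hermite scheme
#' (`stats::splinefun`, `monoH.FC`); `"hyman"` is a Hyman-filtered
#' monotone cubic spline; `"linear"` is piecewise-linear interpolation,
#' retained as the closed-form reference. All pass exactly through every
#' knot and are non-decreasing.
#'
#' A fitted curve carries a `shift` (rupees/month already deducted from
#' expenditures, e.g. a medicine cost); evaluations return
#' `E(p) - shift`. See [shift_curve()].
#'
#' @param x bracket table or numeric microdata vector.
#' @param ... passed to methods.
#' @return Object of class `"expenditure_curve"` with components
#'   `knots` (data.frame `p`, `E`), `kind` (`"monotone_cubic"` or
#'   `"piecewise_linear"`), `method`, `anchor_E0`, `shift`, `p_max`,
#'   `sector_label`.
#' @export
#' @examples
#' cv <- expenditure_curve(mpce_brackets("rural"))
#' predict(cv, p = 0.30)  # 963, a Table-style knot
#' invert_curve(cv, 972)  # population fraction at Rs 972/month
expenditure_curve <- function(x, ...) UseMethod("expenditure_curve")

#' @rdname expenditure_curve
#' @param anchor_E0 expenditure assigned to the poorest individual
#'   (knot at p = 0); must be non-negative and at most the first bracket
#'   bound. Default 0.
#' @param method `"monotone"`, `"hyman"`, or `"linear"`.
#' @param sector_label optional label; defaults to the table's.
#' @export
expenditure_curve.data.frame <- function(x, anchor_E0 = 0,
                                         method = c("monotone", "hyman", "linear"),
                                         sector_label = NULL, ...) {
  method <- match.arg(method)
  validate_brackets(x)
  closed <- !is.na(x$mpce_upper)
  p <- c(0, x$cum_fraction_upper[closed])
  E <- c(anchor_E0, x$mpce_upper[closed])
  if (!is.numeric(anchor_E0) || length(anchor_E0) != 1L || is.na(anchor_E0) ||
      anchor_E0 < 0 || anchor_E0 > E[2])
    stop_invalid("anchor_E0 must lie in [0, first bracket bound]")
  if (anchor_E0 == E[2]) { # degenerate anchor: drop duplicate knot
    p <- p[-2]; E <- E[-2]
  }
  new_expenditure_curve(
    p, E,
    kind = if (method == "linear") "piecewise_linear" else "monotone_cubic",
    method = method, anchor_E0 = anchor_E0,
    sector_label = sector_label %||% (attr(x, "sector_label") %||% "")
  )
}

#' @rdname expenditure_curve
#' @param weights optional non-negative sampling weights, same length
#'   as `x`; must not sum to zero.
#' @export
expenditure_curve.numeric <- function(x, weights = NULL, sector_label = "", ...) {
  if (length(x) < 2L) stop_invalid("microdata must contain at least 2 values")
  if (anyNA(x) || any(x <= 0)) stop_invalid("expenditures must be positive")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || anyNA(weights) || any(weights < 0) ||
      sum(weights) == 0)
    stop_invalid("weights must be non-negative, same length as values, not all zero")
  o <- order(x)
  xs <- x[o]; ws <- weights[o]
  keep <- ws > 0
  xs <- xs[keep]; ws <- ws[keep]
  W <- sum(ws)
  # midpoint plotting positions on cumulative normalized weights
  pp <- (cumsum(ws) - ws / 2) / W
  new_expenditure_curve(c(0, pp), c(xs[1], xs),
                        kind = "piecewise_linear", method = "linear",
                        anchor_E0 = xs[1], sector_label = sector_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_expenditure_curve <- function(p, E, kind, method, anchor_E0,
                                  sector_label = "", shift = 0) {
  if (is.unsorted(p, strictly = TRUE)) stop_invalid("knot fractions must be strictly increasing")
  if (is.unsorted(E)) stop_invalid("knot expenditures must be non-decreasing")
  fun <- if (kind == "piecewise_linear") {
    stats::approxfun(p, E, method = "linear", ties = list("ordered", min))
  } else {
    stats::splinefun(p, E, method = if (method == "hyman") "hyman" else "monoH.FC")
  }
  structure(list(knots = data.frame(p = p, E = E),
                 kind = kind, method = method,
                 anchor_E0 = anchor_E0, shift = shift,
                 p_max = p[length(p)], sector_label = sector_label,
                 .fun = fun),
            class = "expenditure_curve")
}

#' Evaluate an expenditure curve
#'
#' @param object an `"expenditure_curve"`.
#' @param p population fraction(s) in `[0, p_max]`; no extrapolation
#'   beyond the last closed bracket.
#' @param ... unused.
#' @return `E(p) - shift`, rupees/month (may be negative when the shift
#'   exceeds expenditure at small p: resources fully exhausted).
#' @export
predict.expenditure_curve <- function(object, p, ...) {
  if (!is.numeric(p) || anyNA(p))
    stop_invalid("p must be numeric")
  if (any(p < 0) || any(p > object$p_max + 1e-12))
    stop_domain("p outside curve domain [0, ", format(object$p_max), "]")
  object$.fun(pmin(p, object$p_max)) - object$shift
}

#' Invert an expenditure curve at a threshold
#'
#' Finds the smallest population fraction p whose (shifted) expenditure
#' equals `threshold` -- geometrically, the x-coordinate where the
#' poverty line intersects the expenditure curve. Piecewise-linear
#' curves are inverted in closed form segment by segment; cubic curves
#' by bracketed root finding to an absolute tolerance of 1e-8 in p.
#'
#' @param curve an `"expenditure_curve"`.
#' @param threshold rupees/month.
#' @param on_exceed what to do when `threshold` exceeds the curve's
#'   value at the end of its domain: `"error"` raises a domain error;
#'   `"clamp"` returns `p_max` with attribute `clamped = TRUE`.
#' @return Population fraction in `[0, p_max]`. Thresholds below the
#'   curve minimum return 0.
#' @export
invert_curve <- function(curve, threshold, on_exceed = c("error", "clamp")) {
  stopifnot(inherits(curve, "expenditure_curve"))
  on_exceed <- match.arg(on_exceed)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop_invalid("threshold must be a single number")
  target <- threshold + curve$shift
  kn <- curve$knots
  if (target <= kn$E[1]) return(0)
  if (target > kn$E[nrow(kn)]) {
    if (on_exceed == "clamp")
      return(structure(curve$p_max, clamped = TRUE))
    stop_domain("threshold ", format(threshold),
                " exceeds the curve maximum on its domain")
  }
  if (curve$kind == "piecewise_linear") {
    i <- which(kn$E >= target)[1]        # first knot at/above target
    if (kn$E[i] == target) {
      # smallest p: walk back over any flat run at this value
      j <- i
      while (j > 1 && kn$E[j - 1] == target) j <- j - 1
      # value attained within the previous segment only at its right end
      return(kn$p[j])
    }
    p0 <- kn$p[i - 1]; p1 <- kn$p[i]
    e0 <- kn$E[i - 1]; e1 <- kn$E[i]
    return(p0 + (p1 - p0) * (target - e0) / (e1 - e0))
  }
  stats::uniroot(function(p) curve$.fun(p) - target,
                 lower = 0, upper = curve$p_max, tol = 1e-10)$root
}

#' Deduct a monthly cost from an expenditure curve
#'
#' Shifts the whole curve downward by `monthly_cost` rupees/month,
#' the geometric operation behind the post-purchase "curve B": every
#' individual's available resources fall by the medicine price. Shifts
#' accumulate additively; knots are unchanged.
#'
#' @param curve an `"expenditure_curve"`.
#' @param monthly_cost non-negative rupees/month.
#' @return The shifted curve.
#' @export
shift_curve <- function(curve, monthly_cost) {
  stopifnot(inherits(curve, "expenditure_curve"))
  if (!is.numeric(monthly_cost) || length(monthly_cost) != 1L ||
      is.na(monthly_cost) || monthly_cost < 0)
    stop_invalid("monthly_cost must be a single non-negative number")
  curve$shift <- curve$shift + monthly_cost
  curve
}

#' @export
print.expenditure_curve <- function(x, ...) {
  lab <- if (nzchar(x$sector_label)) paste0(" (", x$sector_label, ")") else ""
  cat(sprintf("Expenditure quantile curve%s: %s [%s], %d knots, domain [0, %g]\n",
              lab, x$kind, x$method, nrow(x$knots), x$p_max))
  if (x$shift > 0)
    cat(sprintf("  shifted down by Rs. %.2f/month\n", x$shift))
  rng <- range(x$knots$E) - x$shift
  cat(sprintf("  E(p) range: %.2f to %.2f Rs/month\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.expenditure_curve <- function(x, poverty_line = NULL, n = 400, ...) {
  p <- seq(0, x$p_max, length.out = n)
  graphics::plot(p * 100, predict(x, p), type = "l",
                 xlab = "Cumulative % of population",
                 ylab = "Monthly per-capita expenditure (Rs)",
                 main = paste("Expenditure curve", x$sector_label), ...)
  graphics::points(x$knots$p * 100, x$knots$E - x$shift, pch = 16, cex = 0.6)
  if (!is.null(poverty_line)) {
    z <- if (inherits(poverty_line, "poverty_line"))
      monthly_value(poverty_line) else poverty_line
    graphics::abline(h = z, lty = 2)
  }
  invisible(x)
}
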