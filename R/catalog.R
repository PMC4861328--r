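#' Read a drug price catalog
#'
#' Reads a CSV catalog with columns `name`, `dose_label`,
#' `therapeutic_class`, exactly one of `pre_tax_daily_cost` or
#' `daily_cost_incl_tax`, and optional `rr`, `rr_ci_low`, `rr_ci_high`
#' (primary-prevention relative risk of ischemic heart disease with 95% CI).
#' Pre-tax costs are converted to tax-inclusive costs with `policy`.
#'
#' @param path path to the CSV file.
#' @param policy [tax_policy()] used when the catalog carries pre-tax costs.
#' @return A data.frame of class `"drug_catalog"` with columns `name`,
#'   `dose_label`, `key` (`"name dose_label"`), `therapeutic_class`,
#'   `daily_cost` (rupees/day, tax inclusive), `rr`, `rr_ci_low`,
#'   `rr_ci_high`.
#' @export
read_drug_catalog <- function(path, policy = tax_policy()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "dose_label", "therapeutic_class")
  if (!all(need %in% names(x)))
    stop_invalid("catalog must have columns: ", paste(need, collapse = ", "))
  has_pre <- "pre_tax_daily_cost" %in% names(x)
  has_incl <- "daily_cost_incl_tax" %in% names(x)
  if (has_pre == has_incl)
    stop_invalid("catalog must have exactly one of pre_tax_daily_cost or daily_cost_incl_tax")
  cost <- if (has_pre) apply_taxes(x$pre_tax_daily_cost, policy) else x$daily_cost_incl_tax
  if (anyNA(cost) || any(cost <= 0)) stop_invalid("all daily costs must be positive")
  for (col in c("rr", "rr_ci_low", "rr_ci_high")) if (is.null(x[[col]])) x[[col]] <- NA_real_
  bad <- !is.na(x$rr) & !(x$rr > 0 & x$rr < 1 &
                            (is.na(x$rr_ci_low) | x$rr_ci_low <= x$rr) &
                            (is.na(x$rr_ci_high) | x$rr_ci_high >= x$rr))
  if (any(bad))
    stop_invalid("invalid relative risk rows: ",
                 paste(x$name[bad], x$dose_label[bad], collapse = "; "))
  out <- data.frame(
    name = x$name, dose_label = x$dose_label,
    key = paste(x$name, x$dose_label),
    therapeutic_class = x$therapeutic_class,
    daily_cost = as.numeric(cost),
    rr = as.numeric(x$rr), rr_ci_low = as.numeric(x$rr_ci_low),
    rr_ci_high = as.numeric(x$rr_ci_high),
    stringsAsFactors = FALSE
  )
  class(out) <- c("drug_catalog", "data.frame")
  out
}

#' Default Indian essential-medicine catalog
#'
#' Tax-inclusive daily costs (rupees/day) for common cardiovascular drugs
#' at statutory ceiling prices under a 0% excise / 6% VAT policy, with
#' primary-prevention relative risks where the drug is used in the
#' primary prevention algorithm. The atorvastatin 40mg entry is priced at
#' four times the 10mg daily cost (dose-proportional pricing of the same
#' formulation); the catalog ships it explicitly.
#'
#' @return A `"drug_catalog"` data.frame (see [read_drug_catalog()]).
#' @export
#' @examples
#' head(drug_catalog())
drug_catalog <- function() {
  read_drug_catalog(cvd_extdata("drug_catalog.csv"))
}

#' Cost-effectiveness table for primary prevention drugs
#'
#' Computes the daily-cost-per-unit-RRR ratio for every catalog drug that
#' has a primary-prevention relative risk, sorted ascending (most
#' cost-effective first). Ties are broken by lower daily cost.
#'
#' @param catalog a `"drug_catalog"`.
#' @return data.frame with columns `key`, `therapeutic_class`,
#'   `daily_cost`, `rr`, `rr_ci_low`, `rr_ci_high`, `ce_ratio`.
#' @export
ce_table <- function(catalog = drug_catalog()) {
  x <- catalog[!is.na(catalog$rr), , drop = FALSE]
  x$ce_ratio <- ce_ratio(x$daily_cost, x$rr)
  x <- x[order(x$ce_ratio, x$daily_cost), ]
  rownames(x) <- NULL
  x[, c("key", "therapeutic_class", "daily_cost", "rr",
        "rr_ci_low", "rr_ci_high", "ce_ratio")]
}
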