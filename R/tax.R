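#' Indirect-tax policy for medicine ceiling prices
#'
#' Indian ceiling prices for essential medicines are converted to the
#' maximum retail sales price by adding excise duty and sales tax (VAT).
#' Both are modelled as multiplicative rates; excise is compounded first,
#' then VAT (the order is irrelevant for two multiplicative factors, but
#' is fixed here for documentation).
#'
#' @param excise_rate excise duty as a fraction (default 0, the prevailing
#'   rate for scheduled medicines).
#' @param vat_rate sales tax (VAT) as a fraction (default 0.06).
#' @return An object of class `"tax_policy"`.
#' @export
#' @examples
#' apply_taxes(100, tax_policy()) # 106
tax_policy <- function(excise_rate = 0, vat_rate = 0.06) {
  check_fraction(excise_rate, "excise_rate", allow_one = FALSE)
  check_fraction(vat_rate, "vat_rate", allow_one = FALSE)
  structure(list(excise_rate = excise_rate, vat_rate = vat_rate),
            class = "tax_policy")
}

#' Apply excise duty and VAT to a pre-tax price
#'
#' @param pre_tax_price non-negative price in rupees.
#' @param policy a [tax_policy()].
#' @return Tax-inclusive price: `pre_tax_price * (1 + excise) * (1 + vat)`.
#' @export
apply_taxes <- function(pre_tax_price, policy = tax_policy()) {
  stopifnot(inherits(policy, "tax_policy"))
  if (!is.numeric(pre_tax_price) || anyNA(pre_tax_price) || any(pre_tax_price < 0))
    stop_invalid("pre_tax_price must be non-negative")
  pre_tax_price * (1 + policy$excise_rate) * (1 + policy$vat_rate)
}

#' Cost-effectiveness ratio of a preventive drug
#'
#' Daily cost per unit of relative risk reduction (RRR), where
#' RRR = 1 - RR and RR is the relative risk of ischemic heart disease
#' under treatment. Lower values are more cost-effective; the step-up
#' regimen order is the ascending order of this ratio.
#'
#' @param daily_cost tax-inclusive daily cost in rupees.
#' @param relative_risk relative risk of the outcome under treatment,
#'   strictly between 0 and 1 (a drug with RR >= 1 confers no risk
#'   reduction and has no defined ratio).
#' @return Rupees per day per unit relative risk reduction.
#' @export
#' @examples
#' ce_ratio(1.03, 0.75) # 4.12
ce_ratio <- function(daily_cost, relative_risk) {
  if (!is.numeric(daily_cost) || anyNA(daily_cost) || any(daily_cost <= 0))
    stop_invalid("daily_cost must be positive")
  if (!is.numeric(relative_risk) || anyNA(relative_risk) ||
      any(relative_risk <= 0) || any(relative_risk >= 1))
    stop_invalid("relative_risk must lie strictly between 0 and 1 (no risk reduction otherwise)")
  daily_cost / (1 - relative_risk)
}

#' Combined relative risk reduction of a drug set
#'
#' Risk reductions are treated as additive across agents (the convention
#' used for a second anti-hypertensive), capped at 1. Used for reporting
#' only; the poverty computation depends on costs, not risks.
#'
#' @param relative_risks numeric vector of per-drug relative risks in (0, 1].
#' @return `min(1, sum(1 - relative_risks))`.
#' @export
#' @examples
#' combined_rrr(c(0.75, 0.66)) # 0.59
combined_rrr <- function(relative_risks) {
  if (length(relative_risks) == 0L)
    stop_invalid("relative_risks must be non-empty")
  if (!is.numeric(relative_risks) || anyNA(relative_risks) ||
      any(relative_risks <= 0) || any(relative_risks > 1))
    stop_invalid("relative risks must lie in (0, 1]")
  min(1, sum(1 - relative_risks))
}
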