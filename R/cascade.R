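#' Cardiovascular treatment-need cascade parameters
#'
#' Prevalence parameters of the decision tree that assigns adults to
#' step-up regimens. Adults with high short-term cardiovascular risk
#' (10-year risk > 10%) need at least aspirin (Step 1). Among them,
#' hypertensives without hyperlipidemia need one (stage 1 hypertension,
#' Step 2) or two (stage 2, Step 3) anti-hypertensives; hypertensives
#' with hyperlipidemia additionally need a low-dose (single lipid
#' disorder, Step 4) or high-dose (multiple lipid disorders, Step 5)
#' statin. Adults with prevalent coronary heart disease need the
#' secondary prevention regimen (Step 6), independently of the
#' primary-prevention branch.
#'
#' @param high_risk_frac fraction of adults with high short-term CVD risk.
#' @param htn_given_risk fraction of high-risk adults with hypertension.
#' @param stage1_given_htn fraction of hypertensives with stage 1
#'   hypertension (applied to hypertensives without hyperlipidemia).
#' @param lipid_given_htn fraction of hypertensives who also have
#'   hyperlipidemia.
#' @param single_lipid_given_lipid fraction of hyperlipidemics with a
#'   single lipid disorder.
#' @param chd_prevalence fraction of adults with prevalent coronary
#'   heart disease.
#' @param sector_label label for display.
#' @return Object of class `"cascade_params"`.
#' @export
#' @examples
#' allocate(cascade_params_default("urban"))
cascade_params <- function(high_risk_frac, htn_given_risk, stage1_given_htn,
                           lipid_given_htn, single_lipid_given_lipid,
                           chd_prevalence, sector_label = "") {
  p <- list(high_risk_frac = high_risk_frac,
            htn_given_risk = htn_given_risk,
            stage1_given_htn = stage1_given_htn,
            lipid_given_htn = lipid_given_htn,
            single_lipid_given_lipid = single_lipid_given_lipid,
            chd_prevalence = chd_prevalence)
  for (nm in names(p)) check_fraction(p[[nm]], nm)
  structure(c(p, list(sector_label = sector_label)), class = "cascade_params")
}

#' @rdname cascade_params
#' @param sector `"rural"` or `"urban"`; loads the shipped YAML defaults
#'   (identical conditional prevalences; sectors differ in the high-risk
#'   fraction and CHD prevalence).
#' @export
cascade_params_default <- function(sector = c("rural", "urban")) {
  sector <- match.arg(sector)
  read_cascade_params(cvd_extdata(paste0("cascade_", sector, ".yaml")))
}

#' @rdname cascade_params
#' @param path YAML file with the parameter fields.
#' @export
read_cascade_params <- function(path) {
  y <- yaml::read_yaml(path)
  cascade_params(y$high_risk_frac, y$htn_given_risk, y$stage1_given_htn,
                 y$lipid_given_htn, y$single_lipid_given_lipid,
                 y$chd_prevalence, y$sector_label %||% "")
}

#' @export
print.cascade_params <- function(x, ...) {
  cat(sprintf("Cascade parameters%s:\n",
              if (nzchar(x$sector_label)) paste0(" (", x$sector_label, ")") else ""))
  for (nm in setdiff(names(x), "sector_label"))
    cat(sprintf("  %-26s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Allocate the adult population to regimen steps
#'
#' Expands the cascade tree into the fraction of the adult population on
#' each regimen step. With r = high-risk fraction, h = hypertension
#' given risk, s1 = stage 1 given hypertension, l = hyperlipidemia given
#' hypertension, sl = single lipid disorder given hyperlipidemia:
#' Step 1 = r(1-h); Step 2 = r h (1-l) s1; Step 3 = r h (1-l)(1-s1);
#' Step 4 = r h l sl; Step 5 = r h l (1-sl); Step 6 = CHD prevalence.
#' Steps 1-5 sum to r exactly.
#'
#' @param params a `"cascade_params"`.
#' @return Object of class `"regimen_allocation"`: named numeric vector
#'   of population fractions (`Step 1` .. `Step 6`), with the parameters
#'   attached as an attribute.
#' @export
allocate <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  r <- params$high_risk_frac
  h <- params$htn_given_risk
  s1 <- params$stage1_given_htn
  l <- params$lipid_given_htn
  sl <- params$single_lipid_given_lipid
  shares <- c(
    "Step 1" = r * (1 - h),
    "Step 2" = r * h * (1 - l) * s1,
    "Step 3" = r * h * (1 - l) * (1 - s1),
    "Step 4" = r * h * l * sl,
    "Step 5" = r * h * l * (1 - sl),
    "Step 6" = params$chd_prevalence
  )
  structure(shares, params = params, class = "regimen_allocation")
}

#' @export
print.regimen_allocation <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Adult population shares by regimen%s:\n",
              if (nzchar(p$sector_label)) paste0(" (", p$sector_label, ")") else ""))
  for (nm in names(x))
    cat(sprintf("  %-7s %6.2f %%\n", nm, round_half_up(100 * unclass(x)[[nm]], 2)))
  cat(sprintf("  total   %6.2f %%\n", round_half_up(100 * sum(unclass(x)), 2)))
  invisible(x)
}

#' Perturb one cascade parameter
#'
#' Multiplies a single parameter by `1 + rel_delta`, clamping the result
#' to `[0, 1]` with a warning -- the elementary move of the univariate
#' sensitivity analysis.
#'
#' @param params a `"cascade_params"`.
#' @param field one of the six parameter names.
#' @param rel_delta signed relative change (e.g. `0.10` for +10%).
#' @return A `"cascade_params"` copy with the field perturbed.
#' @export
#' @examples
#' perturb(cascade_params_default("urban"), "chd_prevalence", 0.10)
perturb <- function(params, field, rel_delta) {
  stopifnot(inherits(params, "cascade_params"))
  fields <- setdiff(names(unclass(params)), "sector_label")
  if (!is.character(field) || length(field) != 1L || !(field %in% fields))
    stop_invalid("unknown cascade parameter: ", paste(field, collapse = ", "))
  v <- params[[field]] * (1 + rel_delta)
  if (v < 0 || v > 1) {
    warning("perturbed ", field, " clamped to [0, 1]")
    v <- min(1, max(0, v))
  }
  params[[field]] <- v
  params
}
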