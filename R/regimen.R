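new_regimen <- function(step_label, purpose, drugs) {
  stopifnot(is.data.frame(drugs))
  structure(list(step_label = step_label,
                 purpose = purpose,
                 drugs = drugs,
                 daily_cost = sum(drugs$daily_cost)),
            class = "regimen")
}

#' Daily cost of a regimen
#'
#' @param r a `"regimen"`.
#' @param digits decimals for display rounding; `NA` returns the
#'   unrounded sum.
#' @return Sum of component tax-inclusive daily costs in rupees/day.
#' @export
regimen_cost <- function(r, digits = 2) {
  stopifnot(inherits(r, "regimen"))
  cost <- sum(r$drugs$daily_cost)
  if (is.na(digits)) cost else round_half_up(cost, digits)
}

#' Read a step-up regimen recipe
#'
#' A recipe is a YAML file with a `steps` list; each step has `label`,
#' `purpose` (`primary`/`secondary`) and `drugs` (catalog keys,
#' `"name dose_label"`). The shipped default reproduces the six-step
#' prevention ladder.
#'
#' @param path YAML file; default is the shipped recipe.
#' @return List of steps.
#' @export
read_regimen_recipe <- function(path = cvd_extdata("regimen_recipe.yaml")) {
  rec <- yaml::read_yaml(path)
  if (is.null(rec$steps) || !length(rec$steps))
    stop_invalid("recipe has no steps")
  rec$steps
}

#' Build cost-effectiveness ordered step-up regimens
#'
#' The primary prevention ladder is derived from the catalog itself:
#' drugs carrying a primary-prevention relative risk are ranked by
#' ascending cost-effectiveness ratio (daily cost per unit relative risk
#' reduction, ties broken by lower cost), and Steps 1-4 are the
#' cumulative prefixes of that ranking. Step 5 intensifies the statin by
#' substituting the 40mg atorvastatin dose for the 10mg dose. Step 6 is
#' the secondary prevention regimen (aspirin, thiazide, beta blocker,
#' high-dose statin). When an explicit `recipe` is supplied, regimens are
#' built verbatim from its drug lists instead.
#'
#' @param catalog a `"drug_catalog"` containing, at minimum, the drugs
#'   named by the ladder.
#' @param recipe optional recipe (see [read_regimen_recipe()]); `NULL`
#'   derives the ladder from cost-effectiveness ranking.
#' @return An object of class `"regimen_set"`: a list of `"regimen"`.
#' @export
#' @examples
#' regs <- build_step_regimens(drug_catalog())
#' sapply(regs, regimen_cost)
build_step_regimens <- function(catalog = drug_catalog(), recipe = NULL) {
  stopifnot(inherits(catalog, "drug_catalog"))

  pick <- function(keys) {
    idx <- match(keys, catalog$key)
    if (anyNA(idx))
      stop(errorCondition(
        paste0("catalog is missing drug(s): ",
               paste(keys[is.na(idx)], collapse = ", ")),
        class = c("cvdburden_config_error", "error")))
    catalog[idx, , drop = FALSE]
  }

  if (is.null(recipe)) {
    ranked <- ce_table(catalog)
    if (nrow(ranked) < 1L) stop_invalid("catalog has no drugs with relative risks")
    steps <- lapply(seq_len(nrow(ranked)), function(k) {
      list(label = paste("Step", k), purpose = "primary",
           drugs = ranked$key[seq_len(k)])
    })
    # dose intensification: last primary step repeated with the 40mg statin
    statin <- grep("^atorvastatin", ranked$key, value = TRUE)
    if (length(statin) == 1L && statin == "atorvastatin 10mg") {
      hi <- sub("10mg", "40mg", statin)
      keys5 <- c(setdiff(steps[[length(steps)]]$drugs, statin), hi)
      steps[[length(steps) + 1L]] <- list(label = paste("Step", length(steps) + 1L),
                                          purpose = "primary", drugs = keys5)
      steps[[length(steps) + 1L]] <- list(
        label = paste("Step", length(steps) + 1L), purpose = "secondary",
        drugs = c("aspirin 75mg", "hydrochlorothiazide 12.5mg",
                  "atenolol 50mg", hi))
    }
  } else {
    steps <- recipe
  }

  out <- lapply(steps, function(s)
    new_regimen(s$label, s$purpose, pick(unlist(s$drugs))))
  names(out) <- vapply(out, function(r) r$step_label, character(1))
  structure(out, class = "regimen_set")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%s (%s prevention): Rs. %.2f/day\n  %s\n",
              x$step_label, x$purpose, regimen_cost(x, NA),
              paste(x$drugs$key, collapse = " + ")))
  invisible(x)
}

#' @export
print.regimen_set <- function(x, ...) {
  cat("Step-up prevention regimens (tax-inclusive ceiling prices)\n")
  for (r in x)
    cat(sprintf("  %-7s %-9s Rs. %6.2f/day  %s\n", r$step_label, r$purpose,
                regimen_cost(r), paste(r$drugs$key, collapse = " + ")))
  invisible(x)
}

#' @export
as.data.frame.regimen_set <- function(x, ...) {
  data.frame(
    step_label = vapply(x, function(r) r$step_label, character(1)),
    purpose = vapply(x, function(r) r$purpose, character(1)),
    drugs = vapply(x, function(r) paste(r$drugs$key, collapse = " + "), character(1)),
    daily_cost = vapply(x, function(r) regimen_cost(r, NA), numeric(1)),
    row.names = NULL
  )
}
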