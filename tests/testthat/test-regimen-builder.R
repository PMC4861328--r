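test_that("taxes compound multiplicatively and reject invalid input", {
  expect_equal(apply_taxes(100, tax_policy(0, 0.06)), 106)
  expect_equal(apply_taxes(50, tax_policy(0, 0)), 50)
  # factors commute
  expect_equal(apply_taxes(37.5, tax_policy(0.08, 0.06)),
               37.5 * 1.06 * 1.08)
  expect_error(apply_taxes(-1), class = "cvdburden_invalid_input")
  expect_error(tax_policy(-0.1, 0.06), class = "cvdburden_invalid_input")
  expect_error(tax_policy(0, 1), class = "cvdburden_invalid_input")
})

test_that("a 2-dp pre-tax price exists that displays as the catalog aspirin cost", {
  # brute-force oracle: every 2-dp pre-tax price whose taxed value rounds
  # to 0.13 under half-up display rounding
  pre <- seq(0.01, 0.50, by = 0.01)
  hits <- pre[round_half_up(apply_taxes(pre, tax_policy(0, 0.06)), 2) == 0.13]
  expect_true(0.12 %in% hits)
  expect_equal(apply_taxes(0.12, tax_policy(0, 0.06)), 0.1272)
  expect_equal(round_half_up(0.1272, 2), 0.13)
})

test_that("cost-effectiveness ratio is daily cost per unit risk reduction", {
  expect_equal(ce_ratio(1.03, 0.75), 4.12)
  expect_equal(ce_ratio(0.13, 0.68), 0.40625)
  expect_equal(ce_ratio(1.00, 0.50), 2.00)
  expect_error(ce_ratio(1, 1), class = "cvdburden_invalid_input")
  expect_error(ce_ratio(1, 1.2), class = "cvdburden_invalid_input")
  expect_error(ce_ratio(0, 0.5), class = "cvdburden_invalid_input")
})

test_that("combined risk reduction is additive and capped at one", {
  expect_equal(combined_rrr(0.68), 0.32)
  expect_equal(combined_rrr(c(0.75, 0.66)), 0.59)
  expect_equal(combined_rrr(c(0.5, 0.3, 0.1)), 1.0)
  expect_error(combined_rrr(numeric(0)), class = "cvdburden_invalid_input")
})

test_that("cost-effectiveness ranking yields the published primary-prevention order", {
  ranked <- ce_table(fx_catalog)
  expect_equal(ranked$key, c("aspirin 75mg", "hydrochlorothiazide 12.5mg",
                             "losartan 25mg", "atorvastatin 10mg"))
  expect_true(all(diff(ranked$ce_ratio) > 0))
})

test_that("step-up regimens have the published composition and costs", {
  costs <- vapply(fx_regimens, regimen_cost, numeric(1))
  expect_equal(unname(costs), c(0.13, 1.16, 3.81, 10.07, 28.85, 28.39))
  # steps 1-4 are cumulative prefixes; step 5 swaps statin dose
  for (k in 2:4)
    expect_equal(fx_regimens[[k]]$drugs$key[seq_len(k - 1)],
                 fx_regimens[[k - 1]]$drugs$key)
  expect_setequal(fx_regimens[["Step 5"]]$drugs$key,
                  c(setdiff(fx_regimens[["Step 4"]]$drugs$key, "atorvastatin 10mg"),
                    "atorvastatin 40mg"))
  expect_setequal(fx_regimens[["Step 6"]]$drugs$key,
                  c("aspirin 75mg", "hydrochlorothiazide 12.5mg",
                    "atenolol 50mg", "atorvastatin 40mg"))
  expect_equal(fx_regimens[["Step 6"]]$purpose, "secondary")
  # strict cost monotonicity across the primary ladder
  expect_true(all(diff(costs[1:5]) > 0))
  # totals equal component sums within half a paisa
  for (r in fx_regimens)
    expect_lt(abs(regimen_cost(r, NA) - sum(r$drugs$daily_cost)), 0.005)
})

test_that("regimen cost handles the degenerate empty regimen", {
  expect_equal(regimen_cost(fx_zero_regimen()), 0)
})

test_that("the shipped recipe reproduces the cost-effectiveness ladder", {
  from_recipe <- build_step_regimens(fx_catalog, read_regimen_recipe())
  expect_equal(lapply(from_recipe, function(r) r$drugs$key),
               lapply(fx_regimens, function(r) r$drugs$key))
})

test_that("a missing drug raises a configuration error naming it", {
  crippled <- fx_catalog[fx_catalog$key != "losartan 25mg", ]
  class(crippled) <- class(fx_catalog)
  expect_error(build_step_regimens(crippled, read_regimen_recipe()),
               "losartan 25mg", class = "cvdburden_config_error")
  # without losartan the derived ladder simply has fewer rungs
  expect_lt(length(build_step_regimens(crippled)), length(fx_regimens))
})

test_that("one-drug catalog with one-step recipe builds a single regimen", {
  one <- fx_catalog[fx_catalog$key == "aspirin 75mg", ]
  class(one) <- class(fx_catalog)
  regs <- build_step_regimens(one, list(list(label = "Step 1", purpose = "primary",
                                             drugs = "aspirin 75mg")))
  expect_length(regs, 1L)
  expect_equal(regimen_cost(regs[[1]]), 0.13)
})

test_that("catalog reader applies taxes to pre-tax costs and checks columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,dose_label,therapeutic_class,pre_tax_daily_cost",
               "aspirin,75mg,anti-platelet,0.12"), tmp)
  cat <- read_drug_catalog(tmp)
  expect_equal(cat$daily_cost, 0.12 * 1.06)
  writeLines(c("name,dose_label,therapeutic_class,pre_tax_daily_cost,daily_cost_incl_tax",
               "aspirin,75mg,anti-platelet,0.12,0.13"), tmp)
  expect_error(read_drug_catalog(tmp), "exactly one",
               class = "cvdburden_invalid_input")
})
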