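methods_all <- c("monotone", "hyman", "linear")

test_that("fitted curves reproduce every knot exactly", {
  for (sec in c("rural", "urban")) {
    br <- mpce_brackets(sec)
    closed <- br[!is.na(br$mpce_upper), ]
    for (m in methods_all) {
      cv <- fx_curve(sec, m)
      expect_lt(max(abs(predict(cv, closed$cum_fraction_upper) - closed$mpce_upper)),
                1e-9)
      expect_equal(predict(cv, 0), 0)   # anchor reproduction
    }
  }
})

test_that("bracket knots evaluate to the published bounds", {
  expect_equal(predict(fx_curve("rural", "monotone"), 0.30), 963)
  expect_equal(predict(fx_curve("urban", "monotone"), 0.20), 1239)
})

test_that("piecewise-linear evaluation matches the midpoint oracle between knots", {
  expect_equal(predict(fx_curve("rural", "linear"), 0.35), (963 + 1075) / 2)
})

test_that("curves are non-decreasing on a dense grid and refuse extrapolation", {
  grid <- seq(0, 0.95, length.out = 1000)
  for (m in methods_all) {
    cv <- fx_curve("rural", m)
    expect_false(is.unsorted(predict(cv, grid)))
    expect_error(predict(cv, 0.96), class = "cvdburden_domain_error")
    expect_error(predict(cv, -0.01), class = "cvdburden_domain_error")
  }
})

test_that("inversion finds the intersection with a threshold", {
  lin <- fx_curve("rural", "linear")
  expect_equal(invert_curve(lin, 972),
               linear_invert_oracle(0.30, 963, 0.40, 1075, 972))
  expect_equal(invert_curve(lin, 1006.8),
               linear_invert_oracle(0.30, 963, 0.40, 1075, 1006.8))
  expect_equal(round_half_up(100 * invert_curve(lin, 1006.8), 2), 33.91)
  expect_equal(invert_curve(lin, predict(lin, 0)), 0)  # threshold at anchor
  expect_equal(invert_curve(lin, -5), 0)               # below curve minimum
  expect_error(invert_curve(lin, 5000), class = "cvdburden_domain_error")
  expect_equal(as.numeric(invert_curve(lin, 5000, on_exceed = "clamp")), 0.95)
})

test_that("inversion inverts evaluation wherever the curve is strictly increasing", {
  for (m in methods_all) {
    cv <- fx_curve("urban", m)
    ps <- seq(0.01, 0.94, by = 0.031)
    back <- vapply(ps, function(p) invert_curve(cv, predict(cv, p)), numeric(1))
    expect_lt(max(abs(back - ps)), 1e-6)
  }
})

test_that("shifting deducts a monthly cost, preserves shape, and is additive", {
  cv <- fx_curve("rural", "monotone")
  expect_equal(predict(shift_curve(cv, 0), 0.5), predict(cv, 0.5))
  grid <- seq(0, 0.95, by = 0.05)
  s1 <- shift_curve(shift_curve(cv, 100), 34.8)
  s2 <- shift_curve(cv, 134.8)
  expect_equal(predict(s1, grid), predict(s2, grid))
  expect_equal(predict(s2, grid), predict(cv, grid) - 134.8)
  # shifted inversion equals raised-threshold inversion
  expect_equal(invert_curve(shift_curve(cv, 34.8), 972), invert_curve(cv, 1006.8))
  expect_error(shift_curve(cv, -1), class = "cvdburden_invalid_input")
})

test_that("cubic curves agree with the linear reference at knots and stay inside brackets", {
  for (sec in c("rural", "urban")) {
    lin <- fx_curve(sec, "linear")
    for (m in c("monotone", "hyman")) {
      cub <- fx_curve(sec, m)
      kn <- cub$knots
      expect_equal(predict(cub, kn$p), predict(lin, kn$p), tolerance = 1e-12)
      for (i in seq_len(nrow(kn) - 1)) {
        pp <- seq(kn$p[i], kn$p[i + 1], length.out = 20)
        ev <- predict(cub, pp)
        # monotone interpolation confines each segment to its bracket box
        expect_true(all(ev >= kn$E[i] - 1e-9 & ev <= kn$E[i + 1] + 1e-9))
      }
    }
  }
})

test_that("invalid bracket tables are rejected with offending rows listed", {
  bad <- data.frame(cum_fraction_upper = c(0.1, 0.2, 0.3),
                    mpce_upper = c(500, 400, 600))
  expect_error(expenditure_curve(bad), "offending rows",
               class = "cvdburden_invalid_input")
  open_mid <- data.frame(cum_fraction_upper = c(0.1, 0.5, 1.0),
                         mpce_upper = c(500, NA, 900))
  expect_error(expenditure_curve(open_mid), class = "cvdburden_invalid_input")
  good <- mpce_brackets("rural")
  expect_error(expenditure_curve(good, anchor_E0 = 700),
               class = "cvdburden_invalid_input")  # above first bound
  expect_error(expenditure_curve(good, anchor_E0 = -1),
               class = "cvdburden_invalid_input")
})

test_that("microdata curves use midpoint plotting positions", {
  cv <- expenditure_curve(c(10, 20, 30, 40))
  expect_equal(invert_curve(cv, 20), 0.375)
  expect_equal(invert_curve(cv, 40), 0.875)
  expect_equal(cv$p_max, 0.875)
  # degenerate constant sample: smallest-p convention gives the 0 boundary
  cvc <- expenditure_curve(rep(7, 5))
  expect_equal(invert_curve(cvc, 7), 0)
  # uniform weights are equivalent to no weights
  a <- expenditure_curve(c(10, 20, 25, 30))
  b <- expenditure_curve(c(10, 20, 25, 30), weights = rep(3, 4))
  expect_equal(a$knots, b$knots)
  expect_error(expenditure_curve(c(1, 2), weights = c(0, 0)),
               class = "cvdburden_invalid_input")
  expect_error(expenditure_curve(5), class = "cvdburden_invalid_input")
})

test_that("the empirical curve recovers the median of lognormal draws", {
  s <- simulate_expenditure(10000, seed = 11)
  cv <- expenditure_curve(s$expenditures)
  h <- invert_curve(cv, exp(log(1270)))
  expect_lt(abs(h - 0.5), 2 / sqrt(10000))
})
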