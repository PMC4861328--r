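# Shared fixtures, all built in code (cheap: interpolation fits only).

fx_catalog <- drug_catalog()
fx_regimens <- build_step_regimens(fx_catalog)
fx_line_rural <- poverty_line(32.4, "rural")
fx_line_urban <- poverty_line(46.9, "urban")

fx_curve <- function(sector, method) {
  expenditure_curve(mpce_brackets(sector), method = method)
}

# closed-form inversion of the piecewise-linear curve between two knots
linear_invert_oracle <- function(p0, e0, p1, e1, z) p0 + (p1 - p0) * (z - e0) / (e1 - e0)

# a zero-cost regimen for degenerate-input checks
fx_zero_regimen <- function() {
  cvdburden:::new_regimen("Zero", "primary",
                          fx_catalog[0, , drop = FALSE])
}
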