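test_that("through-origin fit inverts the closed form exactly on clean points", {
  RT <- thermo_config()$RT
  for (ddg in c(-1.2, -2.2, -3.0)) {
    slope_true <- exp(-ddg / RT)
    x <- c(0.001, 0.0026, 0.0064, 0.016, 0.042, 0.111)
    rho <- log1p(slope_true * x)
    pr <- fit_profile(x, rho, fraction_of = "wt")
    expect_equal(unname(coef(pr)), slope_true, tolerance = 1e-12)
    expect_equal(pr$ddG, ddg, tolerance = 1e-10)
    expect_equal(max(abs(pr$residuals)), 0, tolerance = 1e-10)
    expect_equal(pr$r_squared, 1, tolerance = 1e-12)
    # predictions invert back
    expect_equal(predict(pr, x, fraction_of = "wt"), rho)
  }
  # a (f = 0, rho = 0) point carries no information
  x2 <- c(0, 0.01, 0.04)
  rho2 <- log1p(25 * x2)
  expect_equal(coef(fit_profile(x2, rho2, fraction_of = "wt")),
               coef(fit_profile(x2[-1], rho2[-1], fraction_of = "wt")))
  expect_error(fit_profile(0, 0), "positive fraction")
  # fraction given as c_mut/c_total is converted to c_mut/c_wt
  f_tot <- c(0.01, 0.05)
  pr_tot <- fit_profile(f_tot, log1p(25 * f_tot / (1 - f_tot)),
                        fraction_of = "total")
  expect_equal(unname(coef(pr_tot)), 25, tolerance = 1e-12)
})

test_that("a single measurement determines the same profile as a full series", {
  ps <- kras_ps()
  h <- kras_hyp()[kras_hyp()$label == "10C>G", ]
  ser <- make_dilution_series(ps, h, 0.10, 2.5, 6, c_total = 5,
                              config = sim_config(), seed = 42)
  rhos <- series_rhos(ser, h)
  full <- fit_profile(ser$fractions, rhos, fraction_of = "total")
  single <- fit_profile(ser$fractions[2], rhos[2], fraction_of = "total")
  expect_equal(unname(coef(single)), unname(coef(full)), tolerance = 0.2)
  # single-point slope is the exact one-point inversion
  expect_equal(unname(coef(single)),
               expm1(rhos[2]) / (ser$fractions[2] / (1 - ser$fractions[2])),
               tolerance = 1e-12)
})

test_that("dilution-series round trip recovers the simulated ddG", {
  ps <- kras_ps()
  h <- kras_hyp()[kras_hyp()$label == "10C>G", ]
  ddg_true <- -branch_penalty(h)
  # noise-free: exact recovery and perfect linearity
  ser0 <- make_dilution_series(ps, h, 0.10, 2.5, 6, c_total = 5,
                               config = noise_free_config(), seed = 1)
  pr0 <- fit_profile(ser0$fractions, series_rhos(ser0, h),
                     fraction_of = "total")
  # even noise-free, the reference branch is lifted slightly by the
  # mutant's weak cross-binding (~ f * exp(-penalty/RT)), which first-order
  # biases the slope; at a 10% start fraction that bound is ~0.01 kcal/mol
  expect_lt(abs(pr0$ddG - ddg_true), 0.02)
  expect_gt(pr0$r_squared, 1 - 1e-4)
  # default noise: recovery within 0.05 kcal/mol, linearity R^2 > 0.98
  ser <- make_dilution_series(ps, h, 0.10, 2.5, 6, c_total = 5,
                              config = sim_config(), seed = 42)
  pr <- fit_profile(ser$fractions, series_rhos(ser, h),
                    fraction_of = "total")
  expect_lt(abs(pr$ddG - ddg_true), 0.05)  # kcal/mol
  expect_gt(pr$r_squared, 0.98)
})

test_that("detection limits invert the profile at the rho threshold", {
  dl <- detection_limit(81.1, rho_t = 0.5)
  expect_equal(dl$c_mut_over_c_wt, expm1(0.5) / 81.1, tolerance = 1e-12)
  expect_equal(round(dl$c_mut_over_c_wt, 4), 0.008)
  expect_equal(dl$c_mut_over_c_total,
               dl$c_mut_over_c_wt / (1 + dl$c_mut_over_c_wt))
  # proportionality and the small-threshold limit
  expect_equal(detection_limit(162.2, 0.5)$c_mut_over_c_wt,
               dl$c_mut_over_c_wt / 2)
  expect_lt(detection_limit(81.1, 1e-9)$c_mut_over_c_wt, 1e-10)
  expect_error(detection_limit(-3), "positive")
  expect_error(detection_limit(fit_profile(0.05, 0.6), rho_t = -1), "rho_t")
})

test_that("noise-free detection limits are invariant to the fitted subset", {
  slope <- 40
  x <- c(0.002, 0.008, 0.03, 0.1)
  rho <- log1p(slope * x)
  lims <- sapply(list(1:4, 1:2, c(2, 4), 3), function(idx)
    detection_limit(fit_profile(x[idx], rho[idx], fraction_of = "wt"),
                    0.5)$c_mut_over_c_wt)
  expect_equal(max(lims) - min(lims), 0, tolerance = 1e-12)
})

test_that("panel detection limits rank with the mismatch penalties", {
  ps <- kras_ps()
  hyp <- kras_hyp()
  cfg <- noise_free_config()
  RT <- cfg$thermo$RT
  ref <- simulate_array(ps, wt_spec(10), cfg)
  rhos <- vapply(seq_len(nrow(hyp)), function(i) {
    tst <- simulate_array(ps, mix_spec(hyp[i, ], 0.05, 10), cfg)
    attr(branch_fit(ref, tst, hyp[i, ], background_threshold = 0), "rho")
  }, numeric(1))
  pl <- panel_lod(hyp$label, rep(0.05, 12), rhos, rho_t = 0.5,
                  fraction_of = "total")
  pens <- vapply(seq_len(nrow(hyp)), function(i) branch_penalty(hyp[i, ]),
                 numeric(1))
  # larger penalty -> steeper profile -> smaller detection limit
  # (position-independent penalties make limits near-equal within a
  # penalty class, so compare across classes)
  for (i in 1:11) for (j in (i + 1):12) {
    if (pens[i] > pens[j]) expect_lt(pl$lod_total[i], pl$lod_total[j])
    if (pens[i] < pens[j]) expect_gt(pl$lod_total[i], pl$lod_total[j])
  }
  expect_true(attr(pl, "weakest") %in% hyp$label[pens == min(pens)])

  # homogeneous penalties give identical limits
  pen_eq <- default_penalty_table()
  pen_eq$ddG <- rep(2, 12)
  cfg_eq <- noise_free_config(penalties = pen_eq)
  ref_eq <- simulate_array(ps, wt_spec(10), cfg_eq)
  rhos_eq <- vapply(1:3, function(i) {
    tst <- simulate_array(ps, mix_spec(hyp[i, ], 0.05, 10), cfg_eq)
    attr(branch_fit(ref_eq, tst, hyp[i, ], background_threshold = 0), "rho")
  }, numeric(1))
  pl_eq <- panel_lod(hyp$label[1:3], rep(0.05, 3), rhos_eq)
  expect_lt(diff(range(pl_eq$lod_total)), 1e-4)

  # a strong-penalty panel is flagged as LOD < 1%
  pl_strong <- panel_lod(c("a", "b"), c(0.05, 0.05),
                         log1p(0.05 / 0.95 * c(120, 90)))
  expect_true(attr(pl_strong, "lod_below_1pct"))
  expect_false(attr(pl, "lod_below_1pct"))  # the default-table panel is not
})
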