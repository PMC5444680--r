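test_that("a single noise-free species reduces to the plain Langmuir isotherm", {
  ps <- kras_ps()
  cfg <- noise_free_config(A = 2e3, dG_pm = -1)
  spec <- wt_spec(c_total = 5)
  tbl <- simulate_array(ps, spec, cfg)
  # independent oracle: per-probe scalar free energies through duplex_delta_g
  RT <- cfg$thermo$RT
  idx <- seq(1, nrow(ps$probes), by = 23)
  for (i in idx) {
    dg <- duplex_delta_g(ps$probes[i, ], kras_target(), cfg$dG_pm,
                         cfg$penalties)
    expect_equal(tbl$intensity[i], cfg$A * 5 * exp(-dg / RT),
                 tolerance = 1e-12)
  }
})

test_that("competitive mixture intensity matches the hand-computed two-species sum", {
  target <- target_sequence("ACGTACGTACGTA", "toy")
  ps <- design_probeset(target, edge_margin = 4, min_separation = 5)
  RT <- thermo_config()$RT
  # uniform penalty 2*RT, baseline -4*RT: for the 1MM probe matching the
  # mutant, dG_wt/RT = -2 and dG_mut/RT = -4
  pen <- default_penalty_table()
  pen$ddG <- rep(2 * RT, nrow(pen))
  cfg <- noise_free_config(A = 1, dG_pm = -4 * RT, penalties = pen)
  mut <- apply_mutation(target, 5, "C")
  spec <- sample_spec(list(target, mut), c(0.95, 0.05))
  tbl <- simulate_array(ps, spec, cfg)
  probe <- which(ps$probes$n_mismatch == 1 & !is.na(ps$probes$pos1) &
                   ps$probes$pos1 == 5 & ps$probes$var1 == "C")
  expect_equal(tbl$intensity[probe], 0.95 * exp(2) + 0.05 * exp(4),
               tolerance = 1e-12)
  # equal free energies for both species: intensity depends only on c_total
  pm <- which(ps$probes$n_mismatch == 0)
  spec2 <- sample_spec(list(target), 1.0)
  mix_equal <- simulate_array(ps, spec2, cfg)
  spec3 <- sample_spec(list(target, target_sequence(target$bases, "copy")),
                       c(0.4, 0.6))
  expect_equal(simulate_array(ps, spec3, cfg)$intensity[pm],
               mix_equal$intensity[pm])
})

test_that("replicate noise is seeded, unbiased in the median, and optional", {
  ps <- kras_ps()
  cfg <- sim_config()
  spec <- wt_spec(5)
  t1 <- simulate_array(ps, spec, cfg, seed = 99)
  t2 <- simulate_array(ps, spec, cfg, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_array(ps, spec, cfg, seed = 100)
  expect_false(identical(t1$intensity, t3$intensity))
  # noise-free limit equals the expected intensity exactly
  nf <- simulate_array(ps, spec, noise_free_config())
  expect_equal(nf$intensity, unname(expected_intensity(ps, spec,
                                                       noise_free_config())))
  # Monte-Carlo oracle: median of many lognormal replicates ~ expected
  one <- design_probeset("ACGTACGTACGTA", 4, 5)
  one$probes <- one$probes[one$probes$n_mismatch == 0, ]
  cfg_mc <- sim_config(noise_cv = 0.2, background_mean = 0,
                       background_sd = 0, background_threshold = 0,
                       n_replicates = 1e4)
  spec_mc <- sample_spec(list(target_sequence("ACGTACGTACGTA")), 5)
  mc <- simulate_array(one, spec_mc, cfg_mc, seed = 7)
  expect_equal(mc$intensity,
               unname(expected_intensity(one, spec_mc, cfg_mc)),
               tolerance = 0.01)
})

test_that("expected intensity is monotone in the mutant fraction, branch-wise", {
  ps <- kras_ps()
  h <- kras_hyp()[kras_hyp()$label == "10C>G", ]
  cfg <- noise_free_config()
  fr <- c(0.001, 0.01, 0.05, 0.2)
  ints <- sapply(fr, function(f)
    expected_intensity(ps, mix_spec(h, f, 10), cfg))
  mut_probe <- which(ps$probes$probe_id == sprintf("m%02d%s", h$position,
                                                   h$alt_base))
  pm <- which(ps$probes$n_mismatch == 0)
  expect_true(all(diff(ints[mut_probe, ]) > 0))
  expect_true(all(diff(ints[pm, ]) < 0))
})

test_that("below-background flagging and the saturating option behave as documented", {
  ps <- kras_ps()
  cfg <- sim_config(background_threshold = 50)
  tbl <- simulate_array(ps, wt_spec(5), cfg, seed = 3)
  expect_identical(tbl$below_background, tbl$intensity < 50)
  expect_gt(sum(tbl$below_background), 0)  # dim 2MM probes exist at 5 nM
  # saturating isotherm: I = A z/(1+z) < A z, approaching A as z grows
  sat <- noise_free_config(saturating = TRUE)
  lin <- noise_free_config()
  i_sat <- expected_intensity(ps, wt_spec(5), sat)
  i_lin <- expected_intensity(ps, wt_spec(5), lin)
  expect_true(all(i_sat < i_lin))
  expect_true(all(i_sat < sat$A))
})

test_that("dilution series fractions follow the stated start and factor", {
  ps <- kras_ps()
  h <- kras_hyp()[kras_hyp()$label == "10C>G", ]
  ser <- make_dilution_series(ps, h, 0.10, 2.5, 6, c_total = 5,
                              config = noise_free_config(), seed = 1)
  expect_equal(signif(100 * ser$fractions, 2),
               c(10, 4.0, 1.6, 0.64, 0.26, 0.10))
  expect_length(ser$samples, 6)
  expect_equal(attr(ser$samples[[3]]$spec, "c_total"), 5)
  ser2 <- make_dilution_series(ps, h, 0.08, 2, 4,
                               config = noise_free_config(), seed = 1)
  expect_equal(100 * ser2$fractions, c(8, 4, 2, 1))
  ser3 <- make_dilution_series(ps, h, 0.05, 2.5, 1,
                               config = noise_free_config(), seed = 1)
  expect_equal(ser3$fractions, 0.05)
  expect_error(make_dilution_series(ps, h, 0, 2.5, 6), "start_fraction")
  expect_error(make_dilution_series(ps, h, 0.1, 0.5, 6), "dilution_factor")
})

test_that("sample specifications validate concentrations", {
  expect_error(sample_spec(c(a = "ACGTACG"), c(1, 2)), "one concentration")
  expect_error(sample_spec(c(a = "ACGTACG"), -1), ">= 0")
  expect_error(mixture_spec(kras_target(), kras_target(), 1.2), "fraction")
  m <- mixture_spec(kras_target(),
                    apply_mutation(kras_target(), 13, "G"), 0.05, 10)
  expect_equal(sum(m$conc_nM), 10)
  expect_equal(attr(m, "fraction_total"), 0.05)
  # c_mut/c_wt convention converts to the same total
  m2 <- mixture_spec(kras_target(),
                     apply_mutation(kras_target(), 13, "G"),
                     0.05 / 0.95, 10, fraction_of = "wt")
  expect_equal(m2$conc_nM, m$conc_nM)
})
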