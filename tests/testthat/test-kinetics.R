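test_that("inhibition rate reproduces its analytic cases and is affine-invariant", {
  expect_equal(inhibition_rate(10, 10, 2), 0)    # sample == control
  expect_equal(inhibition_rate(10, 2, 2), 100)   # sample == blank
  expect_equal(inhibition_rate(10, 4, 2), 75)
  # common rescaling of all three concentrations changes nothing
  set.seed(31)
  for (i in 1:20) {
    ctl <- runif(1, 5, 20); blk <- runif(1, 0, ctl - 1); smp <- runif(1, 0, 30)
    k <- runif(1, 0.1, 50)
    expect_equal(inhibition_rate(k * ctl, k * smp, k * blk),
                 inhibition_rate(ctl, smp, blk))
  }
  expect_error(inhibition_rate(5, 3, 5), "undefined")
  expect_error(inhibition_rate(-1, 0, 0), "non-negative")
})

test_that("both Michaelis-Menten routes recover exact parameters and agree", {
  S <- c(0.5, 1, 2, 4, 5)
  v <- 2 * S / (1 + S)
  lb <- fit_mm(S, v)
  nl <- fit_mm(S, v, method = "nonlinear")
  expect_equal(lb$km, 1, tolerance = 1e-8)
  expect_equal(lb$vmax, 2, tolerance = 1e-8)
  expect_equal(nl$km, lb$km, tolerance = 1e-8)
  expect_equal(nl$vmax, lb$vmax, tolerance = 1e-8)
  expect_error(fit_mm(S[1:2], v[1:2]), "at least 3")
  # double-reciprocal line with negative intercept: not Michaelis-Menten
  v_bad <- 1 / (1 / S - 0.1)
  expect_error(fit_mm(S, v_bad), "inconsistent")
})

test_that("apparent parameters follow the competitive closed form", {
  km <- 1.3; vmax <- 1.7; ki <- 0.25
  for (I in c(0.2, 0.5)) {
    g <- gen_kinetics(1, "competitive", vmax = vmax, km = km, ki = ki,
                      inhibitor_concs = c(0, I))
    f <- fit_inhibition_series(g$data)
    expect_equal(f$inhibited[[1]]$km, km * (1 + I / ki), tolerance = 1e-8)
    expect_equal(f$inhibited[[1]]$vmax, vmax, tolerance = 1e-8)
  }
})

test_that("every generating mechanism is classified back at zero noise", {
  for (mode in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    g <- gen_kinetics(1, mode)
    fits <- fit_inhibition_series(g$data)
    cls <- classify_inhibition(fits$control, fits$inhibited)
    expected <- c(competitive = "competitive",
                  noncompetitive = "non-competitive",
                  uncompetitive = "uncompetitive", mixed = "mixed")[[mode]]
    expect_equal(cls$mode, expected)
    # fitted apparent parameters equal the generator's truth
    app <- g$truth$apparent
    for (f in fits$inhibited) {
      row <- app[app$inhibitor_conc == f$inhibitor_conc, ]
      expect_equal(f$km, row$km_apparent, tolerance = 1e-7)
      expect_equal(f$vmax, row$vmax_apparent, tolerance = 1e-7)
    }
  }
})

test_that("an uninhibited series classifies as no inhibition", {
  S <- c(0.5, 1, 2, 4, 5)
  v <- 2 * S / (1 + S)
  ctrl <- fit_mm(S, v)
  same <- fit_mm(S, v, inhibitor_conc = 0.5)
  expect_equal(classify_inhibition(ctrl, same)$mode, "none")
  expect_error(classify_inhibition(inhibited = same), "control")
})

test_that("classification is invariant to the inhibitor concentration unit", {
  g <- gen_kinetics(1, "mixed")
  f1 <- fit_inhibition_series(g$data)
  d2 <- g$data
  d2$inhibitor_conc <- d2$inhibitor_conc * 1000   # mg/mL -> ug/mL
  f2 <- fit_inhibition_series(d2)
  expect_equal(classify_inhibition(f1$control, f1$inhibited)$mode,
               classify_inhibition(f2$control, f2$inhibited)$mode)
})

test_that("mixed inhibition with alpha = 1 reduces to non-competitive", {
  gm <- gen_kinetics(1, "mixed", alpha = 1)
  gn <- gen_kinetics(1, "noncompetitive")
  expect_equal(gm$data$velocity, gn$data$velocity, tolerance = 1e-12)
  f <- fit_inhibition_series(gm$data)
  expect_equal(classify_inhibition(f$control, f$inhibited)$mode,
               "non-competitive")
})

test_that("the Lineweaver-Burk table is the double reciprocal of the data", {
  g <- gen_kinetics(1, "competitive")
  tab <- lineweaver_burk_table(g$data)
  expect_equal(tab$inv_substrate, 1 / g$data$substrate_mM)
  expect_equal(tab$inv_velocity, 1 / g$data$velocity)
})

test_that("digestion stability verdicts reflect significance and fold change", {
  expect_true(compare_stability(c(5.1, 5.0, 4.9), c(5.0, 5.1, 4.95))$stable)
  set.seed(32)
  res <- compare_stability(rnorm(3, 5, 0.2), rnorm(3, 33, 0.2))
  expect_false(res$stable)
  expect_true(res$significant)
  expect_gt(res$ratio, 2)
  expect_error(compare_stability(c(1, 2), c(1, 2, 3)), "3 replicates")
  expect_warning(compare_stability(c(5, 5.1, 4.9), c(5, 5.1, 4.9), alpha = 0),
                 "degenerate")
})

test_that("dose-response fitting recovers exact and noisy log-logistic curves", {
  g <- gen_dose_response(seed = 1, ic50 = 5, hill = 1)
  fit <- fit_dose_response(g$data$concentration, g$data$inhibition_pct)
  expect_equal(fit$ic50, 5, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$method, "log_logistic")
  # steeper curve
  g2 <- gen_dose_response(seed = 1, ic50 = 0.8, hill = 2.5)
  fit2 <- fit_dose_response(g2$data$concentration, g2$data$inhibition_pct)
  expect_equal(fit2$ic50, 0.8, tolerance = 1e-6)
  # noisy recovery across seeds (3% assay noise): aggregate error within 10%
  errs <- sapply(1:25, function(s) {
    gn <- gen_dose_response(seed = s, ic50 = 5, hill = 1, sigma = 3)
    abs(fit_dose_response(gn$data$concentration, gn$data$inhibition_pct)$ic50 - 5) / 5
  })
  expect_lt(mean(errs), 0.10)
})

test_that("dose-response preconditions are enforced", {
  conc <- c(0.1, 0.2, 0.5, 1)
  expect_error(fit_dose_response(conc, c(5, 10, 20, 38)), "extend the upper")
  expect_error(fit_dose_response(conc, c(60, 70, 80, 90)), "extend the lower")
  expect_error(fit_dose_response(conc[1:3], c(10, 50, 90)), "at least 4")
  expect_error(fit_dose_response(conc, c(-20, 10, 60, 90)), "band")
})
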