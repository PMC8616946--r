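# Adsorption-energy principle: scaling relation, free energies, partition
# fractions, thresholds and the standard-table audit.

test_that("scaling relation predicts O adsorption from HO adsorption", {
  expect_equal(o_from_oh(0), 1.42)
  expect_equal(o_from_oh(-2.7), 1.87 * (-2.7) + 1.42)
  expect_equal(o_from_oh(1.0), 3.29)
  expect_error(o_from_oh(Inf), class = "sodscreen_invalid_input")
})

test_that("scaling-relation fit recovers exact and noiseless lines", {
  fit <- fit_scaling_relation(c(0, 1), c(1, 3))
  expect_equal(coef(fit), c(intercept = 1, slope = 2))
  expect_equal(fit$residual_rms, 0)
  expect_equal(fit$n_points, 2L)

  pts <- generate_scaling_points(50, slope = 1.87, intercept = 1.42,
                                 noise_sd = 0, seed = 7)
  fit <- fit_scaling_relation(pts)
  expect_equal(fit$slope, 1.87, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.42, tolerance = 1e-10)
  expect_lt(fit$residual_rms, 1e-10)

  expect_error(fit_scaling_relation(c(1, 1), c(5, 6)),
               class = "sodscreen_degenerate_fit")
  expect_error(fit_scaling_relation(1, 5),
               class = "sodscreen_degenerate_fit")
})

test_that("scaling-relation fit is unbiased under Gaussian noise", {
  errs <- vapply(1:40, function(s) {
    pts <- generate_scaling_points(200, noise_sd = 0.2, seed = s)
    fit_scaling_relation(pts)$slope - 1.87
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("free energies reproduce the canonical pH-7 expressions", {
  g0 <- reaction_free_energies(adsorption_energies(0, 0))$drG
  expect_equal(unname(g0), c(-1.3, 1.4, 2.1, 8.54, 16.4))

  g <- reaction_free_energies(adsorption_energies(-2.7, -3.4))$drG
  expect_equal(unname(g), c(-1.3, -1.3, -1.3, 0.791, 2.902),
               tolerance = 1e-12)
})

test_that("each reaction shifts by one Nernst term per pH unit", {
  g7 <- reaction_free_energies(adsorption_energies(0, 0),
                               reaction_conditions(ph = 7))$drG
  g8 <- reaction_free_energies(adsorption_energies(0, 0),
                               reaction_conditions(ph = 8))$drG
  expect_equal(unname(g8 - g7), rep(0.0592, 5))

  cond2 <- reaction_conditions(ph = 9,
                               proton_coefficients = c(1, 2, 0, 1, 1))
  g9 <- reaction_free_energies(adsorption_energies(0, 0), cond2)$drG
  expect_equal(unname(g9 - g7), c(1, 2, 0, 1, 1) * 0.0592 * 2)
})

test_that("an explicit O adsorption energy overrides the scaling relation", {
  ads <- adsorption_energies(-1, -1, e_ads_o = -2)
  expect_false(ads$o_filled)
  g <- reaction_free_energies(ads)$drG
  expect_equal(unname(g[["iv"]]), -1 + -2 + (8.54 - 1.42))
  expect_equal(unname(g[["v"]]), -1 + 2 * -2 + (16.4 - 2 * 1.42))
})

test_that("partition fractions are normalized, bounded and symmetric", {
  pr <- partition_fractions(rep(1.7, 5))
  expect_equal(unname(pr$fractions), rep(0.2, 5))

  pr <- partition_fractions(c(-5, 5, 5, 5, 5))
  expect_equal(pr$x1, 1, tolerance = 1e-30)

  for (seed in 1:20) {
    set.seed(seed)
    pr <- partition_fractions(runif(5, -5, 5))
    expect_equal(sum(pr$fractions), 1, tolerance = 1e-12)
    expect_true(all(pr$fractions >= 0 & pr$fractions <= 1))
    expect_identical(pr$x1, unname(pr$fractions[1]))
  }
  expect_error(partition_fractions(c(1, 2, 3, 4, NA)),
               class = "sodscreen_invalid_input")
})

test_that("partition fractions stay finite at extreme free energies", {
  kT <- 8.617333262e-5 * 298.15
  g <- c(-1, 1, 0.5, 0.2, -0.3) * 1e3 * kT    # |drG|/kT up to 1e3
  pr <- partition_fractions(g)
  expect_true(all(is.finite(pr$fractions)))
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-12)
  expect_equal(pr$x1, 1, tolerance = 1e-100)
})

test_that("x1 sits at 0.5 on the HO threshold boundary", {
  pr <- partition_fractions(
    reaction_free_energies(adsorption_energies(-2.7, 0)))
  expect_equal(pr$x1, 0.5, tolerance = 1e-6)
  expect_false(pr$passes)   # strict inequality: the boundary fails
})

test_that("x1 is strictly increasing in both adsorption energies", {
  set.seed(11)
  for (i in 1:25) {
    ho <- runif(1, -3.2, -0.5)
    h <- runif(1, -4.0, -0.5)
    x0 <- partition_fractions(
      reaction_free_energies(adsorption_energies(ho, h)))$x1
    x_ho <- partition_fractions(
      reaction_free_energies(adsorption_energies(ho + 0.05, h)))$x1
    x_h <- partition_fractions(
      reaction_free_energies(adsorption_energies(ho, h + 0.05)))$x1
    expect_gte(x_ho, x0)
    expect_gte(x_h, x0)
  }
})

test_that("x1 is invariant to pH under equal proton coefficients", {
  set.seed(3)
  for (ph in c(0, 2, 7, 10, 14)) {
    cond <- reaction_conditions(ph = ph)
    x <- partition_fractions(
      reaction_free_energies(adsorption_energies(-2.0, -2.5), cond))$x1
    x7 <- partition_fractions(
      reaction_free_energies(adsorption_energies(-2.0, -2.5)))$x1
    expect_equal(x, x7, tolerance = 1e-12)
  }
})

test_that("criterion thresholds solve side-reaction degeneracy", {
  thr <- criterion_thresholds()
  expect_equal(unname(thr), c(-2.7, -3.4))
  # common pH shift cancels
  expect_equal(unname(criterion_thresholds(reaction_conditions(ph = 2))),
               c(-2.7, -3.4))
  # custom constants: drG1 = 0, drG2 = E + 1 -> threshold -1
  cst <- energy_constants(drG1 = 0, drG2_offset = 1)
  expect_equal(criterion_thresholds(constants = cst)[["ho_threshold"]], -1)
})

test_that("adsorption criterion flags known weak and strong binders", {
  # defect-free ceria (111): H binds too strongly
  expect_false(evaluate_adsorption_criterion(
    adsorption_energies(-2.0, -3.68))$passes)
  # vanadium MOF values: H criterion violated
  expect_false(evaluate_adsorption_criterion(
    adsorption_energies(-0.76, -4.25))$passes)
  # inside the pass rectangle
  expect_true(evaluate_adsorption_criterion(
    adsorption_energies(-2.5, -3.0))$passes)
  # boundary fails under the strict inequality
  expect_false(evaluate_adsorption_criterion(
    adsorption_energies(-2.7, -1.0))$passes)
})

test_that("rectangle and full-x1 modes agree away from the thresholds", {
  set.seed(5)
  thr <- criterion_thresholds()
  for (i in 1:60) {
    ho <- runif(1, -4, 0)
    h <- runif(1, -5, 0)
    if (abs(ho - thr[["ho_threshold"]]) < 0.1 ||
        abs(h - thr[["h_threshold"]]) < 0.1) next
    ads <- adsorption_energies(ho, h)
    expect_identical(
      evaluate_adsorption_criterion(ads, mode = "rectangle")$passes,
      evaluate_adsorption_criterion(ads, mode = "full_x1")$passes,
      info = sprintf("ho=%.3f h=%.3f", ho, h))
  }
})

test_that("x1 grid is monotone and correct at its anchor points", {
  g <- x1_grid(c(-3.2, -1), c(-4, -1), n_ho = 8, n_h = 6)
  expect_true(all(apply(g$x1, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(apply(g$x1, 1, function(row) all(diff(row) >= 0))))

  corner <- x1_grid(c(-2.0, -1.0), c(-2.5, -1.0), n_ho = 2, n_h = 2)
  expect_true(all(corner$x1 > 0.5))

  b <- x1_grid(c(-2.7, -1), c(0, 1), n_ho = 2, n_h = 2)
  expect_equal(b$x1[1, 1], 0.5, tolerance = 1e-6)

  expect_error(x1_grid(c(-1, -1), c(0, 1)),
               class = "sodscreen_invalid_input")
})

test_that("adsorption energy follows the total-energy convention", {
  expect_equal(adsorption_energy_from_totals(-105, -100, -3), -2)
  expect_equal(adsorption_energy_from_totals(-100, -100, 0), 0)
  expect_equal(adsorption_energy_from_totals(-104.5, -100, -3), -1.5)
  expect_error(adsorption_energy_from_totals(NaN, 0, 0),
               class = "sodscreen_invalid_input")
})

test_that("constant audit reconstructs reactions i-ii and flags iii-v", {
  audit <- audit_constants()
  expect_equal(audit$reconstructed[1], -0.86 + 0.0592 * 7 - 0.86)
  expect_lt(abs(audit$reconstructed[1] - (-1.3)), 0.01)
  expect_false(audit$flagged[1])
  # reaction ii rounds to 1.4 at two significant figures
  expect_equal(signif(audit$reconstructed[2], 2), 1.4)
  # reaction iii does not reproduce the canonical constant; flagged
  expect_gt(abs(audit$difference[3]), 0.1)
  expect_true(audit$flagged[3])
  expect_true(all(audit$flagged[4:5]))

  broken <- standard_thermo_table()
  broken$drG9_std <- NA_real_
  expect_error(audit_constants(broken), class = "sodscreen_invalid_input")
})
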