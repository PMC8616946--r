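# Three-stage screening funnel and the supercell planner.

test_that("stability stage reports every violated condition", {
  cfg <- screen_config()
  ok <- material_record("a", n_elements = 2, delta_h_hull = 0.1,
                        omega2_min = 1e-3, e_gap_hse = 1.2)
  expect_true(stage_stability(ok, cfg)$passed)

  zero_gap <- material_record("b", n_elements = 2, delta_h_hull = 0.1,
                              omega2_min = 1e-3, e_gap_hse = 0)
  res <- stage_stability(zero_gap, cfg)
  expect_false(res$passed)
  expect_equal(res$fail_reasons, "zero_gap")

  multi <- material_record("c", n_elements = 3, delta_h_hull = 0.25,
                           omega2_min = 1e-3, e_gap_hse = 1)
  res <- stage_stability(multi, cfg)
  expect_setequal(res$fail_reasons, c("too_many_elements", "hull_exceeded"))

  # strictness at the exact thresholds
  at_hull <- material_record("d", n_elements = 2, delta_h_hull = 0.2,
                             omega2_min = 1e-3, e_gap_hse = 1)
  expect_equal(stage_stability(at_hull, cfg)$fail_reasons, "hull_exceeded")
})

test_that("missing stability data fails with a coded reason, not a pass", {
  r <- material_record("m", n_elements = 2, delta_h_hull = NA,
                       omega2_min = 1e-3, e_gap_hse = 1)
  res <- suppressMessages(stage_stability(r))
  expect_false(res$passed)
  expect_true("missing_data:delta_h_hull" %in% res$fail_reasons)
})

test_that("energy-level stage admits only the configured band types", {
  cfg <- screen_config()
  expect_true(stage_energy_level(passing_record("a", "II"), cfg)$passed)
  expect_true(stage_energy_level(passing_record("a", "I"), cfg)$passed)

  both <- material_record("b", n_elements = 2,
                          band = gapped_summary("b", vbm = 0.8, cbm = 0.0))
  res <- stage_energy_level(both, cfg)
  expect_false(res$passed)
  expect_equal(res$fail_reasons, "disallowed_type")
  expect_equal(res$band_type, "III")

  metal <- material_record("c", n_elements = 1,
                           band = metal_summary("c", 0.2))
  res <- stage_energy_level(metal, cfg)
  expect_false(res$passed)   # IX not in {I, II}
  expect_equal(res$fail_reasons, "disallowed_type")

  none <- material_record("d", n_elements = 2,
                          band = gapped_summary("d", vbm = 2, cbm = 1.2))
  expect_equal(stage_energy_level(none, cfg)$fail_reasons, "no_ifmo")

  wider <- screen_config(allowed_types = c("I", "II", "III", "IX"))
  expect_true(stage_energy_level(both, wider)$passed)
  expect_true(stage_energy_level(metal, wider)$passed)
})

test_that("adsorption stage applies strict thresholds with coded reasons", {
  cfg <- screen_config()
  ok <- material_record("a", e_ads_ho = -1, e_ads_h = -1)
  expect_true(stage_adsorption(ok, cfg)$passed)

  at_thr <- material_record("b", e_ads_ho = -2.7, e_ads_h = -1)
  res <- stage_adsorption(at_thr, cfg)
  expect_false(res$passed)
  expect_equal(res$fail_reasons, "ho_below_threshold")

  mof <- material_record("c", e_ads_ho = -0.76, e_ads_h = -4.25)
  res <- stage_adsorption(mof, cfg)
  expect_false(res$passed)
  expect_equal(res$fail_reasons, "h_below_threshold")

  missing <- material_record("d", e_ads_ho = -1)
  res <- suppressMessages(stage_adsorption(missing, cfg))
  expect_false(res$passed)
  expect_equal(res$fail_reasons, "missing_data:e_ads_h")

  full <- screen_config(adsorption_mode = "full_x1")
  res <- stage_adsorption(mof, full)
  expect_equal(res$fail_reasons, "x1_not_dominant")
  expect_lt(res$x1, 0.5)
})

test_that("funnel counts are non-increasing and survivors are nested", {
  tab <- generate_materials_table(fixture_spec(n_materials = 300, seed = 4))
  rep <- run_screen(tab)
  expect_equal(rep$input_count, 300L)
  expect_true(all(diff(rep$counts) <= 0))
  res <- rep$results
  # stage-k evaluation only for stage-(k-1) survivors
  expect_true(all(is.na(res$stage2_passed[!res$stage1_passed])))
  expect_true(all(!is.na(res$stage2_passed[res$stage1_passed])))
  expect_true(all(is.na(res$stage3_passed[!res$stage2_passed %in% TRUE])))
  # passes carry no reasons; fails carry at least one
  passed_all <- res$stage3_passed %in% TRUE
  expect_true(all(res$fail_reasons[passed_all] == ""))
  expect_true(all(nzchar(res$fail_reasons[!passed_all])))
})

test_that("funnel results are order-invariant and seed-reproducible", {
  tab <- generate_materials_table(fixture_spec(n_materials = 120, seed = 9))
  rep1 <- run_screen(tab)
  shuffled <- tab[rev(seq_along(tab))]
  class(shuffled) <- "materials_table"
  rep2 <- run_screen(shuffled)
  expect_equal(rep1$counts, rep2$counts)
  r1 <- rep1$results[order(rep1$results$material_id), ]
  r2 <- rep2$results[order(rep2$results$material_id), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("the packaged synthetic fixture yields pinned funnel counts", {
  tab <- generate_materials_table(fixture_spec(n_materials = 500, seed = 42))
  rep <- run_screen(tab)
  expect_equal(unname(rep$counts),
               c(500L, 54L, 17L, 15L))
  rep_again <- run_screen(generate_materials_table(
    fixture_spec(n_materials = 500, seed = 42)))
  expect_equal(rep$counts, rep_again$counts)
})

test_that("relaxed thresholds pass everything; degenerate tables error", {
  tab <- generate_materials_table(fixture_spec(n_materials = 80, seed = 2))
  # a huge window tolerance puts every frontier level inside; pushing the
  # target free energy far down sends both adsorption thresholds to -Inf
  lax <- screen_config(max_elements = Inf, hull_max = Inf,
                       omega2_min_threshold = -Inf, gap_min = -Inf,
                       window = potential_window(tolerance = 100),
                       allowed_types = c("I", "II", "III", "IV", "V", "VI",
                                         "VII", "VIII", "IX", "X", "XI"),
                       constants = energy_constants(drG1 = -1e6))
  rep <- run_screen(tab, lax)
  expect_equal(unname(rep$counts[c("input", "stability")]), c(80L, 80L))
  expect_equal(unname(rep$counts[["energy_level"]]), 80L)
  expect_equal(unname(rep$counts[["adsorption"]]), 80L)

  all_fail <- lapply(1:10, function(i)
    material_record(paste0("f", i), n_elements = 9, delta_h_hull = 5,
                    omega2_min = -1, e_gap_hse = 0))
  rep <- run_screen(all_fail)
  expect_equal(unname(rep$counts), c(10L, 0L, 0L, 0L))

  expect_error(run_screen(list()), class = "sodscreen_invalid_table")
  dup <- list(passing_record("x"), passing_record("x"))
  expect_error(run_screen(dup), class = "sodscreen_invalid_table")
})

test_that("supercell planner follows aspect then minimum-length checks", {
  expect_equal(unname(supercell_plan(10, 4)), c(1L, 2L))
  expect_equal(unname(supercell_plan(4, 10)), c(2L, 1L))
  expect_equal(unname(supercell_plan(4, 4)), c(2L, 2L))
  expect_equal(unname(supercell_plan(6, 6)), c(1L, 1L))
  # boundary conventions: aspect strictly > 1.5x; length <= 5 triggers
  expect_equal(unname(supercell_plan(6, 4)), c(2L, 2L))   # 6 = 1.5*4 exactly
  expect_equal(unname(supercell_plan(5, 8)), c(2L, 1L))  # a doubled past 5
  expect_equal(unname(supercell_plan(3, 2)), c(2L, 2L))
  expect_equal(unname(supercell_plan(1, 20)), c(4L, 2L))
  expect_true(all(supercell_plan(1, 20) %in% c(1L, 2L, 4L)))
  expect_error(supercell_plan(0, 5), class = "sodscreen_invalid_input")
})

test_that("supercell planner is idempotent on its own output", {
  set.seed(21)
  for (i in 1:40) {
    a <- runif(1, 2, 12); b <- runif(1, 2, 12)
    m <- supercell_plan(a, b)
    a2 <- a * m[["multiplier_a"]]; b2 <- b * m[["multiplier_b"]]
    if (a2 > 5 && b2 > 5 && a2 <= 1.5 * b2 && b2 <= 1.5 * a2) {
      expect_equal(unname(supercell_plan(a2, b2)), c(1L, 1L))
    }
  }
})
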