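# Sweep-engine mechanics run on the toy clock: seconds-fast and with known
# duty-cycle behaviour (mean expression = offset + amplitude * Ph/Pr).

toy_settings <- sim_settings(entrain_cycles = 3, max_cycles = 200,
                             convergence_tol = 1e-8, output_dt = 0.1)

test_that("a singleton sweep equals direct simulation and conversion", {
  sw <- sweep_single("photoperiod", values = 12, settings = toy_settings,
                     model = "toy")
  direct <- phenotypes(simulate_entrained(light_profile(), toy_settings, "toy"))
  expect_equal(nrow(sw$rows), 1L)
  expect_equal(sw$rows$days_to_flower, direct$days_to_flower)
  expect_equal(sw$rows$hypocotyl_mm, direct$hypocotyl_mm)
  expect_equal(sw$rows$days_to_flower, sw$baseline_row$days_to_flower)
})

test_that("sweeps keep one ordered row per requested value with status", {
  vals <- c(18, 6, 12)
  sw <- sweep_single("photoperiod", values = vals, settings = toy_settings,
                     model = "toy")
  expect_equal(nrow(sw$rows), 3L)
  expect_equal(sw$rows$value, vals)          # order preserved
  expect_equal(sw$rows$ph_hours, vals)
  expect_true(all(sw$rows$status == "ok"))
  expect_error(sweep_single("brightness", values = 1), "unknown sweep property")
  expect_error(sweep_single("photoperiod", values = numeric(0)), "non-empty")
})

test_that("toy end-to-end sweep shows duty-cycle monotonicity", {
  sw <- sweep_single("photoperiod", values = seq(4, 20, by = 4),
                     settings = toy_settings, model = "toy")
  expect_true(all(diff(sw$rows$ft_area) > 0))          # more light, more FT
  expect_true(all(diff(sw$rows$days_to_flower) < 0))   # hence fewer days
})

test_that("failed cells are recorded per row and the sweep continues", {
  bad <- sim_settings(entrain_cycles = 1, max_cycles = 1,
                      convergence_tol = 1e-14, output_dt = 0.1)
  sw <- sweep_single("photoperiod", values = c(6, 12), settings = bad,
                     model = toy_clock_model(0.05))
  expect_equal(nrow(sw$rows), 2L)
  expect_true(all(grepl("error", sw$rows$status)))
  expect_true(all(is.na(sw$rows$days_to_flower)))
})

test_that("stage-1 grid search filters, ranks and recommends", {
  crit <- rec_criteria(max_days = 1e3, max_hypocotyl = 1e3)
  res <- collective_stage1(pr_values = c(20, 24), ph_values = c(10, 12, 22),
                           settings = toy_settings, model = "toy",
                           criteria = crit)
  # (pr=20, ph=22) is invalid and skipped; 5 evaluated cells remain
  expect_equal(res$n_skipped, 1L)
  expect_equal(nrow(res$rows), 5L)
  expect_equal(res$status, "ok")
  # toy model: highest duty cycle flowers earliest
  expect_equal(res$best$pr_hours, 24)
  expect_equal(res$best$ph_hours, 22)
  # the recommendation obeys the criteria-resolved rule and is feasible
  expect_true(res$recommended$days_to_flower <=
                min(res$feasible$days_to_flower) + crit$comparable_days)

  # singleton grid reduces to the base case
  solo <- collective_stage1(pr_values = 24, ph_values = 12,
                            settings = toy_settings, model = "toy",
                            criteria = crit)
  expect_equal(solo$best$days_to_flower, solo$baseline_row$days_to_flower)

  # impossible thresholds give an explicit empty result, not an error
  empty <- collective_stage1(pr_values = 24, ph_values = 12,
                             settings = toy_settings, model = "toy",
                             criteria = rec_criteria(max_days = 1e-3))
  expect_equal(empty$status, "empty feasible set")
  expect_null(empty$best)
})

test_that("stage-1 alternates have shorter photoperiods, ranked by light budget", {
  crit <- rec_criteria(max_days = 1e3, max_hypocotyl = 1e3,
                       comparable_days = 30, comparable_mm = 1e3)
  res <- collective_stage1(pr_values = 24, ph_values = c(14, 16, 18, 20),
                           settings = toy_settings, model = "toy",
                           criteria = crit)
  alt <- res$alternates
  expect_true(all(alt$ph_hours < res$best$ph_hours))
  expect_true(!is.unsorted(alt$eldf_hours))
})

test_that("stage-2 identity cell reproduces the fixed profile; offsets are flagged", {
  fixed <- light_profile(ph_hours = 18)
  crit <- rec_criteria(max_days = 1e3, max_hypocotyl = 1e3)
  res <- collective_stage2(amplitudes = 1, offsets = 0, fixed = fixed,
                           settings = toy_settings, model = "toy",
                           criteria = crit)
  direct <- phenotypes(simulate_entrained(fixed, toy_settings, "toy"))
  expect_equal(res$rows$days_to_flower, direct$days_to_flower)

  res2 <- collective_stage2(amplitudes = c(0.99, 1), offsets = c(0, 0.02),
                            fixed = fixed, settings = toy_settings,
                            model = "toy", criteria = crit)
  flagged <- res2$rows$offset > 0
  expect_true(all(grepl("BACKGROUND_LIGHT", res2$rows$flags[flagged])))
  expect_false(any(grepl("BACKGROUND_LIGHT", res2$rows$flags[!flagged])))
  # ranked by days then energy
  expect_true(!is.unsorted(res2$rows$days_to_flower))
})

test_that("the selection rule prefers no background light within the margin", {
  # two feasible rows 1 day apart: offset-free row must win the recommendation
  rows <- data.frame(pr_hours = 24, ph_hours = 18, dw_hours = 0,
                     tw_hours = 0.05, amplitude = c(0.99, 0.99),
                     offset = c(0.04, 0), days_to_flower = c(20.6, 21.6),
                     hypocotyl_mm = c(1.19, 1.19), ft_area = 1,
                     eldf_hours = c(370, 389), energy_mwh_per_year = 3.62,
                     flags = "", cycles = 12L, residual = 0, status = "ok",
                     stringsAsFactors = FALSE)
  crit <- greenlight:::resolve_criteria(rec_criteria(), rows[1, ])
  pick <- greenlight:::select_recommended(rows, crit)
  expect_equal(pick$offset, 0)
  # beyond the comparability margin the faster schedule wins instead
  rows$days_to_flower <- c(18.0, 21.6)
  pick2 <- greenlight:::select_recommended(rows, crit)
  expect_equal(pick2$offset, 0.04)
})

test_that("influence table summarises all six properties deterministically", {
  mk <- function(property, values)
    sweep_single(property, values = values, settings = toy_settings,
                 model = "toy", cache = test_cache)
  sweeps <- list(mk("photoperiod", c(8, 12, 18)),
                 mk("offset", c(0, 0.03)),
                 mk("amplitude", c(0.95, 1, 1.05)),
                 mk("dawn", c(-6, 0, 6)),
                 mk("twilight", c(0.05, 1)),
                 mk("period_with_half_photoperiod", c(20, 24, 28)))
  tab <- summarize_influence(sweeps)
  expect_equal(nrow(tab), 6L)
  # the toy clock is exactly dawn-invariant
  expect_equal(tab$verdict[tab$property == "dawn"], "No change")
  expect_true(tab$days_improvement_pct[tab$property == "photoperiod"] > 0)
  # determinism: rebuilding the same sweeps gives identical rows
  tab2 <- summarize_influence(sweeps)
  expect_identical(tab, tab2)
  expect_error(summarize_influence(sweeps[-1]), "missing sweep")
})

test_that("the simulation cache returns identical rows and is actually shared", {
  cache <- new_sim_cache()
  s1 <- sweep_single("photoperiod", values = c(10, 12), settings = toy_settings,
                     model = "toy", cache = cache)
  n_after_first <- length(ls(cache))
  s2 <- sweep_single("photoperiod", values = c(10, 12), settings = toy_settings,
                     model = "toy", cache = cache)
  expect_identical(s1$rows, s2$rows)
  expect_equal(length(ls(cache)), n_after_first)  # nothing re-simulated
  expect_gt(n_after_first, 0L)
})
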