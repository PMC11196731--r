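toy_config <- function(...) {
  program_config(
    n_cameras = 2, program_years = 1, service_rounds_per_year = 1,
    staff_days_per_round = 1, round_km = 10, staff_day_cost = 400,
    vehicle_cost_per_km = 1, images_per_year = 1000,
    manual_rate_images_per_day = 2000, ai_fee_per_image = 0.01,
    hardware_unit_costs = list(camera_basic = 500),
    ...
  )
}

test_that("scenario kilometres are the linear product of rounds, distance and years", {
  cfg <- program_config(round_km = 300, service_rounds_per_year = 52,
                        program_years = 3)
  expect_equal(scenario_kilometres(cfg, "manual_manual"), 46800)
  expect_equal(scenario_kilometres(cfg, "manual_ai"), 46800)
  # zero connected rounds means no distance at all
  expect_equal(scenario_kilometres(cfg, "connected_ai"), 0)
})

test_that("connected-camera driving is a sliver of the manual distance under the preset", {
  cfg <- kifcep_preset()
  km_manual <- cfg$round_km * cfg$service_rounds_per_year[["manual_manual"]] *
    cfg$program_years  # hand product
  expect_equal(scenario_kilometres(cfg, "manual_manual"), km_manual)
  expect_lte(scenario_kilometres(cfg, "connected_ai"), 0.01 * km_manual)
})

test_that("manual-scenario costs hand-sum over the toy program", {
  bd <- scenario_cost(toy_config(), "manual_manual")
  expect_equal(bd$hardware, 1000)         # 2 cameras at $500
  expect_equal(bd$travel, 10)             # 10 km at $1
  expect_equal(bd$staff_field, 400)       # 1 staff-day at $400
  expect_equal(bd$staff_processing, 200)  # 1000 images / 2000 per day
  expect_equal(bd$ai_fees, 0)
  expect_equal(bd$total, 1000 + 10 + 400 + 200 + bd$consumables)
})

test_that("the AI scenario swaps processing labour for per-image fees", {
  bd <- scenario_cost(toy_config(), "manual_ai")
  expect_equal(bd$ai_fees, 10)            # 1000 images at $0.01
  expect_equal(bd$staff_processing, 0)
})

test_that("an all-zero program costs nothing in every scenario", {
  cfg <- program_config()
  for (s in scenario_kinds()) {
    bd <- scenario_cost(cfg, s)
    expect_equal(bd$total, 0)
    expect_true(all(as.numeric(bd[-1]) == 0))
  }
})

test_that("invalid configurations and unknown scenarios are rejected", {
  expect_error(program_config(n_cameras = -1), "n_cameras")
  expect_error(program_config(antenna_fraction = 1.5), "antenna_fraction")
  expect_error(program_config(program_years = 0), "program_years")
  expect_error(scenario_cost(toy_config(), "drone_ai"), "unknown scenario")
})

test_that("comparison against the baseline follows the savings arithmetic", {
  cmp <- compare_scenarios(data.frame(
    scenario = c("manual_manual", "manual_ai"), total = c(100, 100)))
  expect_equal(cmp$saving_vs_baseline, c(0, 0))
  expect_equal(cmp$saving_pct, c(0, 0))

  # a dearer scenario shows a negative saving, not an error
  cmp <- compare_scenarios(data.frame(
    scenario = c("manual_manual", "connected_ai"), total = c(100, 150)))
  expect_equal(cmp$saving_vs_baseline[2], -50)
  expect_equal(cmp$saving_pct[2], -50)

  expect_error(
    compare_scenarios(data.frame(scenario = "manual_ai", total = 1)),
    "baseline")
})

test_that("cost components conserve, match the flat oracle and grow monotonically", {
  set.seed(401)
  for (i in 1:200) {
    cfg <- random_program_config()
    s <- sample(scenario_kinds(), 1)
    bd <- scenario_cost(cfg, s)
    comp_sum <- bd$hardware + bd$consumables + bd$staff_field +
      bd$staff_processing + bd$travel + bd$ai_fees + bd$connectivity
    expect_identical(bd$total, comp_sum)
    expect_true(all(as.numeric(bd[-1]) >= 0))
    expect_equal(bd$total, oracle_scenario_cost(cfg, s), tolerance = 1e-12)

    # monotonicity: more cameras / images / dearer staff never cheapen a scenario
    up <- cfg
    up$n_cameras <- cfg$n_cameras + sample(1:20, 1)
    up$images_per_year <- cfg$images_per_year + sample(1:5000, 1)
    up$staff_day_cost <- cfg$staff_day_cost + runif(1, 0, 100)
    expect_gte(scenario_cost(up, s)$total, bd$total)
  }
})

test_that("emissions are linear in distance and match hand arithmetic", {
  cfg <- program_config(round_km = 100000 / 52, service_rounds_per_year = 52,
                        program_years = 1, emission_g_per_km = 180)
  er <- emissions_report(cfg)
  expect_equal(er$co2_kg[er$scenario == "manual_manual"], 18000)
  expect_equal(er$co2_kg[er$scenario == "connected_ai"], 0)

  cfg2 <- kifcep_preset()
  er2 <- emissions_report(cfg2)
  cfg2$round_km <- cfg2$round_km * 2
  er3 <- emissions_report(cfg2)
  expect_equal(er3$co2_kg[1], 2 * er2$co2_kg[1])

  # saving percentage equals the hand computation on kilometres
  km_manual <- scenario_kilometres(cfg2, "manual_manual")
  km_conn <- scenario_kilometres(cfg2, "connected_ai")
  expect_equal(er2$saving_pct[er2$scenario == "connected_ai"],
               round_half_up(100 * (1 - km_conn / km_manual), 1))
})
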