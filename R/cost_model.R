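# Additive seven-component cost model for the three monitoring scenarios.
# Components: hardware (one-off), consumables (per round), staff_field,
# staff_processing, travel, ai_fees, connectivity. Initial deployment travel
# is identical across scenarios and therefore excluded everywhere.

rounds_for <- function(config, scenario) {
  unname(config$service_rounds_per_year[[scenario]])
}

is_ai_scenario <- function(scenario) scenario %in% c("manual_ai", "connected_ai")

#' Vehicle kilometres driven under one scenario
#'
#' Total service-round distance over the program:
#' `round_km * service_rounds_per_year[scenario] * program_years`. Connected
#' cameras keep only their (near-zero) maintenance-round frequency, since
#' images travel over the 4G network instead of in a vehicle.
#'
#' @param config a [program_config()].
#' @param scenario one of [scenario_kinds()].
#' @return Kilometres driven over the whole program (numeric scalar).
#' @export
#' @examples
#' cfg <- program_config(round_km = 300, service_rounds_per_year = 52,
#'                       program_years = 3)
#' scenario_kilometres(cfg, "manual_manual")  # 46800
scenario_kilometres <- function(config, scenario) {
  validate_program_config(config)
  check_scenario(scenario)
  config$round_km * rounds_for(config, scenario) * config$program_years
}

#' Lifetime cost breakdown of one scenario
#'
#' Costs the whole program as a sum of seven components:
#' \describe{
#'   \item{hardware}{one-off purchases — basic camera + SD card for the manual
#'     scenarios; 4G camera + solar panel + SD card, plus a long-range antenna
#'     for the `antenna_fraction` of weak-signal sites, for `connected_ai`.}
#'   \item{consumables}{battery sets consumed over service rounds; only the
#'     manual scenarios pay this, as solar power removes routine battery
#'     changes for connected cameras.}
#'   \item{staff_field}{service-round labour, plus manual-upload labour for
#'     `manual_ai`.}
#'   \item{staff_processing}{manual image classification
#'     (`images / manual_rate` staff-days) for `manual_manual`; for the AI
#'     scenarios only the optional `verification_fraction` share.}
#'   \item{travel}{[scenario_kilometres()] times the per-km vehicle cost.}
#'   \item{ai_fees}{per-image platform fee for the AI scenarios.}
#'   \item{connectivity}{SIM/data plans per camera-year for `connected_ai`.}
#' }
#'
#' @inheritParams scenario_kilometres
#' @return A one-row `data.frame` of class `cost_breakdown` with the seven
#'   components and their `total`.
#' @seealso [compare_scenarios()], [emissions_report()]
#' @export
scenario_cost <- function(config, scenario) {
  validate_program_config(config)
  check_scenario(scenario)
  hw <- config$hardware_unit_costs
  years <- config$program_years
  rounds_total <- rounds_for(config, scenario) * years
  images_total <- config$images_per_year * years

  hardware <- if (scenario == "connected_ai") {
    config$n_cameras * (hw$camera_4g + hw$solar_panel + hw$sd_card) +
      config$antenna_fraction * config$n_cameras * hw$antenna
  } else {
    config$n_cameras * (hw$camera_basic + hw$sd_card)
  }

  consumables <- if (scenario == "connected_ai") 0 else
    config$n_cameras * config$battery_sets_per_round * hw$battery_set *
      rounds_total

  field_days <- config$staff_days_per_round * rounds_total
  if (scenario == "manual_ai")
    field_days <- field_days + config$upload_staff_days_per_round * rounds_total
  staff_field <- field_days * config$staff_day_cost

  processing_days <- if (scenario == "manual_manual")
    images_total / config$manual_rate_images_per_day
  else
    config$verification_fraction * images_total /
      config$manual_rate_images_per_day
  staff_processing <- processing_days * config$staff_day_cost

  travel <- scenario_kilometres(config, scenario) * config$vehicle_cost_per_km

  ai_fees <- if (is_ai_scenario(scenario))
    images_total * config$ai_fee_per_image else 0

  connectivity <- if (scenario == "connected_ai")
    config$n_cameras * years * config$connectivity_cost_per_camera_year else 0

  out <- data.frame(
    scenario = scenario, hardware = hardware, consumables = consumables,
    staff_field = staff_field, staff_processing = staff_processing,
    travel = travel, ai_fees = ai_fees, connectivity = connectivity,
    stringsAsFactors = FALSE
  )
  out$total <- hardware + consumables + staff_field + staff_processing +
    travel + ai_fees + connectivity
  class(out) <- c("cost_breakdown", "data.frame")
  out
}

#' Baseline-relative scenario comparison
#'
#' Lays out each scenario's total cost next to its saving relative to the
#' baseline: `saving = baseline total - scenario total` (negative when a
#' scenario is dearer) and `saving_pct = 100 * saving / baseline total`,
#' rounded half-up to one decimal. The baseline row reports a saving of 0.
#'
#' @param breakdowns a list of [scenario_cost()] results (or a single
#'   `data.frame` with `scenario` and `total` columns).
#' @param baseline scenario kind used as reference; must be present.
#' @return A `data.frame` of class `comparison_report` with columns
#'   `scenario`, `total_cost`, `saving_vs_baseline`, `saving_pct`, baseline
#'   row first.
#' @export
#' @examples
#' totals <- data.frame(
#'   scenario = scenario_kinds(),
#'   total = c(2666628, 2392290, 519652)
#' )
#' compare_scenarios(totals)
compare_scenarios <- function(breakdowns, baseline = BASELINE_SCENARIO) {
  if (is.data.frame(breakdowns)) breakdowns <- list(breakdowns)
  tab <- do.call(rbind, lapply(breakdowns, function(b) {
    if (!is.data.frame(b) || !all(c("scenario", "total") %in% names(b)))
      abort("each breakdown needs 'scenario' and 'total' columns")
    data.frame(scenario = b$scenario, total_cost = b$total,
               stringsAsFactors = FALSE)
  }))
  check_scenario(baseline)
  if (!baseline %in% tab$scenario)
    abort("baseline scenario '%s' absent from the breakdowns", baseline)
  if (anyDuplicated(tab$scenario))
    abort("duplicate scenario rows in the breakdowns")

  tab <- tab[order(tab$scenario != baseline,
                   match(tab$scenario, scenario_kinds())), , drop = FALSE]
  base_total <- tab$total_cost[tab$scenario == baseline]
  tab$saving_vs_baseline <- base_total - tab$total_cost
  tab$saving_pct <- if (base_total > 0)
    round_half_up(100 * tab$saving_vs_baseline / base_total, 1)
  else
    0
  rownames(tab) <- NULL
  class(tab) <- c("comparison_report", "data.frame")
  tab
}

#' Vehicle carbon emissions per scenario
#'
#' Converts each scenario's service-round kilometres to kilograms of CO2
#' using the vehicle's manufacturer emission factor
#' (`co2_kg = km * emission_g_per_km / 1000`, reported to the nearest whole
#' kilogram) and expresses savings relative to the baseline scenario.
#'
#' @param config a [program_config()].
#' @param scenarios scenario kinds to include (baseline must be among them).
#' @param baseline reference scenario.
#' @return A `data.frame` of class `emissions_report` with columns `scenario`,
#'   `km_driven_total`, `co2_kg`, `saving_kg`, `saving_pct`.
#' @export
#' @examples
#' emissions_report(kifcep_preset())
emissions_report <- function(config, scenarios = scenario_kinds(),
                             baseline = BASELINE_SCENARIO) {
  validate_program_config(config)
  for (s in scenarios) check_scenario(s)
  if (!baseline %in% scenarios)
    abort("baseline scenario '%s' absent from 'scenarios'", baseline)
  km <- vapply(scenarios, scenario_kilometres, numeric(1), config = config)
  co2 <- round(km * config$emission_g_per_km / 1000)
  out <- data.frame(scenario = scenarios, km_driven_total = unname(km),
                    co2_kg = unname(co2), stringsAsFactors = FALSE)
  out <- out[order(out$scenario != baseline,
                   match(out$scenario, scenario_kinds())), , drop = FALSE]
  base_kg <- out$co2_kg[out$scenario == baseline]
  out$saving_kg <- base_kg - out$co2_kg
  out$saving_pct <- if (base_kg > 0)
    round_half_up(100 * out$saving_kg / base_kg, 1)
  else
    0
  rownames(out) <- NULL
  class(out) <- c("emissions_report", "data.frame")
  out
}
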