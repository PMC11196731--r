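#' The three monitoring scenarios
#'
#' A monitoring program can be run three ways: `manual_manual` (staff drive to
#' every camera to swap SD cards, then classify images by hand — always the
#' comparison baseline), `manual_ai` (staff still retrieve SD cards but upload
#' the images to an AI classification platform), and `connected_ai`
#' (solar-powered 4G cameras transmit images straight to the AI platform, so
#' routine service rounds all but disappear).
#'
#' @return Character vector of the three scenario kinds, baseline first.
#' @export
#' @examples
#' scenario_kinds()
scenario_kinds <- function() c("manual_manual", "manual_ai", "connected_ai")

BASELINE_SCENARIO <- "manual_manual"

check_scenario <- function(scenario) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% scenario_kinds())
    abort("unknown scenario kind '%s'; expected one of %s",
          paste(scenario, collapse = ","),
          paste(scenario_kinds(), collapse = ", "))
  scenario
}

#' Monitoring-program configuration
#'
#' Bundles every parameter needed to cost one camera-trap monitoring scenario:
#' fleet size and duration, service-round frequency and effort, travel
#' distances and unit costs, image volume and classification rates, AI fees,
#' 4G connectivity plans and the vehicle emission factor.
#'
#' @param n_cameras number of cameras deployed.
#' @param program_years program duration in years (> 0).
#' @param service_rounds_per_year full service rounds (battery/SD visits) per
#'   year, one value per scenario. A single number is recycled to the two
#'   manual scenarios with `connected_ai = 0` (solar power plus direct upload
#'   removes routine rounds); a named vector over [scenario_kinds()] sets each
#'   explicitly.
#' @param staff_days_per_round staff-day equivalents to service every camera
#'   once.
#' @param round_km vehicle kilometres driven per full service round.
#' @param staff_day_cost currency per staff-day.
#' @param vehicle_cost_per_km fuel and running cost per kilometre.
#' @param images_per_year expected image volume per year.
#' @param manual_rate_images_per_day images one staff member classifies per
#'   staff-day.
#' @param ai_fee_per_image currency per AI-processed image.
#' @param upload_staff_days_per_round staff-days per round spent manually
#'   uploading SD contents to the AI platform (`manual_ai` only).
#' @param connectivity_cost_per_camera_year SIM/data-plan cost per camera-year
#'   (`connected_ai` only).
#' @param hardware_unit_costs named list of one-off unit costs:
#'   `camera_basic`, `camera_4g`, `solar_panel`, `antenna`, `sd_card`,
#'   `battery_set`.
#' @param antenna_fraction fraction of 4G cameras needing a long-range
#'   antenna, in \[0, 1\].
#' @param battery_sets_per_round battery sets consumed per camera per service
#'   round (fractional values express change-every-n-rounds schedules).
#' @param emission_g_per_km grams of CO2 emitted per vehicle kilometre
#'   (manufacturer figure).
#' @param verification_fraction fraction of AI-processed images a human
#'   re-checks, costed at the manual classification rate. Defaults to 0: the
#'   scenario comparison treats AI output as final.
#'
#' @return An object of class `program_config` (a validated named list).
#' @seealso [kifcep_preset()], [scenario_cost()], [read_program_config()]
#' @export
#' @examples
#' cfg <- program_config(
#'   n_cameras = 2, program_years = 1, service_rounds_per_year = 1,
#'   staff_days_per_round = 1, round_km = 10, staff_day_cost = 400,
#'   vehicle_cost_per_km = 1, images_per_year = 1000,
#'   manual_rate_images_per_day = 2000,
#'   hardware_unit_costs = list(camera_basic = 500)
#' )
#' scenario_cost(cfg, "manual_manual")$total
program_config <- function(n_cameras = 0,
                           program_years = 1,
                           service_rounds_per_year = 0,
                           staff_days_per_round = 0,
                           round_km = 0,
                           staff_day_cost = 0,
                           vehicle_cost_per_km = 0,
                           images_per_year = 0,
                           manual_rate_images_per_day = 1,
                           ai_fee_per_image = 0,
                           upload_staff_days_per_round = 0,
                           connectivity_cost_per_camera_year = 0,
                           hardware_unit_costs = list(),
                           antenna_fraction = 0,
                           battery_sets_per_round = 0,
                           emission_g_per_km = 0,
                           verification_fraction = 0) {
  hw_defaults <- list(camera_basic = 0, camera_4g = 0, solar_panel = 0,
                      antenna = 0, sd_card = 0, battery_set = 0)
  unknown <- setdiff(names(hardware_unit_costs), names(hw_defaults))
  if (length(unknown))
    abort("unknown hardware_unit_costs entries: %s",
          paste(unknown, collapse = ", "))
  hw <- utils::modifyList(hw_defaults, hardware_unit_costs)

  rounds <- expand_rounds(service_rounds_per_year)

  cfg <- structure(list(
    n_cameras = n_cameras,
    program_years = program_years,
    service_rounds_per_year = rounds,
    staff_days_per_round = staff_days_per_round,
    round_km = round_km,
    staff_day_cost = staff_day_cost,
    vehicle_cost_per_km = vehicle_cost_per_km,
    images_per_year = images_per_year,
    manual_rate_images_per_day = manual_rate_images_per_day,
    ai_fee_per_image = ai_fee_per_image,
    upload_staff_days_per_round = upload_staff_days_per_round,
    connectivity_cost_per_camera_year = connectivity_cost_per_camera_year,
    hardware_unit_costs = hw,
    antenna_fraction = antenna_fraction,
    battery_sets_per_round = battery_sets_per_round,
    emission_g_per_km = emission_g_per_km,
    verification_fraction = verification_fraction
  ), class = "program_config")
  validate_program_config(cfg)
}

expand_rounds <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x)) abort("'service_rounds_per_year' must be numeric")
  if (length(x) == 1L && is.null(names(x))) {
    out <- c(manual_manual = unname(x), manual_ai = unname(x),
             connected_ai = 0)
    return(out)
  }
  if (is.null(names(x)) || !all(names(x) %in% scenario_kinds()))
    abort("'service_rounds_per_year' must be a single number or a vector named by scenario kind")
  out <- c(manual_manual = 0, manual_ai = 0, connected_ai = 0)
  out[names(x)] <- x
  out
}

#' Validate a program configuration
#'
#' Checks that counts, rates and unit costs are non-negative, the program
#' duration is positive, and `antenna_fraction` lies in \[0, 1\].
#'
#' @param cfg a `program_config`.
#' @return `cfg` invisibly; errors describe the offending field.
#' @export
validate_program_config <- function(cfg) {
  if (!inherits(cfg, "program_config"))
    abort("expected a 'program_config' object")
  check_number(cfg$program_years, "program_years", min = .Machine$double.xmin)
  nonneg <- c("n_cameras", "staff_days_per_round", "round_km",
              "staff_day_cost", "vehicle_cost_per_km", "images_per_year",
              "ai_fee_per_image", "upload_staff_days_per_round",
              "connectivity_cost_per_camera_year", "battery_sets_per_round",
              "emission_g_per_km")
  for (f in nonneg) check_number(cfg[[f]], f, min = 0)
  check_number(cfg$manual_rate_images_per_day, "manual_rate_images_per_day",
               min = .Machine$double.xmin)
  check_number(cfg$antenna_fraction, "antenna_fraction", min = 0, max = 1)
  check_number(cfg$verification_fraction, "verification_fraction",
               min = 0, max = 1)
  for (f in names(cfg$hardware_unit_costs))
    check_number(cfg$hardware_unit_costs[[f]],
                 paste0("hardware_unit_costs$", f), min = 0)
  rr <- cfg$service_rounds_per_year
  if (length(rr) != 3L || !all(scenario_kinds() %in% names(rr)))
    abort("'service_rounds_per_year' must cover all three scenarios")
  for (s in scenario_kinds())
    check_number(unname(rr[[s]]), paste0("service_rounds_per_year[", s, "]"),
                 min = 0)
  invisible(cfg)
}

#' @export
print.program_config <- function(x, ...) {
  cat("<program_config>\n")
  cat(sprintf("  %d cameras, %g year(s)\n", x$n_cameras, x$program_years))
  cat(sprintf("  service rounds/yr: manual %g | manual+AI %g | connected %g\n",
              x$service_rounds_per_year[["manual_manual"]],
              x$service_rounds_per_year[["manual_ai"]],
              x$service_rounds_per_year[["connected_ai"]]))
  cat(sprintf("  %g km/round, %g images/yr, emission %g g/km\n",
              x$round_km, x$images_per_year, x$emission_g_per_km))
  invisible(x)
}

#' Kangaroo-Island-scale program preset
#'
#' A ready-made [program_config()] at the scale of the Kangaroo Island feral
#' cat eradication program used as the case study: 200 fixed cameras over 3
#' years, daily SD-card service rounds for the manual scenarios (timely
#' detection of a target animal is paramount in an eradication program), four
#' staff-days per round, and camera sites 30-75 km from the operations base.
#'
#' Unit costs (staff day rates, hardware prices, AI fees, data plans, vehicle
#' running costs) are plausible placeholders, not calibrated figures: the
#' preset reproduces the structure and relative magnitudes of such a program,
#' not its audited totals.
#'
#' @return A `program_config`.
#' @export
#' @examples
#' cmp <- compare_scenarios(lapply(scenario_kinds(), scenario_cost,
#'                                 config = kifcep_preset()))
#' cmp
kifcep_preset <- function() {
  program_config(
    n_cameras = 200,
    program_years = 3,
    # daily rounds while SD cards must be fetched; one annual maintenance
    # visit once solar + 4G remove the routine trips
    service_rounds_per_year = c(manual_manual = 365, manual_ai = 365,
                                connected_ai = 1),
    staff_days_per_round = 4,
    round_km = 500,            # sites 30-75 km from base, several vehicles
    staff_day_cost = 400,
    vehicle_cost_per_km = 0.85,
    images_per_year = 600000,
    manual_rate_images_per_day = 1500,
    ai_fee_per_image = 0.01,
    upload_staff_days_per_round = 0.25,
    connectivity_cost_per_camera_year = 180,
    hardware_unit_costs = list(camera_basic = 500, camera_4g = 800,
                               solar_panel = 150, antenna = 130,
                               sd_card = 25, battery_set = 15),
    antenna_fraction = 0.25,   # weak-signal sites fitted with antennas
    battery_sets_per_round = 0.03,  # ~ one 12-AA set per month of daily rounds
    emission_g_per_km = 220    # manufacturer figure for a diesel 4WD ute
  )
}

#' Read a program configuration from YAML or JSON
#'
#' The file holds one mapping of [program_config()] arguments;
#' `service_rounds_per_year` may be a scalar or a per-scenario mapping and
#' `hardware_unit_costs` a nested mapping.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `program_config`.
#' @export
read_program_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (!is.list(raw)) abort("config file must contain a mapping: %s", path)
  unknown <- setdiff(names(raw), names(formals(program_config)))
  if (length(unknown))
    abort("unknown config fields in %s: %s", path,
          paste(unknown, collapse = ", "))
  do.call(program_config, raw)
}
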