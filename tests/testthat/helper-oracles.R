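# Independent oracles, written as straight-line arithmetic / naive loops so
# they share no code path with the implementation they check.

# --- cost model: flat re-summation of the seven components -------------------
oracle_scenario_cost <- function(cfg, scenario) {
  hw <- cfg$hardware_unit_costs
  yrs <- cfg$program_years
  rounds <- unname(cfg$service_rounds_per_year[[scenario]]) * yrs
  images <- cfg$images_per_year * yrs

  if (scenario == "connected_ai") {
    hardware <- cfg$n_cameras * hw$camera_4g + cfg$n_cameras * hw$solar_panel +
      cfg$n_cameras * hw$sd_card +
      cfg$n_cameras * cfg$antenna_fraction * hw$antenna
    consumables <- 0
  } else {
    hardware <- cfg$n_cameras * hw$camera_basic + cfg$n_cameras * hw$sd_card
    consumables <- cfg$n_cameras * cfg$battery_sets_per_round * rounds *
      hw$battery_set
  }

  field_days <- cfg$staff_days_per_round * rounds
  if (scenario == "manual_ai")
    field_days <- field_days + cfg$upload_staff_days_per_round * rounds

  proc_days <- if (scenario == "manual_manual")
    images / cfg$manual_rate_images_per_day
  else
    cfg$verification_fraction * images / cfg$manual_rate_images_per_day

  km <- cfg$round_km * rounds
  ai <- if (scenario == "manual_manual") 0 else images * cfg$ai_fee_per_image
  conn <- if (scenario == "connected_ai")
    cfg$n_cameras * yrs * cfg$connectivity_cost_per_camera_year else 0

  hardware + consumables + field_days * cfg$staff_day_cost +
    proc_days * cfg$staff_day_cost + km * cfg$vehicle_cost_per_km + ai + conn
}

random_program_config <- function() {
  program_config(
    n_cameras = sample(0:50, 1),
    program_years = runif(1, 0.5, 5),
    service_rounds_per_year = c(manual_manual = sample(0:60, 1),
                                manual_ai = sample(0:60, 1),
                                connected_ai = runif(1, 0, 2)),
    staff_days_per_round = runif(1, 0, 6),
    round_km = runif(1, 0, 800),
    staff_day_cost = runif(1, 0, 900),
    vehicle_cost_per_km = runif(1, 0, 2),
    images_per_year = sample(0:300000, 1),
    manual_rate_images_per_day = runif(1, 100, 4000),
    ai_fee_per_image = runif(1, 0, 0.1),
    upload_staff_days_per_round = runif(1, 0, 1),
    connectivity_cost_per_camera_year = runif(1, 0, 400),
    hardware_unit_costs = list(
      camera_basic = runif(1, 0, 900), camera_4g = runif(1, 0, 1500),
      solar_panel = runif(1, 0, 300), antenna = runif(1, 0, 200),
      sd_card = runif(1, 0, 60), battery_set = runif(1, 0, 40)),
    antenna_fraction = runif(1),
    battery_sets_per_round = runif(1, 0, 1),
    emission_g_per_km = runif(1, 0, 400),
    verification_fraction = sample(c(0, runif(1, 0, 0.3)), 1)
  )
}

# --- detection scoring: naive quadratic re-scorer ----------------------------
# loops image-by-image / trigger-by-trigger, no vectorised shortcuts

oracle_score_images <- function(records, species, observer) {
  records <- records[records$true_label != "UNKNOWN", , drop = FALSE]
  lab <- records[[paste0(observer, "_label")]]
  n_true <- 0L; correct <- 0L; type_i <- 0L
  for (i in seq_len(nrow(records))) {
    if (records$true_label[i] == species) {
      n_true <- n_true + 1L
      if (lab[i] == species) correct <- correct + 1L
    } else if (lab[i] == species) type_i <- type_i + 1L
  }
  c(n_true = n_true, correct = correct, type_i = type_i,
    type_ii = n_true - correct)
}

# brute-force trigger grouping (trigger_id assumed present) and gap merging
oracle_score_sequences <- function(records, species, observer,
                                   gap_seconds = 5) {
  records <- records[records$true_label != "UNKNOWN", , drop = FALSE]
  lab <- records[[paste0(observer, "_label")]]
  key <- paste(records$camera_id, records$trigger_id)
  trigs <- list()
  for (i in seq_len(nrow(records))) {
    k <- key[i]
    t <- trigs[[k]] %||% list(camera = records$camera_id[i], start = Inf,
                              end = -Inf, true = FALSE, pos = FALSE)
    ts <- as.numeric(records$timestamp[i])
    t$start <- min(t$start, ts); t$end <- max(t$end, ts)
    if (records$true_label[i] == species) t$true <- TRUE
    if (lab[i] == species) t$pos <- TRUE
    trigs[[k]] <- t
  }
  count_runs <- function(tt) {
    # tt: list of triggers of one kind; count maximal <gap runs per camera
    if (!length(tt)) return(list(n = 0L, hit = 0L))
    ord <- order(vapply(tt, function(x) x$camera, ""),
                 vapply(tt, function(x) x$start, 0))
    tt <- tt[ord]
    n <- 0L; hit <- 0L; run_pos <- FALSE
    for (i in seq_along(tt)) {
      new_run <- i == 1L || tt[[i]]$camera != tt[[i - 1L]]$camera ||
        tt[[i]]$start - tt[[i - 1L]]$end >= gap_seconds
      if (new_run) {
        if (i > 1L && run_pos) hit <- hit + 1L
        n <- n + 1L; run_pos <- FALSE
      }
      if (tt[[i]]$pos) run_pos <- TRUE
    }
    if (run_pos) hit <- hit + 1L
    list(n = n, hit = hit)
  }
  true_tr <- Filter(function(x) x$true, trigs)
  fp_tr <- Filter(function(x) !x$true && x$pos, trigs)
  res_true <- count_runs(true_tr)
  res_fp <- count_runs(fp_tr)
  c(n_true = res_true$n, correct = res_true$hit, type_i = res_fp$n,
    type_ii = res_true$n - res_true$hit)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
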