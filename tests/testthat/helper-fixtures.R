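# Record-table fixtures built in code.

T0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

# minimal single-observer table; each image its own trigger unless stated
make_records <- function(offsets_s, true_label, obs_label,
                         obs_conf = NA_real_, camera = "cam1",
                         trigger_id = NULL, observer = "ai") {
  df <- data.frame(
    camera_id = camera,
    timestamp = T0 + offsets_s,
    true_label = true_label,
    stringsAsFactors = FALSE
  )
  if (!is.null(trigger_id)) df$trigger_id <- trigger_id
  df[[paste0(observer, "_label")]] <- obs_label
  df[[paste0(observer, "_confidence")]] <- obs_conf
  df
}

# published-margin fixture lives in the package (it is user-facing too)
table2_fixture <- table2_like_records

# random small record table (with trigger ids) for oracle-equivalence runs
random_record_table <- function(n_triggers = 12, n_cameras = 2,
                                species = c("cat", "echidna"),
                                observer_names = c("ai", "human")) {
  cams <- sprintf("c%d", sample.int(n_cameras, n_triggers, replace = TRUE))
  start <- sample.int(200, n_triggers, replace = TRUE)  # dense: forces merges
  n_img <- sample.int(3, n_triggers, replace = TRUE)
  truth_pool <- c(species, "EMPTY", "EMPTY", "UNKNOWN")
  rows <- lapply(seq_len(n_triggers), function(i) {
    truth <- sample(truth_pool, 1)
    data.frame(
      camera_id = cams[i],
      timestamp = T0 + start[i] * 7 + seq_len(n_img[i]) - 1,
      trigger_id = sprintf("%s-t%03d", cams[i], i),
      true_label = truth,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  # de-duplicate accidental same-camera time collisions across triggers
  key <- paste(df$camera_id, df$timestamp, df$trigger_id)
  df <- df[!duplicated(key), , drop = FALSE]
  for (obs in observer_names) {
    lab <- vapply(df$true_label, function(tr) {
      if (tr %in% species && runif(1) < 0.7) tr
      else if (runif(1) < 0.15) sample(species, 1)
      else "EMPTY"
    }, "")
    df[[paste0(obs, "_label")]] <- unname(lab)
    df[[paste0(obs, "_confidence")]] <-
      ifelse(lab == "EMPTY", NA_real_, round(runif(nrow(df), 0.3, 1), 3))
  }
  rownames(df) <- NULL
  df
}
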