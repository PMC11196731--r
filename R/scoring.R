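# Observer scoring: type I (false positive) and type II (false negative)
# error counts at the image and sequence level, one target species at a time
# (one-vs-rest). Records with UNKNOWN ground truth are excluded everywhere.

#' Construct an observer score
#'
#' One row of the species x observer x granularity error table: the number of
#' true items, those the observer classified correctly, false positives
#' (type I) and false negatives (type II). Scores produced by
#' [score_images()] and [score_sequences()] always satisfy
#' `correct + type_ii = n_true`; counts supplied from an external source that
#' break this identity are carried with a warning rather than rejected.
#'
#' @param species target species.
#' @param observer observer name.
#' @param granularity `"image"` or `"sequence"`.
#' @param n_true number of true items of the species.
#' @param correct number the observer classified correctly.
#' @param type_i false-positive count.
#' @param type_ii false-negative count; defaults to `n_true - correct`.
#' @return A one-row `data.frame` of class `observer_score`.
#' @export
observer_score <- function(species, observer, granularity, n_true, correct,
                           type_i, type_ii = n_true - correct) {
  if (!granularity %in% c("image", "sequence"))
    abort("granularity must be 'image' or 'sequence'")
  check_number(n_true, "n_true", min = 0)
  check_number(correct, "correct", min = 0, max = n_true)
  check_number(type_i, "type_i", min = 0)
  check_number(type_ii, "type_ii", min = 0)
  if (correct + type_ii != n_true)
    warning(sprintf(
      "non-conserving counts for %s/%s (%s): correct %d + type II %d != total %d",
      species, observer, granularity, correct, type_ii, n_true), call. = FALSE)
  structure(data.frame(
    species = species, observer = observer, granularity = granularity,
    n_true = n_true, correct = correct, type_i = type_i, type_ii = type_ii,
    stringsAsFactors = FALSE
  ), class = c("observer_score", "data.frame"))
}

#' Score an observer at the image level
#'
#' Counts, over all records with resolved ground truth: `n_true` images whose
#' true label is `species`; `correct`, those the observer also labelled
#' `species`; `type_ii = n_true - correct` (misses); and `type_i`, images of
#' anything else the observer labelled `species` (false positives).
#'
#' @param records a validated record `data.frame`.
#' @param species target species.
#' @param observer observer name (must have a label column in `records`).
#' @return An [observer_score()] with `granularity = "image"`.
#' @export
score_images <- function(records, species, observer) {
  validate_records(records)
  check_observer(records, observer)
  records <- scoring_subset(records)
  truth <- records$true_label == species
  called <- records[[label_col(observer)]] == species
  observer_score(
    species = species, observer = observer, granularity = "image",
    n_true = sum(truth),
    correct = sum(truth & called),
    type_i = sum(!truth & called)
  )
}

#' Score an observer at the sequence level
#'
#' Ground-truth sequences come from [build_sequences()]. A sequence counts as
#' correctly classified as soon as the observer labelled at least one of its
#' images as the species; a sequence with no such image is a type II error.
#' Type I errors are maximal runs — merged under the same `gap_seconds` rule —
#' of observer-positive trigger sets that contain no true image of the
#' species, so a burst of consecutive false-positive triggers counts once.
#'
#' @inheritParams score_images
#' @param gap_seconds sequence split threshold in seconds (inclusive).
#' @return An [observer_score()] with `granularity = "sequence"`.
#' @export
score_sequences <- function(records, species, observer,
                            gap_seconds = SEQUENCE_GAP_S) {
  validate_records(records)
  check_observer(records, observer)
  records <- scoring_subset(records)
  trig <- trigger_table(records, species, observer)

  true_trig <- trig[trig$has_true, , drop = FALSE]
  n_true <- 0L
  correct <- 0L
  for (tt in split(true_trig, true_trig$camera_id)) {
    run <- gap_runs(tt$start_time, tt$end_time, gap_seconds)
    n_true <- n_true + length(unique(run))
    correct <- correct + sum(as.vector(tapply(tt$observer_positive, run, any)))
  }

  fp_trig <- trig[!trig$has_true & trig$observer_positive, , drop = FALSE]
  type_i <- 0L
  for (tt in split(fp_trig, fp_trig$camera_id)) {
    run <- gap_runs(tt$start_time, tt$end_time, gap_seconds)
    type_i <- type_i + length(unique(run))
  }

  observer_score(
    species = species, observer = observer, granularity = "sequence",
    n_true = n_true, correct = correct, type_i = type_i
  )
}

#' Review workload above a confidence threshold
#'
#' How many images a human must verify if every image the observer labelled
#' as `species` with confidence at or above `threshold` is reviewed — correct
#' classifications and false positives alike. Raising the threshold never
#' increases the workload.
#'
#' @inheritParams score_images
#' @param threshold confidence threshold in \[0, 1\]; flagging is inclusive
#'   (`confidence >= threshold`).
#' @return A one-row `data.frame`: `species`, `observer`, `threshold`,
#'   `n_flagged`.
#' @export
review_workload <- function(records, species, observer, threshold) {
  validate_records(records)
  check_observer(records, observer)
  check_number(threshold, "threshold", min = 0)
  records <- scoring_subset(records)
  called <- records[[label_col(observer)]] == species
  cc <- conf_col(observer)
  if (!cc %in% names(records))
    abort("observer '%s' provides no confidences ('%s' column missing)",
          observer, cc)
  conf <- records[[cc]][called]
  if (anyNA(conf))
    abort("missing confidence for %d image(s) labelled '%s' by '%s'",
          sum(is.na(conf)), species, observer)
  data.frame(species = species, observer = observer, threshold = threshold,
             n_flagged = sum(conf >= threshold), stringsAsFactors = FALSE)
}

#' Per-decile confidence histogram
#'
#' Bins the confidences of every image the observer labelled as `species`
#' into ten-percentage-point bins over (0, 100\], split into correct
#' classifications and false positives. Bins are half-open `(low, high]` so
#' 100% lands in the top bin; a confidence of exactly 0 is kept in the lowest
#' bin.
#'
#' @inheritParams review_workload
#' @return A `data.frame` with columns `species`, `observer`, `bin_low`,
#'   `bin_high`, `correct`, `false_positive` (ten rows).
#' @export
confidence_histogram <- function(records, species, observer) {
  validate_records(records)
  check_observer(records, observer)
  records <- scoring_subset(records)
  called <- records[[label_col(observer)]] == species
  cc <- conf_col(observer)
  if (!cc %in% names(records))
    abort("observer '%s' provides no confidences ('%s' column missing)",
          observer, cc)
  conf <- records[[cc]][called]
  if (anyNA(conf))
    abort("missing confidence for %d image(s) labelled '%s' by '%s'",
          sum(is.na(conf)), species, observer)
  truth <- records$true_label[called] == species
  breaks <- seq(0, 100, by = 10)
  bin <- cut(conf * 100, breaks = breaks, include.lowest = TRUE, right = TRUE)
  out <- data.frame(
    species = species, observer = observer,
    bin_low = breaks[-11], bin_high = breaks[-1],
    correct = as.vector(table(bin[truth])),
    false_positive = as.vector(table(bin[!truth])),
    stringsAsFactors = FALSE
  )
  class(out) <- c("confidence_histogram", "data.frame")
  out
}

#' Side-by-side observer comparison table
#'
#' Combines [observer_score()] rows into one row per species x granularity
#' with per-observer `correct`, `type_i`, `type_ii` columns next to the
#' shared `total` count, optionally appending each observer's percent correct
#' (`100 * correct / total`, half-up to one decimal).
#'
#' @param scores a list of observer scores, or a `data.frame` of stacked
#'   score rows.
#' @param percentages append `<observer>_pct_correct` columns?
#' @return A `data.frame` of class `comparison_table`, rows ordered by
#'   species then granularity (images before sequences).
#' @export
#' @examples
#' s1 <- observer_score("echidna", "human", "image", 155, 108, 0)
#' comparison_table(list(s1), percentages = TRUE)$human_pct_correct  # 69.7
comparison_table <- function(scores, percentages = FALSE) {
  check_flag(percentages, "percentages")
  if (is.data.frame(scores)) scores <- list(scores)
  tab <- do.call(rbind, lapply(scores, as.data.frame))
  need <- c("species", "observer", "granularity", "n_true", "correct",
            "type_i", "type_ii")
  if (!all(need %in% names(tab)))
    abort("scores must carry columns: %s", paste(need, collapse = ", "))
  key <- paste(tab$species, tab$granularity, sep = " / ")
  totals <- tapply(tab$n_true, key, function(v) length(unique(v)))
  bad <- names(totals)[totals > 1]
  if (length(bad))
    abort("observers disagree on the total count for: %s (inconsistent ground truth)",
          paste(bad, collapse = "; "))
  if (anyDuplicated(paste(key, tab$observer)))
    abort("duplicate score rows for the same species/granularity/observer")

  keys <- unique(data.frame(species = tab$species,
                            granularity = tab$granularity,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$species, keys$granularity), , drop = FALSE]
  obs_names <- unique(tab$observer)
  out <- keys
  out$total <- NA_real_
  for (i in seq_len(nrow(keys))) {
    sel <- tab$species == keys$species[i] & tab$granularity == keys$granularity[i]
    out$total[i] <- tab$n_true[sel][1L]
    for (obs in obs_names) {
      row <- tab[sel & tab$observer == obs, , drop = FALSE]
      for (col in c("correct", "type_i", "type_ii")) {
        out[i, paste0(obs, "_", col)] <-
          if (nrow(row)) row[[col]][1L] else NA_real_
      }
      if (percentages)
        out[i, paste0(obs, "_pct_correct")] <- if (nrow(row) && out$total[i] > 0)
          round_half_up(100 * row$correct[1L] / out$total[i], 1)
        else NA_real_
    }
  }
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}
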