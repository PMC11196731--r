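# Trigger-set and sequence aggregation.
#
# A camera activation records a burst of up to three images (a trigger set).
# Consecutive trigger sets of the same species separated by less than 5 s are
# one detection sequence — one animal staying in front of the camera; a gap of
# at least 5 s starts a new sequence.

TRIGGER_GAP_S <- 2   # max intra-trigger spacing when bundling without ids
TRIGGER_MAX_IMAGES <- 3L
SEQUENCE_GAP_S <- 5  # "at least 5 s apart" splits sequences

#' Group images into trigger sets
#'
#' Assigns every record to exactly one trigger set. When a `trigger_id`
#' column is present it is authoritative (at most 3 images per trigger);
#' otherwise consecutive same-camera images no more than 2 s apart are
#' bundled greedily into sets capped at 3 images — the tightest window that
#' cannot bridge the 5 s sequence gap.
#'
#' @param records a validated record `data.frame` (see [read_records()]).
#' @return `records` sorted by camera and time, with a `trigger_set`
#'   identifier column added.
#' @seealso [build_sequences()]
#' @export
#' @examples
#' recs <- data.frame(
#'   camera_id = "c1",
#'   timestamp = as.POSIXct("2021-01-01", tz = "UTC") + c(0, 1, 2, 10),
#'   true_label = "cat"
#' )
#' table(group_trigger_sets(recs)$trigger_set)  # sets of 3 and 1
group_trigger_sets <- function(records) {
  validate_records(records)
  key <- paste(records$camera_id, format(records$timestamp, "%Y%m%d%H%M%S"),
               if ("trigger_id" %in% names(records)) records$trigger_id else "",
               sep = "\r")
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup))
    abort("duplicate (camera, timestamp, trigger) records at rows: %s",
          paste(sort(dup), collapse = ", "))

  ord <- order(records$camera_id, records$timestamp)
  records <- records[ord, , drop = FALSE]

  has_ids <- "trigger_id" %in% names(records) && !anyNA(records$trigger_id)
  if ("trigger_id" %in% names(records) && !has_ids &&
      any(!is.na(records$trigger_id)))
    abort("trigger_id must be given for all records or for none")

  if (has_ids) {
    set <- paste(records$camera_id, records$trigger_id, sep = "\r")
    too_big <- names(which(table(set) > TRIGGER_MAX_IMAGES))
    if (length(too_big))
      abort("trigger sets with more than %d images: %s", TRIGGER_MAX_IMAGES,
            paste(gsub("\r", "/", too_big), collapse = ", "))
    records$trigger_set <- paste0(records$camera_id, "#", records$trigger_id)
  } else {
    # rows are sorted by camera then time, so unsplit restores alignment
    records$trigger_set <- unsplit(
      lapply(split(seq_len(nrow(records)), records$camera_id), function(idx) {
        ts <- as.numeric(records$timestamp[idx])
        out <- integer(length(idx))
        set_no <- 0L
        n_in_set <- 0L
        for (i in seq_along(idx)) {
          if (i == 1L || n_in_set >= TRIGGER_MAX_IMAGES ||
              ts[i] - ts[i - 1L] > TRIGGER_GAP_S) {
            set_no <- set_no + 1L
            n_in_set <- 0L
          }
          n_in_set <- n_in_set + 1L
          out[i] <- set_no
        }
        paste0(records$camera_id[idx][1L], "#", sprintf("%06d", out))
      }),
      records$camera_id)
  }
  rownames(records) <- NULL
  records
}

# one row per trigger set: camera, start/end, whether any image is a true
# image of `species`, and (optionally) whether `observer` labelled any image
# as `species`
trigger_table <- function(records, species, observer = NULL) {
  if (!"trigger_set" %in% names(records))
    records <- group_trigger_sets(records)
  f <- factor(records$trigger_set, levels = unique(records$trigger_set))
  tab <- data.frame(
    trigger_set = levels(f),
    camera_id = as.vector(tapply(records$camera_id, f, `[`, 1L)),
    start_time = as.vector(tapply(as.numeric(records$timestamp), f, min)),
    end_time = as.vector(tapply(as.numeric(records$timestamp), f, max)),
    n_images = as.vector(tapply(records$camera_id, f, length)),
    has_true = as.vector(tapply(records$true_label == species, f, any)),
    stringsAsFactors = FALSE
  )
  if (!is.null(observer)) {
    check_observer(records, observer)
    tab$observer_positive <-
      as.vector(tapply(records[[label_col(observer)]] == species, f, any))
  }
  tab[order(tab$camera_id, tab$start_time), , drop = FALSE]
}

# run ids for time-ordered triggers of one camera under the sequence gap rule
gap_runs <- function(start_time, end_time, gap_seconds) {
  n <- length(start_time)
  if (n == 0L) return(integer(0))
  cumsum(c(TRUE, start_time[-1L] - end_time[-n] >= gap_seconds))
}

#' Build detection sequences for one species
#'
#' Keeps the trigger sets that contain at least one true image of `species`
#' and merges consecutive sets on the same camera into sequences: the gap is
#' measured from one trigger's last image to the next trigger's first image,
#' and a gap of at least `gap_seconds` (default 5 s) starts a new sequence.
#'
#' @param records a record `data.frame`; trigger sets are derived with
#'   [group_trigger_sets()] if not already assigned.
#' @param species ground-truth species name.
#' @param gap_seconds inclusive split threshold in seconds.
#' @return A `data.frame` with one row per sequence: `sequence_id`,
#'   `camera_id`, `species`, `start_time`, `end_time`, `n_triggers`,
#'   `n_images`.
#' @export
build_sequences <- function(records, species, gap_seconds = SEQUENCE_GAP_S) {
  check_number(gap_seconds, "gap_seconds", min = 0)
  records <- scoring_subset(records)
  trig <- trigger_table(records, species)
  trig <- trig[trig$has_true, , drop = FALSE]
  if (nrow(trig) == 0L)
    return(data.frame(sequence_id = character(0), camera_id = character(0),
                      species = character(0), start_time = as.POSIXct(character(0)),
                      end_time = as.POSIXct(character(0)),
                      n_triggers = integer(0), n_images = integer(0),
                      stringsAsFactors = FALSE))
  pieces <- lapply(split(trig, trig$camera_id), function(tt) {
    run <- gap_runs(tt$start_time, tt$end_time, gap_seconds)
    data.frame(
      camera_id = tt$camera_id[1L],
      start_time = as.vector(tapply(tt$start_time, run, min)),
      end_time = as.vector(tapply(tt$end_time, run, max)),
      n_triggers = as.vector(tapply(run, run, length)),
      n_images = as.vector(tapply(tt$n_images, run, sum)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$camera_id, out$start_time), , drop = FALSE]
  tz <- attr(records$timestamp, "tzone") %||% "UTC"
  out$start_time <- as.POSIXct(out$start_time, origin = "1970-01-01", tz = tz)
  out$end_time <- as.POSIXct(out$end_time, origin = "1970-01-01", tz = tz)
  out$species <- species
  out$sequence_id <- sprintf("%s/%s#%04d", species, out$camera_id,
                             stats::ave(seq_len(nrow(out)), out$camera_id,
                                        FUN = seq_along))
  rownames(out) <- NULL
  out[, c("sequence_id", "camera_id", "species", "start_time", "end_time",
          "n_triggers", "n_images")]
}
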