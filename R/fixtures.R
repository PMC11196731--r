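#' Synthetic record table matching the published error-table margins
#'
#' Reconstructs a classification-record table whose marginal counts match the
#' published human-versus-machine comparison: 492 true cat images of which
#' the AI classifies 482 (431 with confidence at or above 90%, the rest
#' between 40% and 90%) and misses 10; 2751 empty frames falsely classified
#' as cat with confidences spread over 40-100%; 155 true echidna images all
#' classified by the AI (all but one at or above 90% confidence) plus 500
#' echidna false positives at or above 80%; and a human observer who tags
#' most cats, misses 47 of the echidnas and reports no confidences.
#'
#' The underlying image set was never deposited, so this is a synthetic
#' stand-in: timestamps are an arbitrary 60-second lattice (every image its
#' own trigger and sequence) and confidences are evenly spaced within the
#' published ranges. Counts derived from these margins — review workloads,
#' per-decile histograms, percent-correct figures — reproduce the published
#' worked examples; joint structure beyond the margins is invented.
#'
#' @return A record `data.frame` in the [read_records()] dialect with `ai`
#'   and `human` observers.
#' @export
#' @examples
#' recs <- table2_like_records()
#' review_workload(recs, "cat", "ai", threshold = 0.40)$n_flagged  # 3233
table2_like_records <- function() {
  spread <- function(n, lo, hi) lo + (hi - lo) * (seq_len(n) - 1) / max(n - 1, 1)
  blocks <- list(
    data.frame(true = "cat", ai = "cat",
               conf = c(rep(0.95, 431), spread(51, 0.45, 0.89)),
               human = "cat", stringsAsFactors = FALSE),
    data.frame(true = "cat", ai = EMPTY_LABEL, conf = NA_real_,
               human = c(rep("cat", 7), rep(EMPTY_LABEL, 3)),
               stringsAsFactors = FALSE),
    data.frame(true = EMPTY_LABEL, ai = "cat",
               conf = spread(2751, 0.41, 0.999),
               human = c(rep("cat", 5), rep(EMPTY_LABEL, 2746)),
               stringsAsFactors = FALSE),
    data.frame(true = "echidna", ai = "echidna",
               conf = c(rep(0.95, 154), 0.85),
               human = c(rep("echidna", 108), rep(EMPTY_LABEL, 47)),
               stringsAsFactors = FALSE),
    data.frame(true = EMPTY_LABEL, ai = "echidna",
               conf = spread(500, 0.80, 0.999),
               human = EMPTY_LABEL, stringsAsFactors = FALSE)
  )
  tab <- do.call(rbind, blocks)
  n <- nrow(tab)
  data.frame(
    camera_id = "cam1",
    timestamp = as.POSIXct("2021-03-01 00:00:00", tz = "UTC") + 60 * seq_len(n),
    trigger_id = sprintf("t%05d", seq_len(n)),
    true_label = tab$true,
    ai_label = tab$ai,
    ai_confidence = tab$conf,
    human_label = tab$human,
    human_confidence = NA_real_,
    stringsAsFactors = FALSE
  )
}
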