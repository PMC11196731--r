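test_that("image-level scoring counts hits, misses and false positives", {
  # 10 records: 4 true cats (3 tagged), 2 empties tagged cat, 4 clean empties
  recs <- make_records(
    seq(0, 900, by = 100),
    true_label = c(rep("cat", 4), rep("EMPTY", 6)),
    obs_label = c("cat", "cat", "cat", "EMPTY", "cat", "cat", rep("EMPTY", 4)),
    obs_conf = 0.9)
  s <- score_images(recs, "cat", "ai")
  expect_equal(s$n_true, 4)
  expect_equal(s$correct, 3)
  expect_equal(s$type_ii, 1)
  expect_equal(s$type_i, 2)
})

test_that("perfect and silent observers sit at the scoring extremes", {
  recs <- make_records(seq(0, 500, 100), rep(c("cat", "EMPTY"), 3),
                       rep(c("cat", "EMPTY"), 3), 0.9)
  s <- score_images(recs, "cat", "ai")
  expect_equal(c(s$type_i, s$type_ii), c(0, 0))
  expect_equal(s$correct, s$n_true)

  recs$ai_label <- "EMPTY"
  s <- score_images(recs, "cat", "ai")
  expect_equal(s$correct, 0)
  expect_equal(s$type_ii, s$n_true)
})

test_that("records with unresolved ground truth are excluded from scoring", {
  recs <- make_records(c(0, 100, 200), c("cat", "UNKNOWN", "EMPTY"),
                       c("cat", "cat", "EMPTY"), 0.9)
  s <- score_images(recs, "cat", "ai")
  expect_equal(s$n_true, 1)
  expect_equal(s$type_i, 0)  # the 94%-confidence unknown is not a false positive
})

test_that("an unknown observer raises an error", {
  recs <- make_records(0, "cat", "cat", 0.9)
  expect_error(score_images(recs, "cat", "evorta"), "observer 'evorta'")
  expect_error(score_sequences(recs, "cat", "evorta"), "observer 'evorta'")
})

test_that("one tagged image vindicates the whole sequence", {
  recs <- make_records(0:2, "cat", c("EMPTY", "cat", "EMPTY"), 0.9,
                       trigger_id = rep("A", 3))
  s <- score_sequences(recs, "cat", "ai")
  expect_equal(s$n_true, 1)
  expect_equal(s$correct, 1)

  recs$ai_label <- "EMPTY"
  s <- score_sequences(recs, "cat", "ai")
  expect_equal(s$correct, 0)
  expect_equal(s$type_ii, 1)
})

test_that("sequence scoring matches a hand-enumerated fixture", {
  # two true sequences (second fully missed) + one falsely-tagged empty run
  recs <- rbind(
    make_records(0:2, "cat", c("cat", "EMPTY", "EMPTY"), 0.9,
                 trigger_id = rep("A", 3)),
    make_records(100:102, "cat", "EMPTY", NA, trigger_id = rep("B", 3)),
    make_records(200:202, "EMPTY", "cat", 0.8, trigger_id = rep("C", 3))
  )
  s <- score_sequences(recs, "cat", "ai")
  expect_equal(s$n_true, 2)
  expect_equal(s$correct, 1)
  expect_equal(s$type_ii, 1)
  expect_equal(s$type_i, 1)
})

test_that("consecutive false-positive triggers merge into one type I run", {
  recs <- rbind(
    make_records(0:2, "EMPTY", "cat", 0.8, trigger_id = rep("A", 3)),
    make_records(4:6, "EMPTY", "cat", 0.8, trigger_id = rep("B", 3)),   # 2 s gap
    make_records(20:22, "EMPTY", "cat", 0.8, trigger_id = rep("C", 3))  # >= 5 s
  )
  s <- score_sequences(recs, "cat", "ai")
  expect_equal(s$type_i, 2)
})

test_that("image and sequence scores agree with the naive quadratic oracle", {
  set.seed(1234)
  for (i in 1:100) {
    recs <- random_record_table(n_triggers = sample(6:25, 1))
    for (sp in c("cat", "echidna")) for (obs in c("ai", "human")) {
      s_img <- score_images(recs, sp, obs)
      o_img <- oracle_score_images(recs, sp, obs)
      expect_equal(unlist(s_img[c("n_true", "correct", "type_i", "type_ii")]),
                   o_img, ignore_attr = TRUE)
      s_seq <- score_sequences(recs, sp, obs)
      o_seq <- oracle_score_sequences(recs, sp, obs)
      expect_equal(unlist(s_seq[c("n_true", "correct", "type_i", "type_ii")]),
                   o_seq, ignore_attr = TRUE)
      # conservation holds at both granularities
      expect_equal(s_img$correct + s_img$type_ii, s_img$n_true)
      expect_equal(s_seq$correct + s_seq$type_ii, s_seq$n_true)
    }
  }
})

test_that("review workload counts inclusively and shrinks with the threshold", {
  recs <- make_records(
    seq(0, 500, 100), c("cat", "cat", "EMPTY", "EMPTY", "cat", "EMPTY"),
    c("cat", "cat", "cat", "EMPTY", "EMPTY", "cat"),
    c(0.95, 0.40, 0.55, NA, NA, 0.80))
  expect_equal(review_workload(recs, "cat", "ai", 0.40)$n_flagged, 4)
  expect_equal(review_workload(recs, "cat", "ai", 0.55)$n_flagged, 3)
  expect_equal(review_workload(recs, "cat", "ai", 1.01)$n_flagged, 0)
  # at threshold 0 the workload is every observer-positive image
  s <- score_images(recs, "cat", "ai")
  expect_equal(review_workload(recs, "cat", "ai", 0)$n_flagged,
               s$correct + s$type_i)
  # monotone non-increasing across a sweep
  sweep <- vapply(seq(0, 1, 0.1), function(t)
    review_workload(recs, "cat", "ai", t)$n_flagged, 0)
  expect_true(all(diff(sweep) <= 0))
})

test_that("flagged images without confidences are an error", {
  recs <- make_records(c(0, 100), "cat", "cat", c(0.9, NA))
  expect_error(review_workload(recs, "cat", "ai", 0.4), "missing confidence")
  recs2 <- make_records(0, "cat", "cat", NA, observer = "human")
  recs2$human_confidence <- NULL
  expect_error(review_workload(recs2, "cat", "human", 0.4), "no confidences")
})

test_that("confidence histograms bin per decile into correct vs false positive", {
  recs <- make_records(
    seq(0, 600, 100),
    c("cat", "cat", "cat", "EMPTY", "EMPTY", "EMPTY", "cat"),
    c("cat", "cat", "cat", "cat", "cat", "EMPTY", "EMPTY"),
    c(0.95, 0.95, 0.42, 0.65, 1.0, NA, NA))
  h <- confidence_histogram(recs, "cat", "ai")
  expect_equal(nrow(h), 10)
  expect_equal(h$correct[h$bin_low == 90], 2)
  expect_equal(h$correct[h$bin_low == 40], 1)
  expect_equal(h$false_positive[h$bin_low == 60], 1)
  expect_equal(h$false_positive[h$bin_low == 90], 1)  # 100% sits in the top bin
  # totals reconcile with the image-level score
  s <- score_images(recs, "cat", "ai")
  expect_equal(sum(h$correct), s$correct)
  expect_equal(sum(h$false_positive), s$type_i)

  # all mass at one confidence lands in a single bin
  recs2 <- make_records(seq(0, 300, 100), "cat", "cat", 0.95)
  h2 <- confidence_histogram(recs2, "cat", "ai")
  expect_equal(sum(h2$correct), h2$correct[h2$bin_low == 90])

  # nothing flagged gives an all-zero histogram
  recs3 <- make_records(0, "cat", "EMPTY", NA)
  h3 <- confidence_histogram(recs3, "cat", "ai")
  expect_true(all(h3$correct == 0) && all(h3$false_positive == 0))
})

test_that("comparison tables align observers and append half-up percentages", {
  scores <- list(
    observer_score("echidna", "human", "image", 155, 108, 0),
    observer_score("echidna", "ai", "image", 155, 155, 500)
  )
  tab <- comparison_table(scores, percentages = TRUE)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$total, 155)
  expect_equal(tab$human_pct_correct, 69.7)
  expect_equal(tab$human_type_ii, 47)
  expect_equal(tab$ai_pct_correct, 100)

  # observers disagreeing on the shared total signal broken ground truth
  bad <- list(observer_score("cat", "a", "image", 10, 5, 0),
              observer_score("cat", "b", "image", 12, 5, 0))
  expect_error(comparison_table(bad), "inconsistent ground truth")
})

test_that("externally sourced counts that break conservation warn but carry", {
  expect_warning(
    s <- observer_score("cat", "human", "image", 492, 469, 5, type_ii = 18),
    "non-conserving")
  tab <- comparison_table(list(s), percentages = TRUE)
  expect_equal(tab$human_pct_correct, 95.3)
})
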