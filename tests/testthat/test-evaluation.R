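test_that("single-label evaluation uses the modal event with tie tolerance", {
  gold <- list(
    list(id = "s1", events = c("Binding", "Binding", "Regulation")),
    list(id = "s2", events = c("Binding", "Regulation")))
  res1 <- eval_single_label(c(s1 = "Binding", s2 = "Regulation"), gold)
  expect_equal(res1$accuracy, 1)
  res2 <- eval_single_label(c(s1 = "Regulation", s2 = "Binding"), gold)
  expect_equal(res2$accuracy, 0.5)
  expect_error(eval_single_label(c(s1 = "Binding"), gold), "s2")
})

test_that("single-label P/R/F1 match hand confusion arithmetic", {
  gold <- list(
    list(id = "a", events = "Binding"),
    list(id = "b", events = "Binding"),
    list(id = "c", events = "Regulation"),
    list(id = "d", events = "Regulation"),
    list(id = "e", events = "Transcription"),
    list(id = "f", events = "Transcription"))
  preds <- c(a = "Binding", b = "Regulation", c = "Regulation",
             d = "Regulation", e = "Transcription", f = "Binding")
  res <- eval_single_label(preds, gold)
  # by hand: Binding TP1 FP1 FN1 -> P=50 R=50 F1=50;
  # Regulation TP2 FP1 FN0 -> P=66.67 R=100 F1=80;
  # Transcription TP1 FP0 FN1 -> P=100 R=50 F1=66.67
  pc <- res$report$per_class
  g <- function(ty, col) pc[pc$event_type == ty, col]
  expect_equal(g("Binding", "precision"), 50)
  expect_equal(g("Binding", "f1"), 50)
  expect_equal(g("Regulation", "precision"), 200 / 3, tolerance = 1e-9)
  expect_equal(g("Regulation", "recall"), 100)
  expect_equal(g("Regulation", "f1"), 80)
  expect_equal(g("Transcription", "f1"), 200 / 3, tolerance = 1e-9)
  expect_equal(res$accuracy, 4 / 6)
})

test_that("boundary matching distinguishes exact from the 1-word window", {
  p <- function(s, e, ty = "Binding") list(start_token = s, end_token = e,
                                           type = ty)
  expect_true(match_boundary(p(3, 5), p(3, 5), "exact"))
  expect_false(match_boundary(p(2, 5), p(3, 5), "exact"))
  expect_true(match_boundary(p(2, 5), p(3, 5), "soft"))
  expect_false(match_boundary(p(1, 5), p(3, 5), "soft"))
  expect_false(match_boundary(p(3, 5), p(3, 5, "Regulation"), "exact"))
  expect_false(match_boundary(p(3, 5), p(3, 5, "Regulation"), "soft"))
})

spans_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sentence_id = r[[1]], start_token = as.integer(r[[2]]),
               end_token = as.integer(r[[3]]), type = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("coverage is 100 on identity, 0 on empty predictions", {
  gold <- spans_df(list("s1", 0, 1, "Binding"), list("s1", 3, 4, "Regulation"))
  expect_equal(coverage(gold, gold, "exact"), 100)
  empty <- gold[0, ]
  expect_equal(coverage(empty, gold, "exact"), 0)
  expect_equal(coverage(empty, gold, "soft"), 0)
})

test_that("greedy matching equals optimal matching on unambiguous instances", {
  set.seed(55)
  for (rep in 1:10) {
    gold <- list(); pred <- list()
    for (s in 1:4) {
      # gold spans far apart so soft windows never overlap
      starts <- seq(0, by = 6, length.out = sample(1:3, 1))
      for (st in starts) {
        ty <- sample(EVENT_TYPES, 1)
        gold[[length(gold) + 1]] <- list(paste0("s", s), st, st + 2, ty)
        if (stats::runif(1) < 0.7) {
          jit <- sample(-1:1, 1)
          pred[[length(pred) + 1]] <- list(paste0("s", s), st + jit,
                                           st + 2 + sample(-1:1, 1), ty)
        }
      }
    }
    gold_df <- do.call(spans_df, gold)
    pred_df <- if (length(pred) > 0) do.call(spans_df, pred) else
      gold_df[0, ]
    got <- coverage(pred_df, gold_df, "soft")
    # oracle: windows are disjoint, so each prediction can match at most one
    # gold span and the optimal matching size is just the number of golds
    # with >= 1 matching prediction
    opt <- 0
    for (i in seq_len(nrow(gold_df))) {
      hit <- FALSE
      for (j in seq_len(nrow(pred_df))) {
        if (pred_df$sentence_id[j] == gold_df$sentence_id[i] &&
            match_boundary(pred_df[j, ], gold_df[i, ], "soft")) hit <- TRUE
      }
      opt <- opt + hit
    }
    expect_equal(got, 100 * opt / nrow(gold_df))
  }
})

test_that("span P/R/F1 reports match hand counts", {
  gold <- spans_df(list("s1", 0, 1, "Binding"),
                   list("s1", 4, 5, "Regulation"),
                   list("s2", 0, 2, "Transcription"))
  pred <- spans_df(list("s1", 0, 1, "Binding"),
                   list("s1", 4, 5, "Regulation"),
                   list("s2", 0, 2, "Transcription"))
  rep0 <- span_prf(pred, gold, "exact")
  present <- rep0$per_class[rep0$per_class$tp > 0, ]
  expect_true(all(present$precision == 100 & present$recall == 100 &
                  present$f1 == 100))

  # P=50, R=100 -> F1 = 66.67
  pred2 <- spans_df(list("s1", 0, 1, "Binding"),
                    list("s1", 6, 7, "Binding"))
  gold2 <- spans_df(list("s1", 0, 1, "Binding"))
  r2 <- span_prf(pred2, gold2, "exact")$per_class
  b <- r2[r2$event_type == "Binding", ]
  expect_equal(b$precision, 50)
  expect_equal(b$recall, 100)
  expect_equal(b$f1, 2 * 50 * 100 / 150, tolerance = 1e-9)

  # 3 classes, one FP (Binding) and one FN (Transcription)
  pred3 <- spans_df(list("s1", 0, 1, "Binding"),
                    list("s1", 8, 9, "Binding"),
                    list("s1", 4, 5, "Regulation"))
  gold3 <- spans_df(list("s1", 0, 1, "Binding"),
                    list("s1", 4, 5, "Regulation"),
                    list("s2", 0, 1, "Transcription"))
  r3 <- span_prf(pred3, gold3, "exact")$per_class
  expect_equal(r3[r3$event_type == "Binding", "precision"], 50)
  expect_equal(r3[r3$event_type == "Binding", "recall"], 100)
  expect_equal(r3[r3$event_type == "Regulation", "f1"], 100)
  expect_equal(r3[r3$event_type == "Transcription", "recall"], 0)
  expect_equal(r3[r3$event_type == "Transcription", "f1"], 0)
})

test_that("evaluation is invariant to sentence ordering", {
  set.seed(66)
  rows <- lapply(1:12, function(i)
    list(paste0("s", sample(1:4, 1)), st <- sample(0:8, 1), st + 2,
         sample(EVENT_TYPES, 1)))
  gold <- do.call(spans_df, rows)
  pred <- gold[sample(nrow(gold), 8), ]
  shuffle <- sample(nrow(gold))
  expect_equal(coverage(pred, gold, "soft"),
               coverage(pred, gold[shuffle, ], "soft"))
  a <- span_prf(pred, gold, "exact")
  b <- span_prf(pred[sample(nrow(pred)), ], gold[shuffle, ], "exact")
  expect_equal(a$per_class, b$per_class)
})

test_that("the report formatter mirrors a per-class table with an average row", {
  gold <- spans_df(list("s1", 0, 1, "Binding"))
  rep1 <- span_prf(gold, gold, "exact")
  lines <- format_class_report(rep1)
  expect_length(lines, 11L)   # header + 9 classes + average
  expect_match(lines[1], "Event type")
  expect_match(lines[11], "Average")
  expect_match(lines[grep("^Binding", lines)], "100")
})
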