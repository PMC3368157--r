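# small hand corpus exercising facets
hand_records <- function() {
  list(
    list(doc_id = "d1", title = "cholesterol study",
         abstract = "cholesterol and hepatic lipase in serum.",
         genes = "hepatic lipase", diseases = "hyperthyroidism",
         drugs_chemicals = "cholesterol", cell_lines = character(0),
         event_types = "Binding"),
    list(doc_id = "d2", title = "lipase binding",
         abstract = "hepatic lipase binds cholesterol.",
         genes = "hepatic lipase", diseases = character(0),
         drugs_chemicals = "cholesterol", cell_lines = character(0),
         event_types = c("Binding", "Regulation")),
    list(doc_id = "d3", title = "actin dynamics",
         abstract = "actin polymerises.",
         genes = "actin", diseases = character(0),
         drugs_chemicals = character(0), cell_lines = character(0),
         event_types = "Localization"))
}

test_that("indexing and search honour AND semantics and facet filters", {
  idx <- build_index(hand_records())
  expect_equal(search_index(idx, query())$total, 3L)
  expect_equal(search_index(idx, "cholesterol")$total, 2L)
  expect_equal(search_index(idx, "cholesterol lipase")$total, 2L)
  expect_equal(search_index(idx, "cholesterol actin")$total, 0L)
  expect_equal(search_index(idx, "unknownword")$total, 0L)
  q <- refine(query("cholesterol"), "diseases", "hyperthyroidism")
  expect_equal(search_index(idx, q)$doc_ids, "d1")
  expect_error(build_index(c(hand_records(), hand_records()[1])),
               "duplicate")
})

test_that("rebuilding the index reproduces identical results", {
  i1 <- build_index(hand_records())
  i2 <- build_index(hand_records())
  r1 <- search_index(i1, "cholesterol")
  r2 <- search_index(i2, "cholesterol")
  expect_equal(r1$doc_ids, r2$doc_ids)
  expect_equal(r1$scores, r2$scores)
  expect_equal(r1$facet_counts, r2$facet_counts)
})

test_that("postings and facet counts match a brute-force linear scan", {
  co <- generate_corpus(corpus_config(n_docs = 20L, seed = 31L))
  st <- store_documents(co$documents)
  ments <- annotate_corpus(st, co$lexicons)
  labels_by_doc <- list()
  for (r in co$labeled)
    labels_by_doc[[r$doc_id]] <- c(labels_by_doc[[r$doc_id]], r$labels)
  recs <- indexed_documents(co$documents, ments, labels_by_doc)
  idx <- build_index(recs)
  for (tm in c("bkg0001", "bkg0010", "genp002", "the")) {
    res <- search_index(idx, tm)
    oracle <- scan_search(recs, tm)
    expect_setequal(res$doc_ids, oracle$hits)
    expect_equal(res$total, length(oracle$hits))
    for (f in FACET_FIELDS) {
      o <- oracle$counts[[f]]
      got <- res$facet_counts[[f]]
      expect_setequal(as.character(names(got)), as.character(names(o)))
      if (length(o) > 0) expect_equal(got[names(o)], o[names(o)])
    }
  }
})

test_that("query refinement is pure, invertible and monotone", {
  q0 <- query("cholesterol")
  q1 <- refine(q0, "genes", "hepatic lipase")
  expect_equal(length(q0$filters), 0L)     # purity
  expect_equal(unrefine(q1, "genes", "hepatic lipase"), q0)
  expect_equal(refine(q1, "genes", "hepatic lipase"), q1)  # idempotent
  expect_warning(unrefine(q0, "genes", "x"), "not present")
  q3 <- refine(refine(q1, "diseases", "hyperthyroidism"),
               "event_types", "Binding")
  expect_equal(length(clear_filters(q3)$filters), 0L)
  expect_equal(clear_filters(q3)$terms, q0$terms)

  idx <- build_index(hand_records())
  t0 <- search_index(idx, q0)$total
  t1 <- search_index(idx, q1)$total
  t2 <- search_index(idx, refine(q1, "diseases", "hyperthyroidism"))$total
  expect_true(t0 >= t1 && t1 >= t2)
})

test_that("tag clouds rank by count with normalised weights", {
  res <- list(facet_counts = list(genes = c(a = 4L, b = 2L, c = 1L)))
  class(res) <- "result_set"
  tc <- tag_cloud(res, "genes", 2)
  expect_equal(tc$value, c("a", "b"))
  expect_equal(tc$weight, c(1, 0.5))
  expect_equal(nrow(tag_cloud(res, "genes", 0)), 0L)
  empty <- structure(list(facet_counts = list(genes = integer(0))),
                     class = "result_set")
  expect_equal(nrow(tag_cloud(empty, "genes", 5)), 0L)
})

test_that("autocomplete matches a vocabulary scan, ranked by frequency", {
  idx <- build_index(hand_records())
  expect_true("cholesterol" %in% autocomplete(idx, "chole", 5))
  expect_equal(autocomplete(idx, "zzz", 5), character(0))
  co <- generate_corpus(corpus_config(n_docs = 15L, seed = 77L))
  st <- store_documents(co$documents)
  recs <- indexed_documents(co$documents, annotate_corpus(st, co$lexicons))
  idx2 <- build_index(recs)
  for (pre in c("bkg00", "genp", "b")) {
    got <- autocomplete(idx2, pre, 1000L)
    # oracle: filter the full vocabulary
    vocab <- ls(idx2$postings)
    for (f in FACET_FIELDS) vocab <- union(vocab, tolower(ls(idx2$facets[[f]])))
    expect_setequal(got, vocab[startsWith(vocab, pre)])
    # frequency-descending ordering
    freqs <- vapply(got, function(t) {
      n <- length(idx2$postings[[t]])
      for (f in FACET_FIELDS) {
        for (v in ls(idx2$facets[[f]]))
          if (tolower(v) == t)
            n <- max(n, length(idx2$facets[[f]][[v]]))
      }
      n
    }, integer(1))
    expect_true(all(diff(freqs) <= 0 | diff(freqs) == 0))
    expect_true(!is.unsorted(-freqs))
  }
})

test_that("facet counts honour the click-through contract", {
  idx <- build_index(hand_records())
  res <- search_index(idx, "cholesterol")
  for (f in FACET_FIELDS) {
    cts <- res$facet_counts[[f]]
    for (v in names(cts)) {
      refined <- search_index(idx, refine(res$query, f, v))
      expect_equal(refined$total, unname(cts[[v]]))
    }
  }
})

test_that("the index persists and reloads to identical search behaviour", {
  idx <- build_index(hand_records())
  d <- tempfile()
  write_index(idx, d)
  idx2 <- read_index(d)
  r1 <- search_index(idx, "cholesterol")
  r2 <- search_index(idx2, "cholesterol")
  expect_equal(r1$doc_ids, r2$doc_ids)
  expect_equal(r1$facet_counts, r2$facet_counts)
})
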