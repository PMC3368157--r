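# small deterministic training set: token "attaches" is always a Binding
# trigger, everything else is O
crf_toy_sequences <- function(n = 6L, seed = 13L, len = 5L) {
  set.seed(seed)
  bkg <- c("cells", "were", "treated", "with", "samples", "then")
  lapply(seq_len(n), function(i) {
    toks <- sample(bkg, len - 1L, replace = TRUE)
    pos <- sample(seq_len(len), 1)
    toks <- append(toks, "attaches", after = pos - 1L)
    labels <- rep("O", len)
    labels[pos] <- "B-Binding"
    list(tokens = toks, obs = extract_features(toks),
         labels = labels)
  })
}

test_that("orthographic and affix features match the declared regex list", {
  feats <- extract_features("IL-2")[[1]]
  own <- feats[!grepl("^[+-]1:", feats)]
  expect_true(all(c("ORTH=HasDash", "ORTH=HasDigit", "PRE3=il-",
                    "SUF3=l-2", "W=il-2") %in% own))
  # oracle: apply each declared regex independently
  orth <- orthographic_features()
  expected <- paste0("ORTH=", names(orth)[vapply(orth, function(rx)
    grepl(rx, "IL-2", perl = TRUE), logical(1))])
  expect_setequal(own[startsWith(own, "ORTH=")], expected)

  # Greek lexicon membership
  falpha <- extract_features("alpha")[[1]]
  expect_true("LEX=greek" %in% falpha)

  # "the": no orthographic indicators, only affixes + identity
  fthe <- extract_features("the")[[1]]
  own_the <- fthe[!grepl("^[+-]1:", fthe)]
  expect_false(any(startsWith(own_the, "ORTH=")))
  expect_setequal(own_the, c("W=the", "PRE3=the", "SUF3=the"))
})

test_that("there are exactly 17 declared orthographic indicators", {
  expect_length(orthographic_features(), 17L)
  expect_length(bio_labels(), 19L)
})

test_that("training rejects invalid BIO paths with the sequence index", {
  seqs <- crf_toy_sequences(2L)
  seqs[[2]]$labels[1] <- "I-Binding"
  expect_error(train_crf(seqs), "sequence 2")
})

test_that("a single training sequence is memorised", {
  sq <- crf_toy_sequences(1L)[[1]]
  model <- suppressWarnings(train_crf(list(sq), crf_hyper(max_iter = 100L)))
  expect_equal(viterbi_tag(model, sq$obs), sq$labels)
  expect_true(all(diff(model$objective_trace) >= -1e-8))
})

test_that("all-zero weights decode to the all-O path", {
  model <- suppressWarnings(train_crf(crf_toy_sequences(2L),
                                      crf_hyper(max_iter = 1L)))
  model$W[] <- 0
  model$Trans[] <- 0
  obs <- extract_features(c("cells", "were", "treated"))
  expect_equal(viterbi_tag(model, obs), c("O", "O", "O"))
})

test_that("Viterbi and forward agree with exhaustive path enumeration", {
  model <- suppressWarnings(train_crf(crf_toy_sequences(3L),
                                      crf_hyper(max_iter = 5L)))
  set.seed(99)
  allowed <- model$allowed
  start_ok <- model$start_ok
  for (rep in 1:4) {
    model$W[] <- stats::rnorm(length(model$W), sd = 0.7)
    model$Trans[] <- stats::rnorm(length(model$Trans), sd = 0.7)
    toks <- sample(c("cells", "attaches", "IL-2", "then"), 4, replace = TRUE)
    obs <- extract_features(toks)
    ids <- oracle_feat_ids(model, obs)
    scores <- oracle_all_path_scores(ids, model$W, model$Trans, allowed,
                                     start_ok)
    vit <- viterbi_tag(model, obs)
    vit_score <- crf_path_score(model, obs, vit)
    expect_equal(vit_score, max(scores), tolerance = 1e-9)
    expect_equal(crf_log_partition(model, obs), oracle_logsumexp(scores),
                 tolerance = 1e-9)
    # structural validity of the decoded path
    expect_silent(validate_bio(vit))
    expect_length(vit, length(toks))
  }
})

test_that("the analytic gradient matches finite differences on a toy problem", {
  seqs <- crf_toy_sequences(2L, len = 2L)
  labs <- bio_labels()
  feat_vocab <- sort(unique(unlist(lapply(seqs, function(sq)
    unlist(sq$obs)))))
  feats <- lapply(seqs, function(sq)
    lapply(sq$obs, function(fs) match(fs, feat_vocab)))
  labels <- lapply(seqs, function(sq) match(sq$labels, labs))
  allowed <- biofacet:::bio_transition_matrix()
  start_ok <- unname(biofacet:::bio_start_vector())
  F_ <- length(feat_vocab); L <- length(labs)
  set.seed(5)
  W <- matrix(stats::rnorm(F_ * L, sd = 0.3), F_, L)
  Tr <- matrix(stats::rnorm(L * L, sd = 0.3), L, L)
  res <- biofacet:::crf_negll_grad_cpp(feats, labels, W, Tr, allowed, start_ok)
  negll_at <- function(W, Tr) {
    tot <- 0
    for (s in seq_along(feats)) {
      scores <- oracle_all_path_scores(feats[[s]], W, Tr, allowed, start_ok)
      gold <- oracle_path_score(feats[[s]], labels[[s]], W, Tr, allowed,
                                start_ok)
      tot <- tot + oracle_logsumexp(scores) - gold
    }
    tot
  }
  eps <- 1e-5
  for (probe in list(c(1, 1), c(2, 7), c(F_, 19))) {
    Wp <- Wm <- W
    Wp[probe[1], probe[2]] <- Wp[probe[1], probe[2]] + eps
    Wm[probe[1], probe[2]] <- Wm[probe[1], probe[2]] - eps
    fd <- (negll_at(Wp, Tr) - negll_at(Wm, Tr)) / (2 * eps)
    expect_equal(res$gW[probe[1], probe[2]], fd, tolerance = 1e-5)
  }
  Trp <- Trm <- Tr
  Trp[1, 2] <- Trp[1, 2] + eps; Trm[1, 2] <- Trm[1, 2] - eps
  fd <- (negll_at(Tr = Trp, W = W) - negll_at(Tr = Trm, W = W)) / (2 * eps)
  expect_equal(res$gT[1, 2], fd, tolerance = 1e-5)
})

test_that("a rule-governed synthetic tagging problem is learnt exactly", {
  train <- crf_toy_sequences(10L, seed = 61L)
  test <- crf_toy_sequences(10L, seed = 62L)
  model <- suppressWarnings(train_crf(train, crf_hyper(max_iter = 60L)))
  acc <- mean(unlist(lapply(test, function(sq)
    viterbi_tag(model, sq$obs) == sq$labels)))
  expect_equal(acc, 1)
})

test_that("span decoding and encoding are mutually inverse", {
  toks <- c("a", "b", "c", "d")
  sp <- decode_spans(toks, c("O", "B-Binding", "I-Binding", "O"))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$start_token, 1L)
  expect_equal(sp$end_token, 3L)
  expect_equal(sp$type, "Binding")
  expect_equal(sp$text, "b c")

  expect_equal(nrow(decode_spans(toks, rep("O", 4))), 0L)
  expect_error(decode_spans(toks, c("O", "I-Binding", "O", "O")),
               "invalid BIO|starts with")

  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    labels <- random_bio(n)
    spans <- decode_spans(paste0("t", seq_len(n)), labels)
    expect_equal(encode_spans(n, spans), labels)
  }
})

test_that("BIO JSONL and trigger standoff conversion round-trip", {
  co <- generate_corpus(corpus_config(n_docs = 4L, seed = 19L))
  f <- tempfile(fileext = ".jsonl")
  write_bio_jsonl(lapply(co$bio, function(r) r[c("tokens", "labels")]), f)
  back <- read_bio_jsonl(f)
  expect_equal(length(back), length(co$bio))
  expect_equal(back[[1]]$tokens, co$bio[[1]]$tokens)
  expect_equal(back[[1]]$labels, co$bio[[1]]$labels)

  conv <- triggers_to_bio(co$labeled)
  ids <- vapply(co$labeled, function(r) r$id, character(1))
  bio_ids <- vapply(co$bio, function(r) r$id, character(1))
  for (k in seq_along(conv)) {
    expect_equal(conv[[k]]$labels, co$bio[[match(ids[k], bio_ids)]]$labels)
  }
})
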