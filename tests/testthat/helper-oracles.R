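# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force (loops, enumeration) rather than calling the
# implementation paths they check.

# --- naive Bayes by direct Bayes-rule arithmetic -----------------------------

# counts: list of named numeric vectors (count scale); labels: character.
# Returns function(test_counts) -> posterior over EVENT_TYPES.
bayes_oracle <- function(counts, labels) {
  vocab <- sort(unique(unlist(lapply(counts, names))))
  K <- length(EVENT_TYPES)
  n <- length(counts)
  prior <- numeric(K)
  for (k in seq_len(K)) prior[k] <- (sum(labels == EVENT_TYPES[k]) + 1) / (n + K)
  word_prob <- matrix(0, length(vocab), K, dimnames = list(vocab, EVENT_TYPES))
  for (k in seq_len(K)) {
    tot <- 0
    for (i in seq_len(n)) if (labels[i] == EVENT_TYPES[k]) {
      for (w in names(counts[[i]])) {
        word_prob[w, k] <- word_prob[w, k] + counts[[i]][[w]]
        tot <- tot + counts[[i]][[w]]
      }
    }
    word_prob[, k] <- (word_prob[, k] + 1) / (tot + length(vocab))
  }
  function(x) {
    ll <- log(prior)
    for (k in seq_len(K)) {
      for (w in names(x)) {
        if (w %in% vocab) ll[k] <- ll[k] + x[[w]] * log(word_prob[w, k])
      }
    }
    p <- exp(ll - max(ll))
    setNames(p / sum(p), EVENT_TYPES)
  }
}

# raw tf-idf counts for a sentence, computed by hand (plain loops)
hand_tfidf_counts <- function(train_texts, text) {
  tok <- function(s) {
    ts <- tolower(unlist(strsplit(s, "[^[:alnum:]-]+")))
    ts <- ts[nzchar(ts)]
    ts[grepl("^[a-z]", ts)]
  }
  N <- length(train_texts)
  train_toks <- lapply(train_texts, tok)
  df <- table(unlist(lapply(train_toks, unique)))
  toks <- tok(text)
  toks <- toks[toks %in% names(df)]
  out <- numeric(0)
  for (t in unique(toks)) {
    w <- sum(toks == t) * log(N / as.numeric(df[[t]]))
    if (w > 0) out[t] <- w
  }
  out
}

# --- CRF path enumeration ----------------------------------------------------

# score of one labelled path from raw parameters, computed in R
oracle_path_score <- function(feat_ids, labels_idx, W, Tr, allowed, start_ok) {
  if (!start_ok[labels_idx[1]]) return(-Inf)
  sc <- sum(W[feat_ids[[1]], labels_idx[1]])
  for (t in seq_along(labels_idx)[-1]) {
    a <- labels_idx[t - 1]; b <- labels_idx[t]
    if (!allowed[a, b]) return(-Inf)
    sc <- sc + Tr[a, b] + sum(W[feat_ids[[t]], b])
  }
  sc
}

# all valid path scores of a short sequence (exhaustive enumeration of the
# full L^T path grid, vectorised over paths)
oracle_all_path_scores <- function(feat_ids, W, Tr, allowed, start_ok) {
  T_ <- length(feat_ids); L <- ncol(W)
  S <- t(vapply(feat_ids, function(ids) colSums(W[ids, , drop = FALSE]),
                numeric(L)))                      # T x L emission scores
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(L)), T_)))
  valid <- start_ok[grid[, 1]]
  scores <- S[cbind(1L, grid[, 1])]
  if (T_ > 1L) for (t in 2:T_) {
    valid <- valid & allowed[cbind(grid[, t - 1L], grid[, t])]
    scores <- scores + Tr[cbind(grid[, t - 1L], grid[, t])] +
      S[cbind(t, grid[, t])]
  }
  scores[valid]
}

oracle_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# map observation feature sets to ids in a trained model's vocabulary
oracle_feat_ids <- function(model, observations) {
  lapply(observations, function(fs) {
    ids <- match(fs, model$feat_vocab)
    ids[!is.na(ids)]
  })
}

# --- linear scans ------------------------------------------------------------

# brute-force keyword scan over a documents data.frame
scan_keyword <- function(docs, term) {
  hits <- character(0)
  for (i in seq_len(nrow(docs))) {
    toks <- tolower(unlist(strsplit(paste(docs$title[i], docs$abstract[i]),
                                    "[^[:alnum:]-]+")))
    if (tolower(term) %in% toks) hits <- c(hits, docs$doc_id[i])
  }
  hits
}

# brute-force conjunctive search + facet counts over indexed-document records
scan_search <- function(records, terms, filters = list()) {
  tok <- function(s) {
    ts <- tolower(unlist(strsplit(s, "[^[:alnum:]-]+")))
    ts[nzchar(ts)]
  }
  hits <- character(0)
  for (r in records) {
    toks <- tok(paste(r$title, r$abstract))
    ok <- all(vapply(terms, function(t) tolower(t) %in% toks, logical(1)))
    if (ok) for (f in filters)
      ok <- ok && (f[2] %in% (r[[f[1]]] %||% character(0)))
    if (ok) hits <- c(hits, r$doc_id)
  }
  counts <- lapply(setNames(nm = FACET_FIELDS), function(field) {
    cts <- integer(0)
    for (r in records) {
      if (!(r$doc_id %in% hits)) next
      for (v in unique(r[[field]] %||% character(0)))
        cts[v] <- (if (is.na(cts[v])) 0L else cts[v]) + 1L
    }
    cts
  })
  list(hits = hits, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- small fixture builders --------------------------------------------------

# a tiny two-class labelled corpus with well-separated topic vocabularies
# (each class draws its background from its own word pool) plus a
# class-unique trigger word
toy_two_class <- function(n_per_class = 6L, seed = 1L) {
  set.seed(seed)
  pools <- list(Binding = paste0("bindw", 1:10),
                Gene_expression = paste0("exprw", 1:10))
  triggers <- c(Binding = "attaches", Gene_expression = "expressed")
  mk <- function(label, i) {
    toks <- c(sample(pools[[label]], 4, replace = TRUE), triggers[[label]])
    list(id = paste0(label, i), text = paste(toks, collapse = " "),
         labels = label,
         triggers = list(list(word = triggers[[label]], type = label,
                              token_start = 4L, token_end = 5L)))
  }
  c(lapply(seq_len(n_per_class), function(i) mk("Binding", i)),
    lapply(seq_len(n_per_class), function(i) mk("Gene_expression", i)))
}

# random valid BIO label sequence
random_bio <- function(n_tokens) {
  labels <- character(n_tokens)
  i <- 1L
  while (i <= n_tokens) {
    if (stats::runif(1) < 0.6) {
      labels[i] <- "O"; i <- i + 1L
    } else {
      ty <- sample(EVENT_TYPES, 1L)
      len <- min(sample(1:3, 1L), n_tokens - i + 1L)
      labels[i] <- paste0("B-", ty)
      if (len > 1L) labels[(i + 1L):(i + len - 1L)] <- paste0("I-", ty)
      i <- i + len
    }
  }
  labels
}
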