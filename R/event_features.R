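# Feature extraction for sentence-level event classification: bag-of-words
# TF-IDF with optional gene-name and trigger-word boosting.

#' Tokenize a sentence for bag-of-words features
#'
#' Lowercases, splits on whitespace/punctuation (internal hyphens kept) and
#' drops every token whose first character is not a letter, so numeric
#' artefacts like "-300" disappear while symbols like "p55" survive.
#'
#' @param text Input string.
#' @return Character vector of lowercase tokens, each starting with a letter.
#' @export
tokenize_and_filter <- function(text) {
  toks <- tokenize_text(text)
  toks[grepl("^\\p{L}", toks, perl = TRUE)]
}

#' Fit a TF-IDF model over a sentence corpus
#'
#' Each sentence is one "document" for the idf statistic:
#' \eqn{idf(t) = \ln(N / df(t))} with \eqn{N} the number of training
#' sentences.  No +1 smoothing is applied; a token occurring in every
#' sentence gets idf 0 and contributes nothing.
#'
#' @param sentences Character vector of training sentences.
#' @return Object of class \code{tfidf_model} (vocabulary + idf).
#' @export
fit_tfidf <- function(sentences) {
  stopifnot(length(sentences) > 0L)
  token_lists <- lapply(sentences, tokenize_and_filter)
  df <- table(unlist(lapply(token_lists, unique)))
  n <- length(sentences)
  idf <- log(n / as.numeric(df))
  structure(list(idf = setNames(idf, names(df)), n_docs = n),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model> ", length(x$idf), " terms over ", x$n_docs,
      " sentences\n", sep = "")
  invisible(x)
}

#' Vectorize a sentence under a fitted TF-IDF model
#'
#' Weight of token t is tf(t) * idf(t); the vector is then L2-normalised
#' (or left empty if all weights vanish).  Out-of-vocabulary tokens get
#' weight 0.
#'
#' @param model \code{tfidf_model} from \code{\link{fit_tfidf}}.
#' @param sentence Sentence text.
#' @return Named numeric vector (sparse: only non-zero entries).  The
#'   pre-normalisation L2 norm is kept in the \code{"raw_norm"} attribute so
#'   consumers that need tf-idf mass on its natural count scale (the
#'   multinomial naive Bayes estimator) can restore it.
#' @export
vectorize <- function(model, sentence) {
  if (!inherits(model, "tfidf_model")) stop("fit_tfidf() model required")
  toks <- tokenize_and_filter(sentence)
  toks <- toks[toks %in% names(model$idf)]
  if (length(toks) == 0L) return(setNames(numeric(0), character(0)))
  tf <- table(toks)
  w <- as.numeric(tf) * model$idf[names(tf)]
  w <- w[w > 0]
  v <- setNames(as.numeric(w), names(w))
  out <- l2_normalize(v)
  attr(out, "raw_norm") <- sqrt(sum(v^2))
  out
}

l2_normalize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0 || length(v) == 0L) return(v[v != 0])
  v / nrm
}

#' Boost configuration for feature weighting
#'
#' @param gene_boost_factor Multiplier for the merged gene feature (>= 1).
#' @param trigger_boost_factor Multiplier for trigger-word features (>= 1).
#' @param gene_rename Feature name that absorbs all gene tokens.
#' @return List of class \code{boost_config}.
#' @export
boost_config <- function(gene_boost_factor = 2.0, trigger_boost_factor = 2.0,
                         gene_rename = "protein") {
  stopifnot(gene_boost_factor >= 1, trigger_boost_factor >= 1)
  structure(list(gene_boost_factor = gene_boost_factor,
                 trigger_boost_factor = trigger_boost_factor,
                 gene_rename = gene_rename),
            class = "boost_config")
}

#' Boost gene and trigger features of a TF-IDF vector
#'
#' Gene tokens are removed, their summed weight is added to the single
#' renamed feature (default \code{"protein"}) and that feature is multiplied
#' by the gene boost factor; tokens present in the trigger lexicon (any
#' event class) are multiplied by the trigger boost factor.  The vector is
#' re-normalised to unit L2 norm afterwards, so boosting with both factors
#' at 1.0 and no gene tokens is the identity.
#'
#' @param vec Named numeric vector from \code{\link{vectorize}}.
#' @param gene_tokens Character vector of (lowercased) gene tokens in the
#'   sentence; tokens absent from \code{vec} are ignored with a warning.
#' @param trigger_lexicon \code{trigger_lexicon} object or NULL.
#' @param cfg \code{\link{boost_config}}.
#' @return Boosted, re-normalised named numeric vector.
#' @export
apply_boosting <- function(vec, gene_tokens = character(0),
                           trigger_lexicon = NULL, cfg = boost_config()) {
  if (length(vec) == 0L) return(vec)
  raw_norm <- attr(vec, "raw_norm")
  gene_tokens <- unique(tolower(gene_tokens))
  if (length(gene_tokens) > 0L) {
    unknown <- setdiff(gene_tokens, names(vec))
    if (length(unknown) > 0L)
      warning("gene tokens absent from vector ignored: ",
              paste(unknown, collapse = ", "))
    present <- intersect(gene_tokens, names(vec))
    if (length(present) > 0L) {
      moved <- sum(vec[present])
      vec <- vec[setdiff(names(vec), present)]
      vec[cfg$gene_rename] <- (vec[cfg$gene_rename] %|NA|% 0) + moved
      vec[cfg$gene_rename] <- vec[cfg$gene_rename] * cfg$gene_boost_factor
    }
  }
  if (!is.null(trigger_lexicon)) {
    trig_vocab <- trigger_vocabulary(trigger_lexicon)
    hit <- intersect(names(vec), trig_vocab)
    vec[hit] <- vec[hit] * cfg$trigger_boost_factor
  }
  out <- l2_normalize(vec)
  attr(out, "raw_norm") <- raw_norm
  out
}

`%|NA|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Build a per-class trigger-word lexicon from labelled training data
#'
#' Counts gold trigger words per event class, removes stop words, and orders
#' each class's list by descending frequency (ties broken lexicographically)
#' so the head of the list carries the most discriminative triggers.
#'
#' @param training List of labelled sentences; each element needs
#'   \code{$triggers}, a data.frame/list with \code{word} and \code{type}.
#' @param stopwords Character vector; defaults to the shipped English list.
#' @return Object of class \code{trigger_lexicon}: per event type a
#'   data.frame (word, freq) in rank order.
#' @export
build_trigger_lexicon <- function(training, stopwords = default_stopwords()) {
  counts <- lapply(setNames(nm = EVENT_TYPES), function(x)
    new.env(parent = emptyenv()))
  n_trig <- 0L
  for (inst in training) {
    trigs <- inst$triggers
    if (is.null(trigs) || length(trigs) == 0L) next
    if (is.data.frame(trigs)) {
      words <- trigs$word; types <- trigs$type
    } else {
      words <- vapply(trigs, function(t) t$word, character(1))
      types <- vapply(trigs, function(t) t$type, character(1))
    }
    for (k in seq_along(words)) {
      w <- tolower(words[[k]]); ty <- types[[k]]
      if (!(ty %in% EVENT_TYPES) || w %in% stopwords) next
      env <- counts[[ty]]
      env[[w]] <- (env[[w]] %||% 0L) + 1L
      n_trig <- n_trig + 1L
    }
  }
  if (n_trig == 0L) warning("no trigger words found; empty trigger lexicon")
  tables <- lapply(counts, function(env) {
    ws <- ls(env)
    if (length(ws) == 0L)
      return(data.frame(word = character(0), freq = integer(0),
                        stringsAsFactors = FALSE))
    fr <- vapply(ws, function(w) env[[w]], integer(1))
    ord <- order(-fr, ws)
    data.frame(word = ws[ord], freq = unname(fr[ord]),
               stringsAsFactors = FALSE)
  })
  structure(tables, class = "trigger_lexicon")
}

#' All trigger words of a trigger lexicon (any event class)
#' @param lex \code{trigger_lexicon}.
#' @return Character vector of unique trigger words.
#' @export
trigger_vocabulary <- function(lex) {
  unique(unlist(lapply(unclass(lex), function(tab) tab$word),
                use.names = FALSE))
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  cat("<trigger_lexicon> words per class:\n")
  for (ty in names(x)) cat("  ", ty, ": ", nrow(x[[ty]]), "\n", sep = "")
  invisible(x)
}

#' Read labelled sentences from JSON-lines
#'
#' One object per line: \code{\{"text": ..., "labels": [...],
#' "triggers": [\{"word","type","start","end"\}...], "genes": [...]\}}.
#'
#' @param path JSONL file.
#' @return List of labelled-sentence records.
#' @export
read_labeled_jsonl <- function(path) {
  recs <- read_jsonl(path)
  lapply(recs, function(r) {
    r$labels <- as.character(unlist(r$labels))
    bad <- setdiff(r$labels, EVENT_TYPES)
    if (length(bad) > 0L) stop("unknown event type(s): ",
                               paste(bad, collapse = ", "))
    r
  })
}

#' @rdname read_labeled_jsonl
#' @param records List of labelled-sentence records.
#' @export
write_labeled_jsonl <- function(records, path) {
  write_jsonl(records, path)
}
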