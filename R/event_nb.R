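# Multinomial naive Bayes over TF-IDF features, plus semi-supervised EM.

# Internal representation of prepared training instances:
#   vecs: list of named numeric vectors (TF-IDF, boosted as configured)
#   labels: character vector (single label per instance)
# The feature pipeline (tfidf model, trigger lexicon, boost config) is
# stored on the model so prediction replays it.

#' Feature-set variants for sentence classification
#'
#' \code{bow}: plain TF-IDF bag of words; \code{bow+gene}: gene tokens merged
#' into a boosted "protein" feature; \code{bow+trigger}: trigger words
#' boosted; \code{bow+gene+trigger}: both.  \code{bow+pos} is reserved for a
#' part-of-speech variant and is not implemented.
#'
#' @export
FEATURE_VARIANTS <- c("bow", "bow+gene", "bow+trigger", "bow+gene+trigger",
                      "bow+pos")

# build feature vectors for a list of labelled-sentence records
prepare_features <- function(records, variant, tfidf, trigger_lex, cfg) {
  use_gene <- variant %in% c("bow+gene", "bow+gene+trigger")
  use_trig <- variant %in% c("bow+trigger", "bow+gene+trigger")
  lapply(records, function(r) {
    v <- vectorize(tfidf, r$text)
    gtok <- if (use_gene) gene_tokens_of(r) else character(0)
    if (use_gene || use_trig)
      v <- suppressWarnings(apply_boosting(
        v, gene_tokens = gtok,
        trigger_lexicon = if (use_trig) trigger_lex else NULL, cfg = cfg))
    v
  })
}

# gene token strings from a record's character spans (0-based half-open)
gene_tokens_of <- function(r) {
  spans <- r$genes
  if (is.null(spans) || length(spans) == 0L) return(character(0))
  surf <- vapply(spans, function(sp) {
    sp <- as.integer(unlist(sp))
    substr(r$text, sp[1] + 1L, sp[2])
  }, character(1))
  unlist(lapply(surf, tokenize_and_filter))
}

# reduce a multi-label record to its first label (single-label protocol)
first_labels <- function(records) {
  vapply(records, function(r) r$labels[[1]], character(1))
}

# tf-idf mass on its natural count scale: the unit vector times its
# pre-normalisation norm.  The Laplace +1 pseudo-count is only meaningful
# against counts of this magnitude; length-normalised weights (all <= 1)
# would be drowned by it.
nb_counts <- function(v) {
  scale <- attr(v, "raw_norm") %||% 1
  out <- as.numeric(v) * scale
  names(out) <- names(v)
  out
}

#' Train a multinomial naive Bayes event classifier
#'
#' Single-label protocol: multi-label training sentences contribute their
#' first label only.  Word likelihoods use Laplace (+1) smoothing over the
#' (fractional) TF-IDF weights; class priors are smoothed the same way.
#' Prediction returns the maximum-posterior class, ties broken by
#' \code{\link{EVENT_TYPES}} declaration order; an empty feature vector
#' falls back to the prior alone.
#'
#' @param training List of labelled-sentence records (\code{text},
#'   \code{labels}, optional \code{triggers} / \code{genes}).
#' @param features One of \code{\link{FEATURE_VARIANTS}}.
#' @param cfg \code{\link{boost_config}} used by the boosted variants.
#' @param trigger_lex Optional prebuilt \code{trigger_lexicon}; built from
#'   \code{training} when needed and not supplied.
#' @return Object of class \code{nb_model}.
#' @export
train_nb <- function(training, features = "bow", cfg = boost_config(),
                     trigger_lex = NULL) {
  features <- match.arg(features, FEATURE_VARIANTS)
  if (features == "bow+pos")
    stop("the part-of-speech feature variant is not implemented")
  stopifnot(length(training) > 0L)
  tfidf <- fit_tfidf(vapply(training, function(r) r$text, character(1)))
  if (is.null(trigger_lex) && features %in% c("bow+trigger", "bow+gene+trigger"))
    trigger_lex <- suppressWarnings(build_trigger_lexicon(training))
  vecs <- lapply(prepare_features(training, features, tfidf, trigger_lex, cfg),
                 nb_counts)
  labels <- first_labels(training)
  model <- nb_estimate(vecs, labels, weights = NULL)
  structure(c(model, list(tfidf = tfidf, features = features,
                          trigger_lex = trigger_lex, cfg = cfg)),
            class = "nb_model")
}

# core estimator; `weights` is an optional n x K responsibility matrix
# (columns in EVENT_TYPES order).  Hard labels are one-hot rows.
nb_estimate <- function(vecs, labels = NULL, weights = NULL) {
  K <- length(EVENT_TYPES)
  vocab <- sort(unique(unlist(lapply(vecs, names), use.names = FALSE)))
  V <- length(vocab)
  n <- length(vecs)
  if (is.null(weights)) {
    weights <- matrix(0, n, K, dimnames = list(NULL, EVENT_TYPES))
    weights[cbind(seq_len(n), match(labels, EVENT_TYPES))] <- 1
  }
  class_mass <- colSums(weights)                        # soft class counts
  prior <- (class_mass + 1) / (n + K)                   # Laplace-smoothed
  counts <- matrix(0, V, K, dimnames = list(vocab, EVENT_TYPES))
  for (i in seq_len(n)) {
    v <- vecs[[i]]
    if (length(v) == 0L) next
    idx <- match(names(v), vocab)
    counts[idx, ] <- counts[idx, ] + outer(as.numeric(v), weights[i, ])
  }
  # Laplace +1 over fractional TF-IDF mass
  word_prob <- sweep(counts + 1, 2, colSums(counts) + V, "/")
  list(prior = prior, log_prior = log(prior),
       log_word = log(word_prob), vocab = vocab)
}

# joint log p(class, x) for one feature vector under an nb parameter set
nb_joint_loglik <- function(model, v) {
  ll <- model$log_prior
  if (length(v) > 0L) {
    idx <- match(names(v), model$vocab)
    keep <- !is.na(idx)
    if (any(keep))
      ll <- ll + as.numeric(crossprod(v[keep], model$log_word[idx[keep], ,
                                                              drop = FALSE]))
  }
  ll
}

# posterior over classes (normalised)
nb_posterior <- function(model, v) {
  ll <- nb_joint_loglik(model, v)
  p <- exp(ll - max(ll))
  p / sum(p)
}

# vectorize a raw sentence record through the model's feature pipeline
model_vector <- function(model, record) {
  if (is.character(record)) record <- list(text = record)
  prepare_features(list(record), model$features, model$tfidf,
                   model$trigger_lex, model$cfg)[[1]]
}

# as model_vector but on the count scale used by naive Bayes
model_counts <- function(model, record) nb_counts(model_vector(model, record))

#' Predict the event type of a sentence
#' @param model \code{nb_model}.
#' @param sentence Sentence text or labelled-sentence record.
#' @return Single event type (character).
#' @export
predict_nb <- function(model, sentence) {
  v <- model_counts(model, sentence)
  post <- nb_posterior(model, v)
  EVENT_TYPES[which.max(post)]   # which.max -> first maximum = declared order
}

#' Class posterior probabilities of a sentence under a naive Bayes model
#' @inheritParams predict_nb
#' @return Named numeric vector over \code{\link{EVENT_TYPES}} summing to 1.
#' @export
posterior_nb <- function(model, sentence) {
  setNames(nb_posterior(model, model_counts(model, sentence)), EVENT_TYPES)
}

#' Multi-label prediction from class posteriors
#'
#' Emits every class whose posterior reaches
#' \eqn{\max(1/9,\ \mathrm{top}/2)}; the argmax class always qualifies, so
#' at least one label is returned.
#'
#' @param posterior Named numeric posterior over \code{\link{EVENT_TYPES}}.
#' @return Character vector of event types in declaration order.
#' @export
multilabel_from_posterior <- function(posterior) {
  thr <- max(1 / length(EVENT_TYPES), max(posterior) / 2)
  EVENT_TYPES[posterior[EVENT_TYPES] >= thr]
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> features=", x$features, ", |V|=", length(x$vocab), "\n",
      sep = "")
  invisible(x)
}

# --- semi-supervised EM ------------------------------------------------------

#' Train naive Bayes with EM over unlabelled sentences
#'
#' Initialises naive Bayes on the labelled set, then alternates an E-step
#' (class responsibilities for the unlabelled sentences under the current
#' model) and an M-step (re-estimation from labelled one-hot plus fractional
#' unlabelled counts) until the MAP objective — observed-data log-likelihood
#' plus the Dirichlet(+1) log-prior matching the Laplace smoothing —
#' improves by less than \code{tol} or \code{max_iter} is reached.  With an
#' empty unlabelled set the result equals \code{\link{train_nb}}.
#'
#' @param labeled Non-empty list of labelled-sentence records.
#' @param unlabeled List of records (or plain strings); may be empty.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute improvement threshold on the objective.
#' @inheritParams train_nb
#' @return \code{nb_model} with an additional \code{em_loglik} trace (the
#'   MAP objective per iteration, non-decreasing).
#' @export
train_nb_em <- function(labeled, unlabeled = list(), max_iter = 50L,
                        tol = 1e-6, features = "bow", cfg = boost_config(),
                        trigger_lex = NULL) {
  features <- match.arg(features, FEATURE_VARIANTS)
  stopifnot(length(labeled) > 0L)
  unlabeled <- lapply(unlabeled, function(u)
    if (is.character(u)) list(text = u) else u)
  texts <- vapply(c(labeled, unlabeled), function(r) r$text, character(1))
  tfidf <- fit_tfidf(texts)
  if (is.null(trigger_lex) && features %in% c("bow+trigger", "bow+gene+trigger"))
    trigger_lex <- suppressWarnings(build_trigger_lexicon(labeled))
  lab_vecs <- lapply(prepare_features(labeled, features, tfidf, trigger_lex,
                                      cfg), nb_counts)
  unl_vecs <- lapply(prepare_features(unlabeled, features, tfidf, trigger_lex,
                                      cfg), nb_counts)
  labels <- first_labels(labeled)
  K <- length(EVENT_TYPES)
  nl <- length(lab_vecs); nu <- length(unl_vecs)

  hard <- matrix(0, nl, K, dimnames = list(NULL, EVENT_TYPES))
  hard[cbind(seq_len(nl), match(labels, EVENT_TYPES))] <- 1

  # initialise from the labelled data alone, over the full-corpus vocabulary
  # so the objective is comparable across iterations
  est <- nb_estimate_vocab(lab_vecs, hard, c(lab_vecs, unl_vecs))

  objective <- function(est) {
    obs <- 0
    for (i in seq_len(nl)) {
      ll <- nb_joint_loglik(est, lab_vecs[[i]])
      obs <- obs + ll[match(labels[i], EVENT_TYPES)]
    }
    for (v in unl_vecs) {
      ll <- nb_joint_loglik(est, v)
      obs <- obs + logsumexp(ll)
    }
    # Dirichlet(2) log-prior terms matching the +1 smoothing
    obs + sum(est$log_prior) + sum(est$log_word)
  }

  trace <- objective(est)
  if (!is.finite(trace)) stop("non-finite initial likelihood in EM")
  if (nu > 0L) {
    for (it in seq_len(max_iter)) {
      resp <- t(vapply(unl_vecs, function(v) nb_posterior(est, v),
                       numeric(K)))                       # E-step
      est2 <- nb_estimate(c(lab_vecs, unl_vecs),
                          weights = rbind(hard, resp))    # M-step
      obj <- objective(est2)
      if (!is.finite(obj)) stop("non-finite likelihood in EM iteration ", it)
      est <- est2
      trace <- c(trace, obj)
      if (obj - trace[length(trace) - 1L] < tol) break
    }
  }
  structure(c(est, list(tfidf = tfidf, features = features,
                        trigger_lex = trigger_lex, cfg = cfg,
                        em_loglik = trace)),
            class = "nb_model")
}

# estimate from weighted instances but over the vocabulary of `vocab_vecs`
# (used to initialise EM so the unlabelled tokens are in the model)
nb_estimate_vocab <- function(vecs, weights, vocab_vecs) {
  vocab <- sort(unique(unlist(lapply(vocab_vecs, names), use.names = FALSE)))
  K <- ncol(weights)
  V <- length(vocab)
  n <- length(vecs)
  counts <- matrix(0, V, K, dimnames = list(vocab, colnames(weights)))
  for (i in seq_len(n)) {
    v <- vecs[[i]]
    if (length(v) == 0L) next
    idx <- match(names(v), vocab)
    counts[idx, ] <- counts[idx, ] + outer(as.numeric(v), weights[i, ])
  }
  prior <- (colSums(weights) + 1) / (n + K)
  word_prob <- sweep(counts + 1, 2, colSums(counts) + V, "/")
  list(prior = prior, log_prior = log(prior),
       log_word = log(word_prob), vocab = vocab)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Multi-label prediction under a naive Bayes (or EM) model
#' @inheritParams predict_nb
#' @return Character vector of predicted event types (>= 1 label).
#' @export
predict_nb_multilabel <- function(model, sentence) {
  multilabel_from_posterior(posterior_nb(model, sentence))
}
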