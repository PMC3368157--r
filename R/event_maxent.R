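# Maximum-entropy (multinomial logistic) sentence classifier trained by
# L-BFGS on the L2-penalised conditional log-likelihood.

#' Train a maximum-entropy event classifier
#'
#' Multinomial logistic regression over the TF-IDF feature pipeline,
#' maximising the conditional log-likelihood with a Gaussian (L2) prior of
#' variance \code{sigma2} on the full parameter vector (weights and
#' intercepts), via L-BFGS with analytic gradients.  Multi-label sentences
#' contribute their first label.  If the optimizer stops before the
#' gradient-norm tolerance is met, the best iterate is returned with a
#' warning.
#'
#' The default prior variance of 10 (shared with the CRF module) is weak
#' enough that a class holding only a few percent of the training data can
#' still attain positive margin on a token unique to it; a unit-variance
#' prior measurably cannot (see the methods vignette).
#'
#' @inheritParams train_nb
#' @param sigma2 Gaussian prior variance (default 10).
#' @param max_iter Maximum optimizer iterations (default 200).
#' @param tol Gradient-norm (infinity norm) tolerance (default 1e-5).
#' @return Object of class \code{maxent_model}.
#' @export
train_maxent <- function(training, features = "bow", cfg = boost_config(),
                         trigger_lex = NULL, sigma2 = 10, max_iter = 200L,
                         tol = 1e-5) {
  features <- match.arg(features, FEATURE_VARIANTS)
  if (features == "bow+pos")
    stop("the part-of-speech feature variant is not implemented")
  stopifnot(length(training) > 0L)
  tfidf <- fit_tfidf(vapply(training, function(r) r$text, character(1)))
  if (is.null(trigger_lex) && features %in% c("bow+trigger", "bow+gene+trigger"))
    trigger_lex <- suppressWarnings(build_trigger_lexicon(training))
  vecs <- prepare_features(training, features, tfidf, trigger_lex, cfg)
  labels <- first_labels(training)

  vocab <- sort(unique(unlist(lapply(vecs, names), use.names = FALSE)))
  X <- vecs_to_matrix(vecs, vocab)
  K <- length(EVENT_TYPES)
  y <- match(labels, EVENT_TYPES)
  n <- nrow(X); d <- ncol(X)

  # parameters: d x K weight matrix plus K intercepts, flattened
  unpack <- function(par) list(W = matrix(par[seq_len(d * K)], d, K),
                               b = par[d * K + seq_len(K)])
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1

  negobj <- function(par) {
    p <- unpack(par)
    S <- sweep(X %*% p$W, 2, p$b, "+")
    m <- apply(S, 1, max)
    lse <- m + log(rowSums(exp(S - m)))
    ll <- sum(S[cbind(seq_len(n), y)] - lse)
    ll - sum(par^2) / (2 * sigma2)
  }
  neggrad <- function(par) {
    p <- unpack(par)
    S <- sweep(X %*% p$W, 2, p$b, "+")
    m <- apply(S, 1, max)
    P <- exp(S - m); P <- P / rowSums(P)
    Gw <- crossprod(X, Y - P) - p$W / sigma2
    Gb <- colSums(Y - P) - p$b / sigma2
    c(as.numeric(Gw), Gb)
  }
  par0 <- numeric(d * K + K)
  fit <- stats::optim(par0, fn = function(p) -negobj(p),
                      gr = function(p) -neggrad(p),
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e1,
                                     pgtol = tol))
  gnorm <- max(abs(neggrad(fit$par)))
  if (gnorm > tol)
    warning(sprintf(
      "maxent optimizer stopped with gradient norm %.2e > tol %.2e; returning best iterate",
      gnorm, tol))
  p <- unpack(fit$par)
  structure(list(W = p$W, b = p$b, vocab = vocab, sigma2 = sigma2,
                 grad_norm = gnorm, converged = gnorm <= tol,
                 tfidf = tfidf, features = features,
                 trigger_lex = trigger_lex, cfg = cfg),
            class = "maxent_model")
}

vecs_to_matrix <- function(vecs, vocab) {
  X <- matrix(0, length(vecs), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    idx <- match(names(v), vocab)
    keep <- !is.na(idx)
    X[i, idx[keep]] <- as.numeric(v[keep])
  }
  X
}

#' Class probabilities under a maximum-entropy model
#' @param model \code{maxent_model}.
#' @param sentence Sentence text or labelled-sentence record.
#' @return Named numeric vector over \code{\link{EVENT_TYPES}}, summing to 1.
#' @export
posterior_maxent <- function(model, sentence) {
  v <- model_vector(model, sentence)
  x <- numeric(length(model$vocab))
  idx <- match(names(v), model$vocab)
  keep <- !is.na(idx)
  x[idx[keep]] <- as.numeric(v[keep])
  s <- as.numeric(crossprod(model$W, x)) + model$b
  p <- exp(s - max(s))
  setNames(p / sum(p), EVENT_TYPES)
}

#' Multi-label prediction under a maximum-entropy model
#'
#' Returns every class with probability at or above
#' \eqn{\max(1/9,\ \mathrm{top}/2)} — the argmax always qualifies.
#'
#' @inheritParams posterior_maxent
#' @return Named numeric vector of probabilities of the emitted classes.
#' @export
predict_maxent <- function(model, sentence) {
  p <- posterior_maxent(model, sentence)
  lab <- multilabel_from_posterior(p)
  p[lab]
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model> features=", x$features, ", |V|=", length(x$vocab),
      ", grad_norm=", format(x$grad_norm, digits = 3), "\n", sep = "")
  invisible(x)
}
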