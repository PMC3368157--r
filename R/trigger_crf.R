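# Linear-chain CRF tagging event-trigger phrases with BIO labels over the
# nine event classes (19-label alphabet), with ABNER-style orthographic,
# affix and lexicon features.

#' BIO label alphabet (19 labels)
#'
#' \code{O} first (so an untrained, all-zero model decodes to all-O by the
#' first-maximum tie-break), then \code{B-<type>} and \code{I-<type>} for
#' each of the nine event types in declaration order.
#'
#' @return Character vector of length 19.
#' @export
bio_labels <- function() {
  c("O", paste0("B-", EVENT_TYPES), paste0("I-", EVENT_TYPES))
}

#' The 17 orthographic indicator features
#'
#' Named vector of Perl regular expressions; a token firing a regex gets the
#' feature \code{ORTH=<name>}.  The enumeration is declared data: upper-case
#' shapes, digit shapes, hyphen positions, punctuation, Roman numerals and
#' spelled-out Greek letters.
#'
#' @return Named character vector of length 17.
#' @export
orthographic_features <- function() {
  c(
    InitCaps      = "^[A-Z][a-z]",
    AllCaps       = "^[A-Z]+$",
    CapsMix       = "([A-Z].*[a-z])|([a-z].*[A-Z])",
    HasDigit      = "[0-9]",
    SingleDigit   = "^[0-9]$",
    DoubleDigit   = "^[0-9][0-9]$",
    NaturalNumber = "^[0-9]+$",
    RealNumber    = "^-?[0-9]+[.,][0-9]+$",
    AlphaNumeric  = "([A-Za-z].*[0-9])|([0-9].*[A-Za-z])",
    HasDash       = "-",
    InitDash      = "^-",
    EndDash       = "-$",
    Punctuation   = "^[[:punct:]]+$",
    Roman         = "^[IVXDLCM]+$",
    Greek         = paste0("^(?i)(alpha|beta|gamma|delta|epsilon|zeta|eta|",
                           "theta|iota|kappa|lambda|mu|nu|xi|omicron|pi|rho|",
                           "sigma|tau|upsilon|phi|chi|psi|omega)$"),
    SingleChar    = "^[A-Za-z]$",
    CapLetter     = "^[A-Z]$"
  )
}

# features of one token in isolation (no neighbour copies)
token_features <- function(token, lexicons) {
  orth <- orthographic_features()
  fire <- vapply(orth, function(rx) grepl(rx, token, perl = TRUE), logical(1))
  feats <- paste0("ORTH=", names(orth)[fire], recycle0 = TRUE)
  low <- tolower(token)
  n <- nchar(low)
  if (n >= 3L) feats <- c(feats, paste0("PRE3=", substr(low, 1L, 3L)),
                          paste0("SUF3=", substr(low, n - 2L, n)))
  if (n >= 4L) feats <- c(feats, paste0("PRE4=", substr(low, 1L, 4L)),
                          paste0("SUF4=", substr(low, n - 3L, n)))
  for (nm in names(lexicons))
    if (low %in% lexicons[[nm]]) feats <- c(feats, paste0("LEX=", nm))
  c(paste0("W=", low), feats)
}

#' Extract per-token observation features for the CRF
#'
#' Per token: the token identity (\code{W=}), the 17 orthographic indicators
#' (\code{ORTH=}), 3/4-gram prefixes and suffixes (\code{PRE3=}, \code{PRE4=},
#' \code{SUF3=}, \code{SUF4=}; only when the token is long enough), lexicon
#' membership (\code{LEX=<name>}) for each loaded lexicon, plus copies of
#' the neighbouring tokens' features at offsets -1/+1 and sentence-boundary
#' markers.
#'
#' @param tokens Non-empty character vector of tokens.
#' @param lexicons Named list of character vectors (lowercased members);
#'   defaults to the shipped Greek-letter lexicon.
#' @return List of character vectors (one feature set per token).
#' @export
extract_features <- function(tokens, lexicons = crf_default_lexicons()) {
  stopifnot(length(tokens) > 0L)
  own <- lapply(tokens, token_features, lexicons = lexicons)
  n <- length(tokens)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- if (i > 1L) paste0("-1:", own[[i - 1L]]) else "-1:BOS"
    nxt  <- if (i < n)  paste0("+1:", own[[i + 1L]]) else "+1:EOS"
    out[[i]] <- unique(c(own[[i]], prev, nxt))
  }
  out
}

#' Default hand-prepared lexicons for CRF features
#' @return Named list of character vectors.
#' @export
crf_default_lexicons <- function() {
  list(greek = tolower(bf_read_lines("greek_letters.txt")))
}

# --- BIO structure -----------------------------------------------------------

# transition validity: I-T only after B-T or I-T
bio_transition_matrix <- function() {
  labs <- bio_labels()
  L <- length(labs)
  allowed <- matrix(TRUE, L, L, dimnames = list(labs, labs))
  for (b in labs) {
    if (!startsWith(b, "I-")) next
    ty <- sub("^I-", "", b)
    ok <- c(paste0("B-", ty), paste0("I-", ty))
    allowed[!(labs %in% ok), b] <- FALSE
  }
  allowed
}

bio_start_vector <- function() {
  labs <- bio_labels()
  setNames(!startsWith(labs, "I-"), labs)
}

#' Check that a label sequence is a valid BIO path
#' @param labels Character vector of BIO labels.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_bio <- function(labels) {
  labs <- bio_labels()
  bad <- setdiff(labels, labs)
  if (length(bad) > 0L) stop("unknown BIO label(s): ", paste(bad, collapse = ", "))
  ok_start <- bio_start_vector()
  if (!ok_start[[labels[1]]]) stop("sequence starts with ", labels[1])
  allowed <- bio_transition_matrix()
  for (t in seq_along(labels)[-1])
    if (!allowed[labels[t - 1L], labels[t]])
      stop("invalid BIO transition at position ", t, ": ",
           labels[t - 1L], " -> ", labels[t])
  invisible(TRUE)
}

# --- training ----------------------------------------------------------------

#' CRF training hyperparameters
#' @param sigma2 Gaussian prior variance on all weights (default 10).
#' @param max_iter Maximum L-BFGS iterations (default 300).
#' @param tol Projected-gradient tolerance (default 1e-5).
#' @return List of class \code{crf_hyper}.
#' @export
crf_hyper <- function(sigma2 = 10, max_iter = 300L, tol = 1e-5) {
  structure(list(sigma2 = sigma2, max_iter = max_iter, tol = tol),
            class = "crf_hyper")
}

#' Train a linear-chain CRF trigger tagger
#'
#' Maximises the L2-penalised conditional log-likelihood by L-BFGS with
#' exact forward-backward gradients.  Weights are initialised at zero, so
#' training is deterministic given the data and hyperparameters.  Invalid
#' BIO paths in the training data are rejected with the offending sequence
#' index.
#'
#' @param sequences List of \code{list(obs = <list of feature sets from
#'   \link{extract_features}>, labels = <BIO label vector>)}; observation
#'   and label lists must have equal length.
#' @param hyper \code{\link{crf_hyper}}.
#' @return Object of class \code{crf_model}; \code{$objective_trace} holds
#'   the penalised log-likelihood at each accepted optimizer iterate
#'   (non-decreasing).
#' @export
train_crf <- function(sequences, hyper = crf_hyper()) {
  stopifnot(length(sequences) > 0L)
  labs <- bio_labels()
  for (s in seq_along(sequences)) {
    sq <- sequences[[s]]
    if (length(sq$obs) != length(sq$labels))
      stop("sequence ", s, ": observation/label length mismatch")
    tryCatch(validate_bio(sq$labels),
             error = function(e) stop("sequence ", s, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  feat_vocab <- sort(unique(unlist(lapply(sequences, function(sq)
    unlist(sq$obs, use.names = FALSE)), use.names = FALSE)))
  feats <- lapply(sequences, function(sq)
    lapply(sq$obs, function(fs) match(fs, feat_vocab)))
  labels <- lapply(sequences, function(sq) match(sq$labels, labs))

  L <- length(labs); F_ <- length(feat_vocab)
  allowed <- bio_transition_matrix()
  start_ok <- unname(bio_start_vector())
  npar <- F_ * L + L * L

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$val)
    W <- matrix(par[seq_len(F_ * L)], F_, L)
    Tr <- matrix(par[F_ * L + seq_len(L * L)], L, L)
    res <- crf_negll_grad_cpp(feats, labels, W, Tr, allowed, start_ok)
    val <- list(
      f = res$negll + sum(par^2) / (2 * hyper$sigma2),
      g = c(as.numeric(res$gW), as.numeric(res$gT)) + par / hyper$sigma2)
    cache$par <- par; cache$val <- val
    val
  }
  trace <- numeric(0)
  fit <- stats::optim(
    numeric(npar),
    fn = function(p) { v <- evaluate(p)$f; trace <<- c(trace, v); v },
    gr = function(p) evaluate(p)$g,
    method = "L-BFGS-B",
    control = list(maxit = hyper$max_iter, pgtol = hyper$tol, factr = 1e1))
  # accepted iterates: running minimum of the evaluated objective values
  accepted <- -cummin(trace)   # penalised log-likelihood, non-decreasing
  W <- matrix(fit$par[seq_len(F_ * L)], F_, L,
              dimnames = list(feat_vocab, labs))
  Tr <- matrix(fit$par[F_ * L + seq_len(L * L)], L, L,
               dimnames = list(labs, labs))
  structure(list(W = W, Trans = Tr, feat_vocab = feat_vocab, labels = labs,
                 allowed = allowed, start_ok = start_ok, hyper = hyper,
                 objective_trace = accepted,
                 final_negll = evaluate(fit$par)$f),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("<crf_model> ", length(x$feat_vocab), " features x ",
      length(x$labels), " labels\n", sep = "")
  invisible(x)
}

# map observation feature sets to training feature ids (unknown dropped)
obs_to_ids <- function(model, observations) {
  lapply(observations, function(fs) {
    ids <- match(fs, model$feat_vocab)
    as.integer(ids[!is.na(ids)])
  })
}

#' Viterbi decoding of a token sequence
#'
#' Returns the maximum-score valid BIO path; invalid transitions are
#' structurally excluded and ties resolve to the first label in
#' \code{\link{bio_labels}} order.
#'
#' @param model \code{crf_model}.
#' @param observations List of feature sets from \code{\link{extract_features}}.
#' @return Character vector of BIO labels, one per token.
#' @export
viterbi_tag <- function(model, observations) {
  stopifnot(length(observations) > 0L)
  path <- crf_viterbi_cpp(obs_to_ids(model, observations), model$W,
                          model$Trans, model$allowed, model$start_ok)
  model$labels[path]
}

#' Log-partition (forward algorithm) of an observation sequence
#' @inheritParams viterbi_tag
#' @return log Z, the log-sum of exponentiated scores over all valid paths.
#' @export
crf_log_partition <- function(model, observations) {
  crf_logZ_cpp(obs_to_ids(model, observations), model$W, model$Trans,
               model$allowed, model$start_ok)
}

#' Unnormalised score of one label path
#' @inheritParams viterbi_tag
#' @param labels BIO label vector of the same length.
#' @return Path score (sum of emission and transition weights); -Inf-like
#'   for structurally invalid paths.
#' @export
crf_path_score <- function(model, observations, labels) {
  crf_path_score_cpp(obs_to_ids(model, observations), match(labels, model$labels),
                     model$W, model$Trans, model$allowed, model$start_ok)
}

# --- spans <-> BIO -----------------------------------------------------------

#' Decode BIO labels into typed trigger spans
#'
#' Maximal \code{B-T (I-T)*} runs become spans of type T.  Token intervals
#' are 0-based half-open.
#'
#' @param tokens Character vector of tokens (length defines the sequence).
#' @param labels Valid BIO label vector of the same length.
#' @return data.frame with columns start_token, end_token, type, text.
#' @export
decode_spans <- function(tokens, labels) {
  stopifnot(length(tokens) == length(labels))
  validate_bio(labels)
  out <- list()
  i <- 1L
  while (i <= length(labels)) {
    if (startsWith(labels[i], "B-")) {
      ty <- sub("^B-", "", labels[i])
      j <- i
      while (j < length(labels) && labels[j + 1L] == paste0("I-", ty))
        j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        start_token = i - 1L, end_token = j, type = ty,
        text = paste(tokens[i:j], collapse = " "),
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L)
    return(data.frame(start_token = integer(0), end_token = integer(0),
                      type = character(0), text = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Encode typed trigger spans as a BIO label sequence
#' @param n_tokens Sequence length.
#' @param spans data.frame with start_token, end_token (0-based half-open)
#'   and type.
#' @return Character vector of BIO labels.
#' @export
encode_spans <- function(n_tokens, spans) {
  labels <- rep("O", n_tokens)
  if (nrow(spans) == 0L) return(labels)
  spans <- spans[order(spans$start_token), , drop = FALSE]
  for (k in seq_len(nrow(spans))) {
    s <- spans$start_token[k] + 1L; e <- spans$end_token[k]
    stopifnot(s >= 1L, e <= n_tokens, s <= e)
    labels[s] <- paste0("B-", spans$type[k])
    if (e > s) labels[(s + 1L):e] <- paste0("I-", spans$type[k])
  }
  labels
}

# --- JSONL I/O ---------------------------------------------------------------

#' Read / write BIO token sequences as JSON-lines
#'
#' One object per line: \code{\{"tokens": [...], "labels": [...]\}}.
#' @param path File path.
#' @return List of \code{list(tokens, labels)} records.
#' @export
read_bio_jsonl <- function(path) {
  lapply(read_jsonl(path), function(r)
    list(tokens = as.character(unlist(r$tokens)),
         labels = if (is.null(r$labels)) NULL
                  else as.character(unlist(r$labels))))
}

#' @rdname read_bio_jsonl
#' @param records List of \code{list(tokens, labels)}.
#' @export
write_bio_jsonl <- function(records, path) {
  write_jsonl(records, path)
}

#' Convert labelled-sentence trigger standoff records to BIO sequences
#'
#' Tokenises each sentence with the bag-of-words tokenizer (unfiltered) and
#' converts token-indexed trigger spans to BIO labels.
#'
#' @param records Labelled-sentence records whose \code{triggers} carry
#'   \code{token_start}, \code{token_end} (0-based half-open) and \code{type}.
#' @return List of \code{list(tokens, labels)}.
#' @export
triggers_to_bio <- function(records) {
  lapply(records, function(r) {
    tokens <- tokenize_text(r$text)
    trigs <- r$triggers
    spans <- if (is.null(trigs) || length(trigs) == 0L) {
      data.frame(start_token = integer(0), end_token = integer(0),
                 type = character(0))
    } else if (is.data.frame(trigs)) {
      data.frame(start_token = trigs$token_start, end_token = trigs$token_end,
                 type = trigs$type, stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(trigs, function(t) data.frame(
        start_token = t$token_start, end_token = t$token_end, type = t$type,
        stringsAsFactors = FALSE)))
    }
    list(tokens = tokens, labels = encode_spans(length(tokens), spans))
  })
}
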