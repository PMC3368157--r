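# Dictionary-based entity tagging: pluggable lexicons over gene/protein,
# chemical/drug and disease surface forms.

#' Load a lexicon from TSV
#'
#' Each non-comment row is \code{surface[\\tab canonical]}; a missing
#' canonical id defaults to the surface form itself.  Duplicate surfaces keep
#' the first canonical id (with a warning).
#'
#' @param path TSV file path.
#' @param entity_class One of \code{\link{ENTITY_CLASSES}}.
#' @return An object of class \code{lexicon}.
#' @export
load_lexicon <- function(path, entity_class) {
  entity_class <- match.arg(entity_class, ENTITY_CLASSES)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty lexicon file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  surfaces <- character(0); canon <- character(0)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (!nzchar(p[1])) { warning("malformed lexicon row ", i, " skipped"); next }
    surfaces <- c(surfaces, p[1])
    canon <- c(canon, if (length(p) >= 2L && nzchar(p[2])) p[2] else p[1])
  }
  dup <- duplicated(surfaces)
  if (any(dup)) {
    warning("duplicate lexicon surfaces kept first canonical: ",
            paste(unique(surfaces[dup]), collapse = ", "))
    canon <- canon[!dup]; surfaces <- surfaces[!dup]
  }
  lexicon(setNames(canon, surfaces), entity_class)
}

#' Construct a lexicon from a named character vector
#' @param entries Named character vector: names are surface forms, values
#'   canonical ids.  Unnamed entries are self-canonical.
#' @param entity_class Entity class of all entries.
#' @return \code{lexicon} object.
#' @export
lexicon <- function(entries, entity_class) {
  entity_class <- match.arg(entity_class, ENTITY_CLASSES)
  if (is.null(names(entries))) names(entries) <- entries
  fix <- !nzchar(names(entries))
  names(entries)[fix] <- entries[fix]
  stopifnot(all(nzchar(names(entries))))
  # hashed lookup tables under the case policy: surfaces of <= 4 characters
  # match exactly, longer surfaces match case-insensitively
  exact <- new.env(parent = emptyenv())
  folded <- new.env(parent = emptyenv())
  for (k in seq_along(entries)) {
    s <- names(entries)[k]
    if (nchar(s) <= 4L) {
      if (is.null(exact[[s]])) exact[[s]] <- unname(entries[[k]])
    } else {
      key <- tolower(s)
      if (is.null(folded[[key]])) folded[[key]] <- unname(entries[[k]])
    }
  }
  structure(list(entity_class = entity_class,
                 entries = entries,
                 exact = exact, folded = folded),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon:", x$entity_class, "> ", length(x$entries), " entries\n", sep = "")
  invisible(x)
}

# tokenize keeping character offsets (0-based half-open, sentence-local);
# splits on whitespace/punctuation but keeps internal hyphens
tokenize_with_offsets <- function(text) {
  loc <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*")[[1]]
  if (nrow(loc) == 1L && is.na(loc[1, 1]))
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  data.frame(
    token = stringi::stri_sub(text, loc[, 1], loc[, 2]),
    start = loc[, 1] - 1L,
    end   = loc[, 2],
    stringsAsFactors = FALSE)
}

# lookup a candidate string against a lexicon under the case policy
# (exact case for surfaces <= 4 characters, protecting short symbols like
# p53 vs P53; case-insensitive for longer surfaces); canonical id or NA
lexicon_lookup <- function(lex, candidate) {
  hit <- lex$exact[[candidate]]
  if (!is.null(hit)) return(hit)
  if (nchar(candidate) > 4L) {
    hit <- lex$folded[[tolower(candidate)]]
    if (!is.null(hit)) return(hit)
  }
  NA_character_
}

#' Annotate one sentence with entity mentions
#'
#' Greedy longest-match over token n-grams (n up to 6), scanning left to
#' right; matched spans are consumed so mentions never overlap.  At equal
#' length, ties across entity classes are broken by the priority order
#' gene > dna > rna > cell_line > cell_type > chemical > disease.
#' Surfaces of four characters or fewer must match case exactly; longer
#' surfaces match case-insensitively.
#'
#' @param sentence Sentence text (string) or one-row sentence data.frame
#'   from \code{\link{split_sentences}}.
#' @param lexicons List of \code{lexicon} objects.
#' @param max_ngram Longest token n-gram considered (default 6).
#' @return data.frame with columns doc_id, sentence_index, char_start,
#'   char_end (0-based half-open, sentence-local), entity_class, surface,
#'   canonical.
#' @export
annotate_sentence <- function(sentence, lexicons, max_ngram = 6L) {
  if (is.data.frame(sentence)) {
    text <- sentence$text[1]
    doc_id <- sentence$doc_id[1]
    sent_idx <- sentence$index[1]
  } else {
    text <- sentence; doc_id <- NA_character_; sent_idx <- NA_integer_
  }
  if (inherits(lexicons, "lexicon")) lexicons <- list(lexicons)
  empty <- data.frame(doc_id = character(0), sentence_index = integer(0),
                      char_start = integer(0), char_end = integer(0),
                      entity_class = character(0), surface = character(0),
                      canonical = character(0), stringsAsFactors = FALSE)
  toks <- tokenize_with_offsets(text)
  if (nrow(toks) == 0L || length(lexicons) == 0L) return(empty)

  # order lexicons by class priority for tie-breaks
  prio <- order(match(vapply(lexicons, `[[`, "", "entity_class"), ENTITY_CLASSES))
  lexicons <- lexicons[prio]

  out <- list()
  i <- 1L
  while (i <= nrow(toks)) {
    best <- NULL
    for (n in seq(min(max_ngram, nrow(toks) - i + 1L), 1L)) {
      j <- i + n - 1L
      cand <- substr(text, toks$start[i] + 1L, toks$end[j])
      for (lex in lexicons) {
        canon <- lexicon_lookup(lex, cand)
        if (!is.na(canon)) {
          best <- list(i = i, j = j, class = lex$entity_class,
                       surface = cand, canonical = canon)
          break
        }
      }
      if (!is.null(best)) break   # longest n wins; class priority broke ties
    }
    if (is.null(best)) { i <- i + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      doc_id = doc_id, sentence_index = sent_idx,
      char_start = toks$start[best$i], char_end = toks$end[best$j],
      entity_class = best$class, surface = best$surface,
      canonical = best$canonical, stringsAsFactors = FALSE)
    i <- best$j + 1L            # consume matched span
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Annotate every sentence of every document in a store
#'
#' Deterministic batch contract: the result equals per-sentence annotation
#' applied independently, so re-running yields identical output.
#'
#' @param store \code{doc_store} from \code{\link{store_documents}}.
#' @param lexicons List of \code{lexicon} objects.
#' @return Named list, one data.frame of mentions per doc_id (possibly
#'   zero-row).
#' @export
annotate_corpus <- function(store, lexicons) {
  out <- list()
  for (i in seq_len(nrow(store$docs))) {
    doc <- store$docs[i, , drop = FALSE]
    sents <- split_sentences(doc)
    ments <- lapply(seq_len(nrow(sents)), function(k)
      annotate_sentence(sents[k, , drop = FALSE], lexicons))
    ments <- ments[vapply(ments, nrow, 0L) > 0L]
    out[[doc$doc_id]] <- if (length(ments) > 0L) do.call(rbind, ments) else
      annotate_sentence("", lexicons)  # zero-row frame with right columns
  }
  out
}

#' Write entity mentions as JSON-lines standoff records
#' @param mentions data.frame of mentions (rbind of annotate output).
#' @param path Output path.
#' @export
write_mentions_jsonl <- function(mentions, path) {
  write_jsonl(lapply(seq_len(nrow(mentions)), function(i) list(
    doc_id = mentions$doc_id[i], sentence_index = mentions$sentence_index[i],
    start = mentions$char_start[i], end = mentions$char_end[i],
    class = mentions$entity_class[i], surface = mentions$surface[i],
    canonical = mentions$canonical[i])), path)
  invisible(path)
}
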