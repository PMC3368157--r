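# Data-store layer: XML/text ingestion, sentence segmentation, document store.

#' Create a document record
#'
#' @param doc_id Unique document identifier (PubMed id or synthetic id).
#' @param title Article title.
#' @param abstract Abstract text; may be empty when the citation has none.
#' @param source_uri Optional provenance string.
#' @return A one-row data.frame with class \code{bf_document} columns.
#' @export
document <- function(doc_id, title = "", abstract = "", source_uri = NA_character_) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  data.frame(
    doc_id     = normalize_utf8(doc_id),
    title      = normalize_utf8(title),
    abstract   = normalize_utf8(abstract),
    source_uri = source_uri,
    stringsAsFactors = FALSE
  )
}

# All text enters the package through this: UTF-8, NFC-normalised.
normalize_utf8 <- function(x) {
  if (length(x) == 0L) return(character(0))
  x[is.na(x)] <- ""
  stringi::stri_trans_nfc(enc2utf8(as.character(x)))
}

#' Read Medline-style XML into documents
#'
#' Accepts both MedlineCitation-style XML (\code{PMID}, \code{ArticleTitle},
#' \code{AbstractText} elements) and a minimal fixture dialect of
#' \code{<doc id="..." title="..." abstract="..."/>} elements.  Gzipped files
#' are read transparently.  Citations without an abstract yield a document
#' with an empty abstract; citations without a PMID are skipped with a
#' warning.
#'
#' @param path Path to an XML file, optionally gzip-compressed.
#' @return data.frame of documents in file order (doc_id, title, abstract,
#'   source_uri).
#' @export
read_medline_xml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("XML parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  cites <- xml2::xml_find_all(doc, ".//MedlineCitation")
  out <- list()
  if (length(cites) > 0L) {
    for (i in seq_along(cites)) {
      cite <- cites[[i]]
      pmid <- xml2::xml_text(xml2::xml_find_first(cite, ".//PMID"))
      if (is.na(pmid) || !nzchar(trimws(pmid))) {
        warning("citation ", i, " in '", path, "' has no PMID; skipped")
        next
      }
      title <- xml2::xml_text(xml2::xml_find_first(cite, ".//ArticleTitle"))
      abst  <- xml2::xml_find_all(cite, ".//Abstract/AbstractText")
      abstract <- if (length(abst) == 0L) "" else
        paste(vapply(abst, xml2::xml_text, character(1)), collapse = " ")
      out[[length(out) + 1L]] <- document(trimws(pmid),
                                          if (is.na(title)) "" else title,
                                          abstract, source_uri = path)
    }
  } else {
    # minimal <doc id= title= abstract=> fixture dialect
    nodes <- xml2::xml_find_all(doc, ".//doc")
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      id <- xml2::xml_attr(nd, "id")
      if (is.na(id) || !nzchar(id)) {
        warning("doc element ", i, " in '", path, "' has no id; skipped")
        next
      }
      out[[length(out) + 1L]] <- document(
        id,
        title    = xml2::xml_attr(nd, "title",    default = ""),
        abstract = xml2::xml_attr(nd, "abstract", default = ""),
        source_uri = path
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(doc_id = character(0), title = character(0),
                      abstract = character(0), source_uri = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read plain-text abstracts (one abstract per file)
#'
#' The file name (without extension) becomes the doc_id; the first line is
#' taken as the title and the remainder as the abstract.
#'
#' @param paths Character vector of file paths.
#' @return data.frame of documents.
#' @export
read_text_abstracts <- function(paths) {
  rows <- lapply(paths, function(p) {
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    id <- sub("\\.[^.]*$", "", basename(p))
    document(id,
             title = if (length(lines) >= 1L) lines[[1L]] else "",
             abstract = if (length(lines) >= 2L)
               paste(lines[-1L], collapse = " ") else "",
             source_uri = p)
  })
  do.call(rbind, rows)
}

#' Read / write a JSON-lines document dump
#'
#' One JSON object per line with fields doc_id, title, abstract.
#' @param path File path.
#' @return \code{read_documents_jsonl}: data.frame of documents.
#' @export
read_documents_jsonl <- function(path) {
  recs <- read_jsonl(path)
  do.call(rbind, lapply(recs, function(r)
    document(r$doc_id, r$title %||% "", r$abstract %||% "")))
}

#' @rdname read_documents_jsonl
#' @param docs data.frame of documents.
#' @export
write_documents_jsonl <- function(docs, path) {
  write_jsonl(lapply(seq_len(nrow(docs)), function(i) list(
    doc_id = docs$doc_id[i], title = docs$title[i],
    abstract = docs$abstract[i])), path)
  invisible(path)
}

# --- sentence segmentation ---------------------------------------------------

abbrev_whitelist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- bf_read_lines("abbreviations.txt")
    cache
  }
})

#' Split an abstract into sentences
#'
#' Rule-based splitter: a boundary is a run of \code{.!?} followed by
#' whitespace and an upper-case letter or digit, unless the word carrying the
#' terminal period is on a fixed abbreviation whitelist (e.g. "Fig.",
#' "E.", "et al.").  Deterministic; offsets are 0-based half-open in Unicode
#' code points and slicing the abstract by them reproduces each sentence
#' exactly.
#'
#' @param doc A one-row document data.frame (or a plain string).
#' @return data.frame with columns doc_id, index (0-based), text,
#'   char_start, char_end.
#' @export
split_sentences <- function(doc) {
  if (is.character(doc)) doc <- document("(text)", abstract = doc)
  abstract <- doc$abstract[1]
  doc_id <- doc$doc_id[1]
  empty <- data.frame(doc_id = character(0), index = integer(0),
                      text = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(abstract)) return(empty)

  # candidate boundaries: [.!?]+ then whitespace then [A-Z0-9]
  m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])", abstract, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # last punct char
    for (e in ends) {
      # word carrying the terminal period (look back to previous whitespace)
      prefix <- substr(abstract, 1L, e)
      word <- sub(".*\\s", "", prefix)
      two  <- sub(".*\\s(\\S+\\s\\S+)$", "\\1", prefix)  # catch "et al."
      if (word %in% abbrev_whitelist() || two %in% abbrev_whitelist()) next
      cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops  <- c(cuts, nchar(abstract))
  out <- list()
  idx <- 0L
  for (k in seq_along(starts)) {
    raw <- substr(abstract, starts[k], stops[k])
    # trim leading/trailing whitespace but keep offsets aligned
    lead <- nchar(sub("^\\s*", "", raw))
    s0 <- starts[k] + (nchar(raw) - lead)
    txt <- sub("\\s*$", "", sub("^\\s*", "", raw))
    if (!nzchar(txt)) next
    out[[length(out) + 1L]] <- data.frame(
      doc_id = doc_id, index = idx, text = txt,
      char_start = s0 - 1L,                 # 0-based
      char_end = s0 - 1L + nchar(txt),
      stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# --- document store ----------------------------------------------------------

#' In-memory indexed document store
#'
#' @param docs data.frame of documents with unique doc_ids.
#' @return An object of class \code{doc_store}.
#' @export
store_documents <- function(docs) {
  stopifnot(is.data.frame(docs), "doc_id" %in% names(docs))
  if (anyDuplicated(docs$doc_id))
    stop("duplicate doc_id in store: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "))
  # token postings over lowercased title + abstract
  toks <- lapply(seq_len(nrow(docs)), function(i)
    unique(tokenize_text(paste(docs$title[i], docs$abstract[i]))))
  postings <- new.env(parent = emptyenv())
  for (i in seq_along(toks)) {
    for (tk in toks[[i]]) {
      postings[[tk]] <- c(postings[[tk]], docs$doc_id[i])
    }
  }
  structure(list(docs = docs, postings = postings), class = "doc_store")
}

#' @export
print.doc_store <- function(x, ...) {
  cat("<doc_store> ", nrow(x$docs), " documents\n", sep = "")
  invisible(x)
}

#' Retrieve a document by id
#' @param store A \code{doc_store}.
#' @param doc_id Document id.
#' @return One-row document data.frame.
#' @export
get_document <- function(store, doc_id) {
  i <- match(doc_id, store$docs$doc_id)
  if (is.na(i)) stop("doc_id not found: ", doc_id)
  store$docs[i, , drop = FALSE]
}

#' Scan the store for a keyword
#'
#' Returns ids of documents whose lowercased title+abstract contains the
#' lowercased term as a whole token.
#'
#' @param store A \code{doc_store}.
#' @param term Single search term.
#' @return Character vector of doc_ids, in store order.
#' @export
keyword_scan <- function(store, term) {
  tk <- tolower(trimws(term))
  hits <- store$postings[[tk]]
  if (is.null(hits)) character(0) else
    hits[order(match(hits, store$docs$doc_id))]
}

# shared word tokenizer: lowercase tokens of letters/digits, internal hyphens
# kept ("IL-2" is one token)
tokenize_text <- function(text) {
  text <- tolower(normalize_utf8(text))
  m <- stringi::stri_extract_all_regex(
    text, "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*")[[1]]
  if (length(m) == 1L && is.na(m[1])) character(0) else m
}

# --- JSON-lines helpers (shared by several modules) --------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE,
         simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

write_jsonl <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"), con)
  invisible(path)
}
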