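# Faceted full-text index: inverted text index + facet postings, conjunctive
# search with TF-IDF cosine ranking, facet counts, tag clouds, autocomplete.

#' Facet fields of the shared IE/faceting schema
#' @export
FACET_FIELDS <- c("genes", "diseases", "drugs_chemicals", "cell_lines",
                  "event_types")

#' Assemble indexed documents from annotation output
#'
#' Merges documents with their entity mentions and sentence event labels
#' into the shared schema consumed by \code{\link{build_index}}: one record
#' per document with deduplicated facet values.
#'
#' @param docs data.frame of documents.
#' @param mentions Named list (doc_id -> mention data.frame) from
#'   \code{\link{annotate_corpus}}, or NULL.
#' @param event_labels Named list (doc_id -> character vector of event
#'   types), or NULL.
#' @return List of indexed-document records.
#' @export
indexed_documents <- function(docs, mentions = NULL, event_labels = NULL) {
  class_field <- c(gene = "genes", dna = "genes", rna = "genes",
                   cell_line = "cell_lines", cell_type = "cell_lines",
                   chemical = "drugs_chemicals", disease = "diseases")
  lapply(seq_len(nrow(docs)), function(i) {
    id <- docs$doc_id[i]
    rec <- list(doc_id = id, title = docs$title[i],
                abstract = docs$abstract[i],
                genes = character(0), diseases = character(0),
                drugs_chemicals = character(0), cell_lines = character(0),
                event_types = character(0))
    ms <- mentions[[id]]
    if (!is.null(ms) && nrow(ms) > 0L) {
      for (k in seq_len(nrow(ms))) {
        f <- class_field[[ms$entity_class[k]]]
        rec[[f]] <- union(rec[[f]], ms$canonical[k])
      }
    }
    if (!is.null(event_labels[[id]]))
      rec$event_types <- unique(event_labels[[id]])
    if (grepl("^[0-9]+$", id))
      rec$url <- paste0("https://pubmed.ncbi.nlm.nih.gov/", id, "/")
    rec
  })
}

#' Build a faceted inverted index
#'
#' Tokenizes title+abstract (lowercase; internal hyphens kept) into an
#' inverted index with term frequencies, and stores per-field facet
#' postings.  Rebuilding from the same input is deterministic.
#'
#' @param records List of indexed-document records
#'   (\code{\link{indexed_documents}} or equivalent JSONL input).
#' @return Object of class \code{facet_index}.
#' @export
build_index <- function(records) {
  ids <- vapply(records, function(r) r$doc_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  n <- length(records)
  postings <- new.env(parent = emptyenv())   # term -> named int vec (doc -> tf)
  doc_len <- setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    toks <- tokenize_text(paste(records[[i]]$title, records[[i]]$abstract))
    if (length(toks) == 0L) next
    tf <- table(toks)
    for (t in names(tf)) {
      v <- postings[[t]]
      if (is.null(v)) v <- integer(0)
      v[ids[i]] <- as.integer(tf[[t]])
      postings[[t]] <- v
    }
  }
  facets <- lapply(setNames(nm = FACET_FIELDS), function(f) {
    env <- new.env(parent = emptyenv())      # value -> doc_id vector
    for (i in seq_len(n)) {
      for (v in unique(records[[i]][[f]] %||% character(0))) {
        env[[v]] <- c(env[[v]], ids[i])
      }
    }
    env
  })
  structure(list(records = setNames(records, ids), doc_ids = ids,
                 postings = postings, facets = facets, n_docs = n),
            class = "facet_index")
}

#' @export
print.facet_index <- function(x, ...) {
  cat("<facet_index> ", x$n_docs, " documents, ",
      length(ls(x$postings)), " terms\n", sep = "")
  invisible(x)
}

# --- queries -----------------------------------------------------------------

#' Construct a query
#' @param terms Character vector of free-text terms (tokenized, lowercased).
#' @param filters Optional list of \code{c(field, value)} pairs.
#' @return Object of class \code{facet_query}.
#' @export
query <- function(terms = character(0), filters = list()) {
  terms <- unlist(lapply(terms, tokenize_text), use.names = FALSE)
  structure(list(terms = terms, filters = filters), class = "facet_query")
}

#' @export
print.facet_query <- function(x, ...) {
  cat("<query> terms: [", paste(x$terms, collapse = ", "), "]", sep = "")
  if (length(x$filters) > 0L)
    cat(" + ", paste(vapply(x$filters, function(f)
      paste0(f[1], "=", f[2]), character(1)), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Refine, widen or reset a query
#'
#' \code{refine} appends a facet filter (idempotent on duplicates);
#' \code{unrefine} removes one (no-op with a warning if absent);
#' \code{clear_filters} drops all filters but keeps the text terms.  All
#' three are pure: they return a new query.
#'
#' @param q \code{facet_query}.
#' @param field Facet field name.
#' @param value Facet value.
#' @return New \code{facet_query}.
#' @export
refine <- function(q, field, value) {
  field <- match.arg(field, FACET_FIELDS)
  for (f in q$filters)
    if (identical(f[1], field) && identical(f[2], value)) return(q)
  q$filters <- c(q$filters, list(c(field, value)))
  q
}

#' @rdname refine
#' @export
unrefine <- function(q, field, value) {
  keep <- vapply(q$filters, function(f)
    !(identical(f[1], field) && identical(f[2], value)), logical(1))
  if (all(keep)) {
    warning("filter not present: ", field, "=", value)
    return(q)
  }
  q$filters <- q$filters[keep]
  q
}

#' @rdname refine
#' @export
clear_filters <- function(q) {
  q$filters <- list()
  q
}

# --- search ------------------------------------------------------------------

#' Search the faceted index
#'
#' Candidate set: documents containing ALL query terms (AND semantics) and
#' satisfying ALL facet filters (conjunctive).  Ranking: TF-IDF cosine
#' similarity between the query and title+abstract, ties broken by doc_id.
#' Facet counts are computed over the complete candidate set.  An empty
#' query with no filters returns the whole collection (browsing mode).
#'
#' @param index \code{facet_index}.
#' @param q \code{facet_query} (or a plain string, tokenized as terms).
#' @return Object of class \code{result_set}: \code{total}, \code{doc_ids}
#'   (ranked), \code{scores}, \code{facet_counts}.
#' @export
search_index <- function(index, q) {
  if (is.character(q)) q <- query(q)
  cand <- index$doc_ids
  for (t in unique(q$terms)) {
    v <- index$postings[[t]]
    cand <- intersect(cand, names(v))
    if (length(cand) == 0L) break
  }
  if (length(cand) > 0L) for (f in q$filters) {
    hits <- index$facets[[f[1]]][[f[2]]]
    cand <- intersect(cand, hits %||% character(0))
    if (length(cand) == 0L) break
  }
  # rank by TF-IDF cosine; with no terms the score is 0 and order is doc_id
  scores <- setNames(numeric(length(cand)), cand)
  if (length(cand) > 0L && length(q$terms) > 0L) {
    N <- index$n_docs
    for (t in unique(q$terms)) {
      v <- index$postings[[t]]
      idf <- log(N / length(v))
      scores[cand] <- scores[cand] + as.numeric(v[cand]) * idf^2
    }
    norms <- vapply(cand, function(id) doc_norm(index, id), numeric(1))
    qnorm_ <- sqrt(sum(vapply(unique(q$terms), function(t)
      log(N / length(index$postings[[t]]))^2, numeric(1))))
    nz <- norms > 0 & qnorm_ > 0
    scores[nz] <- scores[nz] / (norms[nz] * qnorm_)
  }
  ord <- if (length(scores) == 0L) integer(0) else
    order(-scores, names(scores))
  ranked <- names(scores)[ord] %||% character(0)
  structure(list(total = length(cand),
                 doc_ids = ranked,
                 scores = scores[ord],
                 facet_counts = facet_counts(index, cand),
                 query = q),
            class = "result_set")
}

# L2 norm of a document's tf-idf vector (over its own terms)
doc_norm <- function(index, id) {
  rec <- index$records[[id]]
  toks <- tokenize_text(paste(rec$title, rec$abstract))
  if (length(toks) == 0L) return(0)
  tf <- table(toks)
  idf <- vapply(names(tf), function(t)
    log(index$n_docs / length(index$postings[[t]])), numeric(1))
  sqrt(sum((as.numeric(tf) * idf)^2))
}

# per-field facet value counts over a candidate doc set
facet_counts <- function(index, cand) {
  lapply(setNames(nm = FACET_FIELDS), function(f) {
    counts <- integer(0)
    for (id in cand) {
      for (v in index$records[[id]][[f]] %||% character(0)) {
        counts[v] <- (if (is.na(counts[v])) 0L else counts[v]) + 1L
      }
    }
    if (length(counts) == 0L) counts else
      counts[order(-counts, names(counts))]
  })
}

#' @export
print.result_set <- function(x, ...) {
  cat("<result_set> ", x$total, " hits\n", sep = "")
  for (id in head(x$doc_ids, 5L)) cat("  ", id, "\n", sep = "")
  invisible(x)
}

#' Tag cloud over a facet field of a result set
#'
#' Top-k values by result-set count (descending, ties lexicographic);
#' weights are counts normalised by the maximum count in the list, so the
#' top value has weight 1 (rendered largest).
#'
#' @param result \code{result_set}.
#' @param field Facet field.
#' @param k Number of values (k <= 0 yields an empty cloud).
#' @return data.frame with columns value, count, weight.
#' @export
tag_cloud <- function(result, field, k) {
  field <- match.arg(field, FACET_FIELDS)
  empty <- data.frame(value = character(0), count = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (k <= 0) return(empty)
  counts <- result$facet_counts[[field]]
  if (length(counts) == 0L) return(empty)
  top <- head(counts, k)
  data.frame(value = names(top), count = as.integer(top),
             weight = as.numeric(top) / max(top),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Prefix autocomplete over the index vocabulary
#'
#' Matches indexed text terms and facet values starting with the lowercased
#' prefix, ordered by collection frequency (documents containing the term)
#' descending, then lexicographically.
#'
#' @param index \code{facet_index}.
#' @param prefix Non-empty prefix string.
#' @param k Maximum number of suggestions.
#' @return Character vector of up to k terms.
#' @export
autocomplete <- function(index, prefix, k = 10L) {
  stopifnot(nzchar(prefix))
  prefix <- tolower(prefix)
  terms <- ls(index$postings)
  freq <- setNames(vapply(terms, function(t)
    length(index$postings[[t]]), integer(1)), terms)
  for (f in FACET_FIELDS) {
    for (v in ls(index$facets[[f]])) {
      lv <- tolower(v)
      n <- length(index$facets[[f]][[v]])
      freq[lv] <- max(freq[lv], n, na.rm = TRUE)
    }
  }
  hits <- freq[startsWith(names(freq), prefix)]
  if (length(hits) == 0L) return(character(0))
  hits <- hits[order(-hits, names(hits))]
  head(names(hits), k)
}

# --- persistence -------------------------------------------------------------

#' Persist / load a faceted index as JSON
#'
#' On-disk layout: a directory with \code{header.json} (document count and
#' ids) and \code{records.jsonl} (the indexed documents); the index
#' structures are rebuilt deterministically on load.
#'
#' @param index \code{facet_index}.
#' @param dir Directory path.
#' @return \code{read_index}: a rebuilt \code{facet_index}.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(n_docs = index$n_docs, doc_ids = index$doc_ids),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  write_jsonl(unname(index$records), file.path(dir, "records.jsonl"))
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  recs <- read_jsonl(file.path(dir, "records.jsonl"))
  recs <- lapply(recs, function(r) {
    for (f in FACET_FIELDS) r[[f]] <- as.character(unlist(r[[f]]))
    r
  })
  build_index(recs)
}
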