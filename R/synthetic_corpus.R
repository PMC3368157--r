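# Deterministic generator of annotated synthetic abstracts: planted entity
# mentions, per-class trigger words, gold event labels and spans, emitted in
# the exact input formats of the other modules.

#' Synthetic corpus configuration
#'
#' @param n_docs Number of abstracts.
#' @param sentences_per_doc Integer range (min, max) of sentences per
#'   abstract.
#' @param background_vocab Size of the background vocabulary.
#' @param triggers_per_class Trigger words per event class.
#' @param disjoint_triggers If TRUE (default) every event class draws from
#'   its own trigger vocabulary, guaranteeing each class at least one token
#'   unique to it (separability).
#' @param lexicon_sizes Named integer vector: entity lexicon sizes for
#'   gene, chemical and disease.
#' @param mention_rate Expected entity mentions per sentence.
#' @param event_probs Probabilities of a sentence carrying 0, 1 or 2 event
#'   classes.
#' @param class_weights Sampling weights over \code{\link{EVENT_TYPES}};
#'   defaults to the 9-class test-instance imbalance
#'   (38, 17, 200, 39, 60, 153, 90, 220, 125).
#' @param label_noise Probability that a gold label is replaced by a random
#'   other class (the trigger word stays).
#' @param splits Optional named integer vector (train/dev/test document
#'   counts summing to \code{n_docs}).
#' @param seed RNG seed; fully determines the corpus.
#' @return List of class \code{corpus_config}.
#' @export
corpus_config <- function(n_docs = 20L,
                          sentences_per_doc = c(6L, 10L),
                          background_vocab = 60L,
                          triggers_per_class = 3L,
                          disjoint_triggers = TRUE,
                          lexicon_sizes = c(gene = 20L, chemical = 12L,
                                            disease = 12L),
                          mention_rate = 0.8,
                          event_probs = c(0.2, 0.6, 0.2),
                          class_weights = c(38, 17, 200, 39, 60, 153, 90,
                                            220, 125),
                          label_noise = 0,
                          splits = NULL,
                          seed = 17L) {
  stopifnot(n_docs >= 1L, length(sentences_per_doc) == 2L,
            sentences_per_doc[1] <= sentences_per_doc[2],
            length(event_probs) == 3L, abs(sum(event_probs) - 1) < 1e-9,
            length(class_weights) == length(EVENT_TYPES),
            label_noise >= 0, label_noise <= 1)
  if (!is.null(splits) && sum(splits) != n_docs)
    stop("splits must sum to n_docs")
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 background_vocab = as.integer(background_vocab),
                 triggers_per_class = as.integer(triggers_per_class),
                 disjoint_triggers = disjoint_triggers,
                 lexicon_sizes = lexicon_sizes,
                 mention_rate = mention_rate,
                 event_probs = event_probs,
                 class_weights = class_weights,
                 label_noise = label_noise,
                 splits = splits,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Named corpus-scale presets
#'
#' \code{"genia-like-small"}: 80 train / 15 dev / 26 test abstracts at
#' roughly 9.4 sentences per abstract, with the 9-class imbalance of the
#' shared-task test set (Positive_regulation most frequent) — a 1/10-scale
#' stand-in for the 800/150/260-abstract event corpus.
#'
#' @param name Preset name.
#' @param seed RNG seed.
#' @return \code{corpus_config}.
#' @export
scale_preset <- function(name, seed = 17L) {
  presets <- c("genia-like-small")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  corpus_config(
    n_docs = 121L,
    sentences_per_doc = c(8L, 11L),
    background_vocab = 60L,
    triggers_per_class = 3L,
    disjoint_triggers = TRUE,
    lexicon_sizes = c(gene = 25L, chemical = 12L, disease = 12L),
    mention_rate = 0.8,
    label_noise = 0,
    splits = c(train = 80L, dev = 15L, test = 26L),
    seed = seed)
}

# run expr under a locally-seeded RNG, restoring global RNG state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# class-tagged trigger vocabulary, unique per class in disjoint mode
make_trigger_vocab <- function(cfg) {
  if (cfg$disjoint_triggers) {
    lapply(setNames(nm = EVENT_TYPES), function(ty)
      paste0(gsub("_", "", tolower(ty)), "x", seq_len(cfg$triggers_per_class)))
  } else {
    pool <- paste0("trigshared", seq_len(max(cfg$triggers_per_class * 3L,
                                             cfg$triggers_per_class)))
    lapply(setNames(nm = EVENT_TYPES), function(ty)
      sample(pool, cfg$triggers_per_class))
  }
}

make_entity_lexicons <- function(cfg) {
  sizes <- cfg$lexicon_sizes
  mk <- function(class, prefix, canon_prefix) {
    n <- sizes[[class]]
    surf <- paste0(prefix, sprintf("%03d", seq_len(n)))
    # a quarter of gene surfaces are two-token phrases, exercising n-gram
    # matching
    if (class == "gene" && n >= 4L) {
      two <- seq_len(n %/% 4L)
      surf[two] <- paste(surf[two], "complex")
    }
    lexicon(setNames(paste0(canon_prefix, seq_len(n)), surf), class)
  }
  list(gene = mk("gene", "genp", "GENE:"),
       chemical = mk("chemical", "chemp", "CHEM:"),
       disease = mk("disease", "disp", "DIS:"))
}

#' Generate a synthetic annotated corpus
#'
#' Each sentence gets 0-2 event classes (per \code{event_probs}, classes
#' drawn by \code{class_weights}); for each assigned class one trigger word
#' from that class's vocabulary is planted at a recorded token position.
#' Entity surfaces from the generated lexicons are planted at recorded
#' character offsets.  The same seed always yields a byte-identical corpus.
#'
#' @param cfg \code{\link{corpus_config}}.
#' @return List of class \code{synthetic_corpus} with elements
#'   \code{documents} (data.frame, incl. split), \code{sentences},
#'   \code{lexicons}, \code{trigger_vocab}, \code{labeled}
#'   (labelled-sentence records), \code{bio} (token/label sequences),
#'   \code{entity_gold} (data.frame of planted mentions) and \code{config}.
#' @export
generate_corpus <- function(cfg = corpus_config()) {
  stopifnot(inherits(cfg, "corpus_config"))
  if (cfg$background_vocab < 20L)
    stop("infeasible config: background vocabulary too small")
  with_local_seed(cfg$seed, {
    background <- paste0("bkg", sprintf("%04d", seq_len(cfg$background_vocab)))
    trig_vocab <- make_trigger_vocab(cfg)
    lexicons <- make_entity_lexicons(cfg)
    splits <- if (is.null(cfg$splits)) c(all = cfg$n_docs) else cfg$splits
    split_of <- rep(names(splits), splits)

    docs <- list(); sents <- list(); labeled <- list(); bio <- list()
    egold <- list()
    for (d in seq_len(cfg$n_docs)) {
      doc_id <- sprintf("S%04d", d)
      n_sent <- sample(seq(cfg$sentences_per_doc[1],
                           cfg$sentences_per_doc[2]), 1L)
      sent_texts <- character(n_sent)
      char_pos <- 0L
      for (s in seq_len(n_sent)) {
        n_bkg <- sample(6:10, 1L)
        tokens <- c("The", sample(background, n_bkg, replace = TRUE))

        # events
        n_ev <- sample(0:2, 1L, prob = cfg$event_probs)
        classes <- if (n_ev > 0L)
          sample(EVENT_TYPES, n_ev, prob = cfg$class_weights) else character(0)
        triggers <- list()
        for (ty in classes) {
          w <- sample(trig_vocab[[ty]], 1L)
          pos <- sample(seq(2L, length(tokens) + 1L), 1L)
          tokens <- append(tokens, w, after = pos - 1L)
          # shift previously planted trigger positions at/after pos
          triggers <- lapply(triggers, function(t) {
            if (t$pos >= pos) t$pos <- t$pos + 1L
            t
          })
          triggers[[length(triggers) + 1L]] <- list(word = w, type = ty,
                                                    pos = pos)
        }

        # entities; never insert strictly inside an earlier multi-token span
        n_ent <- min(2L, stats::rpois(1L, cfg$mention_rate))
        entities <- list()
        for (k in seq_len(n_ent)) {
          cls <- sample(names(lexicons), 1L)
          entry <- sample(seq_along(lexicons[[cls]]$entries), 1L)
          surf <- names(lexicons[[cls]]$entries)[entry]
          canon <- unname(lexicons[[cls]]$entries[[entry]])
          surf_toks <- strsplit(surf, " ", fixed = TRUE)[[1]]
          inside <- unlist(lapply(entities, function(e)
            if (e$n_tok > 1L) seq(e$pos + 1L, e$pos + e$n_tok - 1L)
            else integer(0)))
          allowed_pos <- setdiff(seq(2L, length(tokens) + 1L), inside)
          pos <- allowed_pos[sample.int(length(allowed_pos), 1L)]
          tokens <- append(tokens, surf_toks, after = pos - 1L)
          w <- length(surf_toks)
          triggers <- lapply(triggers, function(t) {
            if (t$pos >= pos) t$pos <- t$pos + w
            t
          })
          entities <- lapply(entities, function(e) {
            if (e$pos >= pos) e$pos <- e$pos + w
            e
          })
          entities[[length(entities) + 1L]] <- list(
            class = cls, surface = surf, canonical = canon, pos = pos,
            n_tok = w)
        }

        # label noise: flip the recorded label, keep the trigger token
        labels <- vapply(triggers, function(t) t$type, character(1))
        if (cfg$label_noise > 0 && length(labels) > 0L) {
          flip <- stats::runif(length(labels)) < cfg$label_noise
          labels[flip] <- vapply(which(flip), function(i)
            sample(setdiff(EVENT_TYPES, labels[i]), 1L), character(1))
        }

        text <- paste(tokens, collapse = " ")
        text <- paste0(text, ".")
        sent_texts[s] <- text

        # token-position starts (0-based chars within the sentence)
        tok_start <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]

        sid <- paste0(doc_id, ":", s - 1L)
        trig_df <- lapply(triggers, function(t) list(
          word = t$word, type = t$type,
          token_start = t$pos - 1L, token_end = t$pos))
        gene_spans <- list()
        for (e in entities) {
          st <- tok_start[e$pos]
          en <- st + nchar(e$surface)
          egold[[length(egold) + 1L]] <- data.frame(
            doc_id = doc_id, sentence_index = s - 1L,
            char_start = st, char_end = en, entity_class = e$class,
            surface = e$surface, canonical = e$canonical,
            stringsAsFactors = FALSE)
          if (e$class == "gene")
            gene_spans[[length(gene_spans) + 1L]] <- c(st, en)
        }
        if (length(labels) > 0L) {
          labeled[[length(labeled) + 1L]] <- list(
            id = sid, doc_id = doc_id, sentence_index = s - 1L,
            text = text, labels = as.character(labels),
            triggers = trig_df, genes = gene_spans,
            split = split_of[d])
        }
        span_df <- if (length(triggers) == 0L)
          data.frame(start_token = integer(0), end_token = integer(0),
                     type = character(0)) else
          do.call(rbind, lapply(triggers, function(t) data.frame(
            start_token = t$pos - 1L, end_token = t$pos,
            type = t$type, stringsAsFactors = FALSE)))
        bio[[length(bio) + 1L]] <- list(
          id = sid, tokens = tokens,
          labels = encode_spans(length(tokens), span_df),
          split = split_of[d])

        sents[[length(sents) + 1L]] <- data.frame(
          doc_id = doc_id, index = s - 1L, text = text,
          char_start = char_pos, char_end = char_pos + nchar(text),
          split = split_of[d], stringsAsFactors = FALSE)
        char_pos <- char_pos + nchar(text) + 1L   # " " separator
      }
      abstract <- paste(sent_texts, collapse = " ")
      title <- paste("Synthetic abstract", d, "on",
                     sample(background, 1L))
      docs[[d]] <- data.frame(doc_id = doc_id, title = title,
                              abstract = abstract,
                              source_uri = NA_character_,
                              split = split_of[d], stringsAsFactors = FALSE)
    }
    structure(list(
      config = cfg,
      documents = do.call(rbind, docs),
      sentences = do.call(rbind, sents),
      lexicons = lexicons,
      trigger_vocab = trig_vocab,
      labeled = labeled,
      bio = bio,
      entity_gold = if (length(egold) > 0L) do.call(rbind, egold) else
        data.frame(doc_id = character(0), sentence_index = integer(0),
                   char_start = integer(0), char_end = integer(0),
                   entity_class = character(0), surface = character(0),
                   canonical = character(0), stringsAsFactors = FALSE)),
      class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$documents), " docs, ",
      nrow(x$sentences), " sentences, ", length(x$labeled),
      " labelled\n", sep = "")
  invisible(x)
}

#' Subset a corpus's labelled/BIO records by split
#' @param corpus \code{synthetic_corpus}.
#' @param split One of the configured split names.
#' @return List with \code{labeled} and \code{bio} of that split.
#' @export
corpus_split <- function(corpus, split) {
  list(
    labeled = Filter(function(r) r$split == split, corpus$labeled),
    bio = Filter(function(r) r$split == split, corpus$bio))
}

#' Write a synthetic corpus in every module's input format
#'
#' Emits fixture Medline-dialect XML (\code{abstracts.xml}), lexicon TSVs
#' (\code{lexicon_<class>.tsv}), labelled-sentence JSONL
#' (\code{labeled.jsonl}), BIO sequence JSONL (\code{bio.jsonl}) and an
#' annotated-document JSONL (\code{indexed.jsonl}).
#'
#' @param corpus \code{synthetic_corpus}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_corpus_files <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # Medline-style XML
  root <- xml2::xml_new_root("MedlineCitationSet")
  for (i in seq_len(nrow(corpus$documents))) {
    cite <- xml2::xml_add_child(root, "MedlineCitation")
    xml2::xml_add_child(cite, "PMID", corpus$documents$doc_id[i])
    art <- xml2::xml_add_child(cite, "Article")
    xml2::xml_add_child(art, "ArticleTitle", corpus$documents$title[i])
    ab <- xml2::xml_add_child(art, "Abstract")
    xml2::xml_add_child(ab, "AbstractText", corpus$documents$abstract[i])
  }
  xml2::write_xml(root, file.path(dir, "abstracts.xml"))
  # lexicon TSVs
  for (cls in names(corpus$lexicons)) {
    lex <- corpus$lexicons[[cls]]
    writeLines(paste(names(lex$entries), unname(lex$entries), sep = "\t"),
               file.path(dir, paste0("lexicon_", cls, ".tsv")))
  }
  # labelled sentences + BIO sequences
  write_jsonl(lapply(corpus$labeled, function(r)
    r[c("id", "text", "labels", "triggers", "genes")]),
    file.path(dir, "labeled.jsonl"))
  write_jsonl(lapply(corpus$bio, function(r) r[c("id", "tokens", "labels")]),
              file.path(dir, "bio.jsonl"))
  # annotated documents in the shared schema (from the gold annotations)
  mentions <- split(corpus$entity_gold, corpus$entity_gold$doc_id)
  labels_by_doc <- list()
  for (r in corpus$labeled)
    labels_by_doc[[r$doc_id]] <- c(labels_by_doc[[r$doc_id]], r$labels)
  recs <- indexed_documents(corpus$documents, mentions, labels_by_doc)
  write_jsonl(recs, file.path(dir, "indexed.jsonl"))
  invisible(dir)
}
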