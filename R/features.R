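# Sparse binary feature extraction from configurable templates.
#
# Every feature is namespaced by template and relative offset, e.g.
# `w[-1]=pain`, `ortho[0]=ALLCAPS`, `brown[0]=1111`, `th[0]=quelene@top5`.
# Out-of-range window positions emit boundary placeholders (<BOS>/<EOS>);
# no template reads across a sentence boundary.

#' Feature extraction configuration
#'
#' @param window Context half-width for word/POS features (tokens on each
#'   side; >= 0). Default 2.
#' @param templates Enabled template names, a subset of
#'   `c("word", "orthographic", "affix", "pos", "combined", "section",
#'   "lexicon", "brown", "thesaurus")`.
#' @param affix_lengths Prefix/suffix lengths for the affix template.
#' @param brown_prefix_lengths Optional integer vector capping Brown bit-path
#'   prefixes to these lengths; `NULL` keeps all prefixes.
#' @param thesaurus_k Number of nearest semantic neighbours used as features.
#' @param section_regex Regex a line-final token must match for the line to be
#'   a section header.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window = 2,
                           templates = c("word", "orthographic", "affix",
                                         "pos", "combined"),
                           affix_lengths = 2:4,
                           brown_prefix_lengths = NULL,
                           thesaurus_k = 20,
                           section_regex = ":$") {
  known <- c("word", "orthographic", "affix", "pos", "combined", "section",
             "lexicon", "brown", "thesaurus")
  bad <- setdiff(templates, known)
  if (length(bad)) abort(paste("unknown template(s):", paste(bad, collapse = ", ")))
  if (window < 0) abort("window must be >= 0")
  structure(list(window = as.integer(window), templates = templates,
                 affix_lengths = affix_lengths,
                 brown_prefix_lengths = brown_prefix_lengths,
                 thesaurus_k = thesaurus_k, section_regex = section_regex),
            class = "feature_config")
}

word_shape <- function(x) {
  s <- gsub("[A-Z]", "X", x)
  s <- gsub("[a-z]", "x", s)
  gsub("[0-9]", "d", s)
}

ortho_flags <- function(x) {
  list(
    INITCAP = grepl("^[A-Z]", x),
    ALLCAPS = grepl("^[A-Z]+$", x),
    ALLDIGITS = grepl("^[0-9]+$", x),
    HASDIGIT = grepl("[0-9]", x),
    HASHYPHEN = grepl("-", x, fixed = TRUE),
    HASSLASH = grepl("/", x, fixed = TRUE),
    PUNCT = grepl("^[[:punct:]]+$", x))
}

# Features for every position of one sentence; returns a list of character
# vectors. `section` is a single label for the sentence (or NULL).
sentence_features <- function(text, pos = NULL, config = feature_config(),
                              brown = NULL, thesaurus = NULL, section = NULL,
                              lexicons = NULL) {
  n <- length(text)
  if (n == 0) return(list())
  tm <- config$templates
  w <- config$window
  out <- rep(list(character(0)), n)
  add <- function(fs) {
    for (i in seq_len(n)) out[[i]] <<- c(out[[i]], fs[[i]])
  }
  pad <- function(v) c(rep("<BOS>", w), v, rep("<EOS>", w))
  has_pos <- !is.null(pos) && !all(is.na(pos))
  if ("word" %in% tm) {
    pt <- pad(text)
    for (d in seq(-w, w)) {
      fs <- paste0("w[", d, "]=", pt[seq_len(n) + w + d])
      add(as.list(fs))
    }
  }
  if ("pos" %in% tm && has_pos) {
    pp <- pad(ifelse(is.na(pos), "<NOPOS>", pos))
    for (d in seq(-w, w)) {
      fs <- paste0("p[", d, "]=", pp[seq_len(n) + w + d])
      add(as.list(fs))
    }
  }
  if ("orthographic" %in% tm) {
    fl <- ortho_flags(text)
    sh <- word_shape(text)
    ortho <- purrr::map(seq_len(n), function(i) {
      on <- names(fl)[vapply(fl, function(v) v[i], logical(1))]
      c(if (length(on)) paste0("ortho[0]=", on),
        paste0("shape[0]=", sh[i]))
    })
    add(ortho)
  }
  if ("affix" %in% tm) {
    aff <- purrr::map(seq_len(n), function(i) {
      tk <- text[i]
      nc <- nchar(tk)
      ls <- config$affix_lengths[config$affix_lengths <= nc]
      c(paste0("pre[0]=", substr(rep(tk, length(ls)), 1, ls)),
        paste0("suf[0]=", substring(rep(tk, length(ls)), nc - ls + 1)))
    })
    add(aff)
  }
  if ("combined" %in% tm) {
    add(purrr::map(seq_len(n), function(i) {
      combined_features(text, pos, i)
    }))
  }
  if ("section" %in% tm && !is.null(section)) {
    add(as.list(rep(paste0("section[0]=", section), n)))
  }
  if ("brown" %in% tm) {
    if (is.null(brown)) abort("brown template enabled but no hierarchy supplied")
    add(purrr::map(text, function(tk) {
      pr <- path_prefixes(tk, brown)
      if (!is.null(config$brown_prefix_lengths)) {
        pr <- truncate_prefix_set(pr, config$brown_prefix_lengths)
      }
      if (length(pr)) paste0("brown[0]=", pr) else character(0)
    }))
  }
  if ("thesaurus" %in% tm) {
    if (is.null(thesaurus)) {
      abort("thesaurus template enabled but no thesaurus supplied")
    }
    add(purrr::map(text, function(tk) {
      fs <- thesaurus_features(thesaurus, tk, k = config$thesaurus_k)
      if (length(fs)) paste0("th[0]=", fs) else character(0)
    }))
  }
  if ("lexicon" %in% tm) {
    if (is.null(lexicons)) abort("lexicon template enabled but no lexicons supplied")
    add(purrr::map(text, function(tk) {
      hits <- purrr::imap(lexicons, function(lx, nm) {
        tag <- lx$tag[match(tolower(tk), tolower(lx$term))]
        if (is.na(tag)) character(0) else paste0("lex[0]=", nm, ":", tag)
      })
      unlist(hits, use.names = FALSE)
    }))
  }
  out
}

#' Token-level feature extraction
#'
#' Extracts the feature strings of one token position; see [feature_config()]
#' for the template inventory.
#'
#' @param text Character vector of sentence tokens.
#' @param position 1-based token position.
#' @param config A [feature_config()].
#' @param pos Optional POS tags (same length as `text`).
#' @param brown,thesaurus,section,lexicons Optional resources; required when
#'   the matching template is enabled.
#' @return Character vector of feature strings.
#' @export
extract_token_features <- function(text, position, config = feature_config(),
                                   pos = NULL, brown = NULL, thesaurus = NULL,
                                   section = NULL, lexicons = NULL) {
  if (position < 1 || position > length(text)) abort("position out of range")
  sentence_features(text, pos, config, brown, thesaurus, section,
                    lexicons)[[position]]
}

#' Conjunction (combined) features
#'
#' The five fixed conjunction patterns: word+POS at the focus, word bigram
#' with the left neighbour, POS bigram with the left neighbour, and word+POS
#' of each adjacent position. Conjunctions whose positions fall outside the
#' sentence are skipped (a single-token sentence yields no bigram
#' conjunctions); POS-bearing conjunctions are skipped when no POS column is
#' present.
#'
#' @param text Sentence tokens.
#' @param pos POS tags or `NULL`.
#' @param position 1-based focus position.
#' @return Character vector of conjunction features.
#' @export
combined_features <- function(text, pos, position) {
  n <- length(text)
  i <- position
  has_pos <- !is.null(pos) && !all(is.na(pos))
  fs <- character(0)
  if (has_pos) fs <- c(fs, paste0("w|p[0]=", text[i], "|", pos[i]))
  if (i > 1) {
    fs <- c(fs, paste0("w[-1]w[0]=", text[i - 1], "|", text[i]))
    if (has_pos) {
      fs <- c(fs, paste0("p[-1]p[0]=", pos[i - 1], "|", pos[i]))
      fs <- c(fs, paste0("w[0]p[-1]=", text[i], "|", pos[i - 1]))
    }
  }
  if (i < n && has_pos) {
    fs <- c(fs, paste0("w[0]p[+1]=", text[i], "|", pos[i + 1]))
  }
  fs
}

# --- section (discourse) detection -------------------------------------------

#' Section labels per sentence
#'
#' A line whose final token matches `section_regex` (default: ends in ":") is
#' a header; its lowercased text (colon stripped) labels itself and every
#' following line until the next header. Lines before any header get "none".
#'
#' @param corpus An `ner_corpus`.
#' @param section_regex Header regex applied to the line-final token.
#' @return Tibble `doc_id`, `line`, `section` aligned with [sentence_index()].
#' @export
section_labels <- function(corpus, section_regex = ":$") {
  idx <- sentence_index(corpus)
  toks <- corpus$tokens
  sec <- character(nrow(idx))
  cur <- "none"; cur_doc <- ""
  for (i in seq_len(nrow(idx))) {
    if (idx$doc_id[i] != cur_doc) { cur <- "none"; cur_doc <- idx$doc_id[i] }
    line_toks <- toks$text[toks$doc_id == idx$doc_id[i] & toks$line == idx$line[i]]
    if (length(line_toks) && grepl(section_regex, line_toks[length(line_toks)])) {
      cur <- trimws(tolower(sub(":$", "", paste(line_toks, collapse = " "))))
    }
    sec[i] <- cur
  }
  dplyr::mutate(idx[, c("doc_id", "line")], section = sec)
}

# --- feature indexer ----------------------------------------------------------

#' Feature indexer: bijective feature-string to integer-id map
#'
#' In training mode the indexer grows as new features are seen; once frozen,
#' unseen features are dropped (test-time behaviour).
#'
#' @param features Optional character vector of features to pre-register
#'   (ids follow their order).
#' @param frozen Start frozen?
#' @return An environment of class `feature_indexer`.
#' @export
feature_indexer <- function(features = character(), frozen = FALSE) {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv(), hash = TRUE, size = 4096L)
  e$rev <- character(0)
  e$frozen <- frozen
  class(e) <- "feature_indexer"
  if (length(features)) {
    e$frozen <- FALSE
    index_features(features, e)
    e$frozen <- frozen
  }
  e
}

#' @export
print.feature_indexer <- function(x, ...) {
  cat(sprintf("<feature_indexer> %d features, frozen: %s\n",
              indexer_size(x), x$frozen))
  invisible(x)
}

#' @rdname feature_indexer
#' @param indexer A `feature_indexer`.
#' @export
indexer_size <- function(indexer) length(indexer$rev)

#' @rdname feature_indexer
#' @export
indexer_features <- function(indexer) indexer$rev

#' @rdname feature_indexer
#' @export
freeze_indexer <- function(indexer) { indexer$frozen <- TRUE; invisible(indexer) }

#' Map feature strings to integer ids
#'
#' Unseen features get fresh ids while the indexer is unfrozen; after
#' freezing they map to `NA` (and are dropped by [featurize_corpus()]).
#'
#' @param strings Character vector of feature strings.
#' @param indexer A [feature_indexer()].
#' @return Integer ids (NA for dropped features).
#' @export
index_features <- function(strings, indexer) {
  if (length(strings) == 0) return(integer(0))
  ids <- unlist(mget(strings, envir = indexer$map,
                     ifnotfound = list(NA_integer_)), use.names = FALSE)
  if (!indexer$frozen && anyNA(ids)) {
    new <- unique(strings[is.na(ids)])
    new_ids <- indexer_size(indexer) + seq_along(new)
    for (k in seq_along(new)) {
      assign(new[k], new_ids[k], envir = indexer$map)
    }
    indexer$rev <- c(indexer$rev, new)
    ids <- unlist(mget(strings, envir = indexer$map,
                       ifnotfound = list(NA_integer_)), use.names = FALSE)
  }
  ids
}

#' Vectorize a corpus into per-sentence feature-id sequences
#'
#' Training mode (no `indexer` given) grows a fresh indexer over the corpus
#' and freezes it; with a frozen indexer supplied, unseen features are
#' dropped.
#'
#' @param corpus An `ner_corpus`.
#' @param config A [feature_config()].
#' @param resources Named list: `brown`, `thesaurus`, `lexicons`.
#' @param indexer Optional frozen [feature_indexer()] (test mode).
#' @return List with `sentences` (the [sentence_index()] tibble), `feats`
#'   (list of per-sentence lists of integer id vectors) and `indexer`.
#' @export
featurize_corpus <- function(corpus, config = feature_config(),
                             resources = list(), indexer = NULL) {
  grow <- is.null(indexer)
  indexer <- indexer %||% feature_indexer()
  idx <- sentence_index(corpus)
  secs <- NULL
  if ("section" %in% config$templates) {
    secs <- section_labels(corpus, config$section_regex)
  }
  if ("pos" %in% config$templates && all(is.na(corpus$tokens$pos)) &&
      nrow(corpus$tokens) > 0) {
    warn("pos template enabled but corpus has no POS column; skipping POS features")
  }
  toks <- corpus$tokens[order(corpus$tokens$doc_id, corpus$tokens$line,
                              corpus$tokens$tok), ]
  key <- paste(toks$doc_id, toks$line)
  grp <- factor(match(key, unique(key)), levels = seq_len(nrow(idx)))
  text_by <- split(toks$text, grp)
  pos_by <- split(toks$pos, grp)
  feats <- purrr::map(seq_len(nrow(idx)), function(i) {
    fs <- sentence_features(
      text_by[[i]], pos_by[[i]], config,
      brown = resources$brown, thesaurus = resources$thesaurus,
      section = if (is.null(secs)) NULL else secs$section[i],
      lexicons = resources$lexicons)
    purrr::map(fs, function(s) {
      ids <- index_features(s, indexer)
      sort(unique(ids[!is.na(ids)]))
    })
  })
  if (grow) freeze_indexer(indexer)
  list(sentences = idx, feats = feats, indexer = indexer)
}

#' Export feature sequences as SVM-light-style sparse lines (debugging aid)
#'
#' @param fz Result of [featurize_corpus()].
#' @param labels Optional per-sentence label vectors.
#' @return Character vector, one token per line: `label id:1 id:1 ...`.
#' @export
write_sparse_lines <- function(fz, labels = NULL) {
  out <- character(0)
  for (i in seq_along(fz$feats)) {
    for (t in seq_along(fz$feats[[i]])) {
      lab <- if (is.null(labels)) "0" else labels[[i]][t]
      ids <- fz$feats[[i]][[t]]
      out <- c(out, paste(c(lab, sprintf("%d:1", ids)), collapse = " "))
    }
  }
  out
}
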