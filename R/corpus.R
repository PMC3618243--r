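# Corpus container and i2b2-dialect readers/writers.
#
# Coordinate system: lines are 1-based, tokens within a line 0-based, spans
# inclusive on both ends — the `L:T` notation of the 2010 i2b2 concept files.

#' Construct an annotated corpus
#'
#' An `ner_corpus` bundles whitespace-tokenized documents with typed entity
#' spans in line:token coordinates. Tokens live in a tibble with one row per
#' token; spans in a tibble with one row per entity. Blank lines are retained
#' through the per-document line count so that text round-trips byte-exactly.
#'
#' @param tokens Tibble with columns `doc_id`, `line` (1-based), `tok`
#'   (0-based), `text`, and optionally `pos` (part-of-speech, supplied as
#'   input, never computed here).
#' @param spans Tibble with columns `doc_id`, `start_line`, `start_tok`,
#'   `end_line`, `end_tok`, `type`, `text`. May be empty.
#' @param n_lines Optional tibble `doc_id`, `n_lines` giving the number of
#'   text lines per document (needed to preserve trailing/blank lines);
#'   defaults to the maximum line index seen among tokens.
#' @param entity_types Character vector of admissible entity types.
#'
#' @return An object of class `ner_corpus`: a list with elements `tokens`,
#'   `spans`, `n_lines`, `entity_types`.
#' @export
ner_corpus <- function(tokens = empty_tokens(), spans = empty_spans(),
                       n_lines = NULL,
                       entity_types = c("problem", "treatment", "test")) {
  tokens <- tibble::as_tibble(tokens)
  spans <- tibble::as_tibble(spans)
  if (!"pos" %in% names(tokens)) tokens$pos <- NA_character_
  need_tok <- c("doc_id", "line", "tok", "text")
  if (!all(need_tok %in% names(tokens))) {
    abort(paste("tokens must have columns", paste(need_tok, collapse = ", ")))
  }
  need_sp <- c("doc_id", "start_line", "start_tok", "end_line", "end_tok",
               "type", "text")
  if (!all(need_sp %in% names(spans))) {
    abort(paste("spans must have columns", paste(need_sp, collapse = ", ")))
  }
  if (nrow(tokens) > 0) {
    if (any(!nzchar(tokens$text))) abort("token text must be non-empty")
    key <- paste(tokens$doc_id, tokens$line, tokens$tok)
    if (anyDuplicated(key)) abort("(doc_id, line, tok) must be unique")
  }
  if (is.null(n_lines)) {
    n_lines <- if (nrow(tokens) == 0) {
      tibble::tibble(doc_id = character(), n_lines = integer())
    } else {
      tokens |>
        dplyr::group_by(.data$doc_id) |>
        dplyr::summarise(n_lines = max(.data$line), .groups = "drop")
    }
  }
  x <- structure(
    list(tokens = tokens, spans = spans,
         n_lines = tibble::as_tibble(n_lines), entity_types = entity_types),
    class = "ner_corpus"
  )
  validate_corpus(x)
  x
}

empty_tokens <- function() {
  tibble::tibble(doc_id = character(), line = integer(), tok = integer(),
                 text = character(), pos = character())
}

empty_spans <- function() {
  tibble::tibble(doc_id = character(), start_line = integer(),
                 start_tok = integer(), end_line = integer(),
                 end_tok = integer(), type = character(), text = character())
}

#' @export
print.ner_corpus <- function(x, ...) {
  cat(sprintf(
    "<ner_corpus> %d document(s), %d sentence(s), %d token(s), %d span(s)\n",
    dplyr::n_distinct(x$tokens$doc_id), n_sentences(x),
    nrow(x$tokens), nrow(x$spans)))
  invisible(x)
}

n_sentences <- function(corpus) {
  nrow(dplyr::distinct(corpus$tokens, .data$doc_id, .data$line))
}

validate_corpus <- function(x) {
  sp <- x$spans
  if (nrow(sp) == 0) return(invisible(x))
  bad_type <- setdiff(unique(sp$type), x$entity_types)
  if (length(bad_type)) {
    abort(paste("unknown entity type(s):", paste(bad_type, collapse = ", ")))
  }
  cov <- span_coverage(x)
  # every span resolves to a contiguous run of existing tokens
  for (i in seq_len(nrow(sp))) {
    ids <- cov[[i]]
    if (anyNA(ids) || length(ids) == 0) {
      abort(sprintf("span %d (%s %d:%d %d:%d) does not resolve to tokens",
                    i, sp$doc_id[i], sp$start_line[i], sp$start_tok[i],
                    sp$end_line[i], sp$end_tok[i]))
    }
  }
  all_ids <- unlist(cov)
  if (anyDuplicated(all_ids)) {
    abort("overlapping entity spans are not representable; rejecting corpus")
  }
  invisible(x)
}

# For each span, the row indices of corpus$tokens it covers (document order).
span_coverage <- function(corpus) {
  toks <- corpus$tokens
  sp <- corpus$spans
  if (nrow(sp) == 0) return(list())
  ord <- order(toks$doc_id, toks$line, toks$tok)
  purrr::map(seq_len(nrow(sp)), function(i) {
    rows <- ord[toks$doc_id[ord] == sp$doc_id[i]]
    lt <- toks$line[rows] * 1e6 + toks$tok[rows]
    a <- sp$start_line[i] * 1e6 + sp$start_tok[i]
    b <- sp$end_line[i] * 1e6 + sp$end_tok[i]
    if (a > b) abort(sprintf("span %d start after end", i))
    start_at <- match(a, lt)
    end_at <- match(b, lt)
    if (is.na(start_at) || is.na(end_at)) return(NA_integer_)
    rows[seq(start_at, end_at)]
  })
}

as_input_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x)) {
    bad <- !validUTF8(x)
    if (any(bad)) {
      abort(sprintf("undecodable bytes at input element %d", which(bad)[1]))
    }
  }
  if (is.character(x) && length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    raw <- readBin(x, what = "raw", n = file.size(x))
    txt <- rawToChar(raw)
    Encoding(txt) <- "UTF-8"
    if (!validUTF8(txt)) {
      abort(sprintf("undecodable bytes in %s", x))
    }
    if (identical(txt, "")) return(character())
    return(strsplit(txt, "\n", fixed = TRUE)[[1]])
  }
  if (!is.character(x)) abort("expected a path, connection or character vector")
  if (length(x) == 1 && grepl("\n", x)) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  if (length(x) == 1 && identical(x, "")) return(character())
  x
}

#' Read a tokenized clinical note
#'
#' Reads UTF-8 text in the i2b2 dialect: one sentence per line, tokens
#' separated by whitespace. No spans are attached.
#'
#' @param x Path, connection, or character vector of lines (a single string
#'   containing newlines is split).
#' @param doc_id Document identifier stored on every token.
#' @param entity_types Passed through to [ner_corpus()].
#' @return An `ner_corpus` with empty spans. Empty input yields a corpus with
#'   zero sentences.
#' @export
read_note_text <- function(x, doc_id = "doc",
                           entity_types = c("problem", "treatment", "test")) {
  lines <- as_input_lines(x)
  toks <- tokens_from_lines(lines, doc_id)
  ner_corpus(
    tokens = toks,
    n_lines = tibble::tibble(doc_id = doc_id, n_lines = length(lines)),
    entity_types = entity_types
  )
}

tokens_from_lines <- function(lines, doc_id) {
  if (length(lines) == 0) return(empty_tokens())
  parts <- strsplit(lines, "[ \t]+")
  parts <- purrr::map(parts, function(p) p[nzchar(p)])
  n <- lengths(parts)
  tibble::tibble(
    doc_id = rep(doc_id, sum(n)),
    line = rep(seq_along(lines), n),
    tok = unlist(purrr::map(n, function(k) seq_len(k) - 1L), use.names = FALSE) %||% integer(),
    text = unlist(parts, use.names = FALSE) %||% character(),
    pos = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus document back to text lines
#'
#' Inverse of [read_note_text()]: one sentence per line, single spaces between
#' tokens, blank lines preserved through the stored line count.
#'
#' @param corpus An `ner_corpus`.
#' @param doc_id Which document to render; default the first.
#' @return Character vector of lines.
#' @export
write_note_text <- function(corpus, doc_id = NULL) {
  doc_id <- doc_id %||% corpus$n_lines$doc_id[1]
  nl <- corpus$n_lines$n_lines[match(doc_id, corpus$n_lines$doc_id)]
  if (is.na(nl)) nl <- 0L
  if (nl == 0) return(character())
  toks <- dplyr::filter(corpus$tokens, .data$doc_id == .env$doc_id)
  out <- character(nl)
  if (nrow(toks) > 0) {
    by_line <- split(toks[order(toks$tok), ], toks$line[order(toks$tok)])
    for (ln in names(by_line)) {
      out[as.integer(ln)] <- paste(by_line[[ln]]$text, collapse = " ")
    }
  }
  out
}

concept_line_re <- paste0(
  "^c=\"(.*)\"\\s+(\\d+):(\\d+)\\s+(\\d+):(\\d+)\\|\\|t=\"([^\"]+)\"\\s*$")

#' Read an i2b2-style concept annotation file
#'
#' Each line has the form `c="<text>" L:T L:T||t="<type>"` with 1-based lines
#' and 0-based inclusive token offsets. Spans are resolved against `corpus`;
#' a case difference between the annotated surface text and the document
#' tokens is a warning (annotation files in the wild disagree on case), a
#' non-resolving coordinate is an error.
#'
#' @param x Path, connection or character vector of annotation lines.
#' @param corpus The `ner_corpus` holding the document the annotations refer to.
#' @param doc_id Document the annotations belong to; default the corpus' first.
#' @return The corpus with the parsed spans attached (replacing any existing
#'   spans for that document).
#' @export
read_concepts <- function(x, corpus, doc_id = NULL) {
  lines <- as_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  doc_id <- doc_id %||% corpus$n_lines$doc_id[1]
  if (length(lines) == 0) {
    sp <- empty_spans()
  } else {
    m <- regmatches(lines, regexec(concept_line_re, lines))
    bad <- which(lengths(m) == 0)
    if (length(bad)) {
      abort(sprintf("malformed concept line %d: %s", bad[1], lines[bad[1]]))
    }
    sp <- tibble::tibble(
      doc_id = doc_id,
      start_line = as.integer(purrr::map_chr(m, 3)),
      start_tok = as.integer(purrr::map_chr(m, 4)),
      end_line = as.integer(purrr::map_chr(m, 5)),
      end_tok = as.integer(purrr::map_chr(m, 6)),
      type = purrr::map_chr(m, 7),
      text = purrr::map_chr(m, 2)
    )
  }
  out <- corpus
  out$spans <- dplyr::bind_rows(
    dplyr::filter(corpus$spans, .data$doc_id != .env$doc_id), sp)
  out <- ner_corpus(out$tokens, out$spans, out$n_lines, out$entity_types)
  check_surface_case(out, doc_id)
  out
}

check_surface_case <- function(corpus, doc_id) {
  sp <- dplyr::filter(corpus$spans, .data$doc_id == .env$doc_id)
  if (nrow(sp) == 0) return(invisible())
  actual <- span_surface_text(corpus)
  keep <- corpus$spans$doc_id == doc_id
  mism <- tolower(sp$text) != tolower(actual[keep])
  if (any(mism)) {
    warn(sprintf("surface text mismatch for %d span(s), e.g. %s vs %s",
                 sum(mism), sp$text[mism][1], actual[keep][mism][1]))
  }
  invisible()
}

# Surface text of each span as it appears in the document.
span_surface_text <- function(corpus) {
  cov <- span_coverage(corpus)
  toks <- corpus$tokens
  purrr::map_chr(cov, function(rows) paste(toks$text[rows], collapse = " "))
}

#' Write spans as i2b2-style concept lines
#'
#' One line per span in document order; surface text is lowercased on write
#' (the i2b2 convention) and re-derived from the document tokens.
#'
#' @param corpus An `ner_corpus`.
#' @param doc_id Document whose spans to write; `NULL` means all documents.
#' @return Character vector of concept lines (empty when no spans).
#' @export
write_concepts <- function(corpus, doc_id = NULL) {
  sp <- corpus$spans
  if (!is.null(doc_id)) {
    keep <- sp$doc_id == doc_id
  } else {
    keep <- rep(TRUE, nrow(sp))
  }
  if (!any(keep)) return(character())
  surf <- tolower(span_surface_text(corpus))[keep]
  sp <- sp[keep, ]
  ord <- order(sp$doc_id, sp$start_line, sp$start_tok)
  sp <- sp[ord, ]
  surf <- surf[ord]
  sprintf("c=\"%s\" %d:%d %d:%d||t=\"%s\"",
          surf, sp$start_line, sp$start_tok, sp$end_line, sp$end_tok, sp$type)
}

#' Read a CoNLL-style token-per-line file
#'
#' Columns are TOKEN, optionally POS, optionally LABEL; blank lines separate
#' sentences. The column count must be constant within a file.
#'
#' @param x Path, connection or character vector.
#' @param doc_id Document id to assign.
#' @param columns Character vector naming the columns, e.g. `c("text")`,
#'   `c("text", "pos")` or `c("text", "pos", "label")`; `NULL` guesses from
#'   the column count (1 = text, 2 = text+pos, 3 = text+pos+label).
#' @param sep Field separator regex (default splits on tabs or spaces).
#' @param entity_types Passed to [ner_corpus()].
#' @return A list with elements `corpus` (an `ner_corpus`, one sentence per
#'   CoNLL sentence) and `labels` (list of per-sentence label character
#'   vectors, `NULL` when no label column).
#' @export
read_conll <- function(x, doc_id = "doc", columns = NULL, sep = "[ \t]+",
                       entity_types = c("problem", "treatment", "test")) {
  lines <- as_input_lines(x)
  if (length(lines) == 0) {
    return(list(corpus = ner_corpus(entity_types = entity_types), labels = NULL))
  }
  blank <- !nzchar(trimws(lines))
  sent_id <- cumsum(c(TRUE, blank[-length(blank)])) # sentence index per line
  rows <- which(!blank)
  fields <- strsplit(trimws(lines[rows]), sep)
  ncol <- lengths(fields)
  if (length(unique(ncol)) > 1) {
    abort(sprintf("ragged CoNLL row at line %d: %d fields, expected %d",
                  rows[which(ncol != ncol[1])[1]],
                  ncol[which(ncol != ncol[1])[1]], ncol[1]))
  }
  k <- ncol[1]
  if (is.null(columns)) {
    columns <- switch(as.character(k),
      "1" = "text", "2" = c("text", "pos"), "3" = c("text", "pos", "label"),
      abort(sprintf("cannot guess column layout with %d columns", k)))
  }
  if (length(columns) != k) abort("columns does not match file column count")
  sent <- sent_id[rows]
  sent <- match(sent, unique(sent)) # renumber 1..S over non-empty sentences
  fm <- do.call(rbind, fields)
  tok_idx <- unlist(purrr::map(rle(sent)$lengths, function(n) seq_len(n) - 1L))
  toks <- tibble::tibble(
    doc_id = doc_id, line = sent, tok = tok_idx,
    text = fm[, match("text", columns)],
    pos = if ("pos" %in% columns) fm[, match("pos", columns)] else NA_character_
  )
  corpus <- ner_corpus(
    tokens = toks,
    n_lines = tibble::tibble(doc_id = doc_id, n_lines = max(sent)),
    entity_types = entity_types)
  labels <- NULL
  if ("label" %in% columns) {
    labels <- split(fm[, match("label", columns)], sent)
    names(labels) <- NULL
  }
  list(corpus = corpus, labels = labels)
}

#' Write a corpus in CoNLL format
#'
#' @param corpus An `ner_corpus`.
#' @param labels Optional list of per-sentence label vectors (as returned by
#'   [encode_corpus_labels()]); written as the last column.
#' @param sep Output field separator (default tab).
#' @return Character vector of lines, blank line between sentences.
#' @export
write_conll <- function(corpus, labels = NULL, sep = "\t") {
  toks <- corpus$tokens
  if (nrow(toks) == 0) return(character())
  toks <- toks[order(toks$doc_id, toks$line, toks$tok), ]
  key <- paste(toks$doc_id, toks$line)
  sent <- match(key, unique(key))
  has_pos <- !all(is.na(toks$pos))
  cols <- list(toks$text)
  if (has_pos) cols <- c(cols, list(ifelse(is.na(toks$pos), "_", toks$pos)))
  if (!is.null(labels)) cols <- c(cols, list(unlist(labels, use.names = FALSE)))
  body <- do.call(paste, c(cols, sep = sep))
  out <- character()
  for (s in unique(sent)) {
    out <- c(out, body[sent == s], "")
  }
  head(out, -1)
}
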