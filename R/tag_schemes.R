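# BIO / BIESO tag schemes: span <-> label-sequence conversion.

#' Tag scheme for span encoding
#'
#' BIO assigns Begin/Inside/Outside labels; BIESO additionally distinguishes
#' End tokens and Single-token entities. With `k` entity types the inventories
#' hold `2k + 1` (BIO) and `4k + 1` (BIESO) labels. Label order is fixed —
#' per type (in the given order) the position tags B, I (and E, S for BIESO),
#' with "O" last — so feature and weight indices are reproducible.
#'
#' @param name `"BIO"` or `"BIESO"`.
#' @param entity_types Ordered character vector of entity type names.
#' @return An object of class `tag_scheme` with elements `name`,
#'   `entity_types`, `labels`.
#' @export
#' @examples
#' tag_scheme("BIO", c("problem", "treatment", "test"))$labels
tag_scheme <- function(name = c("BIO", "BIESO"),
                       entity_types = c("problem", "treatment", "test")) {
  if (!is.character(name) || !name[1] %in% c("BIO", "BIESO")) {
    abort(sprintf("unknown tag scheme '%s'", name[1]))
  }
  name <- name[1]
  pos <- if (name == "BIO") c("B", "I") else c("B", "I", "E", "S")
  typed <- if (length(entity_types)) {
    as.vector(t(outer(entity_types, pos, function(ty, p) paste0(p, "-", ty))))
  } else {
    character()
  }
  labels <- c(typed, "O")
  structure(list(name = name, entity_types = entity_types, labels = labels),
            class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat(sprintf("<tag_scheme %s> %d labels over types {%s}\n", x$name,
              length(x$labels), paste(x$entity_types, collapse = ", ")))
  invisible(x)
}

#' Label inventory of a scheme
#'
#' @param scheme_name `"BIO"` or `"BIESO"`.
#' @param entity_types Ordered entity type names.
#' @return Ordered character vector of labels ("O" last).
#' @export
tagset <- function(scheme_name, entity_types) {
  tag_scheme(scheme_name, entity_types)$labels
}

# --- per-sentence encode -----------------------------------------------------

#' Encode sentence spans as a label sequence
#'
#' @param n_tokens Number of tokens in the sentence.
#' @param starts,ends 0-based inclusive token offsets of the spans.
#' @param types Entity type per span.
#' @param scheme A [tag_scheme()].
#' @return Character vector of length `n_tokens`.
#' @export
encode_tags <- function(n_tokens, starts, ends, types, scheme) {
  labels <- rep("O", n_tokens)
  if (length(starts) == 0) return(labels)
  if (any(starts > ends) || any(starts < 0) || any(ends > n_tokens - 1)) {
    abort("span outside sentence")
  }
  covered <- unlist(purrr::map2(starts, ends, seq))
  if (anyDuplicated(covered)) abort("overlapping spans cannot be encoded")
  if (any(!types %in% scheme$entity_types)) abort("unknown entity type")
  for (i in seq_along(starts)) {
    s <- starts[i] + 1L; e <- ends[i] + 1L; ty <- types[i]
    if (scheme$name == "BIO") {
      labels[s] <- paste0("B-", ty)
      if (e > s) labels[(s + 1):e] <- paste0("I-", ty)
    } else {
      if (s == e) {
        labels[s] <- paste0("S-", ty)
      } else {
        labels[s] <- paste0("B-", ty)
        labels[e] <- paste0("E-", ty)
        if (e > s + 1) labels[(s + 1):(e - 1)] <- paste0("I-", ty)
      }
    }
  }
  labels
}

#' Decode a label sequence into spans, repairing invalid sequences
#'
#' Lenient CoNLL-style decoding: an I (or E) with no compatible open entity
#' starts a new entity of its type; a type change inside a run closes the
#' previous entity; in BIESO a B never closed by an E is closed at the last
#' contiguous same-type token. The number of repairs applied is attached as
#' attribute `"repairs"`.
#'
#' @param labels Character vector of labels from the scheme's inventory.
#' @param scheme A [tag_scheme()].
#' @return Tibble with columns `start`, `end` (0-based inclusive token
#'   offsets) and `type`, in sentence order; attribute `repairs` counts
#'   deviations from a valid encoding.
#' @export
decode_tags <- function(labels, scheme) {
  bad <- setdiff(labels, scheme$labels)
  if (length(bad)) abort(paste("label not in scheme inventory:", bad[1]))
  n <- length(labels)
  starts <- integer(); ends <- integer(); types <- character()
  open_start <- NA_integer_; open_type <- NA_character_
  repairs <- 0L
  close_open <- function(end_at) {
    starts[[length(starts) + 1L]] <<- open_start
    ends[[length(ends) + 1L]] <<- end_at
    types[[length(types) + 1L]] <<- open_type
    open_start <<- NA_integer_; open_type <<- NA_character_
  }
  bieso <- scheme$name == "BIESO"
  for (t in seq_len(n)) {
    lab <- labels[t]
    if (lab == "O") {
      if (!is.na(open_start)) {
        if (bieso) repairs <- repairs + 1L # B/I left unclosed by E
        close_open(t - 2L)
      }
      next
    }
    p <- substr(lab, 1, 1)
    ty <- substring(lab, 3)
    if (p == "B") {
      if (!is.na(open_start)) {
        if (bieso) repairs <- repairs + 1L
        close_open(t - 2L)
      }
      if (bieso) {
        open_start <- t - 1L; open_type <- ty
      } else {
        open_start <- t - 1L; open_type <- ty
      }
    } else if (p == "I") {
      if (is.na(open_start)) {
        repairs <- repairs + 1L
        open_start <- t - 1L; open_type <- ty
      } else if (!identical(open_type, ty)) {
        repairs <- repairs + 1L
        close_open(t - 2L)
        open_start <- t - 1L; open_type <- ty
      }
      # else: continue the open entity
    } else if (p == "E") {
      if (is.na(open_start)) {
        repairs <- repairs + 1L
        open_start <- t - 1L; open_type <- ty
        close_open(t - 1L)
      } else if (!identical(open_type, ty)) {
        repairs <- repairs + 1L
        close_open(t - 2L)
        open_start <- t - 1L; open_type <- ty
        close_open(t - 1L)
      } else {
        close_open(t - 1L)
      }
    } else if (p == "S") {
      if (!is.na(open_start)) {
        repairs <- repairs + 1L
        close_open(t - 2L)
      }
      open_start <- t - 1L; open_type <- ty
      close_open(t - 1L)
    }
  }
  if (!is.na(open_start)) {
    if (bieso) repairs <- repairs + 1L # unterminated B/I at sentence end
    close_open(n - 1L)
  }
  out <- tibble::tibble(start = starts, end = ends, type = types)
  attr(out, "repairs") <- repairs
  out
}

#' Convert a label sequence between schemes
#'
#' Decodes under `from` (with repair) and re-encodes under `to`. The schemes
#' must share an entity-type inventory.
#'
#' @param labels Character label vector.
#' @param from,to [tag_scheme()] objects.
#' @return Character label vector under `to`.
#' @export
convert_tags <- function(labels, from, to) {
  if (!identical(from$entity_types, to$entity_types)) {
    abort("schemes have different entity-type inventories")
  }
  sp <- decode_tags(labels, from)
  encode_tags(length(labels), sp$start, sp$end, sp$type, to)
}

# --- corpus-level wrappers ---------------------------------------------------

#' Encode all corpus spans as per-sentence label sequences
#'
#' Spans must lie within a single line (sentence); the tag encodings cannot
#' represent sentence-crossing entities.
#'
#' @param corpus An `ner_corpus`.
#' @param scheme A [tag_scheme()].
#' @return Named list (by `doc_id<US>line`) of label vectors, in token order,
#'   aligned with [sentence_index()].
#' @export
encode_corpus_labels <- function(corpus, scheme) {
  if (nrow(corpus$spans) > 0 &&
      any(corpus$spans$start_line != corpus$spans$end_line)) {
    abort("sentence-crossing span cannot be encoded")
  }
  idx <- sentence_index(corpus)
  sp <- corpus$spans
  purrr::pmap(idx, function(doc_id, line, n_tokens, ...) {
    keep <- sp$doc_id == doc_id & sp$start_line == line
    encode_tags(n_tokens, sp$start_tok[keep], sp$end_tok[keep],
                sp$type[keep], scheme)
  })
}

#' Sentence table of a corpus
#'
#' @param corpus An `ner_corpus`.
#' @return Tibble `doc_id`, `line`, `n_tokens`, ordered by document and line;
#'   one row per non-empty sentence.
#' @export
sentence_index <- function(corpus) {
  corpus$tokens |>
    dplyr::group_by(.data$doc_id, .data$line) |>
    dplyr::summarise(n_tokens = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$doc_id, .data$line)
}

#' Decode per-sentence label sequences into corpus spans
#'
#' @param corpus An `ner_corpus` (its spans are replaced).
#' @param labels List of per-sentence label vectors aligned with
#'   [sentence_index()].
#' @param scheme A [tag_scheme()].
#' @return The corpus with decoded spans; attribute `repairs` totals the
#'   decoder repairs applied.
#' @export
decode_corpus_labels <- function(corpus, labels, scheme) {
  idx <- sentence_index(corpus)
  stopifnot(length(labels) == nrow(idx))
  toks <- corpus$tokens[order(corpus$tokens$doc_id, corpus$tokens$line,
                              corpus$tokens$tok), ]
  repairs <- 0L
  sp_list <- purrr::map(seq_len(nrow(idx)), function(i) {
    d <- decode_tags(labels[[i]], scheme)
    repairs <<- repairs + attr(d, "repairs")
    if (nrow(d) == 0) return(NULL)
    sent_toks <- toks$text[toks$doc_id == idx$doc_id[i] & toks$line == idx$line[i]]
    tibble::tibble(
      doc_id = idx$doc_id[i],
      start_line = idx$line[i], start_tok = d$start,
      end_line = idx$line[i], end_tok = d$end, type = d$type,
      text = purrr::map2_chr(d$start, d$end,
                             function(s, e) paste(sent_toks[(s:e) + 1], collapse = " ")))
  })
  spans <- dplyr::bind_rows(sp_list)
  if (nrow(spans) == 0) spans <- empty_spans()
  out <- ner_corpus(corpus$tokens, spans, corpus$n_lines, corpus$entity_types)
  attr(out, "repairs") <- repairs
  out
}
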