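# Random indexing: sparse ternary index vectors, context-vector accumulation
# over a symmetric sentence-bounded co-occurrence window, cosine
# nearest-neighbour semantic thesauri, and rank-bucketed neighbour features.

#' Build sparse ternary index vectors
#'
#' Each word gets a vector with exactly `nonzeros` nonzero entries — half +1,
#' half -1 — at positions drawn without replacement from a seeded generator.
#' Near-orthogonality of random index vectors is what makes the accumulated
#' context vectors an approximate low-dimensional projection of the full
#' co-occurrence matrix.
#'
#' @param vocab Character vector of words (order fixes the draws).
#' @param dimension Vector dimension (default 1500).
#' @param nonzeros Number of nonzero entries; must be even and < `dimension`
#'   (default 8).
#' @param seed Integer seed; identical inputs reproduce identical vectors.
#' @return Sparse matrix (`Matrix::dgCMatrix`, vocab x dimension) with
#'   rownames `vocab`.
#' @export
build_index_vectors <- function(vocab, dimension = 1500, nonzeros = 8,
                                seed = 1) {
  if (nonzeros >= dimension) abort("nonzeros must be < dimension")
  if (nonzeros %% 2 != 0) abort("nonzeros must be even")
  V <- length(vocab)
  half <- nonzeros / 2
  pos <- withr::with_seed(seed, {
    t(vapply(seq_len(V), function(i) sample.int(dimension, nonzeros),
             integer(nonzeros)))
  })
  Matrix::sparseMatrix(
    i = rep(seq_len(V), each = nonzeros),
    j = as.integer(t(pos)),
    x = rep(c(rep(1, half), rep(-1, half)), V),
    dims = c(V, dimension), dimnames = list(vocab, NULL))
}

#' Accumulate context vectors over a co-occurrence window
#'
#' For every token occurrence, the index vectors of the tokens within
#' `window` positions on each side (bounded by the sentence) are added to the
#' focus word's context vector. Counts are flat (no distance weighting).
#'
#' @param x Corpus: path, lines, `ner_corpus`, or list of token vectors.
#' @param index Index-vector matrix from [build_index_vectors()]; its
#'   rownames define the vocabulary (tokens outside it are skipped).
#' @param window Tokens on each side (default 4).
#' @return Dense matrix (vocab x dimension) of context vectors.
#' @export
accumulate_context_vectors <- function(x, index, window = 4) {
  sents <- corpus_token_list(x)
  vocab <- rownames(index)
  V <- length(vocab)
  # flatten with sentence ids so all offsets vectorize over the whole corpus
  ids <- match(unlist(sents, use.names = FALSE), vocab)
  sid <- rep(seq_along(sents), lengths(sents))
  TT <- length(ids)
  fi <- integer(0); ni <- integer(0)
  if (TT >= 2) {
    parts <- purrr::map(seq_len(min(window, TT - 1)), function(d) {
      a <- ids[seq_len(TT - d)]
      b <- ids[seq(d + 1, TT)]
      ok <- !is.na(a) & !is.na(b) &
        sid[seq_len(TT - d)] == sid[seq(d + 1, TT)]
      # symmetric window: b is within d of focus a, and vice versa
      list(f = c(a[ok], b[ok]), n = c(b[ok], a[ok]))
    })
    fi <- unlist(purrr::map(parts, "f"), use.names = FALSE)
    ni <- unlist(purrr::map(parts, "n"), use.names = FALSE)
  }
  if (length(fi) == 0) {
    return(matrix(0, V, ncol(index), dimnames = list(vocab, NULL)))
  }
  cooc <- Matrix::sparseMatrix(i = fi, j = ni, x = 1, dims = c(V, V))
  out <- as.matrix(cooc %*% index)
  rownames(out) <- vocab
  out
}

#' Build a random-indexing semantic index from a corpus
#'
#' Convenience wrapper: vocabulary from the corpus (sorted, subject to
#' `min_count`), index vectors, then context accumulation.
#'
#' @inheritParams accumulate_context_vectors
#' @inheritParams build_index_vectors
#' @param min_count Drop words seen fewer times.
#' @return Object of class `semantic_index`: `dimension`, `nonzeros`,
#'   `window`, `seed`, `index` (sparse), `context` (dense).
#' @export
build_semantic_index <- function(x, dimension = 1500, nonzeros = 8,
                                 window = 4, seed = 1, min_count = 1) {
  sents <- corpus_token_list(x)
  cnt <- table(unlist(sents, use.names = FALSE))
  vocab <- sort(names(cnt)[cnt >= min_count])
  if (length(vocab) == 0) abort("empty vocabulary")
  index <- build_index_vectors(vocab, dimension, nonzeros, seed)
  context <- accumulate_context_vectors(sents, index, window)
  structure(list(dimension = dimension, nonzeros = nonzeros, window = window,
                 seed = seed, index = index, context = context),
            class = "semantic_index")
}

#' @export
print.semantic_index <- function(x, ...) {
  cat(sprintf("<semantic_index> %d words, dimension %d, window %d\n",
              nrow(x$context), x$dimension, x$window))
  invisible(x)
}

cosine_to <- function(context, v) {
  nv <- sqrt(sum(v^2))
  norms <- sqrt(rowSums(context^2))
  sims <- as.numeric(context %*% v)
  ok <- norms > 0 & nv > 0
  sims[ok] <- sims[ok] / (norms[ok] * nv)
  sims[!ok] <- NA_real_
  sims
}

#' k nearest semantic neighbours by cosine
#'
#' Self is excluded; words with zero context vectors are excluded; cosine
#' ties break lexicographically by neighbour word.
#'
#' @param index A [build_semantic_index()] result.
#' @param word Focus word.
#' @param k Number of neighbours.
#' @return Tibble `word`, `cosine` with at most `k` rows, cosine
#'   non-increasing. Empty for an unknown word or a zero context vector.
#' @export
nearest_neighbours <- function(index, word, k = 20) {
  ctx <- index$context
  i <- match(word, rownames(ctx))
  if (is.na(i)) return(tibble::tibble(word = character(), cosine = numeric()))
  v <- ctx[i, ]
  if (sum(v^2) == 0) {
    return(tibble::tibble(word = character(), cosine = numeric()))
  }
  sims <- cosine_to(ctx, v)
  cand <- tibble::tibble(word = rownames(ctx), cosine = sims)
  cand <- cand[-i, ]
  cand <- cand[!is.na(cand$cosine), ]
  cand <- cand[order(-cand$cosine, cand$word), ]
  head(cand, k)
}

#' Semantic thesaurus: top-k neighbours of every word
#'
#' @param index A [build_semantic_index()] result.
#' @param k Neighbours per word (the reference configuration keeps 20).
#' @param words Optional subset of focus words.
#' @return Tibble `word`, `neighbour`, `rank`, `cosine`.
#' @export
semantic_thesaurus <- function(index, k = 20, words = NULL) {
  ctx <- index$context
  vocab <- rownames(ctx)
  words <- words %||% vocab
  norms <- sqrt(rowSums(ctx^2))
  keep <- norms > 0
  cn <- ctx[keep, , drop = FALSE] / norms[keep]
  S <- cn %*% t(cn) # full cosine matrix; vocabularies here are small
  kv <- rownames(cn)
  purrr::map_dfr(words[words %in% kv], function(w) {
    sims <- S[w, ]
    sims <- sims[names(sims) != w]
    ord <- order(-sims, names(sims))[seq_len(min(k, length(sims)))]
    tibble::tibble(word = w, neighbour = names(sims)[ord],
                   rank = seq_along(ord), cosine = unname(sims[ord]))
  })
}

rank_bucket <- function(rank, buckets = c(1, 5, 10, 20)) {
  paste0("top", buckets[findInterval(rank, buckets + 1) + 1])
}

#' Thesaurus neighbour features for a word
#'
#' Feature strings are the neighbour words in rank order, tagged with their
#' rank bucket (top1 / top5 / top10 / top20 by default) so the feature space
#' stays small. Unknown words yield no features.
#'
#' @param thesaurus A [semantic_thesaurus()] tibble.
#' @param word Focus word.
#' @param k Max neighbours to use.
#' @param buckets Bucket upper bounds.
#' @return Character vector like `"quelene@top5"` (possibly empty).
#' @export
thesaurus_features <- function(thesaurus, word, k = 20,
                               buckets = c(1, 5, 10, 20)) {
  rows <- thesaurus[thesaurus$word == word & thesaurus$rank <= k, ]
  if (nrow(rows) == 0) return(character(0))
  rows <- rows[order(rows$rank), ]
  paste0(rows$neighbour, "@", rank_bucket(rows$rank, buckets))
}

#' Write / read a thesaurus file
#'
#' Format: one word per line, `word<TAB>neighbour:sim,neighbour:sim,...`.
#'
#' @param thesaurus A [semantic_thesaurus()] tibble.
#' @param path Output file (omit to return lines).
#' @return Lines (invisibly when written to file).
#' @export
write_thesaurus <- function(thesaurus, path = NULL) {
  df <- thesaurus[order(thesaurus$word, thesaurus$rank), ]
  by_word <- split(df, factor(df$word, levels = unique(df$word)))
  lines <- purrr::imap_chr(by_word, function(df, w) {
    paste0(w, "\t", paste(sprintf("%s:%.6f", df$neighbour, df$cosine),
                          collapse = ","))
  })
  lines <- unname(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname write_thesaurus
#' @param x Path or character lines.
#' @export
read_thesaurus <- function(x) {
  lines <- as_input_lines(x)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    entries <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    kv <- strsplit(entries, ":", fixed = TRUE)
    tibble::tibble(word = parts[1],
                   neighbour = purrr::map_chr(kv, 1),
                   rank = seq_along(kv),
                   cosine = as.numeric(purrr::map_chr(kv, 2)))
  })
}
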