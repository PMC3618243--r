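# Brown clustering: greedy agglomerative merging over adjacent-bigram class
# statistics, each step choosing the merge that maximizes the post-merge
# average mutual information (AMI) between adjacent class bigrams. The merge
# sequence defines a binary tree over the vocabulary; each word's bit path
# (root to leaf) and all its prefixes serve as features.
#
# Variant: classic windowed greedy — the num_clusters most frequent words
# start as singleton clusters, the remaining words are inserted by frequency
# order, and after each insertion the pair minimizing AMI loss is merged;
# the final num_clusters clusters are then merged down to one to complete
# the tree. Ties break toward the lexicographically smallest pair of cluster
# creation ids. At each internal node the child containing the earlier-created
# cluster gets bit "0".

OOV_WORD <- "<OOV>"

# AMI of a class bigram count matrix, in bits; marginals are taken from the
# bigram table itself so the quantity is self-consistent.
class_ami <- function(B) {
  tot <- sum(B)
  if (tot == 0) return(0)
  P <- B / tot
  pl <- rowSums(P); pr <- colSums(P)
  nz <- which(P > 0)
  den <- outer(pl, pr)[nz]
  sum(P[nz] * log2(P[nz] / den))
}

merge_bigram_rows <- function(B, a, b) {
  keep <- setdiff(seq_len(nrow(B)), c(a, b))
  nb <- rbind(B[keep, , drop = FALSE], B[a, ] + B[b, ])
  cbind(nb[, keep, drop = FALSE], nb[, a] + nb[, b])
}

# Best merge among active clusters: maximize AMI after merge; ties toward the
# smallest (creation_id_a, creation_id_b). Returns list(a, b, ami_after) with
# a, b row indices into B. AMI after merging (a, b) is computed by an O(K)
# delta: subtract the mutual-information terms touching rows/cols a and b,
# add the terms of the merged row/col — identical to recomputing
# class_ami(merge_bigram_rows(B, a, b)) (the exhaustive test oracle does
# exactly that).
choose_merge <- function(B, cids) {
  K <- nrow(B)
  tot <- sum(B)
  P <- B / tot
  pl <- rowSums(P); pr <- colSums(P)
  q <- matrix(0, K, K)
  nz <- which(P > 0)
  q[nz] <- P[nz] * log2(P[nz] / outer(pl, pr)[nz])
  qrow <- rowSums(q); qcol <- colSums(q)
  ami_before <- sum(qrow)
  f <- function(p, l, r) {
    out <- numeric(length(p))
    ok <- p > 0
    out[ok] <- p[ok] * log2(p[ok] / (l * r)[ok])
    sum(out)
  }
  ord <- order(cids)
  best <- NULL
  for (ii in seq_len(K - 1)) {
    for (jj in seq(ii + 1, K)) {
      a <- ord[ii]; b <- ord[jj]
      removed <- qrow[a] + qrow[b] + qcol[a] + qcol[b] -
        q[a, a] - q[a, b] - q[b, a] - q[b, b]
      keep <- -c(a, b)
      plm <- pl[a] + pl[b]; prm <- pr[a] + pr[b]
      row_new <- P[a, keep] + P[b, keep]
      col_new <- P[keep, a] + P[keep, b]
      corner <- P[a, a] + P[a, b] + P[b, a] + P[b, b]
      added <- f(row_new, rep(plm, K - 2), pr[keep]) +
        f(col_new, pl[keep], rep(prm, K - 2)) +
        f(corner, plm, prm)
      ami <- ami_before - removed + added
      if (is.null(best) || ami > best$ami_after + 1e-12) {
        best <- list(a = a, b = b, ami_after = ami)
      }
    }
  }
  best
}

#' Train a Brown word-cluster hierarchy
#'
#' @param x Unlabeled corpus: a path, character vector of lines (one sentence
#'   per line, whitespace tokens), or a list of token vectors.
#' @param num_clusters Number of clusters in the windowed phase (the paper's
#'   sweep used 50–2000 with 1000 selected; small corpora want small values).
#' @param min_count Words seen fewer times share a single out-of-vocabulary
#'   class.
#' @return Object of class `brown_hierarchy`: `paths` (named character,
#'   word -> bit string), `counts`, `num_clusters`, `min_count`, `merge_log`
#'   (tibble `step`, `cluster_a`, `cluster_b`, `ami_after`), `oov_path`.
#' @export
brown_clusters <- function(x, num_clusters = 1000, min_count = 1) {
  sents <- corpus_token_list(x)
  if (length(sents) == 0 || sum(lengths(sents)) == 0) abort("empty corpus")
  if (num_clusters < 1) abort("num_clusters must be >= 1")
  all_tokens <- unlist(sents, use.names = FALSE)
  cnt <- table(all_tokens)
  low <- names(cnt)[cnt < min_count]
  if (length(low)) {
    sents <- purrr::map(sents, function(s) ifelse(s %in% low, OOV_WORD, s))
    all_tokens <- unlist(sents, use.names = FALSE)
    cnt <- table(all_tokens)
  }
  words <- names(cnt)
  counts <- as.integer(cnt)
  V <- length(words)
  if (num_clusters > V) {
    abort(sprintf("num_clusters (%d) exceeds retained vocabulary size (%d)",
                  num_clusters, V))
  }
  # frequency order: count desc, lexicographic tie-break
  ordv <- order(-counts, words)
  words <- words[ordv]; counts <- counts[ordv]
  wid <- setNames(seq_len(V), words)
  # word-level adjacent bigram counts (within sentences), vectorized over the
  # flattened token stream with a sentence-id guard
  Wb <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                             dims = c(V, V))
  ids <- wid[unlist(sents, use.names = FALSE)]
  sid <- rep(seq_along(sents), lengths(sents))
  TT <- length(ids)
  if (TT >= 2) {
    same <- sid[-TT] == sid[-1]
    pair_i <- ids[-TT][same]
    pair_j <- ids[-1][same]
    if (length(pair_i)) {
      Wb <- Matrix::sparseMatrix(i = pair_i, j = pair_j, x = 1, dims = c(V, V))
    }
  }
  # --- windowed greedy ---
  k0 <- min(num_clusters, V)
  active_words <- purrr::map(seq_len(k0), function(i) i)  # word ids per cluster
  cids <- seq_len(k0)                                      # creation ids
  nodes <- purrr::map(seq_len(k0), function(i) list(word = words[i]))
  next_cid <- k0 + 1L
  inserted <- seq_len(k0)
  B <- cluster_bigrams(Wb, active_words, inserted)
  merge_log <- list()
  step <- 0L
  do_merge <- function(pick) {
    a <- pick$a; b <- pick$b
    # earlier-created child gets bit "0"
    first <- if (cids[a] < cids[b]) a else b
    second <- if (cids[a] < cids[b]) b else a
    step <<- step + 1L
    merge_log[[step]] <<- tibble::tibble(
      step = step, cluster_a = cids[first], cluster_b = cids[second],
      ami_after = pick$ami_after)
    node <- list(left = nodes[[first]], right = nodes[[second]])
    keep <- setdiff(seq_along(cids), c(pick$a, pick$b))
    active_words <<- c(active_words[keep],
                       list(c(active_words[[pick$a]], active_words[[pick$b]])))
    nodes <<- c(nodes[keep], list(node))
    cids <<- c(cids[keep], next_cid)
    next_cid <<- next_cid + 1L
    B <<- merge_bigram_rows(B, pick$a, pick$b)
  }
  if (V > k0) {
    for (widx in seq(k0 + 1, V)) {
      # insert word widx as a fresh singleton cluster, then merge best pair
      inserted <- c(inserted, widx)
      active_words <- c(active_words, list(widx))
      nodes <- c(nodes, list(list(word = words[widx])))
      cids <- c(cids, next_cid)
      next_cid <- next_cid + 1L
      B <- cluster_bigrams(Wb, active_words, inserted)
      do_merge(choose_merge(B, cids))
    }
  }
  # final phase: merge the remaining clusters down to one
  while (length(cids) > 1) {
    do_merge(choose_merge(B, cids))
  }
  paths <- extract_paths(nodes[[1]])
  structure(
    list(paths = paths[words], counts = setNames(counts, words),
         num_clusters = num_clusters, min_count = min_count,
         merge_log = dplyr::bind_rows(merge_log),
         oov_path = unname(paths[OOV_WORD])),
    class = "brown_hierarchy")
}

# class-level bigram counts restricted to inserted words
cluster_bigrams <- function(Wb, active_words, inserted) {
  K <- length(active_words)
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(K), lengths(active_words)),
    j = unlist(active_words), x = 1, dims = c(K, nrow(Wb)))
  as.matrix(S %*% Wb %*% Matrix::t(S))
}

extract_paths <- function(node, prefix = "") {
  if (!is.null(node$word)) {
    return(setNames(prefix, node$word))
  }
  c(extract_paths(node$left, paste0(prefix, "0")),
    extract_paths(node$right, paste0(prefix, "1")))
}

#' @export
print.brown_hierarchy <- function(x, ...) {
  cat(sprintf("<brown_hierarchy> %d words, %d merges, num_clusters=%d\n",
              length(x$paths), nrow(x$merge_log), x$num_clusters))
  invisible(x)
}

# Accepts lines, a path, or a list of token vectors.
corpus_token_list <- function(x) {
  if (is.list(x)) return(x)
  if (inherits(x, "ner_corpus")) {
    toks <- x$tokens[order(x$tokens$doc_id, x$tokens$line, x$tokens$tok), ]
    key <- paste(toks$doc_id, toks$line)
    return(unname(split(toks$text, factor(key, levels = unique(key)))))
  }
  lines <- as_input_lines(x)
  parts <- strsplit(lines, "[ \t]+")
  purrr::map(parts, function(p) p[nzchar(p)])
}

#' All bit-path prefixes of a word
#'
#' For a path of length L, exactly the L prefixes (lengths 1..L). Unknown
#' words map to the out-of-vocabulary class path when one exists (empty set
#' otherwise).
#'
#' @param word A word.
#' @param hierarchy A [brown_clusters()] result.
#' @return Character vector of prefixes.
#' @export
path_prefixes <- function(word, hierarchy) {
  p <- unname(hierarchy$paths[word])
  if (is.na(p)) p <- hierarchy$oov_path
  if (is.null(p) || is.na(p) || !nzchar(p)) return(character(0))
  substring(p, 1, seq_len(nchar(p)))
}

truncate_prefix_set <- function(prefixes, lengths) {
  if (length(prefixes) == 0) return(prefixes)
  full <- nchar(prefixes[length(prefixes)])
  want <- sort(unique(pmin(lengths[lengths > 0], full)))
  prefixes[want]
}

#' Length-capped path prefixes for every word
#'
#' @param hierarchy A [brown_clusters()] result.
#' @param prefix_lengths Positive prefix lengths to keep; lengths exceeding a
#'   word's path collapse to the full path (included once).
#' @return Named list word -> character vector of selected prefixes.
#' @export
truncate_paths <- function(hierarchy, prefix_lengths) {
  if (any(prefix_lengths <= 0)) abort("prefix_lengths must be positive")
  purrr::map(setNames(names(hierarchy$paths), names(hierarchy$paths)),
             function(w) truncate_prefix_set(path_prefixes(w, hierarchy),
                                             prefix_lengths))
}

#' Write / read a Brown paths file
#'
#' The de facto interchange format: tab-separated `bitpath word count`.
#'
#' @param hierarchy A [brown_clusters()] result.
#' @param path Output file (omit to return lines).
#' @return Lines (invisibly when written to a file).
#' @export
write_brown_paths <- function(hierarchy, path = NULL) {
  lines <- sprintf("%s\t%s\t%d", unname(hierarchy$paths),
                   names(hierarchy$paths), unname(hierarchy$counts))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname write_brown_paths
#' @param x Path or character vector of `bitpath<TAB>word[<TAB>count]` lines.
#' @export
read_brown_paths <- function(x) {
  lines <- as_input_lines(x)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  paths <- setNames(purrr::map_chr(parts, 1), purrr::map_chr(parts, 2))
  counts <- if (all(lengths(parts) >= 3)) {
    setNames(as.integer(purrr::map_chr(parts, 3)), names(paths))
  } else NULL
  structure(list(paths = paths, counts = counts, num_clusters = NA_integer_,
                 min_count = NA_integer_, merge_log = NULL,
                 oov_path = unname(paths[OOV_WORD])),
            class = "brown_hierarchy")
}
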