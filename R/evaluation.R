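# Span-level micro-averaged evaluation (exact and inexact matching) and
# paired-system comparison by sentence bootstrap + Wilcoxon signed-rank.

span_table <- function(corpus) {
  sp <- corpus$spans
  sp[order(sp$doc_id, sp$start_line, sp$start_tok, sp$end_line, sp$end_tok), ]
}

# Greedy one-to-one matching in document order; returns logical vector over
# predicted spans (matched = TRUE) and the matched gold indices.
match_spans <- function(gold, pred, mode, require_type = TRUE) {
  used <- rep(FALSE, nrow(gold))
  hit <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(
      !used &
        gold$doc_id == pred$doc_id[i] &
        (if (require_type) gold$type == pred$type[i] else TRUE))
    if (!length(cand)) next
    if (mode == "exact") {
      ok <- gold$start_line[cand] == pred$start_line[i] &
        gold$start_tok[cand] == pred$start_tok[i] &
        gold$end_line[cand] == pred$end_line[i] &
        gold$end_tok[cand] == pred$end_tok[i]
    } else {
      # overlap in (line, token) document order, inclusive coordinates
      a1 <- gold$start_line[cand] * 1e6 + gold$start_tok[cand]
      a2 <- gold$end_line[cand] * 1e6 + gold$end_tok[cand]
      b1 <- pred$start_line[i] * 1e6 + pred$start_tok[i]
      b2 <- pred$end_line[i] * 1e6 + pred$end_tok[i]
      ok <- a1 <= b2 & b1 <= a2
    }
    j <- cand[ok][1]
    if (!is.na(j)) {
      used[j] <- TRUE
      hit[i] <- TRUE
    }
  }
  list(pred_hit = hit, gold_used = used)
}

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_measure = f)
}

#' Span-level micro-averaged evaluation
#'
#' Exact matching credits a predicted span only when an unmatched gold span
#' has identical start, end and type; inexact matching credits any overlap
#' with an unmatched gold span (of the same type, unless
#' `require_type = FALSE`). Matching is one-to-one and greedy in document
#' order; micro-averaging pools counts over all documents.
#'
#' @param gold,pred `ner_corpus` objects over the same documents.
#' @param mode `"exact"`, `"inexact"`, or both (default).
#' @param require_type Must an inexact match agree on entity type? Default
#'   TRUE (the i2b2 "class"-level criterion).
#' @return Tibble with one row per mode and class (`overall` plus each entity
#'   type): `tp`, `fp`, `fn`, `precision`, `recall`, `f_measure`.
#' @export
evaluate_spans <- function(gold, pred, mode = c("exact", "inexact"),
                           require_type = TRUE) {
  mode <- match.arg(mode, several.ok = TRUE)
  gd <- sort(unique(gold$tokens$doc_id))
  pd <- sort(unique(pred$tokens$doc_id))
  if (!identical(gd, pd)) abort("document ids of gold and predicted corpora differ")
  g <- span_table(gold)
  p <- span_table(pred)
  classes <- c("overall", gold$entity_types)
  out <- purrr::map_dfr(mode, function(md) {
    mm <- match_spans(g, p, md, require_type)
    purrr::map_dfr(classes, function(cl) {
      gsel <- if (cl == "overall") rep(TRUE, nrow(g)) else g$type == cl
      psel <- if (cl == "overall") rep(TRUE, nrow(p)) else p$type == cl
      tp <- sum(mm$pred_hit[psel])
      fp <- sum(!mm$pred_hit[psel])
      fn <- sum(!mm$gold_used[gsel])
      m <- prf(tp, fp, fn)
      tibble::tibble(mode = md, class = cl, tp = tp, fp = fp, fn = fn,
                     precision = m[["precision"]], recall = m[["recall"]],
                     f_measure = m[["f_measure"]])
    })
  })
  class(out) <- c("ner_eval", class(out))
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped and tied absolute differences get averaged
#' ranks. For n <= 25 pairs the two-sided p-value comes from the exact null
#' distribution of the signed-rank statistic (all sign patterns); above that,
#' from the normal approximation with tie correction. All differences zero is
#' the degenerate case: statistic 0, p = 1 (no evidence of difference).
#'
#' @param d Numeric vector of paired differences.
#' @return List with `statistic` (sum of positive-difference ranks), `p_value`
#'   and `n` (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(d) {
  if (length(d) < 1) abort("need at least one pair")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n = 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25) {
    # exact null distribution of W+ over all 2^n sign patterns, computed by
    # convolution over the (doubled-to-integer) ranks
    r2 <- as.integer(round(2 * r))
    maxw <- sum(r2)
    dist <- numeric(maxw + 1)
    dist[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(maxw + 1 - rk)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    w2 <- as.integer(round(2 * V))
    support <- seq(0, maxw)
    p_le <- sum(dist[support <= w2])
    p_ge <- sum(dist[support >= w2])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = V, p_value = p, n = n)
}

# Per-sentence exact-mode confusion counts; matching never crosses sentences,
# so bootstrap replicates can pool precomputed per-sentence counts.
sentence_counts <- function(gold, pred) {
  idx <- sentence_index(gold)
  g <- span_table(gold)
  p <- span_table(pred)
  counts <- matrix(0L, nrow(idx), 3,
                   dimnames = list(NULL, c("tp", "fp", "fn")))
  skey <- paste(idx$doc_id, idx$line)
  gkey <- match(paste(g$doc_id, g$start_line), skey)
  pkey <- match(paste(p$doc_id, p$start_line), skey)
  for (i in seq_len(nrow(idx))) {
    gi <- g[which(gkey == i), ]
    pi <- p[which(pkey == i), ]
    mm <- match_spans(gi, pi, "exact")
    counts[i, ] <- c(sum(mm$pred_hit), sum(!mm$pred_hit), sum(!mm$gold_used))
  }
  counts
}

#' Compare two systems by sentence bootstrap + Wilcoxon signed-rank
#'
#' Draws `replicates` bootstrap samples of `sample_size` sentences with
#' replacement (the same draw for both systems), computes each system's
#' exact-mode overall F on every replicate, and applies the Wilcoxon
#' signed-rank test to the paired F-measures.
#'
#' @param gold Gold `ner_corpus`.
#' @param pred_a,pred_b Predicted corpora of the two systems.
#' @param sample_size Sentences per replicate (capped at the number of
#'   available sentences, with a warning). Default 2000.
#' @param replicates Number of bootstrap data sets. Default 200.
#' @param seed Seed for the resampling.
#' @return Object of class `ner_comparison`: `f_a`, `f_b` (length-`replicates`
#'   paired F vectors), `statistic`, `p_value`, `n_replicates`, `sample_size`,
#'   `seed`.
#' @export
bootstrap_compare <- function(gold, pred_a, pred_b, sample_size = 2000,
                              replicates = 200, seed = 1) {
  if (replicates < 1) abort("need at least one bootstrap replicate")
  ca <- sentence_counts(gold, pred_a)
  cb <- sentence_counts(gold, pred_b)
  S <- nrow(ca)
  if (S == 0) abort("no sentences to resample")
  if (sample_size > S) {
    warn(sprintf("sample_size %d exceeds available sentences %d; capping",
                 sample_size, S))
    sample_size <- S
  }
  f_of <- function(cnt) prf(cnt[1], cnt[2], cnt[3])[["f_measure"]]
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(replicates),
               function(b) sample.int(S, sample_size, replace = TRUE))
  })
  f_a <- purrr::map_dbl(draws, function(ix) f_of(colSums(ca[ix, , drop = FALSE])))
  f_b <- purrr::map_dbl(draws, function(ix) f_of(colSums(cb[ix, , drop = FALSE])))
  wt <- wilcoxon_signed_rank(f_a - f_b)
  structure(
    list(f_a = f_a, f_b = f_b, statistic = wt$statistic,
         p_value = wt$p_value, n_replicates = replicates,
         sample_size = sample_size, seed = seed),
    class = "ner_comparison")
}

#' @export
print.ner_comparison <- function(x, ...) {
  cat(sprintf(
    "<ner_comparison> %d replicates of %d sentences\n  mean F: A %.4f vs B %.4f; Wilcoxon V = %.1f, p = %.4g\n",
    x$n_replicates, x$sample_size, mean(x$f_a), mean(x$f_b),
    x$statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.ner_comparison <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$n_replicates), f_a = x$f_a, f_b = x$f_b,
                 difference = x$f_a - x$f_b)
}

#' @export
glance.ner_comparison <- function(x, ...) {
  tibble::tibble(mean_f_a = mean(x$f_a), mean_f_b = mean(x$f_b),
                 statistic = x$statistic, p_value = x$p_value,
                 n_replicates = x$n_replicates, sample_size = x$sample_size)
}
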