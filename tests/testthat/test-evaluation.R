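test_that("perfect predictions give P = R = F = 1 in both modes", {
  d <- fixture_note()
  ev <- evaluate_spans(d, d)
  ov <- ev[ev$class == "overall", ]
  expect_equal(ov$precision, c(1, 1))
  expect_equal(ov$recall, c(1, 1))
  expect_equal(ov$f_measure, c(1, 1))
})

test_that("hand-computed fixtures reproduce the micro-averaged metrics", {
  # gold: problem (1,0)-(1,1), test (2,0)-(2,0); predicted: the problem only
  gold <- corpus_from_sentences(
    list(c("chest", "pain", "x"), c("ecg", "y")),
    list(list(line = 1L, start = 0L, end = 1L, type = "problem"),
         list(line = 2L, start = 0L, end = 0L, type = "test")))
  pred <- corpus_from_sentences(
    list(c("chest", "pain", "x"), c("ecg", "y")),
    list(list(line = 1L, start = 0L, end = 1L, type = "problem")))
  ev <- evaluate_spans(gold, pred, "exact")
  ov <- ev[ev$class == "overall", ]
  expect_equal(ov$tp, 1); expect_equal(ov$fp, 0); expect_equal(ov$fn, 1)
  expect_equal(ov$precision, 1)
  expect_equal(ov$recall, 0.5)
  expect_equal(ov$f_measure, 2 / 3)
  # per-class rows pool to the overall counts
  by_cls <- ev[ev$class != "overall", ]
  expect_equal(sum(by_cls$tp), ov$tp)
  expect_equal(sum(by_cls$fn), ov$fn)
})

test_that("overlap counts inexact but not exact; type must agree", {
  gold <- corpus_from_sentences(
    list(c("a", "b", "c", "d")),
    list(list(line = 1L, start = 0L, end = 1L, type = "problem")))
  pred_over <- corpus_from_sentences(
    list(c("a", "b", "c", "d")),
    list(list(line = 1L, start = 0L, end = 2L, type = "problem")))
  ev <- evaluate_spans(gold, pred_over)
  expect_equal(ev$tp[ev$mode == "exact" & ev$class == "overall"], 0)
  expect_equal(ev$tp[ev$mode == "inexact" & ev$class == "overall"], 1)
  # same offsets, wrong type: no credit even inexactly (type-aware criterion)
  pred_ty <- corpus_from_sentences(
    list(c("a", "b", "c", "d")),
    list(list(line = 1L, start = 0L, end = 1L, type = "test")))
  ev2 <- evaluate_spans(gold, pred_ty)
  expect_equal(ev2$tp[ev2$class == "overall"], c(0L, 0L))
  # ... unless type agreement is switched off
  ev3 <- evaluate_spans(gold, pred_ty, "inexact", require_type = FALSE)
  expect_equal(ev3$tp[ev3$class == "overall"], 1L)
})

test_that("matching is one-to-one and exact TP never exceeds inexact TP", {
  withr::with_seed(14, {
    for (rep in 1:30) {
      n <- 12
      mk_spans <- function() {
        k <- sample(0:4, 1)
        if (k == 0) return(NULL)
        out <- list()
        cuts <- sort(sample(0:(n - 1), 2 * k, replace = FALSE))
        for (i in seq_len(k)) {
          out[[i]] <- list(line = 1L, start = cuts[2 * i - 1],
                           end = cuts[2 * i],
                           type = sample(c("problem", "treatment", "test"), 1))
        }
        out
      }
      sent <- list(paste0("t", 1:n))
      gold <- corpus_from_sentences(sent, mk_spans())
      pred <- corpus_from_sentences(sent, mk_spans())
      ev <- evaluate_spans(gold, pred)
      ex <- ev[ev$mode == "exact" & ev$class == "overall", ]
      ix <- ev[ev$mode == "inexact" & ev$class == "overall", ]
      expect_lte(ex$tp, ix$tp)
      expect_lte(ex$tp, min(nrow(gold$spans), nrow(pred$spans)))
      expect_equal(ex$tp + ex$fp, nrow(pred$spans))
      expect_equal(ex$tp + ex$fn, nrow(gold$spans))
      # swapping gold and predicted swaps P and R and fixes F
      sw <- evaluate_spans(pred, gold)
      swx <- sw[sw$mode == "exact" & sw$class == "overall", ]
      expect_equal(swx$precision, ex$recall)
      expect_equal(swx$recall, ex$precision)
      expect_equal(swx$f_measure, ex$f_measure)
    }
  })
  expect_error(evaluate_spans(fixture_note("a"), fixture_note("b")),
               "document ids")
})

test_that("signed-rank test handles the degenerate and exact regimes", {
  expect_error(wilcoxon_signed_rank(numeric()), "at least one")
  z <- wilcoxon_signed_rank(rep(0, 10))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # agreement with the reference implementation on untied data
  withr::with_seed(25, {
    for (rep in 1:20) {
      d <- round(rnorm(sample(6:20, 1)), 6)
      d <- d[d != 0]
      got <- wilcoxon_signed_rank(d)
      ref <- stats::wilcox.test(d, exact = TRUE, correct = FALSE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("exact p-values match literal enumeration of all sign patterns", {
  withr::with_seed(26, {
    for (rep in 1:12) {
      n <- sample(3:12, 1)
      d <- round(rnorm(n), 1) # rounding induces ties
      d <- d[d != 0]
      if (length(d) == 0) next
      got <- wilcoxon_signed_rank(d)
      r <- rank(abs(d))
      V <- sum(r[d > 0])
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
      W <- as.vector(signs %*% r)
      p_le <- mean(W <= V + 1e-12)
      p_ge <- mean(W >= V - 1e-12)
      p_exp <- min(1, 2 * min(p_le, p_ge))
      expect_equal(got$p_value, p_exp, tolerance = 1e-12)
      # sign-flip symmetry of the two-sided p
      expect_equal(wilcoxon_signed_rank(-d)$p_value, got$p_value,
                   tolerance = 1e-12)
    }
  })
})

test_that("normal approximation with tie correction is used above n = 25", {
  withr::with_seed(27, {
    d <- round(rnorm(40), 1)
    d <- d[d != 0]
    got <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  })
})

make_pred_corpus <- function(gold, drop_lines = integer()) {
  sp <- gold$spans[!gold$spans$start_line %in% drop_lines, ]
  ner_corpus(gold$tokens, sp, gold$n_lines, gold$entity_types)
}

test_that("bootstrap comparison: identical systems yield p = 1", {
  g <- generate_corpus(generator_config(
    seed = 3, n_train_sentences = 60, n_test_sentences = 60,
    n_unlabeled_tokens = 1000, n_test_forms = 10))
  gold <- g$test
  pred <- make_pred_corpus(gold, drop_lines = c(2, 5, 8))
  cmp <- suppressWarnings(
    bootstrap_compare(gold, pred, pred, sample_size = 50, replicates = 50,
                      seed = 4))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$f_a, cmp$f_b)
  # reproducible given the seed
  cmp2 <- suppressWarnings(
    bootstrap_compare(gold, pred, pred, sample_size = 50, replicates = 50,
                      seed = 4))
  expect_identical(cmp$f_a, cmp2$f_a)
  expect_error(bootstrap_compare(gold, pred, pred, replicates = 0),
               "replicate")
})

test_that("a consistently better system is detected at B = 200", {
  for (seed in 1:5) {
    g <- generate_corpus(generator_config(
      seed = seed, n_train_sentences = 80, n_test_sentences = 80,
      n_unlabeled_tokens = 1000, n_test_forms = 10))
    gold <- g$test
    # system A perfect; system B misses the entities of many sentences
    lines <- unique(gold$spans$start_line)
    pred_b <- make_pred_corpus(gold,
                               drop_lines = lines[seq(1, length(lines), 2)])
    cmp <- suppressWarnings(
      bootstrap_compare(gold, gold, pred_b, sample_size = 2000,
                        replicates = 200, seed = seed))
    expect_lt(cmp$p_value, 0.05)
    expect_gt(mean(cmp$f_a), mean(cmp$f_b))
    expect_length(cmp$f_a, 200)
  }
})

test_that("oversized bootstrap samples are capped with a warning", {
  g <- generate_corpus(generator_config(
    seed = 5, n_train_sentences = 60, n_test_sentences = 60,
    n_unlabeled_tokens = 1000, n_test_forms = 10))
  expect_warning(
    cmp <- bootstrap_compare(g$test, g$test, g$test, sample_size = 5000,
                             replicates = 5, seed = 1),
    "capping")
  expect_equal(cmp$sample_size, clinner:::n_sentences(g$test))
})
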