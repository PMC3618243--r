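test_that("index vectors have the configured ternary structure", {
  vocab <- paste0("w", 1:50)
  iv <- build_index_vectors(vocab, dimension = 100, nonzeros = 8, seed = 3)
  expect_equal(dim(iv), c(50, 100))
  m <- as.matrix(iv)
  expect_true(all(rowSums(m != 0) == 8))
  expect_true(all(rowSums(m) == 0))        # half +1, half -1
  expect_true(all(m %in% c(-1, 0, 1)))
  # determinism from the seed
  iv2 <- build_index_vectors(vocab, dimension = 100, nonzeros = 8, seed = 3)
  expect_identical(as.matrix(iv), as.matrix(iv2))
  iv3 <- build_index_vectors(vocab, dimension = 100, nonzeros = 8, seed = 4)
  expect_false(identical(as.matrix(iv), as.matrix(iv3)))
  expect_error(build_index_vectors(vocab, 10, 10), "< dimension")
  expect_error(build_index_vectors(vocab, 100, 7), "even")
})

test_that("random index vectors are nearly orthogonal in expectation", {
  dimension <- 1500
  iv <- as.matrix(build_index_vectors(paste0("w", 1:200), dimension,
                                      nonzeros = 8, seed = 11))
  ivn <- iv / sqrt(rowSums(iv^2))
  withr::with_seed(12, {
    pairs <- cbind(sample(200, 1000, TRUE), sample(200, 1000, TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], ]
    cs <- abs(rowSums(ivn[pairs[, 1], ] * ivn[pairs[, 2], ]))
    expect_lt(mean(cs), 3 / sqrt(dimension))
  })
})

test_that("context accumulation equals the co-occurrence matrix product", {
  # single-token sentences: no neighbours, all context vectors zero
  iv <- build_index_vectors(c("a", "b"), 20, 4, seed = 1)
  ctx0 <- accumulate_context_vectors(list("a", "b", "a"), iv, window = 2)
  expect_true(all(ctx0 == 0))
  # corpus "a b", window 1: context(a) = index(b) and vice versa
  ctx <- accumulate_context_vectors(list(c("a", "b")), iv, window = 1)
  expect_equal(ctx["a", ], as.numeric(iv["b", ]))
  expect_equal(ctx["b", ], as.numeric(iv["a", ]))
  # dense-matrix oracle on a small random corpus: explicit count matrix
  # built by a literal position loop, times the index matrix
  withr::with_seed(8, {
    vocab <- paste0("w", 1:12)
    sents <- lapply(1:30, function(i) sample(vocab, sample(1:9, 1), TRUE))
    window <- 3
    ivr <- build_index_vectors(vocab, 40, 6, seed = 2)
    got <- accumulate_context_vectors(sents, ivr, window = window)
    cooc <- matrix(0, 12, 12, dimnames = list(vocab, vocab))
    for (s in sents) {
      for (i in seq_along(s)) {
        for (j in seq_along(s)) {
          if (i != j && abs(i - j) <= window) {
            cooc[s[i], s[j]] <- cooc[s[i], s[j]] + 1
          }
        }
      }
    }
    expect_equal(got, cooc %*% as.matrix(ivr), tolerance = 1e-12)
  })
})

test_that("nearest neighbours equal brute-force cosine ranking", {
  withr::with_seed(19, {
    for (rep in 1:3) {
      vocab <- paste0("w", seq_len(sample(50:120, 1)))
      sents <- lapply(1:150, function(i) sample(vocab, sample(2:10, 1), TRUE))
      si <- build_semantic_index(sents, dimension = 60, nonzeros = 4,
                                 window = 2, seed = rep)
      for (w in sample(vocab, 5)) {
        nn <- nearest_neighbours(si, w, 10)
        # brute force over the whole vocabulary
        v <- si$context[w, ]
        if (sum(v^2) == 0) {
          expect_equal(nrow(nn), 0)
          next
        }
        sims <- vapply(rownames(si$context), function(u) {
          uu <- si$context[u, ]
          if (sum(uu^2) == 0) return(NA_real_)
          sum(uu * v) / sqrt(sum(uu^2) * sum(v^2))
        }, numeric(1))
        sims <- sims[names(sims) != w & !is.na(sims)]
        ord <- order(-sims, names(sims))[1:10]
        expect_equal(nn$word, names(sims)[ord])
        expect_equal(nn$cosine, unname(sims[ord]), tolerance = 1e-12)
        # ordering invariants
        expect_true(all(diff(nn$cosine) <= 1e-12))
        expect_true(all(nn$cosine >= -1 - 1e-12 & nn$cosine <= 1 + 1e-12))
        expect_false(w %in% nn$word)
      }
    }
  })
})

test_that("identical context vectors are mutual top neighbours at cosine 1", {
  si <- structure(list(
    dimension = 4, nonzeros = 2, window = 1, seed = 1,
    index = NULL,
    context = matrix(c(1, 2, 0, 0,
                       2, 4, 0, 0,
                       0, 0, 3, 1), 3, 4, byrow = TRUE,
                     dimnames = list(c("u", "v", "z"), NULL))),
    class = "semantic_index")
  nn <- nearest_neighbours(si, "u", 1)
  expect_equal(nn$word, "v")
  expect_equal(nn$cosine, 1, tolerance = 1e-12)
  # k beyond the vocabulary returns vocabulary - 1 entries
  expect_equal(nrow(nearest_neighbours(si, "u", 50)), 2)
})

test_that("thesaurus features are the rank-bucketed top neighbours", {
  tc <- generate_two_class_corpus(n_sentences = 150, vocab_per_class = 10,
                                  seed = 6)
  si <- build_semantic_index(tc$lines, dimension = 100, nonzeros = 4,
                             window = 2, seed = 5)
  th <- semantic_thesaurus(si, k = 20)
  expect_equal(thesaurus_features(th, "absent_word"), character(0))
  nn <- nearest_neighbours(si, "alpha01", 20)
  fs <- thesaurus_features(th, "alpha01", 20)
  expect_length(fs, nrow(nn))
  expect_equal(sub("@.*", "", fs), nn$word)
  expect_equal(fs[1], paste0(nn$word[1], "@top1"))
  expect_equal(sub(".*@", "", fs[2]), "top5")
  expect_equal(sub(".*@", "", fs[7]), "top10")
  expect_equal(sub(".*@", "", fs[15]), "top20")
  # k = 1 is the single top neighbour
  expect_equal(thesaurus_features(th, "alpha01", 1),
               paste0(nn$word[1], "@top1"))
})

test_that("planted classes have higher within- than between-class cosine", {
  for (seed in 1:5) {
    tc <- generate_two_class_corpus(n_sentences = 200, vocab_per_class = 10,
                                    seed = seed)
    si <- build_semantic_index(tc$lines, dimension = 300, nonzeros = 8,
                               window = 2, seed = seed + 50)
    ctx <- si$context
    cls <- tc$classes[rownames(ctx)]
    cn <- ctx / sqrt(rowSums(ctx^2))
    S <- cn %*% t(cn)
    same <- outer(cls, cls, "==") & row(S) != col(S)
    expect_gt(mean(S[same]), mean(S[!same]))
  }
})

test_that("thesaurus files round-trip", {
  tc <- generate_two_class_corpus(n_sentences = 100, vocab_per_class = 6,
                                  seed = 9)
  si <- build_semantic_index(tc$lines, dimension = 80, nonzeros = 4,
                             window = 2, seed = 1)
  th <- semantic_thesaurus(si, k = 5)
  back <- read_thesaurus(write_thesaurus(th))
  expect_equal(back$word, th$word)
  expect_equal(back$neighbour, th$neighbour)
  expect_equal(back$rank, th$rank)
  expect_equal(back$cosine, th$cosine, tolerance = 1e-5)
})
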