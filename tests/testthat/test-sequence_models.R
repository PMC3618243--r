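test_that("score_sequence matches independent brute-force summation", {
  m <- random_chain_model(L = 3, nfeat = 4, seed = 2)
  withr::with_seed(5, {
    for (rep in 1:20) {
      N <- sample(1:6, 1)
      feats <- random_feats(N, 4, seed = rep)
      labs <- sample(3, N, replace = TRUE)
      expect_equal(score_sequence(m, feats, labs),
                   brute_score(feats, labs, m$W, m$Trans))
    }
  })
  # zero weights score zero for every labeling
  z <- list(W = matrix(0, 4, 3), Trans = matrix(0, 4, 3),
            labels = paste0("l", 1:3))
  expect_equal(score_sequence(z, random_feats(3, 4), c(1, 3, 2)), 0)
  expect_error(score_sequence(m, random_feats(2, 4), 1), "length mismatch")
})

test_that("viterbi matches exhaustive argmax on 200 random models", {
  withr::with_seed(42, {
    for (rep in 1:200) {
      L <- sample(2:5, 1)
      N <- sample(1:8, 1)
      nfeat <- sample(2:5, 1)
      m <- list(W = matrix(rnorm(nfeat * L), nfeat, L),
                Trans = matrix(rnorm((L + 1) * L), L + 1, L),
                labels = seq_len(L))
      feats <- lapply(seq_len(N), function(i) {
        sort(sample.int(nfeat, sample(1:nfeat, 1)))
      })
      v <- viterbi_decode(m, feats)
      labelings <- all_labelings(N, L)
      scores <- apply(labelings, 1, function(y) {
        brute_score(feats, y, m$W, m$Trans)
      })
      expect_equal(v$score, max(scores), tolerance = 1e-10)
      expect_equal(brute_score(feats, v$path, m$W, m$Trans), v$score,
                   tolerance = 1e-10)
    }
  })
})

test_that("viterbi ties break toward the lowest label index", {
  z <- list(W = matrix(0, 2, 3), Trans = matrix(0, 4, 3), labels = 1:3)
  expect_equal(viterbi_decode(z, random_feats(4, 2))$path, rep(1L, 4))
  # emissions forcing one label per position, zero transitions
  m <- list(W = diag(3) * 5, Trans = matrix(0, 4, 3), labels = 1:3)
  expect_equal(viterbi_decode(m, list(1L, 3L, 2L))$path, c(1L, 3L, 2L))
  expect_equal(viterbi_decode(m, list())$path, integer())
})

test_that("forward_backward log-partition matches brute-force enumeration", {
  # zero-weight closed forms first
  z <- list(W = matrix(0, 2, 4), Trans = matrix(0, 5, 4), labels = 1:4)
  expect_equal(forward_backward(z, random_feats(1, 2))$log_partition, log(4))
  fb <- forward_backward(z, random_feats(2, 2))
  expect_equal(fb$log_partition, 2 * log(4))
  expect_equal(unname(fb$marginals), matrix(0.25, 2, 4))
  withr::with_seed(17, {
    for (rep in 1:60) {
      L <- sample(2:4, 1)
      N <- sample(1:6, 1)
      nfeat <- 3
      m <- list(W = matrix(rnorm(nfeat * L), nfeat, L),
                Trans = matrix(rnorm((L + 1) * L), L + 1, L),
                labels = seq_len(L))
      feats <- random_feats(N, nfeat, seed = 100 + rep)
      fb <- forward_backward(m, feats, pairwise = TRUE)
      labelings <- all_labelings(N, L)
      scores <- apply(labelings, 1, function(y) {
        brute_score(feats, y, m$W, m$Trans)
      })
      lZ <- max(scores) + log(sum(exp(scores - max(scores))))
      expect_equal(fb$log_partition, lZ, tolerance = 1e-8)
      # node marginals agree with enumeration (absolute scale) and sum to one
      post <- exp(scores - lZ)
      expected <- matrix(0, N, L)
      for (t in seq_len(N)) {
        for (l in seq_len(L)) {
          expected[t, l] <- sum(post[labelings[, t] == l])
        }
      }
      expect_lt(max(abs(unname(fb$marginals) - expected)), 1e-8)
      expect_equal(unname(rowSums(fb$marginals)), rep(1, N), tolerance = 1e-8)
      if (N >= 2) {
        pm_expected <- matrix(0, L, L)
        for (a in seq_len(L)) {
          for (b in seq_len(L)) {
            pm_expected[a, b] <-
              sum(post[labelings[, 1] == a & labelings[, 2] == b])
          }
        }
        expect_lt(max(abs(fb$pairwise[[1]] - pm_expected)), 1e-8)
      }
    }
  })
})

test_that("loss-augmented decoding maximizes score plus Hamming loss", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      L <- sample(2:4, 1)
      N <- sample(1:6, 1)
      m <- list(W = matrix(rnorm(3 * L), 3, L),
                Trans = matrix(rnorm((L + 1) * L), L + 1, L),
                labels = seq_len(L))
      feats <- random_feats(N, 3, seed = 200 + rep)
      gold <- sample(L, N, replace = TRUE)
      la <- loss_augmented_decode(m, feats, gold)
      labelings <- all_labelings(N, L)
      objs <- apply(labelings, 1, function(y) {
        brute_score(feats, y, m$W, m$Trans) + sum(y != gold)
      })
      got <- brute_score(feats, la$path, m$W, m$Trans) + la$loss
      expect_equal(got, max(objs), tolerance = 1e-10)
      # argmax objective always >= gold objective (gold has loss 0)
      expect_gte(got + 1e-10, brute_score(feats, gold, m$W, m$Trans))
    }
  })
  # zero weights: maximizes loss alone, tie-break to lowest wrong label
  z <- list(W = matrix(0, 2, 3), Trans = matrix(0, 4, 3), labels = 1:3)
  la <- loss_augmented_decode(z, random_feats(3, 2), c(1L, 2L, 1L))
  expect_equal(la$loss, 3)
  expect_equal(la$path, c(2L, 1L, 2L))
  expect_error(loss_augmented_decode(z, random_feats(2, 2), c(1L, 1L),
                                     loss = "f1"), "unsupported loss")
})

test_that("cutting-plane objective matches the full-constraint QP oracle", {
  # tiny problem: 2 sequences, lengths <= 3, L = 2, few features
  withr::with_seed(31, {
    nfeat <- 2L; L <- 2L
    dataset <- list(
      list(feats = list(1L, c(1L, 2L), 2L), labels = c(1L, 2L, 2L)),
      list(feats = list(2L, 1L), labels = c(2L, 1L)))
    for (C in c(0.5, 2)) {
      fit <- clinner:::train_ssvm_core(
        dataset, nfeat, L,
        ssvm_control(C = C, epsilon = 1e-5))
      expect_true(fit$converged)
      oracle <- qp_oracle_objective(dataset, nfeat, L, C)
      expect_equal(tail(fit$objective, 1), oracle, tolerance = 1e-4)
      # 1-slack formulation reaches the same optimum
      fit1 <- clinner:::train_ssvm_core(
        dataset, nfeat, L,
        ssvm_control(C = C, epsilon = 1e-5, formulation = "1-slack"))
      expect_equal(tail(fit1$objective, 1), oracle, tolerance = 1e-4)
    }
  })
})

test_that("cutting-plane satisfies its own working-set constraints", {
  withr::with_seed(37, {
    nfeat <- 3L; L <- 3L
    dataset <- lapply(1:4, function(i) {
      N <- sample(2:4, 1)
      list(feats = random_feats(N, nfeat, seed = 300 + i),
           labels = sample(L, N, replace = TRUE))
    })
    ctl <- ssvm_control(C = 5, epsilon = 1e-3)
    fit <- clinner:::train_ssvm_core(dataset, nfeat, L, ctl)
    expect_true(fit$converged)
    # slack duality: every working-set constraint satisfied within epsilon
    A <- fit$working_set$A
    viol <- fit$working_set$delta - as.numeric(Matrix::crossprod(A, fit$theta))
    for (i in seq_along(dataset)) {
      js <- which(fit$working_set$ex == i)
      if (length(js)) {
        expect_lte(max(viol[js]), fit$xi[i] + ctl$epsilon + 1e-8)
      }
    }
    # restricted-QP objective is non-decreasing across re-solves
    expect_true(all(diff(fit$objective) >= -1e-8))
    # halving epsilon never lowers attainable objective precision:
    # tighter epsilon reaches an objective at least as large (closer to the
    # full optimum from below)
    fit2 <- clinner:::train_ssvm_core(dataset, nfeat, L,
                                      ssvm_control(C = 5, epsilon = 5e-4))
    expect_gte(tail(fit2$objective, 1), tail(fit$objective, 1) - 1e-6)
  })
})

test_that("SSVM drives training error to zero on a separable corpus", {
  doc <- fixture_separable()
  cfg <- feature_config(window = 1, templates = "word")
  m <- fit_ner(doc, tag_scheme("BIO"), cfg, "ssvm",
               control = ssvm_control(C = 10))
  ev <- evaluate_spans(doc, predict(m, doc), "exact")
  expect_equal(ev$f_measure[ev$class == "overall"], 1)
})

test_that("CRF analytic gradient matches central finite differences", {
  withr::with_seed(41, {
    nfeat <- 3L; L <- 3L; l2 <- 0.5
    dataset <- lapply(1:3, function(i) {
      N <- sample(2:4, 1)
      list(feats = random_feats(N, nfeat, seed = 400 + i),
           labels = sample(L, N, replace = TRUE))
    })
    D <- clinner:::theta_dim(nfeat, L)
    for (pt in 1:5) {
      theta <- rnorm(D, sd = 0.5)
      obj <- clinner:::crf_objective(theta, dataset, nfeat, L, l2)
      h <- 1e-5
      num <- vapply(seq_len(D), function(j) {
        tp <- theta; tm <- theta
        tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
        (clinner:::crf_objective(tp, dataset, nfeat, L, l2)$value -
           clinner:::crf_objective(tm, dataset, nfeat, L, l2)$value) / (2 * h)
      }, numeric(1))
      expect_equal(obj$grad, num, tolerance = 1e-5)
    }
  })
})

test_that("CRF training: L2 shrinks weights and separable data is learned", {
  doc <- fixture_separable()
  cfg <- feature_config(window = 1, templates = "word")
  m_small <- fit_ner(doc, tag_scheme("BIO"), cfg, "crf",
                     control = crf_control(l2 = 0.01))
  ev <- evaluate_spans(doc, predict(m_small, doc), "exact")
  expect_equal(ev$f_measure[ev$class == "overall"], 1)
  # penalty dominance: growing l2 shrinks the weight norm monotonically
  norms <- vapply(c(0.01, 1, 100), function(l2) {
    m <- fit_ner(doc, tag_scheme("BIO"), cfg, "crf",
                 control = crf_control(l2 = l2))
    sqrt(sum(m$W^2) + sum(m$Trans^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  # objective decreases as the iteration budget grows (monotone optimizer)
  dataset <- list(list(feats = list(1L, 2L), labels = c(1L, 2L)),
                  list(feats = list(2L, 1L), labels = c(2L, 1L)))
  vals <- vapply(c(2, 5, 50), function(it) {
    f <- suppressWarnings(
      clinner:::train_crf_core(dataset, 2L, 2L,
                               crf_control(l2 = 0.1, max_iter = it)))
    f$objective
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
})

test_that("both trainers reach 100% training F on the same separable fixture", {
  doc <- fixture_separable()
  cfg <- feature_config(window = 1, templates = "word")
  for (algo in c("ssvm", "crf")) {
    ctl <- if (algo == "ssvm") ssvm_control(C = 10) else crf_control(l2 = 0.01)
    m <- fit_ner(doc, tag_scheme("BIESO"), cfg, algo, control = ctl)
    ev <- evaluate_spans(doc, predict(m, doc), "exact")
    expect_equal(ev$f_measure[ev$class == "overall"], 1,
                 info = algo)
  }
})

test_that("prediction is deterministic and empty documents stay empty", {
  doc <- fixture_separable()
  cfg <- feature_config(window = 1, templates = "word")
  m <- fit_ner(doc, tag_scheme("BIO"), cfg, "ssvm",
               control = ssvm_control(C = 10))
  p1 <- predict(m, doc); p2 <- predict(m, doc)
  expect_identical(p1$spans, p2$spans)
  empty <- read_note_text("")
  pe <- predict(m, empty)
  expect_equal(nrow(pe$spans), 0)
})

test_that("models round-trip bit-exactly through write/read", {
  doc <- fixture_separable()
  m <- fit_ner(doc, tag_scheme("BIO"),
               feature_config(window = 1, templates = "word"), "ssvm",
               control = ssvm_control(C = 10))
  path <- tempfile(fileext = ".rds")
  write_ner_model(m, path)
  m2 <- read_ner_model(path)
  expect_identical(m2$W, m$W)
  expect_identical(m2$Trans, m$Trans)
  expect_identical(indexer_features(m2$indexer), indexer_features(m$indexer))
  p1 <- predict(m, doc); p2 <- predict(m2, doc)
  expect_identical(p1$spans, p2$spans)
  unlink(path)
})
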