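# Shared fixtures, built in code.

# Three-line note with two gold concepts.
fixture_note <- function(doc_id = "d1") {
  doc <- read_note_text(c("history of present illness :",
                          "patient has chest pain today",
                          "ordered cardiogram results pending"), doc_id)
  read_concepts(c('c="chest pain" 2:2 2:3||t="problem"',
                  'c="cardiogram" 3:1 3:1||t="test"'), doc)
}

# Separable toy corpus: one distinct token per entity, repeated contexts.
fixture_separable <- function(doc_id = "sep") {
  doc <- read_note_text(
    c("aa problemx bb", "cc treaty problemx", "testy aa bb",
      "bb problemx cc", "aa treaty cc", "cc testy aa"), doc_id)
  read_concepts(
    c('c="problemx" 1:1 1:1||t="problem"',
      'c="treaty" 2:1 2:1||t="treatment"',
      'c="problemx" 2:2 2:2||t="problem"',
      'c="testy" 3:0 3:0||t="test"',
      'c="problemx" 4:1 4:1||t="problem"',
      'c="treaty" 5:1 5:1||t="treatment"',
      'c="testy" 6:1 6:1||t="test"'), doc)
}

# Random small chain model over `L` labels and `nfeat` features.
random_chain_model <- function(L = 3, nfeat = 4, seed = 1) {
  withr::with_seed(seed, {
    list(W = matrix(rnorm(nfeat * L), nfeat, L),
         Trans = matrix(rnorm((L + 1) * L), L + 1, L),
         labels = paste0("l", seq_len(L)))
  })
}

# Random feature sequence: list of 1-based id vectors.
random_feats <- function(N, nfeat, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(N), function(i) {
      sort(sample.int(nfeat, sample(1:min(3, nfeat), 1)))
    })
  })
}

# All |L|^N labelings, one per row.
all_labelings <- function(N, L) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(L)), N)))
}

# Brute-force sequence score (independent of the C++ path).
brute_score <- function(feats, labels, W, Trans) {
  L <- ncol(W)
  s <- 0
  for (t in seq_along(labels)) {
    y <- labels[t]
    for (f in feats[[t]]) s <- s + W[f, y]
    prev <- if (t == 1) L + 1 else labels[t - 1]
    s <- s + Trans[prev, y]
  }
  s
}

# Corpus from per-sentence token vectors + span list (0-based offsets).
corpus_from_sentences <- function(sents, spans = NULL, doc_id = "doc") {
  toks <- tibble::tibble(
    doc_id = doc_id,
    line = rep(seq_along(sents), lengths(sents)),
    tok = unlist(lapply(lengths(sents), function(k) seq_len(k) - 1L)),
    text = unlist(sents))
  sp <- if (is.null(spans)) NULL else tibble::tibble(
    doc_id = doc_id,
    start_line = vapply(spans, `[[`, 1L, "line"),
    start_tok = vapply(spans, `[[`, 1L, "start"),
    end_line = vapply(spans, `[[`, 1L, "line"),
    end_tok = vapply(spans, `[[`, 1L, "end"),
    type = vapply(spans, `[[`, "", "type"),
    text = NA_character_)
  cp <- ner_corpus(toks, if (is.null(sp)) clinner:::empty_spans() else sp)
  if (!is.null(sp)) cp$spans$text <- clinner:::span_surface_text(cp)
  cp
}

# Primal QP oracle for the margin-rescaling program: enumerate every
# alternative labeling of every training sequence and solve
#   min 0.5 ||w||^2 + (C/m) sum_i xi_i
#   s.t. w' dPsi(i, y') >= loss(i, y') - xi_i  for all i, y' != gold; xi >= 0
# with quadprog's dual active-set method on the primal variables (w, xi).
# Independent of the package's cutting-plane / coordinate-ascent route.
qp_oracle_objective <- function(dataset, nfeat, L, C) {
  m <- length(dataset)
  D <- clinner:::theta_dim(nfeat, L)
  rows <- list() # rows: c(dpsi, e_i indicator for xi), rhs = loss
  rhs <- numeric(0)
  for (i in seq_along(dataset)) {
    inst <- dataset[[i]]
    N <- length(inst$labels)
    for (r in seq_len(L^N)) {
      yp <- arrayInd(r, rep(L, N))[1, ]
      if (all(yp == inst$labels)) next
      dp <- clinner:::psi_diff(inst$feats, inst$labels, yp, nfeat, L)
      row <- numeric(D + m)
      row[dp$i] <- dp$x
      row[D + i] <- 1
      rows[[length(rows) + 1]] <- row
      rhs <- c(rhs, sum(yp != inst$labels))
    }
  }
  for (i in seq_len(m)) { # xi_i >= 0
    z <- numeric(D + m); z[D + i] <- 1
    rows[[length(rows) + 1]] <- z
    rhs <- c(rhs, 0)
  }
  A <- t(do.call(rbind, rows))
  Dmat <- diag(c(rep(1, D), rep(1e-9, m))) # tiny ridge: xi enters linearly
  dvec <- c(rep(0, D), rep(-C / m, m))
  sol <- quadprog::solve.QP(Dmat, dvec, A, rhs)
  0.5 * sum(sol$solution[1:D]^2) + (C / m) * sum(sol$solution[D + 1:m])
}
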