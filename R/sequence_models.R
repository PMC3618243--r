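# Linear-chain scoring, decoding, and the two trainers (structural SVM by
# cutting plane; CRF by penalized conditional likelihood). Both share one
# parameterization: an emission weight block per label over the feature index
# plus an (L+1) x L transition matrix whose last row is the begin-of-sequence
# row. Transition features are label-pair indicators independent of the
# observations; all observation dependence is carried by the emission block.

# --- low-level wrappers ------------------------------------------------------

#' Score a labeling under a linear-chain model
#'
#' The discriminant is the sum over positions of the emission score of the
#' label at that position (sum of weights of the active features) plus the
#' transition weight from the previous label (begin-of-sequence row at
#' position 1).
#'
#' @param model An `ner_model` or a bare list with `W`, `Trans`, `labels`.
#' @param feats List of integer vectors: 1-based active feature ids per token.
#' @param labels Integer vector (1-based label indices) or character labels.
#' @return Scalar score.
#' @export
score_sequence <- function(model, feats, labels) {
  if (is.character(labels)) labels <- match(labels, model$labels)
  if (length(feats) != length(labels)) abort("length mismatch")
  if (anyNA(labels)) abort("label not in model inventory")
  chain_score_path(feats, as.integer(labels), model$W, model$Trans)
}

#' Viterbi decoding
#'
#' Returns the labeling maximizing [score_sequence()]; ties break toward the
#' lowest label index.
#'
#' @inheritParams score_sequence
#' @param cost Optional N x L matrix added to emission scores (used for
#'   margin-rescaled loss-augmented decoding).
#' @return List with `path` (integer labels, 1-based), `labels` (character),
#'   `score`.
#' @export
viterbi_decode <- function(model, feats, cost = NULL) {
  v <- chain_viterbi(feats, model$W, model$Trans, cost)
  v$labels <- model$labels[v$path]
  v
}

#' Loss-augmented decoding under per-token Hamming loss
#'
#' Finds `argmax_y score(x, y) + l(gold, y)` where `l` counts differing
#' positions — exact via Viterbi because Hamming loss decomposes per position.
#'
#' @inheritParams score_sequence
#' @param gold Integer or character gold labeling.
#' @param loss Loss name; only `"hamming"` decomposes and is supported.
#' @return As [viterbi_decode()], plus `loss` (Hamming distance to gold).
#' @export
loss_augmented_decode <- function(model, feats, gold, loss = "hamming") {
  if (!identical(loss, "hamming")) {
    abort("unsupported loss: only the Hamming loss decomposes per position")
  }
  if (is.character(gold)) gold <- match(gold, model$labels)
  N <- length(feats); L <- length(model$labels)
  cost <- matrix(1, N, L)
  cost[cbind(seq_len(N), gold)] <- 0
  v <- viterbi_decode(model, feats, cost)
  v$loss <- sum(v$path != gold)
  v
}

#' Forward-backward: log-partition and marginals
#'
#' Computed in log space.
#'
#' @inheritParams score_sequence
#' @param pairwise Also return pairwise marginals (list of L x L matrices for
#'   positions 2..N).
#' @return List with `log_partition`, `marginals` (N x L, rows sum to 1,
#'   columns named by label), and optionally `pairwise`.
#' @export
forward_backward <- function(model, feats, pairwise = FALSE) {
  out <- chain_forward_backward(feats, model$W, model$Trans, pairwise)
  colnames(out$marginals) <- model$labels
  out
}

# --- joint-feature-map plumbing ---------------------------------------------
# Parameter layout: theta = [vec(W) (nfeat x L, column-major), vec(Trans)].

theta_dim <- function(nfeat, L) nfeat * L + (L + 1L) * L

theta_split <- function(theta, nfeat, L) {
  list(W = matrix(theta[seq_len(nfeat * L)], nfeat, L),
       Trans = matrix(theta[nfeat * L + seq_len((L + 1) * L)], L + 1, L))
}

# Indices (with multiplicity) of Psi(x, y) in the theta layout.
psi_indices <- function(feats, labels, nfeat, L) {
  N <- length(labels)
  em <- unlist(purrr::map2(feats, labels,
                           function(f, y) f + (y - 1L) * nfeat),
               use.names = FALSE)
  prev <- c(L + 1L, labels[-N])
  tr <- nfeat * L + (labels - 1L) * (L + 1L) + prev
  c(em, tr)
}

# Sparse difference Psi(gold) - Psi(ybar) as list(i = indices, x = values).
psi_diff <- function(feats, gold, ybar, nfeat, L) {
  a <- psi_indices(feats, gold, nfeat, L)
  b <- psi_indices(feats, ybar, nfeat, L)
  idx <- c(a, b)
  val <- c(rep(1, length(a)), rep(-1, length(b)))
  agg <- rowsum(val, idx)
  keep <- agg[, 1] != 0
  list(i = as.integer(rownames(agg))[keep], x = agg[keep, 1])
}

# --- structural SVM by cutting plane ----------------------------------------

#' Control parameters for cutting-plane SSVM training
#'
#' @param C Margin/error trade-off (> 0); the slack penalty is `C/m` per
#'   example under the n-slack formulation.
#' @param epsilon Constraint violation tolerance (> 0): training stops when no
#'   example's most violated constraint is violated by more than `epsilon`.
#' @param max_passes Cap on passes over the training set.
#' @param formulation `"n-slack"` (one slack per example) or `"1-slack"`
#'   (a single shared slack over averaged constraints; same optimum, fewer
#'   constraints).
#' @return A list of class `ssvm_control`.
#' @export
ssvm_control <- function(C = 1, epsilon = 0.01, max_passes = NULL,
                         formulation = c("n-slack", "1-slack")) {
  if (!is.numeric(C) || C <= 0) abort("C must be > 0")
  if (!is.numeric(epsilon) || epsilon <= 0) abort("epsilon must be > 0")
  formulation <- match.arg(formulation)
  # 1-slack adds one constraint per pass and so needs a larger pass budget
  max_passes <- max_passes %||% if (formulation == "1-slack") 500 else 100
  structure(list(C = C, epsilon = epsilon, max_passes = max_passes,
                 formulation = formulation),
            class = "ssvm_control")
}

# dataset: list of list(feats = <list of int vectors>, labels = <int vector>)
train_ssvm_core <- function(dataset, nfeat, L, control = ssvm_control()) {
  m <- length(dataset)
  if (m == 0) abort("empty training set")
  D <- theta_dim(nfeat, L)
  one_slack <- control$formulation == "1-slack"
  n_groups <- if (one_slack) 1L else m
  cap <- if (one_slack) control$C else rep(control$C / m, m)
  A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(D, 0))
  delta <- numeric(0); ex <- integer(0); alpha <- numeric(0)
  K <- matrix(0, 0, 0)
  w <- numeric(D)
  xi <- numeric(n_groups)
  objective <- numeric(0)
  converged <- FALSE
  for (pass in seq_len(control$max_passes)) {
    th <- theta_split(w, nfeat, L)
    new_i <- list(); new_x <- list(); new_delta <- numeric(0); new_ex <- integer(0)
    if (one_slack) acc <- list(idx = integer(), val = numeric(), loss = 0)
    for (s in seq_len(m)) {
      inst <- dataset[[s]]
      la <- loss_augmented_decode(
        list(W = th$W, Trans = th$Trans, labels = seq_len(L)),
        inst$feats, inst$labels)
      dpsi <- psi_diff(inst$feats, inst$labels, la$path, nfeat, L)
      loss_s <- sum(la$path != inst$labels)
      if (one_slack) {
        acc$idx <- c(acc$idx, dpsi$i)
        acc$val <- c(acc$val, dpsi$x / m)
        acc$loss <- acc$loss + loss_s / m
      } else {
        viol <- loss_s - sum(w[dpsi$i] * dpsi$x) - xi[s]
        if (viol > control$epsilon) {
          new_i <- c(new_i, list(dpsi$i)); new_x <- c(new_x, list(dpsi$x))
          new_delta <- c(new_delta, loss_s); new_ex <- c(new_ex, s)
        }
      }
    }
    if (one_slack) {
      agg <- rowsum(acc$val, acc$idx)
      keep <- agg[, 1] != 0
      di <- as.integer(rownames(agg))[keep]; dx <- agg[keep, 1]
      viol <- acc$loss - sum(w[di] * dx) - xi[1]
      if (viol > control$epsilon) {
        new_i <- list(di); new_x <- list(dx)
        new_delta <- acc$loss; new_ex <- 1L
      }
    }
    if (length(new_delta) == 0) { converged <- TRUE; break }
    A_new <- Matrix::sparseMatrix(
      i = unlist(new_i), j = rep(seq_along(new_i), lengths(new_i)),
      x = unlist(new_x), dims = c(D, length(new_i)))
    # extend Gram matrix incrementally
    if (ncol(A) > 0) {
      K_cross <- as.matrix(Matrix::crossprod(A, A_new))
      K <- rbind(cbind(K, K_cross),
                 cbind(t(K_cross), as.matrix(Matrix::crossprod(A_new))))
    } else {
      K <- as.matrix(Matrix::crossprod(A_new))
    }
    A <- cbind(A, A_new)
    delta <- c(delta, new_delta)
    ex <- c(ex, new_ex)
    is_new <- c(rep(FALSE, length(alpha)), rep(TRUE, length(new_delta)))
    alpha <- c(alpha, numeric(length(new_delta)))
    alpha <- qp_dual_ascent(K, delta, ex, cap, alpha,
                            tol = control$epsilon / 20)
    w <- as.numeric(A %*% alpha)
    g <- delta - as.numeric(K %*% alpha)
    xi <- vapply(seq_len(n_groups), function(i) {
      js <- which(ex == i)
      if (!length(js)) 0 else max(0, max(g[js]))
    }, numeric(1))
    objective <- c(objective,
                   sum(alpha * delta) - 0.5 * sum(w * w)) # restricted-QP optimum
    # prune constraints inactive at the new solution (keeps the QP small; the
    # solution is unchanged and a pruned constraint can be re-added later)
    keep <- alpha > 0 | is_new
    if (!all(keep)) {
      A <- A[, keep, drop = FALSE]
      K <- K[keep, keep, drop = FALSE]
      delta <- delta[keep]; ex <- ex[keep]; alpha <- alpha[keep]
    }
  }
  th <- theta_split(w, nfeat, L)
  list(W = th$W, Trans = th$Trans, theta = w, xi = xi, alpha = alpha,
       working_set = list(A = A, delta = delta, ex = ex),
       objective = objective, converged = converged,
       n_passes = if (converged) pass else control$max_passes)
}

# --- CRF by penalized conditional likelihood ---------------------------------

#' Control parameters for CRF training
#'
#' @param l2 L2 penalty strength (>= 0); the objective is the negative
#'   conditional log-likelihood plus `l2/2 * ||w||^2`.
#' @param tol Projected-gradient tolerance for the L-BFGS-B optimizer.
#' @param max_iter Iteration cap.
#' @return A list of class `crf_control`.
#' @export
crf_control <- function(l2 = 1.0, tol = 1e-6, max_iter = 200) {
  if (!is.numeric(l2) || l2 < 0) abort("l2 must be >= 0")
  structure(list(l2 = l2, tol = tol, max_iter = max_iter),
            class = "crf_control")
}

# Objective and gradient in the flat theta layout (exported for gradient
# checking in tests via clinner:::crf_objective).
crf_objective <- function(theta, dataset, nfeat, L, l2) {
  th <- theta_split(theta, nfeat, L)
  out <- crf_negloglik_grad(dataset, th$W, th$Trans, l2)
  list(value = out$value, grad = c(as.numeric(out$grad_W), as.numeric(out$grad_T)))
}

train_crf_core <- function(dataset, nfeat, L, control = crf_control()) {
  if (length(dataset) == 0) abort("empty training set")
  D <- theta_dim(nfeat, L)
  fn <- function(theta) crf_objective(theta, dataset, nfeat, L, control$l2)$value
  gr <- function(theta) crf_objective(theta, dataset, nfeat, L, control$l2)$grad
  res <- optim(numeric(D), fn, gr, method = "L-BFGS-B",
               control = list(maxit = control$max_iter, pgtol = control$tol,
                              factr = 1e7))
  if (!res$convergence %in% c(0, 1)) {
    abort(sprintf("CRF optimizer failure (code %d): %s", res$convergence,
                  res$message %||% ""))
  }
  th <- theta_split(res$par, nfeat, L)
  list(W = th$W, Trans = th$Trans, theta = res$par, objective = res$value,
       converged = res$convergence == 0, n_iter = res$counts[["function"]])
}

# --- user-facing fit / predict ----------------------------------------------

#' Fit a clinical NER chain model
#'
#' Featurizes the corpus under `config`, encodes its gold spans under
#' `scheme`, and trains either a structural SVM (cutting-plane, margin
#' rescaling with Hamming loss) or an L2-penalized CRF over the identical
#' feature representation.
#'
#' @param corpus An `ner_corpus` with gold spans.
#' @param scheme A [tag_scheme()]; default BIESO over the corpus types.
#' @param config A [feature_config()].
#' @param algorithm `"ssvm"` or `"crf"`.
#' @param resources Named list of word-representation resources:
#'   `brown` (a [brown_clusters()] hierarchy), `thesaurus` (a
#'   [semantic_thesaurus()] table), `lexicons` (named list of term-to-tag
#'   tibbles). Required when the matching template is enabled.
#' @param control An [ssvm_control()] or [crf_control()]; defaults per
#'   algorithm.
#' @return An object of class `ner_model`.
#' @export
fit_ner <- function(corpus, scheme = NULL, config = feature_config(),
                    algorithm = c("ssvm", "crf"), resources = list(),
                    control = NULL) {
  algorithm <- match.arg(algorithm)
  scheme <- scheme %||% tag_scheme("BIESO", corpus$entity_types)
  control <- control %||%
    if (algorithm == "ssvm") ssvm_control() else crf_control()
  fz <- featurize_corpus(corpus, config, resources)
  gold <- encode_corpus_labels(corpus, scheme)
  L <- length(scheme$labels)
  dataset <- purrr::map2(fz$feats, gold, function(f, g) {
    list(feats = f, labels = match(g, scheme$labels))
  })
  nfeat <- indexer_size(fz$indexer)
  fit <- if (algorithm == "ssvm") {
    train_ssvm_core(dataset, nfeat, L, control)
  } else {
    train_crf_core(dataset, nfeat, L, control)
  }
  if (!isTRUE(fit$converged)) {
    warn(sprintf("%s training stopped before convergence", toupper(algorithm)))
  }
  structure(
    list(algorithm = algorithm, scheme = scheme, config = config,
         labels = scheme$labels, W = fit$W, Trans = fit$Trans,
         indexer = fz$indexer, resources = resources,
         objective = fit$objective, converged = fit$converged,
         control = control, entity_types = corpus$entity_types),
    class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf("<ner_model %s/%s> %d labels, %d features, converged: %s\n",
              toupper(x$algorithm), x$scheme$name, length(x$labels),
              nrow(x$W), x$converged))
  invisible(x)
}

#' Predict entity spans for new documents
#'
#' Features are extracted with the model's frozen indexer (unseen features are
#' dropped), each sentence is Viterbi-decoded, and the label sequences are
#' converted back to spans with lenient repair.
#'
#' @param object An `ner_model`.
#' @param newdata An `ner_corpus`.
#' @param ... Unused.
#' @return The corpus with predicted spans; attribute `labels` holds the raw
#'   per-sentence label sequences and `repairs` the decoder repair count.
#' @export
predict.ner_model <- function(object, newdata, ...) {
  fz <- featurize_corpus(newdata, object$config, object$resources,
                         indexer = object$indexer)
  labs <- purrr::map(fz$feats, function(f) viterbi_decode(object, f)$labels)
  out <- decode_corpus_labels(newdata, labs, object$scheme)
  attr(out, "labels") <- labs
  out
}

#' @export
tidy.ner_model <- function(x, ...) {
  feats <- indexer_features(x$indexer)
  em <- tibble::tibble(
    type = "emission",
    feature = rep(feats, times = length(x$labels)),
    label = rep(x$labels, each = length(feats)),
    from = NA_character_,
    weight = as.numeric(x$W))
  from_labs <- c(x$labels, "<BOS>")
  tr <- tibble::tibble(
    type = "transition",
    feature = NA_character_,
    label = rep(x$labels, each = length(from_labs)),
    from = rep(from_labs, times = length(x$labels)),
    weight = as.numeric(x$Trans))
  dplyr::filter(dplyr::bind_rows(em, tr), .data$weight != 0)
}

#' @export
glance.ner_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    scheme = x$scheme$name,
    n_labels = length(x$labels),
    n_features = nrow(x$W),
    n_parameters = length(x$W) + length(x$Trans),
    objective = if (length(x$objective)) tail(x$objective, 1) else NA_real_,
    converged = x$converged)
}

#' Save / load a fitted model
#'
#' Versioned container; weights round-trip bit-exactly.
#'
#' @param model An `ner_model`.
#' @param path File path.
#' @return `read_ner_model` returns the model; `write_ner_model` the path,
#'   invisibly.
#' @export
write_ner_model <- function(model, path) {
  payload <- unclass(model)
  payload$indexer <- indexer_features(model$indexer) # env -> character
  saveRDS(list(format = "clinner_model", version = 1L, model = payload), path)
  invisible(path)
}

#' @rdname write_ner_model
#' @export
read_ner_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "clinner_model")) abort("not a clinner model file")
  m <- obj$model
  m$indexer <- feature_indexer(m$indexer, frozen = TRUE)
  structure(m, class = "ner_model")
}
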