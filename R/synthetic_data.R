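# Synthetic clinical-note generator.
#
# Emulates the structure of the restricted i2b2 2010 concept-extraction data:
# discharge-summary-like notes with section headers, three entity types
# (problem, treatment, test) realized as 1-4 token phrases, and a controllable
# fraction of test-set entity surface forms that never occur in the labeled
# training data but do occur in the unlabeled corpus. Background text is drawn
# class-conditionally so that words of one semantic class share co-occurrence
# neighbours — the planted structure that Brown clustering and random indexing
# are expected to recover.

# Entity head words are syllable combinations assigned to the three types
# round-robin, so no prefix or suffix identifies a type (or entity-hood):
# recognizing an unseen head requires context or distributional information,
# which is the regime word-representation features target.
entity_head_vocab <- function() {
  syl1 <- c("ka", "re", "mo", "ta", "li", "zu", "ne", "po", "si", "da",
            "vo", "gu", "fe", "xo")
  syl2 <- c("rin", "dex", "lam", "tor", "bex", "nul", "gos", "pid", "vek",
            "zam", "fir", "lox", "nim")
  heads <- as.vector(t(outer(syl1, syl2, paste0))) # 182 distinct tokens
  idx <- seq_along(heads)
  list(problem = heads[idx %% 3 == 1],
       treatment = heads[idx %% 3 == 2],
       test = heads[idx %% 3 == 0])
}

generator_lexicon <- function() {
  list(
    heads = entity_head_vocab(),
    modifiers = c("acute", "chronic", "severe", "mild", "recurrent", "stable",
                  "elevated", "decreased", "bilateral", "left", "right",
                  "persistent", "worsening", "intermittent", "moderate"),
    context = list(
      problem = c("complains", "reports", "denies", "exacerbation",
                  "symptoms", "onset", "episodes", "flare"),
      treatment = c("prescribed", "started", "continued", "dose", "mg",
                    "daily", "tablet", "discontinued"),
      test = c("ordered", "revealed", "showed", "pending", "results",
               "value", "checked", "measured")),
    background = c("the", "patient", "was", "and", "a", "on", "in", "for",
                   "to", "no", "he", "she", "at", "this", "that", "with",
                   "of", "is", "were", "been", "also", "noted", "during",
                   "admission", "course", "home", "follow", "up"),
    sections = list(
      problem = c("history", "of", "present", "illness", ":"),
      treatment = c("medications", ":"),
      test = c("laboratory", "data", ":")))
}

# crude deterministic POS tags so the pos/combined templates have input
pos_lookup <- function(lex) {
  tags <- c(
    setNames(rep("NN", length(unlist(lex$heads))), unlist(lex$heads)),
    setNames(rep("JJ", length(lex$modifiers)), lex$modifiers),
    setNames(rep("VBD", length(unlist(lex$context))), unlist(lex$context)),
    setNames(rep("DT", length(lex$background)), lex$background))
  tags[":"] <- ":"
  tags
}

#' Synthetic-corpus generator configuration
#'
#' Defaults are the desk-scale stated world used throughout the test suite:
#' a 200k-token unlabeled corpus, 400 labeled training sentences, 400 labeled
#' test sentences, and 30% of distinct test entity surface forms absent from
#' training (the regime unsupervised word-representation features target).
#'
#' @param n_train_sentences,n_test_sentences Labeled corpus sizes (text lines
#'   including section headers).
#' @param n_unlabeled_tokens Minimum unlabeled corpus size in tokens.
#' @param oov_entity_fraction Fraction (per entity type) of distinct test-set
#'   entity surface forms that must not occur in training; all forms occur in
#'   the unlabeled corpus.
#' @param n_test_forms Distinct entity surface forms per type in the test set.
#' @param n_train_heads,n_reserved_heads Per type: head words available to
#'   training forms vs reserved for out-of-vocabulary test forms.
#' @param entity_length_probs Probabilities of entity phrase lengths 1-4.
#' @param slot_probs Probabilities of 0, 1, 2 entity slots per sentence.
#' @param sentences_per_section Content sentences under each section header.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_train_sentences = 400, n_test_sentences = 400,
                             n_unlabeled_tokens = 200000,
                             oov_entity_fraction = 0.3, n_test_forms = 20,
                             n_train_heads = 40, n_reserved_heads = 20,
                             entity_length_probs = c(0.45, 0.30, 0.15, 0.10),
                             slot_probs = c(0.15, 0.60, 0.25),
                             sentences_per_section = 8, seed = 1) {
  if (oov_entity_fraction < 0 || oov_entity_fraction > 1) {
    abort("oov_entity_fraction must be in [0, 1]")
  }
  if (abs(sum(entity_length_probs) - 1) > 1e-8 ||
      abs(sum(slot_probs) - 1) > 1e-8) {
    abort("probability vectors must sum to 1")
  }
  heads <- entity_head_vocab()
  if (n_train_heads + n_reserved_heads > length(heads$problem)) {
    abort("not enough head words for the requested train/reserved split")
  }
  structure(
    list(n_train_sentences = n_train_sentences,
         n_test_sentences = n_test_sentences,
         n_unlabeled_tokens = n_unlabeled_tokens,
         oov_entity_fraction = oov_entity_fraction,
         n_test_forms = n_test_forms,
         n_train_heads = n_train_heads, n_reserved_heads = n_reserved_heads,
         entity_length_probs = entity_length_probs, slot_probs = slot_probs,
         sentences_per_section = sentences_per_section, seed = seed),
    class = "generator_config")
}

sample_form <- function(heads, modifiers, length_probs) {
  len <- sample.int(4, 1, prob = length_probs)
  head_w <- sample(heads, 1)
  if (len == 1) return(head_w)
  c(sample(modifiers, len - 1), head_w)
}

# one content sentence; spans as parallel vectors (0-based inclusive offsets).
# Background segments mix function words with modifiers (so a modifier is not
# in itself an entity cue) and each entity is flanked by a type-specific
# context word only with probability ctx_prob (so context cues are helpful
# but not deterministic).
gen_sentence <- function(type_weights, form_pool, lex, slot_probs,
                         forced_form = NULL, forced_type = NULL,
                         ctx_prob = 0.7) {
  types <- names(type_weights)
  bgpool <- c(lex$background, lex$modifiers)
  bg <- function(k) bgpool[sample.int(length(bgpool), k, replace = TRUE)]
  toks <- bg(sample(2:4, 1))
  starts <- integer(); ends <- integer(); stypes <- character()
  n_slots <- sample(0:2, 1, prob = slot_probs)
  if (!is.null(forced_form)) n_slots <- max(1L, n_slots)
  for (k in seq_len(n_slots)) {
    if (k == 1 && !is.null(forced_form)) {
      ty <- forced_type
      form <- forced_form
    } else {
      ty <- sample(types, 1, prob = type_weights)
      form <- form_pool[[ty]][[sample.int(length(form_pool[[ty]]), 1)]]
    }
    ctx <- lex$context[[ty]]
    toks <- c(toks, if (runif(1) < ctx_prob) ctx[sample.int(length(ctx), 1)]
              else bg(1))
    starts <- c(starts, length(toks))
    toks <- c(toks, form)
    ends <- c(ends, length(toks) - 1L)
    stypes <- c(stypes, ty)
    toks <- c(toks, if (runif(1) < ctx_prob) ctx[sample.int(length(ctx), 1)]
              else bg(1), bg(sample(1:3, 1)))
  }
  list(tokens = toks, start = starts, end = ends, type = stypes)
}

build_labeled <- function(n_sentences, form_pool, lex, cfg, doc_prefix,
                          forced = NULL) {
  types <- names(lex$sections)
  tok_rows <- list(); span_rows <- list(); nl_rows <- list()
  line <- 0L; doc_no <- 1L; doc_id <- sprintf("%s_%03d", doc_prefix, doc_no)
  sec_i <- 0L
  total <- 0L
  forced_q <- forced # list of list(type=, form=) placed once each, FIFO
  while (total < n_sentences) {
    if (line == 0L || sec_i >= cfg$sentences_per_section + 1L) {
      if (line >= 3L * (cfg$sentences_per_section + 1L)) {
        # start a new document after the three sections
        nl_rows[[doc_id]] <- tibble::tibble(doc_id = doc_id, n_lines = line)
        doc_no <- doc_no + 1L
        doc_id <- sprintf("%s_%03d", doc_prefix, doc_no)
        line <- 0L
      }
      sec_ty <- types[(floor(line / (cfg$sentences_per_section + 1L))) %% 3 + 1]
      line <- line + 1L; total <- total + 1L; sec_i <- 1L
      hdr <- lex$sections[[sec_ty]]
      tok_rows[[length(tok_rows) + 1L]] <- tibble::tibble(
        doc_id = doc_id, line = line, tok = seq_along(hdr) - 1L, text = hdr)
      cur_weights <- setNames(rep(0.15, 3), types)
      cur_weights[sec_ty] <- 0.7
      next
    }
    forced_form <- NULL; forced_type <- NULL
    if (length(forced_q)) {
      forced_form <- forced_q[[1]]$form
      forced_type <- forced_q[[1]]$type
      forced_q <- forced_q[-1]
    }
    s <- gen_sentence(cur_weights, form_pool, lex, cfg$slot_probs,
                      forced_form, forced_type)
    line <- line + 1L; total <- total + 1L; sec_i <- sec_i + 1L
    tok_rows[[length(tok_rows) + 1L]] <- tibble::tibble(
      doc_id = doc_id, line = line, tok = seq_along(s$tokens) - 1L,
      text = s$tokens)
    if (length(s$start)) {
      span_rows[[length(span_rows) + 1L]] <- tibble::tibble(
        doc_id = doc_id, start_line = line, start_tok = s$start,
        end_line = line, end_tok = s$end, type = s$type,
        text = NA_character_)
    }
  }
  if (length(forced_q)) abort("not enough sentences to place all forced forms")
  nl_rows[[doc_id]] <- tibble::tibble(doc_id = doc_id, n_lines = line)
  toks <- dplyr::bind_rows(tok_rows)
  lex_pos <- pos_lookup(lex)
  toks$pos <- unname(lex_pos[toks$text])
  spans <- if (length(span_rows)) dplyr::bind_rows(span_rows) else empty_spans()
  corpus <- ner_corpus(toks, spans, dplyr::bind_rows(nl_rows))
  corpus$spans$text <- span_surface_text(corpus)
  corpus
}

#' Generate a synthetic clinical corpus
#'
#' Produces an unlabeled corpus (for word-representation training) and labeled
#' train/test corpora with gold spans. Exactly `round(oov_entity_fraction *
#' n_test_forms)` of each type's distinct test surface forms are built on
#' reserved head words that never occur in the training text; every form
#' occurs in the unlabeled corpus.
#'
#' @param config A [generator_config()].
#' @return List with `unlabeled` (character lines), `train`, `test`
#'   (`ner_corpus`), `config`, and `forms` (the per-type form inventories).
#' @export
generate_corpus <- function(config = generator_config()) {
  lex <- generator_lexicon()
  n_oov <- round(config$oov_entity_fraction * config$n_test_forms)
  withr::with_seed(config$seed, {
    types <- names(lex$heads)
    heads_split <- purrr::map(lex$heads, function(h) {
      h <- sample(h)
      list(train = h[seq_len(config$n_train_heads)],
           reserved = h[config$n_train_heads + seq_len(config$n_reserved_heads)])
    })
    make_forms <- function(heads, n) {
      forms <- list(); seen <- character()
      while (length(forms) < n) {
        f <- sample_form(heads, lex$modifiers, config$entity_length_probs)
        key <- paste(f, collapse = " ")
        if (!key %in% seen) {
          forms <- c(forms, list(f)); seen <- c(seen, key)
        }
      }
      forms
    }
    train_pool <- purrr::map(heads_split, function(h) make_forms(h$train, 30))
    reserved_pool <- purrr::map(heads_split, function(h) make_forms(h$reserved, 15))
    if (n_oov > length(reserved_pool[[1]])) {
      abort("infeasible oov_entity_fraction for the reserved form pool")
    }
    # unlabeled corpus: full form inventory, every form forced at least once
    full_pool <- purrr::map2(train_pool, reserved_pool, c)
    forced_all <- purrr::imap(full_pool, function(fl, ty) {
      purrr::map(fl, function(f) list(type = ty, form = f))
    })
    forced_all <- sample(unlist(forced_all, recursive = FALSE))
    unl_acc <- vector("list", 2048); unl_n <- 0L; unl_tokens <- 0L
    wts <- setNames(rep(1 / 3, 3), types)
    qi <- 1L
    while (unl_tokens < config$n_unlabeled_tokens) {
      ff <- if (qi <= length(forced_all)) forced_all[[qi]] else NULL
      qi <- qi + 1L
      s <- gen_sentence(wts, full_pool, lex, config$slot_probs,
                        ff$form, ff$type)
      unl_n <- unl_n + 1L
      if (unl_n > length(unl_acc)) unl_acc <- c(unl_acc, vector("list", length(unl_acc)))
      unl_acc[[unl_n]] <- s$tokens
      unl_tokens <- unl_tokens + length(s$tokens)
    }
    unl_lines <- vapply(unl_acc[seq_len(unl_n)], paste, "", collapse = " ")
    # training corpus from the train pool only
    train <- build_labeled(config$n_train_sentences, train_pool, lex,
                           config, "train")
    # test corpus: distinct forms = shared (seen in train) + reserved (OOV)
    seen_forms <- purrr::map(types, function(ty) {
      keys <- unique(tolower(train$spans$text[train$spans$type == ty]))
      purrr::keep(train_pool[[ty]],
                  function(f) paste(f, collapse = " ") %in% keys)
    })
    names(seen_forms) <- types
    n_shared <- config$n_test_forms - n_oov
    test_pool <- purrr::map(types, function(ty) {
      if (length(seen_forms[[ty]]) < n_shared) {
        abort("training corpus too small to expose enough shared forms")
      }
      c(sample(seen_forms[[ty]], n_shared),
        if (n_oov > 0) sample(reserved_pool[[ty]], n_oov) else list())
    })
    names(test_pool) <- types
    forced_test <- purrr::imap(test_pool, function(fl, ty) {
      purrr::map(fl, function(f) list(type = ty, form = f))
    })
    forced_test <- sample(unlist(forced_test, recursive = FALSE))
    test <- build_labeled(config$n_test_sentences, test_pool, lex, config,
                          "test", forced = forced_test)
    list(unlabeled = unl_lines, train = train, test = test, config = config,
         forms = list(train = train_pool, reserved = reserved_pool,
                      test = test_pool))
  })
}

#' Corpus summary statistics
#'
#' Counts of sentences, tokens and entities per type, and (given a reference
#' corpus) the fraction of distinct entity surface forms absent from the
#' reference — the out-of-vocabulary entity fraction.
#'
#' @param corpus An `ner_corpus`.
#' @param reference Optional reference `ner_corpus` (e.g. the training set).
#' @return One-row tibble.
#' @export
corpus_stats <- function(corpus, reference = NULL) {
  sp <- corpus$spans
  per_type <- purrr::map_int(corpus$entity_types,
                             function(ty) sum(sp$type == ty))
  oov <- NA_real_
  if (!is.null(reference)) {
    test_forms <- unique(tolower(sp$text))
    ref_forms <- unique(tolower(reference$spans$text))
    oov <- if (length(test_forms)) {
      mean(!test_forms %in% ref_forms)
    } else NA_real_
  }
  out <- tibble::tibble(
    n_documents = dplyr::n_distinct(corpus$tokens$doc_id),
    n_sentences = n_sentences(corpus),
    n_tokens = nrow(corpus$tokens),
    n_entities = nrow(sp),
    oov_entity_fraction = oov)
  for (i in seq_along(corpus$entity_types)) {
    out[[paste0("n_", corpus$entity_types[i])]] <- per_type[i]
  }
  out
}

#' Two-class corpus with planted bigram affinity
#'
#' Sentences are runs of words drawn class-conditionally: within a run all
#' words come from one class, so adjacent-bigram statistics separate the
#' classes — the structure Brown clustering's top split should recover.
#'
#' @param n_sentences Number of sentences.
#' @param vocab_per_class Words per class (named `a...` and `b...`).
#' @param runs_per_sentence Class runs per sentence.
#' @param run_length Words per run.
#' @param seed Seed.
#' @return List with `lines` (character) and `classes` (named vector
#'   word -> "a"/"b").
#' @export
generate_two_class_corpus <- function(n_sentences = 400, vocab_per_class = 15,
                                      runs_per_sentence = 3, run_length = 4,
                                      seed = 1) {
  va <- sprintf("alpha%02d", seq_len(vocab_per_class))
  vb <- sprintf("beta%02d", seq_len(vocab_per_class))
  lines <- withr::with_seed(seed, {
    purrr::map_chr(seq_len(n_sentences), function(i) {
      toks <- unlist(purrr::map(seq_len(runs_per_sentence), function(j) {
        if (runif(1) < 0.5) sample(va, run_length, replace = TRUE)
        else sample(vb, run_length, replace = TRUE)
      }))
      paste(toks, collapse = " ")
    })
  })
  list(lines = lines,
       classes = c(setNames(rep("a", vocab_per_class), va),
                   setNames(rep("b", vocab_per_class), vb)))
}
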