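# Experiment wiring: feature-set x tag-scheme x algorithm grids and
# cross-validated hyperparameter tuning.

#' Run a scheme x feature-set x algorithm experiment grid
#'
#' Trains one model per grid cell on `train`, predicts on `test`, and reports
#' exact-mode overall F/recall/precision per cell. A failing cell is recorded
#' (column `error`) and the grid continues.
#'
#' @param train,test `ner_corpus` objects with gold spans.
#' @param schemes Character vector of scheme names (`"BIO"`, `"BIESO"`).
#' @param feature_sets Named list of [feature_config()] objects.
#' @param algorithms Character vector among `"ssvm"`, `"crf"`.
#' @param resources Word-representation resources passed to [fit_ner()].
#' @param controls Optional named list `ssvm`/`crf` of control objects.
#' @return Tibble: one row per cell with `scheme`, `features`, `algorithm`,
#'   `f_measure`, `recall`, `precision`, `error`.
#' @export
run_experiment_grid <- function(train, test, schemes = c("BIO", "BIESO"),
                                feature_sets = list(base = feature_config()),
                                algorithms = c("ssvm", "crf"),
                                resources = list(), controls = list()) {
  grid <- tidyr::expand_grid(scheme = schemes,
                             features = names(feature_sets),
                             algorithm = algorithms)
  purrr::pmap_dfr(grid, function(scheme, features, algorithm) {
    res <- tryCatch({
      model <- fit_ner(train, tag_scheme(scheme, train$entity_types),
                       config = feature_sets[[features]],
                       algorithm = algorithm, resources = resources,
                       control = controls[[algorithm]])
      pred <- predict(model, test)
      ev <- evaluate_spans(test, pred, mode = "exact")
      ov <- ev[ev$class == "overall", ]
      tibble::tibble(f_measure = ov$f_measure, recall = ov$recall,
                     precision = ov$precision, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(f_measure = NA_real_, recall = NA_real_,
                     precision = NA_real_, error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(scheme = scheme, features = features,
                                    algorithm = algorithm), res)
  })
}

#' Format a grid report as "F (R/P)" percentage cells
#'
#' One row per scheme x feature set, one column per algorithm, percentages to
#' two decimals.
#'
#' @param grid Result of [run_experiment_grid()].
#' @return Tibble in wide layout.
#' @export
format_grid_report <- function(grid) {
  grid |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$f_measure), paste0("ERROR: ", .data$error),
      sprintf("%.2f(%.2f/%.2f)", 100 * .data$f_measure, 100 * .data$recall,
              100 * .data$precision))) |>
    dplyr::select("scheme", "features", "algorithm", "cell") |>
    tidyr::pivot_wider(names_from = "algorithm", values_from = "cell")
}

#' Tune hyperparameters by k-fold cross-validation
#'
#' Sentences are partitioned into `folds` folds (deterministically per seed);
#' each grid point is scored by the mean exact-mode overall F over folds and
#' the best point is returned, ties resolved toward the smallest parameter
#' values.
#'
#' @param corpus Training `ner_corpus` with gold spans.
#' @param param_grid Tibble of candidate hyperparameters: column `C` for
#'   SSVM or `l2` for CRF (extra columns are passed through).
#' @param folds Number of folds (default 10, the conventional choice).
#' @param seed Seed for the fold partition.
#' @param algorithm `"ssvm"` or `"crf"`.
#' @param scheme A [tag_scheme()].
#' @param config A [feature_config()].
#' @param resources Passed to [fit_ner()].
#' @param fold_unit `"sentence"` (default) or `"document"`.
#' @return List with `best` (one-row tibble) and `results` (mean F per point).
#' @export
cv_tune <- function(corpus, param_grid, folds = 10, seed = 1,
                    algorithm = c("ssvm", "crf"), scheme = NULL,
                    config = feature_config(), resources = list(),
                    fold_unit = c("sentence", "document")) {
  algorithm <- match.arg(algorithm)
  fold_unit <- fold_unit[1]
  scheme <- scheme %||% tag_scheme("BIESO", corpus$entity_types)
  param_grid <- tibble::as_tibble(param_grid)
  if (nrow(param_grid) == 0) abort("empty parameter grid")
  if (algorithm == "ssvm" && any(param_grid$C <= 0)) abort("C must be > 0")
  if (algorithm == "crf" && any(param_grid$l2 < 0)) abort("l2 must be >= 0")
  idx <- sentence_index(corpus)
  units <- if (fold_unit == "sentence") {
    paste(idx$doc_id, idx$line)
  } else {
    unique(idx$doc_id)
  }
  if (folds > length(units)) abort("more folds than units")
  fold_of <- withr::with_seed(seed, {
    setNames(sample(rep_len(seq_len(folds), length(units))), units)
  })
  sent_fold <- if (fold_unit == "sentence") {
    fold_of[paste(idx$doc_id, idx$line)]
  } else {
    fold_of[idx$doc_id]
  }
  subset_corpus <- function(keep) {
    kidx <- idx[keep, ]
    kk <- paste(corpus$tokens$doc_id, corpus$tokens$line) %in%
      paste(kidx$doc_id, kidx$line)
    sk <- paste(corpus$spans$doc_id, corpus$spans$start_line) %in%
      paste(kidx$doc_id, kidx$line)
    ner_corpus(corpus$tokens[kk, ], corpus$spans[sk, ],
               entity_types = corpus$entity_types)
  }
  results <- purrr::map_dfr(seq_len(nrow(param_grid)), function(gi) {
    ctrl <- if (algorithm == "ssvm") {
      ssvm_control(C = param_grid$C[gi])
    } else {
      crf_control(l2 = param_grid$l2[gi])
    }
    fs <- purrr::map_dbl(seq_len(folds), function(fd) {
      tr <- subset_corpus(sent_fold != fd)
      te <- subset_corpus(sent_fold == fd)
      if (n_sentences(te) == 0 || nrow(te$spans) == 0) return(NA_real_)
      model <- fit_ner(tr, scheme, config, algorithm, resources, ctrl)
      ev <- evaluate_spans(te, predict(model, te), mode = "exact")
      ev$f_measure[ev$class == "overall"]
    })
    dplyr::bind_cols(param_grid[gi, ],
                     tibble::tibble(mean_f = mean(fs, na.rm = TRUE)))
  })
  ord <- do.call(order, c(list(-results$mean_f),
                          as.list(param_grid)))
  list(best = results[ord[1], ], results = results)
}
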