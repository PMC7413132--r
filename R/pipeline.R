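# End-to-end orchestration: apply LFs, fit the generative model, route via
# the heuristic optimizer, optionally distill through the auxiliary text
# model, train the target-modality model with the noise-aware loss, and
# evaluate — with every stochastic stage seeded from one master seed.

#' Pipeline configuration
#'
#' @param coverage_threshold,auc_threshold Routing thresholds of the
#'   heuristic optimizer (defaults 0.90/0.90): the auxiliary distillation
#'   model is trained only if generative-model coverage *or* ROC-AUC on the
#'   development set falls below its threshold.
#' @param tie_policy Majority-vote tie policy (see [majority_vote()]).
#' @param learn_prior Learn the class prior in the generative model.
#' @param aux_spec,target_spec [classifier_spec()] objects for the auxiliary
#'   and target models (their seeds are overridden by derivations from
#'   `seed`).
#' @param include_fully_supervised Also train the fully supervised
#'   comparator arm (same target architecture, hand labels) — every
#'   headline contrast for this method is weak-vs-full supervision, so the
#'   comparator is part of the runner.
#' @param seed Master seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(coverage_threshold = 0.90, auc_threshold = 0.90,
                            tie_policy = "half", learn_prior = TRUE,
                            aux_spec = classifier_spec("auxiliary_text"),
                            target_spec = classifier_spec("target_features"),
                            include_fully_supervised = TRUE, seed = 1L) {
  if (coverage_threshold <= 0 || coverage_threshold > 1 ||
      auc_threshold <= 0 || auc_threshold > 1) {
    abort("routing thresholds must lie in (0, 1].")
  }
  structure(list(coverage_threshold = coverage_threshold,
                 auc_threshold = auc_threshold, tie_policy = tie_policy,
                 learn_prior = learn_prior, aux_spec = aux_spec,
                 target_spec = target_spec,
                 include_fully_supervised = isTRUE(include_fully_supervised),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Heuristic label-source routing
#'
#' The optimizer rule: train the auxiliary distillation model only if either
#' generative-model coverage or ROC-AUC on the development set is less than
#' the configured threshold (default 90%); otherwise use the
#' generative-model labels directly and save the computation.
#'
#' @param dev_coverage Generative-model coverage on the development set.
#' @param dev_auc Generative-model ROC-AUC on the (covered) development set.
#' @param config A [pipeline_config()] (or anything with the two threshold
#'   fields).
#' @return `"use_GM"` or `"use_AUX"`.
#' @export
#' @examples
#' decide_label_source(0.95, 0.95)  # "use_GM"
#' decide_label_source(0.85, 0.95)  # "use_AUX"
decide_label_source <- function(dev_coverage, dev_auc,
                                config = pipeline_config()) {
  stopifnot_scalar_prob(dev_coverage, "dev_coverage")
  stopifnot_scalar_prob(dev_auc, "dev_auc")
  if (dev_coverage < config$coverage_threshold ||
      dev_auc < config$auc_threshold) "use_AUX" else "use_GM"
}

pipeline_dataset <- function(dataset) {
  if (inherits(dataset, "xm_corpus")) dataset <- dataset$data
  dataset <- as_tibble(dataset)
  need <- c("id", "split", "text", "hand_label")
  if (!all(need %in% names(dataset))) {
    abort(paste("dataset needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(dataset$id)) abort("dataset ids must be unique.")
  for (s in c("dev", "test")) {
    lab <- dataset$hand_label[dataset$split == s]
    if (length(lab) == 0L || anyNA(lab)) {
      abort(sprintf("the %s split must be non-empty and fully hand-labeled.", s))
    }
  }
  dataset
}

#' Run the full cross-modal data-programming pipeline
#'
#' Applies the labeling functions, fits the generative label model on the
#' training split, computes development-set coverage and ROC-AUC (the
#' latter over covered dev rows only), routes via [decide_label_source()],
#' optionally trains the auxiliary text model on covered rows and distills
#' full-coverage labels, then trains the target-modality model with the
#' noise-aware loss and evaluates it on the test split. When configured, a
#' fully supervised comparator (same architecture, hand labels) is trained
#' alongside. Development hand labels are used only for the routing rule
#' and early stopping — never for fitting the generative model.
#'
#' @param dataset An `xm_corpus` (see [generate_corpus()]) or a tibble with
#'   columns `id`, `split`, `text`, `hand_label` and numeric target feature
#'   columns.
#' @param lfs A list of [labeling_function()]s.
#' @param config A [pipeline_config()].
#' @return An `xm_pipeline` object; see [glance.xm_pipeline()] for the
#'   one-row summary and `$metrics` for the test-set evaluation.
#' @export
run_cross_modal_pipeline <- function(dataset, lfs,
                                     config = pipeline_config()) {
  t0 <- Sys.time()
  data <- pipeline_dataset(dataset)
  train <- data[data$split == "train", ]
  dev <- data[data$split == "dev", ]
  test <- data[data$split == "test", ]
  if (length(unique(dev$hand_label)) < 2L) {
    abort("the development set must contain both classes (ROC-AUC is undefined otherwise).")
  }
  seeds <- list(gm = derive_seed(config$seed, 1L),
                aux = derive_seed(config$seed, 2L),
                target = derive_seed(config$seed, 3L),
                fs = derive_seed(config$seed, 4L))

  # Stage 1: labeling functions.
  lambda_train <- apply_labeling_functions(train, lfs)
  lambda_dev <- apply_labeling_functions(dev, lfs)
  if (label_coverage(lambda_train) == 0) {
    abort("every labeling function abstained on every training example.")
  }

  # Stage 2: generative label model (training split only; no hand labels).
  gm <- fit_generative_model(lambda_train, learn_prior = config$learn_prior,
                             seed = seeds$gm)
  gm_train <- posterior_labels(lambda_train, gm)
  gm_dev <- posterior_labels(lambda_dev, gm)

  # Stage 3: heuristic optimizer on the development set.
  dev_coverage <- label_coverage(lambda_dev)
  cov_dev <- gm_dev$covered
  dev_auc <- roc_auc(gm_dev$p_pos[cov_dev], dev$hand_label[cov_dev])
  decision <- decide_label_source(dev_coverage, dev_auc, config)

  # Stage 4: optional cross-modal distillation.
  aux_model <- NULL
  if (decision == "use_AUX") {
    aux_spec <- config$aux_spec; aux_spec$seed <- seeds$aux
    dev_aux <- dev[c("id", "text", "tokens"[("tokens" %in% names(dev))])]
    dev_aux$label <- dev$hand_label
    aux_model <- train_probabilistic_classifier(train, gm_train, aux_spec,
                                                dev = dev_aux)
    labels_used <- distill_labels(aux_model, train)
  } else {
    labels_used <- gm_train
  }

  # Stage 5: noise-aware target-modality training.
  tgt_spec <- config$target_spec; tgt_spec$seed <- seeds$target
  dev_tgt <- dev; dev_tgt$label <- dev$hand_label
  target_model <- train_probabilistic_classifier(train, labels_used, tgt_spec,
                                                 dev = dev_tgt)
  test_scores <- predict(target_model, test)
  metrics <- evaluation_report(test_scores, test$hand_label)
  metrics$label_source <- labels_used$source[1]

  # Fully supervised comparator arm.
  fs_model <- NULL; fs_metrics <- NULL
  if (config$include_fully_supervised) {
    if (anyNA(train$hand_label)) {
      warn("training split lacks hand labels; skipping the fully supervised arm.")
    } else {
      fs_spec <- config$target_spec; fs_spec$seed <- seeds$fs
      fs_model <- train_probabilistic_classifier(
        train, tibble(id = train$id, label = train$hand_label), fs_spec,
        dev = dev_tgt)
      fs_scores <- predict(fs_model, test)
      fs_metrics <- evaluation_report(fs_scores, test$hand_label)
      fs_metrics$label_source <- "FS"
    }
  }

  structure(list(
    label_matrix = lambda_train, gm = gm, labels_used = labels_used,
    decision = list(decision = decision, dev_coverage = dev_coverage,
                    dev_auc = dev_auc,
                    coverage_threshold = config$coverage_threshold,
                    auc_threshold = config$auc_threshold),
    aux_model = aux_model, target_model = target_model,
    fs_model = fs_model, metrics = metrics, fs_metrics = fs_metrics,
    test_scores = tibble(id = test$id, p_pos = test_scores),
    config = config, seeds = seeds,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "xm_pipeline")
}

#' @export
print.xm_pipeline <- function(x, ...) {
  cat("<xm_pipeline>\n")
  cat(sprintf("  routing: %s (dev coverage %.3f, dev ROC-AUC %.3f)\n",
              x$decision$decision, x$decision$dev_coverage, x$decision$dev_auc))
  cat(sprintf("  labels used: %s; test ROC-AUC %.3f\n",
              x$labels_used$source[1], x$metrics$roc_auc))
  if (!is.null(x$fs_metrics)) {
    cat(sprintf("  fully supervised comparator: test ROC-AUC %.3f (gap %+.3f)\n",
                x$fs_metrics$roc_auc, x$metrics$roc_auc - x$fs_metrics$roc_auc))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `xm_pipeline`.
#' @param ... Unused.
#' @return A tibble with the routing decision, dev metrics, test ROC-AUC of
#'   the weakly supervised model and (when run) the fully supervised
#'   comparator.
#' @method glance xm_pipeline
#' @export
glance.xm_pipeline <- function(x, ...) {
  tibble(decision = x$decision$decision,
         dev_coverage = x$decision$dev_coverage,
         dev_auc = x$decision$dev_auc,
         label_source = x$labels_used$source[1],
         test_auc = x$metrics$roc_auc,
         fs_test_auc = if (is.null(x$fs_metrics)) NA_real_
                       else x$fs_metrics$roc_auc,
         seed = x$config$seed)
}

#' @method tidy xm_pipeline
#' @export
tidy.xm_pipeline <- function(x, ...) {
  out <- x$metrics
  if (!is.null(x$fs_metrics)) out <- bind_rows(out, x$fs_metrics)
  out |> select(all_of("label_source"), dplyr::everything())
}
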