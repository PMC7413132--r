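# Label-source ablations and data-scaling experiments.

#' Normal-approximation confidence interval over seed replicates
#'
#' Mean and 95% (by default) confidence interval across independent seeded
#' runs, assuming a normally distributed population of replicates.
#'
#' @param x Numeric vector of per-seed values.
#' @param level Confidence level.
#' @return A named numeric vector: `mean`, `lower`, `upper`.
#' @export
replicate_ci <- function(x, level = 0.95) seed_ci(x, level)

#' Label-source ablation
#'
#' Runs the five supervision arms — majority vote (MV), generative model
#' (GM), distillation models trained on each (DM-MV, DM-GM), and full
#' supervision (FS) — under a shared seed schedule, reporting for each arm
#' the development-set label coverage and label ROC-AUC (against dev hand
#' labels; covered rows only for MV/GM, all rows for DM-*) and the test
#' ROC-AUC of a target-modality model trained on that arm's labels. MV and
#' GM label metrics are deterministic; classifier training varies by seed.
#'
#' @param dataset An `xm_corpus` or pipeline-shaped tibble (see
#'   [run_cross_modal_pipeline()]).
#' @param lfs Labeling functions.
#' @param config A [pipeline_config()].
#' @param n_seeds Number of seed replicates (default 5).
#' @return An `xm_ablation` object with `$per_seed` (long tibble) and
#'   `$summary` (per-arm mean and 95% CI per metric).
#' @export
compare_label_sources <- function(dataset, lfs, config = pipeline_config(),
                                  n_seeds = 5L) {
  data <- pipeline_dataset(dataset)
  train <- data[data$split == "train", ]
  dev <- data[data$split == "dev", ]
  test <- data[data$split == "test", ]
  if (anyNA(train$hand_label)) {
    abort("the FS arm needs hand labels on the training split.")
  }
  lambda_train <- apply_labeling_functions(train, lfs)
  lambda_dev <- apply_labeling_functions(dev, lfs)

  mv_train <- majority_vote(lambda_train, config$tie_policy)
  mv_dev <- majority_vote(lambda_dev, config$tie_policy)
  gm <- fit_generative_model(lambda_train, learn_prior = config$learn_prior,
                             seed = config$seed)
  gm_train <- posterior_labels(lambda_train, gm)
  gm_dev <- posterior_labels(lambda_dev, gm)

  dev_quality <- function(labels_dev) {
    keep <- labels_dev$covered
    tibble(label_coverage = mean(keep),
           label_auc = roc_auc(labels_dev$p_pos[keep], dev$hand_label[keep]))
  }
  dev_tgt <- dev; dev_tgt$label <- dev$hand_label

  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed_s <- derive_seed(config$seed, 100L + s)
    arm_labels <- list(MV = mv_train, GM = gm_train)
    arm_quality <- list(MV = dev_quality(mv_dev), GM = dev_quality(gm_dev))
    for (base in c("MV", "GM")) {
      aux_spec <- config$aux_spec
      aux_spec$seed <- derive_seed(seed_s, if (base == "MV") 1L else 2L)
      aux <- train_probabilistic_classifier(train, arm_labels[[base]],
                                            aux_spec, dev = dev_tgt)
      dm <- paste0("DM-", base)
      arm_labels[[dm]] <- distill_labels(aux, train)
      arm_quality[[dm]] <- tibble(
        label_coverage = 1,
        label_auc = roc_auc(predict(aux, dev), dev$hand_label))
    }
    arm_labels$FS <- tibble(id = train$id, label = train$hand_label)
    arm_quality$FS <- tibble(label_coverage = 1, label_auc = 1)

    for (arm in names(arm_labels)) {
      tgt_spec <- config$target_spec
      tgt_spec$seed <- derive_seed(seed_s, 10L + match(arm, names(arm_labels)))
      model <- train_probabilistic_classifier(train, arm_labels[[arm]],
                                              tgt_spec, dev = dev_tgt)
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(source = arm, seed = s), arm_quality[[arm]],
        tibble(test_auc = roc_auc(predict(model, test), test$hand_label)))
    }
  }
  per_seed <- bind_rows(rows)
  summary <- per_seed |>
    tidyr::pivot_longer(c("label_coverage", "label_auc", "test_auc"),
                        names_to = "metric") |>
    group_by(.data$source, .data$metric) |>
    summarise(mean = mean(.data$value),
              lower = replicate_ci(.data$value)[["lower"]],
              upper = replicate_ci(.data$value)[["upper"]],
              .groups = "drop")
  structure(list(per_seed = per_seed, summary = summary,
                 n_seeds = n_seeds, seed = config$seed),
            class = "xm_ablation")
}

#' @export
print.xm_ablation <- function(x, ...) {
  cat("<xm_ablation>", x$n_seeds, "seed replicates\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' @method tidy xm_ablation
#' @export
tidy.xm_ablation <- function(x, ...) x$summary

#' Data-scaling experiment
#'
#' For each unlabeled training-set size in `n_grid` and each seed: simulate,
#' fit the generative model, and record the mean absolute error of the
#' estimated LF accuracies against their true values — and optionally the
#' weakly supervised target model's test ROC-AUC from a full pipeline run.
#' The log-log slope of mean accuracy error versus n is fit by least
#' squares; estimation error is expected to shrink at roughly the n^(-1/2)
#' rate.
#'
#' With `source = "model"` (the default for the estimation-error measure)
#' vote matrices are drawn directly from the symmetric generative model at
#' the config's analytic LF statistics via [simulate_label_matrix()] — the
#' well-specified setting the n^(-1/2) bound describes. With
#' `source = "corpus"` full report corpora are generated and labeled by the
#' built-in LFs; paired keyword/negation rules are then deterministically
#' dependent given the class, so accuracy estimates carry a small
#' asymptotic bias and the error plateaus at large n.
#'
#' @param config A [synthetic_config()]; its `n_train` is overridden by the
#'   grid and its `seed` seeds the whole schedule.
#' @param n_grid Strictly increasing training sizes (at least 3).
#' @param n_seeds Seed replicates per grid point.
#' @param measure `"alpha_error"`, `"auc"`, or both. Measuring AUC forces
#'   `source = "corpus"` (the pipeline needs paired data).
#' @param source `"model"` or `"corpus"` (see above).
#' @param pipeline_cfg Pipeline configuration used when measuring AUC.
#' @return An `xm_scaling` object: `$results` (per n and seed), `$summary`
#'   (per-n means and CIs), `$slope` (log-log slope of mean alpha error;
#'   `NA` if not measured).
#' @export
scaling_experiment <- function(config, n_grid = c(500L, 2000L, 8000L, 32000L),
                               n_seeds = 5L,
                               measure = "alpha_error",
                               source = c("model", "corpus"),
                               pipeline_cfg = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  measure <- match.arg(measure, c("alpha_error", "auc"), several.ok = TRUE)
  source <- match.arg(source)
  if ("auc" %in% measure) source <- "corpus"
  if (length(n_grid) < 3L || any(diff(n_grid) <= 0)) {
    abort("`n_grid` must be strictly increasing with at least 3 points.")
  }
  truth <- analytic_lf_statistics(config)
  rows <- list()
  if (source == "model") {
    for (i in seq_along(n_grid)) {
      for (s in seq_len(n_seeds)) {
        seed_is <- derive_seed(config$seed, i * 1000L + s)
        sim <- simulate_label_matrix(truth$accuracy, truth$propensity,
                                     config$class_prior, n_grid[i],
                                     seed = seed_is)
        gm <- fit_generative_model(sim$matrix, seed = seed_is)
        rows[[length(rows) + 1L]] <- tibble(
          n = n_grid[i], seed = s,
          alpha_error = mean(abs(gm$alpha - truth$accuracy)),
          beta_error = mean(abs(gm$beta - truth$propensity)))
      }
    }
  } else {
    # Per replicate: one corpus at the largest grid size, with smaller sizes
    # taken as nested random subsamples of its training split and the dev
    # and test splits held fixed — the paired design under which "more
    # unlabeled data" is the only thing that changes along the grid.
    lfs <- builtin_labeling_functions(config)
    for (s in seq_len(n_seeds)) {
      seed_s <- derive_seed(config$seed, s)
      cfg <- config
      cfg$n_train <- as.integer(max(n_grid))
      cfg$seed <- seed_s
      corpus <- generate_corpus(cfg)
      data <- corpus$data
      train_ids <- data$id[data$split == "train"]
      perm <- with_seed(derive_seed(seed_s, 17L), sample(train_ids))
      for (i in seq_along(n_grid)) {
        keep <- data$split != "train" | data$id %in% perm[seq_len(n_grid[i])]
        sub <- data[keep, ]
        row <- tibble(n = n_grid[i], seed = s)
        if ("alpha_error" %in% measure) {
          lambda <- apply_labeling_functions(sub[sub$split == "train", ], lfs)
          gm <- fit_generative_model(lambda, seed = seed_s)
          est <- tidy(gm)
          idx <- match(est$lf, truth$lf)
          row$alpha_error <- mean(abs(est$accuracy - truth$accuracy[idx]))
          row$beta_error <- mean(abs(est$propensity - truth$propensity[idx]))
        }
        if ("auc" %in% measure) {
          cfg_pipe <- pipeline_cfg %||% pipeline_config()
          cfg_pipe$seed <- seed_s
          run <- run_cross_modal_pipeline(
            sub, lfs,
            modifyList(cfg_pipe, list(include_fully_supervised = FALSE)))
          row$test_auc <- run$metrics$roc_auc
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- bind_rows(rows)
  summary <- results |>
    group_by(n = .data$n) |>
    summarise(across(dplyr::any_of(c("alpha_error", "beta_error", "test_auc")),
                     mean), .groups = "drop")
  slope <- NA_real_
  if ("alpha_error" %in% measure) {
    fit <- stats::lm(log(alpha_error) ~ log(n), data = summary)
    slope <- unname(stats::coef(fit)[2])
  }
  structure(list(results = results, summary = summary, slope = slope,
                 n_grid = n_grid, n_seeds = n_seeds, seed = config$seed),
            class = "xm_scaling")
}

#' @export
print.xm_scaling <- function(x, ...) {
  cat("<xm_scaling>", length(x$n_grid), "grid points x", x$n_seeds, "seeds\n")
  print(x$summary)
  if (is.finite(x$slope)) {
    cat(sprintf("  log-log slope of accuracy-estimation error: %.3f\n", x$slope))
  }
  invisible(x)
}

#' @method tidy xm_scaling
#' @export
tidy.xm_scaling <- function(x, ...) x$summary

#' @method glance xm_scaling
#' @export
glance.xm_scaling <- function(x, ...) {
  tibble(slope = x$slope, n_min = min(x$n_grid), n_max = max(x$n_grid),
         n_seeds = x$n_seeds)
}
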