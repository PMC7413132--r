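test_that("the noise-aware loss matches its closed form and is linear in the label", {
  # maximal uncertainty at a 0.5 score is ln 2
  expect_equal(noise_aware_loss(0.5, 0.5), log(2), tolerance = 1e-12)
  # hand evaluation of the definition
  expect_equal(noise_aware_loss(0.7, 0.8),
               -0.8 * log(0.7) - 0.2 * log(0.3), tolerance = 1e-12)
  # degenerate labels reduce to plain cross-entropy
  s <- c(0.2, 0.9, 0.6)
  expect_equal(noise_aware_loss(s, c(1, 1, 1)), mean(-log(s)),
               tolerance = 1e-12)
  # linearity: loss(y) = y * loss(1) + (1 - y) * loss(0), pointwise
  set.seed(4)
  for (rep in 1:50) {
    s <- runif(1, 0.01, 0.99); y <- runif(1)
    expect_equal(noise_aware_loss(s, y),
                 y * noise_aware_loss(s, 1) + (1 - y) * noise_aware_loss(s, 0),
                 tolerance = 1e-12)
  }
  # covered mask and degenerate cases
  labs <- tibble::tibble(id = c("a", "b"), p_pos = c(0.5, 0.9),
                         covered = c(FALSE, TRUE), source = "GM")
  expect_equal(noise_aware_loss(c(0.1, 0.5), labs), noise_aware_loss(0.5, 0.9))
  labs$covered <- FALSE
  expect_error(noise_aware_loss(c(0.1, 0.5), labs), "no covered")
})

test_that("analytic network gradients agree with finite differences", {
  set.seed(11)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- runif(5)
  par <- withr::with_seed(2, crossdp:::mlp_init(3, c(4L, 3L)))
  g <- crossdp:::mlp_gradient(par, X, y)
  loss_at <- function(p) noise_aware_loss(crossdp:::mlp_predict(p, X), y)
  h <- 1e-6
  for (l in seq_along(par$W)) {
    for (k in sample(length(par$W[[l]]), 3)) {
      pp <- par; pp$W[[l]][k] <- pp$W[[l]][k] + h
      pm <- par; pm$W[[l]][k] <- pm$W[[l]][k] - h
      expect_equal(g$W[[l]][k], (loss_at(pp) - loss_at(pm)) / (2 * h),
                   tolerance = 1e-5)
    }
    pp <- par; pp$b[[l]][1] <- pp$b[[l]][1] + h
    pm <- par; pm$b[[l]][1] <- pm$b[[l]][1] - h
    expect_equal(g$b[[l]][1], (loss_at(pp) - loss_at(pm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

make_features <- function(n, seed, sep = 2, d = 3, prefix = "e") {
  set.seed(seed)
  y <- sample(c(-1L, 1L), n, replace = TRUE)
  X <- matrix(rnorm(n * d), n, d) + outer(y, rep(sep / 2 / sqrt(d), d))
  colnames(X) <- paste0("f", 1:d)
  dplyr::bind_cols(tibble::tibble(id = sprintf("%s%04d", prefix, 1:n), y = y),
                   tibble::as_tibble(as.data.frame(X)))
}

test_that("training on separable features with true labels separates", {
  data <- make_features(400, seed = 8, sep = 4)
  spec <- classifier_spec("target_features", max_epochs = 40, seed = 1)
  model <- train_probabilistic_classifier(
    data, tibble::tibble(id = data$id, label = data$y), spec)
  expect_gt(roc_auc(predict(model, data), data$y), 0.95)
  expect_identical(model$label_source, "FS")
})

test_that("uninformative 0.5 labels yield chance-level held-out performance", {
  train <- make_features(200, seed = 30)
  test <- make_features(200, seed = 31)
  labs <- tibble::tibble(id = train$id, p_pos = 0.5, covered = TRUE,
                         source = "GM")
  aucs <- vapply(1:10, function(s) {
    spec <- classifier_spec("target_features", max_epochs = 15, seed = s)
    model <- train_probabilistic_classifier(train, labs, spec)
    roc_auc(predict(model, test), test$y)
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("degenerate probabilistic labels reproduce hard-label training exactly", {
  data <- make_features(200, seed = 12)
  spec <- classifier_spec("target_features", max_epochs = 10, seed = 7)
  soft <- tibble::tibble(id = data$id, p_pos = (data$y + 1) / 2,
                         covered = TRUE, source = "GM")
  hard <- tibble::tibble(id = data$id, label = data$y)
  m_soft <- train_probabilistic_classifier(data, soft, spec)
  m_hard <- train_probabilistic_classifier(data, hard, spec)
  expect_identical(m_soft$training_log$train_loss, m_hard$training_log$train_loss)
  expect_identical(predict(m_soft, data), predict(m_hard, data))
})

test_that("early stopping halts at best epoch + patience and keeps best weights", {
  train <- make_features(300, seed = 14)
  dev <- make_features(120, seed = 15, prefix = "d")
  dev$label <- dev$y
  spec <- classifier_spec("target_features", max_epochs = 60, patience = 3,
                          seed = 2)
  model <- train_probabilistic_classifier(
    train, tibble::tibble(id = train$id, label = train$y), spec, dev = dev)
  log <- model$training_log
  expect_lte(nrow(log), model$best_epoch + spec$patience)
  expect_equal(model$best_epoch, which.min(log$dev_loss))
  # inference is deterministic and repeatable
  expect_identical(predict(model, dev), predict(model, dev))
  # dev must be disjoint from training
  expect_error(
    train_probabilistic_classifier(
      train, tibble::tibble(id = train$id, label = train$y), spec,
      dev = dplyr::mutate(train[1:5, ], label = y)),
    "disjoint")
})

test_that("distillation emits full-coverage labels tagged by its training source", {
  corpus <- tibble::tibble(
    id = sprintf("r%03d", 1:60),
    text = c(rep("finding opacity seen", 20), rep("no opacity normal exam", 20),
             rep("routine stable study", 20)))
  labs <- tibble::tibble(id = corpus$id,
                         p_pos = rep(c(0.95, 0.05, 0.5), each = 20),
                         covered = rep(c(TRUE, TRUE, FALSE), each = 20),
                         source = "GM")
  spec <- classifier_spec("auxiliary_text", max_epochs = 20, seed = 3)
  model <- train_probabilistic_classifier(corpus, labs, spec)
  out <- distill_labels(model, corpus)
  expect_true(all(out$covered))
  expect_identical(out$source, rep("DM-GM", 60))
  expect_identical(out$p_pos, distill_labels(model, corpus)$p_pos)
  # uncovered rows get informative scores from the text model
  expect_gt(mean(out$p_pos[1:20]), mean(out$p_pos[21:40]))

  tgt <- train_probabilistic_classifier(
    make_features(50, 1), tibble::tibble(id = make_features(50, 1)$id,
                                         label = make_features(50, 1)$y),
    classifier_spec("target_features", max_epochs = 5, seed = 1))
  expect_error(distill_labels(tgt, corpus), "auxiliary")
})

test_that("exam-level aggregation is the order-invariant instance mean", {
  scores <- tibble::tibble(exam_id = c("e1", "e1", "e1", "e2"),
                           p_pos = c(0.2, 0.4, 0.6, 0.8))
  agg <- aggregate_exam_scores(scores)
  expect_equal(agg$p_pos[agg$exam_id == "e1"], 0.4)
  expect_equal(agg$p_pos[agg$exam_id == "e2"], 0.8)
  expect_equal(agg$n_instances, c(3L, 1L))
  shuffled <- scores[c(3, 1, 4, 2), ]
  expect_equal(aggregate_exam_scores(shuffled), agg)
  expect_error(aggregate_exam_scores(scores[0, ]), "at least one")
  expect_error(aggregate_exam_scores(tibble::tibble(exam_id = NA, p_pos = 1)),
               "missing")
})
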