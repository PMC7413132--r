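# Noise-aware training of probabilistic classifiers, cross-modal label
# distillation, and exam-level score aggregation.
#
# One training engine serves both modalities: a small feedforward network
# (two tanh hidden layers, sigmoid output) trained with Adam on the
# noise-aware cross-entropy. The framework's contract is
# architecture-agnostic — any model emitting P(y = +1) scores fits — and at
# desk scale a compact reference network keeps every run deterministic and
# fast. Auxiliary text is featurized as bag-of-token indicators plus a
# standardized report-length feature; target-modality feature tables are
# standardized column-wise.

#' Classifier specification
#'
#' @param modality `"auxiliary_text"` or `"target_features"`.
#' @param hidden Integer vector of hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience: training halts once the
#'   development-set loss has not improved for more than `patience` epochs
#'   (default 3).
#' @param train_on_uncovered Include uncovered (prior-labeled) rows in
#'   training? Default `FALSE`: rows the label source could not label carry
#'   no information and only dilute gradients.
#' @param seed Integer seed controlling weight initialization and minibatch
#'   order.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(modality = c("target_features", "auxiliary_text"),
                            hidden = c(16L, 8L), learning_rate = 0.01,
                            batch_size = 64L, max_epochs = 60L,
                            patience = 3L, train_on_uncovered = FALSE,
                            seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(patience >= 1L, max_epochs >= 1L, batch_size >= 1L,
            length(hidden) >= 1L, all(hidden >= 1L))
  structure(list(modality = modality, hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 train_on_uncovered = isTRUE(train_on_uncovered),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Noise-aware cross-entropy loss
#'
#' The expected binary cross-entropy under the probabilistic label
#' distribution, averaged over covered examples:
#' \deqn{\frac{1}{n}\sum_i \tilde y_i \, \ell(s_i, +1) +
#'   (1 - \tilde y_i) \, \ell(s_i, -1)}
#' with \eqn{\ell} the log loss. It is exactly linear in \eqn{\tilde y}, and
#' reduces to the standard supervised loss when labels are degenerate
#' (\eqn{\tilde y \in \{0, 1\}}).
#'
#' @param scores Predicted \eqn{P(y = +1)} values in (0, 1).
#' @param labels A `prob_labels` tibble (its `covered` mask is honored) or a
#'   numeric vector of probabilistic labels in `[0, 1]`.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' noise_aware_loss(0.5, 0.5)  # log(2)
noise_aware_loss <- function(scores, labels) {
  if (is.data.frame(labels)) {
    keep <- labels$covered
    y <- labels$p_pos[keep]
    scores <- scores[keep]
  } else {
    y <- as.numeric(labels)
  }
  if (length(y) == 0L) abort("no covered examples: nothing to compute a loss on.")
  if (length(scores) != length(y)) abort("`scores` and `labels` must align.")
  if (any(y < 0 | y > 1)) abort("probabilistic labels must lie in [0, 1].")
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  mean(-(y * log(s) + (1 - y) * log(1 - s)))
}

# ---- feedforward engine -----------------------------------------------------

mlp_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = 1 / sqrt(dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    acts[[l + 1L]] <- tanh(sweep(acts[[l]] %*% par$W[[l]], 2, par$b[[l]], "+"))
  }
  z <- as.numeric(acts[[L]] %*% par$W[[L]]) + par$b[[L]]
  list(scores = sigmoid(z), acts = acts)
}

mlp_predict <- function(par, X) mlp_forward(par, X)$scores

# Gradient of the mean noise-aware cross-entropy w.r.t. all weights.
mlp_gradient <- function(par, X, y) {
  L <- length(par$W)
  fwd <- mlp_forward(par, X)
  n <- nrow(X)
  delta <- matrix((fwd$scores - y) / n, ncol = 1L)  # dL/dz at the output
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (1 - fwd$acts[[l]]^2)
    }
  }
  list(W = gW, b = gb)
}

mlp_train <- function(X, y, X_dev = NULL, y_dev = NULL, spec) {
  with_seed(spec$seed, {
    par <- mlp_init(ncol(X), spec$hidden)
    adam <- list(
      mW = lapply(par$W, function(w) w * 0), vW = lapply(par$W, function(w) w * 0),
      mb = lapply(par$b, function(b) b * 0), vb = lapply(par$b, function(b) b * 0),
      t = 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(X)
    log_epoch <- integer(0); log_train <- numeric(0); log_dev <- numeric(0)
    best <- list(loss = Inf, par = par, epoch = 0L)
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + spec$batch_size - 1L, n)]
        g <- mlp_gradient(par, X[idx, , drop = FALSE], y[idx])
        adam$t <- adam$t + 1
        corr <- sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
        for (l in seq_along(par$W)) {
          adam$mW[[l]] <- b1 * adam$mW[[l]] + (1 - b1) * g$W[[l]]
          adam$vW[[l]] <- b2 * adam$vW[[l]] + (1 - b2) * g$W[[l]]^2
          par$W[[l]] <- par$W[[l]] - spec$learning_rate * corr *
            adam$mW[[l]] / (sqrt(adam$vW[[l]]) + eps)
          adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * g$b[[l]]
          adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * g$b[[l]]^2
          par$b[[l]] <- par$b[[l]] - spec$learning_rate * corr *
            adam$mb[[l]] / (sqrt(adam$vb[[l]]) + eps)
        }
      }
      train_loss <- noise_aware_loss(mlp_predict(par, X), y)
      dev_loss <- if (!is.null(X_dev)) {
        noise_aware_loss(mlp_predict(par, X_dev), y_dev)
      } else NA_real_
      log_epoch <- c(log_epoch, epoch)
      log_train <- c(log_train, train_loss)
      log_dev <- c(log_dev, dev_loss)
      monitor <- if (!is.null(X_dev)) dev_loss else train_loss
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, par = par, epoch = epoch)
      } else if (!is.null(X_dev) && epoch - best$epoch >= spec$patience) {
        break
      }
    }
    list(par = if (!is.null(X_dev)) best$par else par,
         best_epoch = if (!is.null(X_dev)) best$epoch else length(log_epoch),
         log = tibble(epoch = log_epoch, train_loss = log_train,
                      dev_loss = log_dev))
  })
}

# ---- featurization ----------------------------------------------------------

feature_columns <- function(data) {
  drop <- c("id", "exam_id", "split", "hand_label", "text", "tokens", "y")
  cols <- setdiff(names(data), drop)
  cols[vapply(data[cols], is.numeric, logical(1))]
}

build_featurizer <- function(data, modality) {
  if (modality == "auxiliary_text") {
    tokens <- if ("tokens" %in% names(data)) data$tokens
              else tokenize_reports(data$text)
    vocab <- sort(unique(unlist(tokens)))
    lens <- lengths(tokens)
    list(modality = modality, vocab = vocab,
         len_center = mean(lens), len_scale = max(sd(lens), 1e-8))
  } else {
    cols <- feature_columns(data)
    if (length(cols) == 0L) abort("no numeric feature columns found in `data`.")
    X <- as.matrix(as.data.frame(data)[cols])
    centers <- colMeans(X)
    scales <- pmax(apply(X, 2, sd), 1e-8)
    list(modality = modality, cols = cols, centers = centers, scales = scales)
  }
}

featurize <- function(fz, data) {
  if (fz$modality == "auxiliary_text") {
    tokens <- if ("tokens" %in% names(data)) data$tokens
              else tokenize_reports(data$text)
    X <- matrix(0, length(tokens), length(fz$vocab),
                dimnames = list(NULL, fz$vocab))
    for (i in seq_along(tokens)) {
      j <- match(unique(tokens[[i]]), fz$vocab)  # unseen tokens are dropped
      j <- j[!is.na(j)]
      if (length(j) > 0L) X[i, j] <- 1
    }
    cbind(X, .len = (lengths(tokens) - fz$len_center) / fz$len_scale)
  } else {
    X <- as.matrix(as.data.frame(data)[fz$cols])
    sweep(sweep(X, 2, fz$centers, "-"), 2, fz$scales, "/")
  }
}

# ---- training ---------------------------------------------------------------

as_training_labels <- function(labels) {
  labels <- as_tibble(labels)
  if ("p_pos" %in% names(labels)) {
    tibble(id = as.character(labels$id), p_pos = labels$p_pos,
           covered = if ("covered" %in% names(labels)) labels$covered else TRUE,
           source = if ("source" %in% names(labels)) labels$source[1] else "GM")
  } else if ("label" %in% names(labels)) {
    y <- as.integer(labels$label)
    if (!all(y %in% c(-1L, 1L))) abort("hard labels must be -1 or 1.")
    tibble(id = as.character(labels$id), p_pos = (y + 1) / 2,
           covered = TRUE, source = "FS")
  } else {
    abort("`labels` must have a `p_pos` (probabilistic) or `label` (hard) column.")
  }
}

#' Train a probabilistic classifier against probabilistic labels
#'
#' Minimizes the noise-aware cross-entropy of a small feedforward network
#' over the covered training examples, with optional early stopping on a
#' hand-labeled development split (training halts once the dev loss has not
#' improved for more than `spec$patience` epochs, and the best-epoch weights
#' are kept). Fully deterministic given `spec$seed`.
#'
#' @param data Training examples: a tibble with an `id` column plus either
#'   `text`/`tokens` (auxiliary modality) or numeric feature columns (target
#'   modality).
#' @param labels Training labels: a `prob_labels` tibble, or a tibble with
#'   `id` and hard `label` in `{-1, 1}` (degenerate probabilistic labels).
#' @param spec A [classifier_spec()].
#' @param dev Optional development split, disjoint from `data`: a tibble
#'   shaped like `data` with an additional hand-label column `label` in
#'   `{-1, 1}`.
#' @return An `xm_classifier`: network weights, featurizer, `spec`,
#'   `training_log` (per-epoch train/dev losses), `best_epoch`, and the
#'   provenance (`label_source`) of its training labels.
#' @export
train_probabilistic_classifier <- function(data, labels, spec, dev = NULL) {
  data <- as_tibble(data)
  lab <- as_training_labels(labels)
  if (!all(lab$id %in% as.character(data$id))) {
    abort("label ids do not align with `data` ids.")
  }
  lab <- lab[match(as.character(data$id), lab$id), ]
  if (anyNA(lab$p_pos)) abort("every training example needs a label.")
  keep <- if (spec$train_on_uncovered) rep(TRUE, nrow(data)) else lab$covered
  if (!any(keep)) abort("no covered examples: nothing to train on.")

  fz <- build_featurizer(data[keep, ], spec$modality)
  X <- featurize(fz, data[keep, ])
  y <- lab$p_pos[keep]

  X_dev <- NULL; y_dev <- NULL
  if (!is.null(dev)) {
    dev <- as_tibble(dev)
    if (!"label" %in% names(dev)) abort("`dev` needs a hand-label column `label`.")
    if (any(as.character(dev$id) %in% as.character(data$id))) {
      abort("`dev` must be disjoint from the training data.")
    }
    X_dev <- featurize(fz, dev)
    y_dev <- (as.integer(dev$label) + 1) / 2
    if (!all(y_dev %in% c(0, 1))) abort("dev labels must be -1 or 1.")
  }

  res <- mlp_train(X, y, X_dev, y_dev, spec)
  structure(list(par = res$par, featurizer = fz, spec = spec,
                 training_log = res$log, best_epoch = res$best_epoch,
                 label_source = lab$source[1],
                 n_train = sum(keep)),
            class = "xm_classifier")
}

#' @export
print.xm_classifier <- function(x, ...) {
  cat("<xm_classifier>", x$spec$modality, "model,",
      x$n_train, "training examples, labels:", x$label_source, "\n")
  cat(sprintf("  best epoch %d of %d\n", x$best_epoch, nrow(x$training_log)))
  invisible(x)
}

#' Predict scores from a trained classifier
#'
#' @param object An `xm_classifier`.
#' @param newdata A tibble shaped like the training data.
#' @param ... Unused.
#' @return A numeric vector of \eqn{P(y = +1)} scores, one per row of
#'   `newdata`. Inference is deterministic.
#' @export
predict.xm_classifier <- function(object, newdata, ...) {
  mlp_predict(object$par, featurize(object$featurizer, as_tibble(newdata)))
}

#' @method tidy xm_classifier
#' @export
tidy.xm_classifier <- function(x, ...) x$training_log

#' @method glance xm_classifier
#' @export
glance.xm_classifier <- function(x, ...) {
  tibble(modality = x$spec$modality, label_source = x$label_source,
         n_train = x$n_train, epochs = nrow(x$training_log),
         best_epoch = x$best_epoch,
         best_dev_loss = if (all(is.na(x$training_log$dev_loss))) NA_real_
                         else min(x$training_log$dev_loss, na.rm = TRUE),
         seed = x$spec$seed)
}

#' Distill labels through an auxiliary-modality classifier
#'
#' Evaluates a trained auxiliary-text model over every example of a corpus,
#' producing full-coverage probabilistic labels (`covered` all `TRUE`). The
#' provenance tag is `DM-GM` or `DM-MV` according to the labels the model
#' was trained on.
#'
#' @param model An `xm_classifier` with `modality = "auxiliary_text"`.
#' @param corpus Auxiliary examples (tibble with `id` and `text`/`tokens`),
#'   including any rows the generative model left uncovered.
#' @return A `prob_labels` tibble with coverage 1.
#' @export
distill_labels <- function(model, corpus) {
  if (model$spec$modality != "auxiliary_text") {
    abort("distillation requires an auxiliary-modality model.")
  }
  corpus <- as_tibble(corpus)
  src <- switch(model$label_source, "GM" = "DM-GM", "MV" = "DM-MV",
                abort("distillation model must be trained on GM or MV labels."))
  new_prob_labels(corpus$id, predict(model, corpus),
                  rep(TRUE, nrow(corpus)), src)
}

#' Aggregate instance scores to exam level
#'
#' Some studies comprise several target-modality instances (e.g. multiple
#' radiographs per exam); the exam-level score is the arithmetic mean of its
#' instance scores, which is invariant to instance order.
#'
#' @param scores A data frame with an exam grouping column and a numeric
#'   score column.
#' @param score_col,exam_col Column names (defaults `"p_pos"`, `"exam_id"`).
#' @return A tibble with one row per exam: `exam_id`, `p_pos`, `n_instances`.
#' @export
aggregate_exam_scores <- function(scores, score_col = "p_pos",
                                  exam_col = "exam_id") {
  scores <- as_tibble(scores)
  if (!all(c(score_col, exam_col) %in% names(scores))) {
    abort(sprintf("`scores` needs columns `%s` and `%s`.", exam_col, score_col))
  }
  if (nrow(scores) == 0L) abort("every exam needs at least one instance.")
  if (anyNA(scores[[exam_col]]) || anyNA(scores[[score_col]])) {
    abort("exam ids and scores must not be missing.")
  }
  out <- scores |>
    group_by(exam_id = .data[[exam_col]]) |>
    summarise(p_pos = mean(.data[[score_col]]), n_instances = n(),
              .groups = "drop")
  out
}
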