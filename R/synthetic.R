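# Synthetic paired report/target corpora with known ground truth.
#
# Reports are token sequences, not natural prose: the labeling-function
# taxonomy (keyword matchers, negation-aware matchers, structural length
# heuristics) only requires token access, and token-level generation keeps
# every labeling-function statistic analytically computable. Target-modality
# "images" are class-conditional Gaussian feature vectors whose standardized
# mean separation plays the role of task difficulty.

#' Configuration for a synthetic cross-modal corpus
#'
#' @param n_train,n_dev,n_test Split sizes. The development split defaults
#'   to 200 hand-labeled examples, the size used throughout the
#'   applications this design emulates.
#' @param class_prior \eqn{P(y = +1)} (abnormal).
#' @param keywords A data frame with one row per clinical keyword:
#'   `term`, `sensitivity` (P(term affirmed | abnormal)), `specificity`
#'   (1 - P(term affirmed | normal)), `negation_rate` (P("no term" | normal)),
#'   `negation_rate_abnormal` (P("no term" | abnormal), small — negated
#'   mentions occasionally appear in abnormal reports too, which keeps
#'   negation heuristics imperfect).
#' @param filler_vocab Character vector of uninformative filler tokens.
#' @param mean_length_normal,mean_length_abnormal Poisson means for the
#'   filler-token count per class; normal reports are shorter.
#' @param length_threshold Token-count threshold used by the built-in
#'   short-report labeling function.
#' @param target_dim Dimension of the target feature vectors.
#' @param separability Standardized mean difference between the
#'   class-conditional target feature distributions (unit-variance
#'   Gaussians); 0 means the target modality carries no signal.
#' @param label_noise Probability a hand label is flipped relative to the
#'   true label (default 0).
#' @param seed Integer seed; the serialized config plus this seed fully
#'   determine the corpus.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_train = 2000L, n_dev = 200L, n_test = 500L,
                             class_prior = 0.5,
                             keywords = default_keywords(),
                             filler_vocab = sprintf("w%02d", 1:40),
                             mean_length_normal = 8,
                             mean_length_abnormal = 14,
                             length_threshold = 11L,
                             target_dim = 4L, separability = 2,
                             label_noise = 0, seed = 1L) {
  keywords <- as_tibble(keywords)
  if (!"negation_rate_abnormal" %in% names(keywords)) {
    keywords$negation_rate_abnormal <- 0.03
  }
  needed <- c("term", "sensitivity", "specificity", "negation_rate",
              "negation_rate_abnormal")
  if (!all(needed %in% names(keywords))) {
    abort(paste("`keywords` needs columns:", paste(needed, collapse = ", ")))
  }
  stopifnot_scalar_prob(class_prior, "class_prior")
  stopifnot_scalar_prob(label_noise, "label_noise")
  probs <- unlist(keywords[needed[-1]])
  if (any(probs < 0 | probs > 1)) abort("keyword rates must lie in [0, 1].")
  if (any(keywords$sensitivity + keywords$negation_rate_abnormal > 1) ||
      any((1 - keywords$specificity) + keywords$negation_rate > 1)) {
    abort("per-class keyword emission probabilities must sum to at most 1.")
  }
  if (separability < 0) abort("`separability` must be nonnegative.")
  if (nrow(keywords) == 0L && separability == 0) {
    abort("no keywords and zero separability: the corpus would carry no learnable signal.")
  }
  if (any(keywords$term %in% c(filler_vocab, "no"))) {
    abort("keyword terms must not collide with filler tokens or \"no\".")
  }
  structure(list(
    n_train = as.integer(n_train), n_dev = as.integer(n_dev),
    n_test = as.integer(n_test), class_prior = class_prior,
    keywords = keywords, filler_vocab = filler_vocab,
    mean_length_normal = mean_length_normal,
    mean_length_abnormal = mean_length_abnormal,
    length_threshold = as.integer(length_threshold),
    target_dim = as.integer(target_dim), separability = separability,
    label_noise = label_noise, seed = as.integer(seed)
  ), class = "synthetic_config")
}

default_keywords <- function() {
  tibble(
    term = c("opacity", "effusion", "fracture", "lesion"),
    sensitivity = c(0.55, 0.50, 0.45, 0.40),
    specificity = c(0.99, 0.985, 0.99, 0.97),
    negation_rate = c(0.30, 0.25, 0.20, 0.15),
    negation_rate_abnormal = c(0.03, 0.03, 0.03, 0.03)
  )
}

#' Scenario presets: screening vs targeted detection
#'
#' Two labeling-function regimes that determine how the pipeline's heuristic
#' optimizer routes:
#' * `"screening"` — broad-abnormality triage: heuristics are accurate
#'   (~0.85–0.95) but low-coverage (union coverage ~0.6–0.7, below the 90%
#'   routing threshold), so the auxiliary distillation model is worth
#'   training.
#' * `"targeted"` — single-pathology detection: clinicians describe the
#'   finding consistently, so heuristics are both accurate (>0.9) and
#'   high-coverage (>0.95), and the generative-model labels are used
#'   directly.
#'
#' @param name `"screening"` or `"targeted"`.
#' @param ... Overrides passed to [synthetic_config()] (e.g. `n_train`,
#'   `seed`).
#' @return A `synthetic_config`.
#' @export
scenario_preset <- function(name = c("screening", "targeted"), ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(
                     "unknown preset: use \"screening\" or \"targeted\"."))
  base <- if (name == "screening") {
    list(
      class_prior = 0.4,
      keywords = tibble(
        term = c("opacity", "effusion", "fracture", "lesion"),
        sensitivity = c(0.27, 0.22, 0.19, 0.25),
        specificity = c(0.99, 0.985, 0.995, 0.97),
        negation_rate = c(0.14, 0.12, 0.10, 0.08),
        negation_rate_abnormal = c(0.03, 0.03, 0.02, 0.03)
      ),
      mean_length_normal = 8, mean_length_abnormal = 14,
      length_threshold = 7L, separability = 2
    )
  } else {
    list(
      class_prior = 0.5,
      keywords = tibble(
        term = c("hemorrhage", "bleed", "hematoma"),
        sensitivity = c(0.85, 0.80, 0.75),
        specificity = c(0.995, 0.995, 0.99),
        negation_rate = c(0.60, 0.50, 0.40),
        negation_rate_abnormal = c(0.02, 0.02, 0.02)
      ),
      mean_length_normal = 8, mean_length_abnormal = 14,
      length_threshold = 12L, separability = 2
    )
  }
  do.call(synthetic_config, modifyList(base, list(...)))
}

#' Generate a synthetic paired cross-modal corpus
#'
#' Per example: draw the latent label \eqn{y} from the class prior; emit a
#' token report (affirmed keywords at class-conditional sensitivities,
#' negated mentions as `"no <term>"`, Poisson filler with normal reports
#' shorter); emit a target feature vector from the class-conditional
#' Gaussian at the configured separability; assign train/dev/test splits.
#' Hand labels equal the true labels except under `label_noise`.
#' Deterministic given the config (which includes the seed).
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return An `xm_corpus` list: `data` (tibble `id`, `split`, `text`,
#'   `tokens`, `hand_label`, feature columns `f1..fd`), `truth` (tibble
#'   `id`, `y` — held out from the pipeline, for verification only), and
#'   `config`.
#' @export
generate_corpus <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- seed %||% config$seed
  kw <- config$keywords
  N <- config$n_train + config$n_dev + config$n_test
  with_seed(seed, {
    y <- ifelse(runif(N) < config$class_prior, 1L, -1L)
    abn <- y == 1L

    # Keyword units: for each keyword, "" / term / "no term" per example.
    unit_cols <- vector("list", nrow(kw))
    for (k in seq_len(nrow(kw))) {
      u <- runif(N)
      p_aff <- ifelse(abn, kw$sensitivity[k], 1 - kw$specificity[k])
      p_neg <- ifelse(abn, kw$negation_rate_abnormal[k], kw$negation_rate[k])
      unit_cols[[k]] <- ifelse(u < p_aff, kw$term[k],
                        ifelse(u < p_aff + p_neg, paste("no", kw$term[k]), ""))
    }

    n_fill <- rpois(N, ifelse(abn, config$mean_length_abnormal,
                              config$mean_length_normal))
    fillers <- sample(config$filler_vocab, sum(n_fill), replace = TRUE)
    fill_str <- vapply(split(fillers, rep.int(seq_len(N), n_fill)),
                       paste, character(1), collapse = " ")
    fill_full <- character(N)
    fill_full[n_fill > 0L] <- fill_str
    text <- do.call(paste, c(unit_cols, list(fill_full)))
    text <- trimws(gsub(" +", " ", text))

    X <- matrix(rnorm(N * config$target_dim), N, config$target_dim)
    shift <- (config$separability / 2) / sqrt(config$target_dim)
    X <- X + outer(as.numeric(y), rep(shift, config$target_dim))
    colnames(X) <- paste0("f", seq_len(config$target_dim))

    hand <- y
    if (config$label_noise > 0) {
      flip <- runif(N) < config$label_noise
      hand[flip] <- -hand[flip]
    }

    split <- rep(c("train", "dev", "test"),
                 times = c(config$n_train, config$n_dev, config$n_test))
    data <- tibble(
      id = sprintf("ex%06d", seq_len(N)), split = split, text = text,
      tokens = tokenize_reports(text), hand_label = as.integer(hand)) |>
      bind_cols(as_tibble(X))
    structure(list(data = data,
                   truth = tibble(id = data$id, y = as.integer(y)),
                   config = config),
              class = "xm_corpus")
  })
}

#' @export
print.xm_corpus <- function(x, ...) {
  cat("<xm_corpus>", nrow(x$data), "paired examples (",
      sum(x$data$split == "train"), "train /",
      sum(x$data$split == "dev"), "dev /",
      sum(x$data$split == "test"), "test )\n")
  invisible(x)
}

#' Built-in labeling functions for a synthetic corpus
#'
#' The three heuristic families: per-keyword affirmative matchers (vote +1),
#' negation-aware matchers (vote -1 on `"no <term>"`), and a structural
#' short-report heuristic (vote -1 below the configured token-count
#' threshold). Each abstains otherwise.
#'
#' @param config A [synthetic_config()].
#' @return A list of [labeling_function()] objects.
#' @export
builtin_labeling_functions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  c(
    lapply(config$keywords$term, lf_keyword),
    lapply(config$keywords$term, lf_negated_keyword),
    list(lf_short_report(config$length_threshold))
  )
}

# Exact pmf of the total report token count for one class: Poisson filler
# convolved with each keyword's token-count distribution (0, 1 affirmative,
# or 2 negated tokens).
length_pmf <- function(config, abnormal) {
  kw <- config$keywords
  mu <- if (abnormal) config$mean_length_abnormal else config$mean_length_normal
  top <- ceiling(mu + 10 * sqrt(mu) + 20) + 2L * nrow(kw)
  pmf <- dpois(0:top, mu)
  for (k in seq_len(nrow(kw))) {
    p1 <- if (abnormal) kw$sensitivity[k] else 1 - kw$specificity[k]
    p2 <- if (abnormal) kw$negation_rate_abnormal[k] else kw$negation_rate[k]
    kernel <- c(1 - p1 - p2, p1, p2)
    new <- pmf * kernel[1]
    new <- new + c(0, pmf[-length(pmf)]) * kernel[2]
    new <- new + c(0, 0, pmf[seq_len(length(pmf) - 2L)]) * kernel[3]
    pmf <- new
  }
  pmf / sum(pmf)
}

#' Analytic statistics of the built-in labeling functions
#'
#' Closed-form vote propensity and accuracy-given-vote for every built-in
#' LF, derived from the corpus emission probabilities (the short-report
#' heuristic uses the exact token-count distribution obtained by
#' convolution). These are the ground truth that generative-model parameter
#' recovery is measured against.
#'
#' @param config A [synthetic_config()].
#' @return A tibble: `lf`, `vote`, `accuracy`, `propensity`.
#' @export
analytic_lf_statistics <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  kw <- config$keywords
  pi1 <- config$class_prior
  rows <- list()
  for (k in seq_len(nrow(kw))) {
    prop <- pi1 * kw$sensitivity[k] + (1 - pi1) * (1 - kw$specificity[k])
    acc <- if (prop > 0) pi1 * kw$sensitivity[k] / prop else NA_real_
    rows[[length(rows) + 1L]] <- tibble(
      lf = paste0("lf_", kw$term[k]), vote = 1L,
      accuracy = acc, propensity = prop)
  }
  for (k in seq_len(nrow(kw))) {
    prop <- pi1 * kw$negation_rate_abnormal[k] + (1 - pi1) * kw$negation_rate[k]
    acc <- if (prop > 0) (1 - pi1) * kw$negation_rate[k] / prop else NA_real_
    rows[[length(rows) + 1L]] <- tibble(
      lf = paste0("lf_no_", kw$term[k]), vote = -1L,
      accuracy = acc, propensity = prop)
  }
  t <- config$length_threshold
  p_short_abn <- sum(length_pmf(config, TRUE)[seq_len(t)])   # P(len < t), len >= 0
  p_short_nrm <- sum(length_pmf(config, FALSE)[seq_len(t)])
  prop <- pi1 * p_short_abn + (1 - pi1) * p_short_nrm
  rows[[length(rows) + 1L]] <- tibble(
    lf = "lf_short_report", vote = -1L,
    accuracy = if (prop > 0) (1 - pi1) * p_short_nrm / prop else NA_real_,
    propensity = prop)
  bind_rows(rows)
}
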