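# The generative label model: a latent-class model of labeling-function
# votes given the unobserved binary label, fit by minimizing the exact
# negative log marginal likelihood of the observed vote matrix.
#
# Each LF j emits a vote v in {-1, 0, +1} with class-conditional emission
# probabilities P(lambda_j = v | y), conditionally independently across LFs
# given y, with class prior pi = P(y = +1). This is binary Dawid-Skene with
# abstention; it nests the symmetric (accuracy, propensity) factorization
#   P(lambda = 0       | y) = 1 - beta_j
#   P(lambda = sign(y) | y) = beta_j * alpha_j
#   P(lambda = -sign(y)| y) = beta_j * (1 - alpha_j)
# as the special case with class-independent abstention. The class-
# conditional form matters in practice: real LFs are one-sided (a keyword
# matcher only ever votes +1, and fires mostly on positives), and under the
# symmetric factorization the marginal-likelihood optimum for such votes is
# degenerate. The user-facing parameters are the classical summaries:
# accuracy given vote (alpha_j), vote propensity (beta_j), and the prior.
# The binary marginalization is closed-form, so the marginal NLL is exact;
# no sampling is involved.

# Compress a vote matrix to unique rows with multiplicities. Votes are coded
# base-3 (exact in doubles for m <= 33), which makes fitting O(unique rows)
# rather than O(n).
compress_rows <- function(vals) {
  m <- ncol(vals)
  code <- as.numeric((vals + 1L) %*% (3 ^ (seq_len(m) - 1)))
  uniq <- !duplicated(code)
  U <- vals[uniq, , drop = FALSE]
  w <- as.numeric(table(factor(code, levels = code[uniq])))
  list(U = U, w = w, row_of = match(code, code[uniq]))
}

# Symmetric emission table from (alpha, beta): columns abstain / match / miss.
symmetric_emission <- function(alpha, beta) {
  list(pos = cbind(abstain = 1 - beta, pos = beta * alpha,
                   neg = beta * (1 - alpha)),
       neg = cbind(abstain = 1 - beta, pos = beta * (1 - alpha),
                   neg = beta * alpha))
}

# Per-unique-row class-conditional log-likelihoods under an emission table
# (em$pos, em$neg: m x 3 matrices with columns abstain/pos/neg, i.e.
# P(lambda = 0 / +1 / -1 | y)). Returns u x 2 matrix (y = +1, y = -1).
row_loglik <- function(U, em) {
  Apos <- (U == 1L); Aneg <- (U == -1L); Aabs <- (U == 0L)
  lp_pos <- Aabs %*% safe_log(em$pos[, 1]) + Apos %*% safe_log(em$pos[, 2]) +
    Aneg %*% safe_log(em$pos[, 3])
  lp_neg <- Aabs %*% safe_log(em$neg[, 1]) + Apos %*% safe_log(em$neg[, 2]) +
    Aneg %*% safe_log(em$neg[, 3])
  cbind(as.numeric(lp_pos), as.numeric(lp_neg))
}

marginal_nll_emission <- function(U, w, em, prior) {
  lp <- row_loglik(U, em)
  a <- lp[, 1] + log(prior)
  b <- lp[, 2] + log(1 - prior)
  hi <- pmax(a, b)
  ll <- hi + log(exp(a - hi) + exp(b - hi))
  list(nll = -sum(w * ll), r = exp(a - ll))
}

#' Exact marginal negative log-likelihood of a vote matrix
#'
#' Evaluates \eqn{-\sum_i \log \sum_{y \in \{-1,+1\}} P(y) \prod_j
#' P(\Lambda_{ij} \mid y)} under the symmetric accuracy/propensity
#' factorization: \eqn{P(\lambda = 0 \mid y) = 1 - \beta_j},
#' \eqn{P(\lambda = \mathrm{sign}(y) \mid y) = \beta_j \alpha_j},
#' \eqn{P(\lambda = -\mathrm{sign}(y) \mid y) = \beta_j (1 - \alpha_j)}.
#'
#' @param matrix A `label_matrix`.
#' @param alpha,beta Numeric vectors of length m (per-LF accuracy given vote
#'   and vote propensity), strictly inside (0, 1).
#' @param prior Class prior \eqn{P(y = +1)} in (0, 1).
#' @return A nonnegative scalar.
#' @export
#' @examples
#' m <- tibble::tibble(id = "a", lf1 = 1L)
#' gm_marginal_nll(m, alpha = 0.5, beta = 1 - 1e-12, prior = 0.5) # ~ log(2)
gm_marginal_nll <- function(matrix, alpha, beta, prior) {
  validate_label_matrix(matrix)
  vals <- lm_values(matrix)
  if (length(alpha) != ncol(vals) || length(beta) != ncol(vals)) {
    abort("`alpha` and `beta` must have one entry per LF column.")
  }
  stopifnot_scalar_prob(prior, "prior")
  cr <- compress_rows(vals)
  out <- marginal_nll_emission(cr$U, cr$w, symmetric_emission(alpha, beta),
                               prior)
  if (!is.finite(out$nll)) abort("non-finite NLL; check parameter values.")
  out$nll
}

# Derived classical summaries from an emission table.
derived_alpha_beta <- function(em, prior) {
  vote_pos <- em$pos[, 2] + em$pos[, 3]   # P(vote | y = +1)
  vote_neg <- em$neg[, 2] + em$neg[, 3]
  beta <- prior * vote_pos + (1 - prior) * vote_neg
  correct <- prior * em$pos[, 2] + (1 - prior) * em$neg[, 3]
  alpha <- ifelse(beta > 0, correct / beta, NA_real_)
  list(alpha = alpha, beta = beta)
}

#' Fit the generative label model
#'
#' Maximum marginal likelihood for the latent-class vote model, by
#' expectation-maximization on the exact binary marginalization: the E-step
#' computes each row's posterior \eqn{P(y = +1 \mid \Lambda_i)}, the M-step
#' re-estimates the class-conditional emission probabilities (and, when
#' `learn_prior`, the class prior) in closed form. EM monotonically
#' decreases the NLL, so the final NLL never exceeds the initial one, and
#' the whole fit is deterministic given the data and initialization.
#' Initialization tilts each LF's observed vote rates toward
#' better-than-chance accuracy (`alpha_init`, default 0.7) — the regime the
#' method assumes — which selects the label orientation; the class prior
#' starts at `prior_init`.
#'
#' @param matrix A `label_matrix`.
#' @param learn_prior Learn \eqn{\pi} (default) or keep it fixed at
#'   `prior_init` — useful in simulations where the prior is known.
#' @param prior_init Initial (or fixed) class prior.
#' @param alpha_init Assumed initial accuracy-given-vote used to orient the
#'   initialization, recycled over LFs.
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Relative NLL convergence tolerance (default 1e-6).
#' @param seed Integer seed recorded in the fit metadata (the fit itself is
#'   deterministic).
#' @return A `gm_fit` object: `alpha` (accuracy given vote), `beta` (vote
#'   propensity), `prior`, the full `emission` table, `lf_names`, and
#'   `fit_meta` (initial/final NLL, iterations, convergence flag, seed).
#' @export
#' @examples
#' m <- tibble::tibble(id = as.character(1:4),
#'                     lf1 = c(1L, 1L, -1L, 0L),
#'                     lf2 = c(1L, 0L, -1L, -1L),
#'                     lf3 = c(0L, 1L, -1L, -1L))
#' fit <- fit_generative_model(m)
#' tidy(fit)
fit_generative_model <- function(matrix, learn_prior = TRUE,
                                 prior_init = 0.5, alpha_init = 0.7,
                                 max_iter = 1000L, tol = 1e-6, seed = 1L) {
  validate_label_matrix(matrix)
  vals <- lm_values(matrix)
  m <- ncol(vals)
  if (m < 3L) {
    warn(paste("fewer than 3 labeling functions: per-LF accuracies are not",
               "identifiable; estimates will lean on the initialization."))
  }
  cr <- compress_rows(vals)
  U <- cr$U; w <- cr$w; n <- sum(w)
  Aabs <- (U == 0L) * 1; Apos <- (U == 1L) * 1; Aneg <- (U == -1L) * 1
  eps <- 1e-6

  # Initialization: split each LF's observed vote-sign rates between the two
  # classes at odds alpha_init : (1 - alpha_init), so votes start out
  # better than chance and the labels orient consistently.
  q0 <- colMeans(vals == 0L); qp <- colMeans(vals == 1L)
  qn <- colMeans(vals == -1L)
  a0 <- rep_len(alpha_init, m)
  em <- list(pos = cbind(q0, 2 * qp * a0, 2 * qn * (1 - a0)),
             neg = cbind(q0, 2 * qp * (1 - a0), 2 * qn * a0))
  clamp_norm <- function(p) {
    p <- pmin(pmax(p, eps), 1 - eps)
    p / rowSums(p)
  }
  em$pos <- clamp_norm(em$pos); em$neg <- clamp_norm(em$neg)
  prior <- prior_init

  cur <- marginal_nll_emission(U, w, em, prior)
  nll0 <- cur$nll
  nll_prev <- nll0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- cur$r
    wr <- w * r; wn <- w * (1 - r)
    sp <- sum(wr); sn <- sum(wn)
    em$pos <- clamp_norm(cbind(crossprod(Aabs, wr), crossprod(Apos, wr),
                               crossprod(Aneg, wr)) / sp)
    em$neg <- clamp_norm(cbind(crossprod(Aabs, wn), crossprod(Apos, wn),
                               crossprod(Aneg, wn)) / sn)
    if (learn_prior) prior <- min(max(sp / n, eps), 1 - eps)
    cur <- marginal_nll_emission(U, w, em, prior)
    if (!is.finite(cur$nll)) {
      abort("non-finite NLL during optimization; check the label matrix.")
    }
    if (abs(nll_prev - cur$nll) < tol * (abs(nll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    nll_prev <- cur$nll
  }

  dv <- derived_alpha_beta(em, prior)
  dimnames(em$pos) <- dimnames(em$neg) <-
    list(colnames(vals), c("abstain", "pos", "neg"))
  structure(list(
    alpha = setNames(as.numeric(dv$alpha), colnames(vals)),
    beta = setNames(as.numeric(dv$beta), colnames(vals)),
    prior = prior,
    emission = em,
    learn_prior = learn_prior,
    lf_names = colnames(vals),
    fit_meta = list(initial_nll = nll0, final_nll = cur$nll,
                    iterations = iter, converged = converged,
                    seed = as.integer(seed))
  ), class = "gm_fit")
}

#' @export
print.gm_fit <- function(x, ...) {
  cat("<gm_fit> generative label model,", length(x$alpha), "LFs\n")
  cat(sprintf("  prior P(y=+1) = %.3f%s\n", x$prior,
              if (x$learn_prior) "" else " (fixed)"))
  cat(sprintf("  NLL %.4f -> %.4f (%s, %d EM iterations)\n",
              x$fit_meta$initial_nll, x$fit_meta$final_nll,
              if (x$fit_meta$converged) "converged" else "iteration limit",
              x$fit_meta$iterations))
  print(tidy(x), n = 8)
  invisible(x)
}

#' @describeIn fit_generative_model Per-LF tidy summary (`lf`, `accuracy`,
#'   `propensity`).
#' @param x A `gm_fit`.
#' @param ... Unused.
#' @method tidy gm_fit
#' @export
tidy.gm_fit <- function(x, ...) {
  tibble(lf = x$lf_names, accuracy = as.numeric(x$alpha),
         propensity = as.numeric(x$beta))
}

#' @describeIn fit_generative_model One-row fit summary.
#' @method glance gm_fit
#' @export
glance.gm_fit <- function(x, ...) {
  tibble(prior = x$prior, nll = x$fit_meta$final_nll,
         iterations = as.integer(x$fit_meta$iterations),
         converged = x$fit_meta$converged, n_lf = length(x$alpha))
}

#' Simulate a vote matrix from the symmetric generative model
#'
#' Draws an n x m label matrix directly from the accuracy/propensity
#' factorization with known parameters: each LF votes with probability
#' \eqn{\beta_j}, and a vote matches the true label's sign with probability
#' \eqn{\alpha_j}, independently across LFs given the label. The canonical
#' well-specified setting for parameter-recovery and estimation-error
#' scaling studies.
#'
#' @param alpha,beta Per-LF accuracy and propensity in (0, 1).
#' @param prior Class prior \eqn{P(y = +1)}.
#' @param n Number of examples.
#' @param seed Integer seed.
#' @return A list: `matrix` (a `label_matrix`) and `y` (the true labels in
#'   \{-1, 1\}).
#' @export
simulate_label_matrix <- function(alpha, beta, prior, n, seed = 1L) {
  m <- length(alpha)
  stopifnot(length(beta) == m, m >= 1L, n >= 1L)
  with_seed(seed, {
    y <- ifelse(runif(n) < prior, 1L, -1L)
    vals <- vapply(seq_len(m), function(j) {
      v <- integer(n)
      votes <- runif(n) < beta[j]
      correct <- runif(n) < alpha[j]
      v[votes] <- ifelse(correct[votes], y[votes], -y[votes])
      v
    }, integer(n))
    colnames(vals) <- paste0("lf", seq_len(m))
    tbl <- bind_cols(tibble(id = sprintf("sim%06d", seq_len(n))),
                     as_tibble(as.data.frame(vals)))
    list(matrix = new_label_matrix(tbl), y = y)
  })
}

#' Posterior probabilistic labels from a fitted generative model
#'
#' Exact Bayes under the conditional-independence model:
#' \eqn{P(y = +1 \mid \Lambda_i; \hat\theta)}. Rows on which every LF
#' abstains carry no evidence beyond the abstention pattern (and exactly
#' the prior under the symmetric factorization), and are flagged
#' `covered = FALSE` so downstream consumers can exclude them.
#'
#' @param matrix A `label_matrix`.
#' @param fit A `gm_fit`, or a list with `alpha`, `beta`, `prior` (the
#'   symmetric factorization is then assumed).
#' @return A `prob_labels` tibble with `source = "GM"`.
#' @export
posterior_labels <- function(matrix, fit) {
  validate_label_matrix(matrix)
  vals <- lm_values(matrix)
  if (length(fit$alpha) != ncol(vals)) {
    abort("fit dimension does not match the label matrix.")
  }
  em <- fit$emission %||% symmetric_emission(fit$alpha, fit$beta)
  cr <- compress_rows(vals)
  lp <- row_loglik(cr$U, em)
  a <- lp[, 1] + log(fit$prior)
  b <- lp[, 2] + log(1 - fit$prior)
  r <- sigmoid(a - b)[cr$row_of]
  covered <- rowSums(vals != 0L) > 0L
  new_prob_labels(matrix$id, r, covered, "GM")
}
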