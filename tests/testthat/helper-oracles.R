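# Independent oracles and small fixture builders. These deliberately avoid
# the package's own vectorized code paths: plain loops and direct formula
# evaluation, so they can stand as cross-checks.

# Simulate a vote matrix from the symmetric accuracy/propensity model,
# written independently of crossdp::simulate_label_matrix().
sim_matrix_oracle <- function(alpha, beta, prior, n, seed) {
  set.seed(seed)
  m <- length(alpha)
  y <- integer(n)
  vals <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    y[i] <- if (runif(1) < prior) 1L else -1L
    for (j in seq_len(m)) {
      if (runif(1) < beta[j]) {
        vals[i, j] <- if (runif(1) < alpha[j]) y[i] else -y[i]
      }
    }
  }
  colnames(vals) <- paste0("lf", seq_len(m))
  tbl <- dplyr::bind_cols(tibble::tibble(id = as.character(seq_len(n))),
                          tibble::as_tibble(as.data.frame(vals)))
  list(matrix = tbl, y = y)
}

# Brute-force posterior P(y = +1 | row) by direct enumeration of the joint
# P(y, lambda) under the symmetric factorization.
brute_posterior <- function(row, alpha, beta, prior) {
  joint <- function(ycls) {
    p <- if (ycls == 1L) prior else 1 - prior
    for (j in seq_along(row)) {
      p <- p * if (row[j] == 0L) {
        1 - beta[j]
      } else if (row[j] == ycls) {
        beta[j] * alpha[j]
      } else {
        beta[j] * (1 - alpha[j])
      }
    }
    p
  }
  joint(1L) / (joint(1L) + joint(-1L))
}

# All-pairs ROC-AUC oracle, O(n^2), ties counted one-half.
auc_pairs <- function(scores, labels) {
  y <- ifelse(labels %in% c(1, "1"), 1, 0)
  if (all(labels %in% c(-1, 1))) y <- (labels + 1) / 2
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# A small random label matrix for property tests.
rand_label_matrix <- function(n, m, seed) {
  set.seed(seed)
  vals <- matrix(sample(c(-1L, 0L, 1L), n * m, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)), n, m)
  colnames(vals) <- paste0("lf", seq_len(m))
  dplyr::bind_cols(tibble::tibble(id = as.character(seq_len(n))),
                   tibble::as_tibble(as.data.frame(vals)))
}

# A tiny paired corpus with a deterministic structure, for IO and pipeline
# plumbing tests.
tiny_corpus <- function() {
  tibble::tibble(
    id = sprintf("r%02d", 1:6),
    text = c("large pneumothorax on the left",
             "no pneumothorax seen",
             "clear lungs heart normal",
             "pneumonia in right lower lobe",
             "no effusion no pneumothorax",
             "unremarkable study"),
    split = c("train", "train", "train", "train", "dev", "test")
  )
}
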