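# ROC analysis and the DeLong test for paired ROC-AUC comparison.

normalize_binary_labels <- function(labels) {
  y <- as.numeric(labels)
  if (all(y %in% c(-1, 1))) y <- (y + 1) / 2
  if (!all(y %in% c(0, 1))) abort("labels must be binary ({-1,1} or {0,1}).")
  if (length(unique(y)) < 2L) {
    abort("both classes must be present to compute ROC statistics.")
  }
  y
}

#' Area under the ROC curve
#'
#' The Mann–Whitney formulation: the probability that a uniformly random
#' positive example outscores a uniformly random negative one, with ties
#' counted one-half. Computed from mid-ranks in O(n log n).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels in `{-1, 1}` or `{0, 1}`; both classes must
#'   be present.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
roc_auc <- function(scores, labels) {
  y <- normalize_binary_labels(labels)
  if (length(scores) != length(y)) abort("`scores` and `labels` must align.")
  r <- rank(scores)  # mid-ranks handle ties
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values: for each positive, the fraction of negatives it
# outscores (ties 1/2), and symmetrically for negatives.
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg))
  v10 <- (all_r[seq_len(m)] - rank(pos)) / n          # per-positive placements
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(neg)) / m  # per-negative placements
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC-AUCs
#'
#' The nonparametric paired test of DeLong, DeLong and Clarke-Pearson for
#' the difference between the ROC-AUCs of two score vectors evaluated on the
#' same examples, computed with mid-rank placement values (numerically
#' stable under ties). Identical score vectors yield `z = 0`, `p = 1` by
#' convention.
#'
#' @param scores_a,scores_b Paired score vectors on the same examples.
#' @param labels Binary labels (both classes present).
#' @return A `delong_result` list: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_value` (two-sided normal).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- normalize_binary_labels(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    abort("score vectors and labels must align on the same examples.")
  }
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  # 2x2 covariance of (auc_a, auc_b) from placement components
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff <- pa$auc - pb$auc
  if (isTRUE(all.equal(scores_a, scores_b)) || abs(diff) < 1e-15) {
    z <- 0; p <- 1
  } else if (var_diff <= 0) {
    abort("zero estimated variance with unequal AUCs; scores may be degenerate.")
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p_value = p, n_pos = m, n_neg = n),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong test: AUC_a = %.4f, AUC_b = %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' @method tidy delong_result
#' @export
tidy.delong_result <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, estimate = x$auc_a - x$auc_b,
         statistic = x$z, p_value = x$p_value)
}

#' Threshold-based evaluation report
#'
#' ROC-AUC plus precision, recall and F1 at a fixed score threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes present).
#' @param threshold Score cutoff for the hard prediction (default 0.5).
#' @return A one-row tibble: `roc_auc`, `precision`, `recall`, `f1`,
#'   `n_pos`, `n_neg`.
#' @export
evaluation_report <- function(scores, labels, threshold = 0.5) {
  y <- normalize_binary_labels(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tibble(roc_auc = roc_auc(scores, y), precision = precision,
         recall = recall, f1 = f1, n_pos = sum(y == 1), n_neg = sum(y == 0))
}
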