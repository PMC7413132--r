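# Labeling functions, label matrices, majority vote and LF diagnostics.

#' Create a labeling function
#'
#' A labeling function (LF) is a deterministic heuristic mapping one
#' auxiliary-modality example (its token sequence, and optionally the full
#' example record) to a vote: `+1` (positive class), `-1` (negative class),
#' or `0` (abstain). LFs are the unit of supervision in data programming;
#' they may overlap and conflict freely, and the generative label model is
#' responsible for denoising them.
#'
#' @param name Unique identifier for the LF (used as the label-matrix column
#'   name).
#' @param fn A function of the example's token vector (and, when
#'   `needs_meta = TRUE`, a second argument holding the example as a list)
#'   returning exactly one of `-1L`, `0L`, `1L`.
#' @param needs_meta Should `fn` receive the whole example record as a second
#'   argument? Defaults to `FALSE`, which is faster.
#' @return An object of class `labeling_function`.
#' @export
#' @examples
#' lf <- labeling_function("lf_pneumo", function(tokens) {
#'   if (any(startsWith(tokens, "pneumo"))) 1L else 0L
#' })
#' lf$fn(c("small", "pneumothorax", "noted"))
labeling_function <- function(name, fn, needs_meta = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  structure(list(name = name, fn = fn, needs_meta = isTRUE(needs_meta)),
            class = "labeling_function")
}

#' @export
print.labeling_function <- function(x, ...) {
  cat("<labeling_function>", x$name, "\n")
  invisible(x)
}

#' Keyword labeling function
#'
#' Votes `vote` when `term` occurs in the report *unnegated*, i.e. at some
#' position not immediately preceded by the token `"no"`; abstains otherwise.
#' With `prefix = TRUE` the match is on the token prefix (e.g. `"pneumo"`
#' matches `"pneumothorax"`).
#'
#' @param term Token (or token prefix) to match, lowercase.
#' @param vote `+1L` or `-1L`.
#' @param prefix Match token prefixes instead of whole tokens.
#' @param name Optional LF name; defaults to `lf_<term>`.
#' @return A `labeling_function`.
#' @export
lf_keyword <- function(term, vote = 1L, prefix = FALSE,
                       name = paste0("lf_", term)) {
  term <- tolower(term)
  vote <- as.integer(vote)
  stopifnot(vote %in% c(-1L, 1L))
  fn <- function(tokens) {
    hit <- if (prefix) startsWith(tokens, term) else tokens == term
    idx <- which(hit)
    if (length(idx) == 0L) return(0L)
    unnegated <- idx[idx == 1L | tokens[pmax(idx - 1L, 1L)] != "no"]
    if (length(unnegated) > 0L) vote else 0L
  }
  labeling_function(name, fn)
}

#' Negation-aware labeling function
#'
#' Votes `vote` (by default `-1`, i.e. normal) when the bigram
#' `"no <term>"` occurs in the report; abstains otherwise.
#'
#' @inheritParams lf_keyword
#' @export
lf_negated_keyword <- function(term, vote = -1L,
                               name = paste0("lf_no_", term)) {
  term <- tolower(term)
  vote <- as.integer(vote)
  stopifnot(vote %in% c(-1L, 1L))
  fn <- function(tokens) {
    n <- length(tokens)
    if (n < 2L) return(0L)
    if (any(tokens[-n] == "no" & tokens[-1L] == term)) vote else 0L
  }
  labeling_function(name, fn)
}

#' Short-report labeling function
#'
#' A structural heuristic: short reports tend to describe normal studies, so
#' this LF votes `-1` when the report has fewer than `min_tokens` tokens and
#' abstains otherwise.
#'
#' @param min_tokens Token-count threshold.
#' @param name Optional LF name.
#' @export
lf_short_report <- function(min_tokens, name = "lf_short_report") {
  min_tokens <- as.integer(min_tokens)
  fn <- function(tokens) if (length(tokens) < min_tokens) -1L else 0L
  labeling_function(name, fn)
}

#' Apply labeling functions to an auxiliary corpus
#'
#' Runs every LF over every example and assembles the label matrix
#' \eqn{\Lambda \in \{-1,0,1\}^{n \times m}}: one row per example in corpus
#' order, one column per LF in list order. An LF that throws an error on an
#' example aborts with the LF name and example id — abstention is a semantic
#' output, not an error state, so silent abstain-on-error would mask bugs.
#'
#' @param corpus A data frame with columns `id` and `text` (a `tokens`
#'   list-column is used if present, and computed via [tokenize_reports()]
#'   otherwise).
#' @param lfs A list of [labeling_function()] objects with unique names.
#' @return A `label_matrix` tibble: column `id` plus one integer column per
#'   LF.
#' @export
#' @examples
#' corpus <- tibble::tibble(
#'   id = c("r1", "r2"),
#'   text = c("large pneumothorax on the left", "clear lungs")
#' )
#' lfs <- list(lf_keyword("pneumo", prefix = TRUE, name = "lf_pneumo"))
#' apply_labeling_functions(corpus, lfs)
apply_labeling_functions <- function(corpus, lfs) {
  corpus <- as_tibble(corpus)
  if (nrow(corpus) == 0L) abort("`corpus` must contain at least one example.")
  if (!all(c("id", "text") %in% names(corpus)) && !"tokens" %in% names(corpus)) {
    abort("`corpus` must have columns `id` and `text` (or `tokens`).")
  }
  if (length(lfs) == 0L) abort("`lfs` must contain at least one labeling function.")
  if (inherits(lfs, "labeling_function")) lfs <- list(lfs)
  nm <- vapply(lfs, function(l) l$name, character(1))
  if (anyDuplicated(nm)) abort("labeling function names must be unique.")
  ids <- as.character(corpus$id)
  if (anyDuplicated(ids)) abort("corpus ids must be unique.")

  tokens <- if ("tokens" %in% names(corpus)) corpus$tokens
            else tokenize_reports(corpus$text)
  meta <- NULL

  cols <- lapply(lfs, function(lf) {
    if (lf$needs_meta && is.null(meta)) {
      meta <<- lapply(seq_len(nrow(corpus)), function(i)
        as.list(corpus[i, setdiff(names(corpus), "tokens")]))
    }
    votes <- integer(length(tokens))
    for (i in seq_along(tokens)) {
      v <- tryCatch(
        if (lf$needs_meta) lf$fn(tokens[[i]], meta[[i]]) else lf$fn(tokens[[i]]),
        error = function(e) abort(sprintf(
          "labeling function '%s' failed on example '%s': %s",
          lf$name, ids[i], conditionMessage(e)))
      )
      if (length(v) != 1L || is.na(v) || !v %in% c(-1, 0, 1)) {
        abort(sprintf(
          "labeling function '%s' returned an invalid vote on example '%s' (must be -1, 0 or 1).",
          lf$name, ids[i]))
      }
      votes[i] <- as.integer(v)
    }
    votes
  })
  names(cols) <- nm
  new_label_matrix(tibble(id = ids, !!!cols))
}

new_label_matrix <- function(tbl) {
  validate_label_matrix(tbl)
  class(tbl) <- unique(c("label_matrix", class(tbl)))
  tbl
}

validate_label_matrix <- function(tbl) {
  if (!"id" %in% names(tbl)) abort("a label matrix needs an `id` column.")
  if (ncol(tbl) < 2L) abort("a label matrix needs at least one LF column.")
  if (nrow(tbl) < 1L) abort("a label matrix needs at least one row.")
  if (anyDuplicated(tbl$id)) abort("label matrix ids must be unique.")
  vals <- as.matrix(tbl[setdiff(names(tbl), "id")])
  bad <- which(!(vals %in% c(-1, 0, 1)) | is.na(vals))
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1) %% nrow(vals)) + 1
    j <- ((bad[1] - 1) %/% nrow(vals)) + 1
    abort(sprintf(
      "label matrix value out of {-1, 0, 1} at row %d (id '%s'), column '%s'.",
      i, tbl$id[i], colnames(vals)[j]))
  }
  invisible(tbl)
}

# Integer vote matrix (n x m) from a label_matrix tibble.
lm_values <- function(matrix) {
  cols <- setdiff(names(matrix), "id")
  out <- as.matrix(as.data.frame(matrix)[cols])
  storage.mode(out) <- "integer"
  rownames(out) <- matrix$id
  out
}

new_prob_labels <- function(id, p_pos, covered, source) {
  stopifnot(source %in% c("MV", "GM", "DM-MV", "DM-GM", "FS"))
  tbl <- tibble(id = as.character(id), p_pos = as.numeric(p_pos),
                covered = as.logical(covered), source = source)
  if (any(tbl$p_pos < 0 | tbl$p_pos > 1, na.rm = TRUE)) {
    abort("probabilistic labels must lie in [0, 1].")
  }
  class(tbl) <- unique(c("prob_labels", class(tbl)))
  tbl
}

#' Overall coverage of a label matrix
#'
#' The fraction of examples on which at least one LF does not abstain.
#'
#' @param matrix A `label_matrix` (see [apply_labeling_functions()]).
#' @return A fraction in `[0, 1]`.
#' @export
label_coverage <- function(matrix) {
  validate_label_matrix(matrix)
  vals <- lm_values(matrix)
  mean(rowSums(vals != 0L) > 0L)
}

#' Majority-vote probabilistic labels
#'
#' The rule-based baseline: per example, label 1 if strictly more `+1` than
#' `-1` votes, 0 if strictly more `-1`, and — under the default
#' `tie_policy = "half"` — 0.5 on exact ties. Rows on which every LF abstains
#' get `covered = FALSE` (value 0.5 under `"half"`); under
#' `tie_policy = "abstain"` all tied rows are additionally marked uncovered.
#'
#' @param matrix A `label_matrix`.
#' @param tie_policy `"half"` (ties get 0.5, maximal uncertainty under the
#'   noise-aware loss) or `"abstain"` (ties are masked out).
#' @return A `prob_labels` tibble (`id`, `p_pos`, `covered`, `source`) with
#'   `source = "MV"`.
#' @export
#' @examples
#' m <- tibble::tibble(id = c("a", "b"), lf1 = c(1L, 0L), lf2 = c(1L, 0L))
#' majority_vote(m)
majority_vote <- function(matrix, tie_policy = c("half", "abstain")) {
  tie_policy <- tryCatch(match.arg(tie_policy),
                         error = function(e) abort(
                           "`tie_policy` must be \"half\" or \"abstain\"."))
  validate_label_matrix(matrix)
  vals <- lm_values(matrix)
  pos <- rowSums(vals == 1L)
  neg <- rowSums(vals == -1L)
  any_vote <- (pos + neg) > 0L
  p <- ifelse(pos > neg, 1, ifelse(neg > pos, 0, 0.5))
  covered <- if (tie_policy == "half") any_vote else any_vote & (pos != neg)
  new_prob_labels(matrix$id, p, covered, "MV")
}

#' Per-LF diagnostics
#'
#' Coverage, overlap, conflict and (against an optional hand-labeled
#' development set) empirical accuracy for every LF — the summary table used
#' while iterating on LF development.
#'
#' @param matrix A `label_matrix`.
#' @param dev_labels Optional data frame with columns `id` and `label`
#'   (values in `{-1, 1}`) on a subset of the matrix ids.
#' @return A tibble with one row per LF: `lf`, `coverage`, `overlap`,
#'   `conflict`, and `empirical_accuracy` (NA without dev labels or where the
#'   LF abstains on all dev rows).
#' @export
lf_diagnostics <- function(matrix, dev_labels = NULL) {
  validate_label_matrix(matrix)
  vals <- lm_values(matrix)
  m <- ncol(vals)
  nonzero <- vals != 0L
  votes_per_row <- rowSums(nonzero)
  coverage <- unname(colMeans(nonzero))
  overlap <- vapply(seq_len(m), function(j)
    mean(nonzero[, j] & (votes_per_row > 1L)), numeric(1))
  conflict <- vapply(seq_len(m), function(j) {
    others <- vals[, -j, drop = FALSE]
    disagree <- nonzero[, j] &
      rowSums(others != 0L & others != vals[, j]) > 0L
    mean(disagree)
  }, numeric(1))

  acc <- rep(NA_real_, m)
  if (!is.null(dev_labels)) {
    dev_labels <- as_tibble(dev_labels)
    stopifnot(all(c("id", "label") %in% names(dev_labels)))
    unknown <- setdiff(as.character(dev_labels$id), matrix$id)
    if (length(unknown) > 0L) {
      abort(sprintf("dev labels reference unknown ids: %s",
                    paste(head(unknown, 3), collapse = ", ")))
    }
    idx <- match(as.character(dev_labels$id), matrix$id)
    y <- as.integer(dev_labels$label)
    if (!all(y %in% c(-1L, 1L))) abort("dev labels must be -1 or 1.")
    sub <- vals[idx, , drop = FALSE]
    acc <- vapply(seq_len(m), function(j) {
      voted <- sub[, j] != 0L
      if (!any(voted)) return(NA_real_)
      mean(sub[voted, j] == y[voted])
    }, numeric(1))
  }
  tibble(lf = colnames(vals), coverage = coverage, overlap = overlap,
         conflict = conflict, empirical_accuracy = acc)
}
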