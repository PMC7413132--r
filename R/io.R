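# Artifact serialization: JSONL corpora, TSV label matrices / probabilistic
# labels / feature tables, JSON generative-model parameters, YAML synthetic
# configs, and run manifests. Integer tables round-trip bit-exactly;
# probabilities are rendered with 17 significant digits so doubles survive
# the trip unchanged.

fmt_double <- function(x) sprintf("%.17g", x)

#' Write / read an auxiliary corpus as JSONL
#'
#' One JSON object per line: `{"id": ..., "text": ..., "split": ...}`.
#'
#' @param data A tibble with columns `id`, `text`, `split`.
#' @param path File path.
#' @return `read_corpus_jsonl()` returns the tibble (with a `tokens`
#'   list-column recomputed by [tokenize_reports()]).
#' @export
write_corpus_jsonl <- function(data, path) {
  data <- as_tibble(data)
  stopifnot(all(c("id", "text", "split") %in% names(data)))
  lines <- vapply(seq_len(nrow(data)), function(i) {
    jsonlite::toJSON(list(id = as.character(data$id[i]),
                          text = data$text[i], split = data$split[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort(sprintf(
                      "malformed JSONL at line %d: %s", i, conditionMessage(e))))
    if (!all(c("id", "text", "split") %in% names(obj))) {
      abort(sprintf("line %d lacks id/text/split fields.", i))
    }
    tibble(id = as.character(obj$id), text = obj$text, split = obj$split)
  })
  out <- bind_rows(rows)
  out$tokens <- tokenize_reports(out$text)
  out
}

#' Write / read a label matrix as TSV
#'
#' Header `id<TAB>lf_1<TAB>...`, integer cells in `{-1, 0, 1}`; values
#' outside that set raise a validation error naming the row and column.
#'
#' @param matrix A `label_matrix`.
#' @param path File path.
#' @export
write_label_matrix <- function(matrix, path) {
  validate_label_matrix(matrix)
  utils::write.table(as.data.frame(matrix), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"id" %in% names(df)) abort("label-matrix TSV needs an `id` column.")
  for (col in setdiff(names(df), "id")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | !(v %in% c(-1L, 0L, 1L)))
    if (length(bad) > 0L) {
      abort(sprintf(
        "invalid label-matrix cell at row %d, column '%s': %s (must be -1, 0 or 1).",
        bad[1], col, df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  new_label_matrix(as_tibble(df))
}

#' Write / read probabilistic labels as TSV
#'
#' Columns `id`, `p_pos` (full-precision decimal), `covered`, `source`.
#'
#' @param labels A `prob_labels` tibble.
#' @param path File path.
#' @export
write_prob_labels <- function(labels, path) {
  df <- data.frame(id = labels$id, p_pos = fmt_double(labels$p_pos),
                   covered = labels$covered, source = labels$source)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prob_labels
#' @export
read_prob_labels <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character", "character",
                                         "logical", "character"))
  new_prob_labels(df$id, as.numeric(df$p_pos), df$covered, df$source[1])
}

#' Write / read a feature table as TSV
#'
#' An `id` column plus numeric feature columns (full precision), with
#' optional `split`, `hand_label` and `exam_id` columns preserved.
#'
#' @param data A tibble.
#' @param path File path.
#' @export
write_features_tsv <- function(data, path) {
  df <- as.data.frame(as_tibble(data)[setdiff(names(data), c("tokens", "text"))])
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- fmt_double(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  out <- as_tibble(df)
  for (col in setdiff(names(out), c("id", "split", "exam_id"))) {
    num <- suppressWarnings(as.numeric(out[[col]]))
    if (!anyNA(num)) out[[col]] <- num
  }
  if ("hand_label" %in% names(out)) out$hand_label <- as.integer(out$hand_label)
  out$id <- as.character(out$id)
  out
}

#' Write / read fitted generative-model parameters as JSON
#'
#' Serializes every field of the fit (accuracies, propensities, prior, fit
#' metadata) at full precision.
#'
#' @param fit A `gm_fit`.
#' @param path File path.
#' @export
write_gm_params <- function(fit, path) {
  obj <- list(lf_names = fit$lf_names,
              alpha = unname(fit$alpha), beta = unname(fit$beta),
              prior = fit$prior, learn_prior = fit$learn_prior,
              fit_meta = fit$fit_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gm_params
#' @export
read_gm_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    alpha = setNames(as.numeric(obj$alpha), obj$lf_names),
    beta = setNames(as.numeric(obj$beta), obj$lf_names),
    prior = as.numeric(obj$prior), learn_prior = isTRUE(obj$learn_prior),
    lf_names = obj$lf_names,
    fit_meta = obj$fit_meta), class = "gm_fit")
}

#' Write / read a synthetic-corpus configuration as YAML
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @export
write_synthetic_config <- function(config, path) {
  obj <- unclass(config)
  obj$keywords <- lapply(seq_len(nrow(config$keywords)), function(i)
    as.list(config$keywords[i, ]))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$keywords <- bind_rows(lapply(obj$keywords, as_tibble))
  obj$filler_vocab <- as.character(obj$filler_vocab)
  do.call(synthetic_config, obj)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, stage timing and the md5
#' digest of every artifact file, so a run can be audited and re-executed.
#'
#' @param artifacts Named character vector of artifact file paths.
#' @param config A list-like configuration snapshot.
#' @param seeds Named list of stage seeds.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest (e.g. the
#'   routing decision log).
#' @export
write_run_manifest <- function(artifacts, config, seeds, path, extra = list()) {
  digests <- vapply(artifacts, function(f) unname(tools::md5sum(f)),
                    character(1))
  obj <- c(list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = seeds,
    artifacts = lapply(seq_along(artifacts), function(i)
      list(name = names(artifacts)[i], path = unname(artifacts[i]),
           md5 = unname(digests[i]))),
    config = config), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
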