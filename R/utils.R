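# Internal helpers shared across modules.

#' Tokenize report text
#'
#' The canonical tokenization used throughout the package: lowercase, then
#' split on runs of non-alphanumeric characters, dropping empty tokens. The
#' rule is deliberately simple and bit-exact so labeling functions behave
#' identically across sessions and platforms.
#'
#' @param text Character vector of raw report texts.
#' @return A list of character vectors, one per input element.
#' @export
#' @examples
#' tokenize_reports("No focal consolidation; heart size normal.")
tokenize_reports <- function(text) {
  out <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(out, function(tk) tk[nzchar(tk)])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards, so library functions never perturb user
# random streams.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds deterministically
#' from one master seed so that a single `--seed` reproduces every artifact.
#' The derivation is a fixed affine map modulo a Mersenne prime, keeping the
#' result a valid 32-bit integer seed.
#'
#' @param master Integer master seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stage) * 104729 + 1) %%
               2147483647)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

# Numerically safe log, clamping away from 0.
safe_log <- function(x, eps = 1e-300) log(pmax(x, eps))

# Logistic and its inverse, clamped to keep optimization finite.
sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

# Normal-approximation confidence interval across seed replicates.
seed_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  m <- mean(x)
  if (length(x) < 2L) {
    return(c(mean = m, lower = m, upper = m))
  }
  half <- qnorm(1 - (1 - level) / 2) * sd(x) / sqrt(length(x))
  c(mean = m, lower = m - half, upper = m + half)
}
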