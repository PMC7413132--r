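test_that("the marginal NLL matches closed-form values", {
  # single always-voting LF at chance accuracy: both classes explain the
  # vote equally, so the marginal is 1/2
  m1 <- tibble::tibble(id = "a", lf1 = 1L)
  expect_equal(gm_marginal_nll(m1, alpha = 0.5, beta = 1, prior = 0.5),
               log(2), tolerance = 1e-12)
  # an abstain contributes -log(1 - beta) regardless of alpha and prior
  m0 <- tibble::tibble(id = "a", lf1 = 0L)
  for (al in c(0.6, 0.9)) for (pr in c(0.3, 0.7)) {
    expect_equal(gm_marginal_nll(m0, al, 0.2, pr), -log(0.8),
                 tolerance = 1e-12)
  }
  # sign symmetry at prior 1/2
  m <- rand_label_matrix(30, 4, 1)
  neg <- m
  for (col in paste0("lf", 1:4)) neg[[col]] <- -neg[[col]]
  a <- runif(4, 0.55, 0.95); b <- runif(4, 0.2, 0.9)
  expect_equal(gm_marginal_nll(m, a, b, 0.5), gm_marginal_nll(neg, a, b, 0.5),
               tolerance = 1e-10)
  expect_error(gm_marginal_nll(m, a[1:2], b, 0.5), "one entry per LF")
})

test_that("posteriors are exact Bayes under the conditional-independence model", {
  # no evidence returns the prior
  m0 <- tibble::tibble(id = "a", lf1 = 0L, lf2 = 0L)
  fit <- list(alpha = c(0.8, 0.9), beta = c(0.5, 0.6), prior = 0.37)
  expect_equal(posterior_labels(m0, fit)$p_pos, 0.37, tolerance = 1e-12)
  expect_false(posterior_labels(m0, fit)$covered)
  # a single vote from an LF with accuracy 0.9 at prior 1/2
  m1 <- tibble::tibble(id = "a", lf1 = 1L)
  expect_equal(
    posterior_labels(m1, list(alpha = 0.9, beta = 0.5, prior = 0.5))$p_pos,
    0.9, tolerance = 1e-12)
  # two conflicting votes from equally accurate LFs cancel
  m2 <- tibble::tibble(id = "a", lf1 = 1L, lf2 = -1L)
  expect_equal(
    posterior_labels(m2, list(alpha = c(0.8, 0.8), beta = c(0.5, 0.5),
                              prior = 0.5))$p_pos,
    0.5, tolerance = 1e-12)
})

test_that("posteriors agree with brute-force enumeration for m <= 3", {
  set.seed(99)
  for (rep in 1:200) {
    m <- sample(1:3, 1)
    alpha <- runif(m, 0.05, 0.95)
    beta <- runif(m, 0.05, 0.95)
    prior <- runif(1, 0.05, 0.95)
    row <- sample(c(-1L, 0L, 1L), m, replace = TRUE)
    tbl <- dplyr::bind_cols(tibble::tibble(id = "a"),
                            tibble::as_tibble(as.data.frame(
                              matrix(row, 1, dimnames = list(NULL, paste0("lf", 1:m))))))
    got <- posterior_labels(tbl, list(alpha = alpha, beta = beta,
                                      prior = prior))$p_pos
    expect_equal(got, brute_posterior(row, alpha, beta, prior),
                 tolerance = 1e-9)
  }
})

test_that("label-switching symmetry holds exactly", {
  for (seed in 1:5) {
    m <- rand_label_matrix(40, 3, seed)
    neg <- m
    for (col in paste0("lf", 1:3)) neg[[col]] <- -neg[[col]]
    alpha <- runif(3, 0.5, 0.95); beta <- runif(3, 0.2, 0.9)
    prior <- runif(1, 0.1, 0.9)
    p1 <- posterior_labels(m, list(alpha = alpha, beta = beta, prior = prior))
    p2 <- posterior_labels(neg, list(alpha = alpha, beta = beta,
                                     prior = 1 - prior))
    expect_equal(p2$p_pos, 1 - p1$p_pos, tolerance = 1e-12)
  }
})

test_that("fitting recovers parameters from model-simulated votes", {
  alpha <- c(0.6, 0.65, 0.75, 0.85, 0.9)
  beta <- rep(0.7, 5)
  sim <- sim_matrix_oracle(alpha, beta, prior = 0.5, n = 10000, seed = 21)
  fit <- fit_generative_model(sim$matrix, seed = 1)
  expect_lt(mean(abs(fit$alpha - alpha)), 0.05)
  expect_lt(mean(abs(fit$beta - beta)), 0.02)
  expect_lte(fit$fit_meta$final_nll, fit$fit_meta$initial_nll)
  expect_true(fit$fit_meta$converged)
  expect_true(is.finite(fit$fit_meta$final_nll))
  # posteriors rank the true label well
  pl <- posterior_labels(sim$matrix, fit)
  expect_gt(roc_auc(pl$p_pos, sim$y), 0.9)
  # determinism: refitting gives bit-identical parameters
  fit2 <- fit_generative_model(sim$matrix, seed = 1)
  expect_identical(fit$alpha, fit2$alpha)
  expect_identical(fit$prior, fit2$prior)
})

test_that("an LF duplicating the true label is ranked most accurate", {
  alpha <- c(0.7, 0.75, 0.65, 0.8)
  beta <- rep(0.6, 4)
  sim <- sim_matrix_oracle(alpha, beta, prior = 0.5, n = 5000, seed = 5)
  m <- sim$matrix
  m$lf_truth <- as.integer(sim$y)
  fit <- fit_generative_model(m, seed = 1)
  expect_identical(names(which.max(fit$alpha)), "lf_truth")
  expect_gt(fit$alpha[["lf_truth"]], 0.98)
})

test_that("fewer than three LFs warns about identifiability", {
  m <- tibble::tibble(id = as.character(1:20),
                      lf1 = rep(c(1L, -1L, 0L, 1L), 5),
                      lf2 = rep(c(1L, 0L, -1L, 1L), 5))
  expect_warning(fit_generative_model(m, seed = 1), "identifiab")
})

test_that("simulate_label_matrix is deterministic and correctly shaped", {
  s1 <- simulate_label_matrix(c(0.8, 0.7), c(0.5, 0.4), 0.3, 500, seed = 3)
  s2 <- simulate_label_matrix(c(0.8, 0.7), c(0.5, 0.4), 0.3, 500, seed = 3)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$y, s2$y)
  expect_identical(dim(s1$matrix), c(500L, 3L))
  expect_true(all(s1$y %in% c(-1L, 1L)))
  # realized vote rates near beta
  expect_equal(mean(s1$matrix$lf1 != 0), 0.5, tolerance = 0.08)
})
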