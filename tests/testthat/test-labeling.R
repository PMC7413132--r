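test_that("labeling functions vote on keyword evidence and abstain otherwise", {
  corpus <- tiny_corpus()
  lfs <- list(
    lf_keyword("pneumo", prefix = TRUE, name = "lf_pneumo"),
    lf_negated_keyword("pneumothorax")
  )
  lam <- apply_labeling_functions(corpus, lfs)

  expect_s3_class(lam, "label_matrix")
  expect_identical(dim(lam), c(6L, 3L))
  expect_identical(names(lam), c("id", "lf_pneumo", "lf_no_pneumothorax"))
  # prefix match on "pneumothorax" votes abnormal
  expect_identical(lam$lf_pneumo[lam$id == "r01"], 1L)
  # negated mention: matcher abstains, negation LF votes normal
  expect_identical(lam$lf_pneumo[lam$id == "r02"], 0L)
  expect_identical(lam$lf_no_pneumothorax[lam$id == "r02"], -1L)
  # a report with no trigger tokens is an all-abstain row
  expect_true(all(lam[lam$id == "r03", -1] == 0L))
  expect_true(all(unlist(lam[-1]) %in% c(-1L, 0L, 1L)))
})

test_that("an LF that throws is a hard error naming the LF and example", {
  corpus <- tiny_corpus()
  bad <- labeling_function("lf_bad", function(tokens) {
    if ("pneumonia" %in% tokens) stop("lexicon lookup failed")
    0L
  })
  expect_error(apply_labeling_functions(corpus, list(bad)),
               "lf_bad.*r04")
  out_of_range <- labeling_function("lf_two", function(tokens) 2L)
  expect_error(apply_labeling_functions(corpus, list(out_of_range)),
               "invalid vote")
  expect_error(
    apply_labeling_functions(corpus, list(bad, bad)), "unique")
})

test_that("coverage is the fraction of rows with at least one vote", {
  m <- tibble::tibble(id = as.character(1:4),
                      a = c(1L, 0L, 0L, 1L), b = c(0L, 0L, -1L, 1L))
  expect_equal(label_coverage(m), 0.75)
  expect_equal(label_coverage(tibble::tibble(id = "x", a = 0L)), 0)
  expect_equal(label_coverage(tibble::tibble(id = "x", a = 1L, b = -1L)), 1)
  # property: coverage == 1 - fraction of all-zero rows, by row enumeration
  for (seed in 1:5) {
    m <- rand_label_matrix(40, 4, seed)
    vals <- as.matrix(m[-1])
    frac_zero <- mean(apply(vals, 1, function(r) all(r == 0L)))
    expect_equal(label_coverage(m), 1 - frac_zero)
  }
})

test_that("majority vote follows strict majority with explicit tie handling", {
  m <- tibble::tibble(id = as.character(1:4),
                      a = c(1L, 0L, 1L, 0L),
                      b = c(1L, 0L, -1L, 0L),
                      c = c(-1L, 0L, 0L, 1L))
  mv <- majority_vote(m)
  expect_s3_class(mv, "prob_labels")
  expect_identical(mv$source, rep("MV", 4))
  expect_equal(mv$p_pos, c(1, 0.5, 0.5, 1))          # majority, all-abstain, tie
  expect_identical(mv$covered, c(TRUE, FALSE, TRUE, TRUE))
  mv2 <- majority_vote(m, tie_policy = "abstain")
  expect_identical(mv2$covered, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(majority_vote(m, tie_policy = "random"), "tie_policy")
})

test_that("majority vote is invariant to column order and flips under negation", {
  for (seed in 1:5) {
    m <- rand_label_matrix(30, 5, seed)
    mv <- majority_vote(m)
    perm <- m[c("id", sample(paste0("lf", 1:5)))]
    expect_equal(majority_vote(perm)$p_pos, mv$p_pos)
    neg <- m
    for (col in paste0("lf", 1:5)) neg[[col]] <- -neg[[col]]
    expect_equal(majority_vote(neg)$p_pos, 1 - mv$p_pos)
  }
})

test_that("LF diagnostics report coverage, overlap, conflict and dev accuracy", {
  single <- tibble::tibble(id = as.character(1:4), a = c(1L, 0L, -1L, 0L))
  d1 <- lf_diagnostics(single)
  expect_equal(d1$coverage, 0.5)
  expect_equal(d1$overlap, 0)
  expect_equal(d1$conflict, 0)
  expect_true(is.na(d1$empirical_accuracy))

  dup <- tibble::tibble(id = as.character(1:4),
                        a = c(1L, 0L, -1L, 0L), b = c(1L, 0L, -1L, 0L))
  d2 <- lf_diagnostics(dup)
  expect_equal(d2$overlap, d2$coverage)
  expect_equal(d2$conflict, c(0, 0))

  clash <- tibble::tibble(id = as.character(1:3),
                          a = rep(1L, 3), b = rep(-1L, 3))
  expect_equal(lf_diagnostics(clash)$conflict, c(1, 1))

  dev <- tibble::tibble(id = c("1", "3"), label = c(1L, 1L))
  d3 <- lf_diagnostics(single, dev)
  expect_equal(d3$empirical_accuracy, 0.5)  # +1 on id 1 right, -1 on id 3 wrong
  expect_error(lf_diagnostics(single, tibble::tibble(id = "zz", label = 1L)),
               "unknown ids")

  # invariant: conflict <= overlap <= coverage on random matrices
  for (seed in 1:5) {
    d <- lf_diagnostics(rand_label_matrix(50, 4, seed))
    expect_true(all(d$conflict <= d$overlap + 1e-12))
    expect_true(all(d$overlap <= d$coverage + 1e-12))
  }
})

test_that("label matrices validate their domain", {
  bad <- tibble::tibble(id = c("a", "b"), lf1 = c(1L, 2L))
  expect_error(apply_labeling_functions(tibble::tibble(id = "x", text = "a"), list()),
               "at least one")
  expect_error(majority_vote(bad), "row 2.*lf1")
})
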