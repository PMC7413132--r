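test_that("corpus generation is deterministic and matches its configuration", {
  cfg <- synthetic_config(n_train = 9300, n_dev = 200, n_test = 500, seed = 42)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth, c2$truth)
  expect_identical(nrow(c1$data), 10000L)
  expect_identical(sum(c1$data$split == "dev"), 200L)

  # class balance within binomial concentration of the prior
  frac <- mean(c1$truth$y == 1L)
  expect_gt(frac, 0.48); expect_lt(frac, 0.52)

  # realized keyword sensitivity matches the configured emission rate
  abn <- c1$truth$y == 1L
  for (k in seq_len(nrow(cfg$keywords))) {
    term <- cfg$keywords$term[k]
    affirm <- vapply(c1$data$tokens, function(tk) {
      idx <- which(tk == term)
      length(idx) > 0 && any(idx == 1L | tk[pmax(idx - 1L, 1L)] != "no")
    }, logical(1))
    expect_equal(mean(affirm[abn]), cfg$keywords$sensitivity[k],
                 tolerance = 0.03)
  }
  # normal reports are shorter on average
  lens <- lengths(c1$data$tokens)
  expect_gt(mean(lens[abn]), mean(lens[!abn]))
  # hand labels equal truth at zero label noise
  expect_identical(c1$data$hand_label, c1$truth$y)
})

test_that("built-in labeling functions implement the three heuristic families", {
  cfg <- synthetic_config()
  lfs <- builtin_labeling_functions(cfg)
  expect_length(lfs, 2 * nrow(cfg$keywords) + 1)
  by_name <- setNames(lfs, vapply(lfs, function(l) l$name, character(1)))
  expect_identical(by_name$lf_opacity$fn(c("subtle", "opacity", "seen")), 1L)
  expect_identical(by_name$lf_opacity$fn(c("no", "opacity")), 0L)
  expect_identical(by_name$lf_no_opacity$fn(c("no", "opacity")), -1L)
  expect_identical(by_name$lf_no_opacity$fn(c("opacity")), 0L)
  short <- rep("w01", cfg$length_threshold - 1L)
  long <- rep("w01", cfg$length_threshold)
  expect_identical(by_name$lf_short_report$fn(short), -1L)
  expect_identical(by_name$lf_short_report$fn(long), 0L)
})

test_that("analytic LF statistics are exact against Monte Carlo at large n", {
  cfg <- synthetic_config(n_train = 100000L, n_dev = 0L, n_test = 0L, seed = 77)
  # n_dev/n_test 0 keeps this purely a counting exercise
  cfg$n_dev <- 0L; cfg$n_test <- 0L
  corpus <- generate_corpus(cfg)
  lam <- apply_labeling_functions(corpus$data, builtin_labeling_functions(cfg))
  truth <- corpus$truth$y
  an <- analytic_lf_statistics(cfg)
  vals <- as.matrix(lam[-1])
  for (j in seq_len(ncol(vals))) {
    voted <- vals[, j] != 0L
    mc_prop <- mean(voted)
    mc_acc <- mean(vals[voted, j] == truth[voted])
    expect_equal(an$propensity[j], mc_prop, tolerance = 0.01)
    expect_equal(an$accuracy[j], mc_acc, tolerance = 0.01)
  }
})

test_that("analytic statistics handle degenerate and monotone cases", {
  kw <- tibble::tibble(term = "marker", sensitivity = 1, specificity = 1,
                       negation_rate = 0.2, negation_rate_abnormal = 0)
  cfg <- synthetic_config(keywords = kw)
  an <- analytic_lf_statistics(cfg)
  expect_equal(an$accuracy[an$lf == "lf_marker"], 1.0)
  expect_equal(an$accuracy[an$lf == "lf_no_marker"], 1.0)
  # raising sensitivity cannot decrease the matcher's coverage
  cfg_lo <- synthetic_config(keywords = dplyr::mutate(kw, sensitivity = 0.4))
  cfg_hi <- synthetic_config(keywords = dplyr::mutate(kw, sensitivity = 0.8))
  expect_gte(
    analytic_lf_statistics(cfg_hi)$propensity[1],
    analytic_lf_statistics(cfg_lo)$propensity[1])
})

test_that("scenario presets realize their documented regimes", {
  scr <- scenario_preset("screening", n_train = 4000, seed = 2)
  tgt <- scenario_preset("targeted", n_train = 4000, seed = 2)
  expect_error(scenario_preset("deployment"), "unknown preset")

  an_s <- analytic_lf_statistics(scr)
  expect_true(all(an_s$accuracy > 0.78))       # accurate heuristics
  co_s <- generate_corpus(scr)
  lam_s <- apply_labeling_functions(co_s$data[co_s$data$split == "train", ],
                                    builtin_labeling_functions(scr))
  cov_s <- label_coverage(lam_s)
  expect_gt(cov_s, 0.55); expect_lt(cov_s, 0.75)  # low coverage: screening

  an_t <- analytic_lf_statistics(tgt)
  expect_true(all(an_t$accuracy > 0.85))
  co_t <- generate_corpus(tgt)
  lam_t <- apply_labeling_functions(co_t$data[co_t$data$split == "train", ],
                                    builtin_labeling_functions(tgt))
  expect_gt(label_coverage(lam_t), 0.95)          # high coverage: targeted
})

test_that("configurations validate their probability space", {
  expect_error(synthetic_config(class_prior = 1.2), "probability")
  expect_error(
    synthetic_config(keywords = tibble::tibble(
      term = "x", sensitivity = 0.9, specificity = 0.5, negation_rate = 0.6,
      negation_rate_abnormal = 0)),
    "sum to at most 1")
  expect_error(
    synthetic_config(keywords = crossdp:::default_keywords()[0, ], separability = 0),
    "no learnable signal")
  expect_error(
    synthetic_config(keywords = dplyr::mutate(crossdp:::default_keywords(),
                                              term = c("w01", "b", "c", "d"))),
    "collide")
})
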