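---
title: "Cross-modal data programming: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal data programming: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdp)
library(dplyr)
```

## The problem

Training a classifier over a target modality (an image, a CT volume, a
physiological time series) usually requires hand labels that are slow and
expensive to obtain. But many targets arrive *paired* with an auxiliary
modality — most commonly a free-text report — that encodes the label in a
form domain experts can query cheaply with heuristics. Cross-modal data
programming turns that observation into a training pipeline:

1. Experts write **labeling functions** (LFs): deterministic rules
   \(\lambda_j\) mapping an auxiliary example to a vote in \(\{-1, 0, +1\}\),
   where 0 means *abstain*. Rules may overlap, conflict, and be individually
   unreliable.
2. A **generative label model** is fit, without any hand labels, to the
   \(n \times m\) vote matrix \(\Lambda\) by minimizing the exact negative
   log marginal likelihood
   \(-\sum_i \log \sum_{y \in \{-1,+1\}} P(y)\, \prod_j P(\Lambda_{ij} \mid y)\),
   and its posteriors \(\tilde y_i = P(y_i = +1 \mid \Lambda_i)\) become
   confidence-weighted training labels.
3. Optionally, an **auxiliary-modality classifier** is trained to predict
   \(\tilde y\) from the raw report and evaluated over every training point,
   producing full-coverage *distilled* labels \(\tilde y_a\).
4. A **target-modality classifier** is trained against whichever label set
   was selected, using the **noise-aware loss**
   \(\tilde y\,\ell(s, +1) + (1 - \tilde y)\,\ell(s, -1)\) — the exact
   expectation of the loss under the probabilistic label.

A small hand-labeled development set (200 examples by default, the size used
throughout the applications that motivated this design) is reserved for LF
iteration, early stopping, and the routing rule below. It never enters the
generative-model fit.

## The generative label model

`fit_generative_model()` fits a latent-class model of votes: each LF has
class-conditional emission probabilities \(P(\lambda_j = v \mid y)\) over
\(v \in \{-1, 0, +1\}\), votes are conditionally independent across LFs given
the unobserved label, and the class prior \(\pi = P(y = +1)\) may be learned
or fixed. The binary marginalization is closed form, so the marginal NLL is
exact and the fit uses expectation-maximization: the E-step computes each
row's posterior, the M-step re-estimates emissions (and prior) in closed
form. EM decreases the NLL monotonically; convergence is declared at a
relative NLL change below `tol` (default 1e-6) or after `max_iter` (default
1000) iterations. Emission probabilities are clamped to \([10^{-6},
1-10^{-6}]\) and renormalized, keeping every parameter strictly interior.
Fitting is deterministic given the data and initialization; the seed is
recorded in the fit metadata for provenance.

The user-facing parameters are the classical annotator-model summaries:
**accuracy given vote** \(\alpha_j\) and **vote propensity** \(\beta_j\),
derived by marginalizing the emission table, plus the prior. The widely used
symmetric factorization — \(P(\lambda = 0 \mid y) = 1 - \beta_j\),
\(P(\lambda = \mathrm{sign}(y) \mid y) = \beta_j \alpha_j\) — is the special
case with class-independent abstention, and `gm_marginal_nll()` and
`posterior_labels()` accept plain \((\alpha, \beta, \pi)\) parameters in that
form.

**Why the class-conditional form matters.** Real LFs are one-sided: a
keyword matcher only ever votes \(+1\), and fires almost exclusively on
positive cases, so its abstention pattern is strongly class-dependent. Under
the symmetric factorization with \(\pi = 1/2\), every LF's marginal votes
must be sign-balanced — flatly contradicted by one-sided votes — and the
marginal-likelihood optimum degenerates: the fit drives the prior toward 1
and assigns the negative-voting LFs accuracy 0, destroying the posteriors.
(We verified this numerically; the degenerate solution beats the intended
parameterization by thousands of nats on a 20,000-report corpus, and bounding
\(\alpha > 1/2\) or fixing the prior does not rescue it.) The
class-conditional emission model nests the symmetric one, is identifiable
with \(m \ge 3\) conditionally independent LFs, and recovers both regimes
correctly. With fewer than 3 LFs the accuracies are not identifiable and the
fit warns rather than guessing.

**Initialization.** Each LF's observed vote-sign rates are split between the
two classes at odds `alpha_init : (1 - alpha_init)` (default 0.7 : 0.3).
This encodes the method's standing assumption that LFs are better than
random chance, and — more importantly — it is what selects the label
*orientation*: the marginal likelihood is invariant to globally swapping the
classes, and the better-than-chance initialization picks the mode in which
positive votes indicate the positive class. The prior starts at 0.5 (or the
supplied value when `learn_prior = FALSE`, the mode to use in simulations
where the prior is known).

Rows on which every LF abstains are retained, not dropped: they receive the
posterior implied by their (empty) evidence — exactly the prior under the
symmetric factorization — and are flagged `covered = FALSE` so downstream
consumers can exclude them and coverage can be reported separately.

## Majority vote, ties, and diagnostics

`majority_vote()` is the rule-based baseline: strictly more \(+1\) than
\(-1\) votes gives 1, the reverse gives 0. Exact ties are genuinely
ambiguous, and the default `tie_policy = "half"` assigns 0.5 so that ties
carry maximal uncertainty into the noise-aware loss; `"abstain"` masks them
out instead. All-abstain rows are always marked uncovered. LF development is
supported by `lf_diagnostics()` (coverage, overlap, conflict, and empirical
accuracy against the development set), which satisfies
conflict \(\le\) overlap \(\le\) coverage by construction.

LF exceptions are fatal, not treated as abstain: abstention is a semantic
output, and silently converting bugs into abstains would corrupt the label
model's evidence.

## Classifiers and the noise-aware loss

Both modalities are served by one reference classifier: a small feedforward
network (two tanh hidden layers, widths 16 and 8 by default, sigmoid
output) trained with Adam (learning rate 0.01, batch size 64) on the
noise-aware cross-entropy, with early stopping on the development loss at
patience 3 — training halts once the dev loss has not improved for that many
epochs, and the best-epoch weights are kept. The framework's contract is
architecture-agnostic: anything that emits \(P(y = +1)\) scores and accepts
probabilistic labels can stand in. At this package's scale a compact network
is the deliberate choice: the production-scale recurrent text encoders and
deep image backbones that a deployment would use contribute nothing to the
correctness of the supervision machinery being verified here, and a small
network keeps every run deterministic (given the spec's seed, which controls
initialization and minibatch order) and fast. Auxiliary text is featurized
as bag-of-token indicator features over the training-split vocabulary
(unseen tokens at prediction time map outside the vocabulary and are
dropped) plus one standardized report-length feature; target feature tables
are standardized column-wise using training-split statistics.

Two exactness properties pin the loss down: it is linear in \(\tilde y\)
pointwise, and degenerate labels \(\tilde y \in \{0, 1\}\) reproduce
hard-label training bit for bit (identical loss traces under a shared seed).
Analytic gradients are verified against finite differences in the tests.

The auxiliary model trains only on rows the label source covered:
uncovered rows carry a pure-prior label that contains no information about
the example and would only dilute gradients. This is switchable
(`train_on_uncovered = TRUE`) for sensitivity analyses. The auxiliary model
regresses on the *soft* posterior probabilities rather than thresholded
labels — consistent with the probabilistic-label contract throughout — and
`distill_labels()` then scores every training example, yielding
full-coverage labels tagged `DM-GM` (or `DM-MV` when the model was trained
on majority-vote labels).

When one label applies to a group of target instances (an exam with several
radiographs), instance scores are combined by `aggregate_exam_scores()` as
the arithmetic mean — order-invariant by construction.

## The routing rule

`decide_label_source()` implements the pipeline's heuristic optimizer:
train the auxiliary distillation model only if generative-model coverage
*or* ROC-AUC on the development set is **less than** 90% (both thresholds
configurable; the boundary case exactly at 0.90 uses the GM labels). The
development-set ROC-AUC is computed over covered dev rows only, with
coverage entering the rule as its own criterion — the two quantities are
reported separately, and folding uncovered rows into the AUC would conflate
them. When the rule selects the GM labels, the target model trains on the
GM posteriors verbatim; there is no silent distillation.

## The synthetic corpus generator

`generate_corpus()` emulates paired report/target data with a known latent
binary label:

* **Reports** are token sequences, not natural prose — the LF taxonomy
  (keyword matchers, negation-aware matchers, structural length heuristics)
  needs only token access, and token-level generation keeps every LF's true
  accuracy and propensity available in closed form
  (`analytic_lf_statistics()`, with the length heuristic handled by exact
  convolution of the token-count distribution). Each keyword is affirmed
  with class-conditional probability (sensitivity / 1 − specificity),
  negated as the bigram `"no <term>"` (mostly in normal reports, at a small
  rate in abnormal ones so negation heuristics stay imperfect), and
  embedded in Poisson filler with normal reports shorter — the structural
  signal the length LF exploits.
* **Target features** are class-conditional unit-variance Gaussians whose
  standardized mean separation (`separability`, default 2, i.e. a Bayes
  ROC-AUC of about 0.92 at the default dimension) stands in for task
  difficulty. Default dimension 4; splits default to 2000/200/500
  train/dev/test.
* **Hand labels** equal the truth unless `label_noise > 0`, modeling
  single-annotator prospective labels versus consensus reads.

What passing tests on this generator do **not** show: robustness to natural
clinical language, to correlated LF errors beyond the built-in
keyword/negation exclusivity, or to covariate shift between report and
image; the generator makes no attempt at realistic prose or multi-instance
image structure beyond exam-id grouping.

Two presets mirror the regimes that determine routing.
`scenario_preset("screening")` (broad-abnormality triage) has accurate but
low-coverage heuristics — union coverage ≈ 0.64, accuracies ≈ 0.80–0.98 —
and routes to the auxiliary model; `scenario_preset("targeted")`
(single-pathology detection) has accurate, high-coverage heuristics
(coverage > 0.95) and routes to the GM labels directly. The preset
parameters were fixed once to realize those documented regimes and are not
tuned per experiment.

## Evaluation

`roc_auc()` is the Mann–Whitney probability that a random positive
outscores a random negative, ties counted one-half, computed from mid-ranks
(verified against an all-pairs oracle). `delong_test()` implements the
nonparametric paired comparison of two correlated ROC-AUCs via mid-rank
placement values — numerically stable under ties — with a two-sided normal
p-value; identical score vectors return p = 1 by convention, and zero
estimated variance with unequal AUCs is an error rather than a silent
division. The implementation is cross-checked in the tests against an
independent reference implementation and a sign-flip permutation oracle,
and its type-I error is verified by simulation.

Multi-seed summaries use normal-approximation 95% confidence intervals over
seed replicates (default 5 seeds). `compare_label_sources()` runs the five
supervision arms — MV, GM, DM-MV, DM-GM, and fully supervised — under a
shared seed schedule, reporting development-set label coverage and label
ROC-AUC plus the test ROC-AUC of a target model trained on each arm's
labels; MV/GM label metrics are deterministic, and the FS arm's label
quality is definitionally perfect.

`scaling_experiment()` studies estimation error and model performance as
the unlabeled training set grows. Two sources are deliberately exposed:

* `source = "model"` draws vote matrices from the symmetric generative
  model at the config's analytic LF statistics — the well-specified setting
  in which the accuracy-estimation error provably shrinks as
  \(O(n^{-1/2})\); the measured log-log slope sits near −0.5.
* `source = "corpus"` runs the full report-generation route. Here paired
  keyword/negation LFs are deterministically dependent given the class
  (mutually exclusive votes from one emission draw), so the
  conditional-independence fit carries a small asymptotic bias and the
  error plateaus — a useful, honest illustration of what LF dependence does
  to the label model.

For the performance-versus-data curve, each replicate generates one corpus
at the largest grid size and treats smaller sizes as nested random
subsamples of its training split with the dev and test splits held fixed —
the paired design in which "more unlabeled data" is the only thing changing
along the grid. The packaged study uses a 12-dimensional target and a
1000-example test split, sizes at which the learning curve is still rising
and the per-point means are well resolved.

## Numerical and degenerate-input policy

* Probabilities are clamped away from 0/1 only where a log would otherwise
  overflow (loss evaluation at 1e-12, emissions at 1e-6); posteriors are
  computed on the log scale with log-sum-exp.
* A development set without both classes is an error (ROC-AUC undefined), as
  is a label matrix with zero coverage, an all-uncovered label set, and a
  label-matrix cell outside \(\{-1, 0, 1\}\) (reported with row and column).
* Every stochastic stage draws its seed deterministically from one master
  seed via `derive_seed()`, so a single integer reproduces an entire run,
  and artifacts serialize probabilities at 17 significant digits so doubles
  round-trip exactly.

## A worked miniature

```{r example}
cfg <- scenario_preset("screening", n_train = 800, n_test = 200, seed = 1)
corpus <- generate_corpus(cfg)
lfs <- builtin_labeling_functions(cfg)
res <- run_cross_modal_pipeline(corpus, lfs, pipeline_config(seed = 1))
glance(res)
```

The run reports its routing decision (screening coverage is far below 90%,
so the auxiliary model is trained and its distilled labels used), the
development-set metrics that triggered it, and test ROC-AUC for both the
weakly supervised model and the fully supervised comparator trained on the
same architecture with hand labels.

Custom LFs are one-liners; a small synthetic lexicon ships with the package
for experimentation:

```{r lexicon}
lex <- read.delim(system.file("extdata", "mini_lexicon_synthetic.tsv",
                              package = "crossdp"))
head(lex, 4)
my_lfs <- c(
  lapply(lex$term[lex$polarity == 1][1:3], lf_keyword),
  list(lf_short_report(8))
)
apply_labeling_functions(corpus$data[1:5, ], my_lfs)
```

## Known limitations

* Binary tasks only; the multi-class extension of the label model is out of
  scope.
* No learned correlation structure between LFs: the conditional-independence
  model is the documented interpretation, and dependent LFs bias accuracy
  estimates (quantified by the corpus-source scaling experiment) even when
  posterior label quality remains high.
* The reference classifiers are deliberately small; absolute performance
  numbers on real data would require modality-appropriate architectures
  behind the same probabilistic-classifier contract.
* The development set is assumed i.i.d. with the test distribution; no
  shift diagnostics are provided.
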