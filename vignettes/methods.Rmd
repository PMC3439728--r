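---
title: "Side-effect topic models for drug repositioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-effect topic models for drug repositioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setopics)
```

## The idea

Drugs with similar side-effect profiles tend to be effective for the same
diseases. The safety sections of a drug label — Boxed Warning (BW), Warnings
and Precautions (WP), and Adverse Reactions (AR) — describe a drug's adverse
events in standardized vocabulary, so two drugs whose safety text expresses
the same *themes* of adverse events are candidates for sharing an indication.
`setopics` operationalizes this: it reduces each drug's safety text to counts
of dictionary side-effect terms, models the counts with latent Dirichlet
allocation (LDA), measures drug–drug distance between the resulting topic
mixtures, and asks whether each drug's nearest neighbor is already approved
for one of its indications. A neighbor that shares an indication and lacks a
Boxed Warning is additionally flagged as a potential safer alternative.

## From label text to the drug–term matrix

Labels arrive as JSON-lines records (`read_labels()`). Because one drug is
often marketed under several labels, only the most recent label by effective
date is kept (`dedupe_labels()`); undated records lose to dated ones and
remaining ties are broken by comparing a canonical serialization of the
record, so the result never depends on input order.

Term extraction (`extract_terms()`) is deliberately simple and transparent:
text and dictionary terms are lowercased, punctuation is treated as a token
separator, and terms are matched as whole-token phrases. Overlapping
candidates are resolved longest-match-first with matched tokens consumed, so
"acute abdominal pain" yields one match of *abdominal pain* and no match of
*pain*. There is no stemming or fuzzy matching: a side-effect dictionary such
as the MedDRA lowest-level terms is already exhaustive about surface forms,
and exact matching keeps the mapping from text to counts auditable.

`build_matrix()` concatenates the three safety sections per drug, applies the
extractor, keeps the dictionary terms matched in at least one drug (in
dictionary order), and drops drugs that match nothing (with a warning). The
matrix holds occurrence *counts*, not presence flags, because the LDA
generative model is a token-level model and multiplicities carry information;
`binary = TRUE` is available for sensitivity analysis.

## The topic model

LDA assumes each drug d has a topic mixture $\theta_d \sim
\mathrm{Dirichlet}(\alpha)$ and each topic k a term distribution $\phi_k \sim
\mathrm{Dirichlet}(\beta)$; each token is generated by drawing a topic $z
\sim \theta_d$ and then a term $w \sim \phi_z$, so the marginal probability
of a term in drug d is $P(w) = \sum_k P(w \mid z = k)\,P(z = k)$.

Inference is by collapsed Gibbs sampling (`fit_lda()`), the classical choice
for this model: $\theta$ and $\phi$ are integrated out and each token's topic
label is resampled from

$$p(z_i = k \mid \cdot) \propto
\frac{n_{kw}^{-i} + \beta}{n_k^{-i} + V\beta}\,(n_{dk}^{-i} + \alpha),$$

where the count tables exclude token i. The sampler core is compiled (Rcpp)
and draws from R's RNG stream, so a seed fully determines the fit. Estimates
of $\theta$ and $\phi$ are posterior means $(n_{dk} + \alpha)/(N_d +
K\alpha)$ and $(n_{kw} + \beta)/(n_k + V\beta)$ averaged over thinned
post-burn-in samples (defaults: 1000 sweeps, burn-in 500, lag 10, i.e. 50
samples), which gives lower-variance mixtures than a single final state —
the distance layer downstream depends only on $\theta$. The collapsed joint
log-likelihood is recorded every sweep as a convergence diagnostic
(`autoplot()` on the fit shows the trace), and `debug = TRUE` re-verifies the
count-table invariants after every sweep.

Hyperparameter defaults are the common heuristics $\alpha = 50/K$, $\beta =
0.1$. For *parameter-recovery* experiments against synthetic ground truth the
fit should instead use the priors of the generating process (the package's
tests fit with $\alpha = \beta = 0.1$ on corpora generated with those
values): a strong symmetric prior like $\alpha = 10$ pulls every $\hat\theta_d$
toward uniformity and cannot reproduce sparse mixtures, which is a property
of the estimator, not a sampler defect.

## Choosing the number of topics

The topic count is selected from the PCA eigenvalue spectrum of the
mean-centered drug–term matrix (`compute_spectrum()`, divisor $D-1$,
$n = \min(D-1, V)$ eigenvalues). The information loss of keeping k components
is scored as

$$L(k) = \Bigl|\sum_{i=1}^{n} e_i - \lambda \sum_{i=k+1}^{n} e_i\Bigr|,$$

minimized over $k \in [1, n-1]$ with ties toward the smallest k
(`choose_k()`). With the default penalty $\lambda = 2$ this is the imbalance
$|\sum_{i\le k} e_i - \sum_{i>k} e_i|$, so the selected k is where the
leading components carry closest to half the total variance. Written without
the absolute value the score would be monotone in k and always select
$k = 1$; the magnitude reading is the one that produces the intended balance
behavior, and it makes the selection invariant to rescaling the spectrum.
Centering is applied because that is the standard PCA contract; a
`binarize` flag exposes PCA on presence/absence instead of counts.

Two caveats a user should know. First, the balance criterion is a heuristic,
not a likelihood: it reacts to the variance profile of the matrix, and on
corpora of short documents the leading principal component is dominated by
document-length variation, which pushes the selection toward very small k
(on the package's 60-token synthetic labels it selects k = 1–2 even when the
generating process has five well-separated topics). Second, nothing
downstream requires the selected k: `fit_lda()` and `run_pipeline()` accept
any fixed k, and the end-to-end evaluation in the package's own tests fixes
k at the generating value for exactly this reason, exercising the selection
rule separately against an exhaustive-scan oracle.

## Drug distance and nearest neighbors

Per-drug topic mixtures are compared with the Kullback–Leibler divergence
$D_{KL}(P\|Q) = \sum_i P(i)\ln(P(i)/Q(i))$ (natural log — reported distances
are in nats), symmetrized as $D(A,B) = (D_{KL}(A\|B) + D_{KL}(B\|A))/2$.
Because $\theta$ estimates are Dirichlet-smoothed they are strictly positive,
so no zero-handling heuristics are applied; raw distributions containing
zeros are rejected rather than patched. `pairwise_distances()` fills the
full matrix (exactly symmetric, zero diagonal, tiny negative float noise
clipped at zero) and `nearest_neighbors()` scans each row for the
off-diagonal minimum, breaking exact ties toward the lexicographically
smallest drug id. The neighbor relation is directional, as in the pairing
procedure it implements: A's neighbor need not have A as its own.

## Evaluation

`evaluate_pairs()` intersects each query drug's indication set with its
neighbor's; recall is the fraction of drugs whose neighbor shares at least
one indication. Because drugs with a single indication rarely find a partner
for it, `recall_curve()` stratifies recall by a minimum indication count m
(≥ semantics, so "more than three indications" is the m = 4 stratum);
strata with no eligible drug are reported as `NA`, never as zero.

The chance baseline pairs every drug with a uniformly random partner and
averages the stratified recall over trials (`random_null()`, default 10,000
trials). Its exact expectation has closed form — for each eligible drug the
probability that a random partner shares an indication is (number of sharing
partners)/(D−1) — implemented as `analytic_null()` and used as the oracle
for the Monte-Carlo estimate in the test suite.

`bw_replacements()` lists Boxed-Warning drugs whose nearest neighbor lacks a
BW *and* shares an indication — the strict reading of a "safer alternative
for the same disease". An optional relaxed mode searches each BW drug's
nearest non-BW neighbor instead; it is off by default because the primary
definition evaluates the drug actually paired by the model.

`atc_enrichment()` asks whether repositioning success concentrates in
particular therapeutic areas: for each ATC anatomical main group it builds
the 2×2 table (in/out of category) × (success/failure) and computes a
two-sided Fisher's exact p-value by the point-probability convention (sum of
hypergeometric point masses not exceeding the observed table's mass,
computed in log space, no continuity correction; any zero margin gives
p = 1). The convention is stated explicitly because two-sided exact tests
differ between implementations. Raw p-values are reported without
multiplicity correction, matching how such per-category screens are usually
read (14 categories at most).

## The synthetic corpus generator

Real inputs for this analysis — label repositories, a licensed side-effect
dictionary, an indication database — cannot be bundled, so
`generate_corpus()` produces corpora from the model's own generative process
with full ground truth: $\phi_k \sim \mathrm{Dirichlet}(\beta)$ over V
synthetic terms (or over disjoint V/K-term blocks when `disjoint_topics =
TRUE`, giving well-separated topics for recovery experiments), $\theta_d \sim
\mathrm{Dirichlet}(\alpha)$, document lengths $\max(1,
\mathrm{Poisson}(L))$, and tokens drawn topic-first. The drawn tokens are
written verbatim into each label's AR section, so the corpus pushed back
through `build_matrix()` reproduces the generated counts exactly — the
text-extraction layer is tested end to end, not mocked.

Ground truth links evaluation to the topics: each topic owns a disjoint set
of indications; a drug receives all indications of its dominant topic and
each foreign indication independently with probability $\varepsilon$
(`indication_noise`); Boxed-Warning flags are Bernoulli; the ATC letter is a
fixed surjective function of the dominant topic. Defaults are D = 200 drugs,
V = 100 terms, K = 5 topics, $\alpha = \beta = 0.1$, L = 60 tokens,
$\varepsilon = 0.1$, BW probability 0.4 (the rough BW prevalence in curated
label sets), 5 ATC letters.

One indication per topic is the default, chosen analytically: with
$\varepsilon = 0.1$ and K = 5, giving each topic t indications makes the
probability that two *random* drugs share an indication approximately
$0.2 + 0.8\,(1 - 0.9^{2t}\,0.99^{3t})$ — about 0.37 at t = 1 but above 0.6
at t = 3, at which point a chance baseline is so high that no method,
however good, can double it. The single-indication regime keeps the
model-vs-chance separation meaningful and mirrors the empirical fact that
most drugs carry few indications.

What the generator does *not* emulate: realistic English label prose (tokens
are synthetic term strings), a hierarchical dictionary, correlated topics,
indication vocabularies with synonymy, or any systematic relation between BW
status and side-effect profile (BW flags are independent coin flips, so the
BW screen is exercised as a filter, not validated as a safety predictor).
Passing tests on these corpora demonstrate that the machinery recovers
structure the model family can express; they say nothing about whether real
label text satisfies the model's assumptions.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → build-matrix → choose-k → fit-lda →
distances → evaluate, writing every intermediate as plain TSV/JSON plus a
manifest with the configuration, stage seeds and wall times. Each stage's
seed is derived from the global seed by a fixed labeled hash
(`stage_seed()`), so adding or skipping a stage never perturbs another
stage's randomness and a run is reproduced bit-for-bit by its seed. A fixed
`k` skips selection and is recorded as an override in the manifest.

The test suite and the acceptance script run on deliberately modest sizes —
recovery corpora of 200 drugs × 100 terms × ~60 tokens with 1000 Gibbs
sweeps, nulls of 10,000 trials on 50–200 drugs, exhaustive Fisher
enumeration over all 2×2 tables with margins ≤ 15 — sizes at which the
independent oracles (exhaustive scans, closed-form expectations, Polya-urn
products) are exact and cheap. Larger corpora change constants, not the
properties being checked.

## Known limitations

* The eigenvalue balance criterion for k reacts to document-length variance
  (above); on short or length-heterogeneous corpora prefer inspecting the
  loss curve (`autoplot(choose_k(...))`) over trusting `k_star` blindly.
* Indication matching is exact string intersection after normalization; in
  real data the same disease written two ways counts as different
  indications, deflating recall.
* Greedy topic matching (`match_topics()`) is for recovery experiments on
  well-separated truths; it is not a general graph-matching solution.
* The symmetrized K-L distance is not a metric (no triangle inequality),
  which is harmless for nearest-neighbor queries but matters if the distance
  matrix is fed into methods that assume metricity.
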