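# setopics

Drug repositioning from side-effect similarity. `setopics` implements the
hypothesis that drugs with similar side-effect profiles are likely to be
effective for the same disease: it extracts standardized adverse-event terms
from the safety sections of drug labels (Boxed Warning, Warnings and
Precautions, Adverse Reactions), models the resulting drug × term counts with
a latent Dirichlet allocation (LDA) topic model, measures drug–drug distance
between topic mixtures, and evaluates each drug's nearest neighbor for shared
indications — flagging, along the way, Boxed-Warning drugs whose neighbor is a
candidate safer alternative, and therapeutic (ATC) categories enriched in
repositioning candidates.

## The method

For each drug *d* the safety text is reduced to counts over a side-effect
vocabulary. LDA assumes a topic mixture θ<sub>d</sub> ~ Dirichlet(α) per drug
and a term distribution φ<sub>k</sub> ~ Dirichlet(β) per topic, each token
drawn topic-first:

P(w) = Σ<sub>k</sub> P(w | z = k) · P(z = k)

The model is fitted by collapsed Gibbs sampling (compiled, fully seeded);
θ and φ are posterior means averaged over thinned post-burn-in samples. The
number of topics can be chosen from the PCA eigenvalue spectrum
e<sub>1</sub> ≥ … ≥ e<sub>n</sub> of the centered matrix by minimizing the
information loss

L(k) = | Σ<sub>i≤n</sub> e<sub>i</sub> − λ · Σ<sub>i>k</sub> e<sub>i</sub> |,  λ = 2,

i.e. balancing head against tail variance. Drugs are compared with the
symmetrized Kullback–Leibler divergence

D(A,B) = ( KL(A‖B) + KL(B‖A) ) / 2,  KL(P‖Q) = Σ<sub>i</sub> P(i) ln( P(i)/Q(i) ),

and each drug's nearest neighbor is checked for a common indication. Recall
(fraction of drugs whose neighbor shares ≥ 1 indication) is stratified by the
drug's indication count and compared with a 10,000-trial random-pairing null
(plus its closed-form expectation). Category enrichment uses two-sided
Fisher's exact tests on (in/out of ATC class) × (success/failure) tables.

Because the real inputs (label repository, licensed side-effect dictionary,
indication database) cannot be bundled, the package ships a fully seeded
synthetic corpus generator, `generate_corpus()`, that draws labels from the
LDA generative process with ground-truth topic mixtures, topic-linked
indications, Boxed-Warning flags and topic-aligned ATC letters — so every
stage of the pipeline is testable against known truth.

## Worked example

```r
library(setopics)

corp <- generate_corpus(n_drugs = 100, vocab_size = 60, n_topics = 4,
                        mean_doc_length = 40, disjoint_topics = TRUE, seed = 2024)
corp
#> <se_corpus: 100 drugs, 60 terms, 4 true topics>

fit <- fit_lda(corp$matrix, k = 4, alpha = 0.1, beta = 0.1, seed = 1)
fit
#> <lda_fit: 100 drugs, 30 terms, K = 4; 1000 sweeps (50 samples)>

nn <- nearest_neighbors(pairwise_distances(fit))
head(nn, 3)
#> # A tibble: 3 × 3
#>   drug_id  neighbor_id  distance
#>   <chr>    <chr>           <dbl>
#> 1 drug0001 drug0020    0.0553
#> 2 drug0002 drug0092    0.0000464
#> 3 drug0003 drug0087    0.0174

pairs <- evaluate_pairs(nn, corp$labels)
recall_curve(pairs, max_m = 3)
#> # A tibble: 3 × 4
#>       m n_eligible n_success recall
#>   <int>      <int>     <int>  <dbl>
#> 1     1        100        97  0.97
#> 2     2         26        25  0.962
#> 3     3          2         2  1

analytic_null(corp$labels, max_m = 3)
#> # A tibble: 3 × 3
#>       m n_eligible expected_recall
#>   <int>      <int>           <dbl>
#> 1     1        100           0.399
#> 2     2         26           0.605
#> 3     3          2           0.808

bw_replacements(pairs, corp$labels)
#> <bw_report: 38 BW drugs, 28 with a safer-alternative candidate>
```

Reading the numbers: 97 of 100 drugs have a nearest neighbor that shares an
indication, against a 39.9% chance level for random pairing — the topic-space
neighborhood carries real indication signal on this corpus. Of the 38 drugs
with a Boxed Warning, 28 are paired with a BW-free neighbor approved for one
of their indications, the "safer alternative" pattern. `distance` is the
symmetrized K–L divergence in nats (drug0002 and drug0092 have nearly
identical topic mixtures).

The whole chain — simulate, build the matrix, select or fix k, fit, distances,
evaluation tables, manifest — also runs as one reproducible call:

```r
res <- run_pipeline("run1", generator = list(disjoint_topics = TRUE),
                    k = 5, lda = list(alpha = 0.1, beta = 0.1), seed = 42)
```

with every intermediate written as plain TSV/JSON under `run1/`. Real label
corpora enter through `labels_path`/`lexicon_path` (JSON-lines labels,
two-column TSV lexicon); see `?read_labels`.

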