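---
title: "Profile similarity, annotation bias, and the empirical correction"
author: "meshopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile similarity, annotation bias, and the empirical correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshopr)
```

# The model

## Profiles

An annotated corpus assigns each article a set of controlled-vocabulary
terms. Because the vocabulary is hierarchical (tree numbers such as
`C04.557.337`, with parenthood given by dropping the final dot-segment), an
article annotated with a term is treated as annotated with all of that
term's ancestors; propagation happens once, at corpus load, and the raw
curator-assigned terms are retained so a corpus round-trips through the
writer unchanged. Terms outside the hierarchy (the analogue of
supplementary concepts) are legal annotations that simply contribute no
ancestors.

An entity — a drug or a disease — is defined by one vocabulary term; its
bibliography is the set of articles carrying that term post-propagation.
The entity's profile records, for every term $t$ observed in a bibliography
of size $n$:

* the count $k_t$ and fraction $f_t = k_t/n$;
* the one-sided enrichment p-value
  $p_t = P(X \ge k_t)$, $X \sim \mathrm{Hypergeom}(N, K_t, n)$,
  where the background supplies $N$ articles of which $K_t$ carry $t$ —
  exactly the one-sided Fisher exact test on the $2\times2$ table
  $(k,\; n-k,\; K-k,\; N-K-n+k)$;
* a tf-idf weight $w_t = f_t \ln(N/K_t)$.

Assumptions worth making explicit: the test treats the bibliography as a
simple random draw from the background, which ignores within-journal and
within-author correlation of annotation; and the bibliography's own
articles stay inside the background counts (no leave-self-out), the plain
reading of "count of the term in a background set". Profiles keep **all**
observed terms. Thresholding on significance would silently change the
term-set cardinalities $|C|$, $|D|$ that several metrics depend on.

Two background choices are supported: *universal* (all corpus articles;
required for cross-class comparison, and the default everywhere here) and
*class-specific* (articles associated with at least one entity of one
class; useful to de-emphasize terms generic to the class, e.g.
"pharmaceutical preparations" among drugs).

## Numerical choices

The upper tail is delegated to `stats::phyper`, which is computed in
log-space internally and is accurate over the full range; the test suite
checks it against exhaustive probability-mass summation for every margin
combination with $N \le 60$. P-values are clamped below at `1e-300` before
any logarithm: at real-corpus scale deeply annotated terms underflow to
zero, and `log(0)` must never reach a metric. Profile rows are ordered by
ascending p-value with ties broken by term id, making every serialization
deterministic.

The tf-idf weight formula is a design choice (standard bibliography-
relative term frequency times background-relative inverse document
frequency); only the cosine built on the weights is defined by the method,
not the weights themselves, so the exact form is documented rather than
canonical. $\log$ means the natural logarithm throughout; any fixed base
rescales metrics without changing ranks, and therefore no AUC.

## The similarity panel

With $C$, $D$ the term sets of a drug and a disease profile, and the
conventions $p = 1$, $f = 0$, $k = 0$, $w = 0$ for a term absent from a
profile, the panel comprises cosine similarities over weights, p-values
and fractions; $\sum_i \log(c_p(i) + d_p(i) - c_p(i)d_p(i))$; the signed
$\sum_i (\log c_p(i) - \log d_p(i))$; L2 distances of log-p and of
fractions restricted to $C \cap D$; L2 distances of log-p, p, fractions
and counts over all terms; and the counting measures $|C \cup D|$,
$|C| + |D|$, $|C \cap D|$, $|C|$, $|D|$ — the last two being the
bibliometric baselines that use only one profile.

"All terms" means the union of terms present in either profile. For
metrics whose absent-term convention is neutral (differences of p-values,
log-ps, fractions, counts; the combined-p sum) this equals a sum over the
entire vocabulary; for the cosine over p-values it does not — a term
absent from both profiles would contribute $1 \cdot 1$ to numerator and
norms — so the union domain is normative here.

Each metric carries a *polarity*: whether larger values mean a more
similar pair. The choice is consequential only for ROC orientation and for
the correction's "more extreme" direction, and it is configuration-
overridable; the validation layer additionally reports the
orientation-free $\max(\mathrm{AUC}, 1-\mathrm{AUC})$. Two registry
entries deserve a note. The overlap-restricted L2 metrics are registered
*higher-is-similar*: they grow with the size of the shared-term set, which
is the dominant behaviour at realistic profile sizes, and an empty
intersection scores 0, the minimum-evidence value. The signed
sum-of-differences metric is scored on its magnitude (a perfectly matched
pair gives 0), flagged `use_magnitude` in the registry so orientation
happens in exactly one place.

## Annotation bias and the empirical correction

Annotation levels — the number of distinct terms in a profile — vary over
orders of magnitude, and raw similarity scores inherit that variation:
heavily studied entities overlap everything. The corrected score of a pair
with raw score $x_s$ is

$$P\big(X_s \text{ more extreme than } x_s \,\big|\, X_c \approx x_c,\;
X_d \approx x_d\big)$$

estimated empirically: take the drug's peers and the disease's peers —
same-class entities within $\pm h$ percentile of annotation level
(default $h = 5$, i.e. the ~10% most comparably annotated) — pool the raw
scores of every peer-drug × peer-disease pair, and report
$(1 + \#\{\text{pool scores strictly more extreme}\}) / (1 + |\text{pool}|)$.

Percentiles are mid-rank ($100(r - 0.5)/n$ with average ranks), so tied
levels share a percentile; windows are truncated at $[0, 100]$ with no
widening, the conservative reading of "within ±5 percentile" (peer pools
shrink at the extremes rather than borrowing dissimilar peers). The query
pair stays in its own pool and add-one smoothing is applied, the standard
empirical-p construction guaranteeing values in $(0, 1]$; "more extreme"
is a strict inequality in the polarity direction. Pools contain pairs
already co-published before any cutoff — exclusion is a labeling concern,
applied only in validation.

Under a null where scores are i.i.d. and independent of annotation levels,
corrected values are approximately uniform on $(0,1]$ (checked by
Kolmogorov–Smirnov distance where pools reach 200 scores), and on score
matrices with a planted level-driven gradient the correction removes the
score/level correlation; both are exercised in the tests, along with exact
agreement with a naive double-loop counting oracle.

## Validation

Temporal-split labels: a pair co-annotated in any article (post-
propagation, consistent with profile construction) at or before the cutoff
year is *excluded*; a pair first co-annotated after the cutoff is
*positive*; every other drug × disease pair is *negative*. Reference-
collection labels mark listed, resolvable pairs positive, with pre-cutoff
co-occurrence still excluding a pair — the reference sets of interest are
collections of *novel* relationships. Metrics are compared by ROC AUC in
the rank-sum (Mann–Whitney) form with average ranks; the counting
baselines are extremely tie-heavy, and any tie convention other than half
credit would bias their AUCs. Entities with empty pre-cutoff
bibliographies have no profile and drop off the score axes.

# The synthetic-data generator

The generator emulates the statistical structure the method relies on,
with known ground truth:

* a random tree of `nTerms` terms (default 500, depth ≤ 4) with tree
  numbers built by construction;
* `nTopics` latent topics (40), each a random subset of `termsPerTopic`
  terms (15);
* entities (60 drugs, 60 diseases by default) with distinct *leaf*
  defining terms — leaves so that a defining term is never dragged into
  unrelated articles via ancestor propagation — and `topicsPerEntity` (2)
  topics each;
* per-entity publication counts `round(lognormal(2.2, 0.8))` floored at 1:
  a median of ~9 articles and a heavy upper tail, the few-entities-
  dominate shape of real annotation distributions;
* per-article annotation: `termsPerArticle` (8) draws from the entity's
  topic terms, each replaced by a uniform vocabulary term with probability
  `noiseTermRate`, plus the defining term, all dated in the decade before
  the cutoff;
* links planted among *topic-sharing* drug–disease pairs with probability
  `linkRate · ((u_c + u_d)/2)^biasStrength`, where `u` are publication-
  count percentiles — at `biasStrength = 0` links are independent of
  publication volume; each link yields 1 + Poisson(1) co-annotated
  evidence articles dated entirely after the cutoff with probability
  `futureFraction` (temporal positives) and entirely before it otherwise
  (excluded pairs).

Because links are planted at the *topic* level, profile similarity of a
positive pair is an emergent signal — shared vocabulary accumulated across
independent articles — not a tautological copy of the label.

Two frozen scenarios anchor the tests. `"unbiased"` (seed 101) uses the
defaults above: low annotation noise and sizeable topics, so that genuinely
shared topic terms dominate spurious one-sided overlaps and the overlap
metric's AUC margin over both term-count baselines is the planted signal.
`"biased"` (seed 202) enlarges the panel to 120 × 120, widens the
publication-count spread (`lognormal(2.3, 1.2)`), raises the noise rate to
0.2 and sets `biasStrength = 8` with `linkRate = 1`: noise terms
accumulate with bibliography size, so raw overlap scores correlate with
annotation level, and links concentrate on heavily published entities, so
the count baselines become genuinely predictive — the confound the
correction exists to remove.

What the generator does **not** emulate: real vocabulary scale (tens of
thousands of terms, indexing depth ~10-15 terms/article), citation growth
over time, per-class asymmetries in annotation depth, and curated-database
selection effects. Passing tests therefore demonstrate correctness of the
machinery and qualitative reproduction of the bias-and-correction
phenomenon, not the absolute AUC levels reachable on a full literature
corpus.

# Problem sizes and determinism

The benchmark pipeline runs 60 × 60 (unbiased) and 120 × 120 (biased)
panels over corpora of a few thousand articles — sizes chosen so the full
suite, including the exhaustive hypergeometric sweep ($N \le 60$) and a
150 × 150 null-calibration matrix, completes in well under a minute while
keeping peer pools in the hundreds, the regime the correction is designed
for. Every stochastic component flows from an explicit seed: the generator
restores the caller's RNG state, identical configs produce byte-identical
files, and the command-line stages write manifests (options, seed, input
digests, package version) so identical manifests imply identical outputs.

# Known limitations

* The tf-idf weight definition is a documented substitute (see above).
* Polarity at real-corpus scale was fixed from the overlap-growth argument;
  on corpora with very different structure the registry override (or the
  auto-oriented AUC) is the safety net.
* The correction conditions only on annotation *levels*; other confounds
  (entity age, class imbalance) pass through.
* Subheading/qualifier-aware annotation and feature-restricted profiles
  (scoring on a curated term subset) are out of scope.
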