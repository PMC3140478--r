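---
title: "Methods: social network inference for induced-cooperation experiments"
author: "vnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social network inference for induced-cooperation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnet)
```

## The setting

`vnet` analyses behavioural data from field experiments in which a wild
primate group is split into two *cooperation classes*: a two-member
"small" class that can operate one colour of feeder and a "large" class
(everyone else) that can operate the other colour. During the
cooperation phase, paired feeders only release food when at least one
member of each class operates them together, so food access becomes a
matching market in which the small-class members are the short,
in-demand side. The scientific questions are: does induced cooperation
restructure the social network (fewer, stronger partners), and what
predicts who pairs with whom — sex, age class, dominance rank, or
kinship?

The raw inputs are tidy event logs: scan samples taken at ten-minute
intervals (focal id, nearest neighbour within 10 m, distance from the
feeders) and all-occurrence bout records (allogrooming, contact
sitting, play, aggression, submission, cooperation attempts). The unit
of repeated observation is the *sampling period*, one calendar day by
default.

## Bout segmentation

A behavioural bout ends when the behaviour ceases for five seconds or
more, is replaced by another behaviour, or the partner changes. Raw
continuous observation streams are collapsed by `segment_bouts()` into
maximal runs of identical (behaviour, actor, recipient) with
inter-observation gaps strictly under 5 s; the boundary is closed at 5 s
("5 or more" ends the bout). Bouts keep their start time only: all
downstream rates are frequencies, not durations. The same 5-s rule
delimits cooperation attempts when the same partners persist at the
feeders; this is a convention, exposed through the `gap_s` argument,
because no sharper definition of an "attempt" is available.

## Association indices and the three conditions

For each condition the package builds a per-period dyadic occurrence
structure and a symmetric matrix:

* **proximity** — a dyad is associated on a day if any qualifying scan
  links them as nearest neighbours within `max_nn_m` (default 10 m)
  while the record lies beyond `min_feeder_m` (default 10 m) from the
  feeders, so feeder-induced crowding does not contaminate the natural
  spatial network. Scan records carry one feeder distance (the focal's);
  since the partners are within 10 m of each other, that distance is
  used for the pair. Nearest-neighbour links count in either direction.
* **affiliative** — bout counts of allogrooming, contact sitting and
  social play, direction collapsed.
* **cooperation** — bout counts of cooperation attempts at the feeders.

The association index is the *simple ratio* \(\hat\alpha_{ij} =
x_{ij}/d_{ij}\): periods together over periods jointly observable, where
presence is taken directly from the daily record (an individual absent
from the surroundings contributes nothing to its dyads' denominators
that day). The simple ratio is used rather than the half-weight
correction because presence is explicitly tracked per day; dyads with
\(d_{ij}=0\) are missing and excluded everywhere.

## Social differentiation

Social differentiation \(S\) is the coefficient of variation of the
*latent* dyadic association probabilities. The observed CV of
\(\hat\alpha\) overstates it because each \(\hat\alpha_{ij}\) carries
binomial sampling noise, so `social_differentiation()` removes a moment
estimate of that noise. With \(\bar\alpha\) the \(d\)-weighted mean
index,

\[
S^2 \;=\; \max\!\left(0,\;
 \frac{\operatorname{var}_w(\hat\alpha)\;-\;
       \overline{\hat\alpha(1-\hat\alpha)/d}}{\bar\alpha^2}\right).
\]

Rule-of-thumb bands: below 0.3 the society is rather homogeneous,
0.5–2.0 well differentiated, above 2.0 extremely differentiated
(`classify_differentiation()`). Standard errors come from a bootstrap
over sampling periods: days are resampled with replacement and the
estimator recomputed per replicate (`bootstrap_se()`, 10,000 replicates
by default). Replicates where the estimator is undefined are dropped and
counted; more than half undefined aborts with a request for more data.
Only the moment estimator is implemented; a likelihood-based variant is
a known omission, flagged here deliberately.

## Preferred/avoided association test

`preferred_association_test()` compares the mean and the standard
deviation of the dyadic indices against a presence-constrained
("semi-random") null: within each sampling period, the observed
association slots are carried across a uniformly random relabelling of
the individuals *present that day*. Absent individuals never enter the
permuted data and each day keeps its number of associating individuals
and its dyad structure. Two p-values are reported: \(P(\text{null mean}
\le \text{real mean})\) — small when events concentrate on fewer,
stronger partners — and \(P(\text{null SD} \ge \text{real SD})\) —
small when associations are more heterogeneous than chance. p-values
floor at \(1/(n_{perm}+1)\), so 10,000 permutations can express
"p ≤ 0.001". A sequential-swap engine (exchanging members between two
observed dyads of the same day, preserving each individual's
gregariousness) is available via `engine = "swap"` for comparison.

The statistic is computed on whatever layer the occurrence carries —
binary periods-together or bout counts — and is named in the output
rather than forced onto the [0, 1] index scale, since count-based means
can legitimately exceed 1.

This null treats all present individuals as exchangeable. Data whose
generative process is *not* label-exchangeable (for example cooperation
events that can only join the two classes) are compared against a null
that also mixes same-class dyads; the test then reads as "more
structured than free mixing", which is the intended reading of the
experiment's design.

## Mantel grid and partial Mantel tests

Partner-choice drivers are tested by `mantel_test()`: the cross-product
\(Z=\sum A_{ij}B_{ij}\) and the matrix correlation coefficient (MCC,
Pearson over the same cells) between the cooperation (or feeding
proximity) matrix and an attribute-similarity matrix, over the
*between-class mask* only — dyads pairing a small-class with a
large-class member — so same-class co-occurrences at the feeders
(possible when more than two individuals cooperate at once) do not bias
the result. The null permutes the attribute matrix's labels *within*
each cooperation class, which preserves the matching-market structure
and leaves the mask invariant. The test is one-tailed ("greater") by
default, so p-values near 1 are informative: they indicate a tendency
*against* similarity, e.g. a preference for unrelated partners.

Attribute encodings (all config-exposed; these are the minimal monotone
choices): sex and age class as same-class indicators; rank as
\(1-|DS_i-DS_j|/\max\), a rescaled David's Score gap; relatedness as the
coefficient itself. `partial_mantel_test()` residualises both matrices
on control matrices (matriline and sibling indicators) by OLS over the
unmasked cells and reruns the same constrained permutation machinery on
the residuals — regression residuals are used rather than
permutation-of-null-residuals because the residual step is then
deterministic. Individuals with missing relatedness have their dyads
masked out rather than imputed; the pipeline warns and lists them.

## Dominance, clustering, communities

**David's Score** (`davids_score()`): from the directed win matrix of
agonistic bouts started within 5 m of the feeders, \(P_{ij} =
w_{ij}/n_{ij}\), and \(DS = w + w_2 - l - l_2\). Raw proportions are the
default; the dyadic shrinkage \(D_{ij} = P_{ij}-(P_{ij}-0.5)/(n_{ij}+1)\)
is available by flag. Raw scores sum to zero by construction; integer
display is a formatting choice only.

**Ward dendrograms** (`ward_dendrogram()`): individuals are represented
by their row profile of (optionally observability-normalised) rates and
agglomerated under Ward's minimum-variance objective; the stored height
of each merge is exactly the increase in total within-cluster sum of
squares. Ward needs a Euclidean geometry, which the profile distance
guarantees; a direct `1 - rate/max` complement distance is available
with the caveat that it may not be Euclidean. The tree is built with
`stats::hclust(method = "ward.D2")`, whose merge distances relate to the
SS increment by \(\Delta = h^2/2\) — an identity the test suite checks
against a step-by-step exhaustive agglomeration. Fit is summarised by
the **cophenetic correlation coefficient** (`cophenetic_coefficient()`):
1.0 is a perfect fit, 0.8 is conventionally good. Note that Ward
linkage does not reproduce ultrametric inputs (its merge distance
inflates non-linearly when clusters grow), so a coefficient of exactly
1.0 is attainable only for trees whose heights reproduce the input
distances, as average linkage does on ultrametric data.

**Newman communities** (`newman_communities()`): weighted modularity is
maximised by recursive leading-eigenvector bipartitioning of the
generalised modularity matrix, Kernighan–Lin-style refinement of every
split, and a final pass of single-node moves and community merges.
Strengths replace degrees for weighted graphs. Ties between
equal-modularity partitions resolve to the lexicographically smallest
labelling, making the result deterministic and invariant to node
relabelling and uniform weight rescaling. At the group sizes this
package targets (7–19 individuals) the refined search reaches the
exhaustive optimum in the test suite's randomised checks.

## The synthetic-data generator

No field data are distributed with the package, so `sim_config()` /
`simulate_study()` generate datasets with *known ground truth* in the
exact raw formats the pipeline reads. The defaults describe a
plausible study group: 10 individuals (2 small-class), 30 daily
periods, 90% daily presence (matching groups where the mean number
identified per day runs just below group size), mean association
probability 0.2, differentiation 0.4, 48 scans per day, 10 cooperation
events and 10 agonistic encounters per dyad.

Generative choices, each the minimal mechanism for its target:

* **Association**: latent \(\alpha_{ij}\) drawn from a Beta distribution
  with mean \(\mu_\alpha\) and CV \(S\) (the planted differentiation) —
  the minimal two-parameter family on [0, 1] matching the mean/CV
  parameterisation; \(S\) must stay below the Beta bound
  \(\sqrt{(1-\mu)/\mu}\), and \(S=0\) collapses to a point mass. Each
  day, jointly present dyads associate independently with probability
  \(\alpha_{ij}\).
* **Partner choice**: a small-class member picks a present large-class
  partner with probability \(\propto \exp(-\beta\,|r_s - r_l| /
  \mathrm{range}(r))\); \(\beta = 0\) is uniform choice and large
  \(\beta\) makes the rank-nearest partner modal. A single-parameter
  monotone kernel is used because the phenomenon to emulate is rank
  assortment, not any particular mechanism.
* **Dominance**: dyads meet a fixed number of times and the higher
  rank wins each encounter with logistic probability
  \(\mathrm{logit}^{-1}(r_i - r_j)\).
* **Kinship**: a random maternal pedigree inside each matriline, with
  relatedness \(0.5^{d}\) for tree distance \(d\) (0.5
  mother–offspring, 0.25 siblings and grandmother–grandoffspring). This
  pedigree-decay surrogate deliberately varies within matrilines so the
  partial Mantel control matrices are not trivially collinear with
  relatedness — as in real pedigrees, and unlike a pure indicator model.
* **Presence**: i.i.d. Bernoulli per individual-day by default; a
  sticky Markov variant exists for temporally clumped absences.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: spatial structure and home ranges,
learning dynamics over sessions, observer error, temporal
autocorrelation of association within days, and any dependence of
presence on social structure.

## Numerical and design choices

* Sampling period = calendar day; 1-based indices.
* Matrix symmetry is enforced on read at \(10^{-9}\) absolute
  tolerance, with the worst cell named in the error.
* All permutation p-values use the \((1+k)/(n_{perm}+1)\) convention
  with an internal \(10^{-12}\) tie tolerance.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds from its master seed, so `report.json` is
  byte-identical across reruns with the same configuration.
* Multiple testing: none is applied across the Mantel grid, matching
  the original analysis; a Benjamini–Hochberg column can be added by the
  user from the raw p-values.
* Missing relatedness is handled by masking, never imputation.
* The pipeline runs all groups found in the roster, records per-stage
  failures, and raises them together at the end.

## Problem sizes used by the test suite and acceptance script

Chosen as the package's own verification conditions: differentiation
recovery uses 15 individuals × 40 periods × 50 seeds per planted value
\(S \in \{0, 0.4, 0.8, 1.6\}\); permutation-test calibration uses 400
simulated datasets × 1,000 permutations; rank-assortment power uses 100
runs of a 2 + 8 group over 25 periods at \(\beta = 20\); the exhaustive
oracles run at \(n \le 8\). The acceptance script analyses one
10-individual, 30-period group with 2,000 permutations and bootstrap
replicates.

## Known limitations

* The moment estimator of differentiation is biased upward slightly at
  very sparse effort (small \(d_{ij}\)) and truncates at zero.
* The preferred-association test conditions on each day's dyad
  structure; alternative nulls (e.g. gregariousness-preserving swaps)
  answer slightly different questions and are provided for comparison
  only.
* Partial Mantel tests with regression residuals are known to be
  slightly anti-conservative under strong collinearity between the
  control and the tested matrix; interpret borderline p-values with
  care.
* Ward clustering on rate profiles is one of several defensible
  rate-to-distance conventions; the original analysis does not specify
  its transform, so results can differ in detail from other software.
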