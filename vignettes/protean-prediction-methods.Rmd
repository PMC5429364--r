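---
title: "Predicting protean segments: model, features and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protean segments: model, features and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteanrf)
```

## The problem

Intrinsically disordered proteins (IDPs) lack a stable tertiary
structure in isolation, but parts of their disordered regions — the
*protean* segments, also studied as molecular recognition features
(MoRFs) — fold when they bind a partner. Identifying these
disorder-to-order transitioning binding regions from sequence alone is
a per-residue binary classification task: label 1 for residues inside
an annotated protean interval, 0 for everything else (both ordered
residues and disordered residues that stay disordered when bound).
Annotated corpora are heavily imbalanced; typically only one or two
percent of residues are positive.

`proteanrf` implements the full pipeline: track ingestion, a
342-dimensional per-residue feature representation, a random-forest
classifier with cluster-grouped cross-validation, evaluation measures
and curves, and the sequence-consensus analyses (amino-acid
propensities, secondary-structure content, the Altscore statistic)
used to interpret what distinguishes protean from non-protean
sequence.

## Inputs

The predictor consumes, per protein, four tracks that external tools
produce from the raw sequence:

* a PSI-BLAST position-specific scoring matrix (ASCII `-Q` dialect):
  20 substitution log-odds per residue plus a per-position information
  (conservation) value;
* PSIPRED three-state secondary-structure probabilities (`.ss2`);
* a per-residue disorder probability in $[0,1]$ (DISOPRED-style
  `.diso`);
* protean-segment annotations as 1-based inclusive intervals.

Running those external tools is out of scope here; their outputs are
parsed from files, and the synthetic generator (below) emulates all of
them so the pipeline is fully testable offline. All parsers permute
amino-acid columns into a single fixed order (alphabetical by
one-letter code), so no downstream code depends on a file dialect.
Ambiguity codes (X/B/Z/U) are tolerated in sequences; they contribute
nothing to composition or property counts, and their track rows are
used as-is.

## The feature representation

Each residue is described by 342 features in seven groups, most of
them computed over a 15-residue sliding window centred on the residue
(the window size is a parameter, odd values 9–21; 15 matches the
typical protean segment length):

| Group | Content | Columns |
|---|---|---|
| 1 | scaled PSSM scores for each window offset | 1–300 |
| 2 | windowed mean of the conservation value | 301 |
| 3 | window amino-acid composition | 302–321 |
| 4 | polarity/charge fractions, hydropathy, mass | 322–330 |
| 5 | windowed mean P(H), P(E), P(C) | 331–333 |
| 6 | disorder mean + disordered/ordered segment descriptors | 334–340 |
| 7 | disorder topography class and run length | 341–342 |

Raw PSSM scores are scaled linearly to $[0,1]$ using, per amino-acid
column, the minimum and maximum observed over the *training* corpus;
values outside the training range clamp, and a degenerate column
(min = max) maps to 0.5 since a constant carries no information. The
scaler is refitted on every training split during cross-validation so
that test proteins can never stretch the scale.

Two different window conventions are used deliberately. Group 1 is a
positional concatenation, so its dimensionality must not depend on
where the residue sits: missing offsets beyond the termini contribute
zeros. Groups 2–6 are averages, so the window is truncated at the
termini and the divisor is the number of in-sequence positions;
padding with zeros there would bias terminal residues toward zero.
Composition and property fractions additionally divide by the number
of *standard* residues in the window so that ambiguity codes do not
dilute them. Hydropathy (Kyte–Doolittle units) and residue mass (Da)
stay on their natural scales — tree ensembles are invariant to
monotone feature scaling, so rescaling would only obscure the values.

The polarity partition is the textbook one: non-polar
{A,V,L,I,M,F,W,P,G}, polar {S,T,C,Y,N,Q}, acidic-polar {D,E},
basic-polar {K,R,H}; charge positive {K,R,H}, negative {D,E}, neutral
otherwise. Histidine's placement among the basic residues is a
convention, not a deduction; it is recorded here so results are
reproducible.

### Disorder-segment descriptors (group 6)

A residue with disorder score $\ge 0.5$ sits in a *disordered
segment*: the maximal contiguous run of scores $\ge 0.5$ containing
it. Otherwise it sits in the complementary *ordered* run. The seven
features are the windowed mean disorder score, then (length, relative
start, relative stop) of the disordered segment — zeros when the
residue is predicted ordered — and the same triplet for the ordered
segment — zeros when predicted disordered. Exactly one triplet is
therefore always zero, which the tests assert.

Boundary positions are reported as positions divided by the sequence
length (`segment_position_mode = "position"`). An alternative reading
— the relative distance from the residue to the boundary before/after
it — is equally defensible and selectable
(`segment_position_mode = "distance"`); the choice changes feature
values but not the segment partition.

The `>= 0.5` comparison for "disordered" is itself configurable
(`disorder_threshold`), since disorder predictors differ on whether
0.5 exactly is disordered.

### Disorder topography (group 7)

The topography features classify every residue of the disorder track
as part of a peak (+1), a valley (−1) or neither (0), and attach the
length of the contiguous same-class run (0 for class 0). A residue is
on a peak when there is a residue with a score at least 10% lower on
*both* sides, on a valley when both sides hold scores at least 10%
higher.

Two readings of that criterion had to be resolved:

1. **Relative vs absolute 10%.** "10%" of a probability reads most
   naturally as multiplicative ($\le 0.9s$, $\ge 1.1s$); an absolute
   offset of 0.1 is also plausible. The relative form is the default,
   the absolute form is available via `delta_mode = "absolute"`, and
   the 10% itself is the `delta` parameter.
2. **Which residue qualifies.** If *any* residue anywhere on each side
   may qualify, then on a realistic track — a high disordered plateau
   flanked by low ordered regions — nearly every intermediate-score
   residue has both far-lower and far-higher residues on both sides,
   the peak and valley conditions hold simultaneously, and the
   classification collapses. The implementation therefore walks
   outward from the residue and lets the *first* score to leave the
   10% band decide each side's verdict (lower = downhill, higher =
   uphill). This "first deviation" rule describes the local
   topographic element the residue sits on, gives identical answers
   on all simple cases (isolated spike, plateau, monotone ramp,
   constant track), and is what makes a shallow valley inside a high
   plateau detectable at all. A terminus reached without any
   qualifying deviation leaves that side undecided, failing both
   conditions.

The test suite checks the implementation against an $O(L^2)$
brute-force oracle (a literal stepwise walk per residue and side) on
a thousand random tracks, and checks that positive rescaling of the
track never changes a class under the relative criterion.

## Classifier

A random forest of classification trees votes per residue; the score
is the fraction of trees voting positive and a residue is called
protean when the score reaches `p_cut` (ties positive, so at the
default 0.5 a residue is positive when at least half the trees say
so). Defaults are maximum depth 13, 500 trees for a final model and
50 for the exhaustive feature-group search, where the tree count
mostly costs compute rather than ranking accuracy; the structural
tests here use 10–100 trees since they check properties, not absolute
performance. Tree growing is delegated to `ranger` with its default
split criterion (Gini), `mtry = floor(sqrt(p))` and bootstrap
resampling; those defaults are recorded in the trained model's
metadata. No class re-weighting is applied despite the ~2% positive
rate — the operating point is instead chosen via the score cutoff —
but a configuration hook exists.

Per-residue scores are exact tree-vote fractions (obtained from
per-tree predictions, not averaged leaf probabilities), so
`classify(predict_scores(m, x), 0.5)` is literally the majority vote,
and identical seeds give bit-identical score tracks.

## Cross-validation without homolog leakage

Randomly splitting proteins into folds leaks information whenever two
similar sequences end up on opposite sides of the train/test
boundary. Proteins are therefore clustered by sequence similarity
first, and *clusters* are assigned to folds: sorted by size
(descending, ties by cluster id), each cluster goes to the currently
smallest fold, so no cluster ever spans folds and the max–min fold
size difference is bounded by the largest cluster. Balancing is by
protein count, matching the convention of keeping the number of
target proteins consistent across folds.

Cluster files from a dedicated tool (BLASTclust-style, 30% identity
over 50% of the length) are first-class input. When none is supplied,
`greedy_cluster()` provides a documented approximation: two sequences
are linked when a gapless single-diagonal alignment seeded by a
shared 5-mer reaches 30% identity over at least half of the shorter
sequence, and clusters are the connected components (single linkage,
hence transitive).

Out-of-fold predictions from the five rotations cover every residue
exactly once and are pooled before computing MCC, F1 and the
recall–precision curve (micro-averaging), so a single cross-validated
number summarizes the predictor.

## Evaluation conventions

PPV, TPR, F1 and MCC follow their standard definitions from the
confusion counts. Degenerate denominators return 0 (and MCC returns 0
when any marginal is zero), which keeps pooled metrics total. The
recall–precision curve sweeps the cutoff with ties called positive;
its AUC is the trapezoid over recall restricted to thresholds with at
least one predicted positive, anchored at recall 0 with the strictest
such threshold's precision. The random-classifier baseline — the
positive fraction — is reported alongside, because with 2% positives
an AUC of 0.1 can already be five-fold enrichment.

## Consensus analyses

The propensity of amino acid X for a residue class is the frequency
ratio
$\Pr(X) = \frac{N(X)_{class}/N(All)_{class}}{N(X)_{full}/N(All)_{full}}$,
which satisfies $\sum_X f_{full}(X)\Pr(X) = 1$ exactly — the reason a
class covering almost the whole corpus shows propensities pinned near
1.0. A variant dividing the class count by the full-corpus total
(`formula = "unnormalized"`) is provided for comparison; it does not
satisfy the identity and is not the default because it cannot
reproduce the near-unity baseline behaviour that a frequency ratio
guarantees.

The Altscore of a segment is its number of adjacent
secondary-structure call transitions divided by the segment length —
transitions per residue, so that values are comparable across segment
lengths and peak locations land in the 0.05–0.1 range for realistic
switching rates; dividing by length − 1 is available via the
`denominator` argument. Segments with Altscore 0 and purely-coil
segments are excluded from the distribution comparison (they carry no
indecisiveness signal), and histograms use a bin width of 0.025,
fine enough to resolve peaks 0.05 apart.

## The synthetic generator

`generate_corpus()` produces sequences, all three tracks and labels
with the statistical structure the predictor is designed to exploit:

* ordered regions drawn from globular-like amino-acid frequencies;
  disordered regions enriched in P, G, S, D, E, K, R and depleted in
  W, F, Y, I, L, C; planted protean sub-segments re-enriched in the
  large hydrophobics L, I, F, Y, W and the charged D, E, K, R while
  staying depleted in P, G, C — so the propensity analysis has a true
  effect to recover, with the charged-residue enrichment planted
  clearly above the already charged-rich disordered background;
* a disorder track plateauing at 0.82 over disordered regions and
  0.18 elsewhere, with uniform noise of ±0.03 and a valley dipping by
  30% of the plateau (to ≈0.57, still above the 0.5 threshold) at
  each protean segment — so planted segments are valleys by
  construction while remaining inside disordered regions;
* secondary structure from a three-state resampling process: 85% coil
  stationary content in disordered regions, a higher switching rate
  (0.35 vs 0.08–0.10 per residue) inside protean segments — so coil
  content and the Altscore separation are recoverable parameters;
* pseudo-PSSMs peaked on the true residue with integer noise, and
  lower per-position information in disordered regions;
* protean segment lengths log-normal with mode near 15 (hard range
  5–60), one segment in 30% of proteins, giving ≈1.7% positive
  residues over the default 200-protein, 100–300-residue corpus — in
  the 1.4–2.2% band typical of protean-annotated corpora;
* 10% of proteins are mutated copies (~85% identity) of earlier ones,
  so cluster-grouped fold construction has real families to keep
  together; the true family map is written as a cluster file.

The `topography_only` preset strips every signal except topography:
uniform composition, one secondary-structure process, pure-noise
PSSMs, a fully disordered plateau, and — besides the shallow
(15%-deep) valley at each protean segment — one or two longer decoy
valleys per protein. The decoys matter: they make the peak/valley
*class* ambiguous so that only the topographic *run length*
(protean valleys ≈ 11–19 residues, decoys 35–55) separates the
classes, which is what lets the feature-group search and the
feature-importance ranking single out topographic length as the
dominant feature, as a constructed property of this corpus rather
than a claim about real data.

What the generator does **not** emulate: realistic PSI-BLAST score
distributions and profile correlations, sequence repeats and
low-complexity structure, multi-segment and terminal protean
annotations, disorder predictors' long-range smoothness, or biased
annotation noise. Passing tests on this corpus therefore demonstrate
that the machinery is correct and that planted signal of realistic
shape and size is recovered; they do not predict performance on real
annotated proteins, which is dominated by how informative the real
tracks are.

## Problem sizes and numerical choices

The structural tests run on corpora of 12–60 proteins; parameter
recovery and cross-validation use the generator's default 200
proteins (~41,000 residues) with 30-tree forests, and the exhaustive
127-subset search runs on a 40-protein topography-only corpus with
10-tree forests and 3 folds — enumeration and ranking are what is
being checked there, and tree count beyond that mostly buys variance
reduction. The acceptance script (`scripts/acceptance.R`) recomputes
all headline quantities at these sizes in a few minutes on one CPU.

Remaining numerical conventions: scores are written with four
decimals and round-trip exactly at that precision; fold ids and
cluster ids are 1-based; per-fold forest seeds are `seed + fold` so
rotations are independent but reproducible; the feature-group subset
table enumerates the 127 non-empty subsets of {1..7} in bitmask
order with both MCC and F1 rankings attached.

## Known limitations

* The greedy clusterer is a deliberate approximation: gapless
  single-diagonal identity misses gapped homology, so it
  under-clusters relative to a real alignment-based tool; for
  published corpora, use the external tool's cluster file.
* Per-residue scores ignore segment-level structure; no smoothing or
  minimum-length post-processing is applied to the binary calls.
* The propensity analysis treats residues as independent draws;
  segment-level autocorrelation makes its effective sample size
  smaller than the residue count, so small classes have noisier
  propensities than the counts suggest.
* Forest determinism is guaranteed for a fixed `ranger` version and
  single-threaded prediction; the package pins `num.threads = 1`
  everywhere for that reason.
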