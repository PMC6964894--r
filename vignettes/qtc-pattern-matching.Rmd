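---
title: "Recognising spatial movement patterns with the Qualitative Trajectory Calculus"
author: "qtcmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising spatial movement patterns with the Qualitative Trajectory Calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtcmatch)
```

## The problem

Given uniformly sampled 2-D tracks of several moving objects — the
motivating case is camera-based player tracking in team sports at 25 Hz —
an analyst picks a *reference fragment*: the movements of a chosen set of
players during one time window. The task is to find all other windows of
the recording in which the same (or other) players performed a *similar*
spatial movement, where "similar" should be insensitive to where on the
field the movement happens, at what spatial scale, and (to a controlled
degree) at what speed.

Coordinate-based distances (mean Euclidean distance, Fréchet distance,
dynamic time warping on positions) are tied to absolute locations: the
same give-and-go performed on the left wing and on the right wing are far
apart. `qtcmatch` instead describes movement *relatively*, with the basic
Qualitative Trajectory Calculus (QTC~B~).

## The representation

For an ordered pair of objects $(k, l)$ and one inter-sample interval
$t_1 \to t_2$, the relation of $k$ with respect to $l$ is

$$
\chi(k \mid l) =
\begin{cases}
  \texttt{-} & d(k_{t_2}, l_{t_1}) - d(k_{t_1}, l_{t_1}) < -\varepsilon \\
  \texttt{+} & d(k_{t_2}, l_{t_1}) - d(k_{t_1}, l_{t_1}) > +\varepsilon \\
  \texttt{0} & \text{otherwise,}
\end{cases}
$$

with $d$ the Euclidean distance: does $k$ move towards, away from, or
neither with respect to $l$'s position at the start of the interval? One
interval of a fragment is summarised by the *QTC matrix* of all pairwise
two-character cells, and the fragment of $m$ samples by the sequence of
its $m - 1$ matrices. Three consequences drive everything else:

* **Invariance.** Signs of Euclidean distance changes are preserved by
  translation, rotation, reflection and uniform scaling, so two fragments
  whose relative movements agree encode identically wherever and at
  whatever scale they occur.
* **Anchoring.** Adding *static points* (e.g. the four field corners,
  `field_corner_statics()`) to the roster reintroduces location and scale
  sensitivity exactly where the analyst wants it: a player's relation to a
  fixed corner changes when the same run happens elsewhere — provided the
  displaced movement actually flips some player-to-anchor relation. A
  translation parallel to all anchor sight-lines is still invisible; this
  is a property of the calculus, not an artefact.
* **Discreteness.** Small coordinate jitter mostly leaves the symbols
  unchanged, which is the method's native noise robustness.

Static–static pairs are never stored: both of their characters are
constant `'0'`, so they would only inflate the normalization denominator.

## Comparing sequences

Two matrices over the same roster are compared cell by cell; each
character pair contributes its *conceptual distance*, the chain metric
$d(\texttt{-},\texttt{0}) = d(\texttt{0},\texttt{+}) = 1$,
$d(\texttt{-},\texttt{+}) = 2$ (configurable through `cost_scheme()`; the
chain is the canonical neighbourhood structure of the three symbols, and
all default costs are small integers so distances are exactly
reproducible across platforms). Whole sequences are aligned with a
Levenshtein distance in which substituting a matrix costs the cell-sum
above and inserting or deleting a matrix costs the roster's *maximum*
substitution cost $C_{\max} = P \cdot 2 \cdot d_{\max}$, with $P$ the
number of informative pairs. Indels are what make the comparison robust
to speed differences and unequal fragment lengths: the same run performed
faster produces fewer matrices, and the missing ones are bridged at a
bounded, known cost instead of contaminating every later position as a
substitution-only ("pairwise") comparison would. The package keeps that
baseline (`pairwise_distance()`) precisely to expose the contrast, which
the test suite asserts as a strict inequality on time-warped fragments.

Raw costs are normalized to $[0, 1]$ by dividing by
$\max(\mathrm{len}_a, \mathrm{len}_b) \cdot C_{\max}$ — the tight upper
bound reachable by aligning position-wise and paying indels for the
length difference. Two empty sequences have distance 0 by convention.
`qtc_levenshtein_cutoff()` aborts the dynamic program as soon as the
running row minimum exceeds a caller-supplied threshold (every alignment
path crosses every row with non-decreasing cost, so the row minimum is a
valid lower bound); when it returns a number it is the exact distance.

## Matching pipeline

`match_reference()` encodes the (downsampled) reference once, slides a
fully contained window over the recording (starts $0, s, 2s, \dots$ — a
20-second, 500-sample window every 10 samples over a 144,086-sample
recording yields 14,359 candidates), scores every window that does not
overlap the reference, and ranks by normalized distance with earlier
starts breaking ties. Overlapping near-duplicates around each genuine
match are then removed greedily from rank 1 down
(`filter_non_overlapping()`), and `top_k()` returns the analyst's short
list. When `permutable_ids` is given, every role assignment of those
players is tried per window and the minimum kept, so patterns executed by
other players are still found; enumeration is exhaustive ($n!$
assignments), which is exact but meant for small rosters.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window` | reference length | candidate length, samples (500 = 20 s at 25 Hz) |
| `stride` | 10 | samples between candidate starts (0.4 s at 25 Hz) |
| `downsample_factor` | 1 | keep every n-th sample; 10 is typical for 25 Hz tracking, both for speed and to damp noise |
| `epsilon` | 0 m | dead-band below which a distance change reads `'0'` |
| `statics` | none | anchors; `field-corners` places four at a 105 × 68 m pitch |
| `k` | 9 (CLI) | size of the final short list |

`epsilon = 0` is the canonical continuous definition and the default;
the original formulation leans on temporal downsampling rather than a
dead-band for noise control. With noisy real tracking a value near the
per-interval jitter (~0.05 m at 25 Hz) is reasonable. The package's own
invariance tests encode rotated coordinates with `epsilon = 1e-9`, since
rotation introduces ~1e-15 rounding that would otherwise flip exact-zero
distance changes arbitrarily.

## Numerical and design choices

* Time is 0-based uniform sample indices; seconds are derived. Windows
  are half-open and fully contained (no partial trailing window).
  Downsampling keeps the first sample and drops any trailing remainder.
  Non-uniform sampling is rejected, not resampled.
* A coincident anchor (two objects at the same spot) needs no special
  case: the distance-change formula yields `'+'` or `'0'`.
* Candidate windows overlapping the reference are excluded before
  ranking — the reference would otherwise trivially occupy rank 1 — and
  "overlap" means sharing at least one original-resolution sample.
* Ties in normalized distance break by earlier start index, and the
  permutation search enumerates identity first, so equal-cost outcomes
  are deterministic; two runs with the same inputs are byte-identical.
* Under the default scheme all costs are integers and the dynamic
  program does integer-valued arithmetic in doubles, far below the
  precision limit.

## The synthetic scene generator

Real tracking data of professional matches is proprietary, so the test
bed is synthetic: `soccer_scene()` builds seeded random-walk background
traffic on a 105 × 68 m pitch (reflecting boundaries, step sigma 0.15
m/sample) and plants copies of a deterministic two-player
sprint-and-turn-back motif — a parallel attacking run that breaks into a
defensive run halfway, the shape of a common trained pattern — at known,
stride-aligned windows: pure translations (exactly
relation-preserving) and rotated/scaled copies (rotation uniform on
$(-\pi, \pi)$, scale on $(0.7, 1.3)$) with 0.05 m Gaussian positional
noise, roughly the accuracy of good camera tracking. The side-car
annotation of planted windows is the ground truth for retrieval checks.

What the generator does *not* emulate: ball- and opponent-driven
behaviour, physiological speed profiles, out-of-play stoppages, and the
heavy-tailed error bursts of real tracking pipelines. Passing retrieval
tests therefore demonstrate the machinery — encoding, alignment, ranking,
filtering — under controlled conditions, not field performance on real
match data.

Problem sizes used in the shipped checks are deliberate scale-downs of
the motivating case study: scenes of 240 s at 25 Hz (6,000 samples)
with a 250-sample motif, stride 50 and downsample factor 10 for
retrieval; 1,000 random fragment pairs of 2–60 samples for the
normalization bound; exhaustive-enumeration cross-checks on sequences of
length ≤ 5, where all monotone alignments can be enumerated
independently of the dynamic program.

## Known limitations

* Permutation matching is factorial in the permutable roster; beyond ~6
  permutable players it becomes the dominant cost.
* The matcher scores every window (optionally with the cutoff variant
  for screening); there is no indexing or compression of QTC sequences.
* Relations are pairwise only; the calculus used here is the basic
  two-character variant, without side or speed characters.
* Ball possession and play context are outside the representation;
  matches found are purely kinematic.
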