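# qtcmatch

Recognition of recurring spatial movement patterns in uniformly sampled
2-D trajectories of co-moving objects, built around the basic Qualitative
Trajectory Calculus (QTC_B). The motivating use is team-sport analytics: a
coach or analyst selects a game fragment — the movements of a chosen set
of tracked players during a time window — and asks where else in the
match the same relative movement occurred, regardless of where on the
field, at what spatial scale, and tolerant of moderate speed differences.

## The method in brief

For an ordered object pair (k, l) and one inter-sample interval
t1 → t2, QTC_B records whether k moves towards (`-`), away from (`+`), or
neither (`0`) with respect to l's position at t1, by the sign of
d(k_t2, l_t1) − d(k_t1, l_t1) with Euclidean d (an epsilon dead-band
optionally widens the `0` class). All pairwise two-character cells of one
interval form a QTC matrix; a fragment of m samples becomes a sequence of
m − 1 matrices. Since signs of distance changes survive translation,
rotation, reflection and uniform scaling, identically shaped movements
encode identically anywhere on the field; adding static anchor points
(e.g. the four field corners) selectively restores location and scale
sensitivity.

Sequences are compared with a Levenshtein distance: substituting one
matrix for another costs the sum of conceptual distances between the
cell characters (chain metric `-`↔`0`↔`+`: 1 per step, 2 across),
inserting or deleting a matrix costs the roster's maximum substitution
cost C_max = P · 2 · d_max over the P informative pairs. Dividing by
max(len_a, len_b) · C_max yields a normalized distance in [0, 1].
Candidate windows slide over the recording at a fixed stride, are ranked
by normalized distance to the reference, greedily filtered so no kept
window overlaps a better-ranked one, and truncated to the top k. Role
permutations between chosen players can be searched exhaustively, and a
threshold-aborted distance supports fast screening.

## Worked example

Everything below is reproducible — the scene is generated from its seed.

```r
library(qtcmatch)

# synthetic 120 s recording at 25 Hz: two players of random-walk
# background traffic with 5 planted copies of a sprint-and-turn motif
# (3 pure translations, 2 rotated/scaled with 0.05 m noise)
sc <- soccer_scene(seed = 42, duration = 120, motif_length = 250,
                   n_exact = 3, n_transformed = 2, align = 50)
sc$annotation
#>   motif_id start_index end_index                         transform
#> 1 motif_01           0       250                       translation
#> 2 motif_02         650       900                       translation
#> 3 motif_03        1350      1600                       translation
#> 4 motif_04        2050      2300 rot=-0.342,scale=1.196,noise=0.05
#> 5 motif_05        2750      3000  rot=2.068,scale=0.741,noise=0.05

# use the first planted occurrence as the reference fragment and rank
# all disjoint sliding windows by normalized QTC distance
ranked <- match_reference(sc$recording, c("P1", "P2"),
                          ref_start = 0, ref_length = 250,
                          stride = 50, downsample_factor = 10)
top_k(filter_non_overlapping(ranked), 5)
#> <5 ranked candidate fragment(s)>
#>  rank start_index end_index start_seconds raw_cost normalized permutation
#>     1         650       900            26        0 0.00000000        <NA>
#>     2        1350      1600            54        0 0.00000000        <NA>
#>     3        2050      2300            82        0 0.00000000        <NA>
#>     4        2750      3000           110        4 0.04166667        <NA>
#>     5        1600      1850            64       40 0.41666667        <NA>
```

The two disjoint translated copies are retrieved at normalized distance
exactly 0 (identical relative movements), and so is one rotated/scaled
copy — downsampling by 10 absorbed its positional noise entirely. The
other noisy copy scores 0.04, while the best pure-noise window is an
order of magnitude farther (0.42). Rank, window indices, seconds, raw
alignment cost and the normalized distance in [0, 1] are the columns a
TSV export carries.

The QTC representation itself can be inspected:

```r
fr <- make_fragment(sc$recording, c("P1", "P2"), 0, 250)
s  <- encode_sequence(downsample_fragment(fr, 10))
s
#> <QTC sequence: 24 matrices, 2 moving + 0 static objects>
format_qtc_sequence(s)[1:3]
#> [1] "P1|P2:-+" "P1|P2:-+" "P1|P2:-+"
```

(`-+`: in that interval P1 moves towards P2 while P2 moves away from P1.)

## Command line

```sh
Rscript inst/cli/qtcmatch match \
  --input scene.csv --players P1,P2 \
  --ref-start 0 --ref-len 500 --window 500 --stride 10 --downsample 10 \
  --statics field-corners --top-k 9 --output matches.tsv
```

Input is long-format CSV (`timestamp,object_id,x,y`, metres, uniform
timestamps); output is a ranked TSV. `encode` dumps the QTC debug text of
one fragment. A flat `key = value` config file (`--config`) supplies
defaults that explicit flags override; identical invocations produce
byte-identical output.

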