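---
title: "Circularised fingerprint maps: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circularised fingerprint maps: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfmap)
```

## The model

`gfmap` compares genome assemblies as geometric objects rather than by
base-to-base alignment. Each sequence is turned into a cumulative
three-dimensional walk in which every base contributes a unit step on all
three axes:

| base | X | Y | Z |
|------|---|---|---|
| A | +1 | +1 | +1 |
| C | −1 | +1 | −1 |
| G | +1 | −1 | −1 |
| T | −1 | −1 | +1 |

After `n` bases the coordinates count composition biases:
`X_n = (A_n + G_n) − (C_n + T_n)` (purine vs pyrimidine),
`Y_n = (A_n + C_n) − (G_n + T_n)` (amino vs keto), and
`Z_n = (A_n + T_n) − (C_n + G_n)` (weak vs strong hydrogen bonding). This is
the classic Z-curve-style nucleotide walk. A region with a sustained
composition bias — a large tandem array, for instance — draws a long, sharp,
nearly straight line on the map, which is the visual signature everything
downstream builds on.

**Circularisation.** The raw walk depends on where a (circular, or
arbitrarily cut) sequence was opened. `circularise()` removes that
dependence by subtracting the straight line from origin to endpoint,
`K̃_n = K_n − (n/N)·K_N` per axis, forcing the walk to close at the origin.
We read the published construction as exactly this identity-walk-plus-linear
detrend: it is the only reading under which a sustained bias yields a
straight line on a *closed* map, and it reproduces the closure property the
method relies on. Summaries are computed on the circularised points
`n = 1..N`; the origin (`n = 0`) is a construction artefact, not a walk
point, and is excluded — with a hundred thousand points or more the choice
is numerically immaterial, but it is fixed here for reproducibility.

**Map-to-map comparison.** A circularised map is summarised
(`summarise_track()`) by its geometric centre `(X̄, Ȳ, Z̄)`, per-axis
population standard deviations `(σ_X, σ_Y, σ_Z)` — the point cloud is the
complete object, not a sample, hence the divide-by-N convention — the
eigenvalues and eigenvectors of the 3×3 coordinate covariance (the cloud's
shape and orientation), and the mean radius about the centre.

Two genomes `i`, `j` are compared by a weighted Euclidean distance between
centres, each axis weighted by the geometric mean of the two spreads:

$$ d_{(i,j)} = \sqrt{\sqrt{\sigma_{Xi}\sigma_{Xj}}(\bar X_i-\bar X_j)^2
            + \sqrt{\sigma_{Yi}\sigma_{Yj}}(\bar Y_i-\bar Y_j)^2
            + \sqrt{\sigma_{Zi}\sigma_{Zj}}(\bar Z_i-\bar Z_j)^2 } $$

and by the angles between their covariance eigenvectors,
`cos θ_k = C_k^i·C_k^j / (|C_k^i||C_k^j|)`, summed over the three axes to
`Θ = θ_1 + θ_2 + θ_3`. The combined distance is the literal product
`D = d·Θ`. A matrix of `d` or `D` values over `M` genomes
(`build_distance_matrix()`) feeds neighbour joining (`nj_tree()`) or any
external distance-based tree/network program via PHYLIP export
(`write_phylip()`).

## Design choices where the construction was open

Several details of the published construction are not fully specified; the
package fixes them as follows.

- **Eigenvector matching is by eigenvalue rank** (first with first, second
  with second, third with third). Rank matching is the only symmetric,
  deterministic pairing that needs no reference orientation.
- **Angles use the absolute cosine**, `θ = arccos|cos θ| ∈ [0, π/2]`. An
  eigenvector's sign is mathematically arbitrary; without the absolute
  value, two identical genomes could score `θ = π` per axis depending on the
  solver's sign convention. Consequently `Θ ∈ [0, 3π/2]`.
- **`D = d·Θ` is implemented literally**, including its degeneracy: two
  clouds with different centres but identical eigen-orientation score
  `Θ = 0` and therefore `D = 0`. This is a property of the model, not a bug
  in the implementation; it is documented rather than repaired (no epsilon
  floor). `mode = "d"` is available where a pure centre distance is wanted.
- **Zero spread on an axis** zeroes that axis's weight in `d` (the term
  drops out); a completely flat (zero-variance) cloud has no orientation and
  its angle factor is defined as 0, with a warning.
- **Eigenvalue ties** (relative gap below 1e-9) leave the eigenbasis
  arbitrary within the tied subspace; the summary carries a `degenerate`
  flag instead of pretending an orientation. Cosines are clipped to
  `[−1, 1]` before `arccos`.
- **Mean radius** is computed and exported with every summary but does not
  enter `d`; the per-axis spreads are the "radius" proxy that weights the
  distance.
- **Neighbour joining** is implemented in-package with a fixed contract:
  Q-criterion ties break to the lowest index pair in the current cluster
  order (input order, merged clusters appended last), and negative branch
  lengths are clamped to zero with a `clamped` flag on the tree. Two taxa
  yield a single edge split evenly. Minimum-evolution trees and split
  networks are reached through PHYLIP export to external software, which is
  how the method is meant to interoperate; only NJ is needed in-package to
  exercise the pipeline end to end.

## Gap cleaning and coordinates

The walk consumes A/C/G/T only. `clean_ns()` produces the *effective
genome*: `U` becomes `T`, and every run of any other non-ACGT character
(N gap placeholders and IUPAC ambiguity codes alike) is excised, linking the
flanking bases. Every removed run is logged in a gap ledger with its
original 1-based inclusive coordinates, so `map_to_original()` can report
any detected feature in assembly coordinates. `min_run` (default 1)
controls only how a removed run is *classified* in the ledger — runs of at
least `min_run` are assembly gaps, shorter ones ambiguity calls — because an
A/C/G/T-only sequence is non-negotiable for the walk. All package
coordinates are 1-based inclusive; BED exports convert to 0-based half-open
at the boundary. Case is ignored on input: soft-masked lowercase bases are
ordinary bases, not gaps.

## The straight-line detector

The published analyses located composition-biased segments *visually* on
the galaxy of maps; `detect_bias_segments()` formalises that judgement. It
slides a window along each axis of the (normally circularised) track,
fits coordinate against position by least squares, keeps windows that pass
slope and fit thresholds, merges overlapping same-sign windows, and drops
merged runs shorter than a minimum length.

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| `window` | 10 000 | bases | long enough that random-walk wiggle cannot fake a high R²; short relative to the 50-kb scale of interest |
| `min_len` | 50 000 | bases | a BAC-scale array; shorter runs are unremarkable on a chromosome map |
| `min_abs_slope` | 0.2 | coord./base | a pure 5-bp satellite such as GAATG steps X by +3 per 5 bases (slope 0.6) and Y by −1 per 5 (slope −0.2); 0.2 keeps axes where the bias is strong and rejects background drift |
| `min_r2` | 0.98 | — | "sharp straight line": near-perfect linearity, which tandem arrays produce and random sequence does not |
| `step` | `window/5` | bases | boundary resolution of 2 kb at the default window |

These thresholds are this package's calibration, justified by the GAATG
arithmetic above; the original visual analysis published none. All are
configurable per call, via the CLI flags, or via a key=value config file
(flags take precedence over the file, which takes precedence over
defaults). Note that on a circularised track the detrend subtracts the
global slope, so an inserted 50-kb GAATG block in a 250-kb sequence shows an
X slope of about 0.6 − 50 000·0.6/250 000 ≈ 0.48, while its Y slope shrinks
from −0.2 towards −0.16: the Y line is real but needs a laxer
`min_abs_slope` to call, which is why detection is strongest on the X axis
for purine-biased satellites. Detection always runs on the full-resolution
track; `build_ggfm()`'s stride downsamples plotting only.

`pred_delete()` — proofreading errors-deletion — excises a flagged interval
from the *cleaned* sequence (detection coordinates address the effective
genome), extends the ledger with the excised span in original coordinates
(absorbing any N-gaps it contains), and keeps the deleted subsequence on the
object, so every deletion is reversible bookkeeping, not data loss.

## The synthetic generator, and what passing tests show

`random_genome()` draws i.i.d. bases at a chosen GC content;
`make_assembly_pair()` models two releases of one assembly where the later
release gained a composition-biased tandem block — by default a 50-kb
`(GAATG)` array (a pericentromeric satellite monomer) inserted into a 200-kb
antecedent at position 100 001. Those defaults mirror the scale of the
published case study (a megabase-range chromosome region acquiring a
BAC-sized satellite array) reduced to desk scale. `mutate_genome()` applies
i.i.d. substitutions, uniform over the three alternatives, for divergence
gradients in tree tests. All generators are pure functions of parameters
plus seed and never touch the session RNG stream.

Real chromosomes are not i.i.d. sequence: they carry isochores, dispersed
repeats, and satellite families with internal divergence, all of which add
structure to the walk that the generator does not emulate. Passing tests
therefore demonstrate that the geometry behaves as specified — walks close,
shape statistics are rotation-invariant, a clean inserted bias is found
with ≤ 2-kb boundary error and its deletion restores the pairwise `D` to
under 5 % of the pre-deletion value, quartets of nested mutation are
recovered in at least 9 of 10 seeded replicates — not that the default
thresholds are tuned for any particular real genome. On real assemblies the
detector's parameters should be chosen by inspecting the maps, exactly as
the visual method intends.

Test and acceptance problem sizes — 200-kb antecedents, 10–20-kb sequences
for statistical properties, 20 seeded assembly pairs, trees to 12 taxa —
were chosen as the smallest scales at which every property is exercised
meaningfully with comfortable margins.

## Repeat bookkeeping conventions

Tandem arrays are named in core-unit notation: `173U` is a 173-bp monomer
(core unit), `173U1020C` an array of 1 020 copies of it (a core-unit
repeat, equivalent to a higher-order repeat). `parse_cur()`/`format_cur()`
convert between names and sizes. Kbp/Mbp figures round half away from zero
to two decimals, and the raw bp count is always carried alongside, because
published tables are not always consistent about rounding versus
truncation. `scan_motif()` counts exact, case-insensitive, non-overlapping
forward-strand matches (greedy left to right); reverse-complement scanning
is available behind a flag but off by default, matching how telomere-motif
counts are conventionally reported for a given strand. `repeat_fraction()`
sums component lengths *as printed* without overlap resolution — nested
arrays are double-counted, which is how published totals are constructed —
while `union_length()` gives the honest overlap-resolved coverage.

## Known limitations

- `D = d·Θ` is not a metric: it can be zero for distinct genomes (see
  above) and the triangle inequality is not guaranteed. Trees built from it
  are approximations whose value is empirical, not axiomatic.
- The summary (centre, spreads, eigen-structure) is a drastic reduction of
  the map; sequences with different architecture can in principle share a
  summary. The maps themselves (`build_ggfm()`, `contour_grid()`) remain the
  primary diagnostic; the matrix is for batch comparison.
- The detector assumes an approximately uniform background; a genome-wide
  compositional gradient raises the background slope and can mask or mimic
  segments. Inspect the X–Length/Y–Length panels before trusting calls.
- Whether a detected segment is genuinely misassembled is a biological
  judgement outside the package's scope; `pred_delete()` records, it does
  not decide.
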