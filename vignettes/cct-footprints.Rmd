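---
title: "Detecting co-conversion footprints of a homing mitochondrial intron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-conversion footprints of a homing mitochondrial intron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctrace)
library(dplyr)
```

## The biology being modelled

The mitochondrial *cox1* gene of many flowering plants carries a group I
intron at a single canonical insertion site. The intron encodes a homing
endonuclease: in a heteroplasmic cell the enzyme cleaves intron-lacking
alleles at the homing site, and double-strand-break repair copies the intron
— together with a stretch of the *donor's* flanking exon sequence — into the
recipient. The stretch of replaced exon is the **co-conversion tract (CCT)**.
Because plant mitochondrial exons evolve extremely slowly, a CCT shows up as
a tight cluster of substitutions, shared by every member of the recipient
clade, immediately flanking the insertion site — a durable molecular
footprint of horizontal acquisition.

Two other processes leave related footprints. **Retroprocessing** (RNA-mediated
intron loss) copies a spliced, edited mRNA back into the gene: the intron
disappears, and genomic `C` becomes `T` at downstream C-to-U RNA editing
sites. And **secondary intron loss by other routes** can strand a full CCT in
an intron-lacking gene. Distinguishing these scenarios — many horizontal
gains versus one ancient gain followed by rampant loss — is the inferential
problem this package addresses.

`cctrace` provides the full inference chain: in-silico re-implementation of
the PCR/gel presence assay, ancestral exon reconstruction, diagnostic-site
calling with homoplasy filtering, CCT bound estimation, the
retroprocessing-signature test, constrained Dollo gain/loss comparison on
trees with polychotomies, and a forward simulator that generates
ground-truthed data under explicit homing/loss event schedules.

## The coordinate frame

All footprints are expressed in **signed exon positions**: `+k` is the k-th
exon base downstream (3') of the insertion point, `-k` the k-th base
upstream; there is no position 0. Positions are counted on a designated
ungapped reference row (by default the first intron-lacking taxon, or an
explicit reference such as the reconstructed ancestor), so alignment columns
that are gaps in the reference carry no signed position. The mapping between
signed positions and alignment columns is bijective over non-gap columns —
a property the test suite checks over randomized gapped frames. Internally
the insertion point is stored as the 1-based index of the column immediately
5' of it, the natural convention in R.

Raw nucleotide counting is used (not codon counting): the published
footprint coordinates ("+20", "+27", "+35", ...) are nucleotide offsets.

## Diagnostic sites and the homoplasy filter

Given an alignment, a reconstructed ancestor and a declared focal clade of
intron-containing taxa, a position is **diagnostic** when every focal member
shares one concrete base that differs from the ancestral state. Three
conservative choices matter:

* Ambiguity codes other than `A`/`C`/`G`/`T` never count as a shared focal
  state, and positions with an unresolvable (`N`) ancestor are skipped.
* Taxa of unknown intron status are excluded from the intron-lacking
  comparison panel rather than imputed.
* Any occurrence of the derived state in an intron-lacking taxon flags the
  site as **homoplastic** (an occurrence-count threshold is configurable,
  default 1). Flagged sites are reported but excluded from tract bounds;
  recurrent sites such as those 11 bp upstream and 60 bp downstream of the
  insertion site in the Solanaceae are exactly the case this filter exists
  for.

The focal clade may be *any* declared taxon set, not only a clade of the
tree — footprints are sometimes shared across separately rooted acquisition
clades, and the sharing itself is evidence worth quantifying.

The ancestral sequence is reconstructed per column by unit-cost parsimony
(Fitch/Sankoff dynamic programming, exact on multifurcating trees). Ties in
the minimum-change root set are resolved by the majority state among
intron-lacking taxa, then alphabetically; with no tree supplied the
reconstruction falls back to the consensus of intron-lacking taxa. The
dynamic program is checked in the tests against exhaustive enumeration of
all internal-node assignments on small random trees.

## Tract bounds: what "minimum length" means

The **minimum tract length** on each side is defined as the farthest
non-homoplastic diagnostic position — the only definition consistent with
all published minimum lengths (35, 54, 63, 78, 81 bp), each of which equals
its farthest diagnostic site. With no further evidence the tract endpoint is
unbounded above: conversion beyond the last diagnostic site is invisible
whenever donor and recipient happened to agree there.

An **upper bound** on the endpoint exists only when a candidate donor group
is supplied: it is the first position beyond the lower bound at which the
focal clade demonstrably retains the native (ancestral) state while the
donor group differs from it. The resulting endpoint interval `(lower,
upper)` is open on both sides. The banana-family worked example reproduces
this logic: five eudicot-signature sites up to +63, donor-retained native
evidence at +70, endpoint interval (63, 70).

## The retroprocessing signature

For an intron-lacking taxon, the test examines downstream C-to-U editing
sites (within a 600-bp window by default — generous relative to any
published footprint, configurable) whose *ancestral* state is `C`:

* `T` observed at one or more such sites → `retro_signature`;
* `C` retained at all of them → `no_signature` (the gene plausibly never
  carried the intron);
* intron-containing or unknown taxa, or no informative site → `indeterminate`.

Comparison is at the DNA level; no RNA data are modelled. Edit positions are
an input (a prediction tool or experimental table supplies them), not
something the package infers.

A complementary screen, `intron_loss_with_cct()`, recognizes the opposite
footprint: an intron-lacking taxon that matches the focal clade's derived
state at every non-homoplastic diagnostic site — loss with full tract
retention. When screening a loss candidate, diagnostic sites should be
called from the alignment *without* the candidate (the `cynomorium_loss`
fixture bundles this recipe): a tract-bearing intron-lacking taxon would
otherwise flag every site of its own footprint as homoplastic.

## Gain/loss parsimony with polychotomies

Two extreme scenarios are compared by event counts alone (no likelihood —
the comparison mirrors a parsimony argument):

* **Single gain** at a designated node, Dollo-constrained (no regain),
  followed by losses. The minimum number of losses equals the number of
  maximal intron-lacking subtrees below the gain node; unknown tips take
  whichever state minimizes the count and are absorbed into neighbouring
  loss edges for free.
* **Free gains, no losses**: one gain per maximal intron-bearing subtree.

On trees with polychotomies the counts depend on how each polychotomy is
resolved, so a range over all binary resolutions is reported. Resolutions
are enumerated exhaustively up to a cap (10,000); beyond it a per-polychotomy
closed form is used. The closed form is exact because contributions are
additive across polychotomies: at a polychotomy reached from a mixed
context, its absent-only children can be united into a single clade by some
resolution (one loss, the minimum, provided a mixed child anchors the
remainder) or kept pairwise separate by a caterpillar resolution
interleaving them with the mixed children (one loss each, the maximum);
resolutions of distinct polychotomies interact with neither each other nor
the fixed binary parts of the tree. The degenerate case of a gain node all
of whose children lack the intron splits into exactly two clades and is
handled separately. The equality of both routes — and of both with an
independent oracle that enumerates resolutions and loss-edge subsets — is
asserted on 200 random multifurcating trees in the acceptance suite.

Intron/CCT co-occurrence across taxa is summarised as a 2×2 table with a
two-sided exact hypergeometric p-value (`stats::fisher.test`), degenerate
margins flagged with p = 1, and discordant taxa listed by name.

## The simulator

`simulate_locus()` evolves a root exon sequence tip-ward along a rooted
tree under Jukes–Cantor substitution and applies an explicit event schedule
at branch midpoints:

* `homing` — copies the donor lineage's exon states over the recipient at
  every position in `[-L5, +L3]` (contiguous, polarity outward from the
  insertion point — no mosaic tracts) and marks the recipient subtree
  intron-present. The donor may be another lineage (snapshotted at its own
  branch midpoint) or an external sequence.
* `vertical_origin` — marks a subtree intron-present with no conversion.
* `retro_loss` — removes the intron and converts `C` to `T` at every edit
  site within the retro window (default 600 bp) that currently carries `C`.

Jukes–Cantor is implemented through the uniformization identity: with
probability `1 − exp(−4d/3)` a site is redrawn uniformly over all four
bases (possibly silently), giving the textbook `P(observed change) = 3/4 (1
− exp(−4d/3))` for branch length `d` — a property the tests check against a
3-standard-deviation envelope over replicate pairs. Because the redraw is
state-independent, all per-branch draws are fixed up front from the single
seeded RNG stream and reused identically by the baseline pass (which
provides donor midpoint snapshots) and the event pass; outputs are
byte-identical given the same configuration and seed. A donor snapshot
therefore reflects the donor lineage's evolved state without regard to
events scheduled earlier on the donor's own path — exact in the rate-0
regime the recovery tests use, and a documented approximation otherwise.

Substitution is deliberately the only background process: the exons being
emulated are so conserved that model richness beyond Jukes–Cantor would add
parameters without adding realism, and indels, selection, rate
heterogeneity and recombination (beyond the specified tract copy) are not
modelled. The intron sequence itself (default 967 bp, carrying a single
embedded open reading frame of 840 bp, stop codon included) is held
constant after acquisition — intron identity across an acquisition clade
mirrors the near-identical introns observed within real acquisition clades,
and intron evolution is not the object of inference. Consequently, passing
tests demonstrate correctness of the inference machinery under these
idealized conditions, not robustness to alignment error, indels, lineage
sorting or sequencing artefacts in real surveys.

The root sequence can embed concrete footprints of a chosen primer pair
spaced so the intron-less amplicon is exactly 800 bp, which lets the
in-silico survey run end-to-end on simulated data.

## The in-silico survey

Primer matching uses IUPAC degeneracy on both strands (the reverse primer,
written 5'→3' as synthesized, is matched as its reverse complement —
standard PCR convention, which the original survey description leaves
implicit). **Amplicon lengths are counted inclusive of both primer
footprints**; this is the only convention under which the published 800-bp
intron-less product is self-consistent with the primer positions, and it is
stated prominently because product-size conventions are a common source of
off-by-a-primer errors. The built-in registry also ships the alternative
flanking pair whose published product sizes (750 bp and 1735 bp) differ by
985 bp rather than the 967-bp intron length; the discrepancy is inherited
from the source sizes (rounding/geometry) and deliberately left unresolved.

Gel classification: a product within 100 bp of the expected intron-less
size is `absent` (gel-sizing tolerance); at least 500 bp larger is
`present` (the intron is two-thirds of the gene's length — the size classes
are far apart); between the two, `ambiguous`; no product, `no_amplicon`.
The default mismatch budget for primer annealing is 0 (survey DNA quality
is not modelled) and is configurable.

ORF measurement reports the longest ATG-initiated, stop-terminated
forward-strand reading frame, stop codon included, ties broken by smallest
start; it is validated against an exhaustive scanner on random sequences.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| scan `window` | 200 | bp | all published footprints lie within ±81 |
| `homoplasy_threshold` | 1 | occurrences | any recurrence disqualifies a site |
| `threshold_delta` | 500 | bp | intron-present size class |
| gel `tolerance` | 100 | bp | gel-sizing precision |
| `retro_window` | 600 | bp | covers all plausibly informative edit sites |
| `resolution_cap` | 10,000 | resolutions | exhaustive enumeration budget |
| `intron_length` | 967 | bp | observed intron length |
| `orf_length` | 840 | bp | observed endonuclease ORF |
| `max_mismatches` | 0 | bases/primer | idealized annealing |

## Numerical and degenerate-input choices

* Parsimony ties: intron-lacking majority, then alphabetical — deterministic
  and biased toward the native state, which is the conservative direction
  for footprint calling.
* Columns entirely gap/`N` reconstruct as `N` and never yield sites.
* Bounds with no diagnostic sites are 0 with an endpoint interval
  `(0, unbounded)`.
* `embed_orf()` keeps the ORF interior free of `A` outside the start codon
  and scrubs `ATG` triplets from the flanks, then verifies the construction
  by exhaustive scan; geometry that cannot be realized is a configuration
  error rather than a silent retry forever.
* All randomness flows through explicit seeds; the pipeline writes no
  timestamps, so identical runs are byte-identical.

## Validation design and problem sizes

The test suite pairs every non-trivial operation with an independent oracle:
exhaustive internal-assignment enumeration for ancestral states (6-tip
trees), exhaustive resolution-and-loss-subset enumeration for gain/loss
ranges (200 random multifurcating trees of up to 12 tips), brute-force ORF
scanning (random 500-mers), closed-form hypergeometric sums for the exact
test, and construction-based identities for PCR sizing (800/1767 bp).
Parameter recovery uses 500 rate-0 simulations with a densely divergent
donor (one difference per codon) and true 3' tract lengths of 10–81 bp,
checking that the inferred lower bound equals the farthest donor-differing
position within the tract and never exceeds the true length. The
retroprocessing screen is checked for exact truth-table agreement on 50
noiseless replicates, and its specificity under background substitution
(rate 0.02) is measured on a design with five never-had taxa so that
consensus-ancestor fragility does not mask verdict errors. These sizes were
chosen to exercise every code path at exhaustively checkable scales.

## Known limitations

* The CCT lower bound is conditional on donor/recipient divergence: a
  conversion tract through locally identical sequence is invisible, so
  "minimum length" is the correct and only claim.
* The 5' scan is implemented symmetrically but published 5' evidence is
  weak and homoplasy-prone; 5' bounds should be read with the homoplasy
  flags in hand.
* Polychotomy loss ranges assume the Dollo constraint (no regain under the
  single-gain model); a regain-permitting cost model is out of scope.
* The simulator's donor snapshot ignores events earlier on the donor's own
  path (exact at rate 0); schedules with converted donors should be
  composed accordingly.
* Canonical-tract length is quoted in the literature variously as 3–21 bp,
  20 bp or 21 bp depending on which diagnostic sites a lineage retains;
  bounds here are computed from sites, so no single constant is assumed.

## A worked example

```{r example}
fx <- make_fixtures("solanoideae9")
anc <- reconstruct_ancestor(fx$locus)
sites <- call_diagnostic_sites(fx$locus, anc, fx$focal_clade,
                               edit_sites = fx$edit_sites)
report <- cct_bounds(sites)
glance(report)
tidy(report) |> arrange(position)
```

The nine non-homoplastic sites (seven within the canonical 20-bp window,
including the +20 edit-site difference, plus +27 and +35) define a 3'
minimum tract of 35 bp; the two flagged sites (−11, +60) are reported but
excluded from the bound.
```{r retro}
retro <- make_fixtures("retro_loss")
anc2 <- reconstruct_ancestor(retro$locus)
retro_screen(retro$locus, anc2, retro$edit_sites)
```
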