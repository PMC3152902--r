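---
title: "Models and methods behind phylorecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylorecomb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorecomb)
```

`phylorecomb` quantifies homologous recombination among bacterial
phylogroups from grouped segment alignments. This vignette documents the
statistical models, the tunable parameters and their defaults, the numerical
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Input model

The unit of analysis is a `grouped_alignment`: one aligned chromosome
segment with one sequence per strain (equal lengths; residues `A/C/G/T/-/N`),
a phylogroup label per strain, an optional outgroup used only for tree
rooting, and a panel identifier. Segments sharing a panel share strain-pairing
opportunities. All interval coordinates in the package are 0-based,
half-open alignment columns; this makes interval arithmetic unambiguous and
matches BED conventions.

## Conversion detection

Detection asks, for every unordered pair of ingroup strains, whether the
pair agrees over an unusually long run of polymorphic sites.

**Polymorphic projection.** A column is polymorphic when at least two
distinct unambiguous residues (`A/C/G/T`) occur among ingroup strains; gaps
and `N` carry no state. Only these columns are informative for conversion.
For a given pair, sites where either strain is gapped or ambiguous are
skipped and removed from that pair's profile (with a retained map back to
alignment columns).

**Fragment score.** With k matches and m mismatches in a pair's profile,
each match scores +1 and each mismatch −B with

&nbsp;&nbsp;&nbsp;&nbsp;B = ⌈g·k/m⌉,

mismatches terminating fragments outright when `g = 0` or `m = 0`. The
default `gscale` g = 1 makes the expected per-site score drift non-positive
under column shuffling, so maximal segments are meaningful. All maximal
positive-scoring segments are extracted in the Ruzzo–Tompa sense (disjoint;
none extendable or subdividable to a higher score) by recursive best-segment
splitting, with deterministic tie-breaking: maximum score, then smallest
start, then smallest end. Maximality forces fragments to begin and end on
matches. This scoring scheme is our own faithful-in-spirit construction of
the classic gene-conversion run statistic; it is not claimed to be
bit-compatible with any particular external implementation.

**Permutation null.** Each of `n_permutations` replicates shuffles the
*order* of polymorphic columns once for the whole site matrix, preserving
within-column residues and hence the site-frequency spectrum — the standard
null for run-based conversion detection. Each pair's maximum run score is
recorded per replicate.

**Family-wise correction (a deliberate design choice).** Because B adapts to
each pair's own divergence, raw run scores are not comparable across pairs:
a nearly identical within-group pair (small m, large B) has a null maximum
that fluctuates over hundreds of score units, while a divergent between-group
pair's null maximum stays in the tens. Taking the plain maximum of raw
scores over pairs would let the low-divergence pairs dominate the null and
destroy power for exactly the between-group tracts of interest. The
correction therefore studentizes first (single-step max-T): each pair's null
maxima are centred and scaled by their own permutation mean and standard
deviation, and a fragment's

&nbsp;&nbsp;&nbsp;&nbsp;p_global = (1 + #{replicates whose largest
studentized per-pair maximum ≥ the fragment's studentized score}) /
(n_permutations + 1).

The `+1` pseudocount avoids p = 0 from finite replicates. Fragments with
p_global ≤ `alpha` (default 0.05) are reported; the full candidate table is
retained as an attribute. We also evaluated a rank-based min-p aggregation,
but its resolution floor of 1/(n_permutations + 1) is useless whenever the
permutation count is much below (number of pairs)/alpha; max-T behaves well
already at a few hundred replicates.

Defaults: `n_permutations = 10000` (conventional for permutation nulls of
this kind; the package's own experiments use 200–300, which is ample for a
0.05 family-wise gate under max-T), `alpha = 0.05`, `gscale = 1`. The
outgroup is excluded from both the polymorphism call and pair scanning, as
its only role is rooting trees.

**Degenerate inputs.** A segment without polymorphic sites yields an empty
fragment list with a message. A single permutation replicate that ties the
observed maximum gives p_global = 1.

## Masking

`mask_fragments()` replaces the residues of *both* strains of each fragment
over the fragment interval with the alignment gap `-`. Downstream
complete-deletion tree building then excludes those columns, removing the
converted signal from phylogenies. Masking both members is a deliberate
symmetric choice: the detector is direction-blind, and guessing a donor
would be arbitrary. Masking is idempotent and never changes alignment
length or the strain set.

## Tier enumeration

Fragments are tallied per `(segment, category)` cell, where a category is
`intra:G` or `inter:G1|G2` from the pair's group labels:

* **Tier 1** — every fragment is an independent event.
* **Tier 2** — fragments with identical `(start, end)` borders within the
  same segment and category collapse to one event, *regardless of which
  strains carry them*: identical borders across strain pairs are the
  signature of a single transfer into the recipient group before its
  lineages diverged. (The generator's ancestral events reproduce exactly
  this signature, and the tests verify the collapse.)
* **Tier 3** — at most one event per `(segment, category)` cell, because
  most fragments within a cell overlap at least partially.

Tier totals are monotone (tier 1 ≥ tier 2 ≥ tier 3) by construction, and
intra-group fragments are tiered by the same rules so that the inter/intra
comparison can run at any tier.

## The proportional-opportunity exchange test

Under the null, each inter-group strain pairing of a panel is equally likely
to be involved in a conversion, so for category c the expected count is

&nbsp;&nbsp;&nbsp;&nbsp;E_c = Σ_s T_s · n_c(s) / D_s,

with T_s the observed inter-group event total of segment s, n_c(s) the
category's pair count in s's panel, and D_s the panel's total inter-group
pairings. Observed and expected counts are summed over segments per category
(a stratified, CMH-like layout). The test statistic is the Pearson score
X² = Σ_c (O_c − E_c)²/E_c. Because group-pair tables of conversion counts
are mostly empty cells, no asymptotic chi-square reference is used: each
simulation reassigns every segment's T_s events to categories by a
multinomial draw with the segment's opportunity weights, sums across
segments, and recomputes X². The global p-value is the proportion of
simulated scores ≥ the observed score (so the smallest reportable value is
1/n_sims; no pseudocount, matching the plain-proportion definition).
Per-category one-sided tails `p_over`/`p_under` are the proportions of
simulations with a summed category count at least/at most the observed one;
they are reported uncorrected for the number of group pairs, and whether to
adjust them is left to the analyst.

Numerical notes: categories with E_c = 0 and O_c = 0 are skipped; E_c = 0
with O_c > 0 cannot contribute a finite Pearson term and is flagged instead.
A panel whose included categories have zero total pairings is a hard error.
Group exclusion (e.g. a group with too few strains to inform the test)
removes its categories and shrinks derived denominators accordingly;
explicitly supplied panel denominators are kept as given, since they exist
only to reproduce reported totals that cannot be derived from group sizes.

Default `n_sims = 1e6` at the pipeline level — the scale used for the
published analyses this package's layout follows — while the package's own
calibration and power experiments use 1e4 draws, where the Monte-Carlo error
of a 0.05-level tail is about 0.002.

## Inter- versus intra-group comparison

A two-cell chi-square with df = 1: with T = O_intra + O_inter,
E_intra = T·n_intra/(n_intra + n_inter), E_inter = T − E_intra, and
X² = Σ (O − E)²/E with an upper-tail chi-square p-value (reported as
two-tailed approximate). Two rounding modes exist because reported expected
counts in the literature this test reproduces are integers, and the printed
chi-squares are only recoverable when expectations are rounded to whole
counts *before* the statistic:

* `rounding = "integer"` (default): round half away from zero; reproduces
  the reference values X² = 1.415, 4.719, 6.786 from
  `ecoli_tier_counts()`.
* `rounding = "none"`: statistically preferable; gives 1.509, 4.342, 7.700
  on the same inputs, and is invariant to rescaling both opportunity totals.

A rounded expectation of zero is a hard error directing the user to the
unrounded mode. The bundled opportunity totals (258 intra, 772 inter) are
taken as given inputs of the reference collection; they are not derivable
from the package's own combinatorics without the original panel membership.

## Phylogenies and congruence

Distances are Kimura two-parameter,
d = −½·ln((1 − 2P − Q)·√(1 − 2Q)), computed over complete-deletion columns
(every column containing any gap or `N` in any strain removed — the retained
set is independent of strain order). Saturated pairs (log argument ≤ 0) are
a hard error by default; bootstrap replicates cap them instead (default cap
5 substitutions/site) so resampling noise cannot abort a run — silent
capping in the point estimate would distort the tree, which is why it is
opt-in there. Trees are neighbor-joining (the canonical Saitou–Nei
agglomeration via `ape::nj`) with taxa sorted lexicographically first so
ties break deterministically; rooting places the root at the midpoint of the
outgroup's pendant edge, as the placement along that edge is otherwise
arbitrary. Bootstrap support resamples complete-deletion columns with
replacement (study-scale default 1000 replicates).

Group topologies collapse every maximal monophyletic same-group clade to a
single leaf; groups failing monophyly are flagged paraphyletic and
contribute one leaf per maximal clade. Two topologies are *congruent* when
their canonical forms (children sorted recursively) are identical — for
matched leaf multisets this equals rooted-topology isomorphism, i.e.
Robinson–Foulds distance zero. This is a precise surrogate for the informal
"major branch points in identical relative positions" judgement made by eye
in the literature; congruence so defined is an equivalence relation, which
the tests verify. Comparing trees over different group multisets is an
error rather than incongruence, since the question is then ill-posed.
Externally built trees (Newick) can be supplied directly, so methods beyond
NJ can still be compared.

## The synthetic generator

`generate_panel()` emulates the targeted study design: 4 segments of
23 kb, five groups of four strains, and an outgroup, with per-site
independent substitutions and a configurable transition bias
(`ts_tv_ratio = 2`, i.e. two transition events per transversion event —
K2P-compatible, so distance estimates are checkable against configured
branch expectations). Divergence defaults are 0.02 per site on group-founder
branches and 0.002 on strain branches, giving clearly separated groups with
realistic within-group polymorphism, and the outgroup sits at 3× the founder
divergence — mimicking a genuinely deeper split without adding a free
parameter. The phylogeny is a star within and between groups: no nested
coalescent, which keeps the truth bookkeeping exact and suffices to create
the group-block polymorphism structure the detector consumes.

Planted events copy the donor-side sequence over a tract into the recipient:
`"ancestral"` timing copies into the recipient founder before strains are
derived, so every descendant inherits identical tract borders (the tier-2
duplicate mechanism); `"terminal"` timing copies into named strains
afterwards. The truth object records realized borders, donor strain,
carriers and per-segment polymorphic columns; `truth_to_fragments()` turns
it into the fragment rows a perfect detector would emit, so the tier and
exchange machinery can be tested independently of the detector.

What the generator does **not** emulate: indels, selection, codon structure,
rate heterogeneity, nested population structure, or mobile-element content.
Passing tests on synthetic panels therefore demonstrate the correctness and
calibration of the statistics under the stated model, not robustness to
every feature of real backbone alignments.

## Experiment sizes used by the tests and acceptance script

The package's validation experiments are sized to be decisive yet quick:
fragment extraction is checked against exhaustive enumeration on 1000 random
profiles; tier monotonicity on 1000 random fragment sets; exchange-test null
calibration on 300–500 null panels at 1e4 simulations (Kolmogorov–Smirnov
uniformity of p-values); power on 200 seeds with a 4×-enriched group pair;
planted-tract recovery on 40–100 default-configuration panels with a 2-kb
tract and 300 detector permutations; detector family-wise error on 30–40
null panels at 200 permutations. These sizes are the package's chosen
trade-off between Monte-Carlo resolution and turnaround; all are
reproducible from fixed seeds.

## Known limitations

* The detector's penalty and correction are principled reconstructions of a
  classic method's behaviour, not a byte-compatible reimplementation; exact
  fragment lists from other tools will differ in detail.
* Direction of transfer (donor vs recipient) is not inferred; categories are
  unordered group pairs.
* The multinomial exchange test conditions on per-segment totals; it does
  not model overdispersion across segments beyond stratification.
* Congruence classification requires rooted trees; unrooted inputs must be
  rooted (e.g. on an outgroup) first.
* With very small opportunity denominators, integer rounding of expecteds
  can be coarse; the unrounded mode is preferred for anything beyond
  reproducing reported tables.
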