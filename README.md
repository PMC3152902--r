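# phylorecomb

Detection and statistics of gene-conversion exchange among bacterial
phylogroups.

## The problem

The phylogroups of *Escherichia coli* (A, B1, B2, D, E) diverged long ago,
yet their chromosomal "backbone" still records homologous recombination:
tracts of DNA in one strain that were overwritten by the homologous sequence
of a strain from another lineage. Given aligned multi-kilobase backbone
segments from a panel of strains, three questions arise:

1. **Where are the converted tracts?** Between which strain pairs, and with
   what statistical support?
2. **Is between-group exchange random?** If every strain pairing were
   equally likely to exchange DNA, conversions between two groups would be
   proportional to the product of their strain counts. Do the observed
   group-pair counts fit that null?
3. **Is exchange more frequent within groups than between them?**

`phylorecomb` implements this analysis as a tested, reusable pipeline for
grouped alignments, together with segment-wise neighbor-joining phylogenies
(Kimura two-parameter distances, complete deletion, bootstrap) and a
group-level topology-congruence classifier, and a synthetic-panel generator
that plants conversion tracts with known truth so every stage can be
validated end to end.

## Methods at a glance

* **Detection** (`detect_fragments`) condenses each segment to its
  polymorphic sites and, for every pair of ingroup strains, extracts all
  maximal scoring runs of agreement (score +1 per matching site, −B per
  mismatch with B = ⌈g·k/m⌉ from the pair's own match/mismatch totals; the
  `gscale` g defaults to 1, and g = 0 forbids mismatches). Significance is
  assessed by shuffling the polymorphic-column order — one shared shuffle
  per replicate for the whole site matrix — and comparing each fragment's
  studentized score against the null distribution of the maximum studentized
  score over all pairs, which controls the family-wise error rate across
  pairs:
  `p_global = (1 + #{replicates ≥ observed}) / (n_permutations + 1)`.
* **Tier enumeration** (`tier1_events`, `tier2_events`, `tier3_events`)
  counts events at three stringencies: every fragment; fragments with
  identical borders within a segment and group-pair category merged (the
  signature of one ancestral transfer inherited by several descendants); at
  most one event per segment and category.
* **Exchange test** (`exchange_test`): expected counts
  `E_c = Σ_s T_s · n_c(s) / D_s` (events of segment s reallocated
  proportionally to category pair counts, summed over segments), Pearson
  score `X² = Σ_c (O_c − E_c)² / E_c`, and a Monte-Carlo p-value from
  multinomial reassignment of each segment's events (the study-scale default
  is 10⁶ simulated count sets), `p = P(X²_sim ≥ X²_obs)`, plus one-sided
  per-category tails.
* **Inter vs intra** (`inter_vs_intra`): two-cell chi-square (df = 1) with
  expectations proportional to the intra-/inter-group pairing opportunity
  totals; expecteds can be rounded to whole counts to reproduce reported
  integer tables, or left exact.

## Worked example

The package bundles the reference tier counts of a two-panel *E. coli*
collection (groups A, B1, B2, D; 258 intra-group and 772 inter-group
pairing opportunities):

```r
library(phylorecomb)
cnt <- ecoli_tier_counts()
opp <- attr(cnt, "opportunities")
inter_vs_intra(cnt$o_intra[1], cnt$o_inter[1], opp["intra"], opp["inter"])
#> Inter- vs intra-group exchange frequency (chi-square, df = 1)
#>   observed: intra = 40, inter = 95
#>   expected: intra = 34, inter = 101 (rounded)
#>   X^2 = 1.415, two-tailed P = 0.2342
```

Tiers 2 and 3 give X² = 4.719 (P = 0.03) and 6.786 (P = 0.009): the more
conservatively events are counted, the clearer the excess of within-group
over between-group exchange.

A full synthetic round trip:

```r
cfg <- generator_config(planted_events = list(
  planted_event(1, "A", "B2", 5000, 7000, timing = "terminal")))
pan <- generate_panel(cfg, seed = 42)
fr  <- detect_fragments(pan$alignments$seg1,
                        detector_config(n_permutations = 300, seed = 7))
fr[fr$strain1 == "A_1" & fr$strain2 == "B2_1", ]
#>   segment_id strain1 strain2 start  end psite_start psite_end score    p_global category
#> 1       seg1     A_1    B2_1  4988 7193         652       928   260 0.003322259 inter:A|B2
```

The planted 2-kb tract is recovered with borders within a few polymorphic
sites of the truth. `run_pipeline()` chains detection, tier counting, both
tests and (optionally) masked-alignment NJ trees with bootstrap and
congruence classification, writing every stage artifact plus a manifest;
fixed seeds give byte-identical reruns.

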