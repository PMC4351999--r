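---
title: "Virtual PCR and fingerprint statistics for B-ARISA primer evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual PCR and fingerprint statistics for B-ARISA primer evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barisa)
```

## The problem

Bacterial automated ribosomal intergenic spacer analysis (B-ARISA)
estimates community structure from the length heterogeneity of the
16S–23S intergenic spacer (IGS), which spans roughly 100–1500 bp across
bacteria. The assay sees only those organisms whose rDNA operons the
chosen primer pair can bind, so an assay-level question precedes any
ecological one: *what fraction of known bacterial diversity would a
given primer set amplify, and how much non-bacterial material
(chloroplast, mitochondrial, plant, fungal, invertebrate rDNA) would it
amplify by accident?* `barisa` answers both by virtual PCR against
taxonomy-annotated sequence databases, and quantifies the downstream
consequences at the fingerprint level.

Because public databases are moving targets, the package treats
databases as *inputs* (FASTA plus a record-to-lineage table) and ships a
generator that emulates their structure with exactly known ground truth.
Absolute coverage numbers from any particular database snapshot are a
property of that snapshot; what the package guarantees, and what its
tests pin down, is that the machinery measures them correctly.

## Primer matching model

Primers are degenerate oligonucleotides over the 15-letter IUPAC
alphabet, stored 5'→3'. A primer base matches a subject base iff the
nucleotide sets they encode intersect; both sides may be degenerate, so
an N on either side never counts as a mismatch. This is the permissive
convention of in-silico PCR tools; it is deliberately auditable — a
database full of Ns will inflate coverage, and the matching rule makes
that mechanism explicit rather than hidden.

Annealing is modelled as pure Hamming distance under this matching: no
indels, no thermodynamics, and no special weight for 3'-terminal
mismatches. Published mismatch-tolerance numbers for ARISA primers do
not state a positional weighting, so we use the uniform model and flag
the assumption here: a 3'-terminal mismatch suppresses extension far
more than an internal one in a real reaction, so virtual coverage at
budget *m* is an upper bound on what a thermocycler would deliver at
*m* mismatches.

The engine scans every window of primer length on both strands
(databases mix orientations), pairs each forward site with downstream
reverse-complemented reverse-primer sites, and keeps products whose full
length (footprints included) lies within configurable bounds — default
100–2000 bp, loose enough to contain the whole biological IGS range plus
primer footprints. Coordinates are 0-based half-open on the + strand;
the per-primer budget applies to each primer separately (not summed).
When a record yields several products, all are reported and the shortest
is flagged `primary`, since shorter templates win PCR competition; the
fingerprint simulator uses primary products only.

## Coverage and specificity semantics

A taxon counts as *amplified* when at least one member record yields at
least one in-bounds product — no quorum, matching how virtual-PCR
coverage tables are conventionally counted. Denominators are the taxa
represented in the database at each rank (taxa with ≥ 1 record, read
from the taxonomy table); records unassigned at a rank drop out of both
numerator and denominator at that rank. Two caveats follow, and both are
properties of the input rather than the statistic: entries that do not
span the IGS region deflate coverage, and homonymous labels under
different parents would inflate it — the package prevents the latter by
keying taxa on full lineage paths, and can do nothing about the former
except report denominators alongside percentages.

Budget sweeps are computed once at the largest budget and filtered
downward, which makes nesting (amplified sets at budget *m* ⊆ budget
*m*+1) hold by construction; the tests assert it anyway, as a guard on
the filtering logic.

## Fingerprint statistics

Fragment-length profiles are binned on a fixed grid anchored at the
range start (default 100–1500 bp, 2 bp windows — the conventional ARISA
resolution, giving ~700 possible OTUs). Bins are half-open, so a peak
exactly on a boundary goes to the upper bin; the anchoring must be fixed
for cross-run reproducibility and is therefore not configurable
per-sample. Peaks outside the range are dropped (capillary size
standards are unreliable at the extremes); binning conserves the total
abundance of in-range peaks.

Richness is the number of occupied bins. Shannon diversity uses natural
logarithms by default (nats; the base is an argument). Bray-Curtis uses
abundances (peak heights); Jaccard uses presence/absence — the two views
that community comparisons conventionally report side by side.

ANOSIM is implemented in the package because its inferential details
matter for reproducibility: Clarke's R with average ranks for ties,
`p = (1 + #{R_perm ≥ R_obs}) / (1 + n_perm)` (the add-one estimator,
which can never return 0), default 999 permutations, and a permutation
stream that is bit-reproducible under a caller-supplied seed without
disturbing the caller's RNG state. The tests check it three independent
ways: a hand-written brute-force rank implementation, exhaustive
enumeration of all label assignments on 4 samples (exact p), and
`vegan::anosim`. NMDS, by contrast, is a generic optimization with
nothing assay-specific in it, so it is delegated to `vegan::metaMDS`
(Kruskal stress-1, multiple seeded random starts) and wrapped with
`tidy()`/`glance()`/`autoplot()` accessors.

Between-assay agreement is summarized by Pearson correlation of
per-sample richness and Shannon values over matched samples, with
two-sided t-tests (df = n − 2). Two-sided is a choice — there is no
a-priori direction for "primer set A sees more than B" — and published
ARISA comparisons do not always state their test, so cross-study
p-value comparisons should rely on r and n rather than p.

## The synthetic-data generator

`generate_reference_db()` builds one operon-like record per species:

    [random 16S tail] [forward site] [spacer] ... [IGS core]
    ... [spacer] [reverse site, reverse-complemented] [random 23S head]

Binding sites are planted at *exact* mismatch counts: mutated positions
are chosen among non-N primer positions and replaced by a base outside
the primer's IUPAC set at that position, so the mismatch is guaranteed
rather than probable. Every record is then verified by exhaustive
scanning: each primer (and its reverse complement) must hit exactly its
planted window and nothing else within budget 3 on either strand; the
random segments are rejection-resampled until this holds. Ground truth
is therefore analytic — the rank × budget coverage table is computed
from the planted categories and the taxonomy alone, never by scanning —
and the pipeline's acceptance surface is exact equality against it.

Design choices worth recording:

- **Spacer lengths** default to sampling without replacement from the
  even integers in [100, 1500]. Non-spacer segment lengths are constant
  across records, so every record's product length is unique and lands
  in its own 2-bp bin: fingerprint richness comparisons become exact
  counting arguments instead of collision-probability arguments. A
  `"uniform"` mode (integer lengths, with replacement) is available when
  collisions are wanted.
- **Several assays, one database.** Sites for multiple primer sets are
  planted as nested slots in the same record, so coverage comparisons
  between assays share a single database. Site-free slots for "absent"
  species keep segment lengths constant. Mutually similar primer sets
  (e.g. the two long-IGS reverse primers, which share a CCCCATTC core)
  can make the no-spurious-site guarantee unsatisfiable; the generator
  then stops with an error rather than returning approximate truth.
- **Taxonomy** is a balanced hierarchy (default 5 phyla × 2 × 2 × 2 × 2
  = 80 genera) with species assigned to genera cycling across phyla, so
  even small databases span the whole hierarchy. Labels are globally
  unique; the coverage code nonetheless keys on full paths because real
  taxonomies contain homonyms.
- **Non-target databases** (`generate_nontarget_db()`) invert the
  guarantee: a clean species is verified to carry *no* site within
  budget 3 for any supplied assay, and a chosen fraction carries planted
  sites — emulating the handful of plant or algal species a bacterial
  assay can amplify. Their taxonomies use organelle/plant/fungal/
  invertebrate phylum names, a disjoint namespace from the bacterial
  generator's labels.
- **Communities** (`generate_community_profiles()`) are two groups of
  five samples by default — the scale of a typical fingerprinting
  contrast, e.g. fertilized vs unfertilized soil. Each OTU gets one
  fragment length in [100, 1500] (to 0.1 bp, as capillary sizing
  reports) and a log-normal baseline intensity (meanlog 4, sdlog 1 —
  a realistically skewed abundance distribution); samples multiply this
  by a group effect `exp(effect × δ_otu × ±1)` on a fixed per-OTU
  direction, log-normal noise (sd 0.3), and a 10% per-sample dropout
  that makes OTU supports vary between samples the way real
  fingerprints do. With `effect_size = 0` and a fully shared pool the
  groups are exchangeable (ANOSIM R centres on 0); with
  `shared_fraction = 0` the supports are disjoint (Jaccard R = 1
  exactly). All randomness derives from one master seed via named
  per-stage substreams, so every fixture is reproducible byte for byte.

`simulate_fingerprint_from_db()` closes the loop: a community (record
abundances) fingerprinted through an amplification result contributes
one peak per amplified member at its primary product length, and
nothing for members the assay misses. Primer bias thus propagates into
fingerprints as exact, countable dropout — the tests verify that the
richness deficit between a full-coverage and a 60%-coverage assay
equals the planted dropout count sample by sample.

## What the synthetic tests do and do not show

Passing exact-recovery tests shows the measurement machinery is correct:
site finding agrees with an independent scanner, coverage counting
agrees with analytic truth, the statistics match their closed forms and
independent implementations. It does not show that any particular
primer set covers any particular real database well — real records
carry phylogenetically correlated sequence (the generator's flanks are
i.i.d. random), incomplete and erroneous taxonomy annotations, entries
that miss the IGS region entirely, and orientation/quality quirks. The
generator also omits chimeras, sequencing error and amplification
efficiency differences (Non-goals of the virtual PCR model). Results on
real databases inherit those biases; the package's role is to make the
measurement itself trustworthy and the caveats visible.

## Numerical and scale choices

Tolerances in the test suite are exact (`identical`/integer equality)
wherever ground truth is analytic; floating-point closed forms
(uniform-profile Shannon = ln n) are checked to 1e-12; Monte-Carlo
checks (null-centred ANOSIM over 100 generator seeds, permutation p vs
exhaustive p) use bands an order of magnitude wider than the observed
spread. Problem sizes — 1000 random sequences for the oracle
equivalence check, 200 species for coverage recovery, 100-species
non-target screens, 100 null-simulation seeds, six-sample communities
over 80–120-species databases — were chosen so the full suite and the
acceptance script each complete in about a minute on a single CPU while
still exercising every code path at sizes where counting errors cannot
hide. Degenerate inputs are errors, not silent results: empty
databases, all-zero abundance vectors, groups of one sample, taxonomies
with gaps in the rank prefix, and amplified records missing from the
taxonomy all stop with informative messages.
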