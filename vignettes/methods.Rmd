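---
title: "Pre-miRNA discovery and target prediction: models and design choices"
author: "mirkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-miRNA discovery and target prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkit)
```

# The problem

Non-model organisms often have no assembled genome and no curated miRNA
annotation. What they can have cheaply is (i) fragmentary genomic
contigs and (ii) deep small-RNA sequencing. `mirkit` turns those two
inputs into pre-miRNA calls, and a set of 3'UTR sequences into miRNA
target predictions, using only explicit, programmatic criteria. Every
stage can be exercised against seeded synthetic data with a recorded
ground truth, so each claim the package makes about itself is testable.

# The thermodynamic core

## Energy model

Hairpin folding and duplex hybridization share one simplified
nearest-neighbour model, shipped as a readable key-value file
(`system.file("extdata", "energy_model.txt", package = "mirkit")`):

* a symmetric stacking table over the six permitted pair types
  (Watson-Crick plus G:U wobble at reduced stability), with magnitudes
  in the familiar 37 °C range (GC/GC steps near −3.3 kcal/mol, AU/AU
  near −1.1, wobble steps −0.5 to −2.1);
* linear loop penalties: hairpin loop `5.4 + 0.15·(n−3)`, bulge
  `6.0 + 0.8·n`, internal loop `6.5 + 0.8·(n1+n2)` kcal/mol;
* structural limits: terminal loop ≥ 3 nt, at most 15 unpaired bases
  per helix interruption.

The stacking magnitudes are thermodynamically conventional. The
interruption penalties are deliberately placed at the punitive end of
the plausible range: the model's job here is not ensemble
thermodynamics but *discrimination* — a pre-miRNA's signature is one
long, clean stem, so the scan should behave like an inverted-repeat
finder. With cheap interruption penalties, random 120-nt windows
assemble gappy multi-helix "stems" that pass any reasonable energy
threshold by the hundreds per 100 kb; with the shipped penalties the
background rate measured on i.i.d. random sequence is below one
candidate per 10 kb per strand, while perfect planted stems pass the
−15 kcal/mol threshold with more than a three-fold margin. All values
are configurable; every statement the test suite makes is relative to
the shipped table.

## Folding and duplexes

`fold_hairpin()` returns the minimum-energy *single-stem* structure
(one helix with bulges/internal loops, one terminal loop, free ends) by
dynamic programming; multiloops and pseudoknots are out of scope by
design, since candidate precursors are single stem-loops by definition.
Equal-energy ties resolve to the 5'-most, then longest, helix, making
results bit-reproducible. `duplex_mfe()` is the intermolecular
analogue: no intramolecular pairs, zero initiation term, same
interruption limits. Both are validated in the test suite against
exhaustive enumeration of all legal structures on short sequences
(`enumerate_structures()` and a recursion-based pairing enumerator),
and every reported energy is re-derivable by adding table entries along
the reported structure string (`structure_energy()`, `duplex_energy()`).

`scan_hairpins()` applies the folding recursion as a banded dynamic
program across a whole contig, scoring every closing pair with span
between the length bounds (default 60–120 nt) on both strands — an
exhaustive version of sliding fixed-step windows, with the same
survivors after overlap collapse. Thresholds (stem ≥ 18 bp, ΔG ≤ −15
kcal/mol, loop ≤ 20 nt) are explicit stand-ins for the unpublished
internal settings of classical hairpin-extraction tools, and are all
configurable. A Watson–Crick-perfect stem-loop is its own reverse
complement, so identical-energy mirror hits are reported once (plus
strand); the true strand is decided later by read evidence.

# Homology and contaminant rules

The homology criterion used for catalogue mapping, redundancy merging
and the ncRNA blacklist is one rule applied everywhere: optimal local
alignment under match +1 / mismatch −2 / linear gap −3, accepted when
identity over aligned columns is ≥ 0.80 **and** the aligned span covers
≥ 0.50 of the query — the computable reading of "80% similarity in
half of the length" with mismatch/indel costs of 2 and 3. Query length
is used for the coverage denominator (the catalogue hairpin or the
candidate being vetted — the molecule whose identity is in question).
Sequence-redundancy checks run in both orientations, because a
near-palindromic hairpin reported on both strands of one locus is one
precursor.

Tandem-repeat removal scans periods 1–10 at every phase, tolerating one
mismatch per copy for units of ≥ 3 nt (shorter units must repeat
exactly, otherwise a single tolerated mismatch makes any sequence a
period-1 "array"); an array is disqualifying when it has ≥ 3 copies
covering ≥ 60% of the candidate. These thresholds have no published
counterpart and are deliberately conservative defaults.

# Read evidence and classification

Reads are placed on candidate precursors end-to-end, sense strand only,
best (fewest-mismatch, then leftmost) site, up to one mismatch. The
*block* criterion quantifies "block-like alignment outside the loop":
on each arm, the modal read 5' start is found and the block fraction is
the share of that arm's reads starting within ±2 nt of the mode. A
block passes with fraction ≥ 0.5, at least 10 reads, and no overlap
with the terminal loop. The ±2-nt window reflects Drosha/Dicer
processing precision; all three knobs are configurable. The denominator
is arm-restricted so that a precursor expressing both mature and star
strands (roughly a 50/50 split) can pass on both arms.

Classification is then rule-based: an accepted catalogue hit plus a
passing block gives `known`; a passing block without a hit gives
`novel`; anything else is `rejected` — including homology-only
candidates without read support. When both arms carry blocks, the two
block intervals are checked for the canonical ~2-nt 3' overhangs
(tolerance ±1 nt) through the fold's pair map. Candidate strand is
resolved by read evidence: if the reverse-complemented candidate
attracts more reads, the flipped orientation is classified. Note that
a 2-nt overhang physically requires flanking sequence beyond the stem;
on a flankless perfect stem the star check cannot succeed.

# Target prediction

Two engines run independently over every (miRNA, UTR) pair:

* **Hybridization engine** (`hybrid_scan`): all non-overlapping
  local-minimum duplexes are computed; each site's energy is
  normalised as ΔG/ln(L), L the UTR length, and converted to a p-value
  under a per-miRNA extreme-value null. The null is calibrated
  (`calibrate_evd`) by folding the miRNA against composition-matched
  random sequences: a first-order Markov chain fitted to the UTR set's
  dinucleotide profile, with lengths drawn from a normal distribution
  with the set's mean and standard deviation (5000 sequences by
  default). A Gumbel distribution is fitted to the negated normalised
  best-site energies by maximum likelihood. The test suite verifies
  that p-values of *fresh* nulls are uniform (Kolmogorov–Smirnov at
  α = 0.01) — the property that makes the p-values meaningful.
* **Complementarity engine** (`complementarity_scan`): an affine-gap
  Smith–Waterman of the miRNA (in pairing register) against the UTR
  with +5 per Watson–Crick pair, +1 per G:U, −3 per mismatch, gaps
  −8/−2, seed positions 2–8 doubled; sites require score ≥ 80 and a
  hybridization energy co-filter of ≤ −14 kcal/mol. The constants are
  stated defaults in the spirit of classical complementarity-scoring
  tools, not reproductions of any specific program's output.

No seed-pairing constraint is imposed by default (a flag exists),
since non-canonical sites are deliberately kept in scope. Consensus
targets (`consensus`) are one-to-one pairings of hybrid and
complementarity sites for the same (miRNA, UTR) overlapping by ≥ 1 nt;
the overlap rule is a design choice where only "shared similar target
sites" is stated in the literature this mirrors. Consensus can only
shrink the hit set, which is the stringency argument made testable.
Optional Benjamini–Hochberg correction across sites is available and
off by default. Cross-species conservation reports, for each (miRNA,
ortholog group), the species set carrying a consensus site (conserved
when ≥ 2). The UTR-length/site-count relation uses Spearman rank
correlation with a permutation p-value, enumerated exactly whenever
n! fits in the permutation budget (so n = 6 is exact) and sampled
(seeded) otherwise; the test is two-sided on |ρ|.

# The synthetic-data generators

`plant_hairpins()` embeds perfect (optionally mutated) stem-loops at
non-overlapping loci in an i.i.d. random "genome", on random strands.
`simulate_read_stack()` draws ~22-nt reads (lengths uniform 20–24)
whose 5' starts jitter normally around the arm's Dicer site — for the
3p arm, the position implied by the 2-nt overhang geometry — plus a
uniform noise fraction. `plant_target_sites()` embeds perfect,
seed-only, or mismatched reverse-complement sites in random (or
profile-matched Markov) UTRs. All generators are bit-reproducible under
their seeds and return truth tables; every recovery statement in the
tests is computed against those tables only.

What the generators emulate — and what they do not: planted stems are
cleaner than real precursors (real stems carry conserved bulges);
read stacks have no sequencing-error model, no isomiR length ladder
beyond the uniform 20–24, and no colorspace artefacts; UTR backgrounds
carry no repeats or composition gradients. Passing recovery tests
therefore demonstrates correctness of the criteria, not expected
sensitivity on real libraries.

The end-to-end demo (`simulate_dataset()`) fixes one realistic
condition set, chosen once: 8 planted hairpins in 30 kb, 5%
stem divergence (a cross-species conservation scale), a catalogue
containing mutated copies of half the hairpins (so half classify
`known`, half `novel`), three hairpin-shaped blacklist decoys planted
in the contig, read depth 50 with 1-nt jitter and 5% noise, and eight
UTRs with planted sites. The demo's calibration size is 500 to keep a
laptop run short; the package default remains 5000.

# Numerical choices and degenerate inputs

* Ties in folding resolve 5'-most-then-longest; ties in modal-start
  selection resolve leftmost; merge grouping sorts candidates by a
  canonical key before union-find, so merging is order-independent.
* `N` never pairs, never matches in alignments (not even `N` vs `N`),
  and candidates with > 10% `N` are not folded.
* A degenerate calibration (all best-site energies equal, e.g. an
  unpairable miRNA) aborts rather than fitting a zero-scale Gumbel;
  fewer than 100 null sequences is an error.
* Zero variance in either variable makes Spearman's ρ undefined and is
  an error, as is an all-zero count vector in `relative_frequency()`.
* Problem sizes used by the test suite — 100 kb genomes with 20
  planted hairpins, 5000-sequence calibrations, 200-replicate block
  simulations — were chosen as the smallest sizes at which the
  measured rates stabilise.

# Known limitations

* Single-stem folding cannot represent branched precursors (rare
  mirtrons, clustered hairpins fold one stem at a time).
* The homology rule is alignment-identity based; it will not recognise
  structurally conserved but sequence-diverged precursors.
* Energy parameters are a simplified model: reported ΔG values are
  internally consistent and useful for ranking and thresholds, but are
  not comparable to full nearest-neighbour implementations, and no
  attempt is made to reproduce any external folding engine's numbers —
  only sign and ordering behaviour are relied upon.
* p-value calibration is per-miRNA and composition-matched, but
  assumes UTR-like base composition; heavily repetitive targets would
  need a repeat-aware null.
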