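---
title: "Methods: dissecting great ape subterminal heterochromatic caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting great ape subterminal heterochromatic caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtercap)
```

## The biological setting

Chimpanzee, bonobo and gorilla chromosomes carry multi-megabase
subterminal heterochromatic caps that human chromosomes lack. A cap is a
higher-order mosaic of two elements: long tandem arrays of the 32-bp
pCht satellite monomer (arrays range from under 10 kbp to hundreds of
kbp, with species means in the 341–398 kbp range), interdigitated with
~32–34 kbp segmental-duplication (SD) "spacers" that descend from single
euchromatic source loci and are strongly hypomethylated relative to the
satellite arrays (roughly 74–83% CpG methylation in arrays versus 39–50%
in spacers). Allelic caps are unusually divergent (9–11%), while some
caps on *non-homologous* chromosomes are nearly identical — the
signature of ectopic (non-allelic) exchange, apparently mediated by the
spacers. `subtercap` implements the analytical pipeline for these
observations: satellite decomposition, higher-order block typing, spacer
phylogenetics with clock calibration, exchange detection with breakpoint
statistics, and euchromatin-boundary profiling.

## The synthetic cap model

Everything in the package is testable against planted truth because the
first-class simulator (`simulate_cap_set()` and friends) generates caps
under the organisation described above:

* a cap is `n_arrays` satellite arrays alternating with `n_arrays - 1`
  spacer copies; array lengths are log-normal (right-skewed, like the
  observed distribution) with default mean 370 kbp and sd 250 kbp;
* each satellite unit is an independently mutated copy of the 32-bp
  consensus at `unit_mutation_rate` events per base per copy (default
  0.02, consistent with units being generally >80% identical to the
  consensus); 10% of unit mutation events are 1-bp indels, matching the
  observed variant classes (substitutions, small insertions,
  deletions). The indel:substitution ratio is not constrained by
  observation; 10% is an exposed configuration default;
* spacers are substitution-only mutated copies of one ~32 kbp template
  (34 kbp suits a gorilla-like set) at `spacer_divergence` per site — a
  deliberate simplification that keeps spacer copies colinear;
* CpG methylation is truncated-normal around region-level means
  (defaults 0.833 for satellite, 0.40 for spacers — gorilla-like);
  only the means are observationally constrained, the noise law is a
  modelling choice;
* `plant_exchange()` replaces an acceptor cap segment by a verbatim (or
  slightly diverged) donor copy with both endpoints anchored at spacer
  midpoints, recording breakpoints in the truth table;
* `simulate_spacer_evolution()` evolves sequences along an ultrametric
  time tree under an exact Jukes–Cantor embedding: on a branch of
  length $t$ each site is redrawn uniformly with probability
  $1 - e^{-4\mu t/3}$, so two tips with TMRCA $T$ have expected
  p-distance $\tfrac34(1 - e^{-8\mu T/3})$.

What the simulator does *not* emulate: satellite homogenisation and
concerted evolution, gene conversion tracts, spacer indel evolution,
assembly errors, and read-level artefacts. Passing recovery tests on
these caps therefore demonstrates algorithmic correctness under the
stated organisation, not robustness to every property of real
assemblies.

Two catalog-level generators (`simulate_variant_catalog()`,
`simulate_block_windows()`) plant co-occurrence groups and window
archetypes directly at the count level, so the clustering stages can be
tested at scale without sequence-level simulation.

## Satellite decomposition

`scan_units()` finds a maximal non-overlapping set of approximate
matches of the monomer on both strands. Candidates come from an
edit-distance scan (`Biostrings::matchPattern` with indels); each
candidate is realigned globally to the consensus and kept when its span
exceeds `floor(0.9 × 32) = 28` bp and its identity (matches over aligned
columns, gaps included) is at least 0.8. Selection is greedy by
descending alignment score, ties broken by leftmost start then plus
strand. The 0.8 identity floor reflects the observation that units are
generally more than 80% identical to the consensus; the >28 bp retention
rule is the published screen. Units are reported in the consensus frame
as found; no rotational re-phasing is attempted.

`classify_variants()` assigns one id per distinct unit string (ids
ordered by global abundance, ties lexicographic); `merge_arrays()`
joins consecutive units while gaps are ≤ 1 kbp; `call_spacers()`
complements the arrays within the cap extent and reports gaps ≥ 5 kbp.
The 1 kbp and 5 kbp values are configuration knobs with no published
counterpart; they sit an order of magnitude from both the unit scale
(32 bp) and the spacer scale (32 kbp), so results are insensitive to
them on well-formed caps. `derive_consensus()` projects units onto the
consensus coordinate frame and takes column-wise majority bases;
profile columns are normalised over observed A/C/G/T counts (ties broken
by base order, deterministic).

## Composition matrix and two-step k-means

The cap × variant composition matrix uses the published screens: caps
with at least 2,000 units, variants with global count strictly above
100, and cells equal to variant count divided by *all* units in the cap
(the denominator includes units of filtered-out variants; whether the
source analysis included them is not stated — this reading is the
natural one and is fixed here). Hierarchical clustering uses
1 − Pearson correlation with average linkage; cluster support is a
plain bootstrap proportion over column-resampled matrices.
Multiscale-bootstrap AU values are intentionally not reproduced — the
downstream use is only a ">95" support flag, for which plain
proportions suffice. Bootstrap resamples in which some cap loses all
composition variance define no dendrogram and are excluded from the
support denominator.

Step one of the block typing clusters variants by their normalised
profile across caps (each variant's counts divided by its global
count); step two tiles caps into 20 kbp windows, describes each window
by the fraction of its units in each variant cluster, and clusters the
windows. Both steps use k-means with k-means++ seeding, 10 restarts, a
fixed seed, and the mean Euclidean silhouette to choose k over 2–12.
Windows with no units are labelled `unassigned` and excluded rather
than zero-filled (a zero vector is not a composition). Block labels
k1..kK are ordered by decreasing genome-wide abundance so labels are
reproducible. When the best silhouette is ≤ 0.1 the pipeline warns
that there is no co-occurrence structure.

## Spacer phylogenetics

Distance-based inference replaces maximum-likelihood tree building by
design: neighbor-joining on Jukes–Cantor distances (pairwise deletion
of gap/N sites; negative branch estimates clamped to zero) is
dependency-free, exactly testable (NJ reconstructs additive matrices
exactly), and adequate for the statistics built on the trees (RF
comparisons and clock calibration). Externally computed trees can be
supplied as Newick wherever a tree is consumed, so ML trees remain
usable. Bootstrap replicates resample alignment columns; the
majority-rule consensus carries bipartition frequencies as supports.
Robinson–Foulds distances are computed from canonical non-trivial
bipartition sets.

`calibrate_tree()` roots on the outgroup and computes a *balanced*
node height: the mean over the node's children of (edge length + child
height), so each child subtree contributes equally regardless of tip
count. Under a clock every child side estimates the same age, and this
keeps an outgroup's long basal branch from biasing the root height (the
naive pooled tip mean does exactly that on outgroup-rooted trees). A
single substitution rate is then fitted by least squares through the
origin over the calibrated nodes (height ≈ rate × age), node ages are
height/rate, tips sit at age zero, and confidence intervals are
2.5/97.5 percentiles of replicate ages with nodes matched across
replicates by descendant tip set. This percentile CI is an
approximation to likelihood-based dating intervals; coverage on clock
simulations (50 replicates, 10 kbp alignments, calibrations at 15.2 and
19.5 MY, checks at 5.1 and 7.5 MY) is ≥ 90% in the test suite.

## Exchange detection

`anchor_chain_align()` is a desk-scale aligner aimed at the regime
exchange detection actually needs: candidate events are ≥99.5%
identical, where exact 51-mers are dense. Anchors are exact k-mers
sampled every 50 bp *from both sequences* (making the output symmetric
under swapping the pair), with k-mers hitting the partner more than 10
times discarded — this removes consensus-pure satellite k-mers, which
would otherwise anchor everywhere in a tandem landscape. Anchors are
chained per exact diagonal; the sequence between consecutive exact
segments is compared directly when equal-length, aligned globally when
short and unequal, and the chain is split where the gap comparison
falls below 0.7 identity (a gap that far below the homologous regime is
not alignable; bridging it would only dilute the block identity).
Identity is matches over aligned columns including gap columns —
slightly more conservative than gap-compressed identity, by under 0.5%
at the identities of interest; both conventions are reported through
the matches/columns fields.

`detect_exchange_candidates()` merges diagonal-consistent blocks (gap ≤
50 kbp, diagonal offset ≤ 2 kbp) and keeps merged blocks with identity
≥ 0.995 over ≥ 1 Mbp (both thresholds are the published screen;
synthetic tests scale `min_len` down with their caps). Breakpoints are
refined by walking outward from the candidate interior in 2 kbp windows
along the block diagonal until the windowed identity stays below 0.99
for three consecutive windows; the reported uncertainty is the window
size. On planted exchanges, chain edges land within ~200 bp of the true
breakpoints and refinement keeps them inside ±2 kbp.

Whether breakpoint-to-spacer distance should be edge- or
midpoint-measured is not documented; edge distance is used (0 inside a
spacer).

## Resampling statistics

All four tests use the add-one empirical p,
$p = (1 + \#\{\text{null at least as extreme}\})/(n_{\text{perm}}+1)$,
which can never return zero and is exactly uniform on its support under
an exchangeable null — a deliberate correction of the plain
"fraction more extreme" rule.

* **Breakpoint proximity**: observed statistic is the mean
  nearest-spacer distance; null replicates redraw each breakpoint
  uniformly *within its own cap* (preserving cap assignment is the
  conservative reading of "shuffling the breakpoints"). A one-sided
  Wilcoxon rank-sum comparison of the observed distances against the
  pooled null distances is reported alongside, since both statistics
  appear in the source analyses and which was primary is ambiguous.
* **Topology shift**: the alignment is split into two halves; each
  half's NJ tree is compared (RF) to the majority consensus of
  replicate trees of the full alignment, against the null of
  replicate-to-consensus RF distances. The published description says
  "bootstrap trees" without fixing the resample size; here the null
  replicates draw ⌈L/2⌉ columns *without replacement* from the full
  alignment — exactly the sampling process that produces a half
  alignment under a homogeneous null — so observed and null statistics
  are exchangeable and the p-value is calibrated. (A full-length
  bootstrap null is available via `null = "full_bootstrap"`; its
  replicates are centred on their own consensus differently from the
  half trees, which skews p conservative or anti-conservative depending
  on signal strength.) Because RF is a coarse discrete statistic, ties
  make the p slightly conservative; calibration scenarios for
  uniformity checks therefore use enough taxa (36) that RF takes many
  values. An all-identical alignment has no phylogenetic signal and is
  refused.
* **Group identity**: two-sided permutation test on the difference of
  group means (allelic vs non-allelic identities).
* **Feature enrichment**: features are repositioned uniformly on their
  own chromosome with length preserved; the fold change is density in
  targets over genome-wide density, and the p is one-sided "greater".
  Count and bp statistics are both available; the bp statistic has a
  finer support and is the one used in calibration studies.

## Euchromatin boundaries

Boundary regions are the 2 Mbp immediately proximal to a cap (distal
tip for capless arms), clamped to the chromosome, anchored at the last
proximal satellite unit. Profiles are always read
heterochromatin→euchromatin so p- and q-arm regions superimpose; the
10 kbp profile bin is a plotting choice with no published counterpart.
Insertions are unaligned query gaps ≥ 50 bp between syntenic alignment
blocks whose reference-side gap is below 50 bp, optionally classified
by best secondary hit (same chromosome / nonhomologous / unplaced).

## Problem sizes and numerical choices

The test and acceptance workloads are scaled to desk size as the
package's own study design: annotation runs on ~150 kbp caps
(~4,500 units), exchange detection on twenty ~110 kbp cap pairs with
~60 kbp planted events (`min_len` 40 kbp), clock calibration on 50
replicates of 10 kbp five-taxon alignments, topology-shift calibration
on 36-taxon, 1.5 kbp alignments with 100 replicates, and power studies
at the published operating points (11 breakpoints; 15 kbp spacer halves
at ~2% divergence). Headline full-scale numbers (584 Mbp of gorilla
caps, 167 caps, 11 real candidate events, 8 higher-order blocks on real
assemblies) require the T2T assemblies and are out of scope.

Other numerical conventions: all coordinates are 0-based half-open
(BED); every stochastic function takes an integer seed and restores the
caller's RNG state; k-means ties are resolved by the best of 10
restarts under the seeded RNG; consensus ties take the earlier base in
A,C,G,T order; hierarchical-clustering supports are percentages of
valid bootstrap replicates.

## Known limitations

* The anchor aligner targets high-identity colinear homology; it is not
  a general-purpose aligner and will fragment highly divergent or
  heavily rearranged regions (by design — such regions are below the
  exchange screen anyway).
* NJ+JC underestimates deep divergences relative to richer substitution
  models; calibration inherits that bias at large distances.
* The bootstrap-percentile age CI is approximate; it is validated by
  simulation coverage, not theory.
* Spacer evolution is substitution-only in the simulator, so planted
  exchanges are colinear; real events with indels would widen
  breakpoint uncertainty toward the refinement window size.

## A minimal worked example

```{r example, eval = FALSE}
cfg <- cap_config(n_arrays = 6, array_len_mean = 25000,
                  array_len_sd = 8000, spacer_len = 6000,
                  cap_count = 2, seed = 11)
cs <- plant_exchange(simulate_cap_set(cfg), "cap01", "cap02",
                     spacer_from = 2, spacer_to = 4)
blocks <- anchor_chain_align(cs$caps["cap02"], cs$caps["cap01"])
detect_exchange_candidates(blocks, cs$caps[["cap02"]], cs$caps[["cap01"]],
                           spacers = cs$truth$spacers, min_len = 50000)
```
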