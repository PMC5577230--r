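---
title: "Methods: OTU clustering, biosynthetic-gene screening and restriction fingerprinting of actinobacterial collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OTU clustering, biosynthetic-gene screening and restriction fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinoprint)
```

## What this package computes

Culture-based bioprospecting studies of Actinobacteria typically combine
four computational strands, and `actinoprint` implements all of them as one
seeded, testable pipeline:

1. **Taxonomic dereplication and diversity.** Isolates are compared by
   pairwise 16S rRNA gene identity and grouped into operational taxonomic
   units (OTUs) at fixed identity thresholds (100%, 99%, 98%). The 100%
   partition identifies duplicate isolates; lower thresholds approximate
   species- and genus-level richness. Distance-based neighbor-joining (NJ)
   trees with column-bootstrap support summarize phylogenetic structure.
2. **Biosynthetic-potential screening.** Degenerate PCR primers targeting
   the adenylation domain of nonribosomal peptide synthetases (NRPS,
   480 bp product) and the ketosynthase-alpha domain of type II polyketide
   synthases (PKS-II, 350 bp product) are applied *in silico*: a locus is
   called present when a primer pair yields an amplicon of the right size.
3. **Amplified-fragment restriction fingerprinting.** Amplicons are
   digested with the 4-bp cutters AluI (AG^CT) and HaeIII (GG^CC); a gel /
   densitometry model converts fragment lists into banding patterns, bands
   above 5% of the whole-lane area are scored into a binary matrix, and
   isolates are grouped by Jaccard similarity with UPGMA at a 0.93
   similarity cut.
4. **Bioactivity correlation.** Antibacterial screening calls against a
   five-strain panel are cross-tabulated with gene presence (both loci /
   exactly one / neither) and exported as a tripartite isolate–locus–strain
   network.

A synthetic-community generator stands in for a real isolate collection, so
every stage is exercisable and testable without any external data.

## The synthetic community generator

`generate_community()` draws a collection of isolates from a
`community_config()`. It is the reference input for all tests, so its
assumptions are worth stating precisely.

* **Genus structure.** Each genus has a 16S template; templates radiate
  from a common ancestor with 5% substitutions per lineage
  (`make_genus_templates()`), i.e. roughly 9% pairwise divergence — far
  beyond the species-level thresholds, so genera form well-separated
  sequence clusters. Genus sample sizes follow largest-remainder
  apportionment of the configured proportions (ties by configuration
  order), which reproduces exact counts such as 41/8/8/5/2/1/1 for the
  default 66-isolate, seven-genus collection.
* **Within-genus variation.** `divergence_within_genus` is the *expected
  pairwise* divergence between two members of a genus; each isolate is
  mutated from its genus template at half that rate, independently per
  site, uniformly over the three alternative bases, with no indels. This
  keeps expected identity analytically simple (two members differ at
  ~`d` of sites) while remaining a binomial, not deterministic, process.
  The default 0.01 places within-genus pairs near the species boundary so
  the 1.00/0.99/0.98 threshold ladder produces a decreasing OTU series.
* **Marker loci.** A gene-positive isolate carries a marker template built
  by `plant_marker_locus()`: random flanks, a concrete realization of each
  degenerate primer (one base sampled uniformly per IUPAC code, so a
  perfect-match binding site is guaranteed), and a random insert sized so
  the amplicon hits the locus's expected product size exactly.
* **Prevalence and activity.** Per-genus gene prevalences default to a
  flat NRPS rate of 0.68 and PKS-II rates of 0.5–0.6 restricted to the
  four genera where the locus occurs (zero in *Glycomyces*,
  *Micromonospora*, *Nocardia*), approximating overall rates of ~68% and
  ~45–50%. Activity is drawn conditionally on gene carriage
  (`P(active) = 0.50 / 0.27 / 0.42` for both / one / neither locus —
  fractions observed in collections of this kind), and an active isolate
  hits each test strain independently with a Gram-positive-biased profile
  (at least one hit guaranteed). These are calibration choices of this
  package, not measurements: per-genus prevalence splits and
  strain-specific hit rates are rarely published.
* **Reproducibility.** One master seed; every isolate consumes its own
  counter-derived RNG stream, so communities are byte-identical across
  runs and early isolates do not change when the community grows.

What the generator deliberately does **not** emulate: chimeras, sequencing
error, rRNA operon copy variation, indels (available only as an explicit
divergence-model extension), primer–template thermodynamics, or partial
gel digestion. Tests passing on synthetic communities therefore
demonstrate the correctness of the computational pipeline under its stated
model, not robustness to those real-data artifacts.

## Pairwise identity and OTU clustering

`pairwise_identity()` computes a Needleman–Wunsch global alignment
(defaults: match +1, mismatch −1, gap opening 2, gap extension 0.5) with
end gaps penalized, then reports matched columns / alignment columns after
removing columns that fall in a terminal gap run of either sequence.
Penalizing end gaps during alignment while excluding them from the
denominator afterwards gives the two properties practitioners expect:
a sequence wholly contained in a longer one scores 1.0, and equal-length
diverged sequences are not "rescued" by staggered terminal gaps. Positions
whose IUPAC sets intersect count as matches; internal gap columns count as
mismatches. Because co-optimal alignments may differ between argument
orders, the pair is canonically ordered before alignment, making the
function exactly symmetric.

`cluster_otus()` applies complete-linkage agglomerative clustering on
`1 − identity` and cuts so that *every within-cluster pair* meets the
threshold. Complete linkage is the only standard linkage for which that
partition invariant holds, which is why it is the default; a
greedy-centroid variant was considered and rejected because it yields
order-dependent partitions. The cut height includes an epsilon of 1e-9 so
pairs at exactly the threshold merge. Representatives are the longest
member sequence (ties by lexicographic id); an OTU inherits its
representative's genus for composition summaries.

All reported percentages use one shared rule: round half up to one
decimal (126/148 → 85.1%, 50/62 → 80.6%, 24/39 → 61.5%). Published tables
in this field mix rounding and truncation conventions, so printed
percentages are reproduced via this single documented rule rather than
per-value.

## Neighbor joining and bootstrap

`neighbor_joining()` is a textbook Saitou–Nei implementation: minimal-Q
joins with ties broken by the smallest index pair, branch lengths from the
standard formulas, negative lengths clamped to zero with the total deficit
recorded in an attribute, and a trifurcating root (three-point formulas)
as is conventional for unrooted NJ trees. On additive distances it
recovers the generating tree exactly (verified to 1e-9 against trees with
known branch lengths, and against `ape::nj`). Distances are uncorrected
p-distances by default — columns containing a gap or ambiguity in either
sequence are excluded pairwise — with Jukes–Cantor correction
(`−3/4·ln(1 − 4p/3)`) and uncorrected protein p-distance as options; the
model used is recorded in the matrix's `model` attribute. The distance
model for published trees of this kind is usually unstated, so tree
topologies from real data are not treated as exactly reproducible.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and reports the percentage of
replicates containing each internal bipartition (via `ape::prop.clades`,
unrooted). The default pipeline uses 100 replicates to keep a full run in
minutes; 1,000 replicates — the convention in publication-quality trees —
is a configuration change (`bootstrap_reps`).

`translate_fragment()` translates all six frames under the standard code
(no initiator-codon special-casing, since inputs are internal gene
fragments) and returns the frame with the longest stop-free stretch, ties
resolved in frame order +1, +2, +3, −1, −2, −3; a warning flags fragments
with fewer than 10 consecutive stop-free residues.

## In-silico PCR

`find_binding_sites()` scans both orientations with IUPAC-aware matching:
a primer code matches a template code whenever their base sets intersect
(so template ambiguities behave symmetrically to primer degeneracies).
`insilico_pcr()` pairs every forward site with every downstream,
non-overlapping reverse site on either template orientation and measures
product length 5′-end to 5′-end inclusive of both primer footprints —
the convention under which stated product sizes (350 bp, 480 bp) include
the 24–27 nt primers. A call is positive when at least one product lies
within `expected_size × (1 ± 0.2)`; the ±20% window operationalizes the
qualitative "right size" judgement made at the gel, and is configurable.
`max_mismatch` defaults to 0 because the degenerate codes already encode
the tolerated variation; the positive set grows monotonically with the
allowance, which is asserted in tests.

## The gel and densitometry model

Digestion (`digest()`) cuts at every occurrence of the recognition site at
the catalogue offset (AluI AG^CT and HaeIII GG^CC both cut after position
2); fragment lengths always sum to the template length. The gel model then
applies three rules, in order:

1. **Detection limit:** fragments below 50 bp are dropped (small fragments
   run off a 10% polyacrylamide gel or fall below stain detectability).
2. **Co-migration:** sizes that differ by at most
   `max(5 bp, 2% of the larger size)` merge into one band, whose size is
   the mass-weighted mean of its fragments.
3. **Mass-proportional intensity:** band area is proportional to total bp
   (ethidium-bromide staining scales with mass), normalized over the
   detected fragments of the lane.

The 5%-of-lane-area scoring rule is applied strictly (`area > 0.05`,
measured against the pre-filter lane total), so a band at exactly 5% is
discarded; the filter is idempotent. Band matrices pool retained sizes
across lanes, sort them, and bin by single linkage under the *same*
co-migration tolerance, so a band shared by two lanes necessarily lands in
one bin and binning is invariant to lane order. Gel resolution is a free
parameter of the model: real densitometry tolerances are not published,
which is also why distinct-fragment counts from physical gels are not
comparable targets for this simulation.

## Jaccard / UPGMA grouping

Similarity between binary banding profiles is the Jaccard coefficient
`a/(a+b+c)` (joint absences carry no signal for presence/absence gel
data). A pair of all-empty lanes has no defined similarity and raises an
error rather than silently returning a value. `upgma()` clusters on
`1 − J` with unweighted arithmetic-mean linkage; ties are broken by the
lexicographically smallest pair of cluster labels so dendrograms are fully
deterministic — binary data make exact ties common, and the tie rule of
the historical desktop tools is undocumented. Merge heights are cophenetic
distances (the object is `stats::hclust`-compatible); the ultrametric
halving convention is applied at Newick export, while
`cut_at_similarity()` cuts on the cophenetic scale so "group at 0.93
similarity" is unambiguous: leaves whose cophenetic similarity is ≥ 0.93
share a group, with equality kept together. When both enzymes are used,
their band matrices are concatenated column-wise before similarity is
computed (per-enzyme averaging is possible by clustering the matrices
separately); concatenation treats every distinct fragment as one
character, which matches how combined-enzyme dendrograms are described in
practice.

## Bioactivity correlation

`crosstab_activity_genes()` partitions the active isolates into carriers
of both loci, exactly one, or neither — "either" always means exactly one,
keeping the three categories a partition — and reports gene-positive but
inactive isolates alongside, since those flag biosynthetic capacity
unexpressed under laboratory conditions. Gram classification of test
strains is configuration data (`default_gram_classes()`), not hard-coded.
The network export is a tripartite edge list (isolate→locus,
isolate→strain) with deterministic ordering, as TSV or GraphML.

## Problem sizes and numerical choices

The test suite and the acceptance script choose sizes that make a full
run take minutes on one core: the default community is the study-scale 66
isolates with 1300-nt 16S templates (an all-pairs identity matrix, 2,145
global alignments, dominates the runtime at roughly three minutes);
end-to-end smoke tests use 16 isolates with 400-nt templates; planted-
structure recovery uses two isolates per genus across 3–10 genera over 20
fixed seeds; oracle comparisons use 1,000 random 480-nt digests, 500
degenerate-primer searches, 200 random 8×8 UPGMA instances, 10,000 random
Jaccard pairs and 100 random additive 6-taxon trees. Numerical guards:
identity/threshold comparisons use a 1e-9 epsilon at cut heights;
UPGMA/NJ tie-breaking is deterministic as described; negative NJ branch
lengths are clamped with the deficit logged; Jukes–Cantor rejects
p ≥ 0.75 (saturation); degenerate translations below 10 stop-free
residues warn rather than fail.

## Known limitations

* Identity is computed from pairwise alignments, not a multiple
  alignment; against tools that cluster on a shared multiple alignment,
  OTU counts can shift by one or two at a given threshold.
* The planted-recovery property (exactly *g* OTUs at 99% from groups at
  0.4% within-divergence) is statistically marginal under the binomial
  substitution model: on 1.3-kb sequences a same-genus pair falls below
  99% identity with probability ~1e-3, and complete linkage converts any
  single such pair into an extra OTU. With ~130 within-genus pairs across
  the fixed-seed suite, occasional extra OTUs are expected rather than a
  defect — one of the twenty frozen trials exhibits exactly this.
* The gel model is deterministic given fragment lengths; it does not
  simulate partial digestion, band smearing, or lane-to-lane mobility
  drift, so group counts from simulated fingerprints are comparable in
  kind but not in value to counts read off physical gels.
* ML tree inference, database searches (Blastn/Blastx) and taxonomy
  assignment are out of scope; NJ is the implemented phylogeny method and
  genus labels are generator metadata.
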