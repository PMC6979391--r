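---
title: "Methods: detecting TE-mediated turnover of CTCF loop anchors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting TE-mediated turnover of CTCF loop anchors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

CTCF-anchored chromatin loops are strongly conserved between mammalian
genomes even where the underlying DNA is not. Transposable elements (TEs)
carry or acquire CTCF motifs and can therefore *replace* a decayed
ancestral anchor with a nearby, younger binding site while the loop itself
persists — binding-site turnover at the level of 3D genome structure.
`loopover` implements the comparative pipeline needed to find and
characterize such events between two genomes: annotate the repeat origin of
anchor CTCF sites, call orthologous loops by calibrated reciprocal chain
lifting, detect turnover events where a species-specific TE anchors a
conserved loop, quantify the structural consequences of deleting such an
anchor in a contact map, and test whether turnover TEs carry the mutational
signature of an unmethylated history.

# Anchor annotation

A loop-anchor CTCF site is called repeat-derived when at least 10 bp of its
**core motif** (not the ChIP peak) intersect a RepeatMasker element. When a
motif overlaps several repeats we assign the one with maximal overlap,
breaking ties by lower percent divergence and then leftmost start: the rule
is deterministic and favours the best-preserved element. ChIP peaks are
annotated by a stricter rule — the single centre base (the summit when one
is recorded, otherwise `floor(start + length/2)`) must fall inside a
repeat.

Loops are then partitioned: *RE-derived* if at least one anchor is
repeat-derived, *non-RE* if both anchors are affirmatively non-repeat, and
*excluded* when an unidentified anchor leaves the question open (one
unidentified anchor plus one non-RE anchor cannot be called either way).
Enrichment per repeat class or family compares the share of RE-derived
calls against the **length-weighted** genomic background (the family's
share of total repeat bp), so long, abundant families are not credited for
mere genomic mass.

Anchor sites shared by several loops are de-duplicated by exact motif
coordinates; de-duplicating by overlapping ChIP peak instead was
considered and rejected because peak boundaries are caller-dependent while
motif coordinates are stable.

# Loop orthology

Coordinates move between genomes through a block chain (the structure
liftOver consumes). An interval's *matched fraction* is the share of its
bases inside the ungapped blocks of the best-scoring overlapping chain;
the lift is reported only when that fraction reaches `min_match`. Both
anchors must lift, onto one chromosome, for a loop to be liftable.

`min_match` is chosen by the shuffle procedure: shuffle the features
within their chromosome of origin (preserving lengths), lift each shuffled
set, and pick the gate that maximizes the mean lifted count, breaking ties
by the lower coefficient of variation and then by the larger gate. On real
cross-species chains this selects a permissive gate (0.1 is the package
default) because repetitive flanks rarely lift completely.

A lifted loop matches a target loop when **both** anchor midpoints lie
within `w = min(query loop length / 2, vicinity)` of the target's anchor
midpoints. The loop length in the formula is the *query* (lifted) loop's
length — the window must shrink for short loops or neighbouring anchors
would alias, and the query side is the one whose geometry the lift just
established. The vicinity threshold is calibrated by a false-discovery
sweep: `FDR(t)` is the mean matched count over shuffled query sets divided
by the real matched count, and the largest threshold with `FDR < 0.1` is
chosen. Finally, reciprocal best hits (best = smallest summed absolute
anchor offsets) yield at most one orthology call per loop. The distance
tie-break is our automated stand-in for the manual synteny curation a
human analyst would perform; it is declared, deterministic, and tested,
but it is a substitute, not a reconstruction, of expert curation.

# Turnover detection

Given an orthology call, an anchor of the species-A loop is a turnover
candidate when three conditions hold: (i) its motif is repeat-derived;
(ii) the TE locus is species-specific — its interval lifts with a matched
fraction below 0.1, or lifts onto a region with no repeat of the same
family; (iii) the matched species-B anchor's motif is not inside an
orthologous copy of that TE. The lift-and-family rule operationalizes
"present in one genome only" without requiring base-level alignment of
the TE copies. One event is emitted per qualifying anchor side, so a loop
with both anchors turned over yields two events.

Candidates are filtered against the local ChIP landscape within a window
(default: the vicinity threshold, 50 kb): zero other peaks means the TE
site is the only plausible anchor (*replacement*); exactly one other peak
that coincides with an annotated ancestral site means the TE is a
*redundant* shadow anchor; anything busier is dropped as unattributable.

Orientation statistics tally unique anchors (an anchor tethering several
loops counts once) into a 2x2 motif-orientation by anchor-side table and
attach a Pearson chi-square **without** Yates continuity correction — the
correction is deliberately omitted because the uncorrected statistic is
the one whose p-values match the printed desk values on tables of this
size, and the counts here are far from the small-sample regime where the
correction helps. A zero margin flags the table as low-count and the
p-value is reported missing rather than computed.

# Contact-map statistics

Contact matrices are stored upper-triangle sparse and symmetrized on
access; raw maps merge by count summation. Fixed-depth subsampling draws
read pairs **without replacement** (sequential multivariate
hypergeometric), so the subsampled total is exact and complementary
subsamples merge back to the original. VC-sqrt balancing divides each
entry by the square root of the product of its row and column coverages;
zero-coverage bins are excluded. Cross-domain percentage follows
`inter * 100 / (intra + inter)` with diagonal pairs counted as
intra-domain (the convention is configurable in spirit — it is a single
tally rule — and documented because the definition is silent on the
diagonal). The replicate comparison uses Welch's unequal-variance t test
with Welch-Satterthwaite degrees of freedom, computed per subsampled
mini-map after VC-sqrt normalization, matching the order
subsample → normalize → tally. Virtual 4C profiles report the percentage
of all interactions emanating from an anchor window per bin and default to
raw counts; normalized input is accepted but raw is the default because
coverage rescaling distorts the one-vs-all share a 4C track represents.

# TE evolutionary analytics

Each genomic TE is aligned globally to its subfamily consensus
(Needleman-Wunsch, EDNAFULL scoring, gap open 10, extension 0.5; the first
gap base pays both penalties — the convention is locked by a brute-force
dynamic-programming oracle in the test suite). Substitutions are counted
in 12 directional categories (consensus base first), columns containing
any non-ACGT character are skipped, and rates are normalized by the
genomic (ungapped) length. The methylation-associated rate is the mean of
the C-to-T and G-to-A rates per element, the non-methylation rate the mean
of the other ten; both average per element first and across elements
second, so long elements do not dominate.

The permutation test draws, for each of 1000 permutations (200 in the
packaged test runs, which keeps the suite fast at the cost of p-value
granularity), a background cohort matching the turnover cohort's subfamily
frequencies from TEs not involved in looping, without replacement when the
pool allows. The z-score compares the observed mean to the permutation
means and the test is left-tailed: the hypothesis is specifically that
turnover TEs accumulated *fewer* methylation-associated substitutions.
Bonferroni correction covers the 12 single-substitution hypotheses. A
naive one-sample Kolmogorov-Smirnov probability against a normal with the
sample-estimated mean and sd is reported for each permutation
distribution — reported, not asserted, since estimating the parameters
makes the naive KS conservative (a Lilliefors correction was considered
and not used, matching the plain-KS reporting convention).

Jukes-Cantor and Kimura two-parameter distances are computed from the
stored alignment's mismatch, transition and transversion proportions over
columns where both sides are unambiguous bases; the denominator is the
genomic length minus insertion bases (i.e. aligned base-base columns). TE
age is percent divergence divided by the neutral substitution rate
(human 2.2e-9, mouse 4.5e-9 substitutions/site/year).

Fragmented LINE consensus pieces (5' end, ORF2, 3' end) are stitched by
the best terminal overlap under an ungapped +5/-4 scan with a 10 bp
minimum; terminal overlaps between consensus fragments are essentially
ungapped, so a full local aligner adds failure modes without adding
accuracy. Equal-best overlaps at different offsets raise an error listing
the candidates rather than guessing.

# Methylation metaplot

CpG methylation fractions are averaged in 20 bp windows sliding by 10 bp
("sliding" implies overlap; the step is configurable) across ±2 kb of
each motif centre, on a strand-oriented axis (minus-strand motifs are
flipped). The per-window mean is unweighted across CpGs (coverage acts
only as an inclusion filter, ≥1 read), sites average within each origin
category, and windows with no covered CpG at a site are excluded from that
site's contribution rather than imputed. Profiles centre on the motif
midpoint; centring on peak summits was considered and rejected because
summits are caller- and depth-dependent.

# The synthetic two-species dataset

The generator builds an ancestral backbone per chromosome and derives two
genomes from it. Lineage-specific TE insertions and block-boundary spacers
are point insertions into one or both genomes, so the chain between the
genomes covers exactly the syntenic sequence and species-specific TEs lie
entirely outside chain blocks. Implanted structures:

* **Conserved loops** with convergent CTCF motifs (left anchor `+`, right
  anchor `-`), a configurable fraction anchored inside shared TEs.
* **Turnover events**: the ancestral motif is degraded by 3 point
  mutations in genome A and the loop re-anchored at a motif placed inside
  a species-A-specific TE inserted 1-5 kb away, orientation matched to
  the anchor side — reflecting the convergence bias that motivates the
  orientation statistics.
* **Species-specific decoy loops** in each genome, syntenic but unmatched,
  to exercise the orthology FDR.
* **TE cohorts** for the mutational-signature test: turnover TEs diverge
  with the C-to-T/G-to-A channel at 1x, background TEs at 4x, emulating
  unmethylated versus methylated histories. Conditional on a site
  mutating, the three target bases are drawn with the deamination channel
  weighted by the multiplier, so total divergence is held fixed while the
  spectrum shifts.
* **Methylation valleys** (fraction 0.1 within ±150 bp of bound motifs on
  a 0.8 background) at CpG dinucleotides taken from the actual simulated
  sequence.
* **WT/KO contact maps** (2 Mb at 5 kb bins) around the first implanted
  turnover anchor: expected counts follow a distance-decay power law
  (exponent 1) times a domain factor (3x within domains) and a focal loop
  factor (30x at the anchor pair); the KO map removes the boundary and the
  loop. Counts are multinomial at fixed total, so read depth is exact.

Defaults are two chromosomes of 2.5 Mb, 24 conserved loops, 10 turnover
events, 8 decoy loops per genome, five TE subfamilies spanning the four
major classes with 30-40 background copies each, and 2e6 reads per contact
map. These sizes keep a full pipeline run around ten seconds while leaving
every statistic comfortably powered; they are the packaged study
conditions, not tuned quantities. All randomness flows from one root seed;
each artifact stream derives its own stream from it, so components are
independently reproducible.

What the generator does **not** emulate: sequence-level realism (no GC
isochores, tandem repeats, or nested TE insertions), chain fragmentation
from rearrangements (chains are co-linear with insertions and spacer
breaks only), read-level Hi-C noise (bin counts are sampled directly),
ChIP false positives, or partial TE fragments (simulated copies carry
substitutions but no indels, so realignment recovers the implanted truth
exactly). A pipeline that is perfect here can still be challenged by real
data; what passing tests establish is the correctness of the bookkeeping
and statistics, plus recovery under the implanted effect sizes.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; 1-based inclusive
  formats convert at I/O boundaries only, and the conversion is an
  involution (verified by round-trip tests).
* Minus-strand chain targets are pre-flipped to forward coordinates at
  read time with the orientation kept as a flag, so lifting arithmetic
  never branches on strand except at block mapping.
* `pearson_chi2` with a zero margin, `jukes_cantor` at `p >= 0.75`,
  `kimura_2p` outside its log domain, and permutation statistics with zero
  spread all report missing values instead of errors or infinities.
* Subsampling more reads than a map contains, normalizing an all-zero
  matrix, anchoring a virtual 4C outside the map, and overlapping domain
  pairs are errors — silent degradation would corrupt downstream
  statistics.
* The 20% length filter for crossmatch-derived alignments drops elements
  strictly below the threshold ("less than 20%"), and is disabled for the
  realignment path, which does not need it.

# Known limitations

* Reciprocal-best-hit matching resolves multi-loop ambiguities by anchor
  distance only; dense loop clusters closer than the vicinity window can
  be paired with a near-neighbour rather than the true ortholog.
* Anchor side correspondence across genomes assumes co-linear (sense)
  chain orientation for the loop span; inversions spanning a whole loop
  would swap left/right without notice in the turnover side label.
* The species-specificity rule for a TE (lift failure or missing
  same-family repeat) inherits RepeatMasker's family annotations; family
  mislabels in real annotations propagate.
* The vicinity calibration reports an FDR against shuffled placements,
  which is a proxy for — not a measurement of — orthology error on real
  genomes.
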