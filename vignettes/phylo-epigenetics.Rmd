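---
title: "Phylo-epigenetics: CpG dinucleotide variability as a phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylo-epigenetics: CpG dinucleotide variability as a phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloepi)
```

## The idea

CpG dinucleotides are the substrate of DNA methylation, and a
methylated CpG deaminates to TpG (or, on the opposite strand, to CpA)
at a rate 10–50 times above other transitions.  CpG islands of
housekeeping genes are normally unmethylated and highly conserved, yet
across closely related species a distinct minority of their CpGs turns
over.  `phyloepi` treats the per-species presence or absence of each
CpG as a binary character and asks whether those characters alone
carry a usable phylogenetic signal: a "phylo-epigenetic" tree built
only from CpG consistency, compared against the conventional tree
built from all substitutions.

The pipeline is: **classify** dinucleotide sites, **count** the CpG
mutation spectrum, **recode** CpG-class sites to a binary A/T matrix,
build **UPGMA** trees from p-distances of the full and the recoded
alignment, **calibrate** node heights at a known divergence, and
**compare** topologies by Robinson–Foulds distance.

## Site classification

The input is an aligned multi-FASTA of concatenated CpG-island
5′-regions, one record per taxon.  The alignment is read in a fixed,
nonoverlapping dinucleotide frame anchored at the first column, so an
alignment of $n$ columns has $\lfloor n/2 \rfloor$ dinucleotide
sites.  That frame reproduces the "divide the sequence by two and
inspect the lined-up dinucleotides" accounting used for the headline
fractions, at the cost of missing CpGs that straddle the frame; since
the anchor is biologically arbitrary, an `overlapping` mode (every
adjacent column pair) is provided as well, and on any alignment it
finds at least the frame-anchored CpG sites.

Each site is classified from its per-taxon two-letter states:

* `GAPPED` — any taxon has `-` or `N`: excluded from all counts.
  Gap handling is not fixed by the accounting being emulated;
  exclusion is the conservative choice, and the count of excluded
  sites is reported so nothing is silently dropped.
* `CONSISTENT_CPG` — all taxa are `CG`.
* `VARIABLE_CPG` — at least one but not all taxa are `CG`.
* `NONCPG_VARIABLE` / `NONCPG_INVARIANT` — no taxon is `CG`.

Single columns that vary outside all CpG-class sites are tallied
separately (`n_noncpg_snp_columns`) as the single-nucleotide
counterpart of the dinucleotide classes.

Reported fractions follow fixed conventions: the percentage of CpG
sites altered in at least one species is kept at full precision and
also rounded (half-up) to the nearest integer for reports;
per-dinucleotide fractions are rounded half-up to one decimal.

## The mutation spectrum

Over the variable CpG sites, each **distinct** non-CG state at a site
is one event: states one step from CG fall into the six classes
CG→TG, CG→CA, CG→GG, CG→CC, CG→CT, CG→AG; states differing at both
positions go to an explicit `other` bin, never forced into a class.
Counting distinct states (rather than taxa) makes the class total
equal the variable-site count whenever each site carries a single
derived state, which is the regime the class totals of the motivating
dataset sit in (they sum exactly to total minus conserved CpG sites).
The pipeline enforces the direction of that identity that is
guaranteed — class counts plus `other` can never fall below the
number of variable sites — and aborts if it is violated.

Two modelling simplifications are deliberate: CG is taken as
ancestral wherever any taxon retains it (no ancestral-state
reconstruction), and strands are not resolved — CpA is simply the
complementary-strand fingerprint of the same deamination event, which
is why CG→TG and CG→CA are reported together as the "deamination
share" where a single number is wanted.

The per-taxon *perspective counts* answer a different question: for
each species, at how many sites does it retain a CG while at least
one other species shows TG or CA?  The prose this implements is loose
enough to admit other readings; this one is consistent with the
reported per-species extremes and is documented as an interpretation.

## A/T recoding

The recoded matrix has one column per gap-free CpG-class site: `A`
where the taxon carries CG, `T` where it lacks CG at a site where at
least one taxon has it.  A literal reading of the source description
("every same-positioned dinucleotide ... was replaced by a T") would
assign `T` to *every* taxon at variable sites, which destroys all
between-taxon signal and could not produce a resolved tree; the
per-taxon reading used here is the one consistent with the
illustrated A/T alignment, and is flagged prominently as an
interpretation.

Consistent sites become invariant all-`A` columns.  They carry no
topological information but dilute p-distances and therefore set the
branch-length scale before calibration; because the recoded tree is
described as based on consistent *and* variable CpGs, they are kept
by default (`keep_invariant = TRUE`), with the option to drop them.
After calibration the choice is immaterial: rescaling at a named node
erases the overall distance scale.

## Trees

Distances are uncorrected p-distances: mismatches over comparable
columns, where by default a column is comparable for a pair when
neither sequence has `-` or `N` there.  `count_gaps = TRUE`
optionally scores gap/residue columns as differences (gap–gap columns
never count), for alignments where indels should contribute; it is
off by default because indel placement is an alignment artefact as
much as a biological signal.  Whether a distance correction beyond
p-distance should be used is isolated behind the distance interface;
p-distance is the default because at 97–100% identity corrections
are nearly linear and the UPGMA topology is unaffected.

UPGMA is implemented from scratch: repeatedly merge the pair of
clusters at minimal distance, place the parent node at half that
distance, and update distances to the merged pair as the
*size-weighted* arithmetic mean (UPGMA proper, not WPGMA).  Ties are
broken deterministically toward the lexicographically smallest pair
of cluster creation indices, so results are platform-independent;
with distinct pairwise distances the topology is exactly invariant to
input order.  The output is ultrametric by construction (root-to-leaf
spread below $10^{-9}$ in the tests).  A matrix with no variation
yields a zero-height tree rather than an error: every grouping of
identical sequences is equally (un)supported, and downstream
calibration then fails loudly at the zero-height calibration node.

Calibration multiplies every node height by `age / h`, where `h` is
the height of the most recent common ancestor of a named pair — here
chimpanzee–bonobo at 1.7 My — leaving topology and height ratios
untouched.  Tree comparison is the unrooted Robinson–Foulds
bipartition distance; 0 means identical topology.

## The simulator

`sim_config()` / `evolve()` generate ground-truth data with the
statistical structure the analysis assumes: a known tree, a
CpG-island-like root sequence, and context-dependent CpG
hypermutability.

The root sequence plants CpGs at random nonoverlapping frame offsets
until a target fraction of dinucleotide positions is CpG, on a
GC-rich (60% GC) background drawn so that **no** CG occurs outside
the planted set — the planted positions are then an exact ground
truth for classification (recovered exactly at divergence zero).
Evolution along each branch is a Gillespie simulation of an HKY-like
process (transition/transversion ratio `kappa`, default 2) in which
the C→T channel of a C followed by G, and the G→A channel of a G
preceded by C, are multiplied by `lambda`; context is re-evaluated
after every event.  At `lambda = 1` the process reduces *exactly* to
the context-free one (verified by a χ² test on the event log), and
`lambda` is directly the fold excess of CpG deamination transitions,
matching the mechanistic 10–50× range; the default is 20.  Every
event is logged (branch, site, time, from, to, context), and
replaying the log from the root reproduces each leaf exactly.

`hominid_preset()` encodes the seven-taxon study condition:
`(((((human,(neanderthal,denisovan)),(chimp,bonobo)),gorilla),orangutan)`
with node ages 0.43, 0.65, 1.7, 5, 8 and 14 My, sequence length
27,000 (≈ the concatenated-island alignment), and CpG fraction 0.18
(≈ 2,495 CpG sites among 13,530 dinucleotide positions).  No
substitution-rate magnitude is published for these loci; the preset
uses `mu = 3e-4` substitutions/site/My, chosen once so that pairwise
identities land in the observed 97–100% band (minimum pair
human–orangutan ≈ 97.5%); at `lambda = 20` this puts the simulated
CpG alteration fraction near 20–25%, the same order as the ~17%
observed.  The rate is a documented free parameter, not a fit.

What the simulator does **not** emulate: indels (columns are
homologous by construction, so classification ground truth is exact —
real MAFFT alignments contain small gaps), explicit methylation
state or its erasure dynamics, selection, rate variation across
islands, and alignment error.  Passing tests therefore demonstrate
correctness of the accounting and inference machinery under the
stated generative model, not robustness to alignment artefacts.

Randomness: one global seed drives the run; per-branch substreams are
derived deterministically from it, so the same seed always yields the
same alignment.

## Resolution limits worth knowing

The shallowest split in the preset — neanderthal–denisovan, a 0.22 My
internal branch — is carried by only a handful of informative recoded
characters (about 3–4 expected CpG-loss events among ~2,450 binary
columns).  Under the study conditions the recoded tree recovers the
full planted topology in all of the fixed-seed replicates used in the
tests, but across arbitrary seeds the neanderthal–denisovan–human
ordering flips in a substantial minority of runs, in both the genetic
and the recoded tree.  This is the expected Poisson statistics of a
very short branch, and it mirrors the empirical observation that the
genetic and phylo-epigenetic trees of the motivating dataset disagree
precisely on that trio.  Conclusions about such shallow splits from
~27 kb of CpG-island sequence are intrinsically fragile.

## Problem sizes used in the checks

The test suite exercises UPGMA against a brute-force re-averaging
oracle on 100 random 4–8 taxon matrices, recoding against a per-site
Hamming oracle on 50 random alignments, and the full pipeline on ten
27 kb seven-taxon simulations (plus three for the `lambda` monotonicity
check); the whole suite runs in about a minute.  `scripts/acceptance.R`
re-runs the ten-replicate study condition from scratch at a
user-supplied seed and writes the measured headline quantities as
JSON.

## Coordinate conventions

Inside R everything is 1-based and closed, as R users expect; all
*file* interfaces (the BED-like region map, the site report, the
recoded column map) use 0-based half-open column intervals, the
convention of the formats they imitate.  The gap character is `-`
only; `.` is rejected loudly rather than guessed at.
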