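---
title: "Single-molecule RNA structure landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule RNA structure landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscape)
```

## The problem

Chemical probing reagents such as NAI acylate the 2'-hydroxyl of
flexible, mostly unpaired nucleotides. After reverse transcription the
modified sites appear as mutations in the cDNA, and high-accuracy long
reads recover the modification pattern of *each individual molecule*
along its full length. Population-average reactivity profiles wash out
conformational heterogeneity; the point of a single-molecule analysis is
to keep each molecule's pattern separate, fold each molecule under its
own evidence, and then ask how many distinct conformations the
population holds and in what proportions.

`foldscape` implements that pipeline: alignments are reduced to
per-molecule mutation *bit vectors*; bit vectors yield channel mutation
rates and SHAPE reactivities; each molecule's mutated positions become
hard single-strandedness constraints for a stochastic context-free
grammar (SCFG) sampler; sampled structures are encoded as
structural-element strings, embedded by PCA, clustered by k-means into
conformations, and summarised by base-pair probabilities,
single-strandedness likelihoods and positional Shannon entropies.

## Bit vectors

A bit vector stores, per reference position, a 0 (aligned match), 1
(mutation) or a mask (uninformative). Mismatches count as mutations.
Deletions are counted as mutations only when their placement is
unambiguous: a deleted base that sits in, or adjacent to, a reference
homopolymer run of length two or more of the same base could have been
placed anywhere in that run by the aligner, so the whole run is masked
instead. This homopolymer rule is this package's operational definition
of an "unambiguously aligned deletion"; it is deliberately conservative
because a false 1 becomes a hard folding constraint downstream.
Insertions occupy no reference coordinate and are only counted for QC.
Soft-clipped and uncovered positions stay masked, and masked positions
never enter any denominator.

Two filters matter in practice. Only primary alignments are used. Reads
covering less than 90% of the reference (configurable) are dropped, so
that every retained bit vector informs full-length structure rather than
a fragment. Base-quality masking is available but off by default:
consensus long reads are already high accuracy, and a quality filter
would mostly thin coverage.

## Reactivities

The mutation rate at a position is ones / (ones + zeroes) over
informative reads. The raw reactivity combines the treated (+) and
control (−) channels as

$$R = \frac{MR_{(+)} - MR_{(-)}}{1 - MR_{(-)}},$$

a positive-likelihood-ratio estimate of modification; the denominator,
the control channel's true-negative rate, is its specificity. Where the
treated rate falls below the control rate, $R$ is clamped to zero: the
reactivity scale starts at zero and nothing downstream consumes negative
evidence. Normalization to the conventional 0-to-~1 scale uses the
common 2%/8% rule (drop the top 2% of defined values as outliers, divide
by the mean of the next 8%); a boxplot variant is available because
published normalizations differ in detail and the choice is a dialect,
not a result. Profiles with fewer than 20 defined positions are not
normalized — the caller is told to skip rather than silently rescaling
noise. Positions with informative coverage below 50 reads in either
channel are reported but flagged low-confidence.

## The grammar and the sampler

Single-molecule constraints are sparse — a handful of forced-unpaired
positions per molecule — so the folding engine must supply a sensible
prior over structures and then bend it to the constraints. We use a
small unambiguous nested grammar (the classic S/L/F three-non-terminal
form):

```
S -> L S | L
L -> a | a F b
F -> a F b | L S
```

Every pseudoknot-free structure has exactly one derivation, so the
derivation weight *is* the structure weight:

$$w(\text{structure}) = q_u^{\#\text{unpaired}} \cdot
  w_{init}^{\#\text{helices}} \prod_{(i,j)} w_{pair}(i,j) \cdot
  w_{stack}^{\#\text{stacked pairs}}$$

with defaults $q_u = 1$, $w_{pair}$ = 2 (CG/GC), 1.25 (AU/UA), 0.5
(GU/UG), $w_{stack} = 2$ and $w_{init} = 0.002$. The parameterisation
mirrors helix thermodynamics qualitatively: opening a helix pays a
nucleation penalty once, and every stacked extension multiplies the
weight by roughly 2.5–4 for canonical pairs (about 1 for wobble pairs).
The initiation penalty matters more than it looks. Without it, any
chance complementarity is worth pairing, the ensemble is dominated by
dense chimeric folds of many short helices, and a handful of
forced-unpaired constraints cannot move the posterior; with it, short
parasitic helices are barely worth opening, long helices dominate, and
forcing a single interior position of a competing helix to be unpaired
costs that fold a factor of roughly $w_{pair} w_{stack}^2 / w_{init}
\approx 10^3$ — per-molecule evidence becomes nearly decisive. The
grammar is a pluggable parameter table (YAML) because these are
documented defaults, not trained values.

The inside algorithm runs in log space (log-sum-exp throughout), which
keeps 100+-nt transcripts far from overflow at O(L³) cost; stochastic
traceback then draws structures with probability exactly proportional
to their weight. Hairpin loops must hold at least `min_hairpin = 3`
unpaired bases (the steric minimum; the grammar itself cannot close a
loop of one, so values below 2 are rejected). Non-canonical pairs have
weight zero. A position flagged force-unpaired can only be emitted by
the unpaired rule, so constraint violations are structurally impossible,
not merely penalised. Masked positions are left unconstrained: absence
of evidence is not evidence of single-strandedness.

Determinism is end-to-end. The sampler uses its own splitmix64
generator, seeded explicitly; per-molecule child seeds are split off the
root seed by index, so results do not depend on processing order or on
R's global RNG state, and a rerun with the same config is byte-identical.

## Elements, embedding, clustering

Each sampled structure becomes a per-position element string over six
classes — stem `s`, hairpin loop `h`, interior/bulge `i`, multiloop `m`,
5' end `f`, 3' end `t`. An unpaired position takes its class from the
loop that contains it (0 branching helices: hairpin; 1: interior; 2+:
multiloop); exterior positions between top-level helices are coded `m`,
and a structure with no pairs at all is all-`f` by convention. Element
strings are expanded one-hot (6 indicator columns per position) rather
than as ordinal codes, because PCA on ordinal codes would impose an
arbitrary metric between element types; the ordinal encoding exists
behind a flag for sensitivity checks.

PCA is the default embedding, with the sign of each component fixed by
making its largest-magnitude loading positive, so embeddings are fully
reproducible; classical MDS is available behind a flag. Clustering runs
on the embedded coordinates (with a flag to cluster the full one-hot
matrix instead) using `stats::kmeans` — Hartigan–Wong with 10 random
restarts under a fixed seed. (k-means++ initialisation is not available
in base R; multiple seeded restarts serve the same robustness purpose.)
The number of conformations `k` is a judgement call; `suggest_k()`
reports silhouette widths and inertia per candidate `k` so the judgement
is auditable, but makes no automatic choice. Clusters are relabelled in
decreasing abundance so "conformation 1" is always the most populated,
whatever the initialisation.

When several structures are sampled per molecule, reported proportions
are molecule-level: each molecule contributes its per-cluster sample
fractions, so proportions are population fractions of molecules, not of
samples.

Each cluster's representative is chosen consensus-first: the positionwise
most common element string (ties broken in the fixed order
f < t < s < h < i < m) is the cluster's maximum-expected-accuracy
summary, and the member closest to it in Hamming distance is returned,
with ties broken by distance to the cluster centroid and then by read
id. Consensus similarity outranks centroid proximity deliberately — the
consensus is the statistically meaningful object, the centroid a
geometric convenience.

## Ensemble statistics

For any structure collection, $P_{ij}$ is the fraction of structures
containing pair $(i,j)$; the positional pairing probability is
$P_i = \sum_j P_{ij}$ over partners on both sides, the likelihood of
single-strandedness is $1 - P_i$, and the positional Shannon entropy is

$$E_i = \sum_j -P_{ij} \log_{10} P_{ij},$$

summed over pairing partners only, with $0 \log 0 = 0$ by continuity.
Note the unpaired state contributes no term under this definition: a
position unpaired in half the ensemble and paired to one partner in the
other half has $E_i = 0.15$, not $0.30$. An extended entropy that adds
the unpaired state as a term is available behind a flag and clearly
labelled as the non-standard variant. Base-pairing similarity between
two structures is reported as PPV and sensitivity with exact pair
matching; a one-nucleotide slip-tolerant mode exists behind a flag
because published PPV variants differ.

## The synthetic-probing simulator

The simulator draws each molecule's conformation from a weighted mixture
of ground-truth structures, then mutates positions independently:
unpaired positions of that conformation at `p_unpaired_mod` (default
0.06), paired positions at `p_paired_mod` (default 0.005), and an
independent control channel uniformly at `p_background` (default 0.002).
The defaults emulate sparse single-molecule SHAPE signal on
high-accuracy reads — a 125-nt molecule receives on the order of five
informative mutations. `emit_sam()` re-encodes simulated bit vectors as
perfectly coordinated SAM alignments whose mismatches reproduce the
mutation pattern, closing the loop so the alignment-ingestion code is
testable against known truth.

What the simulator does *not* emulate is equally important for reading
test results: sequencing error beyond the encoded mutations, reverse
transcriptase drop-off, amplification bias, per-base reagent chemistry,
partial reads, and any correlation between neighbouring modifications.
Green tests on simulated data show the pipeline recovers the model it
assumes; they do not certify performance on real libraries.

### The three-conformation toy

The bundled `toy_threeway()` transcript is a 125-nt sequence of six
20-nt blocks separated by single-A spacers, in which three 20-pair
helices are pairwise interleaved — a pseudoknot-free structure can
realise at most one of them, so the three conformations are mutually
exclusive by topology. All three helices close 10 CG and 10 AU pairs
with 19 stacking steps, so they carry identical grammar weight. The
blocks were designed once, by annealing at design time: block alphabets
restrict Watson–Crick pairing between non-partner blocks, agreement
runs between blocks (which would create parasitic helices or register
slippage) are capped short enough to be unprofitable under the
initiation penalty, and the spacers prevent any helix from extending
across a block boundary.

A useful calibration for what recovery to expect: with modification
rates 0.06/0.005 a molecule carries about 2.4 informative mutations
against each competing 20-pair helix, so the probability that a
competitor escapes damage entirely is $0.94^{40} \approx 0.08$. Those
molecules are genuinely ambiguous — no classifier, however good, can
assign them better than chance. An ideal Bayes classifier on the exact
generative model therefore plateaus around an adjusted Rand index of
0.63–0.70 at these rates and this length, and the realized pipeline
lands in the same range; mixture *proportions* are much more forgiving,
since ambiguous molecules spread roughly evenly, and are recovered to
within a few percentage points. Deeper per-molecule evidence (longer
molecules or higher modification rates) is what moves ARI, not
algorithmic tuning.

## Problem sizes and numerical choices

The test suite exercises the sampler against exhaustive enumeration on
sequences up to 14 nt (50,000 draws; total variation distance and a
chi-squared goodness-of-fit with low-expectation classes merged), and
the full pipeline on 2,000 simulated molecules of the 125-nt toy —
sizes chosen so the whole suite runs in a few minutes on one CPU while
keeping Monte-Carlo noise well below the tolerances tested.
`scripts/acceptance.R` recomputes the same quantities from scratch at
any seed. Numerical details worth knowing: inside values are
log-domain doubles with log-sum-exp accumulation; traceback uses the
cumulative-sum inverse method with a last-admissible-option fallback
against floating-point slack; PCA on a zero-variance matrix yields
coincident points (handled); k-means ties in cluster size are broken by
original label for determinism.

## Known limitations

- Pseudoknots are outside the model: the grammar is nested, matching
  the dot-bracket representation used throughout.
- The grammar is a documented default, not a trained model; absolute
  ensemble statistics depend on it, though constrained per-molecule
  assignment is driven mostly by the constraints.
- Entropy and pair probabilities are empirical frequencies of the
  sampled ensemble, not thermodynamic partition-function quantities.
- Tree-alignment topological similarity is not implemented; structure
  comparison is base-pair PPV/sensitivity only.
- Isoform assignment expects reads pre-mapped per isoform; it selects
  the best-scoring reference but does not do read mapping itself.
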