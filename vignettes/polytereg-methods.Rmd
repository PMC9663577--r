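---
title: "Models and methods behind polytereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polytereg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytereg)
```

polytereg analyses transcription-factor (TF) cistromes in polyploid genomes
whose subgenomes diverged from a common ancestor and were later reunited by
hybridization — hexaploid wheat, with its A, B and D subgenomes, is the
motivating case. The questions the package addresses are how TF binding is
partitioned among homoeologous promoters, and what role transposable
elements (TEs) — intact copies and degenerated relics — play in creating
subgenome-convergent versus -divergent binding. This vignette explains the
models, the parameters that matter, and the design decisions behind the
implementation; the README shows the code surface.

## Coordinates and inputs

All positional tables are tibbles with `chrom`, `start`, `end` in 0-based
half-open coordinates (BED convention). GFF3 gene models are converted at
the boundary (`read_gff_genes()`), with the TSS at `start` on "+" genes and
`end - 1` on "-" genes. The subgenome of any feature is parsed from the
trailing letter of its chromosome name (configurable regex), mirroring
common polyploid naming without hard-coding it. Readers validate their
invariants (coordinates, summit-in-peak, LTR structure) and name offending
lines, so that downstream stages can assume clean tables.

## Promoter TF affinity (TFAS) and triad balance patterns

The regulatory effect of one TF on one gene is summarized by a
distance-decayed sum over the peaks whose summit falls in the promoter,
defined as the 5-kb window centered on the TSS:

$$\mathrm{TFAS} = \sum_{k=1}^{n} \mathrm{rpkm}_k \; e^{-d_k/2000},$$

with $d_k$ the summit-to-TSS distance in bp and $\mathrm{rpkm}_k$ the
normalized read density of peak $k$. Genes without a qualifying peak score
zero. The window is implemented as the closed condition $|d| \le 2500$; the
2000-bp decay scale and the window size are arguments of `compute_tfas()`.
Membership is decided by the summit, not by peak overlap, because the score
is summit-anchored.

For a 1:1:1 triad the three TFAS values are normalized to proportions and
assigned to the nearest of seven standard patterns by Euclidean distance:
balanced `ABD` at $(1/3, 1/3, 1/3)$, the two-subgenome patterns `AB`, `AD`,
`BD` at permutations of $(0.5, 0.5, 0)$, and the single-subgenome patterns
`A`, `B`, `D` at the unit vectors. Thirds are exact, not the rounded 0.33
sometimes displayed, so the standards lie on the simplex. Triads whose three
TFAS all fall below 0.25 are filtered as unbound; the filter is applied per
TF per triad, reading the score as one TF's regulatory effect. Exact
distance ties are broken by the fixed priority `ABD > AB > AD > BD > A > B >
D`; ties are measure-zero but reachable on exact rational inputs (for
example $(0.75, 0.25, 0)$ is equidistant from `A` and `AB` and resolves to
`AB`).

The minimum distance between any two standards is $\sqrt{1/6} \approx
0.40825$ (`ABD` to any two-subgenome pattern). Any proportion vector within
half that distance (0.2041) of a standard is therefore provably assigned to
it — the property the synthetic data generator relies on: planted
proportions are perturbed inside a ball of radius `noise_radius` (default
0.15) and projected back onto the simplex with the non-expansive Euclidean
projection, so planted labels remain recoverable by construction.

Regulatory divergence of a homoeolog pair is the sum over qualifying TFs
(TFAS > 0.25 for at least one gene) of $|\log_2$ fold-change$|$ in promoter
binding density; expression divergence is the analogous quantity on TPM. A
symmetric pseudocount (default 0.5) is always added on both sides rather
than only when a zero occurs: applying it conditionally would make the
measure discontinuous at zero, while the unconditional form is symmetric,
bounded and configurable. DHS (chromatin openness) divergence of a triad is
the Euclidean distance of its normalized openness proportions from the
balanced point.

## Subgenome homology classes

Regions are classified from reciprocal whole-genome alignment blocks.
"Reciprocally alignable between X and Y" is operationalized as the
intersection of the X-to-Y block footprint with the back-mapped subject
footprint of the Y-to-X blocks — the strictest symmetric reading, since the
block format does not itself guarantee reciprocality. Runs longer than 400
bp count; a base reciprocally alignable to both other subgenomes is
`homo3`, to exactly one `homo2`, to none `specific`. `homo3` runs inside
synteny blocks are reported additionally as `homoeo3` (syntenic homo3), so
the three primary classes always partition the genome. Adjacent blocks are
merged with zero gap tolerance before the length rule — a conservative
choice; features (e.g. merged TFBSs) are located by the class containing
their midpoint, which is deterministic for straddling features (a
majority-overlap alternative is available via `method = "majority"`).

## Merged binding sites, HOT regions, bins and enrichments

Per-TF peaks are unioned into maximal disjoint merged TFBSs; at least one
shared base pair merges, bookended intervals stay separate (the natural
criterion under half-open coordinates). A merged site bound by strictly
more than 12 distinct TFs — 13 or more — is a high-occupancy target (HOT)
region. "Binding sites" are counted as distinct TFs, not peaks, so a TF
with two peaks in one site counts once. Binding similarity between TFs is
the Pearson correlation of presence/absence profiles over consecutive 2-kb
bins anchored at coordinate 0 per chromosome (trailing partial bin kept);
constant profiles yield `NA` rather than a fabricated 0, and an
average-linkage clustering order on $1-r$ accompanies the matrix for
display. Interval-class enrichment is the fraction of query bp in a class
divided by the class's genome fraction; TAD boundaries are 20-kb windows
centered on domain edges, merged when adjacent domains share an edge and
flagged when clipped at a chromosome end.

## TE subfamily enrichment and degenerated TEs

TE subfamilies holding more than 0.1% of the genome are scored. The
enrichment of a query interval set (one TF's peaks, DHS, relic-derived
sites) in subfamily $j$ is

$$\mathrm{ES} = \frac{\text{query bp in subfamily } j \,/\, \text{total query bp}}
{\text{subfamily } j \text{ bp} \,/\, \text{total TE bp}},$$

all lengths in base pairs on flattened footprints (overlapping annotations
of one subfamily are unioned to avoid double counting). For queries derived
from degenerated TEs, the denominator uses non-degenerated elements only.

A degenerated TE (dTE) is a promoter region that retains local sequence
similarity to a TE bound in a sister homoeolog's promoter but carries no
annotated element. For each TE-embedded TFBS, the TE sequence is locally
aligned — both orientations — against the promoters of the sister
homoeologs lacking an annotated copy of that family; alignable regions
overlapping any annotated TE are removed, and optimal alignments longer
than 50 bp are reported. The unparameterised BLASTN call of the original
procedure is replaced by a deterministic threshold set: Smith–Waterman
with match +1, mismatch −2, gap open 5, gap extend 2; minimum length 51
columns; identity at least 60% of alignment columns; a minimum optimal
score of 20 standing in for the database-size-dependent E-value; and an
exact shared 12-mer seed per orientation, mirroring BLAST word seeding.
With this scoring any surviving optimum is effectively above 2/3 identity,
so the length rule is the binding constraint. The TFBS window is projected
through alignment columns and called conserved when at least 70% of it
aligns to bases at 70% or more identity — thresholds reused from the
TFBS-pair similarity criteria. The permutation control re-runs the exact
detection with each TE paired against the promoter of a randomly chosen
different triad; the per-permutation hit counts form the null.

## K2P distances, insertion ages and expansion epochs

Nucleotide distances use the Kimura two-parameter model: with transition
and transversion proportions $p$ and $q$ over gap-free, unambiguous
columns,

$$d = -\tfrac12 \ln(1 - 2p - q) - \tfrac14 \ln(1 - 2q).$$

Zero comparable columns is distinguished from saturation ($1-2p-q \le 0$
or $1-2q \le 0$): the former is an undefined input, the latter a
domain-boundary condition raised as its own error class; distribution-level
operations drop saturated pairs and report the count. Distances are in
substitutions per site ("per 100 bases" is a display scaling only).
Pairwise global alignment (affine gaps, +1/−1/5/1) replaces a multiple
alignment: for two sequences the pairwise optimum is what a pairwise
distance should be computed on, and it is deterministic.

LTR retrotransposons insert with identical 5′ and 3′ LTRs, so the K2P
distance between a copy's two LTRs dates it: $\mathrm{age} = d / (2\mu)$
with $\mu = 1.3\times10^{-8}$ substitutions per site per year by default.
Expansion epochs are profiled from distance distributions: within one
subgenome, pairwise distances of sampled TFBS or TE sequences; across
subgenomes, distances between merged (5′+3′) LTRs of full-length copies,
subsampled proportionally to lineage copy numbers, with lineages under 25
full-length copies skipped. Modes are detected on a Gaussian KDE with
Silverman's bandwidth; a mode must have topographic prominence of at least
5% of the peak density — an explicit detector for what is otherwise a
visual judgement. A family expanded before the subgenome split shows one
common between-lineage mode across all lineage pairs; independently
expanded families show between-lineage modes shifted away from their
within-lineage modes.

## The synthetic polyploid and what it does (not) emulate

`simulate_polyploid()` builds three equal-length subgenomes on a shared
segment mosaic: each segment is present in three, two or one subgenome,
giving exact planted homology classes, and shared segments descend from one
ancestral sequence evolved independently per lineage under the exact
finite-time K2P process (transition:transversion rate ratio 2 — the same
model the estimator assumes, making parameter recovery a fair test). There
are no indels; insertions overwrite background sequence at fixed
coordinates, so coordinates are identical across subgenomes and alignment
blocks, synteny blocks and truth tables are emitted from known homologous
coordinates rather than by running an aligner — homology classification,
not alignment, is the unit under test.

Defaults are chosen as the study conditions: subgenomes of 2 Mb carrying
300 triads and 5 TF peak sets, divergence time 5 million years at $\mu =
1.3\times10^{-8}$ (so sister segments differ by about 0.13
substitutions/site in pairwise distance), an ancestrally expanded
motif-bearing LTR family, an independently per-lineage expanded family
(copy ages uniform on $[0, T]$, LTRs homogenized at insertion), and a
30-copy non-LTR filler family. Gene density is far higher than in a real
wheat chromosome — a deliberate compression so that hundreds of triads fit
in megabases; consequently the homologous genome fraction is higher than
the wheat figures, and homology-fraction statistics are not meaningful
acceptance targets on this toy. Half of the triads carry a promoter TE
fragment; of those, 60% are relic triads where the copy survives annotated
in one subgenome and is degenerated in the two sisters — bases outside the
motif-centered 60-bp window hypermutated at 0.35 per site, the surviving
alignable span drawn uniformly from 80–300 bp, the annotation row dropped.
Each triad's promoter fragment is an independent sequence sharing only the
bound motif with other triads' copies, modelling family members diverged
beyond alignability; this is what makes the permutation null clean, and it
is the regime the detection thresholds are designed for.

Binding is planted per triad: one of the seven patterns drawn from
`balance_mixture` (relic triads are balanced by construction — their
binding site survives in all three promoters), proportions perturbed in a
ball of radius `noise_radius` and projected to the simplex, multiplied by a
lognormal total signal. Peaks for a TF sit at the same TSS offset in all
three promoters (at the motif center where a TE or relic provides it), so
planted proportions pass through the TFAS decay unchanged. Expression is a
monotone power of summed promoter signal with lognormal noise — no noise
model for DAP-seq signal or expression is established for this setting, so
lognormal multiplicative noise is our choice, exposed in the
configuration. DHS intervals around each TSS carry
the summed signal as score.

What the generator does not emulate: read-level noise (peaks are emitted
directly; peak calling is out of scope), indels and rearrangements,
realistic karyotypes and gene spacing, recombination, and TE nesting.
Passing tests on this toy therefore demonstrate the correctness of the
computations and their statistical calibration under the stated model —
not performance on real wheat data, where alignment quality, annotation
error and repeat nesting dominate.

## Numerical and engineering choices

Pairwise alignment is implemented in C++ (Gotoh affine-gap dynamic
programming, local and global, with a linear-memory score-only variant and
an exact shared-k-mer screen); scores follow the `gapOpening +
L * gapExtension` convention of Biostrings, and the test suite cross-checks
scores against `Biostrings::pairwiseAlignment()` on random sequence pairs.
The permutation control runs the seed screen and score-only pass first and
computes a full traceback only for candidates above the score floor —
identical results, a fraction of the cost. Problem sizes in the test suite
(simulated subgenomes of 0.5–2 Mb, 15–50 TE copies per family, 200–1000
permutations) were chosen as the smallest scales at which the statistical
assertions have comfortable margins. Seeds are explicit arguments
everywhere randomness occurs; a simulation is a deterministic function of
its configuration, and repeated runs write byte-identical datasets.

## Known limitations

Region classification assumes the provided alignment blocks are trustworthy
and reasonably complete; it applies the reciprocal rule but cannot recover
homology the aligner missed. The dTE detector reports one optimal local
alignment per TE/promoter pair and orientation — multiple relic fragments
of the same element in one promoter are collapsed into the best one. K2P
saturation makes distances beyond roughly 0.75 substitutions/site
unusable; cross-lineage comparisons of very old families will drop many
pairs and should be read qualitatively. Enrichment scores are ratios of
length fractions and carry no significance measure by themselves; pair
them with a permutation or binomial test when inference is needed.
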