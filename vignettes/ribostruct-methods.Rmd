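---
title: "Models and methods behind ribostruct"
author: "ribostruct maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribostruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostruct)
```

## Scope

ribostruct links in vivo RNA structure probing (SHAPE-Structure-seq) to
translation efficiency and to homoeolog (subgenome) asymmetry in
allopolyploid transcriptomes such as tetraploid wheat. The pipeline starts
from count tables — per-nucleotide reverse-transcription (RT) stop counts
for probed (+) and control (−) channels, and per-transcript RNA-seq and
polysome-seq counts — and ends at riboSNitch calls and population-level
selection statistics. Read mapping, composite-genome variant calling and
UTR re-annotation are upstream of this package; a fully seeded synthetic
generator supplies every input with known ground truth instead.

## SHAPE reactivity

RT stops are converted to rates (`stops / coverage`), the minus-channel
rate is subtracted from the plus-channel rate, and negative values are
clipped to zero. Positions with coverage below `min_coverage` (default 50)
become missing rather than zero; the missingness mask propagates through
all later stages and is never resurrected. The coverage floor is our
choice — it stabilizes the rate estimator at deep but uneven coverage; the
estimator itself is the plain stop-rate difference rather than a
log-ratio drop-off model, matching the simple subtraction description of
the assay, and is isolated in `stop_rate()` so it can be swapped.

Raw profiles are normalized per transcript and replicate with the 2–8%
rule: the top `ceiling(0.02 n)` defined values are set aside as outliers
and everything is divided by the mean of the next `floor(0.08 n + 0.5)`
values. Ties break by value, then position, so results are
bit-reproducible. A worked example: for raw values 0..99 the outliers are
{98, 99}, the divisor is `mean(90:97) = 93.5`, and a raw value of 93.5
would map to 1.0. Transcripts with fewer than 20 defined positions, or a
zero divisor, are dropped with a warning. Replicates are normalized first
and then merged position-wise by the mean of defined values (one missing
replicate leaves the other's value); the inter-replicate Pearson r is
attached for QC. Normalization before merging keeps replicates on a
common scale; the reverse order differs only marginally because the
divisor is close to scale-free.

One consequence of 2–8% normalization matters downstream: the most
reactive bulk class of a transcript always normalizes to about 1, so
normalized reactivities are only comparable across transcripts up to a
per-transcript scale. The riboSNitch caller therefore quantile-matches
one homoeolog's profile onto the other before taking paired differences
(below).

## Secondary structure and base-pairing probabilities

Structures are pseudoknot-free sets of pairs drawn from {GC, AU, GU} with
hairpin loops of at least `min_hairpin = 3` unpaired nucleotides. The
energy of a structure is the sum of its pair energies (defaults GC −3,
AU −2, GU −1) plus, for every paired nucleotide, a SHAPE pseudo-energy
`m·ln(reactivity + 1) + b` with the standard Deigan slope/intercept
(defaults m = 1.8, b = −0.6); missing reactivity contributes nothing.
Boltzmann weights use `exp(−E/kT)` with `kT = 0.6`, a free scale
parameter — temperature effects are out of scope.

This deliberately simple pairwise model — not the nearest-neighbour
Turner rules — was chosen so that an exhaustive enumeration oracle is
exact and affordable: the test suite enumerates every nested structure
for sequences up to 18 nt and requires the dynamic-programming partition
function, per-nucleotide base-pairing probabilities (BPP) and MFE to agree
to 1e−9. The BPP/PPV analyses the package performs downstream are
engine-agnostic, and the energy model is pluggable through
`energy_model()`. Two known consequences of the simplification are worth
stating. First, without stacking there is no helix cooperativity: a
single substitution perturbs pairing only locally, so sequence-only
folds of two homoeologs differ near the variant rather than flipping
whole helices. Large structural flips instead enter through the SHAPE
channel, which is also how they are observed experimentally. Second,
homopolymeric helices carry register entropy that caps per-position BPP
below one.

`bpp[i]` is the probability that nucleotide *i* is paired to **any**
partner (the complement of single-strandedness); the inside–outside
recursion is O(n³) with per-position rescaling for numerical range, and
`p(i,j)` is exposed as a matrix when requested. The MFE traceback is
deterministic: ties prefer leaving a nucleotide unpaired, then the
nearest partner. Transcripts longer than `window = 300` nt are folded in
sliding windows stepped by 150 nt with per-nucleotide BPP averaged over
covering windows (the O(n³) cost makes whole-mRNA exact folds
impractical, and windowed folding reflects the locality of most mRNA
structure); the reported dot-bracket is assembled from non-overlapping
blocks and is local in the same sense.

Agreement with a reference structure uses the conventional reactivity
bands: nucleotides above 0.6 should be single-stranded in the reference
(true positives), nucleotides below 0.3 should be paired (true
negatives), and the 0.3–0.6 band is excluded. PPV treats the in vivo
(SHAPE-directed) structure as predicted and the in silico or
phylogenetic structure as reference.

## Translation efficiency and codon metrics

TE is the ratio of polysome to RNA abundance, computed per replicate on a
length-normalized per-million (TPM) scale by default; a plain per-million
mode exists because within-pair ratios are robust to length
normalization. The point estimate is the mean of replicate TEs and is
missing when RNA abundance is zero in any replicate. Differential TE
between homoeologs is a two-sample Student t test on log2 per-replicate
TEs, Benjamini–Hochberg corrected across pairs; TE enters all
correlations as log2, which is natural for a ratio quantity.

CAI and tAI are geometric means of per-codon relative adaptiveness
(`r = f / max f` over synonymous codons; tAI weights normalized to
max 1), computed in log space, with the stop codon excluded and
N-containing codons skipped with the codon count decremented.

Metagene profiles anchor transcripts at the start and stop codon and
rescale each region to fixed bins (50/100/50); 3-nt periodicity of the
CDS profile is the magnitude of the discrete-Fourier component at period
three normalized by the total signal, giving 1 for a pure (x,0,0) repeat
and 0 for a flat profile.

## Homoeolog asymmetry

Structural asymmetry of a pair is a two-sample Wilcoxon rank-sum test on
the per-nucleotide BPP values of the two homoeologs (a per-transcript
mean-BPP variant backs the summary tables). Treating nucleotides as
exchangeable units ignores their serial correlation along the molecule;
with shared underlying structure the test is conservative, and it is
calibrated when the two BPP samples are genuinely distribution-identical
— both behaviours are exercised by the tests. The |ΔBPP| vs |ΔTE|
coupling is a Pearson correlation on absolute values (ΔTE on the log2
scale, ΔBPP as the difference of regional mean BPP), globally, per
region, and per user-supplied functional group (groups need at least ten
pairs; group significance is BH-flagged).

## riboSNitch calling

Homoeolog pairs are aligned with an affine-gap Needleman–Wunsch aligner
(match +1, mismatch −1, gap open −4, extension −1 per gapped position,
deterministic tie-break diagonal > up > left), validated against an
exhaustive alignment-path oracle. SNVs are mismatch columns with both
bases in ACGU; columns containing N are dropped and counted; indels are
maximal gap runs. eSDC is `(1 − r)·√L` over the L jointly defined aligned
columns.

A riboSNitch is an SNV whose neighbourhood shows significant differences
of both BPP and reactivity: within ±50 alignment columns, paired Wilcoxon
signed-rank tests on the per-column BPP differences and (quantile-matched)
reactivity differences, with a floor of 0.1 on both window
mean-absolute-difference effect sizes, raw p < 0.05 on both tests, and BH
adjusted p-values carried alongside (an adjusted-call mode is a flag).
The quantile matching removes the per-transcript normalization scale
noted above; without it a global offset between two profiles can mask a
local flip, which we observed directly on constructed fixtures. The mean
absolute difference was likewise chosen over a median because a
structural flip affects a contiguous minority of the window, where a
median is blind. SNVs closer together than half a window are tested
jointly as a cluster and flagged non-isolated; SNVs without 20 defined
aligned window positions stay untested and are excluded from riboSNitch
ratios (a strict mode keeps them in the denominator).

## Population genetics

Allele frequencies are per-subpopulation count fractions; the major
allele is the most frequent one with alphabetic tie-break. F_ST for a
site is `σ²_π / (π̄ (1 − π̄))` with the population variance (divide by the
number of subpopulations; a sample-variance mode is a flag) of the global
major allele's frequency — for biallelic sites the choice of allele does
not matter, which a test asserts. Conservation ratios count, per
transcript and SNV class, the sites at which the reference homoeolog's
allele is the reference subpopulation's major allele. Diploid genotypes
contribute two allele counts; missing calls contribute none.

## The synthetic generator

All generator defaults are the study conditions the package is tested
under, fixed once:

* Homoeolog pairs: transcript lengths ~N(500, 50²) nt with ~15% 5′UTR,
  60% CDS (codon multiple), substitutions at 4.58% with 2:1
  transition:transversion weight, indels at 0.2% per nucleotide (1–3 nt
  in UTRs, 3 nt in CDS to preserve frame, outside a 10-nt boundary
  buffer).
* Probing: coverage ~Poisson(200) per position and channel, two
  replicates; plus-channel stops ~Binomial(coverage, background + mod
  rate) with background 0.02 and modification 0.10 for single-stranded,
  0.01 for paired, and 0.25 for hyper-exposed nucleotides (a melted helix
  is fully solvent-exposed, beyond a generic unpaired residue); RT stops
  are independent per position — no drop-off cascade, matching the
  reactivity estimator's assumptions.
* Expression: negative-binomial counts (dispersion 0.01, consistent with
  the near-perfect replicate correlations reported for such libraries)
  around a mean of 500, three replicates, per-pair true log2 TE
  differences ~N(0, 0.8²) with 30% of pairs forced null — an effect-size
  spread chosen so that a large minority of pairs is genuinely
  translationally asymmetric.
* Population: 13/29/28 accessions for the durum (DW), domesticated emmer
  (DEW) and wild emmer (WEW) subpopulations; riboSNitch-labelled sites
  get divergent per-subpopulation allele frequencies (near-fixed in DW),
  other sites share one frequency; diploid genotypes drawn binomially.

Each generator seeds its own documented RNG stream (seed + fixed offset),
so outputs are reproducible regardless of call order.

riboSNitch test fixtures are a separate constructed family: a single
GU-wobble hairpin (13-nt arms) inside unpairable N flanks, with ground
truth "paired" for the A allele and "melted/hyper-exposed" for the B
allele whose mid-stem G→A substitution destabilizes the helix in vivo.
The long flanks keep the melted stem in the outlier tail of the 2–8%
normalization so its reactivity normalizes near 2; probing, reactivity,
SHAPE-directed folding and calling then run exactly as for real data, and
power is assessed over the fixtures whose realized |ΔBPP| reaches 0.5 at
ten or more positions. Null fixtures keep both alleles paired and park
the SNV in a distal poly-A segment.

What the generator does not emulate: RT drop-off cascades and local
sequence bias of the SHAPE adduct, splice isoforms, mapping ambiguity
between subgenomes, linkage between population sites, and real codon
usage. A green test suite therefore demonstrates correct statistical
machinery and recoverable ground truth under these idealized conditions,
not field performance on real libraries.

## Problem sizes and numerical choices

The default synthetic study uses 50 pairs of ~500-nt transcripts; the
test suite folds windows of ≤300 nt, checks the folding engine against
enumeration up to 18 nt, runs 500 null fixtures for the false-positive
rate, and 1000 pairs for null TE calibration — sizes at which every check
runs comfortably on a laptop. Partition-function arithmetic uses
per-position rescaling keyed to the MFE energy density (with automatic
retry at a larger safety factor) rather than log-space accumulation.
Degenerate inputs are defined, not errors: sequences with no legal pair
give all-zero BPP and log Z = 0; empty regions give missing means;
zero-coverage probing gives all-missing reactivity.

## Known limitations

The pairwise energy model under-represents cooperative rearrangements;
windowed BPP is an average over local ensembles, not a transcript-wide
ensemble; the Wilcoxon nucleotide test ignores autocorrelation (it is
conservative in the realistic shared-structure case); TE testing with
two or three replicates has limited per-pair power, so pair-level
significance calls are better read in aggregate; and the riboSNitch
census of a real transcriptome depends on thresholds (window, effect
floor, alpha) that the output records in its headers.
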