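---
title: "STR genotyping from nanopore amplicons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STR genotyping from nanopore amplicons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanostr)
```

## The problem

A short tandem repeat (STR) locus is a stretch of 3–5 nt units repeated
in tandem; forensic genotyping reports each allele as the CE-compatible
designation `n` or `n.r` (n full units, r leftover bases, e.g. 24.2).
Nanopore amplicon reads span the whole repeat, but at a 3–6 % per-base
error rate no single read can be trusted to carry the exact repeat count,
and indel errors concentrate in homopolymer-like repeat tracts. Callers
that align reads to a database of known allele sequences inherit the
database's blind spots: an undocumented variant allele is either dropped
or silently forced onto its nearest catalogued neighbour. `nanostr`
instead reconstructs each allele's sequence *de novo* from read
consensus, then interprets it with only the locus's repeat motifs.

## The pipeline

For each panel locus (reference coordinates of the repeat core,
prefix/suffix flanks, motif set, period):

**1. Spanning reads.** Primary alignments whose aligned reference span
contains the padded core (`[core_start - 3, core_end + 3]`) are taken
from the indexed BAM. Soft-clipped tails belong to the read sequence but
not to the span; secondary/supplementary records are excluded. BAM `SEQ`
fields are already reference-oriented, so no re-orientation is needed.
No mapping-quality or length filter is applied: spanning + primary is the
whole contract, and the flank-identity gate downstream removes chimeric
or misassigned reads more directly.

**2. Core trimming.** Each flank is located in the read by local
(Smith–Waterman) alignment with affine gap penalties. The core is cut
between the flank hits, retaining 3 flank bases on each side (the "pads").
Reads are rejected with an enumerated reason when a flank's identity —
defined as matching columns divided by the *full* flank length, so that a
short chance hit in a flank-less read cannot masquerade as an anchor —
falls below `min_flank_identity`, or when the two hits cross. If a pad
would run past the read edge it is truncated instead of rejecting the
read. Ties between equally scoring flank placements are resolved
outermost (leftmost for the prefix, rightmost for the suffix; implemented
by aligning reversed sequences for the suffix), which maximises the
enclosed core when repeats bleed into a flank.

**3. Clustering.** Trimmed cores (pads included) that are identical or
related by exactly one substitution form one group. "One substitution, no
indels" is deliberate: a 1-nt indel changes the core length and would
corrupt a length-based designation, so indel-bearing reads found their
own (small) clusters. Distinct sequences are processed in descending
order of exact multiplicity with a lexicographic tie-break, each joining
the first cluster whose representative is within one substitution — this
makes the partition independent of read order. A cluster's size is the
supporting-read number (SN); SNR is SN over the largest cluster's SN. The
top three clusters are the candidate alleles.

**4. Repeat-structure inference.** A candidate sequence is decomposed
into tandem motif runs (`[MOTIF]count`) and literal interrupts. The
search is recursive branch-and-score: every *maximal* run of every motif
in a still-undecomposed region spawns a branch, and the regions to the
left and right of a placed run are solved independently (they can never
interact again), which lets results be memoised per region; a branch ends
when its regions contain no motif occurrence. Recursion depth is capped
(default 50) as a hard stop. Each terminal decomposition is scored

    score = (# non-motif bases) + (# non-motif parts)

with one contiguous interrupt segment counting as one part, and the
minimal score wins. Equal unit weights are the natural reading of
"fewest non-motif bases and parts" and are not separately configurable;
the score is integer and small, so ties do occur and are broken
deterministically: fewer blocks, then a longer leftmost run, then the
lexicographically smaller bracket string. The bracket notation
round-trips: `expand_structure(infer_structure(s, motifs)$bracket)`
reproduces `s` exactly, for every input.

Two properties of this search are worth stating. First, restricting
branches to *maximal* runs does not sacrifice optimality in practice: on
exhaustive small inputs and hundreds of repeat-rich random sequences the
search score equals a brute-force dynamic-programming minimum over *all*
segmentations (the test suite asserts this). Second, the phase of a run
is not identifiable from sequence alone — `ATC_[TCGT]12_GGT` and
`ATCT_[CGTT]12_GT` describe the same bases — so equal-score phase
variants are possible; the tie-break makes the reported one
deterministic, and the designation is unaffected (see below).

**5. Designation.** The allele number is length-based:
`L = core_len − pads + designation_offset`, designation
`floor(L/period)` with `.{L mod period}` appended when non-zero. Summing
bracketed run counts instead would *undercount* variant alleles whose
interior interruptions are period-sized (a 98-nt period-4 core with 10
interior non-motif bases is allele 24.2, not 22): forensic nomenclature
counts length, not motif copies. `designation_offset` is the hook for
locus-specific nomenclature corrections (loci whose conventional allele
numbers are offset from the raw repeat length); it defaults to 0.

**6. Genotype call.** Candidates one full period shorter than a stronger
candidate with SNR below `stutter_snr` are removed as stutter artifacts.
The remaining candidates, sorted by SN, pass a decision ladder:

| condition | result |
|---|---|
| no candidates, or major SN < `sn_interpretation` | `Interpretation` |
| single candidate | `Pass`, homozygote |
| minor SNR ≥ threshold and minor SN ≥ `sn_allele` | `Pass`, heterozygote |
| minor SNR ≥ threshold but minor SN < `sn_allele` | `Imbalance` |
| minor SNR < threshold | `Pass`, homozygote (major) |

The last row is a deliberate choice: a minor candidate that fails the
SNR test is treated as noise and the locus is called homozygous rather
than flagged, because sub-threshold minors are overwhelmingly
error/stutter clusters; the `Imbalance` flag is reserved for the
genuinely ambiguous middle ground (convincing ratio, unconvincing count).

## Thresholds and their calibration

| parameter | default | meaning |
|---|---|---|
| `sn_interpretation` | 10 reads | coverage floor for any call |
| `sn_allele` | 25 reads | SN a minor allele needs for a confident heterozygote |
| `snr_het` | 0.30 (per locus) | minor/major ratio above which heterozygosity is entertained |
| `stutter_snr` | 0.30 | SNR ceiling for the one-unit-short stutter filter |
| match/mismatch/gap open/extend | 2 / −3 / 5 / 2 | flank alignment scores |
| `min_flank_identity` | 0.75 | flank anchor acceptance |
| `max_iterations` | 50 | structure-search depth cap |

The SN defaults suit deep amplicon sequencing (hundreds to thousands of
spanning reads per locus). They are *calibratable*: `sweep_thresholds()`
re-calls a truth-paired candidate set over the full SN grid (0–50 by 5)
× SNR grid (0–1 by 0.01), scoring per-locus accuracy as the proportion
of **all** truth items called exactly right — dropped
(`Interpretation`/`Imbalance`) items count against accuracy, otherwise
any threshold could look perfect by dropping its mistakes. The per-locus
SNR threshold is the median of the SNR values attaining peak accuracy at
the chosen SN; `select_sn_threshold()` picks the smallest SN at which
every locus's peak accuracy reaches 0.95 (falling back to the best mean
peak). `recovery_experiment()` packages the whole workflow: calibrate on
training replicates, evaluate on fresh ones.

The flank alignment scores are conventional Smith–Waterman values; the
method is insensitive to them so long as the flanks are ≥ 30 nt, which is
why the panel format recommends that flank length.

## The simulator

`simulate_reads()` emulates the failure modes the caller is built for:
uniform per-base substitutions, insertions and deletions; an indel-rate
multiplier (default 3×) inside homopolymer runs ≥ 4 nt; and stutter —
with probability `stutter_prob` a read loses exactly one unit from its
longest run. Reads cover the full amplicon (flank + core + flank), carry
constant Q20 qualities (the caller never reads qualities), and are
emitted pre-aligned: POS/CIGAR are derived by global alignment of the
noisy read against the amplicon window of the toy reference, so tests are
hermetic and need no external aligner (`--fastq-only` in the CLI supports
out-of-band alignment instead). Minus-strand records keep SEQ
reference-oriented, as an aligner would store it. Everything is
deterministic under the error model's seed, which is isolated from the
caller's RNG state.

What the simulator does *not* model: chemistry-specific error profiles
(R9 vs R10 differ only via the rate settings), quality-correlated errors,
PCR chimeras, multi-contributor mixtures, and real inter-locus coverage
imbalance. Passing the simulated benchmarks therefore demonstrates the
*algorithmic* contract — correct reconstruction and calling under iid
noise plus stutter — not field performance on casework samples.

Toy panels (`build_toy_panel()`) use random 40-nt flanks, random
non-homopolymer motif sets and a 10-unit reference allele per locus,
concatenated into one contig with recorded coordinates. Simulated truth
genotypes (`simulate_genotypes()`) draw unit counts uniformly from 8–14
(the common span of forensic core loci) with heterozygote probability
0.5. Evaluation experiments use a 3-locus panel, 50 training and 200
evaluation replicates at 100× — sizes chosen so the full validation runs
in minutes on one CPU while keeping per-locus counts meaningful.

## What depth buys, and a known limitation

A read supports its allele's cluster only if its trimmed core is
error-free or one substitution away. For a core of length L at per-base
error rate e that probability is roughly `(1−e)^L (1 + 0.6eL)` — about
0.13–0.25 for L between 38 and 62 nt at e = 0.05. At 100× a heterozygote
allele therefore expects a cluster of only ~6–11 reads, colliding with
the fixed coverage floor (10) and any sensible minor-allele SN. The
consequences, which `recovery_experiment()` quantifies and the acceptance
script reports: at 100× with 3 % substitutions + 2 % indels the calling
ratio sits near 0.6 and exact-match accuracy among called results near
0.9, with the residual errors concentrated in heterozygotes whose alleles
differ by three or more units (the longer allele's cluster starves
first). At 300× the same experiment clears 95 % accuracy with a ~0.99
calling ratio under the *default* thresholds — the regime the defaults
were designed for. Deep coverage is not a luxury for this method; it is
the mechanism by which per-read error is converted into consensus
certainty.

## Kinship statistics

`identity_lr()` is the random-match product rule under Hardy–Weinberg:
per-locus LR `1/p²` (homozygote) or `1/(2 p_a p_b)` (heterozygote),
multiplied across loci in log space. `paternity_index()` implements the
standard Essen-Möller trio and motherless-duo forms by explicit
enumeration of consistent maternal/paternal transmissions — X sums
transmission probabilities over the alleged father's alleles, Y replaces
his transmission with population frequencies. No mutation model, no
coancestry (θ) correction, no sibship indices: an incompatible locus is
an exclusion (PI 0) with a warning, and alleles absent from the frequency
table are an error unless an explicit `min_freq` floor is supplied. A
combined PI above 10⁴ is flagged "confirmable", the conventional
standard for parent–child confirmation. Note that a *true* trio can
still show a per-locus PI below 1 when a heterozygous father carries a
common obligate allele (transmission ½ < allele frequency); only the
combined statistic is meaningful.

## Degenerate inputs and numerical choices

* Sequences shorter than the period become a single interrupt
  (score = length + 1).
* An empty spanning-read set, or one with no usable fragments, yields
  `Interpretation` with zeroed tallies, not an error.
* A locus missing from a per-locus `snr_het` map is a configuration
  error — there is no silent fallback; a single unnamed `snr_het` value
  is an explicit all-locus default.
* Cluster and candidate orderings break every tie lexicographically, so
  reports are byte-identical across runs and locus processing orders.
* Combined LR/PI values are accumulated as sums of logs; per-locus
  tables carry the raw values.
* Internal coordinates are 1-based closed (the Bioconductor convention);
  panel files may declare `coord_system: 0based` and are converted at
  load.

## Limitations

Beyond the depth requirement above: no mixture deconvolution (the top-3
candidate cap assumes a single contributor; a tri-allelic pattern
surfaces as an unexpected strong third cluster, not a call); no
sex-chromosome or SNP marker support; no CRAM; no signal-level
(squiggle) analysis; locus-specific designation corrections must be
supplied by the user through `designation_offset`, the package ships
none.
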