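---
title: "Validation-based denoising of multiplexed amplicon pyrosequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation-based denoising of multiplexed amplicon pyrosequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdenoise)
```

## The problem

Marker-gene amplicon surveys (for example 18S or 16S rRNA fragments
pyrosequenced from environmental DNA) observe far more unique sequences
than there are templates in the sample. The excess comes from three
well-characterised error processes: DNA-polymerase substitutions
introduced during PCR, chimeric molecules formed when an aborted
extension product primes a different template, and the
insertion/deletion miscalls at homopolymer runs that dominate
pyrosequencing error. Left in place, these artefacts inflate richness
estimates by orders of magnitude, especially in the low-abundance tail
where the "rare biosphere" lives.

`ampdenoise` takes the *validation* route to this problem rather than
the read-correction route. Algorithms that map or cluster reads onto
inferred parent sequences must pick one representative per cluster and
can therefore canonise an error as a parent. Here no read is ever
edited, merged or reassigned: every unique observed sequence is either
*validated* -- judged to be a real template sequence -- or rejected, and
the validated set is always a subset of the observed set. The evidence
used is purely distributional, resting on three assumptions about
errors: they co-occur with their parent sequences across samples; they
have fewer reads than their parents; and their abundance relative to the
parent is predictable from the error type.

## The four validation steps

**Filtering and binning.** A read is accepted only if it contains an
exact match to the forward MID+primer at its 5' end and (unless
long-amplicon truncation mode is on) the reverse-complemented reverse
primer towards its 3' end, followed by a known reverse MID. Quality
scores are deliberately not used; exact primer/MID structure is the
acceptance criterion. Accepted reads are trimmed, binned by identical
sequence and assigned to samples, giving a unique-sequence x sample
count table. Rows containing ambiguous bases, rows still containing a
primer occurrence, and *global singletons* (one read in the whole
dataset) are removed. Local singletons -- one read in a sample but more
elsewhere -- are kept. Singleton removal is the one step that guarantees
real single-read templates are lost; the trade-off is deliberate and is
probed directly by a test (a template emitted once is never validated).

**Cross-sample (preliminary) validation.** Sequences are grouped either
by the accession of an externally supplied best-hit table or, reference
free, by abundance-sorted 2% single-linkage preclustering. Within a
group, the most abundant sequence is provisionally accepted unless it
is only ever a local singleton, or is rare (fewer than 10 dataset
reads) and confined to one sample; a rare sequence therefore needs at
least 3 reads, presence in more than one sample, and at least 2 reads
somewhere. Every other group member is kept only if it occurs in
samples the top sequence does not, or co-occurs with it at a relative
frequency of at least `freq_cutoff` (default 0.50) in some shared
sample -- errors co-occur with their parents at far lower frequencies.
The single-sample variant (`mode = "SS"`) waives the multi-sample
requirement, lowering the absolute floor from three reads to two.

**Within-sample (secondary) validation.** Groups are now ignored;
within each sample, sequences are ranked by abundance (single-read
sequences are *ambiguous* and excluded). For a candidate daughter and
more abundant sequences of the same sample, three tests apply:

* *indel test* -- if a pair differs only by indels, the lower-ranked
  member is a potential homopolymer miscall and is flagged invalid in
  that sample (no abundance threshold: such errors can be both abundant
  and reproducible);
* *substitution test* -- a daughter differing from a more abundant
  sequence by $n$ substitutions only is flagged when its reads fall
  strictly below $a x^n$, with $a$ the parent's in-sample reads and
  $x = 0.02$ by default;
* *chimera test* -- for each pair of more abundant parents, the
  daughter is scanned left to right along the three-way alignment; if
  it mismatches both parents anywhere it cannot be their chimera,
  otherwise the number of switches $s$ between matching one parent and
  the other is counted and the daughter is flagged when its reads fall
  strictly below $b y^s$, with $b$ the less abundant parent's in-sample
  reads and $y = 0.15$ by default.

Flags never cross samples: a sequence invalid in one sample may be
valid in another.

**Final validation.** Valid observations are collated per sequence and
compared with the replication design: either at least $k$ valid
observations anywhere (default $k = 1$, appropriate without technical
replication), or -- with replicate blocks defined -- a valid observation
in every sample of at least one block. Ambiguous observations never
count as valid, and invalid observations are not vetoes. A sequence is
retained iff it passed the cross-sample step and meets the design rule.

The design fixes a *detection floor*: a valid observation needs two
reads in its sample, so the minimum dataset reads is twice the number
of simultaneously valid samples the rule demands, never below the
cross-sample floor (3 MS / 2 SS). `detection_floor()` computes this;
for example 4-of-5 replicates gives 8 reads, all-3-within-one-center
gives 6, MS with $k=1$ gives 3, SS gives 2. The floor is independent of
sequencing depth, so deeper sequencing makes ever-rarer sequences
validatable.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `freq_cutoff` | 0.50 | minimum co-occurrence frequency (fraction of the group's top sequence, per sample) for an additional group member |
| `rare_dataset_bound` | 10 reads | below this a sequence is "rare" and the multi-sample rule applies (MS) |
| `rare_min_reads_ms` / `rare_min_reads_ss` | 3 / 2 reads | absolute dataset floors of the two modes |
| `sub_x` | 0.02 | per-mismatch abundance proportion of the substitution test ($a x^n$) |
| `chi_y` | 0.15 | per-switch abundance proportion of the chimera test ($b y^s$) |
| `min_valid_obs` / `blocks` | 1 / none | replication-design threshold of the final step |

The defaults are the values calibrated on positive-control Titanium 18S
amplicon runs and are conservative; all are user-settable, and a
different platform or chemistry should re-derive `sub_x`/`chi_y` from
its own positive controls.

## Numerical choices

The original workflow delegated three-way alignment to an external
multiple aligner. For bit-reproducibility this package aligns
internally and deterministically: pairwise global alignment with free
terminal gaps, scored match $+1$, mismatch $0$, gap $-1$. A
cost-minimising formulation with free terminal gaps would be degenerate
(a fully staggered alignment of terminal gaps has zero cost), whereas
this scoring always prefers full overlap of two same-locus amplicons,
however divergent. Ties break match over mismatch over a gap in the
shorter sequence, and gaps are left-shifted through homopolymer runs so
indel placement is canonical. The daughter is then aligned to the
two-row parent profile with the same scheme (a daughter base matching
either parent, or a daughter gap mirroring a parent gap, scores $+1$).
Terminal-gap columns are excluded from mismatch counts, distances and
the chimera scan, so early-terminating reads are not penalised.
Pairwise distance for preclustering is (substitutions + indels) /
alignment columns, terminal gaps excluded. Thresholds are compared with
strict "fewer than" and never rounded. Sequence ties at equal abundance
are broken lexicographically everywhere, which makes grouping, ranking
and flagging order-independent; the pipeline is fully deterministic and
only the simulator consumes a seed.

Two readings of the published rules were genuinely open and were
resolved as follows. The co-occurrence test passes if *any* single
shared sample reaches the cutoff (one high-frequency observation is
evidence of independence from the parent). The rare-sequence bounds
apply to additional group members as well as the top sequence, since
the detection floor is stated uniformly for all validated sequences.
When a group's top sequence is rejected, the next-ranked member is
promoted and re-evaluated, so one bad seed does not annihilate a group.
The indel test flags the lower-ranked member of any indel-only pair.
Valid observations are counted per sample, not per read, and invalid
observations do not veto. In the secondary step the cheap pairwise
indel/substitution tests run before the chimera triples with early exit
at the first flag; only the label of the firing test, not the
valid/invalid outcome, depends on this order.

## The synthetic mock community

`mock_design()` / `simulate_mock()` emulate a positive-control
experiment: 16 clone sequences in three dilution groups (eight at
relative concentration 1, six at 0.1, and a near-identical pair -- a
simulated heterozygote two substitutions apart -- each at half the
group-2 concentration), amplified in five replicate "PCRs" of 2000
reads, each replicate carrying its own MID pair. The published ratios
between dilution groups are not available in machine-readable form, so
1 : 0.1 : 0.05 was chosen once as representative of a two-orders-of-
magnitude abundance range and kept; with the default depth the rarest
clones sit near 11 reads per replicate, comfortably above the 8-read
floor of the 4-of-5 design but far from trivially abundant.

Errors are injected per final read, not per PCR cycle: substitutions at
`2e-4` per base, indels at `1e-3` per homopolymer run (length >= 2,
insertion or deletion with equal probability -- the pyrosequencing error
mode), and single-breakpoint chimeras at `0.01` per read with parents
drawn proportional to concentration and the breakpoint uniform over the
interior. These rates were fixed analytically before any pipeline run
so that the expected abundance of each specific error variant lies well
below the default thresholds (`expected_error_abundance()` gives the
closed forms); the spike-in mechanism of `simulate_mock()` is then used
to place sequences deliberately *above* a threshold, e.g. a 1-mismatch
variant at 60% of its parent's reads, which the pipeline must retain as
a demonstrated false positive.

What the generator does *not* emulate: per-cycle PCR lineages (so error
abundances are binomial around their expectation rather than
branching-process distributed), flowgram-level noise, quality strings,
length-dependent amplification bias, and contamination. Passing the
mock tests therefore shows that the rules are implemented faithfully
and that the thresholds separate errors from templates under the
assumed error model -- not that the defaults are optimal for any
particular real dataset.

## Problem sizes and limitations

The shipped tests and examples run the full pipeline on the default
mock (10^4 reads, 5 replicates, ~600 unique sequences before
filtering), which completes in a few seconds; the enumeration oracle
for the chimera scan is checked on alignments up to 12 columns where
exhaustive enumeration (2^12 label assignments) is feasible.

Known limitations, inherent to the method: real global singletons are
always lost; long amplicons that rarely reach the reverse primer lose
most reads at filtering (truncation mode trades resolution for yield);
under-sampled high-diversity communities can see real rare sequences
rejected when replication is absent; and best-hit grouping makes the
cross-sample step semi-supervised (preclustering mode removes that
dependence). The chimera scan is deliberately not probabilistic -- a
daughter mismatching both parents anywhere is simply not their chimera
-- which keeps the test conservative.

## A minimal run

```{r example}
design <- mock_design(seed = 42)
sim <- simulate_mock(design)
res <- run_pipeline(sim$reads, mock_spec(design),
                    replication_design("MS", min_valid_obs = 4))
res
length(validated_sequences(res))
all(sort(unname(validated_sequences(res))) == sort(design$clones$sequence))
```
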