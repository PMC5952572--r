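---
title: "Contaminant-aware small RNA-seq analysis: models and methods"
author: "srnaclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contaminant-aware small RNA-seq analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaclean)
```

## The problem

Sequencing-based surveys of low-biomass samples — blood plasma above all —
are vulnerable to nucleic-acid contamination carried by laboratory
reagents. Silica-column miRNA extraction kits can shed small RNAs into
every eluate; in sRNA-seq data from plasma these reagent-borne sequences
masquerade as "exogenous" (non-host) RNAs of microbial, plant or fungal
origin. Because the contaminants enter at a roughly fixed amount per
extraction column while genuine sample RNA scales with the sample input,
their relative abundance is inversely proportional to the input volume —
the tell-tale signature this package measures and exploits.

`srnaclean` implements the complete quantitative workflow around this
problem:

1. **Preprocessing** of raw sRNA-seq reads: recursive 3' adapter
   trimming, 5' N clipping, quality filtering, and collapsing of
   identical reads into unique sequences with abundances.
2. **Attribution** of collapsed reads to host vs non-host references,
   with a shuffled-decoy specificity filter, locus construction and
   cross-mapping correction of multi-mapped counts.
3. **Contaminant identification** from extraction-control libraries
   (mock extractions, column eluates, water and no-template controls)
   and a primer-based matching rule tying read sequences to qPCR assays.
4. **Absolute quantification** via a spike-in of known concentration and
   via qPCR standard curves with second-derivative Cq calling.
5. An **exogenous-candidate cascade** that filters non-host sequences
   down to credible exogenous sRNA candidates.
6. **Titration analysis** determining the minimal safe input volume that
   suppresses contaminant signals below a tolerance (default 100 cpm).
7. A **synthetic-data module** that generates references, libraries and
   qPCR curves with the statistical structure the analysis assumes, so
   every stage is testable without external data.

## The composition model (synthetic data)

A simulated library draws its reads multinomially from a copy-number
pool:

* sample-borne (host) sRNA: `endogenous_copies_per_uL * V` copies, split
  across planted host loci with fixed log-normal weights;
* column contaminants: a fixed `contaminant_copies_per_column` per
  sequence, independent of `V`; ultra-clean columns divide these by
  `ultraclean_factor` (default 60, the median fold-reduction observed
  for ultra-clean production columns);
* planted exogenous sRNAs: `exogenous_copies_per_uL * V` (they scale
  with the sample, so their relative abundance is volume-independent);
* spike-in: `copies_per_uL_eluate * eluate_volume_uL` copies (default
  40,000 copies/uL in a 14-uL eluate), added to libraries whose
  metadata requests it;
* water/no-template controls: nothing except configurable carry-over
  (default zero).

Each read is the sRNA insert with independent per-base substitution
errors (default 0.001), followed by the 3' adapter, padded to 75-nt
single-end reads; qualities are constant Q36 with an option to inject
low-quality reads for filter testing. RNA sequences are stored in the
DNA alphabet (`U -> T`), as a sequencer emits them.

Because contaminants are fixed per column while everything else scales
with `V`, the inverse-volume law (log-log slope −1 of contaminant cpm
vs `V`) is *emergent*: nothing in the generator encodes the slope.
With the default pool the sample-borne fraction dominates, so the
realized slope is slightly shallower than −1 (about −0.96; the fixed
spike-in and contaminant copies contribute a small volume-independent
term to the denominator).

Default scales: 2e5 sample-borne copies/uL (so a 100-uL extraction is
dominated by host RNA, with the spike-in at a few percent — spike-ins
should be used near sample levels, not above), contaminant copies per
column following the relative abundance profile of the six confirmed
contaminants with the most abundant near 5000 cpm at 100 uL on a regular
column, and exogenous sRNAs at 4 copies/uL (about 20 cpm, the scale at
which genuine exogenous candidates appear in plasma). The default
titration volumes are 45, 100, 225, 500 and 1115 uL; the default study
design is 28 plasma libraries (5 volumes x 2 column types, replicates
3/3/3/3/2 per column — replication per titration point is exposed as
configuration because published designs use unequal replication) plus
mock, eluate and water controls.

## Preprocessing rules

The chain is fixed: trim -> clip -> quality filter -> collapse.
Adapter occurrences are removed recursively (a pass that removes
nothing terminates the loop); an occurrence is the adapter or an
end-truncated prefix of at least 10 nt, with at most 1 substitution.
The mismatch tolerance is a design choice: exact-only matching would
leave adapters on roughly `1 - (1-e)^21` of reads at substitution
rate `e`. Reads shorter than 15 nt after
trimming/clipping are discarded (shorter sequences are effectively
unmappable and inflate artefact counts). The quality rule retains a
read iff at least 90% of its bases have Phred quality at least 30.

Count tables retain, in study mode, only sequences seen at least 30
times in all analysed libraries together — read literally as the sum
across libraries, which keeps sequences concentrated in a single
library (robustness against multiplexing errors is the stated purpose
of such thresholds). Public-dataset mode instead removes singletons
only, because external studies differ in design and depth. Library
sizes are recorded *before* row filtering so cpm stays anchored to
retained-read totals.

## Attribution

`map_reads()` reports **all** substitution-only alignments with at most
2 mismatches, on both strands — sRNA reads are too short for indel
alignment to add information, and the mismatch tiers used for host
attribution are substitution counts. Host attribution takes priority:
any sequence with a host hit is host, regardless of what else it hits.

The decoy filter shuffles each read (uniform permutation of its
nucleotides, seeded, preserving length and composition) and retains a
non-host genome only if (a) it recruits at least one real read of at
least 25 nt and (b) strictly more real reads than decoy reads. The two
criteria are independently switchable because the underlying
recommendation conjoins two sentences whose logical connective is
ambiguous; the conjunction is the conservative reading.

Cross-mapping correction redistributes multi-mapped counts by
iterative proportional allocation: locus weights start from uniquely
mapping reads; each multi-mapped read's count is split across its loci
in proportion to current weights, and the procedure iterates to a
fixed point (tolerance 1e-6, cap 100 iterations, warning on
non-convergence). When none of a read's loci have any unique evidence
the count is split uniformly — the symmetric limit. Each read's
allocation sums exactly to its count, so totals are conserved by
construction. (An additive pseudocount on the initial weights was
considered and rejected: it distorts the canonical two-locus example —
unique counts 10 and 2 sharing a read of 6 must allocate 5:1, which
requires the weights to be the unique counts themselves.)

Coordinates are 0-based half-open internally and in BED export; SAM
export is 1-based as the format requires.

## Contaminant identification and quantification

A sequence is assigned to a contaminant assay iff it shares an exact
(100% identity) block of at least 14 nt with the assay's primer, the
read being allowed to extend beyond the primer. This is implemented as
longest-common-substring matching, which is equivalent to
100%-identity local alignment of unsubstituted blocks and exactly
testable; ties go to the longest overlap, then panel order. The
packaged panel carries the six qPCR-confirmed column contaminants with
their primers and annealing temperatures, and is checked at load time
for self-consistency (every primer matches its own sRNA).

Sequences detected in more than half of the extraction-control
libraries (at >= 1 copy) are flagged as contaminants; the spike-in is
exempt. The 50% presence default is deliberately looser than the
cascade's 90%-absence rule below — flagging is a screen, the cascade
is the final filter. Running without any control libraries is a hard
error: extraction controls must be sequenced alongside study samples.

Spike-in normalization converts counts to absolute copies per uL of
eluate: `copies(seq) = count(seq)/count(spike) * copies_per_uL_eluate`.
Libraries without detectable spike-in are flagged, never silently
zeroed. Screening of external datasets reports per-assay reads per
million *retained* reads (the denominator choice is documented because
published figures do not state it).

## qPCR analysis

Quantification cycles are called by the second-derivative-maximum
method. The discrete curve is differentiated with fourth-order central
differences; the slope sequence is extended by geometric tails (an
amplification curve's slope decays approximately geometrically into
baseline and plateau) and the second derivative is reconstructed on a
fine sub-cycle grid by Fourier interpolation with exact compensation
of the difference-kernel response. On noise-free sigmoids this locates
the analytic second-derivative maximum to ~0.01 cycles; the canonical
check is the unit-scale logistic with midpoint 25, whose
second-derivative maximum sits at `25 − ln(2+√3) ≈ 23.683`. Noisy
(non-monotone) curves are Savitzky–Golay smoothed (quadratic, window
5) first, at some cost in accuracy. Flat curves (range below the noise
floor) are flagged no-amplification; curves without a genuine positive
curvature peak are flagged invalid.

Standard curves regress Cq on log10 copies over a dilution series
(>= 3 distinct concentrations; the reference design spans seven orders
of magnitude); efficiency is `E = 10^(−1/m) − 1`. Quantification
inverts the regression, `copies = 10^((b − Cq)/(−m))` — the only
reading of the printed quantification formula consistent with
`Cq = b + m·log10(C)`. Replicate Cq values (reactions are run in
duplicate) are averaged before conversion.

The simulated amplification curve is a four-parameter sigmoid whose
midpoint shifts by `−log10(copies)·log(10)/log(1+efficiency)` cycles —
3.3219 cycles per decade at perfect doubling. Defaults put the
one-copy midpoint at cycle 36 with steepness 1.25 cycles, so that a
seven-decade dilution series both stays inside a 40-cycle program and
reaches plateau within it, and the ~5–6-cycle rise matches real
amplification curves.

## The exogenous-candidate cascade

Filters apply in a fixed order; survivor sets are nested:

1. drop sequences assigned to the confirmed contaminants;
2. drop sequences detected in more than 10% of the controls
   ("absent from at least 90%" is read as detected, at >= 1 read, in at
   most 10% of control libraries);
3. drop sequences ever reaching 10 copies in any single control;
4. keep only sequences with **more than** 3 reads in **more than** 7 of
   the 28 plasma libraries — strict inequalities, exactly as printed;
   for other designs the 7-of-28 rescales as the fraction 0.25;
5. drop low-complexity sequences (mononucleotide Shannon entropy below
   1.5 bits, or a homopolymer spanning >= 2/3 of the length — the
   method is a package choice, as no specific complexity measure is
   prescribed for this step);
6. drop sequences with any host hit;
7. drop sequences whose best reference hit (fewest mismatches, then
   longest overlap; ties resolved toward removal) is host/vertebrate
   or belongs to a genus known as a sequencing-kit contaminant.

Whether the plasma-library rule should count replicate libraries or
distinct conditions is ambiguous in the underlying recommendation; the
package counts libraries.

## What the synthetic data does and does not show

The generator reproduces the *structure* the analysis relies on —
copy-number pools, the per-column contaminant mechanism, spike-ins,
multinomial sampling, substitution errors — so passing tests
demonstrate that the pipeline's logic is correct and its estimators
are calibrated under that model. It does not emulate ligation bias,
PCR duplicates, indels, quality-score drift, multiplexing errors or
real microbial pangenomes; agreement on synthetic data therefore does
not certify performance on any particular real dataset, and
quantities that depend on deposited reads and live sequence databases
(numbers of candidate sequences in real plasma, cross-study
contaminant levels, measured depletion efficiencies of column
treatments) are out of reach of the test suite by design.

## Problem sizes used in tests

Unit tests run at small scale (libraries of 10^3–10^4 reads,
references of 20–50 kb). The deeper checks use: a titration of 15
libraries at 4x10^5 reads each for the inverse-volume law; twenty
complete study datasets (28 plasma + 12 control libraries at 10^4
reads) for cascade recovery; and the full seven-decade qPCR dilution
series. When depth is scaled down for the detection-rule checks, the
planted exogenous input rate is scaled up inversely (400 copies/uL at
10^4 reads vs 4 copies/uL at 10^6 reads) so that expected per-library
read counts — what the detection rule actually sees — match the
full-depth study conditions. Thresholds and tolerances are those of
the method itself and are never adapted to the simulation.

## Known limitations

* Host attribution uses genome sequence only; junction-spanning host
  reads (RefSeq exon-junction libraries) are an accepted blind spot.
* Only 3' adapters are trimmed; 5' primer sequences embedded mid-read
  are not searched for.
* `map_reads()` is exhaustive and exact but intended for collapsed,
  filtered tables (hundreds of unique sequences) against reference
  panels up to a few hundred kb, not for genome-scale alignment.
* The decoy comparison uses a count excess, not a statistical test;
  the rule is exposed as configuration rather than guessing intent.
* No melting-curve analysis; poly-adenylation and reverse-transcription
  efficiencies are treated as 1.
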