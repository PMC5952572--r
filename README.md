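# srnaclean

Contaminant-aware analysis of small RNA sequencing data from low-biomass
samples.

## The problem

Small RNAs in blood plasma and other low-biomass samples are profiled by
deep sequencing, and the non-host ("exogenous") fraction of such
libraries has repeatedly been interpreted as microbial or dietary RNA.
A large part of that fraction can instead be carried by the silica
spin columns used for miRNA extraction: reagent-borne small RNAs that
enter each library at a roughly fixed number of copies **per extraction
column**. Because genuine sample RNA scales with the input volume *V*
while the contaminants do not, contaminant relative abundance follows an
inverse-volume law,

    cpm(V) ∝ 1 / V        (log–log slope −1),

which is both the diagnostic signature and the basis for choosing a
safe input volume. `srnaclean` is for sequencing groups and
bioinformaticians who need to (i) detect such reagent contaminants with
extraction-control libraries, (ii) quantify them absolutely via
spike-ins and qPCR standard curves, (iii) filter credible exogenous
sRNA candidates with a strict multi-criteria cascade, and (iv) decide
how much input material makes a protocol safe.

## What is implemented

* **Preprocessing** — recursive 3′ adapter trimming (≥10-nt overlap,
  ≤1 mismatch), 5′ N clipping, quality filtering (≥90% of bases at
  Phred ≥30), read collapsing, and count tables with the 30-count
  retention rule (or singleton removal for public data).
* **Attribution** — exhaustive substitution-only mapping (≤2
  mismatches, both strands), host-first attribution, a shuffled-decoy
  filter for reference genomes (≥1 real read of ≥25 nt, more real than
  decoy reads), locus construction, and cross-mapping correction by
  iterative proportional allocation.
* **Contaminants** — the packaged panel of six qPCR-confirmed column
  contaminants, the primer rule (exact shared block ≥14 nt), control
  flagging, spike-in normalization (40,000 copies/µL eluate by
  default), public-dataset screening (rpm per assay), and depletion
  reports (fold change, percent reduction).
* **qPCR** — second-derivative-maximum Cq calling, standard curves
  `Cq = b + m·log10(C)` with efficiency `E = 10^(−1/m) − 1`, absolute
  quantification `copies = 10^((b − Cq)/(−m))`.
* **Exogenous cascade** — ordered filters: confirmed contaminants →
  control presence (>10% of controls) → control copy cap (≥10 copies) →
  abundance (>3 reads in >7 of 28 plasma libraries) → low complexity →
  host-like → kit-contaminant genera; survivors are the candidates.
* **Titration** — per-contaminant log–log fits and the smallest volume
  (fitted and empirically tested) keeping every contaminant below a
  cpm threshold (default 100 cpm).
* **Synthetic data** — reference sets, titration/mock/eluate/water
  libraries and qPCR amplification curves generated from the
  copy-number composition model, fully seeded.

See `vignettes/srnaclean-methods.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

Quantify a spike-in from simulated, noise-free qPCR data:

```r
library(srnaclean)

dilution <- simulate_qpcr(10^(1:7))          # seven-decade standard series
cps <- call_cp_set(dilution)                 # second-derivative Cq calls
curve <- fit_standard_curve(cps$true_copies, cps$cp)
curve
#> qPCR standard curve: Cq = 34.3521 -3.3211 * log10(copies)
#>   efficiency 100.0%, r^2 = 1.00000, n = 7

mock <- simulate_qpcr(40000)                 # mock extract at spike-in level
quantify_copies(call_cp(mock$fluorescence[, 1])$cp, curve)
#> [1] 39954.9
```

The slope of −3.32 cycles per decade is exactly `−log2(10)` — perfect
per-cycle doubling — and the mock reaction recovers the planted 40,000
copies/µL to 0.1%.

A sequencing-side round trip at reduced depth: simulate a full study
(28 plasma titration libraries plus controls), preprocess, flag
contaminants from the controls and run the cascade:

```r
refs <- make_references(ref_config(), seed = 101)
sim <- simulate_dataset(refs, seed = 202, reads_per_library = 1e4,
                        exogenous_copies_per_uL = 400, kit_copies_per_uL = 400)
collapsed <- lapply(sim$reads, preprocess_library,
                    adapters = "TGGAATTCTCGGGTGCCAAGG")
ct <- build_count_table(collapsed, sim$meta, mode = "study")

panel <- contaminant_panel()
flagged <- flag_control_sequences(ct)
sum(panel$srna_sequence %in% flagged)
#> [1] 6                      # all six planted contaminants flagged

asg <- match_contaminants(rownames(ct$counts), panel)
host_hits <- map_reads(rownames(ct$counts), refs$host)
report <- run_cascade(ct, union(flagged, asg$sequence[!is.na(asg$assay)]),
                      host_hits = host_hits)
report$stage_counts[["candidate"]]
#> [1] 6                      # five planted exogenous sRNAs + the
                             # kit-genus sequence (removed at stage 7
                             # when taxon-labelled references are given)
```

The same analysis runs from files via `run_pipeline()` (modes
`simulate`, `analyze`, `screen`, `qpcr`, `titrate`) or the thin CLI
wrapper in `inst/scripts/srnaclean.R`.

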