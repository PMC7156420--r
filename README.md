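# mdseq

Maximum-depth sequencing (MDS) analysis for ultra-rare somatic mutations:
simulation of barcoded amplicon libraries, barcode-family consensus calling,
mutation-frequency and tropism analyses, and droplet digital PCR (ddPCR)
quantification.

## Why

Carcinogen-induced point mutations arise at frequencies of 10⁻⁴–10⁻⁶ per
template — orders of magnitude below the ~10⁻²–10⁻³ error floor of
conventional amplicon sequencing. MDS tags each template molecule with a
random 14-nt barcode, copies it **linearly** before exponential
amplification, and sequences millions of barcode families. A true template
mutation appears in every read of its family; PCR and sequencer errors do
not, so a family-consensus caller separates signal from noise down to one
mutant per ~2×10⁶ templates (detected frequency 5×10⁻⁷).

`mdseq` implements the full analysis for assays of the Ras hotspot exons:

* **refmodel** — reference amplicons with read-strand ↔ coding-strand cDNA
  coordinate mapping, exhaustive single-substitution variant libraries with
  codon consequences (`Q61L`, `silent`, `nonsense`) and trinucleotide
  classes (`CAN>CTN` / `NTG>NAG`), and oncogenic hotspot enumeration.
* **synthetic data** — a seeded generative model of the whole assay
  (templates → barcodes → linear copies → reads, with linear-copy and
  per-read sequencing errors), ddPCR wells, and expression/WES tables, each
  with a ground-truth manifest.
* **read processing** — pair merging, the 90 %/Q20 quality filter,
  primer-anchored index demultiplexing and layout trimming.
* **family calling** — ≥3-read unique-consensus calling (carcinogen mode),
  ≥2-read engineered-mutation detection (spike-in mode), and the 1.5×10⁵
  barcode-recovery sample QC.
* **frequency analysis** — families-with-mutation / total-families
  frequencies, the 1/(1.5×10⁵) ≈ 6.67×10⁻⁶ detection-limit correction,
  fold-change-over-control heatmap matrices, and complement-strand masking
  of C>T / G>T library artifacts.
* **tropism analysis** — per-position strand-bias summaries and the
  expression-quartile CAN>CTN strand asymmetry analysis.
* **ddpcr** — Poisson-corrected mutant allele fraction,
  `maf = −ln(1−nmu/n) / −ln(1−nDNAconc/n)`, with multi-well pooling.

The shipped FASTA references are synthetic stand-ins carrying the real
hotspot codons (GGT/GGC at cDNA 34–39, CAA at 181–183); see
`vignettes/maximum-depth-sequencing.Rmd` for the model, parameter rationale
and limitations.

## Worked example

Enumerate the oncogenic Ras hotspot substitutions, benchmark a spike-in, and
quantify a ddPCR well:

```r
library(mdseq)

enum <- enumerate_hotspot_mutations()      # GGT/GGC/CAA across 3 Ras genes
enum$n_point_mutations                     # 57
enum$n_distinct_substitutions              # 54
enum$aa_sets$Q61                           # "E" "H" "K" "L" "P" "R"

amp <- mds_amplicons()$Kras_ex2_nt
spk <- spikein_design(data.frame(cdna_pos = c(170, 182), alt = c("G", "T")),
                      present_frequency = 1e-3)
cfg <- simulation_config(amp, n_templates = 5e4, spikeins = list(spk), seed = 7)
sim <- simulate_library(cfg, emit = "records")
cl  <- call_families(sim$reads[sim$reads$pass_qc, ], amp,
                     mode = "spikein", spikein = spk)
sum(cl$status == "DETECTED") / nrow(cl)
#> 0.000903

poisson_maf(ddpcr_well(n = 20000, nmu = 2, nDNAconc = 10000))
#> <maf_result> Mmu=0.0001 MDNAconc=0.6931 copies/droplet, maf=0.0001443 (1 wells)
```

The spike-in caller recovers the 10⁻³ present frequency (48 detected
families among 53,156) and the ddPCR example reproduces the closed-form
Poisson result. A carcinogen-mode run goes through `run_config()` +
`run_pipeline()`, which writes per-sample calls/frequency TSVs and a JSON
run report; `run_benchmark()` produces present-vs-detected dilution tables.
A thin command-line wrapper lives at `inst/scripts/mds.R`
(`sim`, `run`, `benchmark`, `ddpcr` subcommands).

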