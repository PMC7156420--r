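---
title: "Barcode-family consensus calling for ultra-rare mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-family consensus calling for ultra-rare mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdseq)
```

## The problem

Carcinogens such as urethane induce somatic point mutations at rates of
roughly 1 mutant template per 10^4^--10^6^, far below the ~10^-2^--10^-3^
error floor of conventional amplicon sequencing. Maximum-depth sequencing
(MDS) circumvents that floor by tagging each template molecule with a random
14-nt barcode, *linearly* copying the barcoded template several times, and
only then amplifying exponentially and sequencing deeply. All reads sharing
a barcode descend from one template, so a true template mutation appears in
(essentially) every member of the barcode family, whereas polymerase and
sequencer errors strike individual copies or reads and fail the family
consensus. `mdseq` implements the full downstream analysis of such an
assay -- and, because real runs need millions of reads from animal tissue, a
seeded generative model of the assay so that every stage is testable at desk
scale.

## The model

### Reference model and coordinates

A `reference_amplicon` stores the sequenced region in read orientation plus
the bijection onto coding-strand cDNA coordinates (1-based, codon *i* at
positions 3*i*-2..3*i*). Assays may read either the non-transcribed (coding)
strand or the transcribed strand; all mutation keys are normalised to
coding-strand notation while the originating strand is retained, so
opposite-strand assays of the same exon produce identical key sets
(`build_variant_library()` is tested for exactly that involution).
Every single-nucleotide substitution of the amplicon (3 per position) is
enumerated with its trinucleotide context and codon consequence; family
consensus sequences are assigned mutations by exact match against this
library. The shipped FASTA references are *synthetic stand-ins*: the assay's
real exons are not distributed with the package, so fixture sequences were
generated once (fixed seed, no in-frame stops) with the biologically
meaningful features pinned -- GGT at cDNA 34-36, GGC at 37-39 and CAA at
181-183, i.e. the Ras G12/G13/Q61 hotspot codons, including the 5'C context
that makes position 182 a CAN site.

### Generative model of a library

`simulate_library()` draws, per template: one barcode (uniform over 4^14^,
collisions simulated honestly, no deduplication), a number of linear copies
~ Poisson(`lambda_linear`) truncated at 1, and a number of sequenced reads
~ Poisson(`lambda_reads`). The two error processes mirror what the assay
exploits:

* **linear-copy errors** (probability `p_linear_error` per base per copy)
  are inherited by every read that descends from the mutated copy -- reads
  pick their ancestral copy uniformly;
* **sequencing errors** (`p_seq_error` per base) are independent per read.

This two-stage model deliberately replaces a full branching-PCR simulation:
it reproduces the property that matters -- only template-borne mutations are
family-consistent, linear-stage errors are partially consistent, sequencing
errors are not -- at tractable cost. Defaults are `lambda_linear = 10`,
`p_linear_error = 1e-5`, `p_seq_error = 1e-3`, `lambda_reads = 5`. The
first three are not measured quantities of the assay (polymerase error rates
and copy numbers for the protocol are not published); they are
order-of-magnitude values for a high-fidelity polymerase and a modern
Illumina run, exposed in `simulation_config()`. `lambda_reads = 5` was
chosen once so that most families clear the 3-read consensus floor while
per-family depth stays realistic for runs optimised for family *count*.
Phred qualities are drawn from a clipped discretised normal (mean 37, sd 3);
errors are placed independently of the emitted quality, since the pipeline
uses qualities only as a threshold filter. `emit = "records"` skips FASTQ
text serialisation for large simulations and applies the same quality model
as a binomial draw of sub-Q20 base counts; the FASTQ path is exercised end
to end at smaller scale.

What the generator does **not** emulate: indels, chimeric/adapter
read-through reads, GC amplification bias, PCR jackpot size distributions
beyond Poisson, and duplex (two-strand) barcoding. Passing tests on
synthetic data therefore demonstrate the correctness of the *calling logic*
under the stated error model, not the assay's behaviour on real tissue.

### Read processing

Reads follow the layout `[index 0-7 nt][14-nt barcode][primer][target]`.
Processing applies, in order: optional pair merging (best overlap, minimum
length 10, mismatch fraction <= 0.1, disagreements resolved to the
higher-quality base), a quality filter requiring >= 90% of bases at
Phred >= 20 (inclusive at exactly 90%, matching the usual behaviour of the
filter tooling), then primer-anchored demultiplexing: the gene-specific
primer must match within `primer_max_mismatch` (default 2) at offset
`index + barcode` length, longest index tried first, the zero-length index
serving only as fallback. Targets must match the expected length exactly,
which silently discards indel-carrying reads -- a deliberate mirror of
length-filter-based processing. The pair merger is a minimal overlap merger,
not a reimplementation of any particular published tool.

### Family calling

`call_families()` groups records by exact barcode match and applies one of
two rules:

* **carcinogen mode** -- families need >= 3 reads and a *unique consensus*:
  at every position one base carried by >= 90% of members (for sizes <= 9
  this equals unanimity). The consensus is exact-matched against the
  reference and the single-substitution library, yielding `WT`,
  `SINGLE` (one substitution, with its key) or `OTHER` (multi-substitution
  consensus). Since "unique consensus" could be read as unanimity or
  majority, the 0.90 supermajority was adopted as the single rule for both
  modes (it is the explicitly stated spike-in threshold) and is exposed as
  the `agreement` parameter.
* **spike-in mode** -- families need >= 2 reads, and >= 90% of members must
  carry the engineered alternate base at the engineered positions. The
  default requires *all* co-occurring engineered positions
  (`match = "all"`); `match = "single"` scores one specified position,
  which is the more literal reading of how detected frequencies were
  counted for spike-in benchmarking. Both recover the truth on clean data;
  "all" is the more conservative default.

Frequencies divide mutation-carrying family counts by all selected families
(`WT + SINGLE + OTHER`); samples with fewer than 1.5x10^5^ families are
excluded outright. Exact barcode matching (no edit-distance clustering)
slightly inflates the denominator via barcode sequencing errors, but such
spurious families almost never reach 3 concordant reads; the trade-off is
determinism and speed.

### Frequencies, correction and heatmap matrices

`compute_frequencies()` emits an explicit row for all 3L library keys. The
detection-limit pseudo-count 1/(1.5x10^5^) ~ 6.67x10^-6^ -- the reciprocal
of the QC floor -- is added to every frequency before any log transform, so
matrices stay finite and unobserved keys sit exactly at the floor.
`correct_and_fold_change()` follows a fixed order: correct each key, sum
within the group key (nucleotide position, substitution type, or individual
A>T transversion), divide by the arithmetic mean of the PBS control
samples' sums, then log10. The constant is one fixed value for all samples
(a per-sample `1/total_families` variant can be had by passing `constant`
explicitly).

C>T and G>T substitutions *as read* carry deamination/oxidation background,
so `mask_strand_artifacts()` sources each such key from the assay where the
same genomic change reads as G>A or C>A; complementary classes can never be
artifact-prone on both strands, so a two-strand design always has a clean
source. With a single strand available those keys are flagged `masked`
rather than guessed.

### Strand bias and expression quartiles

`strand_bias_summary()` averages corrected frequencies over the amplicon
positions qualifying for a trinucleotide class (e.g. `CAN>CTN`) and its
reverse complement (`NTG>NAG`) -- the same genomic sites viewed from the
other strand -- then reports mean +/- SEM across samples.
`expression_quartile_bias()` sorts genes by mean FPKM (stable sort, ties
broken by gene identifier; remainder genes to the lower quartiles --
both choices exist purely for determinism), sums CAN>CTN counts per tumor,
quartile and annotated gene strand, and summarises as mean +/- SEM across
tumors. Mutations are counted per tumor-occurrence, which is what a
mean-over-tumors presentation implies. Gene strand is an input column; the
package does not compute gene orientation from a genome.

### ddPCR quantification

Droplet occupancy is Poisson, so positive-droplet counts map to
concentrations via `Mmu = -ln(1 - nmu/n)` and
`MDNAconc = -ln(1 - nDNAconc/n)`, with mutant allele fraction
`Mmu/MDNAconc`. `nDNAconc` counts droplets positive for *either* probe.
Multi-well pooling sums droplet counts before the transform, the
maximum-likelihood combination when wells share one concentration; per-well
estimates are reported alongside. The optional delta-method confidence
interval is a convenience output of this package, not part of the assay's
standard read-out.

## Numerical choices and degenerate inputs

* Boundary conventions are inclusive where the rule is stated as a
  threshold: exactly 90% qualifying bases passes, exactly 1.5x10^5^
  families is included, a family of exactly `min_size` reads is callable.
* Consensus ties at a position cannot reach the 0.90 supermajority, so no
  tie-break is ever needed; families failing the rule are dropped
  (`NO_CONSENSUS`), never guessed.
* Amplicon-edge substitutions lack a flank: their context classes are
  `"undefined"` and they are excluded from context-class averaging but kept
  in substitution-class and per-position analyses.
* Saturated ddPCR wells (`nDNAconc == n`), template-free wells and
  inconsistent counts are rejected with specific errors rather than
  producing infinities.
* All simulations are exactly reproducible: one integer seed determines the
  library byte-for-byte.

## Problem sizes used in the checks

The test suite validates the sensitivity claim at its native scale -- one
mutant template among 2x10^6^ barcode families (detected frequency
5x10^-7^) -- plus a 2x10^5^-family scaled variant, a 1.1x10^5^-template
error-suppression run, and dilution series of 10^-3^..10^-5^ at 10^5^
families. These sizes keep a laptop-class run in minutes while preserving
the quantities of interest; all remaining unit tests run on hundreds to
thousands of templates.

## Known limitations

* The consensus rule is unweighted by base quality; a quality-weighted
  consensus might rescue borderline families but is deliberately out of
  scope.
* Linear-copy errors *can* produce fully consistent small families (all
  reads drawn from one mutated copy); with ~10 copies per template this is
  rare but it is the dominant residual false-positive path of the assay
  model, and the spike-in design counters it by requiring co-occurring
  mutations.
* No phasing across families, no duplex reconciliation, no indel calling.
* The expression-quartile analysis takes expression tables and per-gene
  strand annotations as given; it does not recompute them from sequence
  data.
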