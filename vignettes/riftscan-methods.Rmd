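---
title: "Methods: calling and characterizing antisense-L1 fusion transcripts"
author: "riftscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterizing antisense-L1 fusion transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riftscan)
```

## Background and model

Full-length mouse LINE-1 (L1) elements (~7 kb: 5' UTR, ORF1, ORF2,
3' UTR) carry, besides their sense promoter, promoter activity on the
strand antiparallel to the coding strand, located within ORF1. Transcripts
initiated there read "backwards" through the 5' UTR and out of the
element, and can splice into exons of the surrounding gene in that gene's
sense orientation. We call such products retrotransposon-initiated fusion
transcripts (RIFTs). This package implements their discovery from
exon-array intensity data and their sequence-level characterization, with
every element-internal position expressed as a 1-based coordinate on the
element's *sense* strand — the community convention, even though the
transcripts of interest are antisense.

## The calling rule set

`call_rifts()` composes four operations, each exposed separately:

1. **Threshold** (`compute_threshold`): per sample, mean plus
   `sd_multiplier` (default 1) sample standard deviations (n−1
   denominator) of all probe intensities, log2 scale. The comparison is
   strict: a probe exactly at the threshold is not high. Under the
   generator's background model (mean 6, SD 1) the threshold sits near
   log2 intensity 7. The threshold is per-sample rather than pooled:
   array-wide intensity level varies by sample, and a per-sample cut
   keeps the "high" definition self-normalizing.
2. **Flagging** (`call_high_probes`) and **run detection**
   (`find_runs`): within each gene, probes ordered by genomic start;
   all *maximal* runs of at least `min_run` (default 5) consecutive high
   probes are reported. "Consecutive" means adjacent in the gene's probe
   order irrespective of exon boundaries; probes assigned to several
   genes are evaluated independently per gene.
3. **Element matching** (`find_initiating_l1`): candidate initiating
   integrants must exceed 5 kb, belong to an active subfamily (T_F, A,
   G_F, F; RepeatMasker-style names are canonicalized through a
   user-overridable regex table), lie antisense to the gene, be present
   in the sample's strain, and satisfy the distance rule — within 30 kb
   of the gene span and/or within 100 kb of any run probe. Distances are
   nearest-edge gaps (0 when intervals overlap or touch, the IRanges
   convention). The two clauses combine as inclusive-or by default
   because the assay text couples them loosely; a strict and-mode flag
   is provided for sensitivity analyses. Whether "upregulated probes"
   means all run probes or only the boundary ones is not decidable from
   the assay description; all run probes are used, which is the more
   permissive and simpler reading.
4. **Tie-breaking**: among qualifying elements the one nearest the run's
   probes wins, remaining ties going to the lexicographically smaller
   element id. No multiple-testing correction is applied anywhere — the
   assay is a deterministic rule set, not a statistical test.

## The synthetic-data generator

The generator exists so that the full pipeline is testable with known
truth. `gen_genome()` lays out non-overlapping multi-exon genes on one
chromosome (multi-chromosome inputs are supported by the caller, the
generator emits one), then places eligible initiating elements —
full-length (6–7 kb), active-subfamily, antisense, inside an intron of
(or immediately upstream of) a host gene, at most one per gene — and
decoys that each fail exactly the filters they are meant to exercise:
truncated elements, sense-oriented elements, inactive subfamilies,
intergenic fragments. Decoys never nest inside another element's span.

Key emulation choices, fixed once:

* **Noise model**: Gaussian on the log2 scale. Normalized log2 exon-array
  intensities are approximately Gaussian in bulk, and the choice makes
  the threshold and null behaviour analytically checkable: the expected
  fraction of background probes above mean + 1 SD is the upper normal
  tail, 0.159, and the chance of five consecutive high probes in a
  five-probe gene is 0.159^5 ≈ 1.0e-4.
* **Signal**: a planted fusion transcript adds `signal_shift` log2 units
  (default 6 = 6 background SDs) to the probes of the host-gene exons
  downstream of the element in transcription direction, in exactly the
  samples whose tissue matches and whose strain carries the element.
* **TSS placement**: element sense window 2201–2244, the antisense
  promoter region inside ORF1; configurable for the wider windows seen
  in other tissues.
* **Probes per exon**: 4. Exon-array designs vary; four probes per
  probeset is typical and the value is configurable.
* **Gene spacing**: 150 kb. The spacing deliberately exceeds the 100-kb
  probe-join window so that an element in one gene can never satisfy the
  distance clause for a run in a neighbouring gene — planted truth is
  then identifiable, which is what a validation genome is for.
* **Element reference**: 7000 nt with 5' UTR up to 2123, ORF1 from 2124.
  The sequence is synthetic (random, seeded) except for planted
  landmarks: the antisense splice donors `GATGgtgag` at 1838 and
  `TCAGgtgtg` at 1892 (the sense strand carries their reverse
  complements), exactly eight antisense ATG codons spanning two reading
  frames in the sense window 2124–2244, and an antisense TATAA box at
  2698. Positions are faithful; sequence context is not, so
  sequence-level results beyond these landmarks carry no biological
  meaning.
* **Samples**: one per (strain, tissue) pair — five inbred strains by
  two tissues by default; replicates are a matter of adding tissue or
  strain labels.
* **Clone mix**: 70% spliced antisense, 15% unspliced antisense, 15%
  premature sense-polyA decoys, with per-tissue clone counts
  configurable; spliced clones use the two donors in proportion 44:13,
  matching observed usage.

What passing tests on this generator do **not** show: robustness to
non-Gaussian intensity artefacts, cross-hybridization, probes mapping to
several genes, fragmented or nested repeat annotations, or mis-annotated
element boundaries. Real arrays and RepeatMasker tracks have all of
these; the caller's behaviour there is governed by the same filters but
is not certified by the synthetic recovery results.

## Transcript features

`classify_clone()` assigns exactly one label per aligned clone: spliced
antisense fusion (5' block inside an element antisense to the read
direction, later block outside it), unspliced antisense fusion (single
block crossing the element 5' end into flank), premature sense-polyA
(sense-contained with a poly(A) tail), or OTHER. When a clone's 5' end
lies in several overlapping elements, the element antisense to the clone
is preferred — the only orientation it could have initiated from.

`map_tss()` converts each clone's 5'-most aligned base to element sense
coordinates (`pos − start + 1` on plus-strand integrants,
`end − pos + 1` on minus-strand ones; `genomic_to_l1()` /
`l1_to_genomic()` are exact inverses on both strands).

`find_splice_donors()` anchors the junction at the *last exonic base* of
the element block, reporting the exonic 4-mer and intronic 5-mer on the
transcript strand. The last-exonic-base anchor is chosen because it makes
the two canonical donor motifs reproduce at their cited coordinates 1838
and 1892. Intron sides not starting `gt` are returned with
`valid = FALSE` rather than dropped, so non-canonical junctions remain
visible. Splice-site strength scoring is out of scope.

Percentages throughout (`proportion_summary`, donor usage) are integers
rounded half away from zero — the convention that reproduces every
printed count/percent pair (e.g. 44/65 → 68, 13/65 → 20, 363/940 → 39).

## Synonymous recoding

`recode_orf()` maximizes nucleotide divergence per codon: every codon is
replaced by a synonymous codon at maximal Hamming distance (per-codon
maximality is provably optimal and verified exhaustively in the tests;
Met and Trp have no synonyms and stay). The free choice among equally
divergent synonyms is what the two modes spend:

* **`neutral_AT`** keeps the global A/T fraction within `at_tolerance`
  (default 0.01) of the original. Because per-codon A/T contributions
  are small integers, the set of achievable totals can be enumerated
  exactly by dynamic programming over partial sums; the total closest to
  the original composition is selected and codon choices realizing it
  are backtracked (ties: smallest per-codon A/T shift, then alphabetical
  — fully deterministic, no RNG). A greedy single-swap repair was
  considered first but stalls at local optima on about 1% of random
  ORFs; the dynamic programme is exact at negligible cost, so
  `at_feasible = FALSE` certifies that *no* maximal-divergence recoding
  meets the tolerance. Genuine infeasibility exists: codons such as AAA
  (Lys) shift A/T in every maximal-distance synonym, and for short ORFs
  the 1% band is less than one nucleotide.
* **`min_AT`** prefers the G/C-richest maximal-distance synonym,
  emulating fully recoded low-A/T elements. G+C ties are broken toward
  the G-richer, then alphabetically last codon (so TTA → CTG, the
  codon-usage-typical choice), again deterministically.

`motif_disruption()` counts IUPAC-degenerate motif matches before and
after recoding, optionally on both strands, reporting net disruption
(negative when recoding creates sites). No restriction-site or
splice-site avoidance is attempted — synthesis constraints are a
separate design problem — and no codon-usage optimization toward host
expression is performed.

## Catalog comparison and assay arithmetic

`venn_counts()` enumerates all 2^k − 1 disjoint membership regions of
2–5 catalogs. Fusion-transcript identity across groups is the
(gene, element) pair by default; identity is configurable to the element
alone because cross-tissue identity is a definition, not a measurement.
`normalized_reporter_ratio()` subtracts the no-reverse-transcriptase
signal before normalizing to beta-actin, clamping negative corrected
values to zero. `relative_frequency()` is a colony-rate ratio.

## Numerical and interface choices

* Intervals are 1-based inclusive internally (the GRanges convention);
  BED input/output converts at the boundary, GFF3 is native.
* All generators are seeded through the config and leave the global RNG
  untouched; identical configs give byte-identical outputs, which the
  determinism test verifies across full pipeline runs.
* Degenerate inputs: thresholds require ≥ 2 probes; an all-equal sample
  has SD 0 and threshold equal to the common value (nothing is high,
  by strictness); empty gene lists, empty clone sets and empty call
  tables propagate as empty results, not errors; a clone touching no
  element is OTHER/skipped-and-logged, not an error.
* Problem sizes in the shipped validation suite — 200-gene recovery
  genome, 10,000-gene null, 1,000 oracle instances and 1,000 random
  ORFs — were chosen to give stable statistics (binomial standard errors
  a factor ≳3 below the tested effects) while keeping the suite quick to
  run on a laptop.

## Known limitations

The caller is a faithful implementation of a binary rule set: it
quantifies nothing, corrects for no covariates, and inherits the rule
set's blind spots (fusion transcripts initiated by sub-5-kb or
non-canonical-subfamily elements are invisible by definition). Under
background noise a chance run of five high probes near an eligible
element produces an occasional false call (about 10^-4 per five-probe
gene and sample at default settings); the null-rate test pins this to
its binomial expectation. The synthetic element reference reproduces
coordinates and landmark motifs, not real L1 sequence; and clone
alignments are inputs — no aligner is bundled.
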