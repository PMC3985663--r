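# riftscan

Discovery and characterization of **retrotransposon-initiated fusion
transcripts (RIFTs)** — chimeric mRNAs whose 5' ends originate at the
antisense promoter inside ORF1 of mouse LINE-1 (L1) elements and read out
of the element into neighbouring genes.

## Who this is for

Transposon and transcriptome researchers who want a tested, reusable
implementation of the rule-based RIFT assay over exon-array intensities,
plus the downstream characterization steps (clone classification,
transcription-start mapping on element coordinates, splice-donor and
ATG scanning, synonymous ORF recoding, cross-tissue/strain catalog
comparison) — all runnable end to end on a bundled synthetic-data
generator with planted ground truth, so every stage is verifiable without
external downloads.

## The method

A probe *i* of sample *s* is **high** when its normalized log2 intensity
exceeds a per-sample threshold

> t(s) = mean_i x_is + k · sd_i x_is  (k = 1 by default, t ≈ 7 under the
> default background model N(6, 1))

with a strict comparison and the n−1 sample standard deviation. A gene is
a candidate fusion target when it carries a **maximal run of ≥ 5
consecutive high probes** (adjacent in genomic probe order within the
gene). A run becomes a RIFT call when a candidate initiating L1 integrant
exists that is

* longer than 5 kb (full length),
* of a retrotranspositionally active subfamily (T_F, A, G_F or F, mapped
  from RepeatMasker-style names),
* antisense to the gene, and
* within 30 kb of the gene span **and/or** within 100 kb of the run's
  probes (nearest-edge distances; inclusive-or by default, an and-mode is
  available),
* present in the sample's strain (polymorphic integrants are
  strain-aware).

Among surviving candidates the element nearest the run's probes wins.
Transcript features are reported in 1-based coordinates on the element's
sense strand: the antisense promoter TSS window (ORF1 nucleotides
2201–2244), the two canonical antisense splice donors `GATGgtgag`
(coordinate 1838) and `TCAGgtgtg` (1892), and antisense ATG codons per
reading frame. The recoder replaces each codon with a synonymous codon of
maximal Hamming distance while either holding the global A/T fraction
within a tolerance of the original (`neutral_AT`, solved exactly by
dynamic programming over achievable A/T totals) or minimizing A/T
(`min_AT`).

## Worked example

```r
library(riftscan)

cfg     <- generator_config(n_genes = 50, n_l1 = 20, n_rifts = 8, seed = 7)
ann     <- gen_genome(cfg)                      # genes + L1 integrants
planted <- plant_rifts(ann, cfg)                # ground truth
mat     <- gen_probe_matrix(ann, planted, cfg)  # log2 intensities
calls   <- call_rifts(mat, ann)                 # the RIFT assay
str(evaluate_calls(calls, planted, mat))
#> List of 5
#>  $ precision: num 1
#>  $ recall   : num 1
#>  $ tp       : int 35
#>  $ fp       : int 0
#>  $ fn       : int 0
```

Every planted fusion transcript is recovered in every sample whose tissue
and strain carry it, with no false calls. The per-sample attrition log
shows the threshold and how many probes/runs survived each stage:

```r
head(attr(calls, "attrition"), 3)
#>    sample_id threshold n_probes_high n_runs n_runs_matched
#> 1  B6_testis  7.800231            87      4              4
#> 2 DBA_testis  7.507568           100      3              3
#> 3 129_testis  7.602717            86      3              3
```

Clone-level characterization on the same synthetic genome:

```r
ref    <- l1_reference(seed = 7)
clones <- gen_transcript_clones(ann, planted, cfg)
table(vapply(clones, classify_clone, "", l1 = ann$l1))
#> PREMATURE_SENSE_POLYA       SPLICED_AS_RIFT     UNSPLICED_AS_RIFT
#>                     9                    27                     4

donors <- do.call(rbind, Filter(Negate(is.null),
  lapply(clones, find_splice_donors, l1 = ann$l1, ref = ref)))
summarize_donor_usage(donors)
#>       donor l1_sense_coord count percent
#> 1 GATGgtgag           1838    25      93
#> 2 TCAGgtgtg           1892     2       7
```

The spliced clones splice at the two canonical antisense donors, at
element coordinates 1838 and 1892. Count summaries use integer percents
with halves rounded away from zero, e.g. `proportion_summary(21, 27)`
prints `78` — 21 of 27 clones being spliced antisense fusion transcripts.

`run_pipeline(cfg, out_dir = "out")` executes every stage and writes
GFF3/BED/TSV/JSON tables plus a seed-recording manifest;
`inst/scripts/riftscan.R` wraps `simulate`, `call`, `recode` and `run` as
shell subcommands.

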