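# recsplice

Detection and sequence-feature analysis of **recursive splicing (RS)** from
nascent RNA-Seq splice-junction tables.

Long introns are frequently removed in several steps: the spliceosome splices
to an internal *ratchet point* — a juxtaposed 3'SS-AG / 5'SS-GU, so an AGGU
tetramer regenerates a usable 5' splice site after each step — until the
annotated exon–exon junction is reached. These intermediates show up in
nascent RNA as splice junctions lying strictly *inside* annotated introns and
absent from mature RNA. `recsplice` is for transcriptomicists who want to
detect this signal in STAR `SJ.out.tab`-style junction tables and model what
distinguishes recursively spliced introns.

The package implements, end to end:

* **Junction classification.** Constitutive introns are extracted from a GTF
  (identical coordinates in every spanning isoform; no overlap with any other
  intron). Nascent-only junctions with ≥ 3 unique reads are classified per
  host intron into `basic`, `RS5`, `RS3` or `nested` by strand-aware boundary
  comparison, with recursive sites ≥ 75 nt from both annotated splice sites
  and host introns ≥ 150 nt.
* **K-mer mixture models.** Positional and grouped tetramer count matrices
  around splice sites are fitted with latent Dirichlet allocation (batch
  variational Bayes, 6 topics by default). Documents get grade-of-membership
  vectors; each topic's *driving k-mers* are ranked by the Poisson
  Kullback–Leibler score `p·ln(p/q) + q − p` against the other topics' mean.
* **Sequence profiles.** GC metagene curves over exon–intron–exon, windowed
  GC distributions, tetramer-enrichment volcano statistics (Haldane-corrected
  log2FC, Fisher + BH), and splice-site information content.
* **CpG methylation.** Per-exon unweighted mean methylation from bedMethyl,
  with Wilcoxon contrasts (RS genes have less methylated first exons).
* **First↔downstream coupling.** Fisher's exact association between
  first-intron RS and downstream-intron RS over transcripts with ≥ 3 detected
  introns, reported as the cross-product odds ratio.
* **Random-forest RS classifiers** for first and downstream introns (100
  trees, depth 3/2, stratified 1/3 test split) over topic expectations,
  intron length, TPM and methylation, plus covariate-matched controls.
* **RBNS mapping.** In-vitro protein k-mer preferences multiplied onto
  positional k-mer fractions in 15-nt bins over ±75 nt; proteins ranked by
  their strongest positional log2 fold change.
* **LSV-seq validation arithmetic.** Per-group detection rates and
  precision/recall across read thresholds for targeted follow-up counts.
* **A seeded synthetic-data generator** producing every input format (FASTA,
  GTF, SJ tables, TPM, bedMethyl, RBNS TSV) with planted CG motifs, AGGU
  ratchet points, methylation shifts and a tunable coupling odds ratio — so
  the entire pipeline runs and is tested without any external data.

## Worked example

```r
library(recsplice)

cfg    <- synthetic_config(n_genes = 300, seed = 42)
bundle <- generate_rs_bundle(cfg)

introns <- extract_constitutive_introns(bundle$annotation)
cls     <- classify_junctions(introns, bundle$nascent, bundle$mature)
table(cls$introns$rs_class)
#>  basic nested    RS3    RS5
#>    950     55     91    200

st  <- transcript_status(cls)
fit <- first_downstream_fisher(st)
sprintf("coupling odds ratio %.2f (p = %.2g, n = %d)",
        fit$odds_ratio, fit$p_value, fit$n)
#> "coupling odds ratio 2.77 (p = 2.8e-05, n = 298)"

mo <- motif_at_recursive_sites(cls, bundle$genome)
mo[mo$rs_class == "RS5" & mo$site_type == "recursive5", ]
#>   rs_class  site_type n_sites n_edge_excluded aggu_fraction
#> 2      RS5 recursive5     400               0          0.57
```

Reading this: of the 1,296 constitutive introns with junction evidence, 346
carry recursive junctions (200 RS5, 91 RS3, 55 nested — an intron can carry
several classes). Transcripts whose first intron is recursively spliced are
~2.8× more likely (odds) to show downstream recursive splicing in this
300-gene bundle (the generator plants an odds ratio of 2.2; small bundles
fluctuate). 57% of RS5 recursive 5' sites show the AGGU/C ratchet tetramer,
matching the 60% intact fraction the generator planted.

`run_pipeline(out_dir, cfg)` runs every stage in order and writes all result
tables plus a manifest with row counts and checksums; rerunning with the
same config is byte-identical.

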