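# cardiotrio

Trio whole-exome sequencing (trio-WES) is the fastest route to an
etiological diagnosis in cardiomyopathies of the first year of life,
where sarcomeric disease, RASopathies, inborn errors of metabolism,
mitochondrial disorders and ultra-rare syndromes all hide behind the
same hypertrophic or dilated phenotype — and where the result may decide
between targeted therapy, transplant listing and palliative care.

`cardiotrio` implements the diagnostic computation of such a workflow as
a tested, reusable R package, exercised entirely on synthetic data and a
packaged 42-case cohort transcription. It is aimed at bioinformaticians
building or auditing rare-disease trio pipelines.

## What it computes

**Discordant read-pair CNV caller.** From SAM alignment fields alone:
retain records with MAPQ = 60 and 2,500 ≤ |TLEN| ≤ 350,000 (one record
per template), cluster the implied footprints `[pos, pos + |TLEN| − 1]`
by single linkage with a ±5% endpoint tolerance, and rank clusters with
≥ `min_support` templates by support. Everted (RF) clusters are typed as
duplications, FR clusters as deletions.

**Depth stand-in and consensus.** A simplified read-depth caller
(library-size-normalized ratio gates 1.3/0.7, pooled-CV robust z ≥ 3,
run merging) and a reciprocal-overlap (≥ 0.5) consensus between the two
pipelines, with ≥1-base gene annotation.

**Sequential trio prioritization.** Per-variant Mendelian resolution
(de novo, inherited, homozygous-recessive, compound-heterozygous,
X-linked hemizygous with GRCh37 PAR handling), then conjunctive gates:
population frequency (dominant-acting ≤ 1e-4, recessive allele ≤ 5e-3),
gene-panel inheritance-mode and pathogenic-mechanism match, and a
reportable-class gate that suppresses variants of uncertain
significance. Survivors are ranked by class, rarity and model
specificity.

**Cohort statistics.** Exact diagnostic yields per care setting,
inheritance-mode and etiology breakdowns, and turnaround summaries over
`CohortCase` records; the packaged cohort reproduces the study's
headline numbers (29/42 = 69.0% overall, 17/24 = 70.8% urgent,
12/18 = 66.7% non-urgent).

**Synthetic-data generators.** Seeded, byte-deterministic generators for
paired-end SAM with implanted tandem duplications/deletions, trio
variant tables/VCFs with planted causal configurations under all five
models, and exon-target depth matrices — each with a truth manifest.

## Worked example

```r
library(cardiotrio)

## cohort: diagnostic yield and inheritance breakdown
cases <- load_cohort_fixture()
y <- diagnostic_yield(cases, "all")
sprintf("Diagnostic yield (all): %d/%d = %.1f%%", y$n_diagnosed, y$n_total, y$yield_pct)
#> "Diagnostic yield (all): 29/42 = 69.0%"
inheritance_breakdown(cases)$category_counts
#>             de_novo autosomal_recessive            x_linked  inherited_dominant
#>                  13                  10                   2                   4

## CNV: a planted 68-kb tandem duplication among 5,000 background pairs
truth <- cnv_truth(genomic_interval("chrS", 500000, 568047), "tandem_dup", 6)
sim <- simulate_read_pairs(truth = truth, n_background_pairs = 5000, seed = 7)
sam <- tempfile(fileext = ".sam"); writeLines(sim$sam_lines, sam)
call_cnv_discordant(sam)
#>   chrom  start    end sv_type support     source rank
#> 1  chrS 500019 568022     dup       6 discordant    1

## trio: recover a planted homozygous-recessive TNNI3 diagnosis
tt <- trio_truth("ar_homozygous", "TNNI3")
sv <- simulate_trio_vcf(tt, n_noise = 200, proband_sex = "F", seed = 7)
v <- tempfile(fileext = ".vcf"); writeLines(sv$vcf_lines, v)
cand <- prioritize_trio(v, proband_sex = "F")
cand[, c("rank", "model", "gene", "clinical_class", "max_af")]
#>   rank         model  gene clinical_class   max_af
#> 1    1 ar_homozygous TNNI3     pathogenic 0.000186
```

The CNV call recovers the planted interval to within the read length
(support = 6 templates, everted orientation → duplication), and the trio
cascade reports exactly the planted homozygous variant — the 200
Mendelian-consistent noise variants are removed by the frequency, panel
and reportable-class gates.

The `analysis/` directory holds the narrative drivers
(`01_cohort_statistics.R`, `02_cnv_benchmark.R`, `03_trio_recovery.R`);
each states what it finds and writes its tables under `results/`. The
methods vignette (`vignettes/diagnostic-pipeline.Rmd`) documents the
model, the defaults and their rationale, and the limitations.

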