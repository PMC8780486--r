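---
title: "Methods: the trio-WES diagnostic computation for infantile cardiomyopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the trio-WES diagnostic computation for infantile cardiomyopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotrio)
```

# Scope and model of the pipeline

Infantile cardiomyopathies (onset under one year) are genetically
heterogeneous: sarcomeric disease, RASopathies, inborn errors of
metabolism, mitochondrial disorders and ultra-rare syndromes all present
with hypertrophic (HCM) or dilated (DCM) phenotypes. Trio whole-exome
sequencing — proband plus both parents — resolves the transmission model
of every candidate variant directly and is therefore the assay of choice
when a fast etiological diagnosis must guide intensive-care decisions.

`cardiotrio` implements the downstream computation of such a workflow,
from aligned reads and an annotated trio VCF to the cohort statistics:

1. an **in-house discordant read-pair CNV caller** operating on SAM
   alignment fields only (MAPQ and TLEN),
2. a **read-depth CNV stage and dual-pipeline consensus** with gene
   annotation,
3. a **sequential trio variant-prioritization cascade** (inheritance →
   population frequency → gene panel and pathogenic mechanism →
   reportable clinical class),
4. **cohort statistics** (diagnostic yield per care setting, inheritance
   and etiology breakdowns, turnaround summaries) over a packaged
   42-case cohort table, and
5. **seeded synthetic-data generators** that produce every input the
   pipeline consumes, together with machine-readable truth manifests.

Everything runs on synthetic data or on the packaged transcription; no
sequencing data, alignment, or ACMG classification engine is involved.

# The discordant-pair CNV caller

A read pair spanning a deleted segment, or an everted pair straddling a
tandem-duplication junction, shows a template length (TLEN) far outside
the library's insert distribution. The caller retains alignment records
with

* mapping quality **exactly 60** (the unique-mapping cap of short-read
  aligners; the equality reading is deliberate and configurable), and
* **2,500 ≤ |TLEN| ≤ 350,000** bases, bounds inclusive. Inclusivity only
  matters for spans of exactly 2,500 or 350,000 bases; the window itself
  excludes both the normal insert (~150–500 bp) and chromosome-scale
  artifacts.

One record per template is kept (the leftmost, positive-TLEN mate), so
support counts **templates**, not alignment lines — the description of
the original pipeline counts "reads", which is ambiguous by a factor of
two; the choice is documented here and pinned by tests. Records with
TLEN 0 are excluded into a tally.

Each retained pair implies the footprint `[pos, pos + |TLEN| − 1]`.
Footprints on one chromosome are clustered by **single linkage**: two
intervals link when both start and end differ by at most 5% of the mean
of the two spans. The ±5% rule could plausibly apply to positions, spans
or endpoints; we apply it endpoint-wise with the mean span as
denominator, and an exhaustive brute-force transitive-closure oracle in
the test suite pins this exact semantics. Clusters reaching
`min_support` (default 3, this package's choice — the original support
threshold is unpublished) become calls, ranked by support, then span,
then coordinate. Orientation types the call: everted (RF) majority →
duplication, FR majority → deletion, tie → unknown.

# The depth stand-in and the consensus

The second pipeline of the published architecture is a depth-based exome
CNV tool; its model is cited, not described, so this package ships an
explicitly **simplified stand-in**: counts are library-size normalized,
the per-target ratio against the reference-panel mean is gated at 1.3
(duplication) / 0.7 (deletion), and a robust z-score must exceed 3. The
z-score uses a **pooled coefficient of variation** (median across
targets of the reference CV) rather than per-target standard deviations:
with ~10 reference exomes a per-target estimate is so noisy that its
sampling error, not the signal, would dominate the call. Runs of ≥ 2
gated consecutive targets merge into one call.

A **consensus** call is emitted when a discordant-pair call and a depth
call overlap reciprocally by ≥ 0.5 (both directions); the consensus
interval is the intersection, and discordant types degrade to `unknown`.
The published description states only that reported CNVs were detected
by both pipelines; the reciprocal-overlap rule and its 0.5 default are
this package's explicit rendering of "same event", and raising the
threshold can only shrink the consensus (a tested monotonicity).

**Known limitation.** At 200× simulated depth with negative-binomial
size 200, a single-copy duplication (expected ratio 1.5) sits only about
two per-target standard deviations above the 1.3 gate, so requiring
every target in the run to pass makes depth-based duplication recovery
intrinsically unreliable — a weakness depth-based exome callers share in
practice. Deletions (ratio 0.5, ≈5σ) are recovered in ≥95% of seeded
replicates. The simulation-backed recovery guarantees are therefore
stated for deletions; duplications are carried by the discordant caller,
which types them from the everted-pair signature.

# The trio prioritization cascade

`determine_inheritance()` resolves, per variant: de novo (proband het,
parents reference), inherited maternal/paternal, autosomal-recessive
homozygous (proband hom-alt, both parents het), and X-linked hemizygous
(male proband, non-pseudoautosomal chrX, carrier mother, reference
father; PAR boundaries follow the GRCh37 convention, matching the hg19
coordinates the cohort table prints). Mendelian-inconsistent sites are
flagged, never raised as errors; a diploid het call on male non-PAR chrX
is kept and flagged rather than silently converted.

Per gene, a maternal het and a paternal het in the proband additionally
yield a **compound-heterozygous** call. The singleton dominant readings
are retained alongside the compound one, because which reading is
correct is decided by *downstream* evidence the resolver cannot see: in
a recessive-only panel gene the singletons die at the inheritance-mode
match, while a pairing that includes an unreportable allele dies at the
class gate, leaving the true dominant variant reportable. Collapsing
eagerly would silence a pathogenic dominant variant whenever a benign
same-gene het of opposite origin co-occurs. Two variants in two
*different* genes, one per parent, remain two dominant calls — the
cohort's one such case is counted as inherited dominant, matching the
study's own accounting.

The subsequent gates are pure conjunctive predicates (the survivor set
is order-independent, a tested property):

* **Frequency** — dominant-acting models (de novo, inherited dominant,
  X-linked) require every allele ≤ `1e-4`; recessive configurations
  allow carriers in the population, per-allele ≤ `5e-3`. The published
  description states the principle ("consistent with the prevalence and
  incidence of the disease") without numbers; these defaults are the
  package's and are configurable. Absent frequencies count as novel.
* **Panel and mechanism** — the gene must be on the cardiomyopathy panel
  with a mode matching the model (AD / AR / XL), and for genes whose
  disease mechanism is loss-of-function the allele must be truncating or
  splice-disrupting, while gain-of-function/dominant-negative genes
  reject truncating alleles. This is the only classification-adjacent
  logic implemented; full ACMG evidence combining is consumed as an
  input annotation, by design.
* **Reportable class** — only pathogenic and likely-pathogenic calls
  survive; variants of uncertain significance are suppressed from the
  report, mirroring the laboratory policy of the study.

Survivors are ranked by class, then rarity, then model specificity
(de novo / recessive / hemizygous before inherited dominant).

# The packaged cohort and what it reproduces

`load_cohort_fixture()` ships 42 cases: the 29 diagnosed records
transcribed from the study's case listing (IDs preserved) and 13
undiagnosed rows reconstructed so that **every** published aggregate is
satisfied simultaneously — per-setting counts (24 urgent / 18
non-urgent), sex (26 M / 16 F overall, 12/12 urgent, 14/4 non-urgent),
CM type (30 HCM / 12 DCM), clinical class (12 isolated / 30 complex,
with the urgent 5/19 and non-urgent 7/11 splits and the
syndromic/metabolic composition), age means 4.3 / 3.7 / 4.0 months with
median 3.0, five positive family histories and nine prenatal
detections. Those reconstructed rows are marked
`record_source = "margin_synthetic"`; their individual field values are
package choices, constrained only by the margins. Family-history and
prenatal flags cannot be attributed to specific listed cases, so they
are assigned once, avoiding the four inherited-sarcomeric cases whose
transmitting parents are described as healthy with negative family
history. Per-case turnaround days are not published, so `t1_days` /
`t2_days` are absent and turnaround statistics are exercised on
synthetic draws only. The loader re-validates all margins on every load
and fails loudly rather than repairing anything.

```{r cohort}
cases <- load_cohort_fixture()
diagnostic_yield(cases, "urgent")[c("n_diagnosed", "n_total", "yield_pct")]
inheritance_breakdown(cases)$category_counts
```

The inheritance breakdown is reproduced twice: from the case table, and
independently by replaying the 33 transcribed trio genotype rows through
`determine_inheritance()` (13 de novo, 7 homozygous + 3 compound
heterozygous = 10 recessive, 2 X-linked, 4 inherited dominant, with the
two-gene double heterozygote counted as dominant). Indel and
duplication rows use `N`-anchored placeholder alleles because the
listing prints genomic start positions and cDNA notation rather than
VCF alleles; inheritance resolution depends only on the genotypes.

# The synthetic-data generators

The generators define the study conditions for every simulation-backed
claim; their defaults were chosen once, as realistic values for a
clinical exome, and are not tuned per experiment:

* **Read pairs** (`simulate_read_pairs`): one toy chromosome (`chrS`,
  2 Mb) keeps each experiment in seconds; 150 bp reads; insert
  ~Normal(300, 50) truncated positive, FR orientation, MAPQ 60; 5,000
  background pairs per library; 1% low-MAPQ decoy pairs. Supporting
  pairs are placed with ≤ 50 bp per-endpoint jitter, so two supporting
  pairs differ by ≤ 100 bp per endpoint — inside the ±5% linkage
  tolerance even at the minimal 2.5 kb span, which is what makes the
  ≥99% recall property a property of the caller rather than of lucky
  placement. Duplications are written as everted (RF) pairs with
  |TLEN| ≈ span, deletions as FR pairs with |TLEN| ≈ span + insert; the
  convention is recorded in the manifest so the caller's sv-typing is
  testable against it. Reads are emitted as already-aligned,
  coordinate-sorted SAM with placeholder SEQ/QUAL, because the caller
  consumes MAPQ/TLEN/orientation only. Identical seeds give
  byte-identical SAM.
* **Depth counts** (`simulate_depth_counts`): negative-binomial counts
  (mean 200, size 200) over exon-like targets with a shared log-normal
  capture-efficiency factor; case expectations ×1.5 on duplicated and
  ×0.5 on deleted targets; 10 event-free reference exomes.
* **Trios** (`simulate_trio_variants` / `simulate_trio_vcf`): 200
  Mendelian-consistent noise variants per trio (parents drawn from
  Hardy–Weinberg at frequencies log-uniform between 1e-5 and 0.5, child
  by random transmission; classes benign → VUS only), plus planted
  causal variants whose genotypes realize the declared model and whose
  frequencies sit below the corresponding gate. Causal consequences
  honour the panel mechanism. The VCF writer emits haploid genotype
  strings for male non-PAR chrX calls.

What the generators deliberately do **not** model: base-level errors,
GC bias, mosaicism, genotyping error in the parents, population
stratification of allele frequencies, and multi-exon genes for CNV
annotation. Passing tests therefore demonstrate the correctness of the
decision logic under clean Mendelian and insert-size models, not
robustness to caller noise in real exomes.

# Numerical and degenerate-input choices

* Intervals are 1-based inclusive everywhere (matching printed hg19
  coordinates); conversion to BED's 0-based half-open convention happens
  only in `write_cnv_bed()`.
* Cluster representatives take the median of member starts/ends (half-up
  rounding on even counts).
* In the depth caller, targets whose reference mean is zero are dropped;
  a zero pooled CV (degenerate flat panel) yields z = 0 where the case
  equals the reference and ±Inf otherwise, so exactly-uniform profiles
  produce no calls via the ratio gate.
* Yield fractions are exact rationals internally; rounding to one
  decimal happens only at display, so 29/42 prints as 69.0 and 17/24 as
  70.8.
* Empty strata, missing panel genes, unmappable zygosity/origin
  combinations, and fixture-margin violations raise immediately; the
  fixture is never repaired in code.

# Problem sizes used by the test suite and the acceptance script

Clustering is verified against the brute-force oracle on instances up to
200 pairs (20 seeds); discordant recall and false-positive properties
use 200 seeded replicates each (2,000-pair background for recall, the
5,000-pair default for the event-free runs); depth recovery uses 200
replicates over 30 targets; trio recovery uses 500 trios (100 per
inheritance model, 200 noise variants each). These sizes give stable
percentage estimates in seconds per experiment on a single core.
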