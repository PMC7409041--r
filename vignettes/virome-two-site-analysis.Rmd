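---
title: "Comparing two viral metagenomes: TPM abundance, surrogate-table diversity, and k-mer contig sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two viral metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromics)
```

## The analysis this package implements

Viral-enriched metagenomes from two sites of the same ecosystem are often
compared without a common reference: reads are assembled per site, open
reading frames (ORFs) are predicted on the contigs, annotated taxonomically
and functionally, and reads are mapped back to the ORFs. `viromics`
implements everything downstream of that mapping step:

1. **Per-ORF abundance.** For ORF $i$ with mapped-read count $r_i$ and
   length $L_i$ (kbp), the transcripts-per-million value is
   $$\mathrm{TPM}_i = \frac{r_i / L_i}{\sum_j r_j / L_j} \times 10^6 .$$
   Although TPM was designed for cDNA, applied to DNA read counts it
   normalises simultaneously by predicted ORF length and by library size, so
   abundances are comparable between ORFs and between libraries of different
   depth. TPM is invariant to uniform rescaling of counts, which is why the
   unit of counting (mates vs fragments) does not matter; the count table is
   taken as the mapper's resolved assignment and multi-mapping policy is out
   of scope.
2. **Profiles.** Gene TPM is summed by the unique seven-rank lineage string
   (domain;phylum;…;species). The resulting lineage-by-TPM table is the
   *surrogate OTU table*: it plays the role a 16S OTU count table would play
   in a classical diversity analysis. Rank rollups and per-function sums
   (all genes, viral genes, auxiliary metabolic genes) give the
   heatmap-ready matrices for cross-site comparison; two-site matrices
   always use the union of keys with explicit zeros, so a gene present in
   one site appears as 0 — not as a missing row — in the other.
3. **Alpha diversity.** Observed richness, Shannon $H$ (nats, through
   `vegan`), Chao1 and evenness are computed on the surrogate table.
4. **Contig sharing.** Contigs none of whose genes is assigned at the
   phylum level are compared across sites by the Jaccard index of their
   31-mer sets; a pair with $J > 0.1$ (strict) is called *similar*, a contig
   with at least one similar partner in the other site is *shared*, and the
   headline statistic is the fraction of pooled unassigned contigs that are
   shared.
5. **Site statistics.** The virus-to-picoplankton ratio
   $\mathrm{VPR} = \mathrm{VLP\,mL^{-1}} / \mathrm{cells\,mL^{-1}}$ and mean
   read length complete the per-site summary, and `build_report()` bundles
   everything into one machine-readable report.

## Numerical and design choices

**Integerising TPM for Chao1.** Chao1 needs integer counts while the
surrogate table is real-valued. `surrogate_counts()` rounds TPM and floors
positive values below 0.5 to 1, so observed richness equals the number of
lineages with positive abundance. The integerisation is isolated in one
function and the Chao1 variant is a flag: the bias-corrected form
$S + F_1(F_1-1)/(2(F_2+1))$ is the default (it is what the standard ecology
toolkit computes and it is defined when doubletons are absent); the classic
form $S + F_1^2/(2F_2)$ is available and falls back to bias-corrected with a
warning when $F_2 = 0$.

**Evenness.** The package defines evenness as $E = H/S$. Pielou's
$J = H/\ln S$ is the more common index, but $H/S$ is the definition
consistent with the reference tables this package reproduces (for
$H = 4.381$, $S = 2209$: $H/S = 0.00198$ while $H/\ln S = 0.569$), so $E$
is reported as the headline and Pielou's $J$ alongside.

**Canonical k-mers.** Assembled contigs have arbitrary strand, so by default
each 31-mer is replaced by the lexicographic minimum of itself and its
reverse complement before comparison; `canonical = FALSE` preserves the
literal single-strand reading. $k$ must be odd so no k-mer is its own
reverse complement. Windows containing N are dropped; contigs shorter than
$k$ have empty sets, can never be shared, and remain in the denominator.
The Jaccard comparison uses whole-contig k-mer sets (the natural reading of
"similarity in k-mer space"); comparing individual windows would be a
different, alignment-like statistic. Sets are exact — at desk scale
(hundreds of contigs) sketching such as MinHash is unnecessary — and the
all-pairs computation is a sparse contig-by-k-mer matrix cross-product,
algebraically identical to nested-loop set intersection (a property the test
suite verifies against an independent brute-force oracle).

**Shared-fraction denominator.** "Fraction shared" is reported over the
pooled unassigned contigs of both sites; per-site fractions are also
emitted so either reading is available. The threshold comparison is strictly
greater-than.

**Unassignedness.** A lineage may be partial; unknown ranks are padded with
`unclassified_<rank>` (`pad_lineage()`). "Unassigned at phylum" therefore
means an empty lineage or one whose phylum field is `unclassified_phylum`
— both spellings map to the same predicate, and a contig with no predicted
genes at all is also unassigned.

## What the synthetic generator emulates — and what it does not

`simulate_two_site_dataset()` stands in for sampling, sequencing, assembly
and annotation so that every downstream stage can be tested against known
truth:

* **Communities.** Taxon relative abundances are symmetric
  Dirichlet-distributed (concentration exposed; the abundance distribution
  of real communities is unknown, and Dirichlet-multinomial is the standard
  stand-in). Both sites share one ORF catalog and differ in composition.
* **Read mapping.** Counts are one multinomial draw per site with per-ORF
  probability proportional to (taxon proportion / taxon's ORF count) ×
  ORF length. A taxon's proportion is its share of length-normalised
  sequencing effort, divided evenly over its genes; length-proportional
  sampling within a gene is exactly the bias that dividing by $L_i$ in TPM
  removes, so per-taxon summed TPM/10^6 is an unbiased estimator of the
  true proportions. The delta-method standard error of that estimator is
  exported (`tpm_recovery_se()`); it reduces to the binomial
  $\sqrt{p(1-p)/N}$ when all ORF lengths are equal.
* **ORFs.** Lengths are uniform on a configurable range (default
  200–3000 bp; empirical length distributions are deliberately not
  modelled), grouped 1–4 per contig with 1-based inclusive coordinates.
* **Unassigned contig pools.** `n_populations` random ancestor sequences
  (i.i.d. uniform A/C/G/T); a chosen fraction of populations seed contigs in
  both sites, the rest in one; every contig is an independently mutated copy
  (substitutions only, no indels — keeping the k-mer oracle exact). At
  mutation rate $\mu$, a k-mer survives in one copy with probability
  $(1-\mu)^k$ and is shared by two copies with probability about
  $(1-\mu)^{2k}$; at the default $\mu = 0.005$, $k = 31$ this gives
  within-population $J \approx 0.58 \gg 0.1$ while cross-population $J
  \approx 0$, so sharing is recovered essentially without error — the tests
  choose $\mu$ to keep that separation, and `generate_contig_pools()`
  rejects $\mu \ge 0.5$ outright.
* **Seeding.** One master seed is fanned out into per-stage child seeds, so
  each stage is independently reproducible and byte-identical under a
  repeated seed.

Passing tests on this generator show that the *computational* stages are
correct and that the estimators recover truth under the stated sampling
model. They do not validate anything the generator does not model: real
sequence evolution, read errors, assembly artefacts, chimeras, uneven
coverage, or annotation mistakes.

## Problem sizes and defaults

The package's reference study conditions — used by its tests and the
acceptance script as the standard synthetic workload — are: communities of
20–30 taxa over ~150–400 ORFs at library size $10^6$ reads per site
(recovery checks over 20 seeds), and unassigned pools of 40 populations × 5
contigs of 2 kb per occupied site at $\mu = 0.005$, shared-population
fraction 0.25, $k = 31$, threshold 0.1. The all-pairs engine handles these
sizes in seconds on one core.

## Worked example

```{r pipeline}
out <- run_pipeline(seed = 1, n_taxa = 10, n_orfs = 80, library_size = 1e5,
                    n_populations = 12, shared_population_fraction = 0.25,
                    contigs_per_population = 3, contig_length = 1000)
out$report$sites[c("site_id", "vpr", "mean_read_length")]
out$diversity
out$similarity
head(out$report$taxa)
```

The estimated shared fraction can be compared with the generator's truth
labels:

```{r truth}
mean(out$dataset$contig_truth$shared)
out$similarity$shared_fraction
```

## Known limitations

* The surrogate OTU table inherits TPM's compositionality; the diversity
  indices describe relative, not absolute, community structure.
* `chao1` on an integerised TPM table is an approximation whose behaviour
  depends on the integerisation rule; both the rule and the variant are
  explicit flags rather than hidden choices.
* The shared-fraction statistic depends on assembly quality in real data;
  the generator does not model mis-assembly.
* VPR consumes already-tabulated microscopy concentrations; counting itself
  (staining, fields) is wet-lab territory and out of scope.
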