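---
title: "Calling X-inactivation escape genes from allele-resolved counts"
author: "xciescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling X-inactivation escape genes from allele-resolved counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciescape)
```

## The biological setting

In female mammals one X chromosome is epigenetically silenced (X-chromosome
inactivation, XCI), but a minority of X-linked genes *escape* silencing and
remain transcribed from the inactive X (Xi). Measuring escape requires
telling apart reads from the two X homologues. `xciescape` implements the
analysis for an interspecific F1 hybrid design with *completely skewed* XCI:
a C57BL/6 (BL6) × *Mus spretus* cross in which an *Xist* mutation on the
maternal BL6 X forces the paternal *spretus* X to be inactive in every cell
of the F1 tissues (in the Patski cell line the orientation is reversed: the
BL6 X is inactive). Because the Xi is the same haplotype in all cells,
allele-specific reads assigned to that haplotype measure Xi expression
directly, without single-cell phasing.

The two genomes differ at millions of known SNPs. Reads are assigned by the
pseudo-genome strategy: the *spretus* alleles are substituted into the BL6
reference (`substitute_pseudo_genome()`), alignment treats both haplotypes
symmetrically, and each retained read (MAPQ ≥ 30, uniquely mapped) is
segregated by the catalog alleles it covers into BL6-SNP reads, spretus-SNP
reads, or allele-uncertain reads (`assign_reads()`). A read showing alleles
of both haplotypes, or only bases matching neither allele (sequencing
error), carries no clean haplotype information and is classed uncertain —
the conservative reading of "reads containing only one haplotype's SNPs".
Actual alignment is out of scope: the package consumes aligned-read
summaries (minimal SAM or TSV) and per-gene count tables.

## Expression measures

Two measures are carried per gene:

* **RPKM** (diploid): reads per kb of union exon length per million
  high-MAPQ uniquely mapped reads,
  $\mathrm{RPKM}_i = \dfrac{d_i}{(L_i/10^3)\,(T/10^6)}$, where $d_i$ is the
  gene's total exonic read count, $L_i$ its union exon length and $T$ the
  library's high-MAPQ unique read total. This is a plain RPKM on the full
  library denominator; fragment-model refinements of transcript
  quantifiers are deliberately not reproduced.
* **SRPM** (haploid): allele-specific SNP-containing exonic reads per 10
  million high-MAPQ unique reads, $n \times 10^7 / T$. Applied to the
  Xi-assigned count it gives the **Xi-SRPM**, the haploid measure of
  inactive-X expression on which the escape thresholds operate.

## The binomial escape model

For X-linked gene $i$ let $n_{i0}$ and $n_{i1}$ be the allele-specific reads
assigned to the Xi and Xa haplotypes, $n_i = n_{i0} + n_{i1}$. The model is

$$ n_{i0} \sim \mathrm{Binomial}(n_i, p_i), \qquad \hat p_i = n_{i0}/n_i, $$

with a Wald interval $\hat p_i \pm z_{\alpha/2}\sqrt{\hat p_i(1-\hat
p_i)/n_i}$ ($z_{\alpha/2} = 2.575829\ldots$ at the default $\alpha = 0.01$).

Because the two parental genomes are diverged, mapping losses differ between
haplotypes. The experiment-level **mapping-bias ratio** is estimated from
autosomes — where both haplotypes are expressed equally under skewed XCI —
as $r_m = N_{A0}/N_{A1}$, the ratio of pooled allele-specific autosomal
reads on the Xi-carrying versus Xa-carrying haplotype
(`mapping_bias_ratio()`; observed values in this design fall around
1.0–1.4). The corrected estimate is

$$ \bar p_i = \frac{n_{i0}}{n_{i0} + r_m n_{i1}}
           = \frac{\hat p_i}{\hat p_i + r_m(1-\hat p_i)} = f(\hat p_i). $$

**Correcting the limits.** The model states that the confidence limits are
"corrected accordingly", which admits two readings: transform the Wald
limits of $\hat p$ through $f$, or rebuild a Wald interval around $\bar p$.
We transform the limits. $f$ is monotone increasing with $f(0)=0$, so the
transformed limits preserve order, bracket $\bar p = f(\hat p)$ exactly, and
make the escape criterion "corrected lower limit > 0" equivalent to the raw
"lower limit > 0" — the classification is therefore insensitive to this
choice, which is why we prefer the reading that keeps the estimator identity
$\bar p = f(\hat p)$ exact. Raw Wald limits may exit $[0,1]$; the criterion
uses the unclamped lower limit, and limits are clamped only before
transformation and reporting.

**Three escape criteria** (`xci_escape()`, thresholds in
`escape_params()`): a gene is an escape gene when

1. the $100(1-\alpha)\%$ lower confidence limit of $\bar p_i$ exceeds zero
   (default $\alpha = 0.01$, a 99% lower limit);
2. diploid RPKM ≥ 1 (the gene is expressed at all); and
3. Xi-SRPM ≥ 2 — **low-level escape** for Xi-SRPM in $[2, 5)$,
   **high-level escape** for Xi-SRPM ≥ 5.

Genes with $n_i = 0$ are *not assessable* and excluded from escape tallies
but reported; genes failing any criterion are *not escape*. Note that
criterion 1 is deterministic at $n_{i0}=0$: a fully silenced gene can never
be called escape, whatever its coverage. Thresholds are applied to
unrounded values. Biological replicates are analyzed separately, never
pooled; `replicate_concordance()` reports the squared Pearson correlation
of Xi-SRPM between replicate fits as the reproducibility measure (well
above 0.9 in both the original experiments and the synthetic conditions
below). Per-gene intervals are reported without across-gene multiplicity
correction, matching the published procedure; *Xist* receives no special
handling and can be excluded downstream if desired.

## Allele-specific ChIP-seq peaks

Diploid peak calling is upstream (an `intersect_peaks()` utility supports
consensus-of-two-callers peak sets, with overlap defined as ≥ 1 bp). For
each diploid peak $i$ the BL6-SNP read count is modelled as
$n_{i,\mathrm{bl}} \sim \mathrm{Binomial}(n_i, p_i)$. Because skewed XCI
makes the X globally imbalanced, the X null is the pooled background over
all X peaks, $p_X = N_{X,\mathrm{bl}} / (N_{X,\mathrm{bl}} +
N_{X,\mathrm{sp}})$ (`estimate_x_background()`); autosomal peaks may use an
analogous pooled autosomal background or a fixed 0.5
(`fixed_background()`). Peaks with fewer than one allele-specific read per
10 million mapped reads — implemented as
$\lceil \mathrm{total\ mapped} / 10^7 \rceil$ reads — are not assessable.
Assessable peaks are classified with inclusive one-sided exact binomial
tails ($P(K \ge k)$, $P(K \le k)$; the standard conservative convention,
unstated in the original description):

* **BL6-preferred**: upper-tail $p < 0.05$;
* **spretus-preferred**: lower-tail $p < 0.05$;
* **both-preferred**: both tails ≥ 0.25;
* **ambiguous**: the remaining band, smallest tail in $[0.05, 0.25)$. The
  three published labels do not cover this band — consistent with published
  per-class counts not summing to the X-linked totals — so it is reported
  explicitly rather than silently merged.

`summarize_peak_calls()` maps the haplotype labels onto Xa/Xi through the
experiment's Xi orientation, so the same code serves the tissue
(Xi = spretus) and Patski (Xi = BL6) designs.

## The synthetic-data generator

Real libraries at $10^8$ reads with deposited alignments are not usable for
routine testing, so `sim_config()` defines fully synthetic conditions with
known ground truth; every pipeline stage is validated against them.

| parameter | default | rationale |
|---|---|---|
| `library_size` | 2×10⁷ | high-MAPQ unique reads of a desk-scale RNA-seq library |
| `snp_capture_prob` | 0.2 | fraction of exonic reads overlapping ≥ 1 SNP between these diverged genomes |
| `rm_true` | 1.1 | centre of the bias range observed in this design (≈ 1.0–1.4) |
| `n_genes_x`, `n_genes_autosomal` | 300 / 700 | desk-scale stand-in for the ~1100 X / ~27k autosomal genes with exonic SNPs |
| `frac_low_escape`, `frac_high_escape` | 0.1 / 0.1 | escape is a minority state on the X |
| `true_pi_low`, `true_pi_high` | [0.05, 0.15] / [0.20, 0.50] | Xi-expression proportions typical of partial vs robust escape |
| expression depth | lognormal(log 1000, 0.6) | the assessable set is expressed genes with exonic SNPs; heavy right tail |
| `replicate_noise_sd` | 0.1 | log-scale biological replicate variability |

Counts are generated as: diploid depth $\sim$ Poisson around the lognormal
expectation; allele-informative reads by binomial thinning at
`snp_capture_prob`; Xi reads $\sim$ Binomial(informative, true $\pi$);
then each Xa-haplotype read is kept with probability $1/r_m^{\mathrm{true}}$
(the simplest mechanism that makes the realized autosomal ratio
$N_{A0}/N_{A1}$ estimate $r_m^{\mathrm{true}}$). Silenced genes have true
$\pi = 0$ exactly (an optional leak parameter exists); autosomal genes have
true $\pi = 0.5$ before thinning. Library statistics are derived from the
generated counts, exactly as the pipeline would compute them from data.
ChIP peaks draw totals Poisson(30) with a fraction of peaks shifted away
from the background proportion. Identical seeds give identical outputs.

What the generator does **not** emulate: sequencing error, GC and fragment
biases, spliced-alignment artefacts, gene-length–dependent capture,
overdispersion beyond the binomial, and the scale of the real libraries.
Passing the recovery tests therefore shows the estimator and decision rules
are correct under the stated model, not that the thresholds are optimal for
any particular real tissue.

## Numerical and design choices

* Percentages in the SNP location summary use half-away-from-zero rounding
  to one decimal; segregation-table percentages are reported to integer
  precision. All thresholds are applied to unrounded values.
* SNP coordinates are 1-based (VCF convention); exon and peak intervals are
  0-based half-open (BED convention); conversion is centralized in the
  readers, and chromosome spellings "X"/"chrX" are normalized to "chrX".
* Only biallelic SNVs are supported; indel rows are dropped with a counted
  warning. Overlapping exons are unioned before length computation; a read
  overlapping two genes' exons counts for both.
* The classifier works single-pass against one reference plus the catalog;
  the original two-genome mapping-and-reconciliation procedure's residual
  asymmetry is exactly what $r_m$ measures and corrects.
* Whether the published RPKM denominator counts reads from one genome or
  reconciled across both is unstated; we use the single library total,
  a choice of small consequence since it cancels within an experiment's
  threshold comparisons.
* Uniqueness of mapping is taken from the input flag (or a user-supplied
  mapping from SAM optional fields), never recomputed.

Problem sizes used in the shipped validation: replicate-concordance and
recovery runs use the default 1000-gene configuration (20 seeds for the
recovery rates); interval coverage uses 10,000 binomial draws at
$p = 0.3$, $n = 1000$; the exact-tail check enumerates all $k \le n \le 50$
against direct pmf summation.

## A worked run

```{r example}
cfg <- sim_config(seed = 7)
sim <- simulate_rnaseq_experiment(cfg)
sim$lib

on_x <- sim$truth$chrom == "chrX"
x_counts <- sim$counts[on_x, ]; class(x_counts) <- class(sim$counts)
fit <- xci_escape(x_counts, sim$genes, sim$lib)
summary(fit)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(fit)
```

## Known limitations

Beyond the generator's idealizations: the binomial model ignores
overdispersion between SNPs within a gene (a beta-binomial would be the
next refinement); phasing is assumed perfect (given, not inferred); the
design cannot produce reciprocal crosses, so parent-of-origin effects are
confounded with strain effects by construction; and the `ambiguous` peak
band means the four ChIP categories are a partition of assessable peaks,
not of all peaks.
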