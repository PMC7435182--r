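---
title: "Mapping a recessive locus with BSRmap: models and methods"
author: "BSRmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus with BSRmap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(BSRmap))
```

## The problem

A single recessive mutation — here motivated by an EMS-induced leaf-crinkle
mutant of Chinese cabbage — is to be localised from an F2 cross. The
package implements the computational chain that takes such a study from
pooled sequencing data to a candidate gene:

1. **Bulked-segregant scan (BSR-Seq).** Two bulks of phenotypically extreme
   F2 plants (mutant and wild type) are sequenced; per-SNV allele
   frequencies diverge between bulks only near the causal locus.
2. **Mendelian segregation tests.** Chi-squared goodness-of-fit of
   phenotype counts against 3:1 (F2) and 1:1 (backcross) expectations.
3. **Recombinant-based fine mapping.** Marker genotypes of
   recessive-phenotype homozygotes expose recombinant gametes; distances
   come from Kosambi's mapping function, and the locus is bracketed by the
   closest flanking markers that still show recombinants.
4. **Candidate annotation.** Genes overlapping the interval, codon-level
   classification of a candidate substitution, and SNP–phenotype
   co-segregation.
5. **Expression analysis.** Relative expression of the candidate gene by
   the 2^−ΔΔCt method with a two-group t-test.

A synthetic-data generator with full gamete-level ground truth stands in
for raw sequencing data, so every stage is testable end to end.

## The ED statistic and region calling

For a biallelic SNV with alternate-allele frequencies $f_m$ (mutant bulk)
and $f_w$ (wild-type bulk),

$$ED = \sqrt{(f_m - f_w)^2 + \bigl((1-f_m) - (1-f_w)\bigr)^2}
     = \sqrt{2}\,\lvert f_m - f_w\rvert,$$

bounded by $\sqrt 2$. ED is raised to the power $k = 5$ to suppress
mid-range background noise; since $x \mapsto x^k$ is strictly increasing,
ranking (and hence top-quantile selection) is unchanged by the transform —
a property the test suite asserts. Selection keeps the top $q = 1\%$ of
transformed values genome-wide, including ties at the boundary so that
equal evidence is never silently dropped. Before any of this, SNVs must
exceed a per-pool depth of 3 reads (strictly greater; exactly 3 is
removed), applied to each pool separately.

Candidate regions are built by merging consecutive selected SNVs whose gap
is at most `maxGapBp` (default 2 Mb) and keeping clusters with at least
`minSnv` members (default 5). These two parameters are a deliberate design
choice of this package: they are tuned so that a single strong linkage
block at BSA resolution merges into one region. A consequence worth
knowing: at sparse SNV densities (say 6,000 SNVs on a 90 Mb genome), the
top-1% SNVs of a *null* dataset are spaced about 1.5 Mb apart on average —
below the default merge radius — so null data produce broad merged regions
rather than scattered small ones. When screening for the *absence* of a
signal, lower `maxGapBp` below the expected null spacing
(`genome size × q / n_SNV`); the suite demonstrates this at 200 kb. No
sliding-window smoothing is applied: selection is strictly per-SNV.

## Segregation tests and map distances

`chiSquareSegregation()` computes Pearson's $\chi^2 = \sum (O-E)^2/E$
without continuity correction (Yates' correction is available behind a
flag), with the critical value $\chi^2_{0.05,1} = 3.84$ for two classes.
With the classic F2 counts 103:34 the statistic is 0.0024, comfortably
below 3.84, and the observed ratio reports as 3.029:1.

Recombinant gametes are counted from genotype codes of recessive
homozygotes: `A` (mutant-parent homozygote) contributes 0, `H` 1, `B` 2;
missing calls are excluded. The recombination frequency is
$r = \text{recombinants}/(2N)$ — each diploid contributes two gametes —
and only this gamete-level counting reproduces published sub-cM distances:
7 recombinant individuals among 1,575 homozygotes give
$r = 0.00222$ and a Kosambi distance

$$cM = 25\,\ln\frac{1+2r}{1-2r} = 0.22,$$

and 12 give 0.38 cM. For small $r$ the function is linear,
$cM \approx 100r$, with relative error $(4/3)r^2$ (about 0.013% at
$r = 0.01$).

Side assignment for fine mapping uses the identity of recombinant
individuals: markers on opposite sides of the locus have disjoint
recombinant sets, markers on the same side nested ones. The implementation
scans every cut point along the physical marker order and keeps the cut
minimising cross-side shared individuals; any remaining shared individuals
(double crossovers produce them at low frequency in populations of ~1,500)
are reported as conflicts rather than silently resolved. The interval runs
between the closest flanking markers with at least one recombinant;
zero-recombinant markers co-segregate and must fall inside. If every
marker co-segregates the result is "unresolved", not an error.

## Codon-level SNP annotation

`annotateSnp()` maps a genomic substitution through the gene model's CDS
segments (always stored in ascending genomic order; minus-strand genes are
handled by reverse complement, and exon numbering follows transcription
order). The codon containing the site is translated with the standard
nuclear genetic code; effects classify as synonymous, missense or nonsense
(3-letter amino-acid codes, stop = `Ter`). The canonical worked example —
C→T at the second position of an ACT codon — yields ATT: Thr→Ile,
missense. Positions inside the gene but outside the CDS are flagged
`non_coding`. A reference-base mismatch against the supplied genome is
fatal by design: it means coordinates and sequence disagree.

## 2^−ΔΔCt expression analysis

Per replicate, $\Delta Ct = Ct_{target} - Ct_{reference}$; per tissue,
$\Delta\Delta Ct$ subtracts the mean calibrator $\Delta Ct$ (wild type by
default), and the replicate-level fold change is $2^{-\Delta\Delta Ct}$.
Replicate-level folds (not group means) feed a two-sided Welch t-test,
preserving biological-replicate variance; Student's pooled-variance
variant is available behind a flag. With zero noise the configured fold
change is recovered exactly. Under Gaussian Ct noise the fold-change
estimator is lognormal and carries a small upward bias,
$\mathbb{E}[\hat F] = F\,e^{(\ln 2)^2\sigma^2_{\Delta\Delta Ct}/2}$, which
the tests verify in closed form rather than treating as error.

One numerical guard: when both groups have zero variance and equal means
(noiseless null data), the t-statistic is undefined and the p-value is
reported as 1.

## The synthetic-data generator

`simulateF2()` draws each gamete from an F1 meiosis with crossover count
$\sim$ Poisson(length in Morgans) and uniform breakpoints — a
no-interference (Haldane) process. Distances are *reported* via Kosambi
downstream; at the sub-cM scales being recovered the Kosambi–Haldane
discrepancy is negligible, and the simpler generative model is preferred.
The cM→bp map is linear per chromosome. Phenotype follows the
single-recessive rule, giving 3:1 segregation in expectation.

`simulateBulks()` samples bulk members at random from each phenotype
class, computes the true pool frequency as the mean over the bulk's
gametes, then draws Poisson read depth (real per-SNV depth distributions
are platform- and pipeline-dependent; Poisson is this package's choice)
and binomial alternate counts
at the error-adjusted frequency. Sequencing error is symmetric: a read
reports the wrong allele with probability `seqError` (default 0.001, an
Illumina-scale per-base rate).

Defaults mirror the study design this package targets: bulks of 50, mean
depth 20, 2,000 SNVs on each of three 100-cM / 30-Mb chromosomes. The
generator reproduces, and the tests verify: 3:1 phenotypes; 1:2:1 codes at
unlinked markers; conditional marker-genotype frequencies among recessive
homozygotes matching an exact two-locus gamete-frequency enumeration;
fixation of the causal allele in the mutant bulk; and bit-identical output
under a fixed seed.

What the generator does *not* emulate: linkage-disequilibrium structure of
real germplasm, locally varying recombination rate, EMS mutation spectra,
read-level artefacts (mapping bias, strand bias, duplicates), or
transcript-level coverage variation of RNA-seq. Passing recovery tests
therefore demonstrate correctness of the inference chain under the stated
genetic model, not robustness to every artefact of real data.

## Problem sizes and calibration checks

The acceptance-level properties are computed at the study's own scales:
causal-locus recovery of the ED scan over 100 simulated datasets (bulks of
50, depth 20, 6,000 SNVs; observed 99–100% containment), fine-map interval
recovery over 100 populations of 1,575 recessive homozygotes with markers
every 0.2 cM (observed 100%), qPCR fold recovery exact at zero noise and
matching the closed-form lognormal mean at $\sigma_{Ct} = 0.2$, and t-test
type-I error over 1,000 null simulations. The type-I check uses 10
replicates per group: at very small $n$ (e.g. 3) the Welch–Satterthwaite
approximation is conservative (true size ≈ 0.034), so the nominal-0.05
claim is evaluated where the approximation holds, while a separate test
pins the small-$n$ behaviour as conservative-never-anticonservative.

## Known limitations

- The ED scan is biallelic by construction; multiallelic records are
  excluded (or split into biallelic records on request) upstream.
- Region-calling defaults assume BSA-scale SNV densities; see the note on
  null spacing above.
- Fine mapping expects markers on one chromosome and recessive-only
  individuals; unselected tables are refused unless forced.
- No multi-locus map ordering, no QTL interval mapping, no
  amplification-efficiency (Pfaffl) correction for qPCR.
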