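# BSRmap

Map a single recessive locus in an F2 population from bulked-segregant
RNA-seq (BSR-Seq) and marker-based fine mapping, then annotate and
validate the candidate gene. BSRmap is aimed at plant geneticists running
mutant-mapping studies (EMS mutants, natural recessive variants) who have
pooled variant calls for two phenotype-selected bulks, marker genotypes
for recessive-phenotype F2 individuals, and qPCR data for candidate genes.

The package covers five stages, each exposed as ordinary R functions over
Bioconductor containers (`GRanges`-based S4 classes):

- **ED scan** — for each biallelic SNV with alternate-allele frequencies
  `f_m`, `f_w` in the mutant and wild-type bulks,
  `ED = sqrt((f_m - f_w)^2 + ((1 - f_m) - (1 - f_w))^2) = sqrt(2)|f_m - f_w|`.
  ED is raised to the 5th power to suppress background noise, the top 1%
  of ED^5 values are selected genome-wide (ties included), and selected
  SNVs are merged into candidate regions. SNVs must exceed 3× coverage in
  both pools.
- **Segregation tests** — Pearson chi-squared against Mendelian ratios
  (3:1, 1:1) with the `χ²(0.05, 1) = 3.84` criterion.
- **Fine mapping** — recombinant gametes counted from genotype codes of
  recessive homozygotes (`H` = 1, `B` = 2 gametes), `r = rec/(2N)`,
  Kosambi distance `cM = 25·ln((1+2r)/(1−2r))`, marker sides assigned by
  disjointness of recombinant-individual sets, and the locus bracketed by
  the closest flanking markers that still show recombinants.
- **Candidate annotation** — genes overlapping the interval, codon-level
  effect of a substitution (strand-aware, standard genetic code), and
  SNP–phenotype co-segregation under the recessive model.
- **qPCR** — relative expression by `2^−ΔΔCt` with replicate-level fold
  changes and a Welch t-test at α = 0.05.

A simulation module (`simConfig()`, `simulateF2()`, `simulateBulks()`,
`simulateMarkerGenotypes()`, `simulateQpcr()`) generates F2 populations
with gamete-level ground truth, so the whole pipeline can be exercised
without any sequencing data.

## Worked example

```r
library(BSRmap)

## simulate a study: 400 F2 plants, bulks of 50, depth 20,
## 2,000 SNVs on each of 3 chromosomes, causal locus at 50 cM on chr1
cfg <- simConfig(nF2 = 400)
pop <- simulateF2(cfg, seed = 1)
table(phenotypes(pop))
#>   mutant wildtype
#>      110      290

pv  <- simulateBulks(pop, cfg, seed = 2)
res <- scanBsa(pv)
res
#> BsaScanResult: 6000 SNVs scanned, k = 5, q = 0.01
#>   threshold (ED^k): 1.2287 | 64 SNVs selected | 1 region(s)
#> GRanges object with 1 range and 1 metadata column:
#>       seqnames           ranges strand |      nSnv
#>   [1]     chr1 6479312-20704673      * |        64
causalLocus(pop)$bp
#> [1] 15000000        # inside the called region

## segregation arithmetic of a real cross: 103 wild-type vs 34 mutant F2s
chiSquareSegregation(c(103, 34), c(3, 1))
#> Segregation test: observed 103:34 vs expected 3:1
#>   chi-squared = 0.002433 (df = 1), P = 0.9607, critical = 3.84 -> fits
segregationRatio(c(103, 34))$label
#> [1] "3.029:1"

## fine-mapping distances: 7 and 12 recombinants among 1,575 homozygotes
round(kosambiCM(recombinationFrequency(7, 1575)), 2)
#> [1] 0.22
round(kosambiCM(recombinationFrequency(12, 1575)), 2)
#> [1] 0.38

## candidate SNP: C->T at the second position of an ACT codon
genome <- Biostrings::DNAStringSet(c(chrT = "ATGACTTGA"))
gene   <- GeneModel("cand", "chrT", "+", 1, 9, cdsStarts = 1, cdsEnds = 9)
annotateSnp(gene, genome, "chrT", 5, "C", "T")
#> SnpEffect: cand exon 1 codon 2 (ACT->ATT) Thr2Ile - missense

## qPCR fold change, wild type as calibrator
ct <- simulateQpcr(3, foldChange = 4, sdCt = 0)
deltaDeltaCt(ct)$summary
#>      group tissue n meanFold sdFold pValue significant
#> 1   mutant   leaf 3        4      0      0        TRUE
#> 2 wildtype   leaf 3        1      0     NA       FALSE
```

The interval arithmetic works on plain `GRanges`: flanking markers at
100,000 and 226,689 bp give `physicalSpan()` of 126.69 kb.

Readers are provided for the standard formats: `readPooledVariants()`
(VCF with per-sample AD, or a tabular schema), `readMarkerTable()`
(delimited genotype-code tables), `readGeneModels()` (GFF3 or BED12) and
`readCtTable()`.

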