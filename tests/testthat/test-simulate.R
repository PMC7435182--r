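test_that("phenotypes segregate 3:1 within binomial sampling error", {
    pop <- simulateF2(simConfig(nF2 = 4000), seed = 101)
    pMut <- mean(phenotypes(pop) == "mutant")
    se <- sqrt(0.25 * 0.75 / 4000)
    expect_lt(abs(pMut - 0.25), 3 * se)
})

test_that("a 0-cM chromosome yields no recombinant gametes", {
    cfg <- simConfig(nChromosomes = 2, chromLengthCM = c(0, 50),
                     chromLengthBp = c(1e4, 1e7), causalChrom = 2,
                     causalCM = 25)
    pop <- simulateF2(cfg, seed = 7)
    expect_true(all(lengths(pop@breaks[["chr1"]]) == 0L))
})

test_that("marker frequencies among recessive homozygotes match the exact
           two-locus oracle", {
    # marker 1 cM from the causal locus; Haldane r from the crossover model
    d <- 1
    r <- haldaneR(d)
    oracle <- twoLocusMarkerFreqOracle(r)   # P(B), P(H), P(A) | aa
    expect_equal(oracle[2], 2 * r * (1 - r), tolerance = 1e-12)

    cfg <- simConfig(nChromosomes = 1, nF2 = 20000, causalCM = 50)
    pop <- simulateF2(cfg, seed = 42)
    tab <- simulateMarkerGenotypes(pop,
        data.frame(marker = "M", chrom = "chr1", cM = 50 + d))
    calls <- markerCalls(tab)[, 1L]
    n <- length(calls)
    for (k in 1:3) {
        obs <- mean(calls == c("B", "H", "A")[k])
        se <- sqrt(oracle[k] * (1 - oracle[k]) / n)
        expect_lt(abs(obs - oracle[k]), 4 * se + 1e-9)
    }
})

test_that("simulation output is bit-identical under the same seed", {
    cfg <- simConfig(nF2 = 150, nSnvs = 200, bulkSize = 20)
    a <- simulateF2(cfg, seed = 33)
    b <- simulateF2(cfg, seed = 33)
    expect_identical(a@breaks, b@breaks)
    expect_identical(phenotypes(a), phenotypes(b))
    expect_identical(as.data.frame(simulateBulks(a, cfg, seed = 44)),
                     as.data.frame(simulateBulks(b, cfg, seed = 44)))
})

test_that("bulk frequencies fix at the causal locus and stabilise at depth", {
    # a 0-cM chromosome makes every SNV fully linked to the causal locus
    cfg <- simConfig(nChromosomes = 1, chromLengthCM = 0,
                     chromLengthBp = 1e4, causalChrom = 1, causalCM = 0,
                     nF2 = 400, seqError = 0, meanDepth = 1e4, nSnvs = 50)
    pop <- simulateF2(cfg, seed = 5)
    pv <- simulateBulks(pop, cfg, seed = 6)
    f <- alleleFrequencies(pv)
    # recessive selection forces the mutant bulk to fixation
    expect_true(all(f$fMut == 1))
    # one shared pool frequency, so at depth 1e4 the observed wild-type
    # frequencies concentrate tightly around it (law of large numbers)
    expect_lt(stats::sd(f$fWt), 3 * sqrt(0.25 / 1e4))
    expect_lt(abs(mean(f$fWt) - 1 / 3), 0.15)
})

test_that("unlinked SNVs show no mean frequency divergence between bulks", {
    # causal locus on chr1; chr2 carries only unlinked SNVs. SNVs within a
    # replicate share bulk members (they are correlated), so the Monte
    # Carlo error is taken over independent replicates.
    cfg <- simConfig(nChromosomes = 2, nF2 = 240, bulkSize = 30,
                     nSnvs = 40, meanDepth = 20)
    set.seed(13)
    d <- vapply(seq_len(50), function(i) {
        pop <- simulateF2(cfg)
        pv <- simulateBulks(pop, cfg)
        unlinked <- pv[as.character(GenomicRanges::seqnames(pv)) == "chr2"]
        f <- alleleFrequencies(depthFilter(unlinked, 0, verbose = FALSE))
        mean(f$fMut - f$fWt, na.rm = TRUE)
    }, numeric(1))
    expect_lt(abs(mean(d)), 4 * stats::sd(d) / sqrt(length(d)))
})

test_that("marker genotypes follow the stored gametes", {
    cfg <- simConfig(nChromosomes = 1, nF2 = 3000, causalCM = 50)
    pop <- simulateF2(cfg, seed = 21)

    # at the causal locus every recessive homozygote is A
    tabC <- simulateMarkerGenotypes(pop,
        data.frame(marker = "C", chrom = "chr1", cM = 50))
    expect_true(all(markerCalls(tabC) == "A"))
    expect_equal(tabC@population, "recessive")

    # a far marker in the full F2 follows 1:2:1
    tabU <- simulateMarkerGenotypes(pop,
        data.frame(marker = "U", chrom = "chr1", cM = 0), restrict = "all")
    counts <- table(factor(markerCalls(tabU), levels = c("A", "H", "B")))
    st <- chiSquareSegregation(as.integer(counts), c(1, 2, 1))
    expect_equal(st$conclusion, "fits")

    # recombinant gametes at a 0.5-cM marker are binomial around 2*n*r
    n2 <- 1575L
    cfg2 <- simConfig(nChromosomes = 1, nF2 = 6600, causalCM = 50)
    pop2 <- simulateF2(cfg2, seed = 22)
    tabL <- simulateMarkerGenotypes(pop2,
        data.frame(marker = "L", chrom = "chr1", cM = 50.5))
    calls <- markerCalls(tabL)[seq_len(n2), 1L]
    rec <- countRecombinantGametes(calls)[["recombinants"]]
    rTrue <- haldaneR(0.5)
    expect_lt(abs(rec - 2 * n2 * rTrue),
              3 * sqrt(2 * n2 * rTrue * (1 - rTrue)) + 1e-9)
})

test_that("marker positions outside the chromosomes are fatal", {
    pop <- simulateF2(simConfig(nF2 = 50), seed = 3)
    expect_error(simulateMarkerGenotypes(pop,
        data.frame(marker = "X", chrom = "chr1", cM = 500)), "outside")
    expect_error(simulateMarkerGenotypes(pop,
        data.frame(marker = "X", chrom = "chr9", cM = 10)), "outside")
})

test_that("bulk construction fails loudly when a phenotype class is short", {
    cfg <- simConfig(nF2 = 60, bulkSize = 50)
    pop <- simulateF2(cfg, seed = 12)
    expect_error(simulateBulks(pop, cfg, seed = 1), "insufficient")
})

test_that("qPCR simulation encodes the configured fold change", {
    ct0 <- simulateQpcr(3, foldChange = 1, sdCt = 0, seed = 1)
    expect_equal(deltaDeltaCt(ct0)$summary$meanFold, c(1, 1))
    ct4 <- simulateQpcr(3, foldChange = 4, sdCt = 0, seed = 1)
    s <- deltaDeltaCt(ct4)$summary
    expect_equal(s$meanFold[s$group == "mutant"], 4)
    expect_error(simulateQpcr(1, foldChange = 2), ">= 2")
    expect_error(simulateQpcr(3, foldChange = 0), "> 0")
})

test_that("simConfig validates its invariants", {
    expect_error(simConfig(seqError = 0.6), "0.5")
    expect_error(simConfig(causalChrom = 5), "causalChrom")
    expect_error(simConfig(meanDepth = 0), "meanDepth")
})
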