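test_that("segregation chi-square matches the Pearson formula", {
    # hand/brute-force oracle: sum((O-E)^2/E)
    pearson <- function(obs, ratio) {
        e <- sum(obs) * ratio / sum(ratio)
        sum((obs - e)^2 / e)
    }
    st <- chiSquareSegregation(c(103, 34), c(3, 1))
    expect_equal(st$statistic, pearson(c(103, 34), c(3, 1)))
    expect_equal(st$statistic, 0.00243, tolerance = 1e-2)
    expect_equal(st$conclusion, "fits")
    expect_equal(st$criticalValue, 3.84, tolerance = 1e-3)

    expect_equal(chiSquareSegregation(c(75, 25), c(3, 1))$statistic, 0)

    st2 <- chiSquareSegregation(c(26, 24), c(1, 1))
    expect_equal(st2$statistic, 0.08, tolerance = 1e-10)
    expect_equal(st2$conclusion, "fits")

    set.seed(31)
    for (i in 1:20) {
        k <- sample(2:4, 1)
        obs <- rpois(k, 40) + 1
        ratio <- sample(1:4, k, replace = TRUE)
        expect_equal(chiSquareSegregation(obs, ratio)$statistic,
                     pearson(obs, ratio), tolerance = 1e-12)
    }
    # Yates-corrected variant
    stY <- chiSquareSegregation(c(26, 24), c(1, 1), correct = TRUE)
    expect_equal(stY$statistic, sum((abs(c(26, 24) - 25) - 0.5)^2 / 25))
    expect_error(chiSquareSegregation(c(10, 0), c(1, 0)), "zero")
})

test_that("segregation ratios report as x:1 to three decimals", {
    expect_equal(segregationRatio(c(103, 34))$value, 3.029)
    expect_equal(segregationRatio(c(103, 34))$label, "3.029:1")
    expect_equal(segregationRatio(c(26, 24))$value, 1.083)
    expect_equal(segregationRatio(c(50, 50))$label, "1.000:1")
    expect_equal(segregationRatio(c(50, 0))$label, "all:0")
})

test_that("recombinant gametes count H as one and B as two, skipping U", {
    expect_equal(countRecombinantGametes(c("A", "A", "H", "A", "B")),
                 c(recombinants = 3L, individuals = 2L, nScored = 5L))
    expect_equal(countRecombinantGametes(rep("A", 8))[["recombinants"]], 0L)
    expect_equal(countRecombinantGametes(c("U", "A", "H")),
                 c(recombinants = 1L, individuals = 1L, nScored = 2L))
    expect_error(countRecombinantGametes(c("A", "x")), "A, H, B or U")
})

test_that("recombination frequency is recombinants over twice the scored", {
    expect_equal(recombinationFrequency(7, 1575), 7 / 3150)
    expect_equal(recombinationFrequency(0, 100), 0)
    expect_warning(r <- recombinationFrequency(2 * 1575, 1575), "unlinked")
    expect_equal(r, 1)
    expect_error(recombinationFrequency(1, 0), "> 0")
})

test_that("Kosambi distances reproduce the sub-cM fine-mapping values", {
    expect_equal(round(kosambiCM(7 / (2 * 1575)), 2), 0.22)
    expect_equal(round(kosambiCM(12 / (2 * 1575)), 2), 0.38)
    expect_equal(kosambiCM(0), 0)
    expect_equal(kosambiCM(0.25), 25 * log(3))
    expect_error(kosambiCM(0.5), "infinite")
})

test_that("Kosambi is strictly increasing and linear for small r", {
    r <- seq(0, 0.49, by = 0.01)
    cm <- kosambiCM(r)
    expect_false(is.unsorted(cm, strictly = TRUE))
    # cM = 100r (1 + (4/3) r^2 + O(r^4)): the relative error of the linear
    # approximation is (4/3) r^2, i.e. below 0.014% throughout r <= 0.01
    small <- c(1e-4, 1e-3, 0.01)
    relErr <- abs(kosambiCM(small) - 100 * small) / (100 * small)
    expect_true(all(relErr < 4 / 3 * small^2 * 1.01))
})

test_that("fineMap partitions markers by recombinant disjointness", {
    # seven recombinants on one side, twelve different ones on the other,
    # and a co-segregating marker in between
    n <- 1575L
    ids <- paste0("p", seq_len(n))
    calls <- matrix("A", n, 3,
                    dimnames = list(ids, c("SSRS-1", "SSRMG-4", "IndelD-20")))
    calls[1:7, "SSRS-1"] <- "H"
    calls[8:19, "IndelD-20"] <- "H"
    markers <- GenomicRanges::GRanges("A01",
        IRanges::IRanges(c(100000L, 150000L, 226689L), width = 1))
    names(markers) <- colnames(calls)
    tab <- MarkerGenotypeTable(calls, markers, population = "recessive")
    fm <- fineMap(tab)
    res <- markerResults(fm)
    expect_equal(fm@status, "resolved")
    expect_equal(res$side[res$marker == "SSRS-1"], "left")
    expect_equal(res$side[res$marker == "IndelD-20"], "right")
    expect_equal(res$side[res$marker == "SSRMG-4"], "cosegregating")
    expect_equal(fm@cosegregating, "SSRMG-4")
    expect_length(fm@conflicts, 0L)
    expect_equal(GenomicRanges::start(mappedInterval(fm)), 100000L)
    expect_equal(GenomicRanges::end(mappedInterval(fm)), 226689L)
    expect_equal(physicalSpan(fm), 126.69)
    expect_equal(round(res$cM[res$marker == "SSRS-1"], 2), 0.22)
    expect_equal(round(res$cM[res$marker == "IndelD-20"], 2), 0.38)
})

test_that("fineMap recovers a simulated causal locus between flanks", {
    cfg <- simConfig(nChromosomes = 1, nF2 = 6400, causalCM = 50)
    pop <- simulateF2(cfg, seed = 77)
    mk <- data.frame(marker = sprintf("M%02d", 1:9), chrom = "chr1",
                     cM = c(49.5, 49.8, 49.9, 49.95, 50, 50.05, 50.1,
                            50.3, 50.6))
    tab <- simulateMarkerGenotypes(pop, mk)
    fm <- fineMap(tab)
    expect_equal(fm@status, "resolved")
    iv <- mappedInterval(fm)
    bp <- causalLocus(pop)$bp
    expect_lte(GenomicRanges::start(iv), bp)
    expect_gte(GenomicRanges::end(iv), bp)
    # the marker at the causal position co-segregates and sits inside
    expect_true("M05" %in% fm@cosegregating ||
                markerResults(fm)$recombinantGametes[5] > 0)
})

test_that("degenerate and invalid fine-mapping inputs are handled", {
    n <- 30L
    calls <- matrix("A", n, 2,
                    dimnames = list(paste0("p", 1:n), c("M1", "M2")))
    markers <- GenomicRanges::GRanges("A01",
        IRanges::IRanges(c(100L, 200L), width = 1))
    names(markers) <- c("M1", "M2")
    # all co-segregating: unresolved, no interval, not an error
    tab <- MarkerGenotypeTable(calls, markers, population = "recessive")
    fm <- fineMap(tab)
    expect_equal(fm@status, "unresolved")
    expect_null(mappedInterval(fm))

    # one-sided recombinants cannot flank
    calls2 <- calls
    calls2[1:3, "M1"] <- "H"
    tab2 <- MarkerGenotypeTable(calls2, markers, population = "recessive")
    expect_error(fineMap(tab2), "cannot flank")

    # unselected F2 table refused without force
    tab3 <- MarkerGenotypeTable(calls2, markers, population = "all")
    expect_error(fineMap(tab3), "recessive")
})

test_that("physical span is inclusive-kb arithmetic", {
    expect_equal(physicalSpan(GenomicRanges::GRanges("A01",
        IRanges::IRanges(100000, 226689))), 126.69)
    expect_equal(physicalSpan(GenomicRanges::GRanges("A01",
        IRanges::IRanges(5, 5))), 0.00)
    set.seed(41)
    a <- sample.int(1e6, 1)
    b <- a + sample.int(1e5, 1)
    expect_equal(physicalSpan(GenomicRanges::GRanges("A01",
        IRanges::IRanges(a, b))), round((b - a + 1) / 1000, 2))
})
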