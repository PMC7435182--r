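# Toy chromosome with a two-exon gene; CDS is positions 11-19 + 31-36
# giving ATG ACT AAA CAA TGA (Met Thr Lys Gln Stop) on the plus strand.
makeToyLocus <- function() {
    seq <- paste0("CCCCCCCCCC",      # 1-10 spacer
                  "ATGACTAAA",       # 11-19 CDS exon 1
                  "GGGGGGGGGGG",     # 20-30 intron
                  "CAATGA",          # 31-36 CDS exon 2
                  "CCCC")            # trailer
    genome <- Biostrings::DNAStringSet(seq)
    names(genome) <- "chrT"
    gene <- GeneModel("gT", "chrT", "+", 11, 36,
                      cdsStarts = c(11, 31), cdsEnds = c(19, 36))
    list(genome = genome, gene = gene)
}

test_that("gene-interval overlap uses the any-overlap rule, sorted", {
    genes <- list(
        g1 = GeneModel("g1", "A01", "+", 1000, 2000),
        g2 = GeneModel("g2", "A01", "+", 5000, 6000),
        g3 = GeneModel("g3", "A01", "+", 9000, 9500),
        g4 = GeneModel("g4", "A02", "+", 1000, 2000))
    iv <- GenomicRanges::GRanges("A01", IRanges::IRanges(900, 6200))
    hit <- genesInInterval(genes, iv)
    expect_equal(unname(vapply(hit, geneId, character(1))), c("g1", "g2"))

    # 1-bp edge overlap is included
    edge <- GenomicRanges::GRanges("A01", IRanges::IRanges(2000, 2100))
    expect_equal(unname(vapply(genesInInterval(genes, edge), geneId,
                               character(1))), "g1")

    # brute-force per-gene overlap oracle on random annotations
    set.seed(17)
    for (i in 1:10) {
        starts <- sample.int(1e5, 20)
        rnd <- lapply(seq_along(starts), function(j)
            GeneModel(paste0("r", j), "A01", "+", starts[j],
                      starts[j] + sample.int(5000, 1)))
        a <- sort(sample.int(1.1e5, 2))
        ivr <- GenomicRanges::GRanges("A01", IRanges::IRanges(a[1], a[2]))
        expIds <- vapply(rnd, geneId, character(1))[
            vapply(rnd, function(g)
                GenomicRanges::start(geneRange(g)) <= a[2] &&
                GenomicRanges::end(geneRange(g)) >= a[1], logical(1))]
        got <- vapply(genesInInterval(rnd, ivr), geneId, character(1))
        expect_setequal(got, expIds)
    }
})

test_that("the ACT->ATT substitution annotates as Thr->Ile missense", {
    toy <- makeToyLocus()
    # codon 2 is ACT at 14-16; C->T at position 15 (codon position 2)
    eff <- annotateSnp(toy$gene, toy$genome, "chrT", 15, "C", "T")
    expect_equal(eff@refCodon, "ACT")
    expect_equal(eff@altCodon, "ATT")
    expect_equal(eff@refAa, "Thr")
    expect_equal(eff@altAa, "Ile")
    expect_equal(effectClass(eff), "missense")
    expect_equal(eff@codonNumber, 2L)
    expect_equal(eff@positionInCodon, 2L)
    expect_equal(eff@exonIndex, 1L)
})

test_that("synonymous and nonsense substitutions classify correctly", {
    toy <- makeToyLocus()
    # ACT codon position 3: T->C gives ACC, still Thr
    syn <- annotateSnp(toy$gene, toy$genome, "chrT", 16, "T", "C")
    expect_equal(syn@altCodon, "ACC")
    expect_equal(effectClass(syn), "synonymous")
    # codon 4 is CAA (31-33, exon 2): C->T gives TAA stop
    non <- annotateSnp(toy$gene, toy$genome, "chrT", 31, "C", "T")
    expect_equal(non@refCodon, "CAA")
    expect_equal(non@altCodon, "TAA")
    expect_equal(non@altAa, "Ter")
    expect_equal(effectClass(non), "nonsense")
    expect_equal(non@exonIndex, 2L)
})

test_that("intronic positions are flagged non-coding", {
    toy <- makeToyLocus()
    expect_message(
        eff <- annotateSnp(toy$gene, toy$genome, "chrT", 25, "G", "A"),
        "intronic")
    expect_equal(effectClass(eff), "non_coding")
    expect_true(is.na(eff@codonNumber))
})

test_that("reference disagreement and out-of-gene positions are fatal", {
    toy <- makeToyLocus()
    expect_error(annotateSnp(toy$gene, toy$genome, "chrT", 15, "G", "T"),
                 "reference disagreement")
    expect_error(annotateSnp(toy$gene, toy$genome, "chrT", 5, "C", "T"),
                 "outside gene")
    expect_error(annotateSnp(toy$gene, toy$genome, "chrX", 15, "C", "T"),
                 "does not match")
})

test_that("minus-strand annotation equals plus-strand on the reverse
           complement", {
    toy <- makeToyLocus()
    L <- Biostrings::nchar(toy$genome)[[1]]
    rcGenome <- Biostrings::reverseComplement(toy$genome)
    names(rcGenome) <- "chrT"
    # the same physical gene described on the reverse-complemented axis
    flip <- function(p) L - p + 1
    geneRC <- GeneModel("gT", "chrT", "-", flip(36), flip(11),
                        cdsStarts = c(flip(36), flip(19)),
                        cdsEnds = c(flip(31), flip(11)))
    eff <- annotateSnp(toy$gene, toy$genome, "chrT", 15, "C", "T")
    effRC <- annotateSnp(geneRC, rcGenome, "chrT", flip(15), "G", "A")
    for (slot in c("cdsPosition", "codonNumber", "positionInCodon",
                   "refCodon", "altCodon", "refAa", "altAa",
                   "effectClass", "exonIndex"))
        expect_equal(methods::slot(effRC, slot), methods::slot(eff, slot),
                     label = slot)
})

test_that("the standard code maps every sense codon to one amino acid", {
    code <- Biostrings::GENETIC_CODE
    expect_length(code, 64L)
    sense <- code[code != "*"]
    expect_true(all(sense %in% names(Biostrings::AMINO_ACID_CODE)))
    expect_equal(sum(code == "*"), 3L)
})

test_that("co-segregation check follows the recessive concordance rule", {
    all19 <- cosegregationCheck(rep("mut", 19), rep("mutant", 19))
    expect_true(all19$cosegregates)
    expect_equal(all19$nConcordant, 19L)

    one <- cosegregationCheck(c(rep("mut", 18), "het"), rep("mutant", 19))
    expect_false(one$cosegregates)
    expect_equal(one$nConcordant, 18L)

    mixed <- cosegregationCheck(c("mut", "het", "wt"),
                                c("mutant", "wildtype", "wildtype"))
    expect_true(mixed$cosegregates)

    expect_error(cosegregationCheck(character(), character()), "no individuals")
    expect_error(cosegregationCheck("mut", "purple"), "phenotypes")
})
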