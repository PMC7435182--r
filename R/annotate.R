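#' Genes overlapping a genomic interval
#'
#' Returns every gene whose span overlaps the interval by at least one
#' base (the "any overlap" convention), sorted by gene start.
#'
#' @param genes A list of [GeneModel-class] objects (as from
#'   [readGeneModels()]).
#' @param interval A single-range \linkS4class{GRanges} (1-based
#'   inclusive) or a [FineMapResult-class].
#' @return The overlapping subset of \code{genes}, sorted by start.
#' @export
genesInInterval <- function(genes, interval) {
    if (is(interval, "FineMapResult"))
        interval <- mappedInterval(interval)
    iv <- GRanges(interval)
    if (length(iv) != 1L)
        stop("exactly one interval expected")
    if (!length(genes))
        return(genes)
    spans <- GRanges(
        vapply(genes, function(g)
            as.character(seqnames(geneRange(g))), character(1L)),
        IRanges(vapply(genes, function(g) start(geneRange(g)), numeric(1L)),
                vapply(genes, function(g) end(geneRange(g)), numeric(1L))))
    hit <- overlapsAny(spans, iv, ignore.strand = TRUE)
    sel <- genes[hit]
    sel[order(vapply(sel, function(g) start(geneRange(g)), numeric(1L)))]
}

# 1-letter -> 3-letter amino-acid code; stop codons reported as Ter.
.aa3 <- function(aa1) {
    if (aa1 == "*")
        return("Ter")
    unname(Biostrings::AMINO_ACID_CODE[aa1])
}

#' Annotate the codon-level effect of a SNP within a gene
#'
#' Maps a genomic substitution onto the coding sequence of a gene model,
#' respecting strand (the CDS of a minus-strand gene is the reverse
#' complement of its genomic segments), and classifies the change by
#' translating the reference and alternate codons with the standard
#' nuclear genetic code. \code{refBase} and \code{altBase} are given on
#' the forward genomic strand, as in a VCF; they are complemented
#' internally for minus-strand genes.
#'
#' Positions inside the gene but outside every CDS segment (introns,
#' UTRs) yield an effect class of \code{non_coding}. Exons are numbered in
#' transcription order (5' to 3' on the coding strand).
#'
#' @param gene A [GeneModel-class].
#' @param genome A named \linkS4class{DNAStringSet} or the path of a FASTA
#'   file covering the gene's chromosome.
#' @param chrom,pos Genomic location of the substitution (1-based).
#' @param refBase,altBase Forward-strand reference and alternate bases.
#' @return A [SnpEffect-class] object.
#' @examples
#' gm <- GeneModel("g1", "chrT", "+", 1, 9, cdsStarts = 1, cdsEnds = 9)
#' genome <- Biostrings::DNAStringSet(c(chrT = "ATGACTTGA"))
#' annotateSnp(gm, genome, "chrT", 5, "C", "T")  # ACT -> ATT, Thr -> Ile
#' @export
annotateSnp <- function(gene, genome, chrom, pos, refBase, altBase) {
    stopifnot(is(gene, "GeneModel"))
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    gchrom <- as.character(seqnames(gene@gene))
    if (chrom != gchrom)
        stop("SNP chromosome ", chrom, " does not match gene chromosome ",
             gchrom)
    if (pos < start(gene@gene) || pos > end(gene@gene))
        stop("position ", pos, " outside gene ", gene@geneId)
    if (!chrom %in% names(genome))
        stop("chromosome ", chrom, " absent from the genome sequence")
    chromSeq <- genome[[chrom]]
    genomeBase <- as.character(Biostrings::subseq(chromSeq, pos, pos))
    if (genomeBase != refBase)
        stop("reference disagreement at ", chrom, ":", pos, ": genome has ",
             genomeBase, ", expected ", refBase)

    minus <- as.character(strand(gene@gene)) == "-"
    cds <- gene@cds
    segIdx <- which(pos >= start(cds) & pos <= end(cds))
    if (!length(segIdx)) {
        message("position ", chrom, ":", pos,
                " is intronic/UTR within gene ", gene@geneId)
        return(new("SnpEffect", geneId = gene@geneId, exonIndex = NA_integer_,
                   cdsPosition = NA_integer_, codonNumber = NA_integer_,
                   positionInCodon = NA_integer_, refCodon = NA_character_,
                   altCodon = NA_character_, refAa = NA_character_,
                   altAa = NA_character_, effectClass = "non_coding"))
    }

    widths <- width(cds)
    fwdOffset <- if (segIdx > 1L) sum(widths[seq_len(segIdx - 1L)]) else 0L
    fwdOffset <- fwdOffset + (pos - start(cds)[segIdx] + 1L)
    total <- sum(widths)
    cdsPos <- as.integer(if (minus) total - fwdOffset + 1L else fwdOffset)
    exonIndex <- as.integer(if (minus) length(cds) - segIdx + 1L else segIdx)

    segs <- Biostrings::DNAStringSet(lapply(seq_along(cds), function(i)
        Biostrings::subseq(chromSeq, start(cds)[i], end(cds)[i])))
    cdsSeq <- Biostrings::DNAString(paste(as.character(segs), collapse = ""))
    if (minus)
        cdsSeq <- Biostrings::reverseComplement(cdsSeq)

    codonNumber <- as.integer(ceiling(cdsPos / 3))
    posInCodon <- as.integer((cdsPos - 1L) %% 3L + 1L)
    cStart <- 3L * (codonNumber - 1L) + 1L
    cEnd <- min(cStart + 2L, total)
    refCodon <- as.character(Biostrings::subseq(cdsSeq, cStart, cEnd))
    if (nchar(refCodon) < 3L) {
        message("position falls in an incomplete terminal codon of ",
                gene@geneId, "; effect not classifiable")
        return(new("SnpEffect", geneId = gene@geneId,
                   exonIndex = exonIndex, cdsPosition = cdsPos,
                   codonNumber = codonNumber, positionInCodon = posInCodon,
                   refCodon = NA_character_, altCodon = NA_character_,
                   refAa = NA_character_, altAa = NA_character_,
                   effectClass = "non_coding"))
    }
    strandAlt <- if (minus)
        as.character(Biostrings::complement(Biostrings::DNAString(altBase)))
    else altBase
    altCodon <- refCodon
    substr(altCodon, posInCodon, posInCodon) <- strandAlt

    refAa1 <- unname(Biostrings::GENETIC_CODE[refCodon])
    altAa1 <- unname(Biostrings::GENETIC_CODE[altCodon])
    effect <- if (refAa1 == altAa1) "synonymous"
        else if (altAa1 == "*") "nonsense"
        else "missense"
    new("SnpEffect", geneId = gene@geneId, exonIndex = exonIndex,
        cdsPosition = cdsPos, codonNumber = codonNumber,
        positionInCodon = posInCodon, refCodon = refCodon,
        altCodon = altCodon, refAa = .aa3(refAa1), altAa = .aa3(altAa1),
        effectClass = effect)
}

#' Test co-segregation of a candidate SNP with the phenotype
#'
#' Under the single-recessive model an individual's phenotype is mutant if
#' and only if it is homozygous for the mutant allele; a SNP co-segregates
#' with the trait when every tested individual is concordant with that
#' rule.
#'
#' @param genotypes Per-individual SNP genotypes: \code{"mut"} (homozygous
#'   mutant allele), \code{"het"}, or \code{"wt"}.
#' @param phenotypes Per-individual phenotypes: \code{"mutant"} or
#'   \code{"wildtype"} (same order and length as \code{genotypes}).
#' @return A list with \code{nTested}, \code{nConcordant} and
#'   \code{cosegregates} (\code{TRUE} iff all individuals concordant).
#' @examples
#' cosegregationCheck(rep("mut", 19), rep("mutant", 19))
#' @export
cosegregationCheck <- function(genotypes, phenotypes) {
    if (!length(genotypes))
        stop("no individuals to test")
    if (length(genotypes) != length(phenotypes))
        stop("'genotypes' and 'phenotypes' must have the same length")
    if (!all(genotypes %in% c("mut", "het", "wt")))
        stop("genotypes must be 'mut', 'het' or 'wt'")
    if (!all(phenotypes %in% c("mutant", "wildtype")))
        stop("phenotypes must be 'mutant' or 'wildtype'")
    concordant <- (phenotypes == "mutant") == (genotypes == "mut")
    list(nTested = length(genotypes), nConcordant = sum(concordant),
         cosegregates = all(concordant))
}
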