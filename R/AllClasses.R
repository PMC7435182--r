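#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges mcols mcols<- seqnames start end
#'   width strand strand<- reduce countOverlaps findOverlaps
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors DataFrame metadata metadata<- elementNROWS
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<-
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

## ---------------------------------------------------------------------------
## PooledVariants: biallelic SNVs with per-bulk allele depths
## ---------------------------------------------------------------------------

#' PooledVariants: SNVs with read counts in two phenotype-selected bulks
#'
#' A \linkS4class{GRanges}-derived container in which each range is a single
#' biallelic SNV (width 1) carrying reference and alternate allele read counts
#' observed in the mutant bulk and in the wild-type bulk. This is the atom of
#' the bulked-segregant ED scan.
#'
#' Required metadata columns: \code{ref}, \code{alt} (single bases),
#' \code{mutRef}, \code{mutAlt}, \code{wtRef}, \code{wtAlt} (non-negative
#' read counts). Pool depth is the sum of the two counts of that pool.
#'
#' @seealso [readPooledVariants()], [simulateBulks()], [scanBsa()]
#' @export
setClass("PooledVariants", contains = "GRanges")

.validPooledVariants <- function(object) {
    msg <- character()
    need <- c("ref", "alt", "mutRef", "mutAlt", "wtRef", "wtAlt")
    missing <- setdiff(need, colnames(mcols(object)))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all SNV ranges must have width 1")
        cnt <- as.matrix(mcols(object)[, c("mutRef", "mutAlt",
                                           "wtRef", "wtAlt")])
        if (any(!is.finite(cnt)) || any(cnt < 0))
            msg <- c(msg, "allele counts must be finite and non-negative")
        bases <- c(as.character(mcols(object)$ref),
                   as.character(mcols(object)$alt))
        if (!all(bases %in% c("A", "C", "G", "T")))
            msg <- c(msg, "ref/alt must be single bases A/C/G/T")
        if (any(start(object) < 1L))
            msg <- c(msg, "positions must be >= 1")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PooledVariants", .validPooledVariants)

#' Construct a PooledVariants object
#'
#' @param chrom Chromosome identifiers.
#' @param pos 1-based SNV positions.
#' @param ref,alt Single-base reference and alternate alleles.
#' @param mutRef,mutAlt Reference/alternate read counts in the mutant bulk.
#' @param wtRef,wtAlt Reference/alternate read counts in the wild-type bulk.
#'
#' @return A [PooledVariants-class] object sorted by (chromosome, position).
#' @examples
#' pv <- PooledVariants("A01", c(100, 250), ref = c("C", "G"),
#'                      alt = c("T", "A"), mutRef = c(0, 3), mutAlt = c(10, 7),
#'                      wtRef = c(5, 6), wtAlt = c(5, 4))
#' mutDepth(pv)
#' @export
PooledVariants <- function(chrom, pos, ref, alt, mutRef, mutAlt, wtRef, wtAlt) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L),
                  ref = as.character(ref), alt = as.character(alt),
                  mutRef = as.integer(mutRef), mutAlt = as.integer(mutAlt),
                  wtRef = as.integer(wtRef), wtAlt = as.integer(wtAlt))
    new("PooledVariants", .sortLex(gr))
}

## ---------------------------------------------------------------------------
## MarkerGenotypeTable: marker calls for (typically recessive-homozygous) F2s
## ---------------------------------------------------------------------------

#' MarkerGenotypeTable: genotype codes of F2 individuals at mapped markers
#'
#' Holds a matrix of genotype codes (rows = individuals, columns = markers)
#' with the genomic position of every marker. Codes are \code{A} (homozygous
#' for the mutant-parent allele), \code{H} (heterozygous), \code{B}
#' (homozygous for the other parent's allele) and \code{U} (missing).
#'
#' The \code{population} slot records whether the individuals are known to be
#' recessive-phenotype homozygotes (\code{"recessive"}), an unselected F2 set
#' (\code{"all"}), or of unknown origin (\code{"unknown"}). Recombinant
#' counting for fine mapping is only meaningful on a recessive-only table.
#'
#' @seealso [readMarkerTable()], [simulateMarkerGenotypes()], [fineMap()]
#' @export
setClass("MarkerGenotypeTable",
    representation(calls = "matrix", markers = "GRanges",
                   population = "character"))

.validMarkerGenotypeTable <- function(object) {
    msg <- character()
    if (!is.character(object@calls))
        return("'calls' must be a character matrix")
    if (ncol(object@calls) != length(object@markers))
        msg <- c(msg, "number of call columns must equal number of markers")
    if (!identical(colnames(object@calls), names(object@markers)))
        msg <- c(msg, "colnames(calls) must equal marker names")
    if (!all(object@calls %in% c("A", "H", "B", "U")))
        msg <- c(msg, "calls must be one of A, H, B, U")
    if (length(object@population) != 1L ||
        !object@population %in% c("recessive", "all", "unknown"))
        msg <- c(msg, "'population' must be one of recessive/all/unknown")
    if (length(msg)) msg else TRUE
}
setValidity("MarkerGenotypeTable", .validMarkerGenotypeTable)

#' Construct a MarkerGenotypeTable
#'
#' @param calls Character matrix of codes in \{A, H, B, U\}; rows are
#'   individuals (rownames = ids), columns are markers.
#' @param markers Named \linkS4class{GRanges} of marker positions; names must
#'   match \code{colnames(calls)}.
#' @param population One of \code{"recessive"}, \code{"all"},
#'   \code{"unknown"}: provenance of the genotyped individuals.
#'
#' @return A [MarkerGenotypeTable-class] object.
#' @export
MarkerGenotypeTable <- function(calls, markers, population = "unknown") {
    if (is.null(rownames(calls)))
        rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
    if (is.null(names(markers)) && !is.null(colnames(calls)))
        names(markers) <- colnames(calls)
    colnames(calls) <- names(markers)
    new("MarkerGenotypeTable", calls = calls, markers = markers,
        population = population)
}

## ---------------------------------------------------------------------------
## GeneModel: one gene with its coding segments
## ---------------------------------------------------------------------------

#' GeneModel: gene bounds and coding-sequence segments
#'
#' Gene structure sufficient for codon-level SNP annotation: the gene's span,
#' its strand, and its CDS segments stored in ascending genomic order
#' regardless of strand. When the concatenated CDS length is not divisible by
#' three the model is flagged (\code{completeCds = FALSE}) but still usable.
#'
#' @seealso [readGeneModels()], [annotateSnp()], [genesInInterval()]
#' @export
setClass("GeneModel",
    representation(geneId = "character", gene = "GRanges", cds = "GRanges",
                   completeCds = "logical"))

.validGeneModel <- function(object) {
    msg <- character()
    if (length(object@gene) != 1L)
        return("'gene' must be a single range")
    if (!as.character(strand(object@gene)) %in% c("+", "-"))
        msg <- c(msg, "gene strand must be + or -")
    if (length(object@cds)) {
        if (is.unsorted(start(object@cds)))
            msg <- c(msg, "cds segments must be sorted by start")
        if (length(object@cds) > 1L &&
            any(start(object@cds)[-1L] <=
                end(object@cds)[-length(object@cds)]))
            msg <- c(msg, "cds segments must not overlap")
        if (any(start(object@cds) < start(object@gene)) ||
            any(end(object@cds) > end(object@gene)))
            msg <- c(msg, "cds segments must lie within the gene bounds")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GeneModel", .validGeneModel)

#' Construct a GeneModel
#'
#' @param geneId Gene identifier.
#' @param chrom Chromosome.
#' @param strand \code{"+"} or \code{"-"}.
#' @param start,end 1-based inclusive gene bounds.
#' @param cdsStarts,cdsEnds 1-based inclusive CDS segment coordinates (in any
#'   order; stored sorted ascending).
#' @param warnIncomplete Warn when the summed CDS length is not a multiple
#'   of 3.
#'
#' @return A [GeneModel-class] object.
#' @examples
#' gm <- GeneModel("g1", "A01", "+", 1000, 2000,
#'                 cdsStarts = c(1000, 1701), cdsEnds = c(1199, 2000))
#' cdsSegments(gm)
#' @export
GeneModel <- function(geneId, chrom, strand, start, end,
                      cdsStarts = integer(), cdsEnds = integer(),
                      warnIncomplete = TRUE) {
    if (length(cdsStarts) != length(cdsEnds))
        stop("'cdsStarts' and 'cdsEnds' must have equal length")
    cds <- if (length(cdsStarts)) {
        o <- order(cdsStarts)
        GRanges(chrom, IRanges(cdsStarts[o], cdsEnds[o]), strand = strand)
    } else {
        GRanges()
    }
    gene <- GRanges(chrom, IRanges(start, end), strand = strand)
    complete <- length(cds) == 0L || sum(width(cds)) %% 3L == 0L
    if (!complete && warnIncomplete)
        warning("gene ", geneId, ": CDS length ", sum(width(cds)),
                " not divisible by 3; model flagged incomplete")
    new("GeneModel", geneId = geneId, gene = gene, cds = cds,
        completeCds = complete)
}

## ---------------------------------------------------------------------------
## SnpEffect: a classified coding substitution
## ---------------------------------------------------------------------------

#' SnpEffect: codon-level classification of a single-nucleotide substitution
#'
#' Produced by [annotateSnp()]. For coding positions the codon number, the
#' position within the codon, reference and alternate codons, and the
#' reference and alternate amino acids (3-letter codes) are filled in; the
#' effect class is one of \code{synonymous}, \code{missense}, \code{nonsense}
#' or \code{non_coding}.
#'
#' @export
setClass("SnpEffect",
    representation(geneId = "character", exonIndex = "integer",
                   cdsPosition = "integer", codonNumber = "integer",
                   positionInCodon = "integer", refCodon = "character",
                   altCodon = "character", refAa = "character",
                   altAa = "character", effectClass = "character"))

setValidity("SnpEffect", function(object) {
    ok <- object@effectClass %in%
        c("synonymous", "missense", "nonsense", "non_coding")
    if (!ok)
        return("unknown effect class")
    if (object@effectClass != "non_coding") {
        diff <- which(strsplit(object@refCodon, "")[[1L]] !=
                      strsplit(object@altCodon, "")[[1L]])
        if (!identical(diff, object@positionInCodon))
            return("codons must differ exactly at positionInCodon")
    }
    TRUE
})

## ---------------------------------------------------------------------------
## F2Population: simulated ground truth
## ---------------------------------------------------------------------------

#' F2Population: simulated F2 individuals with full gamete-level truth
#'
#' Ground truth from [simulateF2()]: for every individual, the two gametes it
#' received, each stored as a starting parental phase plus crossover
#' breakpoints (in cM) per chromosome. Phenotypes follow the single-recessive
#' rule: an individual is mutant if and only if both gametes carry the
#' mutant-parent allele at the causal locus.
#'
#' Slots are internal; use [phenotypes()], [causalLocus()] and the
#' downstream simulators to interrogate the object.
#'
#' @seealso [simulateF2()], [simulateBulks()], [simulateMarkerGenotypes()]
#' @export
setClass("F2Population",
    representation(nF2 = "integer", chromLengthCM = "numeric",
                   chromLengthBp = "numeric", causal = "list",
                   phase0 = "matrix", breaks = "list",
                   phenotype = "character"))

setValidity("F2Population", function(object) {
    n <- object@nF2
    if (nrow(object@phase0) != 2L * n)
        return("phase0 must have one row per gamete (2 per individual)")
    if (length(object@phenotype) != n)
        return("one phenotype per individual required")
    if (!all(object@phenotype %in% c("mutant", "wildtype")))
        return("phenotypes must be 'mutant' or 'wildtype'")
    TRUE
})

## ---------------------------------------------------------------------------
## BsaScanResult
## ---------------------------------------------------------------------------

#' BsaScanResult: outcome of the ED-based bulked-segregant scan
#'
#' Holds the per-SNV records (allele frequencies, ED, transformed ED and a
#' selection flag), the transform power \code{k}, the top-quantile fraction
#' \code{q}, the selection threshold on the transformed scale, and the called
#' candidate regions.
#'
#' @seealso [scanBsa()]
#' @export
setClass("BsaScanResult",
    representation(records = "GRanges", k = "numeric", q = "numeric",
                   threshold = "numeric", regions = "GRanges"))

setValidity("BsaScanResult", function(object) {
    need <- c("fMut", "fWt", "depthMut", "depthWt", "ed", "edK", "selected")
    if (!all(need %in% colnames(mcols(object@records))))
        return(paste("records must carry columns:",
                     paste(need, collapse = ", ")))
    TRUE
})

## ---------------------------------------------------------------------------
## FineMapResult
## ---------------------------------------------------------------------------

#' FineMapResult: recombinant-based fine mapping outcome
#'
#' Per-marker recombinant counts, recombination frequencies and Kosambi
#' distances together with the side of each marker relative to the trait
#' locus, the flanking interval between the closest markers that still show
#' recombinants, the co-segregating markers, and any conflicts detected in
#' the recombinant patterns.
#'
#' @seealso [fineMap()], [physicalSpan()]
#' @export
setClass("FineMapResult",
    representation(markerResults = "data.frame", interval = "GRangesOrNULL",
                   leftMarker = "character", rightMarker = "character",
                   cosegregating = "character", conflicts = "character",
                   status = "character"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "PooledVariants", function(object) {
    cat("PooledVariants with", length(object), "SNVs on",
        length(seqlevels(object)), "sequence(s)\n")
    callNextMethod()
})

setMethod("show", "MarkerGenotypeTable", function(object) {
    cat("MarkerGenotypeTable:", nrow(object@calls), "individuals x",
        ncol(object@calls), "markers (population:", object@population, ")\n")
    tab <- table(factor(object@calls, levels = c("A", "H", "B", "U")))
    cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel", object@geneId, "|",
        as.character(seqnames(object@gene)), paste0(start(object@gene), "-",
        end(object@gene)), paste0("(", as.character(strand(object@gene)), ")"),
        "|", length(object@cds), "CDS segment(s),",
        sum(width(object@cds)), "bp coding",
        if (!object@completeCds) "[incomplete]" else "", "\n")
})

setMethod("show", "SnpEffect", function(object) {
    if (object@effectClass == "non_coding") {
        cat("SnpEffect:", object@geneId, "- non-coding position\n")
    } else {
        cat("SnpEffect:", object@geneId, "exon", object@exonIndex,
            "codon", object@codonNumber,
            paste0("(", object@refCodon, "->", object@altCodon, ")"),
            paste0(object@refAa, object@codonNumber, object@altAa), "-",
            object@effectClass, "\n")
    }
})

setMethod("show", "F2Population", function(object) {
    cat("F2Population:", object@nF2, "individuals,",
        length(object@chromLengthCM), "chromosome(s)\n")
    cat("  causal locus:", object@causal$chrom, "at",
        round(object@causal$cM, 3), "cM (bp", object@causal$bp, ")\n")
    cat("  phenotypes: mutant", sum(object@phenotype == "mutant"),
        "/ wildtype", sum(object@phenotype == "wildtype"), "\n")
})

setMethod("show", "BsaScanResult", function(object) {
    cat("BsaScanResult: ", length(object@records), " SNVs scanned, k = ",
        object@k, ", q = ", object@q, "\n", sep = "")
    cat("  threshold (ED^k):", signif(object@threshold, 6), "|",
        sum(mcols(object@records)$selected), "SNVs selected |",
        length(object@regions), "region(s)\n")
    if (length(object@regions))
        show(object@regions)
})

setMethod("show", "FineMapResult", function(object) {
    cat("FineMapResult (", object@status, ")\n", sep = "")
    print(object@markerResults, row.names = FALSE)
    if (!is.null(object@interval) && length(object@interval)) {
        cat("  interval: ", as.character(seqnames(object@interval)), ":",
            start(object@interval), "-", end(object@interval),
            " (", physicalSpan(object), " kb)\n", sep = "")
    }
    if (length(object@cosegregating))
        cat("  co-segregating:", paste(object@cosegregating, collapse = ", "),
            "\n")
    if (length(object@conflicts))
        cat("  conflicts:", paste(object@conflicts, collapse = "; "), "\n")
})
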