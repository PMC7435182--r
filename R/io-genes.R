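#' Read gene models from GFF3 or BED12
#'
#' Builds one [GeneModel-class] per gene. For GFF3 input, CDS features are
#' taken from the first mRNA of each gene (a message is emitted when a gene
#' has several transcripts); genes whose CDS lies outside the gene bounds
#' are a fatal error. For BED12 input each line is one gene: blocks are the
#' exons and the coding segments are the intersection of the blocks with the
#' thick (CDS) region, following UCSC semantics.
#'
#' CDS segments are always stored in ascending genomic order, for genes on
#' either strand.
#'
#' @param file Path to a GFF3 (\code{.gff}, \code{.gff3}) or BED
#'   (\code{.bed}) file.
#' @param format \code{"auto"}, \code{"gff3"} or \code{"bed"}.
#' @param verbose Emit messages.
#'
#' @return A named list of [GeneModel-class] objects sorted by
#'   (chromosome, gene start).
#' @export
readGeneModels <- function(file, format = c("auto", "gff3", "bed"),
                           verbose = TRUE) {
    format <- match.arg(format)
    if (!file.exists(file))
        stop("file not found: ", file)
    if (format == "auto")
        format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed"
                  else "gff3"
    models <- if (format == "gff3")
        .readGenesGff3(file, verbose)
    else
        .readGenesBed12(file, verbose)
    ord <- order(vapply(models, function(g)
                     as.character(seqnames(g@gene)), character(1L)),
                 vapply(models, function(g) start(g@gene), numeric(1L)))
    models[ord]
}

.featId <- function(gr) {
    id <- gr$ID
    if (is.null(id)) rep(NA_character_, length(gr)) else as.character(id)
}

.featParent <- function(gr) {
    p <- gr$Parent
    if (is.null(p))
        return(rep(NA_character_, length(gr)))
    vapply(as.list(p), function(x)
        if (length(x)) as.character(x[[1L]]) else NA_character_,
        character(1L))
}

.readGenesGff3 <- function(file, verbose) {
    gff <- rtracklayer::import(file, format = "gff3")
    type <- as.character(gff$type)
    genes <- gff[type == "gene"]
    mrnas <- gff[type %in% c("mRNA", "transcript")]
    cds <- gff[type == "CDS"]
    if (!length(genes))
        stop("no gene features in ", file)
    geneIds <- .featId(genes)
    mrnaParent <- .featParent(mrnas)
    mrnaIds <- .featId(mrnas)
    cdsParent <- .featParent(cds)
    models <- vector("list", length(genes))
    for (i in seq_along(genes)) {
        gid <- geneIds[i]
        tx <- which(mrnaParent == gid)
        if (length(tx) > 1L)
            .msg("gene ", gid, ": ", length(tx),
                 " transcripts, using the first", verbose = verbose)
        segs <- if (length(tx)) {
            cds[cdsParent == mrnaIds[tx[1L]]]
        } else {
            cds[cdsParent == gid]   # CDS attached directly to the gene
        }
        if (length(segs) &&
            (min(start(segs)) < start(genes)[i] ||
             max(end(segs)) > end(genes)[i]))
            stop("gene ", gid, ": CDS outside gene bounds")
        models[[i]] <- GeneModel(gid,
            as.character(seqnames(genes)[i]),
            as.character(strand(genes)[i]),
            start(genes)[i], end(genes)[i],
            cdsStarts = start(segs), cdsEnds = end(segs))
    }
    names(models) <- geneIds
    models
}

.readGenesBed12 <- function(file, verbose) {
    bed <- rtracklayer::import(file, format = "bed")
    if (is.null(bed$blocks))
        stop("BED file has no block (exon) structure; BED12 required")
    models <- vector("list", length(bed))
    for (i in seq_along(bed)) {
        blocks <- IRanges::shift(bed$blocks[[i]], start(bed)[i] - 1L)
        thick <- bed$thick[i]
        segs <- IRanges::restrict(blocks, start = start(thick),
                                  end = end(thick))
        segs <- segs[width(segs) > 0L]
        models[[i]] <- GeneModel(bed$name[i],
            as.character(seqnames(bed)[i]), as.character(strand(bed)[i]),
            start(bed)[i], end(bed)[i],
            cdsStarts = start(segs), cdsEnds = end(segs))
    }
    names(models) <- bed$name
    models
}
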