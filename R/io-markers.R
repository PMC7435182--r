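#' Read a marker genotype table
#'
#' Parses the delimited layout used for fine-mapping genotype data: the
#' first row holds marker identifiers, the second and third rows the
#' chromosome and 1-based position of each marker, and every subsequent row
#' one individual's calls. The first column carries row labels (header cell
#' arbitrary, then \code{chrom}, \code{pos}, then individual ids). Comma or
#' tab delimiters are detected automatically.
#'
#' Genotype symbols are translated through \code{codeMap} into the fixed
#' alphabet \code{A} (homozygous mutant-parent), \code{H} (heterozygous),
#' \code{B} (homozygous other parent), \code{U} (missing); any symbol not in
#' the map becomes \code{U} with a warning.
#'
#' @param file Path to the delimited file.
#' @param codeMap Named character vector mapping input symbols to
#'   \code{A/H/B/U}.
#' @param population Provenance of the genotyped individuals
#'   (\code{"recessive"}, \code{"all"} or \code{"unknown"}); see
#'   [MarkerGenotypeTable-class].
#' @param verbose Emit messages.
#'
#' @return A [MarkerGenotypeTable-class] object.
#' @export
readMarkerTable <- function(file,
                            codeMap = c(A = "A", H = "H", B = "B", U = "U",
                                        a = "A", h = "H", b = "B",
                                        "-" = "U", N = "U", n = "U"),
                            population = "unknown", verbose = TRUE) {
    if (!file.exists(file))
        stop("file not found: ", file)
    sep <- .sniffDelim(file)
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 4L)
        stop("marker table needs marker/chrom/pos rows plus >= 1 individual")
    cells <- strsplit(lines, sep, fixed = TRUE)
    len <- lengths(cells)
    if (any(len != len[1L]))
        stop("ragged marker table: row ", which(len != len[1L])[1L],
             " has ", len[which(len != len[1L])[1L]], " fields, expected ",
             len[1L])
    markerIds <- cells[[1L]][-1L]
    if (tolower(cells[[2L]][1L]) != "chrom" ||
        tolower(cells[[3L]][1L]) != "pos")
        stop("rows 2 and 3 must be labelled 'chrom' and 'pos'")
    chrom <- cells[[2L]][-1L]
    pos <- as.numeric(cells[[3L]][-1L])
    if (anyNA(pos))
        stop("non-numeric marker position in row 3")
    body <- cells[-(1:3)]
    ids <- vapply(body, `[`, character(1L), 1L)
    raw <- t(vapply(body, function(r) r[-1L], character(length(markerIds))))
    if (length(markerIds) == 1L)
        raw <- matrix(raw, ncol = 1L)
    mapped <- matrix(unname(codeMap[raw]), nrow = nrow(raw))
    unknown <- is.na(mapped)
    if (any(unknown)) {
        warning(sum(unknown), " unrecognised genotype symbol(s) mapped to U")
        mapped[unknown] <- "U"
    }
    dimnames(mapped) <- list(ids, markerIds)
    markers <- GRanges(chrom, IRanges(pos, width = 1L))
    names(markers) <- markerIds
    MarkerGenotypeTable(mapped, markers, population = population)
}

#' Write a marker genotype table
#'
#' Writes the layout read by [readMarkerTable()]; a write/read round trip
#' reproduces the table.
#'
#' @param x A [MarkerGenotypeTable-class] object.
#' @param file Output path.
#' @param sep Field delimiter.
#' @return Invisibly, \code{file}.
#' @export
writeMarkerTable <- function(x, file, sep = "\t") {
    stopifnot(is(x, "MarkerGenotypeTable"))
    m <- markerRanges(x)
    hdr <- c(paste(c("id", names(m)), collapse = sep),
             paste(c("chrom", as.character(seqnames(m))), collapse = sep),
             paste(c("pos", start(m)), collapse = sep))
    calls <- markerCalls(x)
    rows <- vapply(seq_len(nrow(calls)), function(i)
        paste(c(rownames(calls)[i], calls[i, ]), collapse = sep),
        character(1L))
    writeLines(c(hdr, rows), file)
    invisible(file)
}
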