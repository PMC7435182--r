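#' Read pooled SNV calls for two bulks
#'
#' Reads the variant calls produced upstream (alignment + pileup) for the
#' mutant and wild-type bulks and returns one [PooledVariants-class] record
#' per biallelic SNV. Two formats are supported: VCF 4.x with per-sample
#' allele depths (an \code{AD} FORMAT field), and a plain delimited table
#' with columns \code{chrom, pos, ref, alt, mut_ref, mut_alt, wt_ref,
#' wt_alt}.
#'
#' Indel records are always excluded (the ED scan is defined on
#' single-nucleotide variants). Multiallelic records are skipped by default;
#' with \code{multiallelic = "split"} each alternate allele becomes its own
#' biallelic record using that allele's depth against the reference depth.
#' Records lacking allele depths are skipped with a warning. Output is
#' always sorted by (chromosome lexicographic, position ascending).
#'
#' @param file Path to the VCF or table file.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or
#'   \code{"table"}.
#' @param mutSample,wtSample Sample identifiers of the mutant and wild-type
#'   bulks (required for VCF input).
#' @param multiallelic \code{"skip"} (default) or \code{"split"}.
#' @param verbose Emit progress/skip messages.
#'
#' @return A [PooledVariants-class] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref\talt\tmut_ref\tmut_alt\twt_ref\twt_alt",
#'              "A01\t100\tC\tT\t0\t10\t5\t5"), f)
#' readPooledVariants(f)
#' @export
readPooledVariants <- function(file, format = c("auto", "vcf", "table"),
                               mutSample = NULL, wtSample = NULL,
                               multiallelic = c("skip", "split"),
                               verbose = TRUE) {
    format <- match.arg(format)
    multiallelic <- match.arg(multiallelic)
    if (!file.exists(file))
        stop("file not found: ", file)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", file,
                            ignore.case = TRUE)) "vcf" else "table"
    if (format == "vcf")
        .readPooledVcf(file, mutSample, wtSample, multiallelic, verbose)
    else
        .readPooledTable(file, verbose)
}

.readPooledVcf <- function(file, mutSample, wtSample, multiallelic, verbose) {
    if (is.null(mutSample) || is.null(wtSample))
        stop("'mutSample' and 'wtSample' are required for VCF input")
    vcf <- VariantAnnotation::readVcf(file)
    smp <- colnames(vcf)
    for (s in c(mutSample, wtSample))
        if (!s %in% smp)
            stop("sample '", s, "' not present in VCF (samples: ",
                 paste(smp, collapse = ", "), ")")
    if (!"AD" %in% rownames(VariantAnnotation::geno(
            VariantAnnotation::header(vcf))))
        stop("VCF has no per-sample allele-depth (AD) FORMAT field")

    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    ad <- VariantAnnotation::geno(vcf)$AD

    nAlt <- elementNROWS(altL)
    multi <- nAlt > 1L
    if (any(multi) && multiallelic == "skip")
        .msg("skipping ", sum(multi), " multiallelic record(s)",
             verbose = verbose)

    out <- list()
    for (i in seq_along(rr)) {
        if (multi[i] && multiallelic == "skip")
            next
        adM <- ad[i, mutSample][[1L]]
        adW <- ad[i, wtSample][[1L]]
        if (is.null(adM) || is.null(adW) || anyNA(adM) || anyNA(adW) ||
            length(adM) < nAlt[i] + 1L || length(adW) < nAlt[i] + 1L) {
            warning("record ", names(rr)[i] %||% i,
                    " lacks allele depths; skipped")
            next
        }
        alts <- as.character(altL[[i]])
        for (j in seq_along(alts)) {
            if (nchar(ref[i]) != 1L || nchar(alts[j]) != 1L)
                next   # indel or MNV allele: SNV-only scan
            out[[length(out) + 1L]] <- data.frame(
                chrom = as.character(seqnames(rr)[i]), pos = start(rr)[i],
                ref = ref[i], alt = alts[j],
                mutRef = adM[1L], mutAlt = adM[j + 1L],
                wtRef = adW[1L], wtAlt = adW[j + 1L])
        }
    }
    if (!length(out))
        return(PooledVariants(character(), integer(), character(),
                              character(), integer(), integer(), integer(),
                              integer()))
    d <- do.call(rbind, out)
    PooledVariants(d$chrom, d$pos, d$ref, d$alt, d$mutRef, d$mutAlt,
                   d$wtRef, d$wtAlt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readPooledTable <- function(file, verbose) {
    sep <- .sniffDelim(file)
    d <- read.table(file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt",
              "wt_ref", "wt_alt")
    missing <- setdiff(need, colnames(d))
    if (length(missing))
        stop("variant table lacks column(s): ",
             paste(missing, collapse = ", "))
    snv <- nchar(d$ref) == 1L & nchar(d$alt) == 1L
    if (any(!snv))
        .msg("dropping ", sum(!snv), " non-SNV row(s)", verbose = verbose)
    d <- d[snv, , drop = FALSE]
    PooledVariants(d$chrom, d$pos, d$ref, d$alt, d$mut_ref, d$mut_alt,
                   d$wt_ref, d$wt_alt)
}

#' Write pooled variants as a delimited table
#'
#' Writes the tabular representation accepted back by
#' [readPooledVariants()]; reading the written file reproduces the object.
#'
#' @param x A [PooledVariants-class] object.
#' @param file Output path.
#' @param sep Field delimiter (tab by default).
#' @return Invisibly, \code{file}.
#' @export
writePooledVariantsTable <- function(x, file, sep = "\t") {
    stopifnot(is(x, "PooledVariants"))
    d <- data.frame(chrom = as.character(seqnames(x)), pos = start(x),
                    ref = mcols(x)$ref, alt = mcols(x)$alt,
                    mut_ref = mcols(x)$mutRef, mut_alt = mcols(x)$mutAlt,
                    wt_ref = mcols(x)$wtRef, wt_alt = mcols(x)$wtAlt)
    write.table(d, file, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(file)
}
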