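#' Read a qPCR cycle-threshold (Ct) table
#'
#' Reads a delimited table of per-replicate qPCR measurements with columns
#' \code{sample}, \code{group}, \code{tissue}, \code{ct_target} and
#' \code{ct_reference} (delimiter sniffed; \code{sample_id} accepted for
#' \code{sample}). Ct values must be finite and positive.
#'
#' @param file Path to the Ct table.
#' @return A data.frame with the standardised columns above.
#' @seealso [deltaDeltaCt()], [simulateQpcr()]
#' @export
readCtTable <- function(file) {
    if (!file.exists(file))
        stop("file not found: ", file)
    sep <- .sniffDelim(file)
    d <- read.table(file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
    if ("sample_id" %in% colnames(d) && !"sample" %in% colnames(d))
        colnames(d)[colnames(d) == "sample_id"] <- "sample"
    need <- c("sample", "group", "tissue", "ct_target", "ct_reference")
    missing <- setdiff(need, colnames(d))
    if (length(missing))
        stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
    ct <- c(d$ct_target, d$ct_reference)
    if (any(!is.finite(ct)) || any(ct <= 0))
        stop("Ct values must be finite and > 0")
    d[, need]
}

#' Write a qPCR Ct table
#'
#' @param x Data.frame as returned by [readCtTable()] or [simulateQpcr()].
#' @param file Output path.
#' @param sep Field delimiter.
#' @return Invisibly, \code{file}.
#' @export
writeCtTable <- function(x, file, sep = "\t") {
    write.table(x, file, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(file)
}
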