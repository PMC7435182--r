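# Internal helpers shared across modules.

#' @importFrom utils read.table write.table head
NULL

# Detect the delimiter of a small delimited text file (tab or comma).
.sniffDelim <- function(file) {
    first <- readLines(file, n = 1L)
    if (length(first) == 0L)
        stop("empty file: ", file)
    nTab <- lengths(regmatches(first, gregexpr("\t", first)))
    nCom <- lengths(regmatches(first, gregexpr(",", first)))
    if (nTab >= nCom) "\t" else ","
}

.msg <- function(..., verbose = TRUE) {
    if (isTRUE(verbose))
        message(...)
    invisible(NULL)
}

# Lexicographic chromosome order, positions ascending: the deterministic
# ordering every reader guarantees.
.sortLex <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
    sort(gr, ignore.strand = TRUE)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
        stop("'", name, "' must be a single number in [", lower, ", ",
             upper, "]")
    invisible(x)
}
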