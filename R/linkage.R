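#' Chi-squared test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit test of observed phenotype-class counts against
#' an expected ratio such as 3:1 (F2) or 1:1 (backcross). The statistic is
#' \eqn{\chi^2 = \sum (O - E)^2 / E} without continuity correction by
#' default; the Yates-corrected variant is available via
#' \code{correct = TRUE}. The observed ratio is judged to fit when the
#' statistic is below the \eqn{\chi^2} critical value at the chosen alpha
#' (3.84 for one degree of freedom at 0.05).
#'
#' @param observed Integer vector of class counts (>= 2 classes).
#' @param ratio Expected ratio, e.g. \code{c(3, 1)}.
#' @param correct Apply the Yates continuity correction.
#' @param alpha Significance level for the critical value.
#'
#' @return A list of class \code{segregationTest} with elements
#'   \code{observed}, \code{expected}, \code{ratio}, \code{statistic},
#'   \code{df}, \code{pValue}, \code{criticalValue} and \code{conclusion}
#'   (\code{"fits"} or \code{"rejects"}).
#' @examples
#' chiSquareSegregation(c(103, 34), c(3, 1))
#' @export
chiSquareSegregation <- function(observed, ratio, correct = FALSE,
                                 alpha = 0.05) {
    if (length(observed) < 2L || length(observed) != length(ratio))
        stop("need >= 2 classes and matching 'observed'/'ratio' lengths")
    if (sum(observed) <= 0)
        stop("total count must be > 0")
    p <- ratio / sum(ratio)
    expected <- sum(observed) * p
    if (any(expected == 0))
        stop("expected count of zero; ratio class impossible")
    df <- length(observed) - 1L
    if (correct) {
        stat <- sum((abs(observed - expected) - 0.5)^2 / expected)
        pValue <- stats::pchisq(stat, df, lower.tail = FALSE)
    } else {
        ct <- suppressWarnings(stats::chisq.test(observed, p = p))
        stat <- unname(ct$statistic)
        pValue <- ct$p.value
    }
    crit <- stats::qchisq(1 - alpha, df)
    structure(list(observed = observed, expected = expected, ratio = ratio,
                   statistic = stat, df = df, pValue = pValue,
                   criticalValue = crit,
                   conclusion = if (stat < crit) "fits" else "rejects"),
              class = "segregationTest")
}

#' @export
print.segregationTest <- function(x, ...) {
    cat("Segregation test: observed", paste(x$observed, collapse = ":"),
        "vs expected", paste(x$ratio, collapse = ":"), "\n")
    cat(sprintf("  chi-squared = %.4g (df = %d), P = %.4g, critical = %.2f -> %s\n",
                x$statistic, x$df, x$pValue, x$criticalValue,
                x$conclusion))
    invisible(x)
}

#' Observed segregation ratio as x:1
#'
#' @param observed Two class counts (dominant class first).
#' @return A list with \code{value} (first/second to 3 decimals; \code{Inf}
#'   when the second count is zero) and a display \code{label} such as
#'   \code{"3.029:1"} (\code{"all:0"} for a zero denominator).
#' @examples
#' segregationRatio(c(103, 34))$label
#' @export
segregationRatio <- function(observed) {
    if (length(observed) != 2L)
        stop("exactly two class counts required")
    if (observed[2L] == 0)
        return(list(value = Inf, label = "all:0"))
    v <- round(observed[1L] / observed[2L], 3)
    list(value = v, label = sprintf("%.3f:1", v))
}

#' Count recombinant gametes at one marker
#'
#' Among recessive-phenotype homozygotes every non-mutant marker allele
#' marks a recombinant gamete: a call of \code{A} contributes 0, \code{H}
#' contributes 1 and \code{B} contributes 2 recombinant gametes; \code{U}
#' calls are excluded from the scored total.
#'
#' @param calls Character vector of codes in \{A, H, B, U\} from
#'   recessive-phenotype individuals.
#' @return Named integer vector: \code{recombinants} (gametes),
#'   \code{individuals} (individuals carrying >= 1 recombinant gamete) and
#'   \code{nScored}.
#' @examples
#' countRecombinantGametes(c("A", "A", "H", "A", "B"))
#' @export
countRecombinantGametes <- function(calls) {
    if (!all(calls %in% c("A", "H", "B", "U")))
        stop("calls must be A, H, B or U")
    scored <- calls[calls != "U"]
    c(recombinants = sum((scored == "H") + 2L * (scored == "B")),
      individuals = sum(scored != "A"),
      nScored = length(scored))
}

#' Recombination frequency from recombinant gametes
#'
#' \eqn{r = } recombinant gametes / (2 x scored individuals): each diploid
#' individual contributes two gametes. Values above 0.5 indicate an
#' unlinked (or mis-scored) marker and trigger a warning.
#'
#' @param recombinants Recombinant gamete count.
#' @param nScored Number of scored individuals.
#' @return The recombination frequency \code{r}.
#' @examples
#' recombinationFrequency(7, 1575)
#' @export
recombinationFrequency <- function(recombinants, nScored) {
    if (nScored <= 0)
        stop("'nScored' must be > 0")
    if (recombinants < 0 || recombinants > 2 * nScored)
        stop("'recombinants' must lie in [0, 2 * nScored]")
    r <- recombinants / (2 * nScored)
    if (r > 0.5)
        warning("r = ", signif(r, 4), " > 0.5: marker behaves as unlinked")
    r
}

#' Kosambi map distance
#'
#' Converts a recombination frequency to an additive map distance in
#' centimorgans with Kosambi's mapping function,
#' \deqn{cM = 25 \ln\frac{1 + 2r}{1 - 2r},}
#' which allows for crossover interference. For small \eqn{r} the distance
#' approaches \eqn{100r}. Distances are returned at full precision; round
#' to 2 decimals for reporting.
#'
#' @param r Recombination frequency in [0, 0.5) (vectorised).
#' @return Map distance in cM.
#' @examples
#' round(kosambiCM(7 / (2 * 1575)), 2)  # 0.22
#' @export
kosambiCM <- function(r) {
    if (any(r < 0 | r >= 0.5))
        stop("'r' must be in [0, 0.5): distance is infinite at r = 0.5")
    25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Fine-map a recessive locus from recombinant marker patterns
#'
#' Places the trait locus between flanking markers using the genotype
#' table of recessive-phenotype homozygotes. Per marker, recombinant
#' gametes are counted (\code{H} = 1, \code{B} = 2), converted to a
#' recombination frequency and a Kosambi distance. Markers are then
#' partitioned into a left and a right group: recombinant individuals seen
#' on one side of the locus are disjoint from those on the other side,
#' while markers on the same side share (nested) recombinant sets. The
#' implementation scans every cut point along the physical marker order
#' and keeps the cut with the fewest cross-side shared recombinant
#' individuals; remaining shared individuals are reported as conflicts.
#' The mapped interval runs from the closest left marker with recombinants
#' to the closest right marker with recombinants; markers without
#' recombinants co-segregate with the trait and must fall inside.
#'
#' @param table A [MarkerGenotypeTable-class] of recessive homozygotes
#'   (\code{population} must not be \code{"all"} unless
#'   \code{force = TRUE}). All markers must lie on one chromosome.
#' @param force Allow a table whose provenance is not recessive-only.
#'
#' @return A [FineMapResult-class]. When every marker co-segregates the
#'   status is \code{"unresolved"} and no interval is returned.
#' @examples
#' cfg <- simConfig(nChromosomes = 1, nF2 = 2000)
#' pop <- simulateF2(cfg, seed = 11)
#' mk <- data.frame(marker = paste0("M", 1:5), chrom = "chr1",
#'                  cM = c(48, 49.5, 50, 50.7, 52))
#' tab <- simulateMarkerGenotypes(pop, mk)
#' fineMap(tab)
#' @export
fineMap <- function(table, force = FALSE) {
    stopifnot(is(table, "MarkerGenotypeTable"))
    if (table@population == "all" && !force)
        stop("recombinant counting requires recessive-phenotype ",
             "individuals only; use force = TRUE to override")
    m <- markerRanges(table)
    if (length(unique(as.character(seqnames(m)))) != 1L)
        stop("fine mapping expects markers on a single chromosome")
    ord <- order(start(m))
    m <- m[ord]
    calls <- markerCalls(table)[, ord, drop = FALSE]

    nm <- length(m)
    cnt <- t(apply(calls, 2L, countRecombinantGametes))
    recSets <- lapply(seq_len(nm), function(j) {
        cl <- calls[, j]
        rownames(calls)[cl %in% c("H", "B")]
    })
    r <- vapply(seq_len(nm), function(j)
        recombinationFrequency(cnt[j, "recombinants"], cnt[j, "nScored"]),
        numeric(1L))
    cM <- ifelse(r < 0.5, kosambiCM(pmin(r, 0.4999999)), NA_real_)

    hasRec <- cnt[, "recombinants"] > 0L
    res <- data.frame(marker = names(m), chrom = as.character(seqnames(m)),
                      pos = start(m),
                      recombinantGametes = cnt[, "recombinants"],
                      recombinantIndividuals = cnt[, "individuals"],
                      nScored = cnt[, "nScored"], r = r, cM = cM,
                      side = "cosegregating", stringsAsFactors = FALSE)

    if (!any(hasRec)) {
        return(new("FineMapResult", markerResults = res, interval = NULL,
                   leftMarker = character(), rightMarker = character(),
                   cosegregating = names(m), conflicts = character(),
                   status = "unresolved"))
    }
    # choose the cut (between physical positions) with the fewest shared
    # recombinant individuals across sides
    crossShared <- function(cut) {
        left <- which(hasRec & seq_len(nm) <= cut)
        right <- which(hasRec & seq_len(nm) > cut)
        if (!length(left) || !length(right))
            return(NA_integer_)
        shared <- unique(unlist(lapply(left, function(i)
            lapply(right, function(j) intersect(recSets[[i]],
                                                recSets[[j]])))))
        length(shared)
    }
    cuts <- seq_len(nm - 1L)
    cost <- vapply(cuts, crossShared, integer(1L))
    if (all(is.na(cost)))
        stop("cannot flank: recombinant markers on one side only")
    best <- cuts[which.min(cost)]
    side <- ifelse(seq_len(nm) <= best, "left", "right")
    side[!hasRec] <- "cosegregating"
    res$side <- side

    leftIdx <- max(which(hasRec & side == "left"))
    rightIdx <- min(which(hasRec & side == "right"))
    interval <- GRanges(as.character(seqnames(m))[1L],
                        IRanges(start(m)[leftIdx], start(m)[rightIdx]))
    conflicts <- character()
    minCost <- min(cost, na.rm = TRUE)
    if (minCost > 0)
        conflicts <- c(conflicts, paste0(minCost, " recombinant ",
            "individual(s) shared between the two sides (non-monotone ",
            "pattern)"))
    coseg <- names(m)[!hasRec]
    inside <- !hasRec & start(m) >= start(m)[leftIdx] &
        start(m) <= start(m)[rightIdx]
    outOfInterval <- names(m)[!hasRec & !inside]
    if (length(outOfInterval))
        conflicts <- c(conflicts, paste0("co-segregating marker(s) outside ",
            "the interval: ", paste(outOfInterval, collapse = ", ")))
    new("FineMapResult", markerResults = res, interval = interval,
        leftMarker = names(m)[leftIdx], rightMarker = names(m)[rightIdx],
        cosegregating = coseg, conflicts = conflicts, status = "resolved")
}

#' Physical span of a fine-mapped interval in kb
#'
#' \code{(end - start + 1) / 1000}, reported to 2 decimals.
#'
#' @param interval A [FineMapResult-class] or a single-range
#'   \linkS4class{GRanges}.
#' @return Length in kilobases.
#' @examples
#' physicalSpan(GenomicRanges::GRanges("A01",
#'              IRanges::IRanges(100000, 226689)))
#' @export
physicalSpan <- function(interval) {
    if (is(interval, "FineMapResult")) {
        if (is.null(interval@interval) || !length(interval@interval))
            stop("no interval: fine mapping was unresolved")
        interval <- interval@interval
    }
    gr <- GRanges(interval)
    if (length(gr) != 1L)
        stop("exactly one interval expected")
    round(width(gr) / 1000, 2)
}
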