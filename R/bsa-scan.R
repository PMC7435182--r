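#' Filter SNVs by per-pool sequencing depth
#'
#' Keeps variants whose read depth is strictly greater than \code{minDepth}
#' in \emph{both} bulks (a coverage "greater than 3X" rule by default, so a
#' depth of exactly 3 is removed and 4 passes).
#'
#' @param x A [PooledVariants-class] object.
#' @param minDepth Depth that must be exceeded in each pool.
#' @param verbose Report how many variants were removed.
#'
#' @return The filtered [PooledVariants-class] object.
#' @export
depthFilter <- function(x, minDepth = 3, verbose = TRUE) {
    stopifnot(is(x, "PooledVariants"))
    keep <- mutDepth(x) > minDepth & wtDepth(x) > minDepth
    if (any(!keep))
        .msg("depthFilter: removed ", sum(!keep), " of ", length(x),
             " variants (depth <= ", minDepth, " in a pool)",
             verbose = verbose)
    x[keep]
}

#' Per-pool alternate-allele frequencies
#'
#' \code{f = alt / (ref + alt)} for each bulk. Variants with zero depth in
#' either pool (which cannot occur after [depthFilter()]) get \code{NA}
#' frequencies and a warning; downstream code excludes them.
#'
#' @param x A [PooledVariants-class] object.
#' @return A data.frame with columns \code{fMut} and \code{fWt}, one row
#'   per variant.
#' @export
alleleFrequencies <- function(x) {
    stopifnot(is(x, "PooledVariants"))
    dM <- mutDepth(x)
    dW <- wtDepth(x)
    zero <- dM == 0 | dW == 0
    if (any(zero))
        warning(sum(zero), " variant(s) with zero depth in a pool; ",
                "frequencies set to NA")
    fM <- ifelse(dM > 0, mcols(x)$mutAlt / dM, NA_real_)
    fW <- ifelse(dW > 0, mcols(x)$wtAlt / dW, NA_real_)
    data.frame(fMut = fM, fWt = fW)
}

#' Euclidean-distance statistic between bulk allele frequencies
#'
#' For a biallelic SNV with alternate-allele frequencies \eqn{f_m} and
#' \eqn{f_w} in the two bulks,
#' \deqn{ED = \sqrt{(f_m - f_w)^2 + ((1 - f_m) - (1 - f_w))^2}
#'          = \sqrt{2}\,|f_m - f_w|,}
#' so \eqn{0 \le ED \le \sqrt 2}. Larger values indicate tighter linkage of
#' the SNV to the phenotype the bulks were selected on.
#'
#' @param fMut,fWt Alternate-allele frequencies in [0, 1] (vectorised).
#' @return The ED values.
#' @examples
#' edStatistic(1, 0)     # sqrt(2), maximal divergence
#' edStatistic(0.5, 0.5) # 0
#' @export
edStatistic <- function(fMut, fWt) {
    stopifnot(all(fMut >= 0 & fMut <= 1, na.rm = TRUE),
              all(fWt >= 0 & fWt <= 1, na.rm = TRUE))
    sqrt((fMut - fWt)^2 + ((1 - fMut) - (1 - fWt))^2)
}

#' Power transform of the ED statistic
#'
#' Raising ED to a power \code{k} (5 by default) suppresses the
#' mid-range background noise of unlinked SNVs while preserving the
#' ranking, since \eqn{x^k} is strictly increasing for \eqn{x \ge 0}.
#'
#' @param ed ED values (>= 0).
#' @param k Positive integer power.
#' @return \code{ed^k}.
#' @export
powerTransform <- function(ed, k = 5) {
    stopifnot(all(ed >= 0, na.rm = TRUE), k >= 1)
    ed^k
}

#' Top-quantile selection threshold
#'
#' Ranks the transformed ED values and returns the value of the
#' \code{ceiling(q * n)}-th largest, so that records at or above the
#' threshold form the top \code{q} fraction; ties at the boundary are all
#' included by the caller's \code{>=} comparison.
#'
#' @param values Numeric vector (non-empty).
#' @param q Fraction in (0, 1); 0.01 selects the top 1\%.
#' @return The threshold value.
#' @export
topQuantileThreshold <- function(values, q = 0.01) {
    values <- values[!is.na(values)]
    if (!length(values))
        stop("no values to threshold")
    if (q <= 0 || q >= 1)
        stop("'q' must be in (0, 1)")
    m <- ceiling(q * length(values))
    sort(values, decreasing = TRUE)[m]
}

#' Merge selected SNVs into candidate regions
#'
#' Per chromosome, consecutive selected SNVs whose gap is at most
#' \code{maxGapBp} are merged into one cluster; clusters with at least
#' \code{minSnv} members are reported as candidate regions spanning
#' [first SNV, last SNV].
#'
#' @param selected A \linkS4class{GRanges} (or [PooledVariants-class]) of
#'   selected SNV positions.
#' @param maxGapBp Maximum gap (bp) between consecutive SNVs in a cluster.
#' @param minSnv Minimum SNVs per reported region.
#' @return A \linkS4class{GRanges} of regions with a \code{nSnv} metadata
#'   column, sorted by (chromosome, start).
#' @export
callRegions <- function(selected, maxGapBp = 2e6, minSnv = 5) {
    gr <- granges(.sortLex(GRanges(selected)))
    if (!length(gr))
        return(GRanges())
    merged <- reduce(gr, min.gapwidth = maxGapBp)
    mcols(merged)$nSnv <- countOverlaps(merged, gr)
    merged <- merged[mcols(merged)$nSnv >= minSnv]
    .sortLex(merged)
}

#' Bulked-segregant ED scan
#'
#' The full association scan: depth filtering, per-pool allele
#' frequencies, the ED statistic, the \code{k}-th power transform, the
#' genome-wide top-\code{q} threshold (ties included) and region calling.
#' The result is invariant to the input record order.
#'
#' @param variants A [PooledVariants-class] object.
#' @param k Power applied to ED (default 5).
#' @param q Top quantile used for selection (default 0.01).
#' @param minDepth Per-pool depth that must be exceeded (default 3).
#' @param maxGapBp Region-merging gap (default 2 Mb).
#' @param minSnv Minimum selected SNVs per region (default 5).
#' @param verbose Emit messages.
#'
#' @return A [BsaScanResult-class] object.
#' @examples
#' pop <- simulateF2(simConfig(nF2 = 300, nSnvs = 500), seed = 7)
#' pv <- simulateBulks(pop, simConfig(nF2 = 300, nSnvs = 500), seed = 8)
#' res <- scanBsa(pv)
#' scanRegions(res)
#' @export
scanBsa <- function(variants, k = 5, q = 0.01, minDepth = 3,
                    maxGapBp = 2e6, minSnv = 5, verbose = TRUE) {
    stopifnot(is(variants, "PooledVariants"))
    variants <- new("PooledVariants", .sortLex(variants))
    kept <- depthFilter(variants, minDepth, verbose = verbose)
    if (!length(kept))
        stop("no variants pass the depth filter")
    f <- alleleFrequencies(kept)
    ok <- !is.na(f$fMut) & !is.na(f$fWt)
    kept <- kept[ok]
    f <- f[ok, , drop = FALSE]
    ed <- edStatistic(f$fMut, f$fWt)
    edK <- powerTransform(ed, k)
    thr <- topQuantileThreshold(edK, q)
    sel <- edK >= thr
    rec <- granges(kept)
    mcols(rec) <- DataFrame(fMut = f$fMut, fWt = f$fWt,
                            depthMut = mutDepth(kept),
                            depthWt = wtDepth(kept),
                            ed = ed, edK = edK, selected = sel)
    regions <- callRegions(rec[sel], maxGapBp = maxGapBp, minSnv = minSnv)
    new("BsaScanResult", records = rec, k = k, q = q, threshold = thr,
        regions = regions)
}

#' Plot transformed ED values along a chromosome
#'
#' A per-chromosome scatter of ED^k against position with the selection
#' threshold and the called regions overlaid; the standard read-out of the
#' bulked-segregant scan.
#'
#' @param result A [BsaScanResult-class] object.
#' @param chrom Chromosome to plot (default: the first one).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, \code{NULL}.
#' @importFrom graphics abline rect points
#' @export
plotScan <- function(result, chrom = NULL, ...) {
    stopifnot(is(result, "BsaScanResult"))
    rec <- result@records
    if (is.null(chrom))
        chrom <- as.character(seqnames(rec)[1L])
    rec <- rec[as.character(seqnames(rec)) == chrom]
    plot(start(rec), mcols(rec)$edK, pch = 16, cex = 0.4,
         col = ifelse(mcols(rec)$selected, "firebrick", "grey50"),
         xlab = paste(chrom, "position (bp)"),
         ylab = sprintf("ED^%g", result@k), ...)
    abline(h = result@threshold, lty = 2)
    reg <- result@regions
    reg <- reg[as.character(seqnames(reg)) == chrom]
    if (length(reg))
        rect(start(reg), 0, end(reg), result@threshold,
             col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
    invisible(NULL)
}
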