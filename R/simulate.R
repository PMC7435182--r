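#' Simulation configuration for a recessive-locus F2 design
#'
#' Collects the parameters of the simulated study design: an F2 population
#' segregating a single recessive causal locus, two phenotype-selected bulks
#' sequenced at a given mean depth, and a per-read error rate. Defaults
#' mirror the design the package targets: bulks of 50 plants each, mean
#' depth 20 reads per SNV per bulk, 2,000 SNVs on each of three 100-cM
#' chromosomes.
#'
#' @param nChromosomes Number of chromosomes.
#' @param chromLengthCM Genetic length per chromosome in cM (recycled).
#' @param chromLengthBp Physical length per chromosome in bp (recycled);
#'   the cM-to-bp map is linear per chromosome.
#' @param causalChrom Index of the chromosome carrying the causal locus.
#' @param causalCM Genetic position (cM) of the causal locus.
#' @param nF2 Number of F2 individuals to simulate.
#' @param bulkSize Individuals per phenotype bulk.
#' @param meanDepth Mean sequencing depth per SNV per bulk (Poisson).
#' @param seqError Probability that a read reports the wrong allele
#'   (applied symmetrically); must be in [0, 0.5).
#' @param nSnvs SNVs per chromosome.
#'
#' @return A validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nF2 = 200)
#' cfg$bulkSize
#' @export
simConfig <- function(nChromosomes = 3, chromLengthCM = 100,
                      chromLengthBp = 3e7, causalChrom = 1, causalCM = 50,
                      nF2 = 400, bulkSize = 50, meanDepth = 20,
                      seqError = 0.001, nSnvs = 2000) {
    .assertScalarNumber(nChromosomes, "nChromosomes", 1)
    chromLengthCM <- rep_len(chromLengthCM, nChromosomes)
    chromLengthBp <- rep_len(chromLengthBp, nChromosomes)
    if (any(chromLengthCM < 0) || any(chromLengthBp < 1))
        stop("chromosome lengths must be non-negative (cM) and >= 1 (bp)")
    .assertScalarNumber(causalChrom, "causalChrom", 1, nChromosomes)
    .assertScalarNumber(causalCM, "causalCM", 0, chromLengthCM[causalChrom])
    .assertScalarNumber(nF2, "nF2", 1)
    .assertScalarNumber(bulkSize, "bulkSize", 1)
    .assertScalarNumber(meanDepth, "meanDepth", 1e-9)
    if (!is.numeric(seqError) || seqError < 0 || seqError >= 0.5)
        stop("'seqError' must be in [0, 0.5)")
    .assertScalarNumber(nSnvs, "nSnvs", 1)
    structure(list(nChromosomes = as.integer(nChromosomes),
                   chromLengthCM = chromLengthCM,
                   chromLengthBp = chromLengthBp,
                   causalChrom = as.integer(causalChrom),
                   causalCM = causalCM, nF2 = as.integer(nF2),
                   bulkSize = as.integer(bulkSize), meanDepth = meanDepth,
                   seqError = seqError, nSnvs = as.integer(nSnvs)),
              class = "SimConfig")
}

.chromNames <- function(n) paste0("chr", seq_len(n))

# Linear cM -> bp map; a 0-cM chromosome collapses to position 1.
.cm2bp <- function(cM, lenCM, lenBp) {
    if (lenCM == 0)
        return(rep(1L, length(cM)))
    pmax(1L, pmin(as.integer(round(cM / lenCM * lenBp)), as.integer(lenBp)))
}

#' Simulate an F2 population segregating one recessive locus
#'
#' Each F2 individual receives two gametes drawn from independent F1
#' meioses. Per chromosome a gamete carries a random starting parental
#' phase and a crossover count drawn from Poisson(length in Morgans) with
#' breakpoints uniform along the chromosome (a no-interference, Haldane
#' process). The phenotype follows the single-recessive rule: mutant if and
#' only if both gametes carry the mutant-parent allele at the causal locus,
#' so phenotypes segregate 3:1 in expectation.
#'
#' @param config A [simConfig()] object.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return An [F2Population-class] ground-truth object.
#' @examples
#' pop <- simulateF2(simConfig(nF2 = 100), seed = 1)
#' table(phenotypes(pop))
#' @export
simulateF2 <- function(config, seed = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    if (!is.null(seed))
        set.seed(seed)
    nG <- 2L * config$nF2
    breaks <- vector("list", config$nChromosomes)
    phase0 <- matrix(0L, nrow = nG, ncol = config$nChromosomes)
    for (c in seq_len(config$nChromosomes)) {
        L <- config$chromLengthCM[c]
        nco <- stats::rpois(nG, L / 100)
        pts <- stats::runif(sum(nco), 0, L)
        idx <- factor(rep.int(seq_len(nG), nco), levels = seq_len(nG))
        bl <- split(pts, idx)
        breaks[[c]] <- lapply(bl, sort)
        phase0[, c] <- stats::rbinom(nG, 1L, 0.5)
    }
    names(breaks) <- .chromNames(config$nChromosomes)
    causalChromName <- .chromNames(config$nChromosomes)[config$causalChrom]
    causal <- list(chrom = causalChromName, cM = config$causalCM,
                   bp = .cm2bp(config$causalCM,
                               config$chromLengthCM[config$causalChrom],
                               config$chromLengthBp[config$causalChrom]))
    pop <- new("F2Population", nF2 = config$nF2,
               chromLengthCM = stats::setNames(config$chromLengthCM,
                                               names(breaks)),
               chromLengthBp = stats::setNames(config$chromLengthBp,
                                               names(breaks)),
               causal = causal, phase0 = phase0, breaks = breaks,
               phenotype = rep("wildtype", config$nF2))
    gAll <- .gameteAlleles(pop, causalChromName, config$causalCM)
    odd <- seq(1L, nG, by = 2L)
    mutant <- gAll[odd, 1L] == 1L & gAll[odd + 1L, 1L] == 1L
    pop@phenotype <- ifelse(mutant, "mutant", "wildtype")
    validObject(pop)
    pop
}

# Allele (1 = mutant-parent) of every gamete at the given cM positions on
# one chromosome; rows are gametes (2i-1, 2i belong to individual i).
.gameteAlleles <- function(pop, chrom, cM) {
    br <- pop@breaks[[chrom]]
    ci <- match(chrom, names(pop@breaks))
    ph <- pop@phase0[, ci]
    m <- vapply(seq_along(br), function(g)
        (ph[g] + findInterval(cM, br[[g]])) %% 2L,
        integer(length(cM)))
    if (length(cM) == 1L) matrix(m, ncol = 1L) else t(m)
}

#' Simulate sequenced phenotype bulks over random SNVs
#'
#' Selects \code{bulkSize} mutant-phenotype and \code{bulkSize}
#' wild-type-phenotype individuals, then, at random SNV positions on each
#' chromosome, computes the true pool frequency of the mutant-parent allele
#' (the mean over the bulk's gametes), draws a Poisson read depth per pool
#' and binomial alternate-read counts at the error-adjusted frequency.
#' The alternate allele of every SNV is the mutant-parent allele.
#'
#' @param pop An [F2Population-class] object.
#' @param config The [simConfig()] used (supplies bulk size, depth, error
#'   rate and SNV count).
#' @param seed Optional integer seed.
#'
#' @return A [PooledVariants-class] object.
#' @export
simulateBulks <- function(pop, config, seed = NULL) {
    stopifnot(is(pop, "F2Population"), inherits(config, "SimConfig"))
    if (!is.null(seed))
        set.seed(seed)
    mut <- which(pop@phenotype == "mutant")
    wt <- which(pop@phenotype == "wildtype")
    b <- config$bulkSize
    if (length(mut) < b)
        stop("insufficient mutant individuals: need ", b, ", have ",
             length(mut))
    if (length(wt) < b)
        stop("insufficient wild-type individuals: need ", b, ", have ",
             length(wt))
    mutIdx <- sample(mut, b)
    wtIdx <- sample(wt, b)
    gi <- function(ind) sort(c(2L * ind - 1L, 2L * ind))
    chroms <- names(pop@breaks)
    out <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
        lenBp <- pop@chromLengthBp[ci]
        lenCM <- pop@chromLengthCM[ci]
        bp <- sort(sample.int(lenBp, min(config$nSnvs, lenBp)))
        cM <- bp / lenBp * lenCM
        aAll <- .gameteAlleles(pop, chroms[ci], cM)
        aM <- aAll[gi(mutIdx), , drop = FALSE]
        aW <- aAll[gi(wtIdx), , drop = FALSE]
        fM <- colMeans(aM)
        fW <- colMeans(aW)
        e <- config$seqError
        pM <- fM * (1 - e) + (1 - fM) * e
        pW <- fW * (1 - e) + (1 - fW) * e
        dM <- stats::rpois(length(bp), config$meanDepth)
        dW <- stats::rpois(length(bp), config$meanDepth)
        altM <- stats::rbinom(length(bp), dM, pM)
        altW <- stats::rbinom(length(bp), dW, pW)
        refBase <- sample(c("A", "C", "G", "T"), length(bp), replace = TRUE)
        altBase <- vapply(refBase, function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
        out[[ci]] <- data.frame(chrom = chroms[ci], pos = bp,
                                ref = refBase, alt = altBase,
                                mutRef = dM - altM, mutAlt = altM,
                                wtRef = dW - altW, wtAlt = altW)
    }
    d <- do.call(rbind, out)
    PooledVariants(d$chrom, d$pos, d$ref, d$alt, d$mutRef, d$mutAlt,
                   d$wtRef, d$wtAlt)
}

#' Read marker genotypes off the simulated gametes
#'
#' Genotype codes are deterministic given the stored crossover truth:
#' \code{A} when both gametes carry the mutant-parent allele, \code{B} when
#' neither does, \code{H} otherwise. With
#' \code{restrict = "recessive_only"} only mutant-phenotype individuals are
#' genotyped (the fine-mapping design).
#'
#' @param pop An [F2Population-class] object.
#' @param markerPositions Data.frame with columns \code{marker},
#'   \code{chrom} and \code{cM}.
#' @param restrict \code{"recessive_only"} or \code{"all"}.
#'
#' @return A [MarkerGenotypeTable-class]; marker bp positions follow the
#'   linear cM-to-bp map of the simulated chromosomes.
#' @export
simulateMarkerGenotypes <- function(pop, markerPositions,
                                    restrict = c("recessive_only", "all")) {
    stopifnot(is(pop, "F2Population"))
    restrict <- match.arg(restrict)
    mp <- as.data.frame(markerPositions)
    stopifnot(all(c("marker", "chrom", "cM") %in% colnames(mp)))
    bad <- !mp$chrom %in% names(pop@breaks) |
        mp$cM < 0 | mp$cM > pop@chromLengthCM[mp$chrom]
    if (any(bad))
        stop("marker(s) outside the simulated chromosomes: ",
             paste(mp$marker[bad], collapse = ", "))
    ind <- if (restrict == "recessive_only")
        which(pop@phenotype == "mutant") else seq_len(pop@nF2)
    if (!length(ind))
        stop("no individuals to genotype under restrict = '", restrict, "'")
    calls <- matrix("U", nrow = length(ind), ncol = nrow(mp),
                    dimnames = list(paste0("ind", ind), mp$marker))
    for (ch in unique(mp$chrom)) {
        sel <- which(mp$chrom == ch)
        gAll <- .gameteAlleles(pop, ch, mp$cM[sel])
        a1 <- gAll[2L * ind - 1L, , drop = FALSE]
        a2 <- gAll[2L * ind, , drop = FALSE]
        g <- a1 + a2          # 2 = A, 1 = H, 0 = B
        calls[, sel] <- c("B", "H", "A")[g + 1L]
    }
    bp <- integer(nrow(mp))
    for (i in seq_len(nrow(mp)))
        bp[i] <- .cm2bp(mp$cM[i], pop@chromLengthCM[mp$chrom[i]],
                        pop@chromLengthBp[mp$chrom[i]])
    markers <- GRanges(mp$chrom, IRanges(bp, width = 1L))
    names(markers) <- mp$marker
    MarkerGenotypeTable(calls, markers,
                        population = if (restrict == "recessive_only")
                            "recessive" else "all")
}

#' Simulate a qPCR Ct table with a known fold change
#'
#' Generates per-replicate target and reference cycle thresholds for a
#' mutant and a wild-type group. The reference gene Ct is constant up to
#' noise; the mutant target Ct is shifted by \code{-log2(foldChange)}
#' relative to wild type, so the configured fold change is exactly
#' recoverable by [deltaDeltaCt()] at zero noise.
#'
#' @param nPerGroup Biological replicates per group (>= 2).
#' @param foldChange True mutant/wild-type expression ratio (> 0).
#' @param sdCt Standard deviation of the Gaussian Ct noise.
#' @param tissue Tissue/stage label attached to the measurements.
#' @param ctReference Baseline reference-gene Ct.
#' @param ctTargetWt Baseline wild-type target-gene Ct.
#' @param seed Optional integer seed.
#'
#' @return A data.frame in the layout of [readCtTable()].
#' @examples
#' simulateQpcr(3, foldChange = 4, sdCt = 0, seed = 1)
#' @export
simulateQpcr <- function(nPerGroup = 3, foldChange = 4, sdCt = 0.2,
                         tissue = "leaf", ctReference = 18,
                         ctTargetWt = 22, seed = NULL) {
    if (!is.null(seed))
        set.seed(seed)
    if (foldChange <= 0)
        stop("'foldChange' must be > 0")
    if (nPerGroup < 2)
        stop("'nPerGroup' must be >= 2")
    n <- as.integer(nPerGroup)
    grp <- rep(c("mutant", "wildtype"), each = n)
    base <- ifelse(grp == "mutant", ctTargetWt - log2(foldChange),
                   ctTargetWt)
    data.frame(sample = paste0(grp, "_", rep(seq_len(n), 2L)),
               group = grp, tissue = tissue,
               ct_target = base + stats::rnorm(2L * n, 0, sdCt),
               ct_reference = ctReference + stats::rnorm(2L * n, 0, sdCt))
}
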