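#' Relative expression by the 2^-ddCt method
#'
#' Livak-style relative quantification. Per replicate,
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; per tissue,
#' \eqn{\Delta\Delta Ct} is the replicate's \eqn{\Delta Ct} minus the mean
#' \eqn{\Delta Ct} of the calibrator group in the same tissue, and the
#' replicate-level fold change is \eqn{2^{-\Delta\Delta Ct}}. Group
#' summaries are the mean and standard deviation of the replicate folds,
#' so the calibrator group's mean fold is 1 by construction only in
#' expectation of \eqn{\Delta Ct}; its mean \eqn{\Delta\Delta Ct} is
#' exactly 0. Each non-calibrator group is compared with the calibrator by
#' a two-sided t-test on the replicate folds (Welch by default).
#'
#' Tissues lacking calibrator measurements are skipped with a warning.
#'
#' @param ct Data.frame of Ct measurements as from [readCtTable()] or
#'   [simulateQpcr()].
#' @param calibrator Group used as calibrator (default \code{"wildtype"}).
#' @param varEqual Use Student's (pooled-variance) t-test instead of
#'   Welch's.
#' @param alpha Significance level.
#'
#' @return A list with \code{summary} (data.frame: group, tissue, n,
#'   meanFold, sdFold, pValue, significant) and \code{replicates}
#'   (data.frame of per-replicate dCt, ddCt and fold).
#' @examples
#' ct <- simulateQpcr(3, foldChange = 4, sdCt = 0)
#' deltaDeltaCt(ct)$summary
#' @export
deltaDeltaCt <- function(ct, calibrator = "wildtype", varEqual = FALSE,
                         alpha = 0.05) {
    need <- c("group", "tissue", "ct_target", "ct_reference")
    missing <- setdiff(need, colnames(ct))
    if (length(missing))
        stop("Ct data lacks column(s): ", paste(missing, collapse = ", "))
    ct$dCt <- ct$ct_target - ct$ct_reference
    reps <- list()
    summ <- list()
    for (tis in unique(ct$tissue)) {
        sub <- ct[ct$tissue == tis, , drop = FALSE]
        calib <- sub[sub$group == calibrator, , drop = FALSE]
        if (!nrow(calib)) {
            warning("tissue '", tis, "': no calibrator ('", calibrator,
                    "') measurements; skipped")
            next
        }
        calibMean <- mean(calib$dCt)
        sub$ddCt <- sub$dCt - calibMean
        sub$fold <- 2^(-sub$ddCt)
        reps[[tis]] <- sub
        calibFolds <- sub$fold[sub$group == calibrator]
        for (g in unique(sub$group)) {
            folds <- sub$fold[sub$group == g]
            p <- if (g == calibrator || length(folds) < 2L ||
                     length(calibFolds) < 2L) NA_real_
                 else groupTTest(folds, calibFolds,
                                 varEqual = varEqual)$pValue
            summ[[paste(g, tis)]] <- data.frame(
                group = g, tissue = tis, n = length(folds),
                meanFold = mean(folds), sdFold = stats::sd(folds),
                pValue = p,
                significant = !is.na(p) && p < alpha)
        }
    }
    if (!length(summ))
        stop("no tissue had calibrator measurements")
    list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
         replicates = do.call(rbind, c(reps, make.row.names = FALSE)))
}

#' Two-group t-test on replicate fold changes
#'
#' Two-sided two-sample t-test (Welch's unequal-variance form by
#' default). When both groups have zero variance and equal means -- the
#' degenerate noiseless case where \code{t.test} is undefined -- the
#' p-value is 1 (no evidence of difference).
#'
#' @param x,y Numeric vectors of replicate values (>= 2 each).
#' @param varEqual Pool the variances (Student's test).
#' @param alpha Significance level.
#' @return A list with \code{pValue} and \code{significant}.
#' @examples
#' groupTTest(c(1.1, 0.9, 1.0), c(3.8, 4.1, 4.2))
#' @export
groupTTest <- function(x, y, varEqual = FALSE, alpha = 0.05) {
    if (length(x) < 2L || length(y) < 2L)
        stop("at least two replicates per group are required")
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (isTRUE(all.equal(mean(x), mean(y)))) 1
        else 0
    } else {
        stats::t.test(x, y, var.equal = varEqual)$p.value
    }
    list(pValue = p, significant = p < alpha)
}
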