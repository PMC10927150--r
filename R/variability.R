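#' Per-gene mean and variance by treatment-time group
#'
#' Sample mean and unbiased sample variance of log2 cpm across the
#' individuals within each treatment-by-time group. Groups with a single
#' individual are flagged (variance undefined).
#'
#' @param logcpm gene x sample log2 cpm matrix.
#' @param samples data.frame with `individual`, `treatment`, `time`
#'   matching the columns of `logcpm`.
#' @return list with `mean` and `variance` (gene x group matrices,
#'   columns `<treatment>.<time>`), `n` (individuals per group) and
#'   `flagged` (groups with n < 2).
#' @export
groupMeanVariance <- function(logcpm, samples) {
    grp <- paste(samples$treatment, samples$time, sep = ".")
    groups <- unique(grp)
    mu <- matrix(NA_real_, nrow(logcpm), length(groups),
                 dimnames = list(rownames(logcpm), groups))
    va <- mu
    n <- setNames(integer(length(groups)), groups)
    for (g in groups) {
        cols <- which(grp == g)
        n[g] <- length(unique(samples$individual[cols]))
        sub <- logcpm[, cols, drop = FALSE]
        mu[, g] <- rowMeans(sub)
        if (ncol(sub) >= 2)
            va[, g] <- rowSums((sub - mu[, g])^2) / (ncol(sub) - 1)
    }
    list(mean = mu, variance = va, n = n,
         flagged = names(n)[n < 2])
}

#' Per-gene variance-ratio test against vehicle
#'
#' For each gene, `F = s2_drug / s2_veh` with a two-sided p-value from
#' the F distribution on (nDrug - 1, nVeh - 1) degrees of freedom:
#' `p = 2 * min(P(F <= f), P(F >= f))`, capped at 1 (the var.test
#' convention). Genes with zero vehicle variance are excluded.
#'
#' @param drugVar,vehVar per-gene variance vectors.
#' @param nDrug,nVeh group sizes (individuals).
#' @return data.frame `gene`, `F`, `p` for testable genes, with
#'   attribute `"nExcluded"`.
#' @export
varianceTestPerGene <- function(drugVar, vehVar, nDrug, nVeh) {
    if (nDrug < 2 || nVeh < 2) stop("both groups need >= 2 individuals")
    ok <- is.finite(drugVar) & is.finite(vehVar) & vehVar > 0
    f <- drugVar[ok] / vehVar[ok]
    lower <- pf(f, nDrug - 1, nVeh - 1)
    p <- pmin(2 * pmin(lower, 1 - lower), 1)
    genes <- names(drugVar)[ok]
    if (is.null(genes)) genes <- which(ok)
    out <- data.frame(gene = genes, F = unname(f), p = unname(p))
    attr(out, "nExcluded") <- sum(!ok)
    out
}

#' Group-level variance shift test
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-gene log
#' variance ratios drug/vehicle; the direction is the sign of the median
#' log ratio.
#'
#' @param drugVars,vehVars paired per-gene variance vectors.
#' @return list with `p`, `direction` (+1/-1/0) and `medianLogRatio`.
#' @export
groupVarianceShiftTest <- function(drugVars, vehVars) {
    ok <- is.finite(drugVars) & is.finite(vehVars) &
        drugVars > 0 & vehVars > 0
    lr <- log(drugVars[ok] / vehVars[ok])
    if (!length(lr) || all(lr == 0))
        return(list(p = 1, direction = 0, medianLogRatio = 0))
    wt <- suppressWarnings(wilcox.test(lr, mu = 0))
    md <- median(lr)
    list(p = wt$p.value, direction = sign(md), medianLogRatio = md)
}

#' Cluster groups by their variance-change profiles
#'
#' Pairwise Spearman correlation (mid-ranks for ties) between the
#' per-gene F-statistic vectors of each group, clustered with average
#' linkage on `1 - rho`.
#'
#' @param fMatrix gene x group matrix of F statistics (shared gene
#'   universe; NAs dropped row-wise).
#' @return list with `correlation`, `order`, `hclust`.
#' @export
varianceProfileClustering <- function(fMatrix) {
    fMatrix <- as.matrix(fMatrix)
    fMatrix <- fMatrix[complete.cases(fMatrix), , drop = FALSE]
    keep <- apply(fMatrix, 2, function(x) length(unique(x)) > 1)
    if (!all(keep)) {
        warning("dropping constant F-statistic group(s): ",
                paste(colnames(fMatrix)[!keep], collapse = ", "))
        fMatrix <- fMatrix[, keep, drop = FALSE]
    }
    rho <- cor(fMatrix, method = "spearman")
    hc <- hclust(as.dist(1 - rho), method = "average")
    list(correlation = rho, order = hc$order, hclust = hc)
}

#' Inter-individual variability analysis of a count study
#'
#' Convenience wrapper: computes log2 cpm (TMM-normalised) on the
#' expressed genes, per-group means/variances, per-gene F tests of each
#' drug-time group against the vehicle at the same timepoint, the
#' group-level variance shift tests, and the Spearman clustering of the
#' F-statistic profiles.
#'
#' @param experiment a [CardioExperiment-class].
#' @return list with `groupStats`, `fTests` (named list of data.frames),
#'   `shiftTests` (data.frame group, p, direction), `clustering`.
#' @export
variabilityAnalysis <- function(experiment) {
    cts <- counts(experiment)
    keep <- filterExpressed(log2Cpm(cts))
    cts <- cts[keep, , drop = FALSE]
    nf <- tmmFactors(cts)
    lc <- log2Cpm(cts, normFactors = nf)
    samples <- data.frame(individual = individuals(experiment),
                          treatment = treatments(experiment),
                          time = timepoints(experiment))
    gs <- groupMeanVariance(lc, samples)
    drugs <- setdiff(unique(samples$treatment), "VEH")
    times <- unique(samples$time)
    fTests <- list(); shift <- list()
    fMat <- NULL
    for (tp in times) {
        vehKey <- paste("VEH", tp, sep = ".")
        for (dr in drugs) {
            key <- paste(dr, tp, sep = ".")
            ft <- varianceTestPerGene(gs$variance[, key],
                                      gs$variance[, vehKey],
                                      gs$n[key], gs$n[vehKey])
            fTests[[key]] <- ft
            st <- groupVarianceShiftTest(gs$variance[, key],
                                         gs$variance[, vehKey])
            shift[[key]] <- data.frame(group = key, p = st$p,
                                       direction = st$direction,
                                       medianLogRatio = st$medianLogRatio)
            fcol <- setNames(rep(NA_real_, nrow(lc)), rownames(lc))
            fcol[ft$gene] <- ft$F
            fMat <- cbind(fMat, fcol)
        }
    }
    colnames(fMat) <- names(fTests)
    list(groupStats = gs, fTests = fTests,
         shiftTests = do.call(rbind, c(shift, make.row.names = FALSE)),
         clustering = varianceProfileClustering(fMat))
}
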