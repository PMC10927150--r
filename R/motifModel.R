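#' Moderated test statistics per drug-vs-vehicle pair
#'
#' For each (drug, timepoint) pair the samples of that drug and the
#' vehicle at the same timepoint are modelled with the donor as a
#' blocking factor, using library sizes and TMM factors computed on the
#' full experiment, and the moderated t statistic for the treatment
#' effect is extracted. These per-pair statistics are the input to the
#' joint motif model.
#'
#' @param experiment a [CardioExperiment-class].
#' @param pairs data.frame with columns `drug`, `time`; defaults to all
#'   non-vehicle treatments crossed with all timepoints.
#' @return list with `t` (gene x pair moderated-t matrix), `df`
#'   (per-pair total degrees of freedom), `tables` (the per-pair
#'   contrast tables) and `expressed`.
#' @export
conditionStatistics <- function(experiment, pairs = NULL) {
    trt <- treatments(experiment); tm <- timepoints(experiment)
    if (is.null(pairs))
        pairs <- expand.grid(drug = setdiff(unique(trt), "VEH"),
                             time = unique(tm), stringsAsFactors = FALSE)
    cts <- counts(experiment)
    keep <- filterExpressed(log2Cpm(cts))
    cts <- cts[keep, , drop = FALSE]
    nf <- tmmFactors(cts)
    libs <- colSums(cts)
    tmat <- NULL; dfs <- numeric(0); tables <- list()
    for (i in seq_len(nrow(pairs))) {
        drug <- pairs$drug[i]; tp <- pairs$time[i]
        sel <- tm == tp & trt %in% c(drug, "VEH")
        if (!any(trt[sel] == drug) || !any(trt[sel] == "VEH"))
            stop("no samples for pair ", drug, ".", tp)
        sub <- cts[, sel, drop = FALSE]
        indiv <- factor(individuals(experiment)[sel])
        isDrug <- as.numeric(trt[sel] == drug)
        design <- stats::model.matrix(~ indiv + isDrug)
        pw <- precisionWeights(sub, design, libSizes = libs[sel],
                               normFactors = nf[sel])
        tabs <- moderatedFit(pw$logcpm, pw$weights, design, "isDrug")
        tb <- tabs[[1]]
        key <- paste(drug, tp, sep = ".")
        tables[[key]] <- tb
        tmat <- cbind(tmat, tb$moderated_t)
        dfs <- c(dfs, tb$df_total[1])
    }
    colnames(tmat) <- names(tables)
    rownames(tmat) <- tables[[1]]$gene
    names(dfs) <- names(tables)
    list(t = tmat, df = dfs, tables = tables, expressed = rownames(tmat))
}

## log density of the alternative component: a central t scaled by
## sqrt(1 + v), i.e. dt(t / sqrt(1+v), df) / sqrt(1+v)
.logF1 <- function(tvals, df, v) {
    dt(tvals / sqrt(1 + v), df = df, log = TRUE) - 0.5 * log1p(v)
}

## Minimum variance inflation of the DE component. Below this the
## alternative density collapses onto the null and the per-condition DE
## probabilities become unidentifiable (any q fits equally well, and EM
## stalls far from the maximum), so the DE component is required to be
## at least twice as wide (1 + v >= 5) as the null. Detectable effects
## inflate the statistic variance far beyond this.
.vFloor <- 4

## One EM run from a given start; returns fit components
.emRun <- function(tmat, df, K, Q, pi0, v, maxIter, tol,
                   updateVEvery = 1L) {
    G <- nrow(tmat); D <- ncol(tmat)
    logf0 <- vapply(seq_len(D),
                    function(d) dt(tmat[, d], df = df[d], log = TRUE),
                    numeric(G))
    logf1 <- vapply(seq_len(D),
                    function(d) .logF1(tmat[, d], df[d], v[d]),
                    numeric(G))
    eps <- 1e-6
    trace <- numeric(0)
    ll <- -Inf
    for (iter in seq_len(maxIter)) {
        # E-step ---------------------------------------------------------
        # log of the per-gene, per-motif likelihood Pi_d (q f1 + (1-q) f0)
        m <- pmax(logf0, logf1)
        e0 <- exp(logf0 - m); e1 <- exp(logf1 - m)
        logA <- matrix(0, G, K)      # log pi_k + sum_d log mix
        Wsum <- matrix(0, G, D)      # sum_k z w (filled after z known)
        Wk <- vector("list", K)
        for (k in seq_len(K)) {
            qk <- Q[k, ]
            mix <- sweep(e1, 2, qk, "*") + sweep(e0, 2, 1 - qk, "*")
            logA[, k] <- log(pi0[k]) + rowSums(log(mix) + m)
            # responsibility of the DE component within motif k
            Wk[[k]] <- sweep(e1, 2, qk, "*") / mix
        }
        mrow <- apply(logA, 1, max)
        z <- exp(logA - mrow)
        rs <- rowSums(z)
        llNew <- sum(mrow + log(rs))
        z <- z / rs
        trace <- c(trace, llNew)
        # M-step ---------------------------------------------------------
        piNew <- colMeans(z)
        piNew <- pmax(piNew, 1e-12); piNew <- piNew / sum(piNew)
        Qnew <- Q
        for (k in seq_len(K)) {
            zk <- z[, k]
            Qnew[k, ] <- colSums(zk * Wk[[k]]) / max(sum(zk), 1e-12)
            Wsum <- Wsum + zk * Wk[[k]]
        }
        Qnew <- pmin(pmax(Qnew, eps), 1 - eps)
        if (iter %% updateVEvery == 0L) {
            for (d in seq_len(D)) {
                u <- Wsum[, d]
                if (sum(u) < 1e-8) next
                td <- tmat[, d]; dfd <- df[d]
                obj <- function(lv) sum(u * .logF1(td, dfd, exp(lv)))
                opt <- optimize(obj, interval = c(log(.vFloor), log(1e4)),
                                maximum = TRUE, tol = 1e-3)
                # keep the old value if the search did not improve it,
                # preserving the EM ascent property
                if (opt$objective > obj(log(v[d]))) v[d] <- exp(opt$maximum)
            }
            logf1 <- vapply(seq_len(D),
                            function(d) .logF1(tmat[, d], df[d], v[d]),
                            numeric(G))
        }
        done <- is.finite(ll) &&
            abs(llNew - ll) < tol * (abs(ll) + 1)
        pi0 <- piNew; Q <- Qnew; ll <- llNew
        if (done) break
    }
    # final E-step quantities at the converged parameters
    m <- pmax(logf0, logf1)
    e0 <- exp(logf0 - m); e1 <- exp(logf1 - m)
    logA <- matrix(0, G, K)
    Wk <- vector("list", K)
    for (k in seq_len(K)) {
        qk <- Q[k, ]
        mix <- sweep(e1, 2, qk, "*") + sweep(e0, 2, 1 - qk, "*")
        logA[, k] <- log(pi0[k]) + rowSums(log(mix) + m)
        Wk[[k]] <- sweep(e1, 2, qk, "*") / mix
    }
    mrow <- apply(logA, 1, max)
    z <- exp(logA - mrow)
    rs <- rowSums(z)
    loglik <- sum(mrow + log(rs))
    z <- z / rs
    dePost <- matrix(0, G, D)
    for (k in seq_len(K)) dePost <- dePost + z[, k] * Wk[[k]]
    list(pi = pi0, Q = Q, v = v, z = z, dePosterior = dePost,
         loglik = loglik, trace = c(trace, loglik),
         converged = length(trace) < maxIter)
}

#' Fit the correlation-motif mixture model
#'
#' Genes are modelled as a K-component mixture: motif k carries a vector
#' `Q[k, ]` of per-contrast probabilities of differential expression.
#' Under no differential expression the moderated t of contrast d
#' follows a central t with the contrast's total degrees of freedom;
#' under differential expression it follows the same t scaled by
#' `sqrt(1 + v_d)`, with the variance inflation `v_d` estimated in the
#' M-step by one-dimensional golden-section search. EM runs from
#' `nRestarts` seeded starts (short runs, the best continued to
#' convergence at relative log-likelihood change < 1e-6).
#'
#' @param tmat gene x contrast moderated-t matrix.
#' @param df per-contrast total degrees of freedom.
#' @param K number of motifs (>= 1).
#' @param seed master seed; restart seeds derive from it.
#' @param nRestarts number of EM starts (default 10).
#' @param maxIter EM iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance.
#' @return A [MotifFit-class].
#' @export
fitMotifs <- function(tmat, df, K, seed = 1L, nRestarts = 10,
                      maxIter = 500, tol = 1e-6) {
    stopifnot(K >= 1, nrow(tmat) > K)
    G <- nrow(tmat); D <- ncol(tmat)
    if (length(df) == 1) df <- rep(df, D)
    shortIter <- 15L
    cand <- vector("list", nRestarts)
    for (r in seq_len(nRestarts)) {
        set.seed(as.integer((as.numeric(seed) * 1000 + r) %% 2147483587))
        Q0 <- matrix(runif(K * D, 0.1, 0.9), K, D)
        pi0 <- rexp(K) + 0.5; pi0 <- pi0 / sum(pi0)
        v0 <- rep(max(1, .vFloor), D)
        cand[[r]] <- list(Q = Q0, pi = pi0, v = v0)
    }
    shorts <- lapply(cand, function(st)
        .emRun(tmat, df, K, st$Q, st$pi, st$v, shortIter, tol,
               updateVEvery = 5L))
    best <- shorts[[which.max(vapply(shorts, `[[`, 0, "loglik"))]]
    fit <- .emRun(tmat, df, K, best$Q, best$pi, best$v, maxIter, tol,
                  updateVEvery = 5L)
    p <- (K - 1) + K * D + D
    condNames <- colnames(tmat)
    if (is.null(condNames)) condNames <- paste0("d", seq_len(D))
    dimnames(fit$Q) <- list(paste0("motif", seq_len(K)), condNames)
    dimnames(fit$z) <- list(rownames(tmat), rownames(fit$Q))
    dimnames(fit$dePosterior) <- list(rownames(tmat), condNames)
    new("MotifFit", K = as.integer(K), pi = unname(fit$pi), Q = fit$Q,
        v = unname(fit$v), genePosterior = fit$z,
        dePosterior = fit$dePosterior, loglik = fit$loglik,
        bic = -2 * fit$loglik + p * log(G),
        aic = -2 * fit$loglik + 2 * p,
        loglikTrace = fit$trace, conditions = condNames,
        converged = fit$converged)
}

#' Choose the number of motifs by BIC
#'
#' Fits the motif model for each K in `kRange` and returns the
#' BIC-minimising K together with the full score table (`p = (K - 1) +
#' K D + D` free parameters).
#'
#' @param tmat,df,seed,nRestarts,maxIter,tol as in [fitMotifs()].
#' @param kRange candidate motif numbers (default 1:8).
#' @param keepFits return the fitted models as well.
#' @return list with `bestK`, `scores` (data.frame K, loglik, bic, aic)
#'   and, if requested, `fits`.
#' @export
selectMotifNumber <- function(tmat, df, kRange = 1:8, seed = 1L,
                              nRestarts = 10, maxIter = 500,
                              tol = 1e-6, keepFits = FALSE) {
    stopifnot(length(kRange) >= 1)
    fits <- lapply(kRange, function(K)
        fitMotifs(tmat, df, K, seed = seed, nRestarts = nRestarts,
                  maxIter = maxIter, tol = tol))
    scores <- data.frame(
        K = kRange,
        loglik = vapply(fits, function(f) f@loglik, 0),
        bic = vapply(fits, function(f) f@bic, 0),
        aic = vapply(fits, function(f) f@aic, 0))
    bestK <- kRange[which.min(scores$bic)]
    out <- list(bestK = bestK, scores = scores)
    if (keepFits) out$fits <- setNames(fits, paste0("K", kRange))
    out
}

## classify one motif's Q row against the response templates
.labelMotif <- function(qrow, earlyPairs, latePairs, minResponsive = 3) {
    respEarly <- sum(qrow[earlyPairs] > 0.5) >= min(minResponsive,
                                                    length(earlyPairs))
    respLate <- sum(qrow[latePairs] > 0.5) >= min(minResponsive,
                                                  length(latePairs))
    if (respEarly && respLate) return("ESR")
    if (respEarly) return("EAR")
    if (respLate) return("LR")
    if (all(qrow <= 0.5)) return("NR")
    "other"
}

#' Assign genes to response signatures
#'
#' A gene is uniquely assigned to a motif when its posterior membership
#' exceeds 0.5 for that motif and is below 0.5 for every other motif
#' (strict inequalities; ties stay unassigned). Motifs are labelled from
#' their Q rows over the TOP2i contrasts: responsive at a timepoint when
#' the DE probability exceeds 0.5 for at least 3 of the 4 TOP2i drugs;
#' early-only gives EAR, late-only LR, both ESR, a row at or below 0.5
#' everywhere NR, and anything else "other".
#'
#' @param fit a [MotifFit-class].
#' @param top2i TOP2 inhibitor drug labels used for labelling.
#' @param timepoints two timepoint labels, early first.
#' @param minResponsive drugs required above 0.5 per timepoint
#'   (default 3 of 4).
#' @return list with `labels` (per-gene factor incl. `"unassigned"`),
#'   `motifLabels` (per-motif), `assignedFraction`, and `motifIndex`
#'   (per-gene assigned motif or NA).
#' @export
assignSignatures <- function(fit, top2i = c("DOX", "EPI", "DNR", "MTX"),
                             timepoints = c("3h", "24h"),
                             minResponsive = 3) {
    z <- genePosterior(fit)
    Q <- motifPatterns(fit)
    cond <- colnames(Q)
    earlyPairs <- intersect(paste(top2i, timepoints[1], sep = "."), cond)
    latePairs <- intersect(paste(top2i, timepoints[2], sep = "."), cond)
    if (!length(earlyPairs) && !length(latePairs))
        stop("no TOP2i contrasts found among: ",
             paste(cond, collapse = ", "))
    motifLabels <- apply(Q, 1, .labelMotif, earlyPairs = earlyPairs,
                         latePairs = latePairs,
                         minResponsive = minResponsive)
    top <- max.col(z, ties.method = "first")
    topP <- z[cbind(seq_len(nrow(z)), top)]
    others <- if (ncol(z) == 1) rep(-Inf, nrow(z))
              else apply(z, 1, function(r) max(r[-which.max(r)]))
    assigned <- topP > 0.5 & others < 0.5
    motifIndex <- ifelse(assigned, top, NA_integer_)
    labels <- ifelse(assigned, motifLabels[top], "unassigned")
    names(labels) <- rownames(z)
    list(labels = labels,
         motifLabels = motifLabels,
         assignedFraction = mean(assigned),
         motifIndex = motifIndex)
}

#' Stringent drug-specific response genes
#'
#' Genes significant only for the drug of interest: adjusted p below
#' `stringent` for the target drug and above `lenient` for every other
#' drug at the same timepoint.
#'
#' @param tables named list of contrast tables for one timepoint (names
#'   are drug labels or `<drug>.<time>`).
#' @param targetDrug drug of interest; must name an entry of `tables`.
#' @param stringent adjusted-p threshold for the target (default 0.01).
#' @param lenient adjusted-p floor for all other drugs (default 0.05).
#' @return character vector of gene identifiers.
#' @export
drugSpecificGenes <- function(tables, targetDrug, stringent = 0.01,
                              lenient = 0.05) {
    hit <- grep(paste0("^", targetDrug, "($|\\.)"), names(tables))
    if (length(hit) != 1)
        stop("no (unique) table for drug ", targetDrug)
    target <- tables[[hit]]
    genes <- target$gene
    sel <- target$p_adj < stringent
    for (j in setdiff(seq_along(tables), hit)) {
        tb <- tables[[j]]
        if (!identical(tb$gene, genes))
            stop("contrast tables do not share a gene universe")
        sel <- sel & tb$p_adj > lenient
    }
    genes[sel]
}
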