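# Independent brute-force / closed-form oracles used across the suite.
# These deliberately re-derive results from first principles and never
# call the implementation paths they check.

# peak rule evaluated literally, point by point, on an explicitly
# loop-smoothed series
oraclePeaks <- function(x, window = 5, prob = 0.6) {
    n <- length(x)
    h <- (window - 1) / 2
    s <- vapply(seq_len(n), function(i)
        mean(x[max(1, i - h):min(n, i + h)]), 0)
    gate <- quantile(s, prob, names = FALSE)
    hits <- integer(0)
    for (i in 2:(n - 1))
        if (s[i] > s[i - 1] && s[i] > s[i + 1] && s[i] > gate)
            hits <- c(hits, i)
    hits
}

# Benjamini-Hochberg by the textbook step-up definition
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}

# one-sided Fisher p as an explicit hypergeometric tail sum
oracleHyper <- function(a, b, c, d) {
    # P(X >= a) where X ~ Hypergeom(m = a + c, n = b + d, k = a + b)
    m <- a + c; n2 <- b + d; k <- a + b
    xs <- max(0, k - n2):min(k, m)
    probs <- exp(lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k))
    sum(probs[xs >= a])
}

# all-pairs nearest-TSS scan with the lexicographic tie-break
oracleNearestTss <- function(snps, tss) {
    out <- data.frame(id = snps$id, gene_id = NA_character_,
                      distance = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(snps))) {
        j <- which(tss$chrom == snps$chrom[i])
        if (!length(j)) next
        d <- abs(tss$tss[j] - snps$pos[i])
        dm <- min(d)
        cand <- sort(as.character(tss$gene_id[j][d == dm]))
        out$gene_id[i] <- cand[1]
        out$distance[i] <- dm
    }
    out
}

# trimmed weighted mean of M-values, written straight from the published
# algorithm (reference by upper quartile, 30%/5% double trim, inverse
# delta-method variance weights, factors rescaled to multiply to 1)
oracleTmm <- function(counts) {
    lib <- colSums(counts)
    uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        obs <- counts[, j]; rf <- counts[, ref]
        nO <- lib[j]; nR <- lib[ref]
        logR <- log2((obs / nO) / (rf / nR))
        absE <- (log2(obs / nO) + log2(rf / nR)) / 2
        v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
        fin <- is.finite(logR) & is.finite(absE)
        logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
        if (max(abs(logR)) < 1e-6) return(1)
        n <- length(logR)
        loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
        loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
        keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
        2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    }, 0)
    f / exp(mean(log(f)))
}

# bisection root of f(x) - 0.5 for the fixed-upper 4PL curve
oracleLd50Bisect <- function(b, cc, e, lo = 1e-12, hi = 1e12,
                             iter = 200) {
    f <- function(x) cc + (1 - cc) / (1 + exp(b * (log(x) - log(e)))) - 0.5
    if (f(lo) * f(hi) > 0) return(NA_real_)
    for (i in seq_len(iter)) {
        mid <- sqrt(lo * hi)
        if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    sqrt(lo * hi)
}

# does the smallest subtree containing `members` contain nothing else?
subtreeExclusive <- function(hc, members) {
    for (k in rev(seq_along(hc$labels))) {
        ct <- cutree(hc, k = k)
        cl <- unique(ct[members])
        if (length(cl) == 1)
            return(setequal(names(ct)[ct == cl], members))
    }
    FALSE
}

# match fitted motifs to planted ones by minimal total L1 distance over
# all permutations (K small)
matchMotifs <- function(Qfit, Qtrue) {
    K <- nrow(Qtrue)
    perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
        out
    }
    best <- NULL; bestCost <- Inf
    for (p in perms(seq_len(K))) {
        cost <- sum(abs(Qfit[p, , drop = FALSE] - Qtrue))
        if (cost < bestCost) { bestCost <- cost; best <- p }
    }
    best
}

# small synthetic experiment shared by unit tests (cached per session)
.tinySim <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateCounts(simDesign(nGenes = 600, seed = 303))
        cache
    }
})
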