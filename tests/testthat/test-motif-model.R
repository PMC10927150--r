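test_that("per-pair moderated statistics are calibrated and deterministic", {
    sim <- .tinySim()
    cs <- conditionStatistics(sim$experiment)
    expect_equal(ncol(cs$t), 10)
    expect_equal(colnames(cs$t)[1], "DOX.3h")
    # deterministic
    cs2 <- conditionStatistics(sim$experiment)
    expect_identical(cs$t, cs2$t)
    # null genes in a null condition follow the reference t distribution
    nr <- intersect(names(sim$truth$motif)[sim$truth$motif == "NR"],
                    rownames(cs$t))
    ks <- suppressWarnings(
        ks.test(cs$t[nr, "TRZ.24h"],
                function(q) pt(q, df = cs$df[["TRZ.24h"]])))
    expect_gt(ks$p.value, 0.01)
    # planted DE columns carry systematically larger statistics
    lr <- intersect(names(sim$truth$motif)[sim$truth$motif == "LR"],
                    rownames(cs$t))
    expect_gt(mean(abs(cs$t[lr, "DOX.24h"])), 2 * mean(abs(cs$t[nr, "DOX.24h"])))
})

test_that("the EM likelihood is monotone and posteriors are simplexes", {
    sim <- .tinySim()
    cs <- conditionStatistics(sim$experiment)
    fit <- fitMotifs(cs$t, cs$df, K = 3, seed = 2, nRestarts = 3)
    expect_true(all(diff(fit@loglikTrace) > -1e-6))
    expect_equal(unname(rowSums(genePosterior(fit))),
                 rep(1, nrow(genePosterior(fit))), tolerance = 1e-10)
    expect_equal(sum(motifFrequencies(fit)), 1, tolerance = 1e-10)
    expect_true(all(motifPatterns(fit) >= 0 & motifPatterns(fit) <= 1))
    expect_true(all(dePosterior(fit) >= -1e-12 &
                    dePosterior(fit) <= 1 + 1e-12))
})

test_that("a single null motif is recovered as silence", {
    # null t matrix: no DE anywhere
    set.seed(10)
    tmat <- matrix(rt(3000 * 4, df = 10), 3000, 4,
                   dimnames = list(paste0("g", 1:3000),
                                   c("DOX.3h", "DOX.24h", "TRZ.3h",
                                     "TRZ.24h")))
    fit <- fitMotifs(tmat, rep(10, 4), K = 1, seed = 1, nRestarts = 3)
    expect_true(all(motifPatterns(fit) < 0.05))
    # DE posteriors vanish except for chance extremes in the tails
    expect_lt(mean(dePosterior(fit)), 0.02)
    expect_lt(quantile(dePosterior(fit), 0.99), 0.2)
})

test_that("BIC selects one motif for unstructured data", {
    set.seed(11)
    tmat <- matrix(rt(2000 * 4, df = 12), 2000, 4)
    colnames(tmat) <- c("DOX.3h", "DOX.24h", "TRZ.3h", "TRZ.24h")
    sel <- selectMotifNumber(tmat, rep(12, 4), kRange = 1:3, seed = 1,
                             nRestarts = 3)
    expect_equal(sel$bestK, 1)
    # BIC exceeds AIC by (log G - 2) * p
    p <- (sel$scores$K - 1) + sel$scores$K * 4 + 4
    expect_equal(sel$scores$bic - sel$scores$aic,
                 p * (log(2000) - 2), tolerance = 1e-8)
})

test_that("signature assignment applies the strict posterior rule", {
    z <- rbind(c(0.9, 0.05, 0.03, 0.02),
               c(0.5, 0.5, 0, 0),
               c(0.2, 0.3, 0.3, 0.2),
               c(0.05, 0.9, 0.03, 0.02))
    rownames(z) <- paste0("g", 1:4)
    Q <- rbind(
        c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),      # EAR: 3h only
        c(0, 0, 0, 0, 0, 1, 1, 1, 1, 0),      # LR: 24h only
        c(1, 1, 1, 1, 0, 1, 1, 1, 1, 0),      # ESR: both
        c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0))      # NR
    colnames(Q) <- c("DOX.3h", "EPI.3h", "DNR.3h", "MTX.3h", "TRZ.3h",
                     "DOX.24h", "EPI.24h", "DNR.24h", "MTX.24h",
                     "TRZ.24h")
    rownames(Q) <- paste0("motif", 1:4)
    fit <- new("MotifFit", K = 4L, pi = rep(0.25, 4), Q = Q,
               v = rep(10, 10), genePosterior = z,
               dePosterior = matrix(0, 4, 10), loglik = 0, bic = 0,
               aic = 0, loglikTrace = 0, conditions = colnames(Q),
               converged = TRUE)
    sg <- assignSignatures(fit)
    expect_equal(unname(sg$labels),
                 c("EAR", "unassigned", "unassigned", "LR"))
    expect_equal(sg$assignedFraction, 0.5)
    expect_equal(unname(sg$motifLabels),
                 c("EAR", "LR", "ESR", "NR"))
})

test_that("motif labels derive from patterns, not from motif order", {
    sim <- .tinySim()
    cs <- conditionStatistics(sim$experiment)
    fit <- fitMotifs(cs$t, cs$df, K = 4, seed = 5, nRestarts = 3)
    sg <- assignSignatures(fit)
    # permute the motifs: labels per gene must not change
    perm <- c(3, 1, 4, 2)
    fit2 <- new("MotifFit", K = 4L, pi = fit@pi[perm],
                Q = fit@Q[perm, ], v = fit@v,
                genePosterior = fit@genePosterior[, perm],
                dePosterior = fit@dePosterior, loglik = fit@loglik,
                bic = fit@bic, aic = fit@aic,
                loglikTrace = fit@loglikTrace,
                conditions = fit@conditions, converged = TRUE)
    sg2 <- assignSignatures(fit2)
    expect_identical(sg$labels, sg2$labels)
})

test_that("a motif matching no template is labelled other", {
    qrow <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)  # only 2 of 4 drugs at 3h
    names(qrow) <- c("DOX.3h", "EPI.3h", "DNR.3h", "MTX.3h", "TRZ.3h",
                     "DOX.24h", "EPI.24h", "DNR.24h", "MTX.24h",
                     "TRZ.24h")
    expect_equal(
        top2tox:::.labelMotif(qrow,
                              paste(c("DOX", "EPI", "DNR", "MTX"), "3h",
                                    sep = "."),
                              paste(c("DOX", "EPI", "DNR", "MTX"), "24h",
                                    sep = ".")),
        "other")
})

test_that("drug-specific gene selection equals a brute-force filter", {
    genes <- paste0("g", 1:200)
    set.seed(12)
    mkTab <- function() data.frame(gene = genes,
                                   p_adj = runif(200, 0, 0.2))
    for (rep in 1:20) {
        tabs <- list(DOX = mkTab(), EPI = mkTab(), DNR = mkTab(),
                     MTX = mkTab())
        got <- drugSpecificGenes(tabs, "DNR")
        want <- genes[tabs$DNR$p_adj < 0.01 & tabs$DOX$p_adj > 0.05 &
                      tabs$EPI$p_adj > 0.05 & tabs$MTX$p_adj > 0.05]
        expect_identical(got, want)
    }
    # explicit boundary cases
    tabs <- list(
        DOX = data.frame(gene = "g", p_adj = 0.005),
        EPI = data.frame(gene = "g", p_adj = 0.5),
        DNR = data.frame(gene = "g", p_adj = 0.8))
    expect_identical(drugSpecificGenes(tabs, "DOX"), "g")
    tabs$EPI$p_adj <- 0.04
    expect_identical(drugSpecificGenes(tabs, "DOX"), character(0))
    expect_error(drugSpecificGenes(tabs, "XXX"), "no")
})
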