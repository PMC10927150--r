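test_that("the 2x2 chi-square matches the textbook computation", {
    # equal proportions: no difference
    eq <- chisqProportions(10, 10, 10, 10)
    expect_equal(eq$p, 1)
    # hand-computed Yates-corrected statistic for (30,70) vs (10,90)
    tab <- matrix(c(30, 70, 10, 90), 2)
    n <- sum(tab)
    exp_ <- outer(rowSums(tab), colSums(tab)) / n
    stat <- sum((abs(tab - exp_) - 0.5)^2 / exp_)
    got <- chisqProportions(30, 70, 10, 90)
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$p, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # transposition symmetry
    sw <- chisqProportions(10, 90, 30, 70)
    expect_equal(sw$statistic, got$statistic)
    expect_equal(sw$p, got$p)
    expect_error(chisqProportions(0, 0, 5, 5), "margin")
})

test_that("category-vs-reference enrichment builds the right table", {
    categ <- paste0("c", 1:50)
    ref <- paste0("r", 1:500)
    # same annotated fraction in both: p = 1
    ann <- c(categ[1:10], ref[1:100])
    same <- enrichmentVsReference(categ, ref, ann)
    expect_equal(same$propCategory, same$propReference)
    expect_equal(same$p, 1)
    # maximal enrichment
    extreme <- enrichmentVsReference(categ, ref, categ)
    expect_lt(extreme$p, 1e-20)
    expect_equal(extreme$propCategory, 1)
    expect_equal(extreme$propReference, 0)
    expect_error(enrichmentVsReference(c("a", "b"), c("b", "c"), "a"),
                 "disjoint")
})

test_that("planted over-representation is detected with high power", {
    set.seed(31)
    hits <- 0
    for (i in 1:40) {
        universe <- paste0("g", 1:5000)
        ann <- sample(universe, 500)
        # category enriched threefold for the annotation
        inAnn <- sample(ann, 150)
        outAnn <- sample(setdiff(universe, ann), 350)
        categ <- c(inAnn, outAnn)
        ref <- setdiff(universe, categ)
        res <- enrichmentVsReference(categ, ref, ann)
        if (res$p < 0.05) hits <- hits + 1
    }
    expect_gte(hits / 40, 0.95)
})

test_that("Fisher over-representation equals the hypergeometric tail", {
    set.seed(32)
    universe <- paste0("g", 1:60)
    for (i in 1:200) {
        nq <- sample(5:30, 1)
        ns <- sample(5:30, 1)
        query <- sample(universe, nq)
        sets <- list(S = sample(universe, ns))
        res <- overrepresentationTest(query, universe, sets)
        a <- length(intersect(query, sets$S))
        b <- nq - a
        c_ <- ns - a
        d <- 60 - a - b - c_
        expect_equal(res$p, oracleHyper(a, b, c_, d), tolerance = 1e-12)
    }
    # query equal to one set: that set minimises p
    sets <- list(A = universe[1:10], B = universe[11:30],
                 C = universe[31:60])
    res <- overrepresentationTest(universe[1:10], universe, sets)
    expect_equal(res$set[which.min(res$p)], "A")
    expect_warning(
        overrepresentationTest(universe[1:5], universe,
                               list(empty = c("zz1", "zz2"),
                                    ok = universe[1:8])),
        "skipped")
})

test_that("null queries produce calibrated over-representation p-values", {
    set.seed(33)
    universe <- paste0("g", 1:2000)
    sets <- lapply(1:50, function(i) sample(universe, 100))
    names(sets) <- paste0("S", 1:50)
    ps <- numeric(0)
    for (i in 1:20) {
        query <- sample(universe, 200)
        res <- overrepresentationTest(query, universe, sets)
        ps <- c(ps, res$p)
    }
    # one-sided discrete test: at most ~5% of null sets significant
    expect_lt(mean(ps < 0.05), 0.08)
})

test_that("strand-aware TSS extraction follows the BED convention", {
    genes <- data.frame(chrom = c("chr1", "chr1"),
                        start = c(100L, 200L), end = c(150L, 260L),
                        gene_id = c("plus", "minus"),
                        strand = c("+", "-"))
    tss <- tssFromIntervals(genes)
    expect_equal(tss$tss, c(100L, 259L))
    genes$strand[1] <- "*"
    expect_error(tssFromIntervals(genes), "strand")
})

test_that("nearest TSS annotation matches the stated rules", {
    tss <- data.frame(chrom = "chr1", tss = c(1000L, 3000L),
                      gene_id = c("geneB", "geneA"))
    snps <- data.frame(chrom = "chr1", pos = c(1000L, 2000L, 2900L),
                       id = c("s1", "s2", "s3"))
    out <- nearestTss(snps, tss)
    expect_equal(out$gene_id, c("geneB", "geneA", "geneA"))
    expect_equal(out$distance, c(0, 1000, 100))
    # s2 is equidistant: the lexicographically smaller gene wins
    # chromosome with no TSS: unannotated
    out2 <- nearestTss(data.frame(chrom = "chrX", pos = 5L, id = "sX"),
                       tss)
    expect_true(is.na(out2$gene_id))
})

test_that("nearest TSS equals the all-pairs oracle on random inputs", {
    set.seed(34)
    for (i in 1:20) {
        tss <- data.frame(
            chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
            tss = sample.int(1e5, 50),
            gene_id = paste0("gene", sample(100, 50)))
        snps <- data.frame(
            chrom = sample(c("chr1", "chr2", "chr3"), 20,
                           replace = TRUE),
            pos = sample.int(1e5, 20),
            id = paste0("rs", 1:20))
        got <- nearestTss(snps, tss)
        want <- oracleNearestTss(snps, tss)
        expect_equal(got$gene_id, want$gene_id)
        expect_equal(got$distance, want$distance)
    }
})

test_that("locus annotation unions sources and filters to expressed genes", {
    tables <- list(
        DOX.24h = data.frame(gene = c("a", "b", "c"),
                             log2fc = c(2, -1, 0.2),
                             p_adj = c(0.001, 0.5, 0.9)),
        DOX.3h = data.frame(gene = c("a", "b", "c"),
                            log2fc = c(0.1, 0, 0),
                            p_adj = c(0.8, 0.9, 0.7)))
    sig <- c(a = "LR", b = "NR", c = "NR")
    out <- annotateGwasGenes(snpGenes = c("a", "zz"),
                             eqtlGenes = c("a", "b"),
                             expressedUniverse = c("a", "b", "c"),
                             tables = tables, signatures = sig,
                             geneSets = list(chromreg = c("b")))
    expect_equal(sort(out$gene), c("a", "b"))      # zz not expressed
    expect_equal(out$source[out$gene == "a"], "closest+eqtl")
    expect_true(out$de_DOX.24h[out$gene == "a"])
    expect_false(out$de_DOX.3h[out$gene == "a"])
    expect_equal(out$signature[out$gene == "a"], "LR")
    expect_true(out$in_chromreg[out$gene == "b"])
})

test_that("a planted late-response locus gene is reported as such", {
    sim <- simulateCounts(simDesign(nGenes = 1200, seed = 91))
    de <- deAnalysis(sim$experiment)
    truth <- sim$truth
    lr <- names(truth$motif)[truth$motif == "LR" &
                             abs(truth$log2fc[, "DOX.24h"]) > 1.5]
    lr <- intersect(lr, de$expressed)[1]
    out <- annotateGwasGenes(snpGenes = lr, eqtlGenes = character(0),
                             expressedUniverse = de$expressed,
                             tables = de$tables)
    expect_true(out[[paste0("de_", "DOX.24h")]])
    expect_false(out[[paste0("de_", "TRZ.24h")]])
})
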