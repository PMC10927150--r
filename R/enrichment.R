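#' Chi-square test of proportions on a 2x2 table
#'
#' Tests whether the proportion of "in"-annotation genes differs between
#' two categories, with Yates continuity correction by default.
#'
#' @param aIn,aOut counts in/out of the annotation for category A.
#' @param bIn,bOut counts in/out of the annotation for category B.
#' @param correct apply Yates continuity correction (default TRUE).
#' @return list with `statistic`, `p`, `table`.
#' @export
chisqProportions <- function(aIn, aOut, bIn, bOut, correct = TRUE) {
    tab <- matrix(c(aIn, aOut, bIn, bOut), nrow = 2,
                  dimnames = list(c("in", "out"), c("A", "B")))
    if (any(tab < 0)) stop("counts must be non-negative")
    rs <- rowSums(tab); cs <- colSums(tab)
    if (any(rs == 0))
        stop("zero margin: annotation row '",
             names(rs)[rs == 0][1], "' is empty")
    if (any(cs == 0))
        stop("zero margin: category column '",
             names(cs)[cs == 0][1], "' is empty")
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Annotation enrichment of a category against a reference set
#'
#' Builds the 2x2 contingency table of annotation membership for a
#' category gene set versus a disjoint reference set and applies the
#' chi-square test of proportions.
#'
#' @param categoryGenes,referenceGenes disjoint character vectors.
#' @param annotation character vector of annotated genes (e.g. a curated
#'   regulator list).
#' @param correct Yates correction flag.
#' @return list with `statistic`, `p`, `negLog10P`, `propCategory`,
#'   `propReference`, `table`.
#' @export
enrichmentVsReference <- function(categoryGenes, referenceGenes,
                                  annotation, correct = TRUE) {
    categoryGenes <- unique(categoryGenes)
    referenceGenes <- unique(referenceGenes)
    if (length(intersect(categoryGenes, referenceGenes)))
        stop("category and reference gene sets must be disjoint")
    if (!length(categoryGenes) || !length(referenceGenes))
        stop("empty gene set")
    aIn <- sum(categoryGenes %in% annotation)
    bIn <- sum(referenceGenes %in% annotation)
    res <- chisqProportions(aIn, length(categoryGenes) - aIn,
                            bIn, length(referenceGenes) - bIn,
                            correct = correct)
    c(res, list(negLog10P = -log10(res$p),
                propCategory = aIn / length(categoryGenes),
                propReference = bIn / length(referenceGenes)))
}

#' Over-representation test over a gene-set collection
#'
#' One-sided Fisher exact test of each gene set against the query within
#' the universe, BH-adjusted across sets. Sets with no members in the
#' universe are skipped with a warning.
#'
#' @param queryGenes character vector, subset of `universe`.
#' @param universe background gene identifiers.
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param fdr significance threshold recorded in the output.
#' @return data.frame `set`, `nSet`, `nOverlap`, `oddsRatio`, `p`,
#'   `p_adj`, `significant`.
#' @export
overrepresentationTest <- function(queryGenes, universe, geneSets,
                                   fdr = 0.05) {
    queryGenes <- unique(queryGenes); universe <- unique(universe)
    if (!all(queryGenes %in% universe))
        stop("query genes must be a subset of the universe")
    rows <- list()
    for (nm in names(geneSets)) {
        set <- intersect(unique(geneSets[[nm]]), universe)
        if (!length(set)) {
            warning("gene set '", nm, "' has no universe members; skipped")
            next
        }
        a <- length(intersect(queryGenes, set))
        b <- length(queryGenes) - a
        c_ <- length(set) - a
        d <- length(universe) - a - b - c_
        ft <- fisher.test(matrix(c(a, b, c_, d), 2), alternative = "greater")
        rows[[nm]] <- data.frame(set = nm, nSet = length(set),
                                 nOverlap = a,
                                 oddsRatio = unname(ft$estimate),
                                 p = ft$p.value)
    }
    if (!length(rows)) stop("no testable gene sets")
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < fdr
    rownames(out) <- NULL
    out
}

#' Strand-aware transcription start sites from gene intervals
#'
#' BED-style 0-based, half-open intervals: the TSS of a plus-strand gene
#' is the interval start; of a minus-strand gene the interval end minus
#' one.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`,
#'   `strand`.
#' @return data.frame `chrom`, `tss`, `strand`, `gene_id`.
#' @export
tssFromIntervals <- function(genes) {
    if (!all(genes$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    data.frame(chrom = genes$chrom,
               tss = ifelse(genes$strand == "+", genes$start,
                            genes$end - 1L),
               strand = genes$strand,
               gene_id = genes$gene_id)
}

#' Nearest transcription start site for each SNP
#'
#' For every SNP, the gene whose strand-aware TSS on the same chromosome
#' minimises the unsigned distance; exact distance ties are broken by
#' the lexicographically smaller gene identifier. SNPs on chromosomes
#' without any TSS are returned unannotated (`NA`) and counted.
#'
#' @param snps data.frame `chrom`, `pos` (0-based), `id`.
#' @param tss data.frame `chrom`, `tss`, `gene_id` (see
#'   [tssFromIntervals()]).
#' @return data.frame `id`, `chrom`, `pos`, `gene_id`, `distance`.
#' @export
nearestTss <- function(snps, tss) {
    out <- data.frame(id = snps$id, chrom = snps$chrom, pos = snps$pos,
                      gene_id = NA_character_, distance = NA_real_,
                      stringsAsFactors = FALSE)
    for (ch in unique(snps$chrom)) {
        si <- which(snps$chrom == ch)
        tj <- which(tss$chrom == ch)
        if (!length(tj)) next
        # sort TSS by position, then gene_id so the first minimum found
        # at equal distance is the lexicographic winner
        tpos <- tss$tss[tj]; tgene <- as.character(tss$gene_id[tj])
        o <- order(tpos, tgene)
        tpos <- tpos[o]; tgene <- tgene[o]
        for (i in si) {
            d <- abs(snps$pos[i] - tpos)
            dmin <- min(d)
            cand <- tgene[d == dmin]
            out$gene_id[i] <- min(cand)
            out$distance[i] <- dmin
        }
    }
    out
}

#' Annotate candidate toxicity-locus genes with response data
#'
#' Combines nearest-TSS genes and user-supplied eQTL genes, filters to
#' the expressed universe, de-duplicates, and annotates each gene with
#' its per-contrast log2 fold change, DE flags at the chosen FDR, its
#' response-signature label, and membership in each supplied gene set.
#'
#' @param snpGenes character vector of nearest-TSS genes (e.g.
#'   `nearestTss(...)$gene_id`).
#' @param eqtlGenes character vector of eQTL-derived genes.
#' @param expressedUniverse expressed gene identifiers.
#' @param tables named list of contrast tables.
#' @param signatures per-gene signature labels (named character), e.g.
#'   from [assignSignatures()]; optional.
#' @param geneSets named list of annotation gene sets; optional.
#' @param fdr DE flag threshold (default 0.05).
#' @return data.frame, one row per locus gene, with `gene`, `source`,
#'   `signature`, one `lfc_*` and `de_*` column per contrast, and one
#'   `in_*` column per gene set.
#' @export
annotateGwasGenes <- function(snpGenes, eqtlGenes, expressedUniverse,
                              tables, signatures = NULL,
                              geneSets = NULL, fdr = 0.05) {
    snpGenes <- unique(snpGenes[!is.na(snpGenes)])
    eqtlGenes <- unique(eqtlGenes[!is.na(eqtlGenes)])
    all <- union(snpGenes, eqtlGenes)
    all <- all[all %in% expressedUniverse]
    if (!length(all))
        return(data.frame(gene = character(), source = character()))
    src <- vapply(all, function(g) {
        paste(c("closest"[g %in% snpGenes], "eqtl"[g %in% eqtlGenes]),
              collapse = "+")
    }, character(1))
    out <- data.frame(gene = all, source = src, row.names = NULL)
    out$signature <- if (!is.null(signatures))
        unname(signatures[all]) else NA_character_
    for (cn in names(tables)) {
        tb <- tables[[cn]]
        idx <- match(all, tb$gene)
        out[[paste0("lfc_", cn)]] <- tb$log2fc[idx]
        out[[paste0("de_", cn)]] <- tb$p_adj[idx] < fdr
    }
    for (sn in names(geneSets))
        out[[paste0("in_", sn)]] <- all %in% geneSets[[sn]]
    out
}
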