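#' Log2 counts per million
#'
#' `log2((count + 0.5) / (libSize * normFactor + 1) * 1e6)`, the
#' pseudo-count convention of the precision-weight transform.
#'
#' @param counts gene x sample count matrix.
#' @param libSizes per-sample library sizes; default column sums.
#' @param normFactors per-sample normalisation factors; default 1.
#' @return matrix of log2 cpm values.
#' @export
log2Cpm <- function(counts, libSizes = colSums(counts),
                    normFactors = rep(1, ncol(counts))) {
    if (any(libSizes <= 0)) stop("library sizes must be positive")
    eff <- libSizes * normFactors
    t(log2(t(counts + 0.5) / (eff + 1) * 1e6))
}

#' Expression filter
#'
#' Keeps genes whose mean log2 cpm across samples is at least 0; genes
#' with mean below 0 are treated as unexpressed.
#'
#' @param logcpm gene x sample log2 cpm matrix.
#' @return logical vector (one entry per gene) of retained genes.
#' @export
filterExpressed <- function(logcpm) {
    if (!nrow(logcpm)) stop("empty matrix")
    rowMeans(logcpm) >= 0
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Between-sample scaling factors per Robinson-Oshlack: log-ratios to a
#' reference sample (the one whose upper quartile is closest to the mean
#' upper quartile) are doubly trimmed (30% by M, 5% by A) and averaged
#' with precision weights; factors are rescaled to multiply to 1.
#' Delegates to the standard edgeR implementation.
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of normalisation factors.
#' @export
tmmFactors <- function(counts) {
    if (ncol(counts) < 2) stop("need at least 2 samples")
    dge <- edgeR::DGEList(counts = counts)
    dge <- edgeR::calcNormFactors(dge, method = "TMM")
    setNames(dge$samples$norm.factors, colnames(counts))
}

#' Precision weights from the mean-variance trend
#'
#' Fits gene-wise linear models, smooths sqrt(residual SD) against
#' average log-count with lowess (span 0.5) and converts the predicted
#' standard deviation at each observation's fitted log-count into an
#' inverse-variance weight (the voom transform).
#'
#' @param counts gene x sample counts (already filtered).
#' @param design design matrix (full rank).
#' @param libSizes,normFactors per-sample library sizes and norm factors.
#' @param span lowess span, default 0.5.
#' @return list with `logcpm` (the log2 cpm matrix) and `weights`
#'   (matching matrix of positive observation weights).
#' @export
precisionWeights <- function(counts, design,
                             libSizes = colSums(counts),
                             normFactors = rep(1, ncol(counts)),
                             span = 0.5) {
    if (qr(design)$rank < ncol(design)) stop("design must be full rank")
    if (nrow(counts) - 0 <= 0) stop("empty count matrix")
    if (ncol(counts) <= ncol(design))
        stop("no residual degrees of freedom")
    v <- limma::voom(counts, design,
                     lib.size = libSizes * normFactors, span = span)
    list(logcpm = v$E, weights = v$weights)
}

#' Moderated differential-expression fit
#'
#' Weighted least squares per gene followed by empirical-Bayes variance
#' moderation and BH adjustment within each contrast (the limma
#' pipeline). Residual variances are shrunk towards a common prior with
#' method-of-moments prior df, and the moderated t uses the total
#' degrees of freedom.
#'
#' @param logcpm gene x sample log2 cpm matrix.
#' @param weights matching observation-weight matrix (or NULL).
#' @param design design matrix.
#' @param contrasts contrast matrix (coefficients x contrasts) as from
#'   [limma::makeContrasts], or a character vector of coefficient names.
#' @return named list of contrast tables, each a data.frame with
#'   `gene`, `log2fc`, `moderated_t`, `p`, `p_adj`, `avg_log2cpm`,
#'   `df_total`; plus attribute `"s2_prior"`/`"df_prior"`.
#' @export
moderatedFit <- function(logcpm, weights, design, contrasts) {
    fit <- limma::lmFit(logcpm, design, weights = weights)
    if (is.character(contrasts)) {
        cm <- matrix(0, ncol(design), length(contrasts),
                     dimnames = list(colnames(design), contrasts))
        for (cc in contrasts) cm[cc, cc] <- 1
        contrasts <- cm
    }
    fit2 <- limma::contrasts.fit(fit, contrasts)
    fit2 <- limma::eBayes(fit2)
    if (any(fit2$df.residual <= 0)) stop("zero residual degrees of freedom")
    out <- lapply(colnames(contrasts), function(cn) {
        p <- fit2$p.value[, cn]
        data.frame(gene = rownames(logcpm),
                   log2fc = fit2$coefficients[, cn],
                   moderated_t = fit2$t[, cn],
                   p = p,
                   p_adj = p.adjust(p, method = "BH"),
                   avg_log2cpm = fit2$Amean,
                   df_total = fit2$df.total,
                   row.names = NULL)
    })
    names(out) <- colnames(contrasts)
    attr(out, "s2_prior") <- fit2$s2.prior
    attr(out, "df_prior") <- fit2$df.prior
    attr(out, "s2_post") <- fit2$s2.post
    attr(out, "sigma") <- fit2$sigma
    out
}

#' Full differential-expression analysis of a count study
#'
#' Runs the expression pipeline end to end: log2 cpm + mean >= 0 filter,
#' TMM factors, precision weights under a treatment-by-time group model
#' with the donor as an additive blocking factor, moderated fits, and
#' one drug-vs-vehicle contrast per (drug, timepoint).
#'
#' @param experiment a [CardioExperiment-class].
#' @param fdr unused here; kept so callers can carry their threshold.
#' @return list with `tables` (named list of contrast tables,
#'   `<drug>.<time>`), `expressed` (gene names kept), `normFactors`,
#'   `design`, and `logcpm`.
#' @export
deAnalysis <- function(experiment, fdr = 0.05) {
    cts <- counts(experiment)
    keep <- filterExpressed(log2Cpm(cts))
    cts <- cts[keep, , drop = FALSE]
    nf <- tmmFactors(cts)
    grp <- factor(paste(treatments(experiment), timepoints(experiment),
                        sep = "."))
    indiv <- factor(individuals(experiment))
    design <- stats::model.matrix(~ 0 + grp + indiv)
    colnames(design) <- sub("^grp", "", colnames(design))
    pw <- precisionWeights(cts, design, normFactors = nf)
    drugs <- setdiff(unique(treatments(experiment)), "VEH")
    times <- unique(timepoints(experiment))
    pairs <- expand.grid(drug = drugs, time = times,
                         stringsAsFactors = FALSE)
    cm <- matrix(0, ncol(design), nrow(pairs),
                 dimnames = list(colnames(design),
                                 paste(pairs$drug, pairs$time,
                                       sep = ".")))
    for (i in seq_len(nrow(pairs))) {
        cm[paste(pairs$drug[i], pairs$time[i], sep = "."), i] <- 1
        cm[paste("VEH", pairs$time[i], sep = "."), i] <- -1
    }
    tables <- moderatedFit(pw$logcpm, pw$weights, design, cm)
    list(tables = tables, expressed = rownames(cts), normFactors = nf,
         design = design, logcpm = pw$logcpm)
}

#' Correlation structure of drug responses
#'
#' Pearson correlation between the per-gene log2 fold-change vectors of
#' all contrast pairs, followed by average-linkage hierarchical
#' clustering on `1 - r`.
#'
#' @param tables named list of contrast tables sharing a gene universe.
#' @return list with `correlation` (symmetric matrix), `order`
#'   (dendrogram leaf order) and `hclust`.
#' @export
responseCorrelationMatrix <- function(tables) {
    genes <- tables[[1]]$gene
    lfc <- vapply(tables, function(tb) {
        if (!identical(tb$gene, genes))
            stop("contrast tables do not share a gene universe")
        tb$log2fc
    }, numeric(length(genes)))
    keep <- apply(lfc, 2, sd) > 0
    if (!all(keep)) {
        warning("dropping constant log2fc group(s): ",
                paste(colnames(lfc)[!keep], collapse = ", "))
        lfc <- lfc[, keep, drop = FALSE]
    }
    r <- cor(lfc, method = "pearson")
    hc <- hclust(as.dist(1 - r), method = "average")
    list(correlation = r, order = hc$order, hclust = hc)
}
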