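#' @import methods
#' @importFrom stats median quantile rnorm runif rnbinom rexp dt pf pt
#'   p.adjust cor cor.test sd var prcomp hclust as.dist optimize setNames
#'   fisher.test chisq.test wilcox.test t.test lowess approx coef resid
#'   complete.cases aggregate
#' @importFrom utils read.delim write.csv read.csv write.table head tail
#' @importFrom stats model.matrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CardioExperiment: counts plus the drug-treatment design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' `colData` is guaranteed to carry the three design variables of a
#' multi-donor drug-response study: `individual`, `treatment` and `time`.
#' The first assay (`"counts"`) holds non-negative integer read counts
#' with genes as rows and samples as columns.
#'
#' @slot . inherits all slots from `SummarizedExperiment`.
#' @export
setClass("CardioExperiment", contains = "SummarizedExperiment")

setValidity("CardioExperiment", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("individual", "treatment", "time")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData must contain: ",
                             paste(miss, collapse = ", ")))
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "an assay named 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (ncol(cts) > 0 && any(colSums(cts) <= 0))
            msg <- c(msg, "every sample must have a positive column sum")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a CardioExperiment
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param samples data.frame with one row per column of `counts` and columns
#'   `individual`, `treatment`, `time`. Row names (or a `sample_id` column)
#'   must match `colnames(counts)`.
#' @return A [CardioExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(12, 40), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sam <- data.frame(sample_id = paste0("s", 1:4),
#'                   individual = c("i1", "i1", "i2", "i2"),
#'                   treatment  = c("DOX", "VEH", "DOX", "VEH"),
#'                   time = "24h")
#' ce <- CardioExperiment(cts, sam)
#' @export
CardioExperiment <- function(counts, samples) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' needs row (gene) and column (sample) names")
    if ("sample_id" %in% colnames(samples))
        rownames(samples) <- samples$sample_id
    samples <- samples[colnames(counts), , drop = FALSE]
    if (anyNA(samples$individual))
        stop("sample sheet does not cover all count columns")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays  = list(counts = counts),
        colData = S4Vectors::DataFrame(samples))
    new("CardioExperiment", se)
}

#' @describeIn CardioExperiment the raw count matrix
#' @param object,x a `CardioExperiment`
#' @export
counts <- function(object) SummarizedExperiment::assay(object, "counts")

#' @describeIn CardioExperiment per-sample treatment labels
#' @export
treatments <- function(object) {
    as.character(SummarizedExperiment::colData(object)$treatment)
}

#' @describeIn CardioExperiment per-sample donor labels
#' @export
individuals <- function(object) {
    as.character(SummarizedExperiment::colData(object)$individual)
}

#' @describeIn CardioExperiment per-sample timepoint labels
#' @export
timepoints <- function(object) {
    as.character(SummarizedExperiment::colData(object)$time)
}

#' Simulation design for the synthetic study
#'
#' Captures everything needed to generate a negative-binomial count study
#' with planted response motifs: the donor panel, the drug panel, the
#' timepoints, the motif structure over drug-by-time contrasts, and the
#' noise model.
#'
#' @slot nIndividuals number of donors.
#' @slot treatments treatment labels; must contain `"VEH"`.
#' @slot timepoints timepoint labels.
#' @slot nGenes number of genes.
#' @slot motifSpec data.frame with columns `label`, `proportion` and one
#'   indicator column per contrast (`<drug>.<time>`) giving the planted
#'   0/1 differential-expression pattern of the motif.
#' @slot dispersion negative-binomial dispersion (scalar).
#' @slot libSizeRange min/max library size (reads).
#' @slot individualSd log2-scale SD of per-donor, per-gene effects.
#' @slot varianceInflation named numeric, `"<drug>.<time>"` -> multiplier
#'   applied to the donor-effect SD in that group.
#' @slot lfcLocation,lfcScale planted |log2FC| is
#'   `abs(rnorm(1, 0, lfcScale)) + lfcLocation` with a random sign.
#' @slot baselineMean,baselineSd lognormal (log2 cpm) baseline parameters.
#' @slot seed RNG seed; a fixed seed gives byte-identical output.
#' @export
setClass("SimDesign", representation(
    nIndividuals = "integer",
    treatments = "character",
    timepoints = "character",
    nGenes = "integer",
    motifSpec = "data.frame",
    dispersion = "numeric",
    libSizeRange = "numeric",
    individualSd = "numeric",
    varianceInflation = "numeric",
    lfcLocation = "numeric",
    lfcScale = "numeric",
    baselineMean = "numeric",
    baselineSd = "numeric",
    seed = "integer"))

setValidity("SimDesign", function(object) {
    msg <- character()
    if (object@nGenes <= 0L) msg <- c(msg, "nGenes must be positive")
    if (length(object@treatments) == 0L)
        msg <- c(msg, "treatments must be non-empty")
    if (!"VEH" %in% object@treatments)
        msg <- c(msg, "treatments must include the vehicle 'VEH'")
    if (object@nIndividuals < 1L)
        msg <- c(msg, "need at least one individual")
    if (any(object@dispersion <= 0)) msg <- c(msg, "dispersion must be > 0")
    ms <- object@motifSpec
    if (abs(sum(ms$proportion) - 1) > 1e-8)
        msg <- c(msg, "motif proportions must sum to 1")
    qcols <- setdiff(colnames(ms), c("label", "proportion"))
    if (length(qcols)) {
        qv <- as.matrix(ms[, qcols, drop = FALSE])
        if (!all(qv %in% c(0, 1)))
            msg <- c(msg, "motif q-vector entries must be 0 or 1")
    }
    if (any(object@varianceInflation <= 0))
        msg <- c(msg, "variance inflation factors must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimDesign", function(object) {
    cat("SimDesign:", object@nGenes, "genes,",
        object@nIndividuals, "individuals,",
        length(object@treatments), "treatments x",
        length(object@timepoints), "timepoints\n")
    cat("  motifs:", paste(sprintf("%s (%.2f)", object@motifSpec$label,
                                   object@motifSpec$proportion),
                           collapse = ", "), "\n")
    infl <- object@varianceInflation[object@varianceInflation != 1]
    if (length(infl))
        cat("  variance inflation:",
            paste(names(infl), infl, sep = "=", collapse = ", "), "\n")
    cat("  seed:", object@seed, "\n")
})

#' Fitted dose-response curve with fixed upper asymptote
#'
#' Parameters of `f(x) = c + (1 - c) / (1 + exp(b * (log(x) - log(e))))`
#' (the four-parameter log-logistic with the upper asymptote pinned at 1)
#' together with the derived LD50, the concentration at which fitted
#' viability equals 0.5 on the absolute scale. The LD50 is `NA` when the
#' fitted curve never crosses 0.5 (lower asymptote `c >= 0.5` or a
#' degenerate flat fit).
#'
#' @slot b slope (positive for decreasing viability).
#' @slot c lower asymptote, in `[0, 1)`.
#' @slot d upper asymptote, fixed at 1.
#' @slot e inflection concentration (same units as the input doses).
#' @slot ld50 LD50 (`NA_real_` when undefined).
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical; `FALSE` flags a degenerate/failed fit.
#' @slot diagnostics character notes from the fitting routine.
#' @export
setClass("DoseResponseFit", representation(
    b = "numeric", c = "numeric", d = "numeric", e = "numeric",
    ld50 = "numeric", rss = "numeric", converged = "logical",
    diagnostics = "character"))

setValidity("DoseResponseFit", function(object) {
    msg <- character()
    if (!identical(object@d, 1)) msg <- c(msg, "upper asymptote d must be 1")
    if (object@converged) {
        if (!is.na(object@c) && (object@c < 0 || object@c >= 1))
            msg <- c(msg, "lower asymptote c must lie in [0, 1)")
        if (!is.na(object@e) && object@e <= 0)
            msg <- c(msg, "inflection e must be positive")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "DoseResponseFit", function(object) {
    if (object@converged) {
        cat(sprintf("DoseResponseFit: b = %.4g, c = %.4g, d = 1, e = %.4g\n",
                    object@b, object@c, object@e))
        cat(sprintf("  LD50 = %s, RSS = %.4g\n",
                    if (is.na(object@ld50)) "undefined"
                    else sprintf("%.4g", object@ld50), object@rss))
    } else {
        cat("DoseResponseFit: degenerate/failed fit (",
            paste(object@diagnostics, collapse = "; "), ")\n", sep = "")
    }
})

#' Fitted correlation-motif model
#'
#' The result of jointly modelling the moderated test statistics of all
#' drug-by-time contrasts as a mixture over motifs, where each motif is a
#' vector of per-contrast differential-expression probabilities.
#'
#' @slot K number of motifs.
#' @slot pi motif frequencies (simplex of length K).
#' @slot Q K x D matrix of per-motif, per-contrast DE probabilities.
#' @slot v length-D variance-inflation parameters of the alternative
#'   (differentially expressed) t-density.
#' @slot genePosterior G x K posterior motif-membership probabilities.
#' @slot dePosterior G x D posterior per-gene, per-contrast DE
#'   probabilities.
#' @slot loglik final log-likelihood.
#' @slot bic,aic model-selection scores.
#' @slot loglikTrace per-iteration log-likelihood of the winning EM run.
#' @slot conditions contrast labels (columns of Q).
#' @slot converged logical.
#' @export
setClass("MotifFit", representation(
    K = "integer", pi = "numeric", Q = "matrix", v = "numeric",
    genePosterior = "matrix", dePosterior = "matrix",
    loglik = "numeric", bic = "numeric", aic = "numeric",
    loglikTrace = "numeric", conditions = "character",
    converged = "logical"))

setValidity("MotifFit", function(object) {
    msg <- character()
    if (abs(sum(object@pi) - 1) > 1e-8)
        msg <- c(msg, "motif frequencies must sum to 1")
    if (any(object@Q < -1e-12 | object@Q > 1 + 1e-12))
        msg <- c(msg, "Q entries must lie in [0, 1]")
    if (nrow(object@genePosterior) > 0) {
        rs <- rowSums(object@genePosterior)
        if (max(abs(rs - 1)) > 1e-6)
            msg <- c(msg, "gene posterior rows must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MotifFit", function(object) {
    cat(sprintf(
        "MotifFit: K = %d motifs over %d contrasts, %d genes\n",
        object@K, ncol(object@Q), nrow(object@genePosterior)))
    cat(sprintf("  loglik = %.2f, BIC = %.2f, AIC = %.2f%s\n",
                object@loglik, object@bic, object@aic,
                if (object@converged) "" else " (not converged)"))
    cat("  pi:", paste(sprintf("%.3f", object@pi), collapse = " "), "\n")
})

#' @describeIn MotifFit motif frequencies
#' @param object a `MotifFit`
#' @export
motifFrequencies <- function(object) object@pi

#' @describeIn MotifFit the K x D matrix of DE probabilities
#' @export
motifPatterns <- function(object) object@Q

#' @describeIn MotifFit G x K posterior motif memberships
#' @export
genePosterior <- function(object) object@genePosterior

#' @describeIn MotifFit G x D posterior DE probabilities
#' @export
dePosterior <- function(object) object@dePosterior

#' @describeIn MotifFit named vector of model scores
#' @export
modelScores <- function(object) {
    c(loglik = object@loglik, bic = object@bic, aic = object@aic)
}
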