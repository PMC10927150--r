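#' Default planted motif structure
#'
#' Builds the motif specification used by [simDesign()]: four response
#' motifs over the drug-by-time contrast space. Non-response (NR) genes
#' are silent everywhere; late-response (LR) genes respond to the four
#' TOP2 inhibitors at 24 h only; early-acute (EAR) genes at 3 h only;
#' early-sustained (ESR) genes at both timepoints. TRZ never responds.
#'
#' @param drugs non-vehicle treatment labels.
#' @param timepoints timepoint labels, early first.
#' @param top2i subset of `drugs` that inhibit TOP2.
#' @param proportions named proportions for NR, LR, EAR, ESR (sum to 1).
#' @return data.frame with `label`, `proportion` and one 0/1 column per
#'   contrast named `<drug>.<time>`.
#' @export
defaultMotifSpec <- function(drugs = c("DOX", "EPI", "DNR", "MTX", "TRZ"),
                             timepoints = c("3h", "24h"),
                             top2i = c("DOX", "EPI", "DNR", "MTX"),
                             proportions = c(NR = 0.50, LR = 0.35,
                                             EAR = 0.08, ESR = 0.07)) {
    contrasts <- as.vector(outer(drugs, timepoints, paste, sep = "."))
    early <- paste(top2i, timepoints[1], sep = ".")
    late  <- paste(top2i, timepoints[2], sep = ".")
    q <- matrix(0L, 4, length(contrasts),
                dimnames = list(c("NR", "LR", "EAR", "ESR"), contrasts))
    q["LR",  late]  <- 1L
    q["EAR", early] <- 1L
    q["ESR", c(early, late)] <- 1L
    out <- data.frame(label = rownames(q),
                      proportion = as.numeric(proportions[rownames(q)]),
                      q, check.names = FALSE)
    rownames(out) <- NULL
    out
}

#' Specify a synthetic count study
#'
#' The defaults emulate the study design the package targets: six donors,
#' five drugs plus vehicle, two timepoints, four planted response motifs,
#' and inflated donor-to-donor variability in the anthracycline groups at
#' 24 h.
#'
#' @param nIndividuals number of donors (default 6).
#' @param treatments treatment labels incl. `"VEH"`.
#' @param timepoints timepoint labels.
#' @param nGenes number of genes.
#' @param motifSpec see [defaultMotifSpec()].
#' @param dispersion NB dispersion (default 0.05), the residual
#'   technical/within-donor noise left once donor effects are modelled
#'   explicitly.
#' @param libSizeRange library-size range in reads (default 2-4 M;
#'   a desk-scale stand-in for tens of millions of reads).
#' @param individualSd log2 SD of donor effects (default 0.3).
#' @param varianceInflation named multipliers (`"<drug>.<time>"`) of the
#'   donor-effect SD; defaults to 1.5 for DOX/EPI/DNR at 24h.
#' @param lfcLocation,lfcScale planted effect-size law
#'   `|N(0, lfcScale)| + lfcLocation`.
#' @param baselineMean,baselineSd baseline log2 cpm distribution.
#' @param seed integer RNG seed.
#' @return A validated [SimDesign-class].
#' @export
simDesign <- function(nIndividuals = 6,
                      treatments = c("DOX", "EPI", "DNR", "MTX", "TRZ",
                                     "VEH"),
                      timepoints = c("3h", "24h"),
                      nGenes = 5000,
                      motifSpec = NULL,
                      dispersion = 0.05,
                      libSizeRange = c(2e6, 4e6),
                      individualSd = 0.3,
                      varianceInflation = NULL,
                      lfcLocation = 0.5,
                      lfcScale = 1,
                      baselineMean = 4,
                      baselineSd = 2,
                      seed = 1L) {
    drugs <- setdiff(treatments, "VEH")
    if (is.null(motifSpec)) {
        if (length(drugs)) {
            top2i <- intersect(c("DOX", "EPI", "DNR", "MTX"), drugs)
            if (!length(top2i)) top2i <- drugs
            motifSpec <- defaultMotifSpec(drugs, timepoints, top2i)
        } else {
            motifSpec <- data.frame(label = "NR", proportion = 1)
        }
    }
    contrasts <- as.vector(outer(drugs, timepoints, paste, sep = "."))
    if (is.null(varianceInflation)) {
        varianceInflation <- setNames(rep(1, length(contrasts)), contrasts)
        ac24 <- paste(intersect(c("DOX", "EPI", "DNR"), drugs),
                      timepoints[length(timepoints)], sep = ".")
        varianceInflation[intersect(ac24, contrasts)] <- 1.5
    }
    new("SimDesign",
        nIndividuals = as.integer(nIndividuals),
        treatments = as.character(treatments),
        timepoints = as.character(timepoints),
        nGenes = as.integer(nGenes),
        motifSpec = motifSpec,
        dispersion = dispersion,
        libSizeRange = libSizeRange,
        individualSd = individualSd,
        varianceInflation = varianceInflation,
        lfcLocation = lfcLocation, lfcScale = lfcScale,
        baselineMean = baselineMean, baselineSd = baselineSd,
        seed = as.integer(seed))
}

#' Simulate a negative-binomial count study with planted motifs
#'
#' Counts are drawn as
#' `NB(mean = cpm_gs / sum(cpm_s) * L_s, size = 1/dispersion)` where the
#' per-gene, per-sample cpm combines a lognormal baseline, a donor effect
#' shared across that donor's samples (scaled by the group's variance
#' inflation factor), and `2^log2FC` for contrasts in which the gene's
#' motif is differentially expressed. Vehicle samples carry no planted
#' effects.
#'
#' @param design a [SimDesign-class].
#' @return list with `experiment` (a [CardioExperiment-class]) and
#'   `truth`, a list holding the per-gene motif label, the G x D true
#'   log2FC matrix, the latent donor-effect matrix and the per-group
#'   variance factors.
#' @examples
#' sim <- simulateCounts(simDesign(nGenes = 200, seed = 7))
#' table(sim$truth$motif)
#' @export
simulateCounts <- function(design) {
    stopifnot(is(design, "SimDesign"))
    validObject(design)
    set.seed(design@seed)
    G <- design@nGenes
    drugs <- setdiff(design@treatments, "VEH")
    contrasts <- as.vector(outer(drugs, design@timepoints, paste,
                                 sep = "."))
    D <- length(contrasts)
    ms <- design@motifSpec
    qcols <- setdiff(colnames(ms), c("label", "proportion"))
    qmat <- as.matrix(ms[, qcols, drop = FALSE])
    if (D && !setequal(qcols, contrasts))
        stop("motifSpec columns do not match the design's contrasts")

    genes <- sprintf("gene_%05d", seq_len(G))
    motif <- sample(ms$label, G, replace = TRUE, prob = ms$proportion)
    lfcMag <- abs(rnorm(G, 0, design@lfcScale)) + design@lfcLocation
    lfcSign <- sample(c(-1, 1), G, replace = TRUE)
    lfcMat <- matrix(0, G, D, dimnames = list(genes, contrasts))
    if (D) {
        idx <- match(motif, ms$label)
        lfcMat <- (lfcMag * lfcSign) * qmat[idx, contrasts, drop = FALSE]
        dimnames(lfcMat) <- list(genes, contrasts)
    }

    baseline <- rnorm(G, design@baselineMean, design@baselineSd)
    inds <- sprintf("ind%d", seq_len(design@nIndividuals))
    donorEff <- matrix(rnorm(G * length(inds), 0, design@individualSd),
                       G, length(inds), dimnames = list(genes, inds))
    # latent donor-response variability, expressed only in groups with
    # inflation > 1 and shared between them, so that variance-inflated
    # groups show correlated per-gene variance changes
    donorResp <- matrix(rnorm(G * length(inds), 0, design@individualSd),
                        G, length(inds), dimnames = list(genes, inds))

    grid <- expand.grid(individual = inds, treatment = design@treatments,
                        time = design@timepoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$sample_id <- paste(grid$individual, grid$treatment, grid$time,
                            sep = "_")
    nS <- nrow(grid)
    libSizes <- runif(nS, design@libSizeRange[1], design@libSizeRange[2])

    cts <- matrix(0L, G, nS, dimnames = list(genes, grid$sample_id))
    for (s in seq_len(nS)) {
        tr <- grid$treatment[s]; tm <- grid$time[s]
        key <- paste(tr, tm, sep = ".")
        k <- if (key %in% names(design@varianceInflation))
            design@varianceInflation[[key]] else 1
        # total donor effect has SD individualSd * k: the baseline donor
        # component plus sqrt(k^2 - 1) of the shared response component
        log2cpm <- baseline + donorEff[, grid$individual[s]] +
            sqrt(max(k^2 - 1, 0)) * donorResp[, grid$individual[s]]
        if (tr != "VEH" && D) log2cpm <- log2cpm + lfcMat[, key]
        rel <- 2^log2cpm
        mu <- rel / sum(rel) * libSizes[s]
        cts[, s] <- rnbinom(G, mu = mu, size = 1 / design@dispersion)
    }
    experiment <- CardioExperiment(
        cts, data.frame(sample_id = grid$sample_id,
                        individual = grid$individual,
                        treatment = grid$treatment,
                        time = grid$time))
    truth <- list(motif = setNames(motif, genes),
                  log2fc = lfcMat,
                  donorEffect = donorEff,
                  donorResponse = donorResp,
                  varianceFactor = design@varianceInflation,
                  libSizes = setNames(libSizes, grid$sample_id))
    list(experiment = experiment, truth = truth)
}

#' Four-parameter log-logistic viability curve
#'
#' `ll4(x) = c + (1 - c) / (1 + exp(b * (log(x) - log(e))))` with the
#' upper asymptote fixed at 1. Positive `b` gives decreasing viability.
#'
#' @param x concentration (same units as `e`); `x > 0`.
#' @param b slope.
#' @param c lower asymptote.
#' @param e inflection dose.
#' @export
ll4 <- function(x, b, c, e) c + (1 - c) / (1 + exp(b * (log(x) - log(e))))

#' Simulate a viability plate read-out
#'
#' Emulates a resazurin-type fluorescence viability plate: quadruplicate
#' drug wells over an 8-point dilution series, matched vehicle wells at
#' each concentration, and cell-free background wells. Raw fluorescence
#' is `background + scale * (truth + noise)` where `truth` is the 4PL
#' viability for drug wells and 1 for vehicle wells.
#'
#' @param trueParams named list, one entry per drug, each `c(b=, c=, e=)`
#'   or `NULL` for a drug with no kill (flat viability 1).
#' @param concentrations dose series in uM (default the 8-point series
#'   50, 10, 5, 1, 0.5, 0.1, 0.05, 0.01).
#' @param nReps wells per (drug, concentration); default 4.
#' @param noiseSd Gaussian noise SD on the viability scale; >= 0.
#' @param background plate background fluorescence (RFLU).
#' @param scale fluorescence units per unit viability.
#' @param nBackgroundWells cell-free wells per plate (default 6).
#' @param seed RNG seed.
#' @return data.frame with columns `plate`, `well`, `drug`, `conc_uM`,
#'   `rflu`, `is_background`.
#' @export
simulateViabilityPlate <- function(trueParams,
                                   concentrations = c(50, 10, 5, 1, 0.5,
                                                      0.1, 0.05, 0.01),
                                   nReps = 4, noiseSd = 0.02,
                                   background = 50, scale = 1000,
                                   nBackgroundWells = 6, seed = 1L) {
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    for (p in trueParams) {
        if (is.null(p)) next
        if (p[["e"]] <= 0) stop("inflection dose e must be positive")
        if (p[["c"]] < 0 || p[["c"]] >= 1)
            stop("lower asymptote c must lie in [0, 1)")
    }
    set.seed(seed)
    rows <- list()
    wellNo <- 0L
    addWells <- function(drug, conc, viab, n, isBg = FALSE) {
        noise <- if (noiseSd > 0) rnorm(n, 0, noiseSd) else rep(0, n)
        rflu <- background + scale * (viab + noise)
        wells <- sprintf("W%03d", wellNo + seq_len(n))
        wellNo <<- wellNo + n
        data.frame(plate = "P1", well = wells, drug = drug,
                   conc_uM = conc, rflu = rflu, is_background = isBg)
    }
    # cell-free background wells carry only the plate background
    rows[[length(rows) + 1L]] <- addWells("NONE", 0, 0, nBackgroundWells,
                                          isBg = TRUE)
    for (conc in concentrations)
        rows[[length(rows) + 1L]] <- addWells("VEH", conc, 1, nReps)
    for (drug in names(trueParams)) {
        p <- trueParams[[drug]]
        for (conc in concentrations) {
            viab <- if (is.null(p)) 1
                    else ll4(conc, p[["b"]], p[["c"]], p[["e"]])
            rows[[length(rows) + 1L]] <- addWells(drug, conc, viab, nReps)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Simulate a fluorescence calcium-transient trace
#'
#' A baseline-1 intensity series sampled at `fs` frames/s with
#' `rateHz * durationS` regularly spaced transient events. Each event has
#' the kernel `A * (1 - exp(-t/riseTau)) * exp(-t/decayTau)` rescaled to
#' peak amplitude `A`, plus optional Gaussian noise.
#'
#' @param rateHz beat rate (events/s); `fs > 2 * rateHz` required.
#' @param riseTau,decayTau rise and decay time constants in seconds.
#' @param amplitude peak amplitude above baseline (dF/F0 units).
#' @param durationS recording length in seconds.
#' @param fs sampling rate, frames/s (default 31.34).
#' @param noiseSd Gaussian noise SD.
#' @param seed RNG seed.
#' @return list with `time` (s), `intensity`, `eventTimes` (s, truth),
#'   and `fs`.
#' @export
simulateCalciumTrace <- function(rateHz = 1, riseTau = 0.05,
                                 decayTau = 0.25, amplitude = 1,
                                 durationS = 10, fs = 31.34,
                                 noiseSd = 0, seed = 1L) {
    if (decayTau <= 0) stop("decayTau must be positive")
    if (riseTau <= 0) stop("riseTau must be positive")
    if (durationS <= 0) stop("durationS must be positive")
    if (fs <= 2 * rateHz)
        stop("sampling rate must exceed twice the beat rate")
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    set.seed(seed)
    n <- floor(durationS * fs)
    tt <- (seq_len(n) - 1) / fs
    nEvents <- floor(rateHz * durationS)
    period <- 1 / rateHz
    # first event placed half a period in so the rising flank is resolved
    eventTimes <- (seq_len(nEvents) - 0.5) * period
    eventTimes <- eventTimes[eventTimes < durationS]
    kernel <- function(t) {
        s <- ifelse(t < 0, 0, (1 - exp(-t / riseTau)) * exp(-t / decayTau))
        tPeak <- riseTau * log(1 + decayTau / riseTau)
        peak <- (1 - exp(-tPeak / riseTau)) * exp(-tPeak / decayTau)
        s / peak
    }
    intensity <- rep(1, n)
    for (e in eventTimes) intensity <- intensity +
        amplitude * kernel(tt - e)
    if (noiseSd > 0) intensity <- intensity + rnorm(n, 0, noiseSd)
    tPeak <- riseTau * log(1 + decayTau / riseTau)
    list(time = tt, intensity = intensity, eventTimes = eventTimes,
         peakTimes = eventTimes + tPeak, fs = fs)
}
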