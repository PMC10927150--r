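#' Background-subtract and vehicle-normalise a viability plate
#'
#' For each plate the mean fluorescence of the cell-free background wells
#' is subtracted from every well; each drug well is then divided by the
#' mean background-corrected fluorescence of the vehicle wells at the
#' same concentration. Vehicle wells therefore average to viability 1 by
#' construction. Values above 1 are retained: normalisation noise is
#' informative to the curve fit.
#'
#' @param readings data.frame with columns `plate`, `well`, `drug`,
#'   `conc_uM`, `rflu`, `is_background`.
#' @return data.frame `plate`, `drug`, `conc_uM`, `well`, `viability`
#'   for all non-background, non-vehicle wells plus the vehicle wells.
#' @examples
#' plate <- simulateViabilityPlate(list(DOX = c(b = 1.5, c = 0, e = 2)),
#'                                 noiseSd = 0)
#' head(normalizePlate(plate))
#' @export
normalizePlate <- function(readings) {
    need <- c("plate", "well", "drug", "conc_uM", "rflu", "is_background")
    miss <- setdiff(need, colnames(readings))
    if (length(miss))
        stop("plate table lacks columns: ", paste(miss, collapse = ", "))
    out <- lapply(split(readings, readings$plate), function(pl) {
        bg <- pl$rflu[pl$is_background]
        if (!length(bg))
            stop("plate ", pl$plate[1], " has no background wells")
        corrected <- pl$rflu - mean(bg)
        pl$corrected <- corrected
        test <- pl[!pl$is_background, , drop = FALSE]
        veh <- test[test$drug == "VEH", , drop = FALSE]
        vehMean <- tapply(veh$corrected, veh$conc_uM, mean)
        concKey <- as.character(test$conc_uM)
        missing <- setdiff(unique(concKey), names(vehMean))
        if (length(missing))
            stop("no vehicle wells for concentration(s): ",
                 paste(missing, collapse = ", "), " on plate ",
                 pl$plate[1])
        denom <- vehMean[concKey]
        if (any(denom <= 0))
            stop("mean vehicle fluorescence <= 0 at concentration(s): ",
                 paste(unique(concKey[denom <= 0]), collapse = ", "))
        data.frame(plate = test$plate, drug = test$drug,
                   conc_uM = test$conc_uM, well = test$well,
                   viability = as.numeric(test$corrected / denom))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Fit a log-logistic dose-response curve with fixed upper asymptote
#'
#' Least-squares fit of `c + (1 - c)/(1 + exp(b (log x - log e)))` to
#' viability fractions. Initialisation is deterministic: `e0` is the
#' geometric mean of the concentrations bracketing viability 0.5 (median
#' concentration when the data never cross 0.5), `b0 = 1`, `c0` is the
#' minimum mean viability clipped to `[0, 0.45]`; five multiplicative
#' jitters of `e0` serve as restarts. Flat data (no dose effect) yield a
#' degenerate fit flagged `converged = FALSE` with an undefined LD50.
#'
#' @param conc positive concentrations (one per observation).
#' @param viability viability fractions (same length).
#' @return A [DoseResponseFit-class].
#' @export
fitLL4FixedUpper <- function(conc, viability) {
    ok <- is.finite(conc) & is.finite(viability) & conc > 0
    conc <- conc[ok]; viability <- viability[ok]
    if (length(unique(conc)) < 4)
        stop("need at least 4 distinct positive concentrations")
    means <- tapply(viability, conc, mean)
    doses <- as.numeric(names(means))
    o <- order(doses)
    doses <- doses[o]; means <- as.numeric(means)[o]

    flatFit <- function(note) {
        fit <- new("DoseResponseFit", b = NA_real_, c = NA_real_, d = 1,
                   e = NA_real_, ld50 = NA_real_,
                   rss = sum((viability - mean(viability))^2),
                   converged = FALSE, diagnostics = note)
        fit
    }
    if (var(viability) < 1e-12 || diff(range(means)) < 0.02)
        return(flatFit("no dose effect detected; flat response"))

    below <- which(means < 0.5)
    above <- which(means >= 0.5)
    e0 <- if (length(below) && length(above)) {
        hi <- max(doses[above]); lo <- min(doses[below][doses[below] > 0])
        sqrt(hi * lo)
    } else median(doses)
    c0 <- min(max(min(means), 0), 0.45)
    residFn <- function(par) {
        ll4(conc, par[["b"]], par[["cc"]], par[["e"]]) - viability
    }
    best <- NULL
    for (jit in c(1, 0.25, 4, 0.0625, 16)) {
        fit <- tryCatch(
            minpack.lm::nls.lm(
                par = c(b = 1, cc = c0, e = e0 * jit),
                lower = c(b = 1e-6, cc = 0, e = 1e-9),
                upper = c(b = 100, cc = 0.999, e = 1e9),
                fn = residFn,
                control = minpack.lm::nls.lm.control(maxiter = 500)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(fit$fvec^2)
        if (is.null(best) || rss < best$rss - 1e-12)
            best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
        return(flatFit("non-convergence after restarts"))
    cf <- best$fit$par
    out <- new("DoseResponseFit", b = unname(cf[["b"]]),
               c = unname(cf[["cc"]]), d = 1, e = unname(cf[["e"]]),
               ld50 = NA_real_, rss = best$rss, converged = TRUE,
               diagnostics = character())
    out@ld50 <- extractLD50(out)
    out
}

#' Extract the LD50 from a fitted dose-response curve
#'
#' The unique concentration at which fitted viability equals 0.5 on the
#' absolute scale: `e * exp(log((1 - c)/(0.5 - c) - 1)/b)` when the lower
#' asymptote `c < 0.5`; undefined (`NA`) otherwise, including degenerate
#' flat fits.
#'
#' @param fit a [DoseResponseFit-class].
#' @return LD50 in dose units, or `NA_real_`.
#' @export
extractLD50 <- function(fit) {
    stopifnot(is(fit, "DoseResponseFit"))
    if (!fit@converged || is.na(fit@c) || fit@c >= 0.5) return(NA_real_)
    ratio <- (1 - fit@c) / (0.5 - fit@c) - 1
    if (ratio <= 0) return(NA_real_)
    unname(fit@e * exp(log(ratio) / fit@b))
}

#' Summarise LD50s across individuals and compare drugs
#'
#' Per-individual LD50 is the mean over replicate differentiations; the
#' per-drug summary is the median across individuals. Each drug's
#' per-individual LD50s are compared with the reference drug by a
#' two-sided Welch two-sample t test.
#'
#' @param ld50Table data.frame with columns `drug`, `individual`,
#'   `replicate`, `ld50` (NA for undefined fits).
#' @param reference drug all others are tested against (default "DOX").
#' @return list with `perIndividual`, `perDrug` (median, n, estimable)
#'   and `comparisons` (drug, t, df, p vs reference).
#' @export
summarizeLD50 <- function(ld50Table, reference = "DOX") {
    perInd <- aggregate(ld50 ~ drug + individual, data = ld50Table,
                        FUN = function(x) mean(x, na.rm = TRUE),
                        na.action = stats::na.pass)
    perInd$ld50[!is.finite(perInd$ld50)] <- NA_real_
    drugs <- unique(perInd$drug)
    perDrug <- do.call(rbind, lapply(drugs, function(d) {
        v <- perInd$ld50[perInd$drug == d]
        data.frame(drug = d, median_ld50 = median(v, na.rm = TRUE),
                   n = sum(!is.na(v)), estimable = any(!is.na(v)))
    }))
    comparisons <- data.frame(drug = character(), t = numeric(),
                              df = numeric(), p = numeric())
    if (reference %in% drugs) {
        ref <- perInd$ld50[perInd$drug == reference]
        ref <- ref[!is.na(ref)]
        for (d in setdiff(drugs, reference)) {
            v <- perInd$ld50[perInd$drug == d]
            v <- v[!is.na(v)]
            if (length(v) >= 2 && length(ref) >= 2 &&
                (sd(v) > 0 || sd(ref) > 0)) {
                tt <- t.test(v, ref)
                comparisons <- rbind(comparisons, data.frame(
                    drug = d, t = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value))
            } else if (length(v) >= 2 && length(ref) >= 2) {
                # identical constant vectors: no evidence of difference
                comparisons <- rbind(comparisons, data.frame(
                    drug = d, t = 0, df = length(v) + length(ref) - 2,
                    p = 1))
            }
        }
    }
    list(perIndividual = perInd, perDrug = perDrug,
         comparisons = comparisons)
}

#' Correlate viability with LDH cellular stress
#'
#' LDH activities are first normalised to the matched vehicle value for
#' the same individual and concentration, then Spearman rank correlation
#' between viability and normalised LDH is computed per drug across
#' concentrations and individuals.
#'
#' @param viabilityTable data.frame `individual`, `drug`, `conc_uM`,
#'   `viability`.
#' @param ldhTable data.frame `individual`, `drug`, `conc_uM`, `ldh`;
#'   must contain `VEH` rows for every (individual, concentration).
#' @return data.frame `drug`, `rho`, `p`, `n`; `rho` is `NA` with fewer
#'   than 3 matched pairs or zero rank variance.
#' @export
correlateStress <- function(viabilityTable, ldhTable) {
    veh <- ldhTable[ldhTable$drug == "VEH", , drop = FALSE]
    key <- function(d) paste(d$individual, d$conc_uM, sep = "|")
    vehLdh <- setNames(veh$ldh, key(veh))
    ldh <- ldhTable[ldhTable$drug != "VEH", , drop = FALSE]
    denom <- vehLdh[key(ldh)]
    if (anyNA(denom))
        stop("missing vehicle LDH for some (individual, concentration)")
    ldh$ldh_norm <- ldh$ldh / denom
    merged <- merge(viabilityTable, ldh[, c("individual", "drug",
                                            "conc_uM", "ldh_norm")],
                    by = c("individual", "drug", "conc_uM"))
    out <- do.call(rbind, lapply(split(merged, merged$drug), function(d) {
        n <- nrow(d)
        if (n < 3 || length(unique(d$ldh_norm)) < 2 ||
            length(unique(d$viability)) < 2)
            return(data.frame(drug = d$drug[1], rho = NA_real_,
                              p = NA_real_, n = n))
        ct <- suppressWarnings(
            cor.test(d$viability, d$ldh_norm, method = "spearman"))
        data.frame(drug = d$drug[1], rho = unname(ct$estimate),
                   p = ct$p.value, n = n)
    }))
    rownames(out) <- NULL
    out
}
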