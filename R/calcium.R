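#' Centred moving-average smoothing
#'
#' Window mean using the available neighbours within `(window - 1)/2`
#' frames of each point, so the series keeps its length and the edges are
#' smoothed with partial windows. `window = 1` returns the input.
#'
#' @param x numeric series.
#' @param window odd positive window length in frames.
#' @return smoothed series, same length as `x`.
#' @export
smoothTrace <- function(x, window = 5) {
    n <- length(x)
    if (window < 1 || window >= n)
        stop("smoothing window must be in [1, length(x) - 1]")
    if (window %% 2 == 0) stop("smoothing window must be odd")
    if (window == 1) return(x)
    h <- (window - 1) / 2
    vapply(seq_len(n),
           function(i) mean(x[max(1, i - h):min(n, i + h)]), 0)
}

#' Representative trace of a recording
#'
#' Each region of interest (ROI) is normalised to its own baseline,
#' F/F0 with F0 the 10th percentile of that ROI, and the normalised
#' traces are averaged frame-wise. ROIs with non-positive F0 are dropped
#' with a warning.
#'
#' @param rois numeric matrix, ROI x frame.
#' @return numeric series of frame-wise mean normalised intensity.
#' @export
representativeTrace <- function(rois) {
    rois <- as.matrix(rois)
    if (nrow(rois) < 1) stop("need at least one ROI")
    f0 <- apply(rois, 1, quantile, probs = 0.1, names = FALSE)
    keep <- f0 > 0
    if (!any(keep)) stop("all ROIs have non-positive baseline F0")
    if (!all(keep))
        warning(sum(!keep), " ROI(s) dropped: non-positive baseline F0")
    norm <- rois[keep, , drop = FALSE] / f0[keep]
    colMeans(norm)
}

#' Detect calcium-transient peaks
#'
#' After moving-average smoothing, frame `i` is a peak iff it is strictly
#' greater than both neighbours and greater than the 0.6 quantile of the
#' (by default smoothed) series. Endpoints are never peaks.
#'
#' @param intensity numeric series, length >= 3.
#' @param smoothWindow odd moving-average window (frames), default 5.
#' @param quantileProb amplitude gate quantile, default 0.6.
#' @param gateOnSmoothed apply the quantile gate to the smoothed series
#'   (default) or to the raw one.
#' @return integer frame indices of detected peaks.
#' @examples
#' tr <- simulateCalciumTrace(rateHz = 1, durationS = 10, noiseSd = 0)
#' length(detectPeaks(tr$intensity))
#' @export
detectPeaks <- function(intensity, smoothWindow = 5, quantileProb = 0.6,
                        gateOnSmoothed = TRUE) {
    n <- length(intensity)
    if (n < 3) stop("series must have at least 3 frames")
    s <- smoothTrace(intensity, smoothWindow)
    gate <- quantile(if (gateOnSmoothed) s else intensity,
                     probs = quantileProb, names = FALSE)
    i <- 2:(n - 1)
    peaks <- i[s[i] > s[i - 1] & s[i] > s[i + 1] & s[i] > gate]
    as.integer(peaks)
}

#' Extract transient features around detected peaks
#'
#' For each peak, the window from the preceding trough to the following
#' trough (minima between consecutive peaks; recording edges act as
#' troughs for terminal peaks) is fitted with
#' `baseline + A * exp(-(t - mu)^2 / (2 sigma^2))`. Features per
#' transient: amplitude `A`; FWHM `2 sqrt(2 log 2) * sigma` in seconds;
#' rising slope, the maximum discrete derivative (per second) on the
#' rising flank; decay slope, the minimum on the decaying flank.
#' Transients whose fit fails or whose fitted width exceeds the local
#' inter-peak interval are excluded and counted.
#'
#' @param intensity raw (unsmoothed) numeric series.
#' @param peaks integer peak indices, e.g. from [detectPeaks()].
#' @param fs sampling rate in frames/s.
#' @return list with `features` (data.frame peak, amplitude,
#'   rising_slope, decay_slope, fwhm), `summary` (named means plus
#'   `beat_rate`), `nExcluded`.
#' @export
fitTransients <- function(intensity, peaks, fs) {
    if (length(peaks) < 1) stop("need at least one peak")
    n <- length(intensity)
    troughBetween <- function(a, b) a + which.min(intensity[a:b]) - 1L
    bounds <- matrix(NA_integer_, length(peaks), 2)
    for (j in seq_along(peaks)) {
        lo <- if (j == 1) 1L else troughBetween(peaks[j - 1], peaks[j])
        hi <- if (j == length(peaks)) n
              else troughBetween(peaks[j], peaks[j + 1])
        bounds[j, ] <- c(lo, hi)
    }
    rows <- list(); nExcluded <- 0L
    for (j in seq_along(peaks)) {
        lo <- bounds[j, 1]; hi <- bounds[j, 2]; pk <- peaks[j]
        idx <- lo:hi
        tt <- (idx - 1) / fs
        yy <- intensity[idx]
        base0 <- min(yy)
        a0 <- intensity[pk] - base0
        # half-max crossing width as a sigma seed
        half <- base0 + a0 / 2
        above <- which(yy >= half)
        sig0 <- max(diff(range(tt[above])), 2 / fs) / 2.355
        fit <- tryCatch(
            minpack.lm::nlsLM(
                yy ~ b0 + A * exp(-(tt - mu)^2 / (2 * sg^2)),
                start = list(b0 = base0, A = a0,
                             mu = (pk - 1) / fs, sg = sig0),
                lower = c(b0 = -Inf, A = 0, mu = min(tt),
                          sg = 0.5 / fs),
                control = minpack.lm::nls.lm.control(maxiter = 100)),
            error = function(e) NULL)
        interPeak <- (hi - lo) / fs
        if (is.null(fit) || coef(fit)[["sg"]] > interPeak ||
            coef(fit)[["A"]] <= 0) {
            nExcluded <- nExcluded + 1L
            next
        }
        cf <- coef(fit)
        riseIdx <- lo:pk
        decayIdx <- pk:hi
        rise <- if (length(riseIdx) > 1)
            max(diff(intensity[riseIdx])) * fs else NA_real_
        decay <- if (length(decayIdx) > 1)
            min(diff(intensity[decayIdx])) * fs else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
            peak = pk, amplitude = cf[["A"]],
            rising_slope = rise, decay_slope = decay,
            fwhm = 2 * sqrt(2 * log(2)) * cf[["sg"]])
    }
    if (!length(rows))
        stop("all transient fits failed (", nExcluded, " excluded)")
    features <- do.call(rbind, rows)
    dur <- n / fs
    summary <- c(amplitude = mean(features$amplitude),
                 rising_slope = mean(features$rising_slope, na.rm = TRUE),
                 decay_slope = mean(features$decay_slope, na.rm = TRUE),
                 fwhm = mean(features$fwhm),
                 beat_rate = beatRate(peaks, dur))
    list(features = features, summary = summary, nExcluded = nExcluded)
}

#' Beat rate
#'
#' Number of detected peaks divided by the recording duration.
#'
#' @param peaks integer peak indices (or any vector; only the count is
#'   used).
#' @param durationS recording duration in seconds.
#' @return events per second.
#' @export
beatRate <- function(peaks, durationS) {
    if (durationS <= 0) stop("durationS must be positive")
    length(peaks) / durationS
}

#' PCA of calcium-transient features across conditions
#'
#' Features are standardised to zero mean and unit variance, then a PCA
#' is computed across conditions. Zero-variance features are dropped
#' with a warning.
#'
#' @param featureMatrix numeric matrix, condition x feature (typically
#'   the five per-condition feature means).
#' @return list with `scores` (condition x PC), `varianceFraction`
#'   (sums to 1), and `dropped` feature names.
#' @export
featurePCA <- function(featureMatrix) {
    featureMatrix <- as.matrix(featureMatrix)
    if (nrow(featureMatrix) < 2) stop("need at least 2 conditions")
    sds <- apply(featureMatrix, 2, sd)
    dropped <- colnames(featureMatrix)[sds == 0]
    if (length(dropped))
        warning("zero-variance feature(s) dropped: ",
                paste(dropped, collapse = ", "))
    keep <- featureMatrix[, sds > 0, drop = FALSE]
    if (!ncol(keep)) stop("no features with non-zero variance")
    pc <- prcomp(keep, center = TRUE, scale. = TRUE)
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x, varianceFraction = vf, dropped = dropped)
}
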