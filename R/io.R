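#' Read a count matrix with its sample sheet
#'
#' Accepts a tab-separated gene x sample table (first column = gene
#' identifiers) or a MatrixMarket file accompanied by `<path>.rownames`
#' and `<path>.colnames` text files (one identifier per line). Counts
#' must be non-negative integers; duplicate gene identifiers are
#' rejected.
#'
#' @param countsPath path to the `.tsv`/`.txt` or `.mtx` file.
#' @param samplesPath path to a CSV sample sheet with columns
#'   `sample_id`, `individual`, `treatment`, `time`.
#' @return A [CardioExperiment-class].
#' @export
readCounts <- function(countsPath, samplesPath) {
    if (grepl("\\.mtx$", countsPath)) {
        m <- as.matrix(Matrix::readMM(countsPath))
        rn <- readLines(paste0(countsPath, ".rownames"))
        cn <- readLines(paste0(countsPath, ".colnames"))
        dimnames(m) <- list(rn, cn)
    } else {
        tab <- read.delim(countsPath, check.names = FALSE)
        rn <- as.character(tab[[1]])
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- rn
    }
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene identifiers in ", countsPath)
    if (any(!is.finite(m)))
        stop("non-numeric cells in ", countsPath)
    bad <- which(m != round(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-integer or negative count at row '",
             rownames(m)[bad[1, 1]], "', column '",
             colnames(m)[bad[1, 2]], "'")
    storage.mode(m) <- "integer"
    samples <- read.csv(samplesPath, stringsAsFactors = FALSE)
    orphans <- setdiff(colnames(m), samples$sample_id)
    if (length(orphans))
        stop("count columns missing from the sample sheet: ",
             paste(orphans, collapse = ", "))
    CardioExperiment(m, samples)
}

#' Write a count study to disk
#'
#' Writes the counts as a gene x sample TSV (or MatrixMarket triplet
#' plus `.rownames`/`.colnames` files) and the design as a CSV sample
#' sheet, the formats [readCounts()] accepts.
#'
#' @param experiment a [CardioExperiment-class].
#' @param countsPath output `.tsv` or `.mtx` path.
#' @param samplesPath output CSV path.
#' @return invisibly, the two paths.
#' @export
writeCounts <- function(experiment, countsPath, samplesPath) {
    m <- counts(experiment)
    if (grepl("\\.mtx$", countsPath)) {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), countsPath)
        writeLines(rownames(m), paste0(countsPath, ".rownames"))
        writeLines(colnames(m), paste0(countsPath, ".colnames"))
    } else {
        tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
        write.table(tab, countsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    sheet <- data.frame(sample_id = colnames(experiment),
                        individual = individuals(experiment),
                        treatment = treatments(experiment),
                        time = timepoints(experiment))
    write.csv(sheet, samplesPath, row.names = FALSE, quote = FALSE)
    invisible(c(countsPath, samplesPath))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
    names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
    sets
}

#' Read SNPs or gene intervals from a BED file
#'
#' Minimal BED (0-based, half-open). For SNP files, columns are chrom,
#' start, end, name; `pos` is the start. For gene files, columns chrom,
#' start, end, name, score, strand.
#'
#' @param path BED file path.
#' @param type `"snp"` or `"gene"`.
#' @return data.frame; for SNPs `chrom`, `pos`, `id`; for genes
#'   `chrom`, `start`, `end`, `gene_id`, `strand`.
#' @export
readBed <- function(path, type = c("snp", "gene")) {
    type <- match.arg(type)
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (type == "snp") {
        data.frame(chrom = tab[[1]], pos = as.integer(tab[[2]]),
                   id = if (ncol(tab) >= 4) as.character(tab[[4]])
                        else paste0("snp", seq_len(nrow(tab))))
    } else {
        if (ncol(tab) < 6) stop("gene BED needs 6 columns incl. strand")
        data.frame(chrom = tab[[1]], start = as.integer(tab[[2]]),
                   end = as.integer(tab[[3]]),
                   gene_id = as.character(tab[[4]]),
                   strand = as.character(tab[[6]]))
    }
}

## stable stage seed derived from the master seed and the stage name,
## kept below 2^31
stageSeed <- function(masterSeed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
    as.integer((as.numeric(masterSeed) * 7919 + h) %% 2147483587)
}

#' Default pipeline configuration
#'
#' All analysis constants in one place: thresholds (FDR 0.05, stringent
#' drug-specific rule 0.01/0.05, posterior cut 0.5, expression filter at
#' mean log2 cpm 0, peak quantile 0.6, smoothing window 5), the motif-K
#' search range, and the synthetic-study size used when no counts are
#' supplied.
#'
#' @param seed master seed; per-stage seeds derive from it.
#' @param nGenes synthetic gene count.
#' @param kRange candidate motif numbers.
#' @param nRestarts EM restarts.
#' @return named list.
#' @export
pipelineConfig <- function(seed = 1L, nGenes = 2000, kRange = 1:6,
                           nRestarts = 10) {
    list(seed = as.integer(seed), nGenes = nGenes, kRange = kRange,
         nRestarts = nRestarts,
         fdr = 0.05, stringent = c(0.01, 0.05), posterior = 0.5,
         expressionFilter = 0, peakQuantile = 0.6, smoothWindow = 5)
}

#' Run the full expression pipeline
#'
#' Simulates (or loads) a count study, then runs differential
#' expression, motif fitting with BIC selection, signature assignment,
#' drug-specific gene calls, variance analysis, and writes tidy CSV
#' outputs plus a JSON manifest with the seeds, the constants used, and
#' per-file row counts and checksums. Outputs are deterministic given
#' the config seed.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param countsPath,samplesPath optional real data; when `NULL` a
#'   synthetic study is generated from the config seed.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        countsPath = NULL, samplesPath = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    emit <- function(df, name) {
        path <- file.path(outDir, name)
        write.csv(df, path, row.names = FALSE)
        files <<- c(files, path)
        path
    }
    if (is.null(countsPath)) {
        design <- simDesign(nGenes = config$nGenes,
                            seed = stageSeed(config$seed, "simulate"))
        sim <- simulateCounts(design)
        experiment <- sim$experiment
        truthTab <- data.frame(gene = names(sim$truth$motif),
                               motif = unname(sim$truth$motif))
        emit(truthTab, "truth_motifs.csv")
    } else {
        if (!file.exists(countsPath))
            stop("counts path does not exist: ", countsPath)
        experiment <- readCounts(countsPath, samplesPath)
    }

    de <- deAnalysis(experiment, fdr = config$fdr)
    for (cn in names(de$tables))
        emit(de$tables[[cn]], paste0("contrast_", cn, ".csv"))
    corr <- responseCorrelationMatrix(de$tables)
    emit(data.frame(group = rownames(corr$correlation),
                    round(corr$correlation, 10)),
         "response_correlation.csv")

    cs <- conditionStatistics(experiment)
    sel <- selectMotifNumber(cs$t, cs$df, kRange = config$kRange,
                             seed = stageSeed(config$seed, "motifs"),
                             nRestarts = config$nRestarts,
                             keepFits = TRUE)
    emit(sel$scores, "motif_scores.csv")
    fit <- sel$fits[[paste0("K", sel$bestK)]]
    qt <- data.frame(motif = rownames(motifPatterns(fit)),
                     round(motifPatterns(fit), 8))
    emit(qt, "motif_patterns.csv")
    sig <- assignSignatures(fit)
    emit(data.frame(gene = names(sig$labels),
                    signature = unname(sig$labels)),
         "signatures.csv")
    emit(data.frame(gene = rownames(dePosterior(fit)),
                    round(dePosterior(fit), 8)),
         "de_posterior.csv")

    times <- unique(timepoints(experiment))
    drugs <- setdiff(unique(treatments(experiment)), "VEH")
    dsRows <- list()
    for (tp in times) {
        tabs <- de$tables[paste(drugs, tp, sep = ".")]
        for (dr in drugs) {
            g <- drugSpecificGenes(tabs, dr,
                                   stringent = config$stringent[1],
                                   lenient = config$stringent[2])
            if (length(g))
                dsRows[[paste(dr, tp)]] <- data.frame(
                    drug = dr, time = tp, gene = g)
        }
    }
    ds <- if (length(dsRows)) do.call(rbind, c(dsRows,
                                               make.row.names = FALSE))
          else data.frame(drug = character(), time = character(),
                          gene = character())
    emit(ds, "drug_specific_genes.csv")

    va <- variabilityAnalysis(experiment)
    emit(va$shiftTests, "variance_shift_tests.csv")
    emit(data.frame(group = rownames(va$clustering$correlation),
                    round(va$clustering$correlation, 10)),
         "variance_profile_correlation.csv")

    manifest <- list(
        package = "top2tox",
        version = as.character(utils::packageVersion("top2tox")),
        seed = config$seed,
        constants = config[c("fdr", "stringent", "posterior",
                             "expressionFilter", "peakQuantile",
                             "smoothWindow")],
        bestK = sel$bestK,
        assignedFraction = sig$assignedFraction,
        files = lapply(files, function(f) {
            list(name = basename(f),
                 rows = length(readLines(f)) - 1L,
                 md5 = unname(tools::md5sum(f)))
        }))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
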