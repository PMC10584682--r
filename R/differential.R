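## Median-of-ratios normalization and per-feature differential testing of
## expression / peak signal between control and mutant.

#' @importFrom stats pt p.adjust
NULL

.countsOf <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts")
    else as.matrix(x)
}

.conditionOf <- function(x) {
    cond <- SummarizedExperiment::colData(x)$condition
    if (is.null(cond))
        stop("colData must contain a 'condition' column", call. = FALSE)
    cond
}

#' Median-of-ratios size factors
#'
#' For each sample j the factor is the median, over features with a
#' positive geometric mean across samples, of the ratio of the sample's
#' count to that feature's geometric mean.  This is the classic
#' reference-pseudo-sample normalization of count matrices; it requires
#' at least one feature with nonzero counts in every sample.  Factors
#' are standardized to unit geometric mean, which leaves between-sample
#' ratios untouched and makes the estimate idempotent: re-estimating on
#' a normalized matrix returns factors of exactly 1.
#'
#' @param x A `SummarizedExperiment` with assay `counts`, or a count
#'   matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @seealso [normalizeCounts()]
#' @examples
#' m <- matrix(c(10, 20, 100, 200, 30, 60), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' computeSizeFactors(m)  # b has twice the depth of a
#' @export
computeSizeFactors <- function(x) {
    m <- .countsOf(x)
    ok <- rowSums(m > 0) == ncol(m)
    if (!any(ok))
        stop("no feature with nonzero counts in all samples; ",
             "size factors are undefined", call. = FALSE)
    logGeo <- rowMeans(log(m[ok, , drop = FALSE]))
    sf <- apply(m[ok, , drop = FALSE], 2L,
                function(col) median(exp(log(col) - logGeo)))
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor", call. = FALSE)
    ## standardize to unit geometric mean: ratios between samples are
    ## untouched, and re-estimating on a normalized matrix gives exactly 1
    sf / exp(mean(log(sf)))
}

#' Normalize a count matrix by size factors
#'
#' @param x A `SummarizedExperiment` with assay `counts`, or a matrix.
#' @param factors Per-sample factors from [computeSizeFactors()].
#' @return Matrix of normalized counts (`count / factor`).
#' @export
normalizeCounts <- function(x, factors = computeSizeFactors(x)) {
    m <- .countsOf(x)
    if (any(!is.finite(factors) | factors <= 0))
        stop("size factors must be positive", call. = FALSE)
    if (length(factors) != ncol(m))
        stop("one size factor per sample required", call. = FALSE)
    sweep(m, 2L, factors, "/")
}

## Welch two-sample test on rows of a matrix, vectorized.
## Returns two-sided p; rows where both groups have zero variance get
## p = 1 when the means agree and NA otherwise.
.rowWelch <- function(m, g1, g2) {
    n1 <- length(g1); n2 <- length(g2)
    x1 <- m[, g1, drop = FALSE]; x2 <- m[, g2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tstat), df)
    degenerate <- se2 == 0
    p[degenerate & m1 == m2] <- 1
    p[degenerate & m1 != m2] <- NA_real_
    p
}

#' Per-feature differential test between control and mutant
#'
#' Counts are normalized by median-of-ratios size factors.  Per feature,
#' the log2 fold change is `log2((meanMutant + 0.5) / (meanControl +
#' 0.5))` on normalized counts (pseudocount 0.5 guards zeros) and the P
#' value comes from a two-sided Welch test on `log2(normalized + 1)`.
#' Calls are `down` when `p < deAlpha` and the fold change is negative,
#' `up` when positive, otherwise `unchanged`; with `fdrMode` the call
#' thresholds the Benjamini-Hochberg adjusted P value instead.
#'
#' @param x A features-x-samples `SummarizedExperiment` with assay
#'   `counts` and `condition` (`control`/`mutant`) in `colData`; at
#'   least 2 replicates per condition.
#' @param config An [AnalysisConfig-class].
#' @return A [S4Vectors::DataFrame] with columns `feature_id`,
#'   `mean_control`, `mean_mutant`, `log2fc`, `p_value`, `padj`, `call`;
#'   `metadata()` records the pseudocounts and size factors.
#' @examples
#' cfg <- SynthConfig(seed = 5, nGenes = 40L)
#' sim <- simulatePeaks(simulateGenome(cfg), cfg)
#' head(deTest(simulateCounts(sim$truth, cfg)))
#' @export
deTest <- function(x, config = AnalysisConfig()) {
    cond <- .conditionOf(x)
    g1 <- which(cond == "control")
    g2 <- which(cond == "mutant")
    if (length(g1) < 2L || length(g2) < 2L)
        stop("need >= 2 replicates per condition (control: ", length(g1),
             ", mutant: ", length(g2), ")", call. = FALSE)
    sf <- computeSizeFactors(x)
    norm <- normalizeCounts(x, sf)
    meanC <- rowMeans(norm[, g1, drop = FALSE])
    meanM <- rowMeans(norm[, g2, drop = FALSE])
    log2fc <- log2((meanM + 0.5) / (meanC + 0.5))
    p <- .rowWelch(log2(norm + 1), g1, g2)
    padj <- p.adjust(p, method = "BH")
    pEff <- if (config@fdrMode) padj else p
    call <- rep("unchanged", nrow(norm))
    call[!is.na(pEff) & pEff < config@deAlpha & log2fc < 0] <- "down"
    call[!is.na(pEff) & pEff < config@deAlpha & log2fc > 0] <- "up"
    out <- DataFrame(feature_id = rownames(norm),
                     mean_control = unname(meanC), mean_mutant = unname(meanM),
                     log2fc = unname(log2fc), p_value = unname(p),
                     padj = unname(padj), call = call)
    metadata(out) <- list(pseudocount_fc = 0.5, pseudocount_log = 1,
                          size_factors = sf, fdr_mode = config@fdrMode,
                          alpha = config@deAlpha)
    out
}

#' Gene-level direction of H3K4me3 peak-signal change
#'
#' Runs [deTest()] on a peaks-x-samples count matrix and aggregates
#' peak calls to genes: a gene is `reduced` when at least one of its
#' peaks is called down and none up, `increased` when at least one is up
#' and none down, otherwise `unchanged` (genes with conflicting peaks
#' are counted and reported via a message).  Peaks present in the counts
#' but absent from the assignment are skipped with a message.
#'
#' @param peakCounts A peaks-x-samples `SummarizedExperiment` (assay
#'   `counts`, `condition` in `colData`); row names are peak names.
#' @param assignment Peak-to-gene map: a `GRangesList` from
#'   [assignPeaksToGenes()] (peak `name` columns are used) or a named
#'   list of character vectors of peak names per gene.
#' @param config An [AnalysisConfig-class].
#' @return A `data.frame` with columns `gene_id` and `direction`
#'   (`increased`/`reduced`/`unchanged`), one row per gene in the
#'   assignment; attribute `peak_de` carries the peak-level
#'   [deTest()] table.
#' @export
peakSignalChange <- function(peakCounts, assignment,
                             config = AnalysisConfig()) {
    peakToGene <- if (methods::is(assignment, "GRangesList")) {
        nm <- lapply(assignment, function(p) as.character(p$name))
        setNames(rep(names(nm), lengths(nm)), unlist(nm, use.names = FALSE))
    } else {
        setNames(rep(names(assignment), lengths(assignment)),
                 unlist(assignment, use.names = FALSE))
    }
    de <- deTest(peakCounts, config)
    known <- de$feature_id %in% names(peakToGene)
    if (any(!known))
        message(sum(!known), " peak(s) in the count matrix have no gene ",
                "assignment and were skipped")
    gene <- peakToGene[de$feature_id[known]]
    callByGene <- split(de$call[known], gene)
    direction <- vapply(callByGene, function(cl) {
        up <- any(cl == "up"); down <- any(cl == "down")
        if (down && !up) "reduced"
        else if (up && !down) "increased"
        else "unchanged"
    }, character(1))
    nConflict <- sum(vapply(callByGene, function(cl)
        any(cl == "up") && any(cl == "down"), logical(1)))
    if (nConflict > 0L)
        message(nConflict, " gene(s) with conflicting peak calls set to ",
                "unchanged")
    allGenes <- if (is.null(names(assignment))) unique(gene)
                else names(assignment)
    out <- data.frame(
        gene_id = allGenes,
        direction = ifelse(allGenes %in% names(direction),
                           direction[allGenes], "unchanged"))
    attr(out, "peak_de") <- de
    out
}

#' Write a differential-test table as TSV
#'
#' @param de A [deTest()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDETable <- function(de, path) {
    write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
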