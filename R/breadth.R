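## Peak-to-gene assignment, per-gene breadth scoring and the quartile
## broad/medium/narrow classification.

#' @importFrom GenomicRanges reduce resize findOverlaps pintersect distance
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Merge possibly overlapping intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases; abutting intervals are merged.  This is the union step behind
#' breadth scoring, exposed for testing and reuse.
#'
#' @param intervals An `IRanges` (possibly unsorted/overlapping).
#' @return A sorted, disjoint `IRanges` covering the same bases.
#' @examples
#' mergeIntervals(IRanges::IRanges(c(1, 51), c(100, 150)))  # 1-150
#' @export
mergeIntervals <- function(intervals) {
    if (!methods::is(intervals, "IRanges"))
        stop("intervals must be an IRanges", call. = FALSE)
    IRanges::reduce(intervals, min.gapwidth = 1L)
}

#' Assign peaks to genes by largest overlap with the promoter-to-TES window
#'
#' A peak is a candidate for every gene whose window
#' `[TSS - promoterUpstream, TES]` (strand-oriented) it overlaps by at
#' least 1 bp.  A peak overlapping several windows goes to the gene with
#' the largest overlap; ties break by smaller distance to the TSS, then
#' lexicographic `gene_id`.  Peaks overlapping no window are dropped with
#' a message reporting the count.
#'
#' @param peaks A peak `GRanges`.
#' @param genes Gene models (`GRanges` with `gene_id`).
#' @param config An [AnalysisConfig-class].
#' @return A named `GRangesList`, one (possibly empty) element per gene.
#'   `metadata()$nDropped` records the number of unassigned peaks.
#' @seealso [geneBreadth()]
#' @export
assignPeaksToGenes <- function(peaks, genes, config = AnalysisConfig()) {
    windows <- resize(genes, GenomicRanges::width(genes) +
                      config@promoterUpstream, fix = "end")
    hits <- findOverlaps(peaks, windows, ignore.strand = TRUE)
    assignedPeak <- integer(0)
    assignedGene <- character(0)
    if (length(hits)) {
        q <- queryHits(hits); s <- subjectHits(hits)
        ov <- GenomicRanges::width(pintersect(
            GenomicRanges::granges(peaks)[q],
            GenomicRanges::granges(windows)[s], ignore.strand = TRUE))
        tss <- tssPositions(genes)[s]
        tssGr <- GRanges(seqnames(genes)[s], IRanges(tss, width = 1L))
        tssDist <- distance(GenomicRanges::granges(peaks)[q], tssGr,
                            ignore.strand = TRUE)
        ord <- order(q, -ov, tssDist, genes$gene_id[s])
        keep <- ord[!duplicated(q[ord])]
        assignedPeak <- q[keep]
        assignedGene <- genes$gene_id[s[keep]]
    }
    nDropped <- length(peaks) - length(assignedPeak)
    if (nDropped > 0L)
        message(nDropped, " peak(s) overlapped no gene window and were dropped")
    out <- methods::as(S4Vectors::split(
        peaks[assignedPeak],
        factor(assignedGene, levels = sort(genes$gene_id))), "GRangesList")
    metadata(out)$nDropped <- nDropped
    out
}

#' Per-gene H3K4me3 breadth
#'
#' Breadth is the total merged span (bp) of the peaks assigned to a gene;
#' peak-caller fragmentation of one domain into abutting or overlapping
#' pieces therefore does not deflate the score.  Genes with no assigned
#' peaks get breadth 0.
#'
#' @param assignment A `GRangesList` from [assignPeaksToGenes()].
#' @return An unclassified [BreadthTable-class] (rank and group `NA`).
#' @export
geneBreadth <- function(assignment) {
    breadth <- vapply(assignment,
                      function(p) sum(GenomicRanges::width(reduce(p))),
                      numeric(1))
    BreadthTable(names(assignment), as.numeric(breadth))
}

#' Classify genes into broad/medium/narrow breadth groups
#'
#' Genes are ranked by breadth (descending, ties broken by ascending
#' `gene_id` for a deterministic partition).  The first
#' `floor(quartileLow * N)` genes form the `broad` group, the last
#' `floor(quartileLow * N)` the `narrow` group and the remainder the
#' `medium` group; with the default quartile of 0.25 this is the
#' top-25 / middle-50 / bottom-25 percent split.  Genes with breadth 0
#' are excluded first (with a message), as the grouping describes genes
#' that carry a domain.
#'
#' @param table A [BreadthTable-class] (classified or not).
#' @param config An [AnalysisConfig-class].
#' @return A classified [BreadthTable-class] with `rank` and `group`
#'   filled; `metadata()` of `breadthData()` records the number of
#'   zero-breadth genes excluded.
#' @examples
#' bt <- BreadthTable(paste0("g", 1:4), c(10, 400, 30, 8000))
#' breadthData(classifyBreadth(bt, AnalysisConfig()))  # sizes 1/2/1
#' @export
classifyBreadth <- function(table, config = AnalysisConfig()) {
    tab <- breadthData(table)
    zero <- tab$breadth == 0
    if (any(zero)) {
        message(sum(zero), " gene(s) with breadth 0 excluded from ",
                "classification")
        tab <- tab[!zero, , drop = FALSE]
    }
    n <- nrow(tab)
    if (n < 4L)
        stop("need at least 4 genes with nonzero breadth to classify, got ",
             n, call. = FALSE)
    ord <- order(-tab$breadth, tab$gene_id)
    tab <- tab[ord, , drop = FALSE]
    nCut <- floor(config@quartileLow * n)
    group <- rep("medium", n)
    if (nCut > 0L) {
        group[seq_len(nCut)] <- "broad"
        group[seq.int(n - nCut + 1L, n)] <- "narrow"
    }
    out <- BreadthTable(tab$gene_id, tab$breadth,
                        rank = seq_len(n), group = group)
    metadata(out@tab)$nZeroExcluded <- sum(zero)
    methods::validObject(out)
    out
}

#' Median normalized expression per breadth group
#'
#' Convenience summary behind the expression-by-breadth-group comparison:
#' per-gene mean of median-of-ratios normalized counts over control
#' samples, summarised as the median within each breadth group.
#'
#' @param se A genes-x-samples `SummarizedExperiment` with assay `counts`
#'   and `condition` in `colData`.
#' @param table A classified [BreadthTable-class].
#' @return A `data.frame` with columns `group`, `n`,
#'   `median_normalized_expression`.
#' @export
expressionByBreadthGroup <- function(se, table) {
    norm <- normalizeCounts(se, computeSizeFactors(se))
    ctrl <- SummarizedExperiment::colData(se)$condition == "control"
    geneMean <- rowMeans(norm[, ctrl, drop = FALSE])
    grp <- geneGroups(table)
    common <- intersect(names(grp), rownames(norm))
    res <- lapply(levels(grp), function(g) {
        ids <- intersect(common, names(grp)[grp == g])
        data.frame(group = g, n = length(ids),
                   median_normalized_expression =
                       if (length(ids)) median(geneMean[ids]) else NA_real_)
    })
    do.call(rbind, res)
}
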