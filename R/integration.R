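## Intersection of reduced-H3K4me3 and reduced-expression gene sets with
## breadth-group composition, plus the small volcano and delta-delta-Ct
## utilities.

#' Venn overlap of reduced-H3K4me3 and reduced-expression gene sets
#'
#' Intersects the two gene sets and summarises the overlap as a
#' percentage of the reduced-H3K4me3 set (1 decimal, the precision the
#' Venn percentage is conventionally reported at) together with the
#' broad/medium/narrow composition of the overlap (percents to
#' 2 decimals).
#'
#' @param reducedPeakGenes Character vector: genes with reduced H3K4me3
#'   signal.
#' @param reducedExprGenes Character vector: genes with reduced
#'   expression.
#' @param groups A classified [BreadthTable-class], or a named character
#'   or factor vector mapping gene id to group; every overlap gene must
#'   be present.
#' @return An [IntegrationSummary-class].
#' @examples
#' grp <- setNames(rep(c("broad", "narrow"), each = 3), paste0("g", 1:6))
#' overlapSummary(paste0("g", 1:4), paste0("g", 3:6), grp)
#' @export
overlapSummary <- function(reducedPeakGenes, reducedExprGenes, groups) {
    reducedPeakGenes <- unique(as.character(reducedPeakGenes))
    reducedExprGenes <- unique(as.character(reducedExprGenes))
    if (length(reducedPeakGenes) == 0L)
        stop("no genes with reduced H3K4me3: overlap percentage undefined",
             call. = FALSE)
    if (methods::is(groups, "BreadthTable"))
        groups <- geneGroups(groups)
    grp <- setNames(as.character(groups), names(groups))
    overlap <- intersect(reducedPeakGenes, reducedExprGenes)
    missing <- setdiff(overlap, names(grp))
    if (length(missing))
        stop("overlap gene(s) missing from the breadth grouping: ",
             paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
    counts <- vapply(c("broad", "medium", "narrow"),
                     function(g) sum(grp[overlap] == g), integer(1))
    pct <- if (length(overlap))
        round(100 * counts / length(overlap), 2L) else counts * 0
    new("IntegrationSummary",
        nReducedPeaks = length(reducedPeakGenes),
        nReducedExpression = length(reducedExprGenes),
        nOverlap = length(overlap),
        pctOverlap = round(100 * length(overlap) / length(reducedPeakGenes), 1L),
        composition = DataFrame(group = c("broad", "medium", "narrow"),
                                count = unname(counts),
                                percent = unname(pct)))
}

#' Write an IntegrationSummary as JSON and TSV
#'
#' @param summary An [IntegrationSummary-class].
#' @param jsonPath,tsvPath Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary as a list.
#' @export
writeIntegrationSummary <- function(summary, jsonPath = NULL, tsvPath = NULL) {
    lst <- list(
        n_reduced_peaks = summary@nReducedPeaks,
        n_reduced_expression = summary@nReducedExpression,
        n_overlap = summary@nOverlap,
        pct_overlap_of_reduced_peaks = summary@pctOverlap,
        composition = as.data.frame(summary@composition))
    if (!is.null(jsonPath))
        jsonlite::write_json(lst, jsonPath, auto_unbox = TRUE, digits = NA)
    if (!is.null(tsvPath))
        write.table(lst$composition, tsvPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    invisible(lst)
}

#' Classify volcano-plot entries by fold change and P value
#'
#' An entry is `increased` when its fold change is strictly above `fcUp`
#' and its P value below `deAlpha`; `decreased` when the fold change is
#' strictly below `fcDown` with P below `deAlpha`; otherwise
#' `unchanged`.  Fold changes exactly on a threshold are unchanged
#' (strict inequalities).
#'
#' @param x A `data.frame` with columns `name`, `fold_change`
#'   (positive) and `p_value` in `[0, 1]`.
#' @param config An [AnalysisConfig-class].
#' @return `x` with an added `call` column.
#' @examples
#' volcanoClassify(data.frame(name = "aKG", fold_change = 20,
#'                            p_value = 0.001))
#' @export
volcanoClassify <- function(x, config = AnalysisConfig()) {
    fc <- x$fold_change
    p <- x$p_value
    if (any(!is.finite(fc) | fc <= 0))
        stop("fold_change must be positive", call. = FALSE)
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p_value must be in [0, 1]", call. = FALSE)
    call <- rep("unchanged", nrow(x))
    call[fc > config@fcUp & p < config@deAlpha] <- "increased"
    call[fc < config@fcDown & p < config@deAlpha] <- "decreased"
    x$call <- call
    x
}

#' Relative expression by the delta-delta-Ct rule
#'
#' Per sample, `deltaCt = ct_reference - ct_target`; relative expression
#' is `2^deltaCt` rescaled so that the mean over control samples equals
#' 1.
#'
#' @param x A `data.frame` with columns `sample`, `condition` (at least
#'   one `control` row), `ct_target`, `ct_reference`.
#' @return `x` with added `delta_ct` and `rel_expression` columns.
#' @examples
#' deltaDeltaCt(data.frame(sample = c("c1", "t1"),
#'   condition = c("control", "treated"),
#'   ct_target = c(25, 24), ct_reference = c(20, 20)))
#' @export
deltaDeltaCt <- function(x) {
    need <- c("sample", "condition", "ct_target", "ct_reference")
    if (!all(need %in% colnames(x)))
        stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
    if (anyNA(x$ct_reference) || anyNA(x$ct_target))
        stop("missing Ct value", call. = FALSE)
    ctrl <- x$condition == "control"
    if (!any(ctrl))
        stop("need at least one control sample", call. = FALSE)
    dct <- x$ct_reference - x$ct_target
    rel <- 2^dct / mean(2^dct[ctrl])
    x$delta_ct <- dct
    x$rel_expression <- rel
    x
}
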