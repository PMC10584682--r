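#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom IRanges SimpleRleList
NULL

#' Accessors for broadH3K4 classes
#'
#' Small accessor generics: `coverageData()` returns the per-chromosome
#' `RleList` of a [CoverageTrack-class]; `totalMappedReads()` its library
#' size; `breadthData()` the per-gene `DataFrame` of a
#' [BreadthTable-class]; `geneGroups()` a named factor of group labels;
#' `profileMatrix()` the groups-by-bins matrix of a [Metaprofile-class];
#' `groupSizes()` the genes per group; `vennCounts()` the three Venn
#' counts of an [IntegrationSummary-class] and `composition()` its
#' breadth-group composition table.
#'
#' @param x An object of the documented class.
#' @return See the individual descriptions above.
#' @examples
#' bt <- BreadthTable(c("a", "b", "c", "d"), c(400, 30, 2000, 900))
#' breadthData(classifyBreadth(bt, AnalysisConfig()))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coverageData", function(x) standardGeneric("coverageData"))

#' @rdname accessors
#' @export
setGeneric("totalMappedReads", function(x) standardGeneric("totalMappedReads"))

#' @rdname accessors
#' @export
setGeneric("breadthData", function(x) standardGeneric("breadthData"))

#' @rdname accessors
#' @export
setGeneric("geneGroups", function(x) standardGeneric("geneGroups"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname accessors
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' @rdname accessors
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' @rdname accessors
#' @export
setMethod("coverageData", "CoverageTrack", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("totalMappedReads", "CoverageTrack", function(x) x@totalMappedReads)

#' @rdname accessors
#' @export
setMethod("breadthData", "BreadthTable", function(x) x@tab)

#' @rdname accessors
#' @export
setMethod("geneGroups", "BreadthTable", function(x) {
    stats::setNames(factor(x@tab$group, levels = c("broad", "medium", "narrow")),
                    x@tab$gene_id)
})

#' @rdname accessors
#' @export
setMethod("profileMatrix", "Metaprofile", function(x) x@profile)

#' @rdname accessors
#' @export
setMethod("groupSizes", "Metaprofile", function(x) x@nGenes)

#' @rdname accessors
#' @export
setMethod("vennCounts", "IntegrationSummary", function(x) {
    c(reduced_peaks = x@nReducedPeaks,
      reduced_expression = x@nReducedExpression,
      overlap = x@nOverlap)
})

#' @rdname accessors
#' @export
setMethod("composition", "IntegrationSummary", function(x) x@composition)

#' @rdname accessors
#' @export
setMethod("groupSizes", "BreadthTable", function(x) {
    grp <- x@tab$group
    c(broad = sum(grp == "broad", na.rm = TRUE),
      medium = sum(grp == "medium", na.rm = TRUE),
      narrow = sum(grp == "narrow", na.rm = TRUE))
})
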