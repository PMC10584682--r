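#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## SynthConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic-data generator
#'
#' `SynthConfig` holds every parameter of the synthetic genome, peak,
#' coverage and count simulation.  All randomness in the generator flows
#' from `seed`; two runs with identical configurations are bit-identical.
#'
#' @slot seed Integer seed for all generator randomness.
#' @slot nGenes Number of genes to place.
#' @slot nChroms Number of chromosomes.
#' @slot geneLengthRange Length-2 numeric, min/max gene length in bp.
#' @slot chromLength Chromosome length in bp, or `NA` to size each
#'   chromosome to fit its genes.
#' @slot identityFraction Fraction of genes designated "identity" genes,
#'   which carry broad H3K4me3 domains.
#' @slot breadthMeanlogBroad,breadthSdlogBroad Log-space location/scale of
#'   the log-normal breadth distribution for identity genes (bp).
#' @slot breadthMeanlogNarrow,breadthSdlogNarrow Log-normal parameters for
#'   all other genes (bp).
#' @slot downstreamAllowance Maximum distance (bp) a domain may extend past
#'   the transcription end site before being truncated.
#' @slot fragmentDomains Logical; when `TRUE` each domain is split into up
#'   to `maxFragments` sub-peaks separated by `fragmentGap` bp gaps, to
#'   exercise interval merging downstream.
#' @slot maxFragments,fragmentGap Fragmentation geometry (count, bp).
#' @slot expressionCouplingSlope d(log2 mean count) / d(log10 breadth):
#'   how strongly expression is coupled to domain breadth.
#' @slot baseMeanCount Expected counts at the 1 kb reference breadth.
#' @slot nbDispersion Negative-binomial dispersion theta
#'   (variance = mu + mu^2/theta).
#' @slot nReplicates Replicates per condition in simulated count matrices.
#' @slot plantedFraction Fraction of identity genes receiving the mutant
#'   effect (breadth shrink plus expression reduction).
#' @slot breadthReductionFactor Multiplicative breadth shrink in the
#'   mutant, in (0, 1).
#' @slot bodyBias Fraction of the lost breadth removed from the
#'   TES-proximal (gene-body) end of the domain; 1 means all loss is
#'   inside the gene body.
#' @slot expressionReductionLog2FC Planted log2 fold change of expression
#'   for affected genes (mutant vs control).
#' @slot coverageDepth Expected per-base read depth inside peaks; the
#'   background outside peaks is 2 percent of this.
#' @slot readLength Read length in bp; coverage is Poisson-sampled per
#'   `readLength`-sized bin.
#'
#' @seealso [simulateGenome()], [simulatePeaks()], [simulateCoverage()],
#'   [simulateCounts()], [simulatePeakCounts()]
#' @export
setClass("SynthConfig",
    representation(
        seed = "integer",
        nGenes = "integer",
        nChroms = "integer",
        geneLengthRange = "numeric",
        chromLength = "numeric",
        identityFraction = "numeric",
        breadthMeanlogBroad = "numeric",
        breadthSdlogBroad = "numeric",
        breadthMeanlogNarrow = "numeric",
        breadthSdlogNarrow = "numeric",
        downstreamAllowance = "numeric",
        fragmentDomains = "logical",
        maxFragments = "integer",
        fragmentGap = "numeric",
        expressionCouplingSlope = "numeric",
        baseMeanCount = "numeric",
        nbDispersion = "numeric",
        nReplicates = "integer",
        plantedFraction = "numeric",
        breadthReductionFactor = "numeric",
        bodyBias = "numeric",
        expressionReductionLog2FC = "numeric",
        coverageDepth = "numeric",
        readLength = "integer"
    ),
    prototype(
        seed = 1234L,
        nGenes = 800L,
        nChroms = 4L,
        geneLengthRange = c(5000, 60000),
        chromLength = NA_real_,
        identityFraction = 0.25,
        breadthMeanlogBroad = log(20000),
        breadthSdlogBroad = 0.8,
        breadthMeanlogNarrow = log(1000),
        breadthSdlogNarrow = 0.7,
        downstreamAllowance = 20000,
        fragmentDomains = FALSE,
        maxFragments = 3L,
        fragmentGap = 200,
        expressionCouplingSlope = 2,
        baseMeanCount = 500,
        nbDispersion = 100,
        nReplicates = 3L,
        plantedFraction = 0.3,
        breadthReductionFactor = 0.5,
        bodyBias = 1,
        expressionReductionLog2FC = -1,
        coverageDepth = 10,
        readLength = 50L
    )
)

setValidity("SynthConfig", function(object) {
    msg <- NULL
    fr <- c(identityFraction = object@identityFraction,
            plantedFraction = object@plantedFraction,
            bodyBias = object@bodyBias)
    bad <- fr < 0 | fr > 1
    if (any(bad))
        msg <- c(msg, paste0(names(fr)[bad][1L], " must be in [0, 1]"))
    if (object@breadthReductionFactor <= 0 || object@breadthReductionFactor >= 1)
        msg <- c(msg, "breadthReductionFactor must be in (0, 1)")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion (theta) must be > 0")
    if (object@coverageDepth <= 0)
        msg <- c(msg, "coverageDepth must be > 0")
    if (object@readLength < 1L)
        msg <- c(msg, "readLength must be >= 1")
    if (length(object@geneLengthRange) != 2L ||
        any(object@geneLengthRange < 1) ||
        diff(object@geneLengthRange) < 0)
        msg <- c(msg, "geneLengthRange must be an increasing pair of lengths")
    if (object@nGenes < 0L || object@nChroms < 1L)
        msg <- c(msg, "nGenes must be >= 0 and nChroms >= 1")
    if (object@nReplicates < 1L)
        msg <- c(msg, "nReplicates must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Create a synthetic-data configuration
#'
#' Constructs a [SynthConfig-class] object.  Arguments override the
#' defaults documented there; everything else keeps its default.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param ... Named slot overrides, e.g. `nGenes = 200`,
#'   `plantedFraction = 0`.
#' @return A validated `SynthConfig` object.
#' @examples
#' cfg <- SynthConfig(seed = 7, nGenes = 50L)
#' cfg
#' @export
SynthConfig <- function(seed = 1234L, ...) {
    args <- list(...)
    intSlots <- c("nGenes", "nChroms", "maxFragments", "nReplicates",
                  "readLength")
    for (s in intersect(names(args), intSlots))
        args[[s]] <- as.integer(args[[s]])
    do.call(new, c(list("SynthConfig", seed = as.integer(seed)), args))
}

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig | seed", object@seed, "|", object@nGenes, "genes on",
        object@nChroms, "chromosome(s)\n")
    cat("  identity fraction", object@identityFraction,
        "| planted fraction", object@plantedFraction,
        "| breadth shrink", object@breadthReductionFactor,
        "| body bias", object@bodyBias, "\n")
    cat("  NB(mu, theta =", object@nbDispersion, "), base mean",
        object@baseMeanCount, ",", object@nReplicates,
        "replicates/condition\n")
})

## ---------------------------------------------------------------------------
## AnalysisConfig
## ---------------------------------------------------------------------------

#' Analysis parameters
#'
#' Tunable parameters of the breadth, metaprofile, differential and
#' integration stages.
#'
#' @slot promoterUpstream Promoter window extension upstream of the TSS
#'   (bp) used when assigning peaks to genes.
#' @slot quartileLow,quartileHigh Quantile cuts of the breadth ranking;
#'   the top `quartileLow` fraction of genes is "broad", the bottom
#'   `quartileLow` fraction "narrow", the rest "medium".
#' @slot deAlpha Significance threshold on the per-feature P value.
#' @slot fcUp,fcDown Fold-change thresholds of the volcano rule
#'   (strictly above `fcUp` or strictly below `fcDown`).
#' @slot flankBp,flankBinBp Metaprofile flank extent and fixed bin width
#'   (bp).
#' @slot nBodyBins Number of length-scaled bins across the gene body.
#' @slot fdrMode Logical; when `TRUE`, differential calls use
#'   Benjamini-Hochberg adjusted P values instead of raw P values.
#' @export
setClass("AnalysisConfig",
    representation(
        promoterUpstream = "numeric",
        quartileLow = "numeric",
        quartileHigh = "numeric",
        deAlpha = "numeric",
        fcUp = "numeric",
        fcDown = "numeric",
        flankBp = "numeric",
        flankBinBp = "numeric",
        nBodyBins = "integer",
        fdrMode = "logical"
    ),
    prototype(
        promoterUpstream = 2000,
        quartileLow = 0.25,
        quartileHigh = 0.75,
        deAlpha = 0.05,
        fcUp = 2,
        fcDown = 0.5,
        flankBp = 2000,
        flankBinBp = 50,
        nBodyBins = 100L,
        fdrMode = FALSE
    )
)

setValidity("AnalysisConfig", function(object) {
    msg <- NULL
    if (!(object@quartileLow > 0 && object@quartileLow < object@quartileHigh &&
          object@quartileHigh < 1))
        msg <- c(msg, "need 0 < quartileLow < quartileHigh < 1")
    if (object@deAlpha <= 0 || object@deAlpha >= 1)
        msg <- c(msg, "deAlpha must be in (0, 1)")
    if (object@fcUp <= 1 || object@fcDown >= 1 || object@fcDown <= 0)
        msg <- c(msg, "need fcDown < 1 < fcUp with fcDown > 0")
    if (object@flankBp <= 0 || object@flankBinBp <= 0 ||
        object@flankBp %% object@flankBinBp != 0)
        msg <- c(msg, "flankBp must be a positive multiple of flankBinBp")
    if (object@nBodyBins < 1L)
        msg <- c(msg, "nBodyBins must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Create an analysis configuration
#'
#' @param ... Named slot overrides of [AnalysisConfig-class] defaults,
#'   e.g. `deAlpha = 0.01`.
#' @return A validated `AnalysisConfig` object.
#' @examples
#' AnalysisConfig(promoterUpstream = 1000)
#' @export
AnalysisConfig <- function(...) {
    args <- list(...)
    if ("nBodyBins" %in% names(args))
        args$nBodyBins <- as.integer(args$nBodyBins)
    do.call(new, c(list("AnalysisConfig"), args))
}

setMethod("show", "AnalysisConfig", function(object) {
    cat("AnalysisConfig | promoter -", object@promoterUpstream,
        "bp | quartiles", object@quartileLow, "/", object@quartileHigh, "\n")
    cat("  alpha", object@deAlpha, "| FC thresholds >", object@fcUp,
        "or <", object@fcDown, if (object@fdrMode) "| BH-FDR on" else "", "\n")
    cat("  metaprofile: +/-", object@flankBp, "bp flank in",
        object@flankBinBp, "bp bins,", object@nBodyBins, "body bins\n")
})

## ---------------------------------------------------------------------------
## CoverageTrack
## ---------------------------------------------------------------------------

#' Stepwise per-base coverage with a library size
#'
#' A `CoverageTrack` couples a per-chromosome run-length encoded signal
#' (an [IRanges::RleList]) with the total number of mapped reads of the
#' library it came from, which is what reads-per-million scaling needs
#' (coverage mass alone depends on read length, so the read count is an
#' explicit input, never inferred).
#'
#' @slot coverage A `SimpleRleList`, one numeric [S4Vectors::Rle] per
#'   chromosome; values are finite and non-negative.
#' @slot totalMappedReads Positive number of mapped reads in the library.
#'
#' @seealso [readBedGraph()], [rpmScale()], [geneProfile()]
#' @export
setClass("CoverageTrack",
    representation(coverage = "SimpleRleList", totalMappedReads = "numeric"))

setValidity("CoverageTrack", function(object) {
    msg <- NULL
    if (length(object@totalMappedReads) != 1L ||
        !is.finite(object@totalMappedReads) || object@totalMappedReads <= 0)
        msg <- c(msg, "totalMappedReads must be a single positive number")
    for (chr in names(object@coverage)) {
        v <- S4Vectors::runValue(object@coverage[[chr]])
        if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
            msg <- c(msg, paste0("coverage on ", chr,
                                 " has negative or non-finite values"))
            break
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a CoverageTrack
#'
#' @param coverage An `RleList` (or coercible list of `Rle`) of per-base
#'   signal, one element per chromosome.
#' @param totalMappedReads Total mapped reads of the library.
#' @return A `CoverageTrack`.
#' @examples
#' cov <- IRanges::RleList(chr1 = S4Vectors::Rle(c(0, 2, 0), c(100, 50, 100)))
#' CoverageTrack(cov, totalMappedReads = 1e6)
#' @export
CoverageTrack <- function(coverage, totalMappedReads) {
    new("CoverageTrack", coverage = methods::as(coverage, "SimpleRleList"),
        totalMappedReads = as.numeric(totalMappedReads))
}

setMethod("show", "CoverageTrack", function(object) {
    nstep <- sum(vapply(object@coverage,
                        function(r) length(S4Vectors::runValue(r)), 1L))
    cat("CoverageTrack |", length(object@coverage), "chromosome(s),",
        nstep, "steps |", format(object@totalMappedReads, big.mark = ","),
        "mapped reads\n")
})

## ---------------------------------------------------------------------------
## BreadthTable
## ---------------------------------------------------------------------------

#' Per-gene H3K4me3 breadth and group assignment
#'
#' One row per gene with the merged peak span assigned to it (`breadth`,
#' bp), its rank (1 = broadest) and its `broad`/`medium`/`narrow` group.
#' Rank and group are `NA` until [classifyBreadth()] fills them.
#'
#' @slot tab A [S4Vectors::DataFrame] with columns `gene_id`, `breadth`,
#'   `rank`, `group`.
#' @seealso [geneBreadth()], [classifyBreadth()]
#' @export
setClass("BreadthTable", representation(tab = "DFrame"))

setValidity("BreadthTable", function(object) {
    tab <- object@tab
    need <- c("gene_id", "breadth", "rank", "group")
    if (!all(need %in% colnames(tab)))
        return(paste("missing columns:",
                     paste(setdiff(need, colnames(tab)), collapse = ", ")))
    if (anyDuplicated(tab$gene_id))
        return("duplicated gene_id")
    if (any(tab$breadth < 0))
        return("negative breadth")
    grp <- tab$group
    if (!all(is.na(grp) | grp %in% c("broad", "medium", "narrow")))
        return("group must be broad/medium/narrow or NA")
    if (!anyNA(grp) && nrow(tab) > 0L) {
        ## ordering: every broad breadth >= every medium >= every narrow
        if (sum(grp == "medium") &&
            ((sum(grp == "broad") &&
              min(tab$breadth[grp == "broad"]) < max(tab$breadth[grp == "medium"])) ||
             (sum(grp == "narrow") &&
              min(tab$breadth[grp == "medium"]) < max(tab$breadth[grp == "narrow"]))))
            return("group breadths out of order")
    }
    TRUE
})

#' Construct a BreadthTable
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param breadth Non-negative numeric breadths (bp), parallel to
#'   `gene_id`.
#' @param rank,group Optional rank and group columns; left `NA` for an
#'   unclassified table (see [classifyBreadth()]).
#' @return A `BreadthTable`.
#' @examples
#' bt <- BreadthTable(paste0("g", 1:8), c(50000, 200, 9000, 4e4, 120, 3e3, 70, 800))
#' classifyBreadth(bt, AnalysisConfig())
#' @export
BreadthTable <- function(gene_id, breadth, rank = NA_integer_, group = NA_character_) {
    new("BreadthTable", tab = DataFrame(
        gene_id = as.character(gene_id),
        breadth = as.numeric(breadth),
        rank = as.integer(rank),
        group = as.character(group)))
}

setMethod("show", "BreadthTable", function(object) {
    tab <- object@tab
    cat("BreadthTable |", nrow(tab), "genes")
    if (!anyNA(tab$group) && nrow(tab) > 0L) {
        n <- table(factor(tab$group, c("broad", "medium", "narrow")))
        cat(" | broad", n[["broad"]], "medium", n[["medium"]],
            "narrow", n[["narrow"]])
    } else cat(" (unclassified)")
    cat("\n")
    if (nrow(tab)) print(utils::head(as.data.frame(tab), 5L))
})

## ---------------------------------------------------------------------------
## Metaprofile
## ---------------------------------------------------------------------------

#' Group-mean metagene coverage profile
#'
#' Mean RPM per bin across genes, per breadth group, over a fixed
#' upstream flank, a length-scaled gene body (TSS to TES) and a fixed
#' downstream flank.
#'
#' @slot profile Numeric matrix, groups x bins.
#' @slot nGenes Named integer; genes contributing per group.
#' @slot binType Character, one of `upstream`/`body`/`downstream` per bin.
#' @slot binLabel Character bin labels (flank offsets in bp, body
#'   percentages).
#' @seealso [groupMetaprofile()]
#' @export
setClass("Metaprofile",
    representation(profile = "matrix", nGenes = "integer",
                   binType = "character", binLabel = "character"))

setValidity("Metaprofile", function(object) {
    if (ncol(object@profile) != length(object@binType) ||
        ncol(object@profile) != length(object@binLabel))
        return("bin annotation length disagrees with profile columns")
    v <- object@profile[is.finite(object@profile)]
    if (length(v) && any(v < 0))
        return("profile values must be >= 0")
    if (!identical(sort(rownames(object@profile)), sort(names(object@nGenes))))
        return("nGenes names must match profile rows")
    TRUE
})

setMethod("show", "Metaprofile", function(object) {
    cat("Metaprofile |", nrow(object@profile), "group(s) x",
        ncol(object@profile), "bins (",
        sum(object@binType == "upstream"), "up /",
        sum(object@binType == "body"), "body /",
        sum(object@binType == "downstream"), "down )\n")
    for (g in rownames(object@profile))
        cat("  ", g, ": n =", object@nGenes[[g]], ", mean RPM =",
            signif(mean(object@profile[g, ], na.rm = TRUE), 4L), "\n")
})

## ---------------------------------------------------------------------------
## IntegrationSummary
## ---------------------------------------------------------------------------

#' Venn counts and breadth-group composition of an overlap
#'
#' Summary of the intersection between genes with reduced H3K4me3 signal
#' and genes with reduced expression: the Venn counts, the overlap as a
#' percentage of reduced-H3K4me3 genes (1 decimal), and the
#' broad/medium/narrow composition of the overlap (percents to
#' 2 decimals).
#'
#' @slot nReducedPeaks,nReducedExpression,nOverlap Venn counts.
#' @slot pctOverlap Overlap as percent of reduced-H3K4me3 genes.
#' @slot composition [S4Vectors::DataFrame] with columns `group`,
#'   `count`, `percent`.
#' @seealso [overlapSummary()]
#' @export
setClass("IntegrationSummary",
    representation(nReducedPeaks = "integer", nReducedExpression = "integer",
                   nOverlap = "integer", pctOverlap = "numeric",
                   composition = "DFrame"))

setValidity("IntegrationSummary", function(object) {
    msg <- NULL
    if (object@nOverlap > min(object@nReducedPeaks, object@nReducedExpression))
        msg <- c(msg, "overlap larger than an input set")
    if (sum(object@composition$count) != object@nOverlap)
        msg <- c(msg, "composition counts must sum to the overlap")
    if (object@nOverlap > 0L &&
        abs(sum(object@composition$percent) - 100) > 0.02)
        msg <- c(msg, "composition percents must sum to 100 (within rounding)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "IntegrationSummary", function(object) {
    cat("IntegrationSummary | reduced H3K4me3:", object@nReducedPeaks,
        "| reduced expression:", object@nReducedExpression,
        "| overlap:", object@nOverlap,
        sprintf("(%.1f%% of reduced H3K4me3)\n", object@pctOverlap))
    comp <- as.data.frame(object@composition)
    for (i in seq_len(nrow(comp)))
        cat(sprintf("   %-7s %5d  (%.2f%%)\n", comp$group[i],
                    comp$count[i], comp$percent[i]))
})
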