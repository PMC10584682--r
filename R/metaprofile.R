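## RPM scaling and strand-oriented, length-scaled TSS->TES metagene
## coverage profiles.

#' Scale a coverage track to reads per million mapped reads
#'
#' Multiplies every value by `1e6 / totalMappedReads`.  The library size
#' is kept on the returned track, so applying the scale twice compounds
#' it; scale once, after reading.
#'
#' @param track A [CoverageTrack-class].
#' @return A [CoverageTrack-class] in RPM units.
#' @export
rpmScale <- function(track) {
    total <- totalMappedReads(track)
    if (!is.finite(total) || total <= 0)
        stop("totalMappedReads must be > 0", call. = FALSE)
    scaled <- methods::as(lapply(coverageData(track),
                                 function(r) r * (1e6 / total)),
                          "SimpleRleList")
    CoverageTrack(scaled, total)
}

## Per-base values for positions from:to on one chromosome. Positions
## before base 1 or past the chromosome end are NA (unavailable);
## positions inside the chromosome but past the last run are 0.
.baseValues <- function(rle, from, to, chromLen = length(rle)) {
    npos <- to - from + 1L
    out <- rep(NA_real_, npos)
    lo <- max(from, 1L)
    hi <- min(to, chromLen)
    if (hi >= lo) {
        hiRun <- min(hi, length(rle))
        vals <- if (hiRun >= lo)
            as.numeric(S4Vectors::window(rle, lo, hiRun)) else numeric(0)
        if (hi > hiRun) vals <- c(vals, rep(0, hi - hiRun))
        out[(lo - from + 1L):(hi - from + 1L)] <- vals
    }
    out
}

## mean of consecutive fixed-width bins, NA-aware (truncated flank bins
## average over their available bases)
.fixedBinMeans <- function(v, binWidth) {
    nb <- length(v) %/% binWidth
    m <- matrix(v, nrow = binWidth, ncol = nb)
    ok <- colSums(!is.na(m))
    s <- colSums(m, na.rm = TRUE)
    ifelse(ok > 0, s / ok, NA_real_)
}

## mean of nBins equal fractional-width bins across v (no NAs expected):
## bin i covers (L*(i-1)/n, L*i/n] in continuous coordinates, with
## fractional bases weighted proportionally
.scaledBinMeans <- function(v, nBins) {
    L <- length(v)
    cum <- c(0, cumsum(v))
    S <- function(x) {
        i0 <- floor(x)
        frac <- x - i0
        cum[i0 + 1] + ifelse(frac > 0, frac * v[pmin(i0 + 1, L)], 0)
    }
    edges <- L * (0:nBins) / nBins
    diff(S(edges)) / diff(edges)
}

#' Scaled metagene profile of one gene
#'
#' Bins the coverage around a gene into a fixed-width upstream flank
#' (`flankBp` in `flankBinBp` bins), a length-scaled gene body
#' (`nBodyBins` equal fractional-width bins from TSS to TES, fractional
#' bases weighted proportionally) and a fixed-width downstream flank.
#' Each bin is the mean per-base signal within it.  Minus-strand genes
#' are reported 5'->3', so bin 1 is always the far upstream flank.
#' Flank bins reaching past a chromosome edge average over their
#' available bases (`NA` when fully outside).
#'
#' @param gene A length-1 `GRanges` gene model.
#' @param track A [CoverageTrack-class] (typically RPM-scaled).
#' @param config An [AnalysisConfig-class].
#' @return Named numeric vector of bin means, length
#'   `2 * flankBp / flankBinBp + nBodyBins`.
#' @seealso [groupMetaprofile()]
#' @export
geneProfile <- function(gene, track, config = AnalysisConfig()) {
    if (length(gene) != 1L)
        stop("gene must be a single range", call. = FALSE)
    if (GenomicRanges::width(gene) < 1L)
        stop("gene length must be >= 1 bp", call. = FALSE)
    chr <- as.character(seqnames(gene))
    cov <- coverageData(track)
    rle <- if (chr %in% names(cov)) cov[[chr]] else Rle(0, 0)
    chromLen <- length(rle)
    s <- GenomicRanges::start(gene)
    e <- GenomicRanges::end(gene)
    minus <- as.character(strand(gene)) == "-"
    flank <- config@flankBp
    body <- .baseValues(rle, s, e, chromLen)
    if (minus) {
        up <- rev(.baseValues(rle, e + 1L, e + flank, chromLen))
        down <- rev(.baseValues(rle, s - flank, s - 1L, chromLen))
        body <- rev(body)
    } else {
        up <- .baseValues(rle, s - flank, s - 1L, chromLen)
        down <- .baseValues(rle, e + 1L, e + flank, chromLen)
    }
    body[is.na(body)] <- 0  # gene bodies are expected inside the chromosome
    prof <- c(.fixedBinMeans(up, config@flankBinBp),
              .scaledBinMeans(body, config@nBodyBins),
              .fixedBinMeans(down, config@flankBinBp))
    names(prof) <- .binLabels(config)$label
    prof
}

.binLabels <- function(config) {
    nf <- as.integer(config@flankBp / config@flankBinBp)
    nb <- config@nBodyBins
    list(
        type = c(rep("upstream", nf), rep("body", nb), rep("downstream", nf)),
        label = c(sprintf("up:%d", -config@flankBp +
                              config@flankBinBp * (seq_len(nf) - 1L)),
                  sprintf("body:%d", seq_len(nb)),
                  sprintf("down:+%d", config@flankBinBp * (seq_len(nf) - 1L))))
}

#' Group-mean metagene profiles
#'
#' Computes [geneProfile()] for every classified gene and averages the
#' vectors (unweighted, `NA`-aware) within each breadth group.
#'
#' @param genes Gene models (`GRanges` with `gene_id`) covering every
#'   classified gene.
#' @param groups A classified [BreadthTable-class].
#' @param track A [CoverageTrack-class] (typically RPM-scaled).
#' @param config An [AnalysisConfig-class].
#' @return A [Metaprofile-class].
#' @export
groupMetaprofile <- function(genes, groups, track, config = AnalysisConfig()) {
    grp <- geneGroups(groups)
    if (anyNA(grp))
        stop("groups must be a classified BreadthTable", call. = FALSE)
    missing <- setdiff(names(grp), genes$gene_id)
    if (length(missing))
        stop("classified gene(s) absent from gene models: ",
             paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
    labs <- .binLabels(config)
    lev <- levels(grp)
    nBins <- length(labs$type)
    prof <- matrix(NA_real_, nrow = length(lev), ncol = nBins,
                   dimnames = list(lev, labs$label))
    nGenes <- setNames(integer(length(lev)), lev)
    idx <- setNames(seq_along(genes), genes$gene_id)
    for (g in lev) {
        ids <- names(grp)[grp == g]
        if (length(ids) == 0L)
            stop("empty breadth group: ", g, call. = FALSE)
        acc <- matrix(NA_real_, nrow = length(ids), ncol = nBins)
        for (k in seq_along(ids))
            acc[k, ] <- geneProfile(genes[idx[[ids[k]]]], track, config)
        prof[g, ] <- colMeans(acc, na.rm = TRUE)
        nGenes[[g]] <- length(ids)
    }
    prof[is.nan(prof)] <- NA_real_
    new("Metaprofile", profile = prof, nGenes = nGenes,
        binType = labs$type, binLabel = labs$label)
}

#' Write a metaprofile as TSV
#'
#' Long format: one row per group and bin with the bin label, bin type,
#' mean RPM and group size.
#'
#' @param mp A [Metaprofile-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMetaprofile <- function(mp, path) {
    m <- profileMatrix(mp)
    df <- data.frame(
        group = rep(rownames(m), each = ncol(m)),
        bin = rep(mp@binLabel, nrow(m)),
        bin_type = rep(mp@binType, nrow(m)),
        mean_rpm = as.vector(t(m)),
        n_genes = rep(groupSizes(mp)[rownames(m)], each = ncol(m)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
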