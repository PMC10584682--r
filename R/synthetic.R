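## Synthetic genomes, H3K4me3 domains, coverage and count matrices with
## known ground truth.  Every function seeds its own stream from
## config@seed plus a fixed stage offset, so outputs are bit-reproducible
## for a given SynthConfig and independent of call order.

#' @importFrom stats rlnorm rnbinom rpois runif setNames median
NULL

.seedOffset <- c(genome = 11L, peaks = 23L, coverage = 37L, counts = 53L,
                 peakCounts = 71L)

## gaps between adjacent genes (bp); kept >= 10 kb so that domains with
## the default downstream allowance cannot reach the next gene body far
## enough to win the largest-overlap assignment
.gapRange <- c(15000, 25000)

#' Simulate a toy annotated genome
#'
#' Places `nGenes` non-overlapping genes across `nChroms` chromosomes
#' with inter-gene gaps of 15-25 kb (always >= 10 kb), gene lengths
#' uniform in `geneLengthRange`, and strands alternating `+`/`-`
#' deterministically.  Chromosome lengths are recorded as `seqlengths`;
#' when `chromLength` is set, genes that do not fit raise an error.
#'
#' @param config A [SynthConfig-class].
#' @return A `GRanges` of gene models with a `gene_id` column and
#'   seqlengths set.
#' @examples
#' genes <- simulateGenome(SynthConfig(seed = 1, nGenes = 10L))
#' genes
#' @export
simulateGenome <- function(config) {
    methods::validObject(config)
    set.seed(config@seed + .seedOffset[["genome"]])
    n <- config@nGenes
    chroms <- paste0("chr", seq_len(config@nChroms))
    if (n == 0L) {
        gr <- GRanges(gene_id = character(0))
        return(gr)
    }
    lens <- round(runif(n, config@geneLengthRange[1L],
                        config@geneLengthRange[2L]))
    gaps <- round(runif(n, .gapRange[1L], .gapRange[2L]))
    chromOf <- sort(rep_len(seq_len(config@nChroms), n))
    start <- integer(n)
    ## leading margin so that domains extending past the TES of the first
    ## (possibly minus-strand) gene never run off the chromosome start
    pos <- setNames(rep(.gapRange[2L], config@nChroms), chroms)
    for (i in seq_len(n)) {
        chr <- chroms[chromOf[i]]
        start[i] <- pos[[chr]] + gaps[i] + 1
        pos[[chr]] <- start[i] + lens[i] - 1
    }
    if (!is.na(config@chromLength)) {
        over <- pos + .gapRange[1L] > config@chromLength
        if (any(over))
            stop("chromosome too small to place genes with the required ",
                 "gaps (need ", max(pos + .gapRange[1L]), " bp on ",
                 names(pos)[over][1L], ")", call. = FALSE)
        seqlen <- setNames(rep(config@chromLength, config@nChroms), chroms)
    } else {
        seqlen <- pos + .gapRange[1L]
    }
    gr <- GRanges(chroms[chromOf], IRanges(start, width = lens),
                  strand = rep_len(c("+", "-"), n),
                  gene_id = sprintf("g%04d", seq_len(n)),
                  seqlengths = seqlen)
    gr
}

## place one domain for gene i; returns start/end of the contiguous span
.domainSpan <- function(tss, tes, strandPlus, breadth) {
    if (strandPlus) c(tss, tss + breadth - 1) else c(tss - breadth + 1, tss)
}

#' Simulate H3K4me3 domains with planted mutant effects
#'
#' Each gene receives one H3K4me3 domain anchored at its TSS and
#' extending into the gene body, with breadth drawn log-normally:
#' identity genes from the broad distribution (right tail beyond 40 kb),
#' all others from the narrow one.  Breadths exceeding the gene span plus
#' `downstreamAllowance` are truncated and flagged.  A planted subset of
#' identity genes shrinks in the mutant by `breadthReductionFactor`, with
#' `bodyBias` of the lost span removed from the TES-proximal (gene body)
#' end, and carries `expressionReductionLog2FC` into the count
#' simulation.  With `fragmentDomains = TRUE` each domain is emitted as
#' up to `maxFragments` sub-peaks separated by `fragmentGap` bp gaps.
#'
#' @param genes Non-overlapping gene models from [simulateGenome()].
#' @param config A [SynthConfig-class].
#' @return A list with elements `control` and `mutant` (peak `GRanges`
#'   with `name` and `score` columns) and `truth`, a
#'   [S4Vectors::DataFrame] with per-gene columns `gene_id`,
#'   `is_identity`, `drawn_breadth` (the raw log-normal draw),
#'   `true_breadth_control`/`true_breadth_mutant` (realized contiguous
#'   spans), `truncated`, `n_fragments`, `is_planted`,
#'   `true_log2fc_expression`.
#' @examples
#' cfg <- SynthConfig(seed = 3, nGenes = 20L)
#' sim <- simulatePeaks(simulateGenome(cfg), cfg)
#' sim$truth[1:3, ]
#' @export
simulatePeaks <- function(genes, config) {
    methods::validObject(config)
    set.seed(config@seed + .seedOffset[["peaks"]])
    n <- length(genes)
    empty <- function() GRanges(name = character(0), score = numeric(0))
    if (n == 0L)
        return(list(control = empty(), mutant = empty(),
                    truth = DataFrame(gene_id = character(0))))
    nIdentity <- round(config@identityFraction * n)
    isIdentity <- logical(n)
    isIdentity[sample.int(n, nIdentity)] <- TRUE
    drawn <- numeric(n)
    drawn[isIdentity] <- rlnorm(nIdentity, config@breadthMeanlogBroad,
                                config@breadthSdlogBroad)
    drawn[!isIdentity] <- rlnorm(n - nIdentity, config@breadthMeanlogNarrow,
                                 config@breadthSdlogNarrow)
    drawn <- pmax(round(drawn), 50)
    cap <- GenomicRanges::width(genes) + config@downstreamAllowance
    bc <- pmin(drawn, cap)
    truncated <- drawn > cap
    isPlanted <- logical(n)
    idIdx <- which(isIdentity)
    nPlanted <- round(config@plantedFraction * length(idIdx))
    if (nPlanted > 0L)
        isPlanted[idIdx[sample.int(length(idIdx), nPlanted)]] <- TRUE
    bm <- bc
    bm[isPlanted] <- pmax(round(bc[isPlanted] * config@breadthReductionFactor),
                          50)
    loss <- bc - bm
    tesLoss <- round(config@bodyBias * loss)
    tssLoss <- loss - tesLoss

    tss <- tssPositions(genes)
    plus <- as.character(strand(genes)) == "+"
    ctrlStart <- ifelse(plus, tss, tss - bc + 1)
    ctrlEnd <- ifelse(plus, tss + bc - 1, tss)
    mutStart <- ifelse(plus, tss + tssLoss, tss - bc + 1 + tesLoss)
    mutEnd <- ifelse(plus, tss + bc - 1 - tesLoss, tss - tssLoss)

    nFragDrawn <- rep(1L, n)
    if (config@fragmentDomains)
        nFragDrawn <- sample.int(config@maxFragments, n, replace = TRUE)
    ## only fragment domains wide enough for k pieces of >= 100 bp each;
    ## the truth table records the fragment count actually emitted for the
    ## control domain
    fragOk <- function(w, k) k > 1L & w >= k * (config@fragmentGap + 100)
    nFrag <- ifelse(fragOk(bc, nFragDrawn), nFragDrawn, 1L)

    buildPeaks <- function(startv, endv) {
        pieces <- vector("list", n)
        for (i in seq_len(n)) {
            s <- startv[i]; e <- endv[i]
            w <- e - s + 1
            k <- if (fragOk(w, nFrag[i])) nFrag[i] else 1L
            gap <- config@fragmentGap
            if (k > 1L) {
                inner <- floor(seq(s, e + 1, length.out = k + 1L))
                ps <- inner[-(k + 1L)]
                pe <- inner[-1L] - 1L
                pe[-k] <- pe[-k] - gap
                pieces[[i]] <- data.frame(
                    start = ps, end = pe,
                    name = sprintf("%s_pk%d", genes$gene_id[i], seq_len(k)),
                    chrom = as.character(seqnames(genes))[i])
            } else {
                pieces[[i]] <- data.frame(
                    start = s, end = e,
                    name = paste0(genes$gene_id[i], "_pk1"),
                    chrom = as.character(seqnames(genes))[i])
            }
        }
        do.call(rbind, pieces)
    }
    ctrlDf <- buildPeaks(ctrlStart, ctrlEnd)
    mutDf <- buildPeaks(mutStart, mutEnd)
    ## widen seqlengths where a domain spills past the last gene
    sl <- seqlengths(genes)
    for (chr in names(sl)) {
        hi <- ctrlDf$end[ctrlDf$chrom == chr]
        if (length(hi)) sl[[chr]] <- max(sl[[chr]], max(hi) + 1)
    }
    toGR <- function(df)
        GRanges(df$chrom, IRanges(df$start, df$end), strand = "*",
                name = df$name, score = 0, seqlengths = sl)
    control <- toGR(ctrlDf)
    mutant <- toGR(mutDf)
    truth <- DataFrame(
        gene_id = genes$gene_id,
        is_identity = isIdentity,
        drawn_breadth = drawn,
        true_breadth_control = as.numeric(bc),
        true_breadth_mutant = as.numeric(bm),
        truncated = truncated,
        n_fragments = nFrag,
        is_planted = isPlanted,
        true_log2fc_expression = ifelse(isPlanted,
                                        config@expressionReductionLog2FC, 0))
    list(control = control, mutant = mutant, truth = truth)
}

#' Simulate a ChIP-seq coverage track over a peak set
#'
#' Expected per-base signal is `coverageDepth` inside peaks and 2 percent
#' of it outside (background).  Reads are Poisson-sampled per
#' `readLength`-sized bin with rate equal to the mean per-base depth over
#' the bin (so partial bins at peak edges get intermediate rates), and
#' the coverage value across a bin is its sampled read count.  The track
#' records the summed read count as `totalMappedReads`.
#'
#' @param peaks A peak `GRanges` with `seqlengths` set (see
#'   [simulatePeaks()]).
#' @param config A [SynthConfig-class].
#' @return A [CoverageTrack-class].
#' @export
simulateCoverage <- function(peaks, config) {
    methods::validObject(config)
    if (config@coverageDepth <= 0)
        stop("coverageDepth must be > 0", call. = FALSE)
    sl <- seqlengths(peaks)
    if (length(sl) == 0L || anyNA(sl))
        stop("peaks must carry seqlengths to simulate coverage over",
             call. = FALSE)
    set.seed(config@seed + .seedOffset[["coverage"]])
    bg <- 0.02 * config@coverageDepth
    rl <- config@readLength
    peakCov <- IRanges::coverage(GenomicRanges::reduce(peaks))
    covs <- list()
    total <- 0
    for (chr in names(sl)) {
        len <- sl[[chr]]
        nbins <- ceiling(len / rl)
        binW <- c(rep(rl, nbins - 1L), len - (nbins - 1L) * rl)
        pc <- if (chr %in% names(peakCov)) peakCov[[chr]] else Rle(0L, len)
        if (length(pc) < len) pc <- c(pc, Rle(0L, len - length(pc)))
        starts <- seq.int(1L, by = rl, length.out = nbins)
        frac <- IRanges::viewMeans(
            IRanges::Views(pc, IRanges(starts, width = binW)))
        lambda <- bg + (config@coverageDepth - bg) * frac
        reads <- rpois(nbins, lambda)
        covs[[chr]] <- Rle(as.numeric(reads), binW)
        total <- total + sum(reads)
    }
    if (total <= 0) total <- 1
    CoverageTrack(methods::as(covs, "SimpleRleList"), total)
}

.nbMeans <- function(truth, config) {
    muC <- config@baseMeanCount *
        2^(config@expressionCouplingSlope *
           log10(truth$true_breadth_control / 1000))
    muM <- muC * 2^truth$true_log2fc_expression
    list(control = muC, mutant = muM)
}

.countSE <- function(ids, muC, muM, config) {
    nr <- config@nReplicates
    theta <- config@nbDispersion
    n <- length(ids)
    drawCol <- function(mu) rnbinom(n, mu = mu, size = theta)
    m <- cbind(
        matrix(unlist(lapply(seq_len(nr), function(j) drawCol(muC))), ncol = nr),
        matrix(unlist(lapply(seq_len(nr), function(j) drawCol(muM))), ncol = nr))
    colnames(m) <- c(paste0("ctrl_", seq_len(nr)), paste0("mut_", seq_len(nr)))
    rownames(m) <- ids
    storage.mode(m) <- "integer"
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = DataFrame(
            condition = rep(c("control", "mutant"), each = nr),
            row.names = colnames(m)))
}

#' Simulate an RNA-seq count matrix coupled to domain breadth
#'
#' Control means follow the breadth-expression coupling
#' `mu = baseMeanCount * 2^(slope * log10(breadth / 1 kb))` on the true
#' control breadth; mutant means additionally carry each gene's planted
#' log2 fold change.  Counts are negative-binomial `NB(mu, theta)` with
#' `theta = nbDispersion`, `nReplicates` per condition.
#'
#' @param truth The `truth` table from [simulatePeaks()].
#' @param config A [SynthConfig-class].
#' @return A `SummarizedExperiment` (genes x samples) with assay
#'   `counts` and `condition` in `colData`.
#' @export
simulateCounts <- function(truth, config) {
    methods::validObject(config)
    if (config@nbDispersion <= 0)
        stop("nbDispersion (theta) must be > 0", call. = FALSE)
    set.seed(config@seed + .seedOffset[["counts"]])
    mu <- .nbMeans(truth, config)
    .countSE(truth$gene_id, mu$control, mu$mutant, config)
}

#' Simulate a per-domain ChIP signal count matrix
#'
#' Quantifies each gene's H3K4me3 domain as an NB count with mean
#' `breadth * coverageDepth / readLength` (the expected number of reads
#' in the domain) per condition, so the mutant-to-control signal ratio of
#' a planted domain tracks its breadth reduction.  Feature ids are
#' `<gene_id>_domain`.
#'
#' @param truth The `truth` table from [simulatePeaks()].
#' @param config A [SynthConfig-class].
#' @return A `SummarizedExperiment` (domains x samples) with assay
#'   `counts` and `condition` in `colData`.
#' @export
simulatePeakCounts <- function(truth, config) {
    methods::validObject(config)
    set.seed(config@seed + .seedOffset[["peakCounts"]])
    muC <- truth$true_breadth_control * config@coverageDepth / config@readLength
    muM <- truth$true_breadth_mutant * config@coverageDepth / config@readLength
    .countSE(paste0(truth$gene_id, "_domain"), muC, muM, config)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits GFF3 gene models, control/mutant narrowPeak files, control and
#' mutant bedGraph coverage (with read-count sidecars), gene and domain
#' count TSVs, the condition map and the ground-truth table.
#'
#' @param config A [SynthConfig-class].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the written file paths.
#' @export
writeSyntheticData <- function(config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    genes <- simulateGenome(config)
    sim <- simulatePeaks(genes, config)
    covC <- simulateCoverage(sim$control, config)
    covM <- simulateCoverage(sim$mutant, config)
    counts <- simulateCounts(sim$truth, config)
    peakCounts <- simulatePeakCounts(sim$truth, config)
    paths <- list(
        genes = file.path(dir, "genes.gff3"),
        peaks_control = file.path(dir, "peaks_control.narrowPeak"),
        peaks_mutant = file.path(dir, "peaks_mutant.narrowPeak"),
        coverage_control = file.path(dir, "coverage_control.bedGraph"),
        coverage_mutant = file.path(dir, "coverage_mutant.bedGraph"),
        counts = file.path(dir, "gene_counts.tsv"),
        peak_counts = file.path(dir, "domain_counts.tsv"),
        condition = file.path(dir, "conditions.tsv"),
        truth = file.path(dir, "truth.tsv"))
    writeGFF3Genes(genes, paths$genes)
    writePeaks(sim$control, paths$peaks_control, "narrowPeak")
    writePeaks(sim$mutant, paths$peaks_mutant, "narrowPeak")
    writeBedGraph(covC, paths$coverage_control)
    writeBedGraph(covM, paths$coverage_mutant)
    writeCounts(counts, paths$counts, paths$condition)
    ## gene and domain matrices share one condition map
    writeCounts(peakCounts, paths$peak_counts, paths$condition)
    write.table(as.data.frame(sim$truth), paths$truth, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(paths)
}
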