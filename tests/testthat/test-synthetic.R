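test_that("genome simulation is seeded, gap-respecting and overlap-free", {
    expect_length(simulateGenome(smallConfig(nGenes = 0L)), 0L)

    ## determinism
    g1 <- simulateGenome(smallConfig(nGenes = 2L))
    g2 <- simulateGenome(smallConfig(nGenes = 2L))
    expect_identical(GenomicRanges::ranges(g1), GenomicRanges::ranges(g2))

    ## brute-force all-pairs overlap check on 200 genes
    genes <- simulateGenome(smallConfig(seed = 5L, nGenes = 200L))
    n <- length(genes)
    chrom <- as.character(GenomicRanges::seqnames(genes))
    s <- GenomicRanges::start(genes); e <- GenomicRanges::end(genes)
    overlaps <- 0L
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
        if (chrom[i] == chrom[j] && s[i] <= e[j] && s[j] <= e[i])
            overlaps <- overlaps + 1L
    expect_identical(overlaps, 0L)

    ## gaps between neighbours on a chromosome are >= 10 kb
    for (chr in unique(chrom)) {
        idx <- which(chrom == chr)
        gaps <- s[idx][-1L] - e[idx][-length(idx)] - 1L
        expect_true(all(gaps >= 10000))
    }

    ## explicit chromosome length too small -> error
    expect_error(simulateGenome(smallConfig(nGenes = 50L, nChroms = 1L,
                                            chromLength = 1e5)),
                 "too small")
})

test_that("peak simulation anchors domains at the TSS and plants the shrink rule", {
    cfg <- smallConfig(seed = 11L)
    genes <- simulateGenome(cfg)
    sim <- simulatePeaks(genes, cfg)
    tss <- tssPositions(genes)
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    byGene <- split(seq_along(sim$control),
                    sub("_pk\\d+$", "", sim$control$name))[genes$gene_id]
    for (i in seq_along(genes)) {
        pk <- sim$control[byGene[[i]]]
        anchor <- if (plus[i]) min(GenomicRanges::start(pk))
                  else max(GenomicRanges::end(pk))
        expect_equal(anchor, unname(tss[i]))
    }

    ## null effect: no planting leaves the mutant identical
    cfg0 <- smallConfig(seed = 11L, plantedFraction = 0)
    sim0 <- simulatePeaks(simulateGenome(cfg0), cfg0)
    expect_identical(sim0$control, sim0$mutant)
    expect_true(all(sim0$truth$true_breadth_mutant ==
                    sim0$truth$true_breadth_control))
    expect_true(all(sim0$truth$true_log2fc_expression == 0))
    expect_false(any(sim0$truth$is_planted))

    ## planted genes are identity genes
    expect_true(all(sim$truth$is_identity[sim$truth$is_planted]))
})

test_that("breadth shrink removes the lost span from the TES-proximal end", {
    ## a 10 kb domain halved with bodyBias = 1: start fixed, end moves
    ## 5 kb toward the TSS (plus-strand gene)
    genes <- handGenes()[1]  # + strand, 10001-20000
    cfg <- smallConfig(breadthReductionFactor = 0.5, bodyBias = 1,
                       plantedFraction = 1, identityFraction = 1,
                       nGenes = 1L)
    ## force a deterministic 10 kb draw by a degenerate log-normal
    cfg@breadthMeanlogBroad <- log(10000)
    cfg@breadthSdlogBroad <- 1e-9
    sim <- simulatePeaks(genes, cfg)
    expect_equal(GenomicRanges::start(sim$mutant),
                 GenomicRanges::start(sim$control))
    expect_equal(GenomicRanges::end(sim$control) -
                 GenomicRanges::end(sim$mutant), 5000L)
    expect_equal(sim$truth$true_breadth_mutant, 5000)

    ## bodyBias = 0 moves the TSS-proximal end instead
    cfg@bodyBias <- 0
    sim2 <- simulatePeaks(genes, cfg)
    expect_equal(GenomicRanges::end(sim2$mutant),
                 GenomicRanges::end(sim2$control))
    expect_equal(GenomicRanges::start(sim2$mutant) -
                 GenomicRanges::start(sim2$control), 5000L)
})

test_that("identity-gene breadth tail matches the configured log-normal", {
    cfg <- SynthConfig(seed = 13L, nGenes = 1000L, nChroms = 4L)
    sim <- simulatePeaks(simulateGenome(cfg), cfg)
    truth <- sim$truth
    drawn <- truth$drawn_breadth[truth$is_identity]
    pTail <- stats::plnorm(40000, cfg@breadthMeanlogBroad,
                           cfg@breadthSdlogBroad, lower.tail = FALSE)
    expect_gt(pTail, 0.05)  # the broad class reaches past 40 kb
    phat <- mean(drawn > 40000)
    halfWidth <- stats::qnorm(0.995) * sqrt(pTail * (1 - pTail) / length(drawn))
    expect_lt(abs(phat - pTail), halfWidth + 1e-12)
})

test_that("coverage simulation matches Poisson expectations and is seeded", {
    peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
                                   name = "p", score = 0,
                                   seqlengths = c(chr1 = 10000))
    cfg <- smallConfig(coverageDepth = 10, readLength = 50L)
    tr <- simulateCoverage(peak, cfg)
    inPeak <- sum(as.numeric(coverageData(tr)$chr1[1001:2000])) / 50
    ## expected reads in the peak: 10 * (1000 / 50) = 200, sd = sqrt(200)
    expect_lt(abs(inPeak - 200), 4 * sqrt(200))
    expect_identical(coverageData(simulateCoverage(peak, cfg)),
                     coverageData(tr))

    ## background is 2% of depth
    bgBins <- as.numeric(coverageData(tr)$chr1[3001:10000])
    expect_lt(mean(bgBins), 1)  # 0.2 expected reads per 50 bp bin
})

test_that("count simulation obeys the coupling, the NB model and the planted effect", {
    cfg <- smallConfig(seed = 21L)
    sim <- simulatePeaks(simulateGenome(cfg), cfg)

    ## flat coupling, no planting: all genes share the base mean
    cfgFlat <- smallConfig(seed = 21L, expressionCouplingSlope = 0,
                           plantedFraction = 0)
    simFlat <- simulatePeaks(simulateGenome(cfgFlat), cfgFlat)
    seFlat <- simulateCounts(simFlat$truth, cfgFlat)
    m <- SummarizedExperiment::assay(seFlat)
    expect_lt(abs(mean(m) - cfgFlat@baseMeanCount),
              5 * sqrt(stats::var(as.numeric(m)) / length(m)))

    ## theta -> Inf approximates Poisson: variance ~ mean
    cfgPois <- smallConfig(seed = 22L, nGenes = 10L, nReplicates = 500L,
                           expressionCouplingSlope = 0, plantedFraction = 0,
                           nbDispersion = 1e6)
    simP <- simulatePeaks(simulateGenome(cfgPois), cfgPois)
    mP <- SummarizedExperiment::assay(simulateCounts(simP$truth, cfgPois))
    ratio <- apply(mP, 1L, stats::var) / rowMeans(mP)
    expect_lt(abs(mean(ratio) - 1), 0.15)

    ## law of large numbers on the planted fold change at n = 50
    cfg50 <- smallConfig(seed = 23L, nReplicates = 50L, plantedFraction = 1,
                         identityFraction = 1)
    sim50 <- simulatePeaks(simulateGenome(cfg50), cfg50)
    se50 <- simulateCounts(sim50$truth, cfg50)
    cond <- SummarizedExperiment::colData(se50)$condition
    m50 <- SummarizedExperiment::assay(se50)
    ratios <- rowMeans(m50[, cond == "mutant"]) /
        rowMeans(m50[, cond == "control"])
    expect_lt(abs(median(ratios) - 0.5), 0.05)
})

test_that("expression is monotone in breadth tercile under positive coupling", {
    cfg <- smallConfig(seed = 31L)
    sim <- simulatePeaks(simulateGenome(cfg), cfg)
    se <- simulateCounts(sim$truth, cfg)
    cond <- SummarizedExperiment::colData(se)$condition
    ctrlMean <- rowMeans(SummarizedExperiment::assay(se)[, cond == "control"])
    terc <- cut(rank(sim$truth$true_breadth_control, ties.method = "first"),
                3L, labels = c("low", "mid", "high"))
    med <- tapply(ctrlMean, terc, median)
    expect_true(med[["high"]] > med[["mid"]])
    expect_true(med[["mid"]] > med[["low"]])
})

test_that("the full synthetic bundle is bit-reproducible on disk", {
    cfg <- smallConfig(seed = 77L, nGenes = 30L)
    d1 <- tempfile("synth1"); d2 <- tempfile("synth2")
    p1 <- writeSyntheticData(cfg, d1)
    p2 <- writeSyntheticData(cfg, d2)
    for (nm in names(p1)) {
        expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                         info = nm)
    }
})
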