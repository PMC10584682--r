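seFromMatrix <- function(m, condition) {
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(condition = condition,
                                       row.names = colnames(m)))
}

test_that("size factors obey symmetry, scale equivariance and a hand oracle", {
    ## identical libraries -> all factors 1
    m <- matrix(rep(c(10L, 40L, 100L), 3L), ncol = 3L,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
    expect_equal(unname(computeSizeFactors(m)), c(1, 1, 1))

    ## tripling one sample triples its factor
    set.seed(8)
    big <- matrix(rpois(600, 100), ncol = 3L,
                  dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:3)))
    m2 <- cbind(big, s4 = big[, 1L] * 3L)
    sf <- computeSizeFactors(m2)
    expect_equal(unname(sf[["s4"]] / sf[["s1"]]), 3)

    ## 7-feature x 3-sample hand matrix against a spreadsheet-style
    ## manual computation (geometric means and medians written out)
    hand <- matrix(c(100, 200, 400,
                     50, 100, 200,
                     10, 20, 40,
                     80, 160, 320,
                     0, 5, 10,     # zero row: excluded (geomean 0)
                     60, 120, 240,
                     30, 60, 120), ncol = 3L, byrow = TRUE,
                   dimnames = list(paste0("g", 1:7), c("a", "b", "c")))
    geo <- apply(hand[-5L, ], 1L, function(r) prod(r)^(1 / 3))
    manual <- apply(hand[-5L, ], 2L, function(col) median(col / geo))
    expect_equal(computeSizeFactors(hand), manual)
    expect_equal(unname(manual), c(0.5, 1, 2))

    ## all-zero-in-some-sample matrix is rejected
    allz <- matrix(c(0L, 5L, 3L, 0L), ncol = 2L,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
    expect_error(computeSizeFactors(allz), "size factors are undefined")
})

test_that("size factors match the DESeq2 median-of-ratios implementation", {
    set.seed(31)
    m <- matrix(rnbinom(101 * 4, mu = 60, size = 10), ncol = 4L,
                dimnames = list(sprintf("g%03d", 1:101), paste0("s", 1:4))) + 1L
    m[, 3L] <- m[, 3L] * 2L
    ours <- computeSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))  # same unit-geometric-mean scale
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("normalization divides by factors and is idempotent", {
    set.seed(9)
    m <- matrix(rpois(300, 50) + 1L, ncol = 3L,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:3)))
    expect_equal(normalizeCounts(m, c(1, 1, 1)), m * 1.0)
    ## a single sample is its own reference: factor 1
    single <- m[, 1L, drop = FALSE]
    expect_equal(unname(computeSizeFactors(single)), 1)
    ## re-estimating on normalized counts returns factors ~ 1
    norm <- normalizeCounts(m, computeSizeFactors(m))
    expect_equal(unname(computeSizeFactors(norm)), rep(1, 3L),
                 tolerance = 1e-6)
    expect_error(normalizeCounts(m, c(1, 0, 1)), "positive")
})

test_that("the differential test is null-safe and guards zeros", {
    set.seed(10)
    ctrl <- matrix(rpois(30, 40), ncol = 3L)
    m <- cbind(ctrl, ctrl)  # mutant replicates are copies of control
    dimnames(m) <- list(paste0("g", 1:10),
                        c(paste0("c", 1:3), paste0("m", 1:3)))
    m["g1", ] <- 0L  # all-zero feature
    se <- seFromMatrix(m, rep(c("control", "mutant"), each = 3L))
    de <- deTest(se)
    expect_true(all(de$log2fc == 0))
    expect_true(all(de$call == "unchanged"))
    expect_equal(de$log2fc[de$feature_id == "g1"], 0)  # pseudocount guard
    expect_equal(de$p_value[de$feature_id == "g1"], 1)

    expect_error(deTest(se[, 1:4]), ">= 2 replicates")
})

test_that("the Welch engine agrees with feature-by-feature stats::t.test", {
    cfg <- smallConfig(seed = 61L, nGenes = 150L)
    sim <- simulatePeaks(simulateGenome(cfg), cfg)
    se <- simulateCounts(sim$truth, cfg)
    de <- deTest(se)
    norm <- normalizeCounts(se, computeSizeFactors(se))
    lg <- log2(norm + 1)
    cond <- SummarizedExperiment::colData(se)$condition
    pRef <- apply(lg, 1L, function(v)
        stats::t.test(v[cond == "mutant"], v[cond == "control"])$p.value)
    expect_equal(de$p_value, unname(pRef), tolerance = 1e-12)

    ## planted genes are recovered with the expected sensitivity and the
    ## same calls as the straight-line reference
    refCall <- ifelse(pRef < 0.05 & de$log2fc < 0, "down",
                      ifelse(pRef < 0.05 & de$log2fc > 0, "up", "unchanged"))
    expect_equal(de$call, unname(refCall))
    planted <- sim$truth$is_planted
    expect_gte(mean(de$call[planted] == "down"), 0.8)
})

test_that("sample order is irrelevant and label swap mirrors the result", {
    cfg <- smallConfig(seed = 67L, nGenes = 80L)
    sim <- simulatePeaks(simulateGenome(cfg), cfg)
    se <- simulateCounts(sim$truth, cfg)
    de <- deTest(se)

    perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
    dePerm <- deTest(se[, perm])
    expect_equal(dePerm$p_value, de$p_value)
    expect_equal(dePerm$log2fc, de$log2fc)
    expect_equal(dePerm$call, de$call)

    swapped <- se
    SummarizedExperiment::colData(swapped)$condition <-
        ifelse(SummarizedExperiment::colData(se)$condition == "control",
               "mutant", "control")
    deSwap <- deTest(swapped)
    expect_equal(deSwap$log2fc, -de$log2fc)
    expect_equal(deSwap$call,
                 c(up = "down", down = "up",
                   unchanged = "unchanged")[de$call],
                 ignore_attr = TRUE)
})

test_that("gene direction aggregates peak calls by the any-down/none-up rule", {
    ## build a peak-level count matrix with known outcomes
    set.seed(12)
    nrep <- 4L
    mk <- function(muC, muM) as.integer(c(rpois(nrep, muC), rpois(nrep, muM)))
    m <- rbind(
        gA_p1 = mk(2000, 200),   # strongly down
        gA_p2 = mk(100, 100),    # flat
        gB_p1 = mk(200, 2000),   # strongly up
        gC_p1 = mk(2000, 150),   # down
        gC_p2 = mk(150, 2000),   # up -> conflict
        gD_p1 = mk(120, 120),    # flat
        orphan = mk(50, 50))     # not in the assignment
    ## stable background features so median-of-ratios factors stay near 1
    bg <- t(vapply(1:60, function(i) mk(150, 150), integer(2L * nrep)))
    rownames(bg) <- sprintf("bg%02d", 1:60)
    m <- rbind(m, bg)
    colnames(m) <- c(paste0("c", 1:nrep), paste0("m", 1:nrep))
    se <- seFromMatrix(m, rep(c("control", "mutant"), each = nrep))
    assignment <- list(gA = c("gA_p1", "gA_p2"), gB = "gB_p1",
                       gC = c("gC_p1", "gC_p2"), gD = "gD_p1",
                       gE = character(0))
    msgs <- capture_messages(dir <- peakSignalChange(se, assignment))
    expect_match(paste(msgs, collapse = " "), "no gene assignment")
    expect_match(paste(msgs, collapse = " "), "conflicting")
    got <- setNames(dir$direction, dir$gene_id)
    expect_equal(unname(got[c("gA", "gB", "gC", "gD", "gE")]),
                 c("reduced", "increased", "unchanged", "unchanged",
                   "unchanged"))

    ## rule replay: recompute gene calls from the peak-level table
    de <- attr(dir, "peak_de")
    for (g in names(assignment)) {
        calls <- de$call[de$feature_id %in% assignment[[g]]]
        expected <- if (any(calls == "down") && !any(calls == "up")) "reduced"
                    else if (any(calls == "up") && !any(calls == "down"))
                        "increased"
                    else "unchanged"
        expect_identical(unname(got[[g]]), expected)
    }
})

test_that("most planted genes are called reduced at the peak level", {
    cfg <- SynthConfig(seed = 71L, nGenes = 400L, nChroms = 2L)
    sim <- simulatePeaks(simulateGenome(cfg), cfg)
    pc <- simulatePeakCounts(sim$truth, cfg)
    assignment <- setNames(as.list(paste0(sim$truth$gene_id, "_domain")),
                           sim$truth$gene_id)
    dir <- peakSignalChange(pc, assignment)
    planted <- sim$truth$gene_id[sim$truth$is_planted]
    got <- setNames(dir$direction, dir$gene_id)
    expect_gte(mean(got[planted] == "reduced"), 0.8)
})
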