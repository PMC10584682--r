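## Shared fixtures: small seeded configurations and in-code file writers.

smallConfig <- function(seed = 42L, ...) {
    args <- utils::modifyList(list(nGenes = 120L, nChroms = 2L), list(...))
    do.call(SynthConfig, c(list(seed = seed), args))
}

## write lines to a tempfile, return the path
tmpWrite <- function(lines, ext = ".txt") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

## a tiny hand-made gene set: two + genes and one - gene on chr1
handGenes <- function() {
    GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(c(10001, 50001, 90001), c(20000, 60000, 100000)),
        strand = c("+", "-", "+"),
        gene_id = c("gA", "gB", "gC"),
        seqlengths = c(chr1 = 150000))
}

## deterministic coverage track: value `val` on [from, to], 0 elsewhere
flatTrack <- function(val, from, to, chromLen = 150000, total = 1e6,
                      chrom = "chr1") {
    r <- S4Vectors::Rle(c(0, val, 0),
                        c(from - 1, to - from + 1, chromLen - to))
    cov <- IRanges::RleList(r, compress = FALSE)
    names(cov) <- chrom
    CoverageTrack(cov, total)
}

## brute-force bitmap union length of half-open-style integer intervals
## given as an IRanges (1-based closed)
bitmapUnionLength <- function(ir) {
    if (length(ir) == 0L) return(0L)
    hit <- logical(max(IRanges::end(ir)))
    for (i in seq_along(ir))
        hit[IRanges::start(ir)[i]:IRanges::end(ir)[i]] <- TRUE
    sum(hit)
}
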