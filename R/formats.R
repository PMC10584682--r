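## Readers and writers for the genomic and tabular formats the pipeline
## touches.  Files use the usual on-disk conventions (GFF3 1-based closed,
## BED family 0-based half-open); in memory everything is GRanges/IRanges
## (1-based closed), with rtracklayer doing the conversion at the boundary.

#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges mcols mcols<- strand strand<- seqnames
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom IRanges IRanges coverage
#' @importFrom S4Vectors Rle RleList runValue runLength
#' @importFrom utils read.delim write.table
NULL

.nonCommentLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines) & !grepl("^(track|browser)\\b", lines)
    list(lines = lines[keep], lineno = which(keep))
}

.checkIntColumns <- function(fields, lineno, cols, what) {
    for (j in cols) {
        if (grepl("[^0-9-]", fields[[j]]) ||
            is.na(suppressWarnings(as.integer(fields[[j]]))))
            stop(what, ": non-integer coordinate at line ", lineno,
                 " (column ", j, ": '", fields[[j]], "')", call. = FALSE)
    }
    invisible(TRUE)
}

## ---------------------------------------------------------------------------
## GFF3
## ---------------------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Reads records of one feature type (default `"gene"`) from a GFF3 file
#' into a stranded `GRanges` with a `gene_id` column taken from the `ID`
#' attribute.  GFF3 is 1-based closed, the same convention as `GRanges`,
#' so coordinates carry over unchanged.  The TSS of a gene is its start
#' for `+` genes and its end for `-` genes (use [tssPositions()]);
#' unstranded records are rejected because metagene profiles need an
#' orientation.
#'
#' @param path Path to a GFF3 file.
#' @param featureType Feature type (column 3) to extract.
#' @return A sorted `GRanges` with mcols column `gene_id`.
#' @seealso [writeGFF3Genes()], [tssPositions()]
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tdemo\tgene\t101\t200\t.\t+\t.\tID=g1"), gff)
#' readGFF3Genes(gff)
#' @export
readGFF3Genes <- function(path, featureType = "gene") {
    nc <- .nonCommentLines(path)
    for (i in seq_along(nc$lines)) {
        fields <- strsplit(nc$lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 9L)
            stop("malformed GFF3 record at line ", nc$lineno[i],
                 ": expected 9 tab-separated columns, got ", length(fields),
                 call. = FALSE)
        .checkIntColumns(fields, nc$lineno[i], c(4L, 5L), "GFF3")
    }
    if (length(nc$lines) == 0L)
        return(GRanges(gene_id = character(0)))
    gr <- rtracklayer::import(path, format = "gff3",
                              feature.type = featureType)
    if (length(gr) == 0L)
        return(GRanges(gene_id = character(0)))
    ids <- mcols(gr)$ID
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        stop("GFF3 ", featureType, " record without an ID attribute",
             call. = FALSE)
    if (anyDuplicated(ids))
        stop("duplicated gene ID in GFF3: ",
             ids[duplicated(ids)][1L], call. = FALSE)
    if (any(strand(gr) == "*"))
        stop("gene with unknown strand '.': profiles require orientation",
             call. = FALSE)
    out <- GRanges(seqnames(gr), IRanges::ranges(gr), strand = strand(gr),
                   gene_id = as.character(ids))
    GenomicRanges::sort(out)
}

#' Write gene models to GFF3
#'
#' @param genes A `GRanges` with a `gene_id` column (as returned by
#'   [readGFF3Genes()] or [simulateGenome()]).
#' @param path Output path.
#' @param featureType Feature type to write in column 3.
#' @return Invisibly, `path`.
#' @export
writeGFF3Genes <- function(genes, path, featureType = "gene") {
    out <- genes
    mcols(out) <- NULL
    mcols(out)$source <- "broadH3K4"
    mcols(out)$type <- featureType
    mcols(out)$ID <- genes$gene_id
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Strand-aware TSS and TES positions
#'
#' The transcription start site of a `+` gene is its lowest coordinate
#' and its transcription end site the highest; for `-` genes the two are
#' swapped.
#'
#' @param genes Stranded `GRanges` of gene models.
#' @return `tssPositions()`/`tesPositions()`: integer vector of 1-based
#'   positions, named by `gene_id` when present.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
#'                             strand = "-", gene_id = "g1")
#' tssPositions(g)  # 200
#' @export
tssPositions <- function(genes) {
    pos <- ifelse(as.character(strand(genes)) == "+",
                  GenomicRanges::start(genes), GenomicRanges::end(genes))
    if (!is.null(genes$gene_id)) names(pos) <- genes$gene_id
    pos
}

#' @rdname tssPositions
#' @export
tesPositions <- function(genes) {
    pos <- ifelse(as.character(strand(genes)) == "+",
                  GenomicRanges::end(genes), GenomicRanges::start(genes))
    if (!is.null(genes$gene_id)) names(pos) <- genes$gene_id
    pos
}

## ---------------------------------------------------------------------------
## BED6 / narrowPeak
## ---------------------------------------------------------------------------

#' Read peak calls (BED6 or ENCODE narrowPeak)
#'
#' Reads a BED-family peak file (0-based half-open on disk) into a
#' `GRanges`.  For `dialect = "narrowPeak"` the 10th column is parsed as
#' the summit offset from the peak start; the conventional `-1` (no
#' summit) is stored as `NA`.
#'
#' @param path Path to the peak file.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @return A `GRanges` with mcols `name`, `score` and (for narrowPeak)
#'   `signalValue`, `pValue`, `qValue`, `summitOffset`.
#' @seealso [writePeaks()]
#' @export
readPeaks <- function(path, dialect = c("bed6", "narrowPeak")) {
    dialect <- match.arg(dialect)
    nc <- .nonCommentLines(path)
    minCols <- if (dialect == "bed6") 6L else 10L
    for (i in seq_along(nc$lines)) {
        fields <- strsplit(nc$lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < minCols)
            stop("malformed ", dialect, " record at line ", nc$lineno[i],
                 ": expected >= ", minCols, " columns", call. = FALSE)
        .checkIntColumns(fields, nc$lineno[i], c(2L, 3L), dialect)
        if (as.numeric(fields[3L]) <= as.numeric(fields[2L]))
            stop(dialect, ": end <= start at line ", nc$lineno[i],
                 call. = FALSE)
    }
    if (length(nc$lines) == 0L)
        return(GRanges(name = character(0), score = numeric(0)))
    gr <- if (dialect == "narrowPeak") {
        rtracklayer::import(path, format = "BED",
            extraCols = c(signalValue = "numeric", pValue = "numeric",
                          qValue = "numeric", peak = "integer"))
    } else {
        rtracklayer::import(path, format = "BED")
    }
    if (dialect == "narrowPeak") {
        summit <- mcols(gr)$peak
        summit[!is.na(summit) & summit < 0] <- NA_integer_
        bad <- !is.na(summit) & summit >= GenomicRanges::width(gr)
        if (any(bad))
            stop("narrowPeak summit offset outside the peak (record ",
                 which(bad)[1L], ")", call. = FALSE)
        mcols(gr)$summitOffset <- summit
        mcols(gr)$peak <- NULL
    }
    gr
}

#' Write peak calls (BED6 or ENCODE narrowPeak)
#'
#' Emits 0-based half-open BED coordinates.  For narrowPeak, missing
#' summit offsets are written as the conventional `-1` and the
#' `signalValue`/`pValue`/`qValue` columns default to `0`/`-1`/`-1` when
#' absent.
#'
#' @param peaks A `GRanges` with at least a `name` column.
#' @param path Output path.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @return Invisibly, `path`.
#' @export
writePeaks <- function(peaks, path, dialect = c("bed6", "narrowPeak")) {
    dialect <- match.arg(dialect)
    sc <- if (is.null(peaks$score)) rep(0, length(peaks)) else peaks$score
    df <- data.frame(
        chrom = as.character(seqnames(peaks)),
        start = GenomicRanges::start(peaks) - 1L,
        end = GenomicRanges::end(peaks),
        name = if (is.null(peaks$name)) paste0("peak", seq_along(peaks))
               else peaks$name,
        score = sc,
        strand = sub("\\*", ".", as.character(strand(peaks))))
    if (dialect == "narrowPeak") {
        pick <- function(col, default)
            if (is.null(mcols(peaks)[[col]])) rep(default, length(peaks))
            else mcols(peaks)[[col]]
        summit <- pick("summitOffset", NA_integer_)
        summit[is.na(summit)] <- -1L
        df$signalValue <- pick("signalValue", 0)
        df$pValue <- pick("pValue", -1)
        df$qValue <- pick("qValue", -1)
        df$peak <- summit
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

## ---------------------------------------------------------------------------
## bedGraph
## ---------------------------------------------------------------------------

#' Read a bedGraph coverage track
#'
#' Reads a bedGraph (0-based half-open steps) into a [CoverageTrack-class].
#' Steps must be non-overlapping with finite, non-negative values;
#' adjacent steps with equal value are merged by the run-length encoding,
#' and gaps between steps are zero.  The total mapped read count is not
#' derivable from coverage mass (it depends on read length), so it is
#' taken from `totalMappedReads` or, when that is `NULL`, from a sidecar
#' file `<path>.reads` holding a single integer.
#'
#' @param path Path to a bedGraph file.
#' @param totalMappedReads Total mapped reads of the library, or `NULL`
#'   to read the sidecar file.
#' @return A [CoverageTrack-class].
#' @seealso [writeBedGraph()], [rpmScale()]
#' @export
readBedGraph <- function(path, totalMappedReads = NULL) {
    if (is.null(totalMappedReads)) {
        sidecar <- paste0(path, ".reads")
        if (!file.exists(sidecar))
            stop("totalMappedReads not given and no sidecar file ",
                 sidecar, call. = FALSE)
        totalMappedReads <- as.numeric(readLines(sidecar, n = 1L))
    }
    if (!is.finite(totalMappedReads) || totalMappedReads <= 0)
        stop("totalMappedReads must be > 0", call. = FALSE)
    nc <- .nonCommentLines(path)
    if (length(nc$lines) == 0L)
        return(CoverageTrack(RleList(compress = FALSE), totalMappedReads))
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (any(!is.finite(gr$score) | gr$score < 0))
        stop("bedGraph has negative or non-finite values", call. = FALSE)
    if (!IRanges::isDisjoint(gr))
        stop("bedGraph has overlapping steps", call. = FALSE)
    cov <- IRanges::coverage(gr, weight = "score")
    CoverageTrack(cov, totalMappedReads)
}

#' Write a bedGraph coverage track
#'
#' Writes every run of the track (including zero runs, so that a
#' read-back reproduces the track exactly) and, when `sidecar = TRUE`, a
#' `<path>.reads` file with the total mapped read count.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @param sidecar Write the `<path>.reads` sidecar file?
#' @return Invisibly, `path`.
#' @export
writeBedGraph <- function(track, path, sidecar = TRUE) {
    cov <- coverageData(track)
    rows <- lapply(names(cov), function(chr) {
        r <- cov[[chr]]
        if (length(r) == 0L) return(NULL)
        ends <- cumsum(runLength(r))
        data.frame(chrom = chr, start = c(0L, ends[-length(ends)]),
                   end = ends, value = runValue(r))
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), value = numeric(0))
    write.table(format(df, scientific = FALSE, trim = TRUE), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    if (sidecar)
        writeLines(format(totalMappedReads(track), scientific = FALSE),
                   paste0(path, ".reads"))
    invisible(path)
}

## ---------------------------------------------------------------------------
## Count matrices
## ---------------------------------------------------------------------------

#' Read a count matrix with a condition map
#'
#' Reads a features-by-samples TSV of non-negative integer counts (first
#' column feature ids, header of sample ids) together with a two-column
#' condition TSV (`sample`, `condition` with values `control`/`mutant`)
#' into a `SummarizedExperiment` whose `colData` carries the condition.
#'
#' @param path Path to the count TSV.
#' @param conditionPath Path to the condition-map TSV.
#' @return A `SummarizedExperiment` with assay `counts`.
#' @seealso [writeCounts()], [deTest()]
#' @export
readCounts <- function(path, conditionPath) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("duplicated feature id in count matrix: ",
             ids[duplicated(ids)][1L], call. = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicated sample id in count matrix", call. = FALSE)
    if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers", call. = FALSE)
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    cond <- read.delim(conditionPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "condition") %in% colnames(cond)))
        stop("condition map needs columns 'sample' and 'condition'",
             call. = FALSE)
    missing <- setdiff(colnames(m), cond$sample)
    if (length(missing))
        stop("sample(s) missing from condition map: ",
             paste(missing, collapse = ", "), call. = FALSE)
    condition <- cond$condition[match(colnames(m), cond$sample)]
    if (!all(condition %in% c("control", "mutant")))
        stop("condition must be 'control' or 'mutant'", call. = FALSE)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = DataFrame(condition = condition, row.names = colnames(m)))
}

#' Write a count matrix and its condition map
#'
#' @param se A `SummarizedExperiment` with assay `counts` and a
#'   `condition` column in `colData`.
#' @param path Output path for the count TSV.
#' @param conditionPath Output path for the condition TSV.
#' @return Invisibly, `path`.
#' @export
writeCounts <- function(se, path, conditionPath) {
    m <- SummarizedExperiment::assay(se, "counts")
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cond <- data.frame(sample = colnames(se),
                       condition = SummarizedExperiment::colData(se)$condition)
    write.table(cond, conditionPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
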