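## One-call orchestration: simulate (or load real inputs) -> breadth ->
## metaprofile -> differential -> integrate, with TSV outputs per stage
## and a JSON run manifest.

#' @importFrom tools md5sum
NULL

.configToSynth <- function(lst, seed = NULL) {
    args <- lst
    if (!is.null(seed)) args$seed <- seed
    if (is.null(args$seed)) args$seed <- 1234L
    do.call(SynthConfig, args)
}

.configToAnalysis <- function(lst) {
    if (is.null(lst)) AnalysisConfig() else do.call(AnalysisConfig, lst)
}

#' Read a pipeline configuration file
#'
#' The YAML configuration mirrors [SynthConfig-class] (section
#' `synthetic`) and [AnalysisConfig-class] (section `analysis`)
#' field-for-field, plus a top-level `seed`, an optional `outdir` and an
#' optional `inputs` section of real input files (which switches the
#' simulate stage off).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `seed`, `synthetic`, `analysis`,
#'   `inputs`, `outdir`.
#' @seealso [runPipeline()]
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    list(seed = cfg$seed, synthetic = cfg$synthetic,
         analysis = cfg$analysis, inputs = cfg$inputs, outdir = cfg$outdir)
}

.loadInputs <- function(inputs) {
    genes <- readGFF3Genes(inputs$genes)
    list(
        genes = genes,
        peaksControl = readPeaks(inputs$peaks_control, "narrowPeak"),
        peaksMutant = readPeaks(inputs$peaks_mutant, "narrowPeak"),
        covControl = readBedGraph(inputs$coverage_control),
        covMutant = readBedGraph(inputs$coverage_mutant),
        counts = readCounts(inputs$counts, inputs$condition),
        peakCounts = if (is.null(inputs$peak_counts)) NULL
                     else readCounts(inputs$peak_counts, inputs$condition),
        truth = NULL)
}

#' Run the full broad-domain analysis pipeline
#'
#' Executes the stages in dependency order -- simulate (skipped when the
#' configuration lists real inputs), breadth scoring and classification,
#' metagene profiling of the control and mutant coverage, differential
#' testing of gene expression and of per-domain peak signal, and
#' integration of the two reduced gene sets -- writing each stage's
#' outputs under `outdir/{simulate,breadth,profile,diff,integrate}/` and
#' a JSON manifest (`manifest.json`, with configuration hash, seed and
#' per-file md5 checksums) last.  Identical configurations produce
#' byte-identical outputs.
#'
#' @param config Path to a YAML configuration (see
#'   [readPipelineConfig()]) or an equivalent list.
#' @param outdir Output directory; overrides the configuration.
#' @param seed Integer; overrides the configuration seed.
#' @return Invisibly, the manifest as a list (also written as JSON).
#' @examples
#' \donttest{
#' out <- tempfile("run")
#' mf <- runPipeline(list(seed = 1, synthetic = list(nGenes = 60L)),
#'                   outdir = out)
#' names(mf$files)
#' }
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
    cfg <- if (is.character(config)) readPipelineConfig(config) else config
    if (is.null(outdir)) outdir <- cfg$outdir
    if (is.null(outdir))
        stop("no output directory: give outdir or set it in the config",
             call. = FALSE)
    if (is.null(seed)) seed <- cfg$seed
    synth <- .configToSynth(cfg$synthetic, seed)
    ana <- .configToAnalysis(cfg$analysis)
    stageDir <- function(s) {
        d <- file.path(outdir, s)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        d
    }
    files <- character(0)
    keep <- function(p) { files[length(files) + 1L] <<- p; p }
    stage <- "simulate"
    mf <- tryCatch({
        ## ---- simulate or load -------------------------------------------
        if (is.null(cfg$inputs)) {
            simDir <- stageDir("simulate")
            paths <- writeSyntheticData(synth, simDir)
            for (p in unlist(paths)) keep(p)
            keep(file.path(simDir, "coverage_control.bedGraph.reads"))
            keep(file.path(simDir, "coverage_mutant.bedGraph.reads"))
            genes <- simulateGenome(synth)
            sim <- simulatePeaks(genes, synth)
            dat <- list(genes = genes,
                        peaksControl = sim$control,
                        peaksMutant = sim$mutant,
                        covControl = simulateCoverage(sim$control, synth),
                        covMutant = simulateCoverage(sim$mutant, synth),
                        counts = simulateCounts(sim$truth, synth),
                        peakCounts = simulatePeakCounts(sim$truth, synth),
                        truth = sim$truth)
            message("simulate: ", length(dat$genes), " genes, ",
                    length(dat$peaksControl), " control peaks")
        } else {
            dat <- .loadInputs(cfg$inputs)
            message("inputs: ", length(dat$genes), " genes, ",
                    length(dat$peaksControl), " control peaks")
        }

        ## ---- breadth ----------------------------------------------------
        stage <- "breadth"
        assignment <- assignPeaksToGenes(dat$peaksControl, dat$genes, ana)
        bt <- classifyBreadth(geneBreadth(assignment), ana)
        btab <- as.data.frame(breadthData(bt))
        d <- stageDir("breadth")
        write.table(btab, keep(file.path(d, "breadth.tsv")), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        message("breadth: ", nrow(btab), " genes classified (",
                sum(btab$group == "broad"), " broad)")

        ## ---- profile ----------------------------------------------------
        stage <- "profile"
        d <- stageDir("profile")
        classifiedGenes <- dat$genes[dat$genes$gene_id %in% btab$gene_id]
        mpC <- groupMetaprofile(classifiedGenes, bt, rpmScale(dat$covControl),
                                ana)
        mpM <- groupMetaprofile(classifiedGenes, bt, rpmScale(dat$covMutant),
                                ana)
        writeMetaprofile(mpC, keep(file.path(d, "metaprofile_control.tsv")))
        writeMetaprofile(mpM, keep(file.path(d, "metaprofile_mutant.tsv")))

        ## ---- differential -----------------------------------------------
        stage <- "diff"
        d <- stageDir("diff")
        deGenes <- deTest(dat$counts, ana)
        writeDETable(deGenes, keep(file.path(d, "de_genes.tsv")))
        peakAssign <- if (is.null(dat$truth)) {
            assignment
        } else {
            ## synthetic domain counts are quantified per gene domain
            setNames(as.list(paste0(dat$truth$gene_id, "_domain")),
                     dat$truth$gene_id)
        }
        peakDir <- peakSignalChange(dat$peakCounts, peakAssign, ana)
        writeDETable(attr(peakDir, "peak_de"),
                     keep(file.path(d, "de_peaks.tsv")))
        write.table(peakDir, keep(file.path(d, "peak_direction.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        message("diff: ", sum(deGenes$call == "down"),
                " genes down, ", sum(peakDir$direction == "reduced"),
                " genes with reduced peak signal")

        ## ---- integrate --------------------------------------------------
        stage <- "integrate"
        d <- stageDir("integrate")
        reducedExpr <- deGenes$feature_id[deGenes$call == "down"]
        reducedPeaks <- peakDir$gene_id[peakDir$direction == "reduced"]
        summary <- if (length(reducedPeaks))
            overlapSummary(reducedPeaks, reducedExpr, bt) else NULL
        if (!is.null(summary)) {
            writeIntegrationSummary(summary,
                keep(file.path(d, "integration.json")),
                keep(file.path(d, "integration.tsv")))
        } else {
            message("integrate: no genes with reduced peak signal; ",
                    "summary skipped")
        }
        expr <- expressionByBreadthGroup(dat$counts, bt)
        write.table(expr, keep(file.path(d, "expression_by_group.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)

        list(dat = dat, bt = bt, summary = summary)
    }, error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })

    ## ---- manifest (written last) ---------------------------------------
    cfgNorm <- list(seed = synth@seed,
                    synthetic = .slotList(synth),
                    analysis = .slotList(ana),
                    inputs = cfg$inputs)
    cfgYaml <- yaml::as.yaml(cfgNorm)
    manifest <- list(
        tool = "broadH3K4",
        version = as.character(utils::packageVersion("broadH3K4")),
        seed = synth@seed,
        config_md5 = .stringMd5(cfgYaml),
        config = cfgNorm,
        files = as.list(setNames(unname(tools::md5sum(files)), files)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

.slotList <- function(obj) {
    nm <- methods::slotNames(class(obj))
    out <- lapply(nm, function(s) methods::slot(obj, s))
    names(out) <- nm
    out
}

.stringMd5 <- function(s) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(s, tf)
    unname(tools::md5sum(tf))
}
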