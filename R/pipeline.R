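#' Default pipeline parameters
#'
#' One place for every constant of the PAS pipeline: cluster half-width
#' \code{w} (25 nt), internal-priming window (-30..+10) and run length
#' (7 A), signal window (-30..0), 3'UTR extension cap (5000 nt), minimum
#' summed PAS count before testing (10), APA pair-selection FDR (0.05),
#' and the differential-expression thresholds (FDR 0.01, fold change 2).
#' Every field can be overridden from the pipeline config.
#'
#' @param w,ipWindow,ipRunLength,signalWindow,utrExtensionCap,minPasCount
#'   see above.
#' @param apaFdr,deFdr,deFc,seed see above.
#' @return named list of parameters.
#' @export
pipelineParams <- function(w = 25L, ipWindow = c(-30L, 10L),
                           ipRunLength = 7L, signalWindow = c(-30L, 0L),
                           utrExtensionCap = 5000L, minPasCount = 10L,
                           apaFdr = 0.05, deFdr = 0.01, deFc = 2,
                           seed = 1L) {
    list(w = as.integer(w), ipWindow = as.integer(ipWindow),
         ipRunLength = as.integer(ipRunLength),
         signalWindow = as.integer(signalWindow),
         utrExtensionCap = as.integer(utrExtensionCap),
         minPasCount = as.numeric(minPasCount),
         apaFdr = as.numeric(apaFdr), deFdr = as.numeric(deFdr),
         deFc = as.numeric(deFc), seed = as.integer(seed))
}

#' Run the full APA pipeline
#'
#' Orchestrates simulate (optional) -> read events -> cluster -> filter
#' -> extend/assign/rank -> differential PAS usage + switch calling +
#' differential expression, writing every stage artifact and a
#' reproducibility manifest into \code{outdir}. Reruns with the same
#' config are byte-identical.
#'
#' The config (YAML file or list) has up to three blocks:
#' \describe{
#'   \item{params}{overrides for [pipelineParams()].}
#'   \item{simulate}{overrides for [ApaSimConfig()]; when present the
#'     inputs are generated into \code{outdir/sim}.}
#'   \item{inputs}{\code{genome} (FASTA), \code{annotation} (TSV),
#'     \code{samples} (sample sheet TSV with columns sample, group,
#'     replicate, path); required when there is no simulate block.}
#' }
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param outdir output directory.
#' @param signalSet polyadenylation-signal hexamers (default
#'   [pasSignalSet()]).
#' @return invisibly, the manifest list.
#' @importFrom Biostrings readDNAStringSet
#' @export
runPipeline <- function(config, outdir, signalSet = pasSignalSet()) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    params <- do.call(pipelineParams, c(cfg$params))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    if (!is.null(cfg$simulate)) {
        simCfg <- do.call(ApaSimConfig, c(cfg$simulate,
            if (is.null(cfg$simulate$seed)) list(seed = params$seed)))
        sim <- stage("simulate", simulateApaDataset(simCfg))
        simDir <- file.path(outdir, "sim")
        stage("simulate", writeSimulation(sim, simDir))
        inputs <- list(genome = file.path(simDir, "genome.fa"),
                       annotation = file.path(simDir, "genes.tsv"),
                       samples = file.path(simDir, "samples.tsv"))
    } else {
        inputs <- cfg$inputs
        if (is.null(inputs$genome) || is.null(inputs$annotation) ||
            is.null(inputs$samples))
            stop("config needs either a 'simulate' or an 'inputs' block ",
                 "(genome, annotation, samples)")
    }

    genome <- stage("load", readDNAStringSet(inputs$genome))
    names(genome) <- sub("\\s.*$", "", names(genome))
    sheet <- stage("load", utils::read.delim(inputs$samples,
                                             stringsAsFactors = FALSE))
    ann <- stage("load", readGeneAnnotation(
        inputs$annotation,
        stats::setNames(Biostrings::width(genome), names(genome))))

    events <- stage("callpas",
        readCleavageEvents(sheet$path, samples = sheet$sample))
    clusters <- stage("callpas", clusterEvents(events, w = params$w))
    pe <- stage("callpas", buildCountMatrix(clusters, sheet))

    fparams <- pasFilterParams(ipWindow = params$ipWindow,
                               ipRunLength = params$ipRunLength,
                               signalWindow = params$signalWindow,
                               signalSet = signalSet)
    filt <- stage("filter", filterPas(pe, genome, fparams))
    kept <- filt$kept

    extGenes <- stage("assign",
        extendThreePrime(ann, cap = params$utrExtensionCap))
    kept <- stage("assign", rankPas(assignPas(kept, extGenes)))

    results <- stage("diffapa",
        nbTest(kept, minCount = params$minPasCount))
    switches <- stage("diffapa",
        callApaSwitches(results, alpha = params$apaFdr))
    de <- stage("de", callDeGenes(kept, fdr = params$deFdr,
                                  fc = params$deFc,
                                  minCount = params$minPasCount))

    wtsv <- function(x, f) utils::write.table(
        x, file.path(outdir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
    seeds <- SummarizedExperiment::rowRanges(pe)
    wtsv(data.frame(
        pas_id = rownames(pe),
        chrom = as.character(GenomicRanges::seqnames(seeds)),
        site = GenomicRanges::start(seeds) - 1L,
        strand = as.character(GenomicRanges::strand(seeds)),
        total = seeds$total), "pas_clusters.tsv")
    wtsv(cbind(pas_id = rownames(pe),
               as.data.frame(SummarizedExperiment::assay(pe, "counts"))),
         "pas_counts.tsv")
    wtsv(filt$removalLog, "removal_log.tsv")
    keptRR <- SummarizedExperiment::rowRanges(kept)
    wtsv(data.frame(pas_id = rownames(kept),
                    gene_id = keptRR$gene_id, rank = keptRR$rank),
         "pas_assignment.tsv")
    wtsv(results, "pas_tests.tsv")
    wtsv(switches, "apa_switches.tsv")
    wtsv(de, "de_genes.tsv")

    nApa <- length(apaGenes(kept))
    manifest <- list(
        params = params,
        inputs = lapply(inputs, function(f)
            list(path = f, md5 = unname(tools::md5sum(f)))),
        counts = list(
            events = length(events),
            clusters = nrow(pe),
            removed_by_filter = nrow(filt$removalLog),
            kept = nrow(kept),
            assigned = sum(!is.na(keptRR$gene_id)),
            apa_genes = nApa,
            tested_pas = nrow(results),
            switches = nrow(switches),
            switches_class_I = unname(attr(switches, "classCounts")["I"]),
            switches_class_II = unname(attr(switches, "classCounts")["II"]),
            cool_up = sum(de$category == "CoolUp"),
            cool_down = sum(de$category == "CoolDown")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
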