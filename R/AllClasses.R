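#' Configuration for the synthetic 3' end sequencing generator
#'
#' An \code{ApaSimConfig} bundles every tunable of the synthetic-data
#' generator: genome/gene layout, per-gene poly(A)-site (PAS) multiplicity,
#' negative-binomial expression parameters, cleavage-position jitter,
#' internal-priming artifact rate, and the planted condition effects
#' (APA switches between a \emph{low} and a \emph{high} temperature group,
#' and differentially expressed genes).
#'
#' @slot nGenes number of genes to place.
#' @slot pasPerGeneRange integer(2), min/max true PASs per gene (min >= 1).
#' @slot nReplicates replicates per condition group.
#' @slot groups character(2), condition group labels; first = low
#'   temperature, second = high temperature.
#' @slot geneMean expected reads per gene per sample (NB mean).
#' @slot geneDispersion NB dispersion phi, so that Var = mu + phi * mu^2.
#' @slot switchFraction fraction of genes carrying a planted APA switch.
#' @slot switchDelta usage-proportion shift applied to the proximal/distal
#'   PAS pair of switch genes in the low group, in [0, 1).
#' @slot deFraction fraction of genes with a planted expression shift.
#' @slot deLog2fc magnitude of the planted log2 expression shift (low vs
#'   high); sign alternates over the planted genes.
#' @slot jitterScale maximum absolute cleavage-position offset (nt).
#' @slot artifactFraction fraction of a gene's reads emitted at its
#'   internal-priming artifact site.
#' @slot seed integer seed; all generator randomness derives from it.
#'
#' @seealso [simulateApaDataset()]
#' @export
setClass("ApaSimConfig",
    representation(
        nGenes = "integer",
        pasPerGeneRange = "integer",
        nReplicates = "integer",
        groups = "character",
        geneMean = "numeric",
        geneDispersion = "numeric",
        switchFraction = "numeric",
        switchDelta = "numeric",
        deFraction = "numeric",
        deLog2fc = "numeric",
        jitterScale = "integer",
        artifactFraction = "numeric",
        seed = "integer"
    )
)

setValidity("ApaSimConfig", function(object) {
    msg <- NULL
    chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
    chk(length(object@nGenes) == 1L && object@nGenes >= 0L,
        "nGenes must be a single non-negative integer")
    chk(length(object@pasPerGeneRange) == 2L &&
            object@pasPerGeneRange[1L] >= 1L &&
            object@pasPerGeneRange[2L] >= object@pasPerGeneRange[1L] &&
            object@pasPerGeneRange[2L] <= 3L,
        "pasPerGeneRange must be (min, max) with 1 <= min <= max <= 3")
    chk(length(object@nReplicates) == 1L && object@nReplicates >= 1L,
        "nReplicates must be >= 1")
    chk(length(object@groups) == 2L && !anyDuplicated(object@groups),
        "groups must be two distinct labels")
    chk(is.finite(object@geneMean) && object@geneMean > 0,
        "geneMean must be positive and finite")
    chk(is.finite(object@geneDispersion) && object@geneDispersion > 0,
        "geneDispersion must be positive and finite")
    chk(object@switchFraction >= 0 && object@switchFraction <= 1,
        "switchFraction must be in [0, 1]")
    chk(object@switchDelta >= 0 && object@switchDelta < 1,
        "switchDelta must be in [0, 1)")
    chk(object@deFraction >= 0 && object@deFraction <= 1,
        "deFraction must be in [0, 1]")
    chk(is.finite(object@deLog2fc), "deLog2fc must be finite")
    chk(object@jitterScale >= 0L, "jitterScale must be non-negative")
    chk(object@artifactFraction >= 0 && object@artifactFraction < 1,
        "artifactFraction must be in [0, 1)")
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed must be a single integer")
    if (is.null(msg)) TRUE else msg
})

#' Construct an [ApaSimConfig-class]
#'
#' Defaults reproduce the sampling design the pipeline targets: three
#' biological replicates in each of two pooled temperature groups, 1--3
#' PASs per gene, NB gene counts (mean 200, dispersion 0.1), cleavage
#' jitter up to +/- 8 nt, 5\% internal-priming artifact reads, and a 0.3
#' usage-proportion shift for planted switch genes.
#'
#' @param nGenes,pasPerGeneRange,nReplicates,groups,geneMean,geneDispersion
#'   see the class documentation.
#' @param switchFraction,switchDelta,deFraction,deLog2fc,jitterScale,artifactFraction,seed
#'   see the class documentation.
#' @return a validated \code{ApaSimConfig}.
#' @examples
#' cfg <- ApaSimConfig(nGenes = 20, seed = 7)
#' @export
ApaSimConfig <- function(nGenes = 200L, pasPerGeneRange = c(1L, 3L),
                         nReplicates = 3L, groups = c("low", "high"),
                         geneMean = 200, geneDispersion = 0.1,
                         switchFraction = 0.25, switchDelta = 0.3,
                         deFraction = 0.1, deLog2fc = log2(2.5),
                         jitterScale = 8L, artifactFraction = 0.05,
                         seed = 1L) {
    new("ApaSimConfig",
        nGenes = as.integer(nGenes),
        pasPerGeneRange = as.integer(pasPerGeneRange),
        nReplicates = as.integer(nReplicates),
        groups = as.character(groups),
        geneMean = as.numeric(geneMean),
        geneDispersion = as.numeric(geneDispersion),
        switchFraction = as.numeric(switchFraction),
        switchDelta = as.numeric(switchDelta),
        deFraction = as.numeric(deFraction),
        deLog2fc = as.numeric(deLog2fc),
        jitterScale = as.integer(jitterScale),
        artifactFraction = as.numeric(artifactFraction),
        seed = as.integer(seed))
}

setMethod("show", "ApaSimConfig", function(object) {
    cat("ApaSimConfig\n")
    cat("  genes:", object@nGenes,
        " PAS/gene:", paste(object@pasPerGeneRange, collapse = "-"),
        " replicates:", object@nReplicates, "x", length(object@groups),
        "groups (", paste(object@groups, collapse = "/"), ")\n")
    cat("  NB mean:", object@geneMean, " dispersion:", object@geneDispersion,
        "\n")
    cat("  switch fraction:", object@switchFraction,
        " delta:", object@switchDelta,
        " DE fraction:", object@deFraction,
        " DE log2FC:", signif(object@deLog2fc, 3), "\n")
    cat("  jitter: +/-", object@jitterScale, "nt ",
        " artifact fraction:", object@artifactFraction,
        " seed:", object@seed, "\n")
})

#' Ground truth of a synthetic APA dataset
#'
#' Records everything the generator planted, so that recovery by the
#' analysis pipeline can be scored: true PAS positions with per-group
#' usage proportions, internal-priming artifact sites, switch genes with
#' their planted class, and genes with a planted expression shift.
#'
#' @slot truePas \code{GRanges} (width 1; the cleavage site) with columns
#'   \code{gene_id}, \code{pas_index} (0 = most proximal), \code{usage_low},
#'   \code{usage_high}.
#' @slot artifactSites \code{GRanges} (width 1) with column \code{gene_id};
#'   each site sits on a sense-strand run of >= 7 A.
#' @slot switchGenes \code{DataFrame} with \code{gene_id} and
#'   \code{class} ("I": distal PAS preferred at low temperature;
#'   "II": proximal preferred).
#' @slot deGenes \code{DataFrame} with \code{gene_id} and
#'   \code{log2_shift} (low vs high).
#' @export
setClass("ApaSimTruth",
    representation(
        truePas = "GRanges",
        artifactSites = "GRanges",
        switchGenes = "DataFrame",
        deGenes = "DataFrame"
    )
)

setValidity("ApaSimTruth", function(object) {
    msg <- NULL
    tp <- object@truePas
    need <- c("gene_id", "pas_index", "usage_low", "usage_high")
    if (!all(need %in% colnames(S4Vectors::mcols(tp))))
        msg <- c(msg, paste("truePas must carry columns:",
                            paste(need, collapse = ", ")))
    else if (length(tp)) {
        for (col in c("usage_low", "usage_high")) {
            sums <- tapply(S4Vectors::mcols(tp)[[col]],
                           S4Vectors::mcols(tp)$gene_id, sum)
            if (any(abs(sums - 1) > 1e-9))
                msg <- c(msg, paste0(col,
                    " proportions must sum to 1 per gene"))
        }
    }
    if (!all(c("gene_id", "class") %in% colnames(object@switchGenes)))
        msg <- c(msg, "switchGenes must carry gene_id and class")
    if (length(object@switchGenes$class) &&
            !all(object@switchGenes$class %in% c("I", "II")))
        msg <- c(msg, "switch class must be 'I' or 'II'")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ApaSimTruth-class planted true PASs.
#' @param x an \code{ApaSimTruth}.
#' @export
setMethod("truePas", "ApaSimTruth", function(x) x@truePas)

#' @describeIn ApaSimTruth-class planted internal-priming sites.
#' @export
setMethod("artifactSites", "ApaSimTruth", function(x) x@artifactSites)

#' @describeIn ApaSimTruth-class planted APA switch genes.
#' @export
setMethod("switchGenes", "ApaSimTruth", function(x) x@switchGenes)

#' @describeIn ApaSimTruth-class planted differentially expressed genes.
#' @export
setMethod("deGenes", "ApaSimTruth", function(x) x@deGenes)

setMethod("show", "ApaSimTruth", function(object) {
    cat("ApaSimTruth\n")
    cat("  true PASs:     ", length(object@truePas), "in",
        length(unique(object@truePas$gene_id)), "genes\n")
    cat("  artifact sites:", length(object@artifactSites), "\n")
    cat("  switch genes:  ", nrow(object@switchGenes),
        sprintf("(class I: %d, class II: %d)",
                sum(object@switchGenes$class == "I"),
                sum(object@switchGenes$class == "II")), "\n")
    cat("  DE genes:      ", nrow(object@deGenes), "\n")
})

#' PAS-by-sample count container
#'
#' A \code{PasExperiment} extends \code{RangedSummarizedExperiment}: rows
#' are called poly(A)-site clusters (width-1 ranges at the cluster seed,
#' with filter flags, gene assignment and proximal/distal rank as row
#' metadata), columns are samples with \code{group} and \code{replicate}
#' in \code{colData}, and the \code{"counts"} assay holds per-sample read
#' counts.
#'
#' @export
#' @import SummarizedExperiment
setClass("PasExperiment", contains = "RangedSummarizedExperiment")

setValidity("PasExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0) || any(cnt != round(cnt)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("group", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must carry 'group' and 'replicate'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "pas_ids (rownames) must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a [PasExperiment-class]
#'
#' @param counts integer matrix, PAS x sample; rownames are pas_ids.
#' @param rowRanges \code{GRanges} of cluster seeds, parallel to rows.
#' @param colData \code{DataFrame}/data.frame with at least \code{group}
#'   and \code{replicate}, rownames = sample names.
#' @return a validated \code{PasExperiment}.
#' @export
PasExperiment <- function(counts, rowRanges, colData) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = rowRanges,
        colData = S4Vectors::DataFrame(colData))
    new("PasExperiment", se)
}

#' @describeIn PasExperiment-class the condition group of each sample.
#' @param x a \code{PasExperiment}.
#' @export
setMethod("sampleGroups", "PasExperiment", function(x)
    stats::setNames(as.character(SummarizedExperiment::colData(x)$group),
                    colnames(x)))

#' @describeIn PasExperiment-class gene ids with >= 2 assigned PASs
#'   (APA genes); requires [assignPas()] to have been run.
#' @export
setMethod("apaGenes", "PasExperiment", function(x) {
    gid <- SummarizedExperiment::rowRanges(x)$gene_id
    if (is.null(gid))
        stop("no gene assignment present; run assignPas() first")
    tab <- table(gid[!is.na(gid)])
    sort(names(tab)[tab >= 2L])
})

setMethod("show", "PasExperiment", function(object) {
    callNextMethod()
    grp <- table(SummarizedExperiment::colData(object)$group)
    cat("sample groups:", paste(names(grp), grp, sep = "=", collapse = ", "),
        "\n")
})

#' Flow-cytometry gate thresholds
#'
#' Thresholds defining the mRuby-negative gate (\code{redMax}) and, within
#' it, the GFP-positive ("gate 2") versus GFP-negative ("gate 3") split
#' (\code{greenSplit}) used by [enhancerActivity()].
#'
#' @slot redMax events with red intensity below this are mRuby-negative.
#' @slot greenSplit mRuby-negative events with green intensity at or above
#'   this fall in gate 2, below it in gate 3.
#' @slot minEvents minimum gate-2 occupancy for a non-zero activity call.
#' @export
setClass("GateSet",
    representation(redMax = "numeric", greenSplit = "numeric",
                   minEvents = "integer"))

setValidity("GateSet", function(object) {
    msg <- NULL
    if (!(length(object@redMax) == 1L && is.finite(object@redMax) &&
          object@redMax > 0))
        msg <- c(msg, "redMax must be a single positive finite number")
    if (!(length(object@greenSplit) == 1L && is.finite(object@greenSplit) &&
          object@greenSplit > 0))
        msg <- c(msg, "greenSplit must be a single positive finite number")
    if (object@minEvents < 1L)
        msg <- c(msg, "minEvents must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a [GateSet-class]
#'
#' @param redMax,greenSplit,minEvents see the class documentation.
#' @export
GateSet <- function(redMax, greenSplit, minEvents = 100L) {
    new("GateSet", redMax = as.numeric(redMax),
        greenSplit = as.numeric(greenSplit),
        minEvents = as.integer(minEvents))
}

#' @describeIn GateSet-class upper red-intensity bound of the
#'   mRuby-negative gate.
#' @param x a \code{GateSet}.
#' @export
setMethod("redMax", "GateSet", function(x) x@redMax)

#' @describeIn GateSet-class green-intensity threshold between gate 3 and
#'   gate 2.
#' @export
setMethod("greenSplit", "GateSet", function(x) x@greenSplit)

#' @describeIn GateSet-class minimum events required in gate 2.
#' @export
setMethod("minEvents", "GateSet", function(x) x@minEvents)

setMethod("show", "GateSet", function(object) {
    cat("GateSet: red <", signif(object@redMax, 4),
        "(mRuby-negative); green split at", signif(object@greenSplit, 4),
        "; min events:", object@minEvents, "\n")
})
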