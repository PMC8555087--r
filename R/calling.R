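#' Read per-sample cleavage events from BED6 files
#'
#' Each BED record carries one read's inferred cleavage position: the
#' 0-based BED start is the position of the last transcribed nucleotide
#' before the poly(A) tail. Records must have at least six fields and a
#' defined strand (\code{+} or \code{-}); anything else is rejected with
#' the file and line number.
#'
#' @param paths character vector of BED6 file paths.
#' @param samples sample id per file; defaults to the file base name.
#' @return a width-1 \code{GRanges} with a \code{sample} column
#'   (1-based start = cleavage site).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t99\t100\tr1\t1\t+", f)
#' readCleavageEvents(f, samples = "s1")
#' @importFrom rtracklayer import
#' @export
readCleavageEvents <- function(paths,
                               samples = sub("\\.bed$", "", basename(paths))) {
    stopifnot(length(paths) == length(samples))
    grs <- vector("list", length(paths))
    for (i in seq_along(paths)) {
        lines <- readLines(paths[i])
        lines <- lines[nzchar(lines)]
        if (length(lines)) {
            fields <- strsplit(lines, "\t", fixed = TRUE)
            nf <- lengths(fields)
            if (any(nf < 6L))
                stop("malformed BED line ", which(nf < 6L)[1L], " in ",
                     paths[i], ": expected >= 6 tab-separated fields")
            str <- vapply(fields, `[[`, character(1L), 6L)
            if (any(!str %in% c("+", "-")))
                stop("unknown strand on line ",
                     which(!str %in% c("+", "-"))[1L], " in ", paths[i],
                     ": strand must be '+' or '-'")
        }
        gr <- rtracklayer::import(paths[i], format = "BED")
        gr <- GRanges(GenomicRanges::seqnames(gr),
                      IRanges(start = GenomicRanges::start(gr), width = 1L),
                      strand = GenomicRanges::strand(gr))
        gr$sample <- rep(samples[i], length(gr))
        grs[[i]] <- gr
    }
    if (!length(grs)) return(GRanges(sample = character()))
    out <- suppressWarnings(do.call(c, grs))
    out
}

#' Cluster cleavage events into poly(A) sites
#'
#' Greedy clustering within each (chromosome, strand): events at identical
#' positions are first aggregated across samples; then, repeatedly, the
#' unassigned position with the highest total read count becomes a cluster
#' seed (ties broken towards the smallest genomic coordinate) and absorbs
#' every unassigned position within \code{w} nt on either side. Cluster
#' counts are the per-sample sums over the absorbed positions, so read
#' counts are conserved exactly. Clusters on different strands never merge.
#'
#' @param events width-1 \code{GRanges} with a \code{sample} column, as
#'   from [readCleavageEvents()] or [simulateReads()] (a named list of
#'   per-sample \code{GRanges} is also accepted).
#' @param w cluster half-width in nt; the cluster window spans
#'   \code{seed - w .. seed + w} inclusive. Default 25.
#' @return \code{GRanges} of cluster seeds with columns \code{pas_id},
#'   \code{total} and a \code{counts} matrix column (one column per
#'   sample observed in the input), sorted by position.
#' @examples
#' ev <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(rep(c(100, 110, 130), c(30, 5, 8)), width = 1),
#'     strand = "+")
#' ev$sample <- "s1"
#' clusterEvents(ev, w = 25)  # two clusters: seeds 100 (35 reads) and 130
#' @export
clusterEvents <- function(events, w = 25L) {
    if (is.list(events))
        events <- suppressWarnings(do.call(c, unname(events)))
    stopifnot(is(events, "GRanges"), w >= 0L)
    if (is.null(events$sample))
        stop("events must carry a 'sample' column")
    if (!length(events)) {
        out <- GRanges()
        out$pas_id <- character()
        out$total <- integer()
        out$counts <- matrix(0L, 0L, 0L)
        return(out)
    }
    sampleNames <- sort(unique(events$sample))
    chrom <- as.character(GenomicRanges::seqnames(events))
    strand <- as.character(GenomicRanges::strand(events))
    if (any(strand == "*"))
        stop("events must have a defined strand")
    pos <- GenomicRanges::start(events)
    key <- paste(chrom, strand, pos, sep = "\r")
    tab <- table(factor(key), factor(events$sample, levels = sampleNames))
    counts <- matrix(as.integer(tab), nrow = nrow(tab),
                     dimnames = dimnames(tab))
    parts <- strsplit(rownames(counts), "\r", fixed = TRUE)
    uchrom <- vapply(parts, `[[`, character(1L), 1L)
    ustrand <- vapply(parts, `[[`, character(1L), 2L)
    upos <- as.integer(vapply(parts, `[[`, character(1L), 3L))
    utotal <- rowSums(counts)

    seedRows <- integer(0)
    memberOf <- integer(length(upos))   # row index of each position's seed
    for (grpKey in unique(paste(uchrom, ustrand, sep = "\r"))) {
        rows <- which(paste(uchrom, ustrand, sep = "\r") == grpKey)
        o <- order(upos[rows])
        rows <- rows[o]
        p <- upos[rows]
        t <- utotal[rows]
        n <- length(rows)
        assigned <- logical(n)
        pick <- order(-t, p)           # fixed counts => static greedy order
        for (j in pick) {
            if (assigned[j]) next
            lo <- findInterval(p[j] - w - 1L, p) + 1L
            hi <- findInterval(p[j] + w, p)
            mem <- lo:hi
            mem <- mem[!assigned[mem]]
            assigned[mem] <- TRUE
            memberOf[rows[mem]] <- rows[j]
            seedRows <- c(seedRows, rows[j])
        }
    }
    agg <- rowsum(counts, group = memberOf, reorder = FALSE)
    agg <- agg[match(as.character(seedRows), rownames(agg)), , drop = FALSE]
    ord <- order(uchrom[seedRows], upos[seedRows], ustrand[seedRows])
    seedRows <- seedRows[ord]
    agg <- agg[ord, , drop = FALSE]
    lv <- GenomeInfoDb::seqlevels(events)
    out <- GRanges(
        seqnames = factor(uchrom[seedRows], levels = lv),
        ranges = IRanges(start = upos[seedRows], width = 1L),
        strand = ustrand[seedRows])
    out$pas_id <- sprintf("%s:%d:%s", uchrom[seedRows], upos[seedRows] - 1L,
                          ustrand[seedRows])
    out$total <- as.integer(rowSums(agg))
    dimnames(agg) <- list(out$pas_id, sampleNames)
    out$counts <- agg
    out
}

#' Build a PAS-by-sample count matrix
#'
#' Arranges cluster counts into a [PasExperiment-class] whose columns
#' follow the sample sheet. Samples present in the sheet but absent from
#' the clusters get zero columns; a sample observed in the clusters but
#' missing from the sheet is an error. The grand total of the matrix
#' equals the number of events that went into [clusterEvents()].
#'
#' @param clusters output of [clusterEvents()].
#' @param sampleSheet data.frame with columns \code{sample}, \code{group},
#'   \code{replicate}.
#' @return a [PasExperiment-class].
#' @export
buildCountMatrix <- function(clusters, sampleSheet) {
    stopifnot(is(clusters, "GRanges"),
              all(c("sample", "group", "replicate") %in%
                  colnames(sampleSheet)))
    obs <- colnames(clusters$counts)
    missing <- setdiff(obs, sampleSheet$sample)
    if (length(missing))
        stop("sample(s) missing from sample sheet: ",
             paste(missing, collapse = ", "))
    m <- matrix(0L, nrow = length(clusters), ncol = nrow(sampleSheet),
                dimnames = list(clusters$pas_id, sampleSheet$sample))
    if (length(obs))
        m[, obs] <- clusters$counts[, obs, drop = FALSE]
    rr <- clusters
    rr$counts <- NULL
    cd <- S4Vectors::DataFrame(group = sampleSheet$group,
                               replicate = sampleSheet$replicate,
                               row.names = sampleSheet$sample)
    names(rr) <- rownames(m)
    PasExperiment(counts = m, rowRanges = rr, colData = cd)
}
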