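#' Canonical polyadenylation signal hexamers
#'
#' The twelve canonical metazoan poly(A)-signal variants, sense strand,
#' DNA alphabet. Used as the default \code{signalSet} of
#' [pasFilterParams()]; a custom set can be supplied directly or loaded
#' from a file (one hexamer per line) with [readSignalSet()].
#'
#' @return character vector of 12 hexamers.
#' @examples
#' pasSignalSet()
#' @export
pasSignalSet <- function() {
    c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
      "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' @rdname pasSignalSet
#' @param path file with one hexamer per line.
#' @export
readSignalSet <- function(path) {
    x <- toupper(trimws(readLines(path)))
    x <- x[nzchar(x)]
    validateSignalSet(x)
    x
}

validateSignalSet <- function(x) {
    if (!length(x)) stop("signal set must be non-empty")
    if (any(nchar(x) != 6L) || any(grepl("[^ACGT]", x)))
        stop("signals must be hexamers over the ACGT alphabet")
    invisible(x)
}

#' Sequence-filter parameters
#'
#' Windows are expressed as inclusive sense-strand (transcript
#' orientation) offsets relative to the cleavage site (offset 0 = the
#' last transcribed nucleotide). Defaults: internal-priming scan over
#' -30..+10 for a run of >= 7 consecutive A, and a polyadenylation-signal
#' requirement within -30..0.
#'
#' @param ipWindow integer(2), internal-priming scan window.
#' @param ipRunLength minimum A-run length flagging internal priming.
#' @param signalWindow integer(2), window that must contain a signal.
#' @param signalSet character vector of sense-strand hexamers.
#' @return a validated list of class \code{pas_filter_params}.
#' @export
pasFilterParams <- function(ipWindow = c(-30L, 10L), ipRunLength = 7L,
                            signalWindow = c(-30L, 0L),
                            signalSet = pasSignalSet()) {
    stopifnot(length(ipWindow) == 2L, ipWindow[1L] <= ipWindow[2L],
              length(signalWindow) == 2L,
              signalWindow[1L] <= signalWindow[2L],
              ipRunLength >= 1L)
    validateSignalSet(signalSet)
    structure(list(ipWindow = as.integer(ipWindow),
                   ipRunLength = as.integer(ipRunLength),
                   signalWindow = as.integer(signalWindow),
                   signalSet = toupper(signalSet)),
              class = "pas_filter_params")
}

#' Extract the sense-strand sequence context around cleavage sites
#'
#' Returns, for each site, the transcript-orientation sequence covering
#' inclusive offsets \code{fromOff..toOff} relative to the cleavage site:
#' on the + strand the genomic slice \code{[site+fromOff, site+toOff]};
#' on the - strand the reverse complement of
#' \code{[site-toOff, site-fromOff]}. Windows are clipped at chromosome
#' bounds, in which case the returned string is shorter than
#' \code{toOff - fromOff + 1}.
#'
#' @param genome named \code{DNAStringSet}.
#' @param chrom,strand,site parallel vectors locating the cleavage sites
#'   (1-based genomic coordinate of the last transcribed nucleotide).
#' @param fromOff,toOff inclusive sense-strand offsets.
#' @return character vector of contexts.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAA"))
#' senseContext(g, "chr1", "+", 5, -1, 1)  # "TAC"
#' senseContext(g, "chr1", "-", 5, -1, 1)  # "GTA" (revcomp of "TAC")
#' @export
senseContext <- function(genome, chrom, strand, site, fromOff, toOff) {
    stopifnot(fromOff <= toOff)
    n <- max(length(chrom), length(strand), length(site))
    chrom <- rep_len(as.character(chrom), n)
    strand <- rep_len(as.character(strand), n)
    site <- rep_len(as.integer(site), n)
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
        stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    chromStr <- as.character(genome)
    lens <- nchar(chromStr)[match(chrom, names(genome))]
    gFrom <- ifelse(strand == "+", site + fromOff, site - toOff)
    gTo <- ifelse(strand == "+", site + toOff, site - fromOff)
    gFrom <- pmax(gFrom, 1L)
    gTo <- pmin(gTo, lens)
    out <- character(n)
    ok <- gFrom <= gTo
    out[ok] <- substring(chromStr[match(chrom[ok], names(genome))],
                         gFrom[ok], gTo[ok])
    neg <- ok & strand == "-"
    if (any(neg)) out[neg] <- revComp(out[neg])
    out
}

#' Internal-priming artifact test
#'
#' A site is flagged as an internal-priming artifact if its sense-strand
#' context over \code{ipWindow} contains a run of at least
#' \code{ipRunLength} consecutive \code{A}: the oligo-dT primer of the 3'
#' library protocol can anneal to such genomic A-rich stretches instead
#' of a true poly(A) tail.
#'
#' @param genome named \code{DNAStringSet}.
#' @param sites width-1 \code{GRanges} of cluster seeds (or a
#'   [PasExperiment-class]).
#' @param params a [pasFilterParams()] list.
#' @return logical vector, one per site.
#' @export
isInternalPriming <- function(genome, sites, params = pasFilterParams()) {
    gr <- if (is(sites, "PasExperiment"))
        SummarizedExperiment::rowRanges(sites) else sites
    ctx <- senseContext(genome, as.character(GenomicRanges::seqnames(gr)),
                        as.character(GenomicRanges::strand(gr)),
                        GenomicRanges::start(gr),
                        params$ipWindow[1L], params$ipWindow[2L])
    grepl(paste0("A{", params$ipRunLength, ",}"), ctx)
}

#' Polyadenylation-signal test
#'
#' TRUE when at least one hexamer of \code{signalSet} lies fully inside
#' the sense-strand context over \code{signalWindow} (with the default
#' -30..0 window, valid start offsets are -30..-5; a hexamer straddling
#' the cleavage site does not count).
#'
#' @inheritParams isInternalPriming
#' @return logical vector, one per site.
#' @export
hasPolyASignal <- function(genome, sites, params = pasFilterParams()) {
    gr <- if (is(sites, "PasExperiment"))
        SummarizedExperiment::rowRanges(sites) else sites
    ctx <- senseContext(genome, as.character(GenomicRanges::seqnames(gr)),
                        as.character(GenomicRanges::strand(gr)),
                        GenomicRanges::start(gr),
                        params$signalWindow[1L], params$signalWindow[2L])
    containsAnyHexamer(ctx, params$signalSet)
}

#' Filter a PAS database on sequence context
#'
#' Evaluates both sequence filters for every cluster, records the flags
#' (\code{internal_priming}, \code{has_signal}) on the row metadata, and
#' keeps only clusters that are not internal-priming artifacts AND carry
#' a polyadenylation signal. Both filters are always evaluated so the
#' removal log can report every reason (\code{IP}, \code{NO_SIGNAL}, or
#' \code{IP,NO_SIGNAL}). Decisions are per-cluster, so the result does
#' not depend on input order.
#'
#' @param x a [PasExperiment-class] (or \code{GRanges} of seeds).
#' @param genome named \code{DNAStringSet}.
#' @param params a [pasFilterParams()] list.
#' @return list with \code{kept} (filtered object), \code{flagged} (the
#'   full object with flag columns) and \code{removalLog} (data.frame:
#'   pas_id, reason).
#' @export
filterPas <- function(x, genome, params = pasFilterParams()) {
    ip <- isInternalPriming(genome, x, params)
    sig <- hasPolyASignal(genome, x, params)
    gr <- if (is(x, "PasExperiment"))
        SummarizedExperiment::rowRanges(x) else x
    flagged <- x
    if (is(x, "PasExperiment")) {
        SummarizedExperiment::rowRanges(flagged)$internal_priming <- ip
        SummarizedExperiment::rowRanges(flagged)$has_signal <- sig
    } else {
        flagged$internal_priming <- ip
        flagged$has_signal <- sig
    }
    keep <- !ip & sig
    reason <- character(sum(!keep))
    bad <- which(!keep)
    reason <- paste0(ifelse(ip[bad], "IP", ""),
                     ifelse(ip[bad] & !sig[bad], ",", ""),
                     ifelse(!sig[bad], "NO_SIGNAL", ""))
    pasIds <- if (is(x, "PasExperiment")) rownames(x) else gr$pas_id
    list(kept = flagged[keep, ],
         flagged = flagged,
         removalLog = data.frame(pas_id = pasIds[bad], reason = reason,
                                 stringsAsFactors = FALSE))
}
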