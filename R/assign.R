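#' Extend annotated 3' ends for PAS-to-gene assignment
#'
#' Because 3'UTR annotations are typically too short for 3' end
#' sequencing data, each gene's assignment region is extended downstream
#' of its annotated 3' end by \code{min(cap, floor(d / 2))} nt, where
#' \code{d} is the sense-strand distance from the annotated 3' end to the
#' start (5' end) of the nearest downstream gene on the same chromosome
#' and strand. Genes with no downstream neighbour are extended by
#' \code{min(cap, distance to the chromosome end)}. Abutting genes
#' (\code{d = 0}) get no extension; opposite-strand genes never cap the
#' extension.
#'
#' @param annotation \code{GRanges} with \code{gene_id} and
#'   \code{annotated3p} (1-based coordinate of the 3'-terminal annotated
#'   nucleotide), with \code{seqlengths} set, as produced by
#'   [simulateGenome()] or [readGeneAnnotation()].
#' @param cap maximum extension in nt (default 5000).
#' @return the annotation with added columns \code{extension} and
#'   \code{extended3p} (1-based coordinate of the last nucleotide of the
#'   extended region).
#' @examples
#' ann <- GenomicRanges::GRanges(c("c:1-1000:+", "c:4001-5000:+"),
#'     gene_id = c("a", "b"), annotated3p = c(1000L, 5000L))
#' GenomeInfoDb::seqlengths(ann) <- c(c = 20000L)
#' extendThreePrime(ann)$extension  # 1500 (= floor(3000/2)), then 5000
#' @export
extendThreePrime <- function(annotation, cap = 5000L) {
    stopifnot(is(annotation, "GRanges"),
              !is.null(annotation$annotated3p))
    lens <- GenomeInfoDb::seqlengths(annotation)
    if (any(is.na(lens)))
        stop("annotation must carry seqlengths for every chromosome")
    n <- length(annotation)
    chrom <- as.character(GenomicRanges::seqnames(annotation))
    strand <- as.character(GenomicRanges::strand(annotation))
    a3p <- annotation$annotated3p
    ext <- integer(n)
    for (i in seq_len(n)) {
        same <- which(chrom == chrom[i] & strand == strand[i])
        same <- setdiff(same, i)
        if (strand[i] == "+") {
            startsDown <- GenomicRanges::start(annotation)[same]
            startsDown <- startsDown[startsDown > a3p[i]]
            d <- if (length(startsDown))
                min(startsDown) - a3p[i] - 1L
            else lens[[chrom[i]]] - a3p[i]
        } else {
            endsDown <- GenomicRanges::end(annotation)[same]
            endsDown <- endsDown[endsDown < a3p[i]]
            d <- if (length(endsDown)) a3p[i] - max(endsDown) - 1L
                 else a3p[i] - 1L
        }
        d <- max(d, 0L)
        halve <- if (strand[i] == "+")
            length(startsDown) > 0L else length(endsDown) > 0L
        ext[i] <- if (halve) min(cap, d %/% 2L) else min(cap, d)
    }
    annotation$extension <- as.integer(ext)
    annotation$extended3p <- as.integer(
        ifelse(strand == "+", a3p + ext, a3p - ext))
    annotation
}

# full assignment region (gene body plus 3' extension) per gene
assignmentRegions <- function(extGenes) {
    strand <- as.character(GenomicRanges::strand(extGenes))
    lo <- ifelse(strand == "+", GenomicRanges::start(extGenes),
                 extGenes$extended3p)
    hi <- ifelse(strand == "+", extGenes$extended3p,
                 GenomicRanges::end(extGenes))
    GRanges(GenomicRanges::seqnames(extGenes),
            IRanges(start = pmin(lo, hi), end = pmax(lo, hi)),
            strand = strand, gene_id = extGenes$gene_id,
            annotated3p = extGenes$annotated3p)
}

#' Assign filtered PASs to genes
#'
#' A PAS is assigned to a gene when its seed lies within the gene's body
#' plus 3' extension on the gene's strand. When several genes' regions
#' contain the seed, the gene whose annotated 3' end is nearest (absolute
#' sense-strand distance; ties broken towards the lexicographically
#' smallest \code{gene_id}) wins, so assignment is a function. Unassigned
#' PASs get \code{gene_id = NA} and are excluded from downstream usage
#' analysis.
#'
#' @param x a [PasExperiment-class] (or \code{GRanges} of seeds).
#' @param extGenes output of [extendThreePrime()].
#' @return \code{x} with a \code{gene_id} row column.
#' @importFrom GenomicRanges findOverlaps
#' @export
assignPas <- function(x, extGenes) {
    gr <- if (is(x, "PasExperiment"))
        SummarizedExperiment::rowRanges(x) else x
    regions <- assignmentRegions(extGenes)
    hits <- findOverlaps(gr, regions, ignore.strand = FALSE)
    gid <- rep(NA_character_, length(gr))
    if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        s <- S4Vectors::subjectHits(hits)
        dist <- abs(GenomicRanges::start(gr)[q] - regions$annotated3p[s])
        ord <- order(q, dist, regions$gene_id[s])
        q <- q[ord]; s <- s[ord]
        first <- !duplicated(q)
        gid[q[first]] <- regions$gene_id[s[first]]
    }
    if (is(x, "PasExperiment")) {
        SummarizedExperiment::rowRanges(x)$gene_id <- gid
    } else {
        x$gene_id <- gid
    }
    x
}

#' Rank assigned PASs from proximal to distal
#'
#' Within each gene, PASs are ordered by sense-strand position from the
#' gene's start: rank 0 is the most proximal PAS (nearest the gene start
#' in the direction of transcription), the highest rank the most distal.
#' Unassigned PASs keep \code{rank = NA}.
#'
#' @param x a [PasExperiment-class] (or \code{GRanges}) carrying
#'   \code{gene_id}, as from [assignPas()].
#' @return \code{x} with an integer \code{rank} row column. Genes with
#'   two or more assigned PASs are the APA genes ([apaGenes()]).
#' @export
rankPas <- function(x) {
    gr <- if (is(x, "PasExperiment"))
        SummarizedExperiment::rowRanges(x) else x
    if (is.null(gr$gene_id)) stop("run assignPas() first")
    pos <- GenomicRanges::start(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    rank <- rep(NA_integer_, length(gr))
    for (g in unique(gr$gene_id[!is.na(gr$gene_id)])) {
        idx <- which(gr$gene_id == g)
        sense <- if (strand[idx[1L]] == "+") pos[idx] else -pos[idx]
        rank[idx] <- order(order(sense)) - 1L
    }
    if (is(x, "PasExperiment")) {
        SummarizedExperiment::rowRanges(x)$rank <- rank
    } else {
        x$rank <- rank
    }
    x
}

#' Read a gene annotation TSV
#'
#' Reads the 0-based half-open annotation format written by
#' [writeSimulation()] (columns gene_id, chrom, start, end, strand,
#' annotated_3p_end) into the 1-based \code{GRanges} used internally.
#'
#' @param path annotation TSV.
#' @param seqlengths named integer vector of chromosome lengths (e.g.
#'   from the genome FASTA); required for [extendThreePrime()].
#' @return \code{GRanges} with \code{gene_id} and \code{annotated3p}.
#' @importFrom utils read.delim
#' @export
readGeneAnnotation <- function(path, seqlengths) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand",
              "annotated_3p_end")
    if (!all(need %in% colnames(tab)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    ann <- GRanges(factor(tab$chrom, levels = names(seqlengths)),
                   IRanges(start = tab$start + 1L, end = tab$end),
                   strand = tab$strand,
                   gene_id = tab$gene_id,
                   annotated3p = as.integer(tab$annotated_3p_end + 1L))
    GenomeInfoDb::seqlengths(ann) <- seqlengths
    ann
}
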