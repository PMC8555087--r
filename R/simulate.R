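#' Simulate a genome and non-overlapping gene annotation
#'
#' Places \code{nGenes} genes on two synthetic chromosomes of uniform base
#' composition. Each gene gets a territory wide enough for its body, a
#' downstream region where true PASs will later be planted, and an
#' intergenic gap, so that genes never overlap on either strand and every
#' downstream PAS falls inside the 3'UTR extension region used for gene
#' assignment.
#'
#' Coordinates are 1-based inclusive inside R (\code{GRanges}); files
#' written by [writeSimulation()] use the 0-based half-open convention of
#' BED and of the annotation TSV. The annotated 3' end is the coordinate
#' of the gene's last transcribed (3'-terminal) annotated nucleotide.
#'
#' @param cfg an [ApaSimConfig-class].
#' @param chromLength optional integer(1): force each chromosome to this
#'   length. An error is raised if the genes do not fit.
#' @return list with \code{genome} (a named \code{DNAStringSet}) and
#'   \code{annotation} (a \code{GRanges} with \code{gene_id} and
#'   \code{annotated3p}).
#' @examples
#' sim <- simulateGenome(ApaSimConfig(nGenes = 10, seed = 3))
#' @importFrom GenomicRanges GRanges strand start end
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
#' @export
simulateGenome <- function(cfg, chromLength = NULL) {
    stopifnot(is(cfg, "ApaSimConfig"))
    validObject(cfg)
    withSeed(deriveSeed(cfg@seed, 1L), {
        nChrom <- if (cfg@nGenes > 1L) 2L else 1L
        geneChrom <- rep(seq_len(nChrom), length.out = cfg@nGenes)
        bodyLen <- if (cfg@nGenes)
            sample(300:800, cfg@nGenes, replace = TRUE) else integer()
        geneStrand <- if (cfg@nGenes)
            sample(c("+", "-"), cfg@nGenes, replace = TRUE) else character()
        pasRoom <- 340L   # room downstream of the annotated 3' end
        gap <- 400L       # intergenic spacer inside each territory
        flank <- 200L

        starts <- ends <- a3p <- integer(cfg@nGenes)
        chromLens <- integer(nChrom)
        for (ch in seq_len(nChrom)) {
            idx <- which(geneChrom == ch)
            cursor <- flank + 1L
            for (i in idx) {
                if (geneStrand[i] == "+") {
                    starts[i] <- cursor
                    ends[i] <- cursor + bodyLen[i] - 1L
                    a3p[i] <- ends[i]
                } else {
                    starts[i] <- cursor + pasRoom
                    ends[i] <- starts[i] + bodyLen[i] - 1L
                    a3p[i] <- starts[i]
                }
                cursor <- cursor + bodyLen[i] + pasRoom + gap
            }
            chromLens[ch] <- cursor + flank
        }
        if (!is.null(chromLength)) {
            if (any(chromLens > chromLength))
                stop("genome too short to place ", cfg@nGenes,
                     " genes: need >= ", max(chromLens), " nt per chromosome")
            chromLens[] <- as.integer(chromLength)
        }
        chromNames <- paste0("chr", seq_len(nChrom))
        seqs <- DNAStringSet(vapply(chromLens, function(n)
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""), character(1L)))
        names(seqs) <- chromNames

        ann <- GRanges(
            seqnames = factor(chromNames[geneChrom], levels = chromNames),
            ranges = IRanges(start = starts, end = ends),
            strand = geneStrand,
            gene_id = sprintf("gene%04d", seq_len(cfg@nGenes)),
            annotated3p = a3p)
        GenomeInfoDb::seqlengths(ann) <- stats::setNames(chromLens,
                                                         chromNames)
        list(genome = seqs, annotation = ann)
    })
}

# write `seq` on the sense strand of `strand` so that its first base sits
# at sense offset `fromOff` relative to `site` (1-based genomic, chars)
writeSenseSeq <- function(chars, strand, site, fromOff, seqStr) {
    n <- nchar(seqStr)
    if (strand == "+") {
        pos <- site + fromOff + seq_len(n) - 1L
        chars[pos] <- strsplit(seqStr, "", fixed = TRUE)[[1L]]
    } else {
        pos <- site - fromOff - n + seq_len(n)
        chars[pos] <- strsplit(revComp(seqStr), "", fixed = TRUE)[[1L]]
    }
    chars
}

readSenseSeq <- function(chars, strand, site, fromOff, toOff) {
    if (strand == "+") {
        paste(chars[(site + fromOff):(site + toOff)], collapse = "")
    } else {
        revComp(paste(chars[(site - toOff):(site - fromOff)],
                      collapse = ""))
    }
}

# substitute bases (with C) until the sense window [fromOff, toOff] around
# `site` has no A-run >= runLen; positions in `protect` (sense offsets)
# are never touched
breakARuns <- function(chars, strand, site, fromOff, toOff, runLen,
                       protect = integer()) {
    repeat {
        ctx <- readSenseSeq(chars, strand, site, fromOff, toOff)
        m <- regexpr(paste0("A{", runLen, ",}"), ctx)
        if (m == -1L) return(chars)
        offs <- fromOff + (as.integer(m) - 1L) +
            seq_len(attr(m, "match.length")) - 1L
        cand <- setdiff(offs, protect)
        pick <- cand[ceiling(length(cand) / 2)]
        chars <- writeSenseSeq(chars, strand, site, pick, "C")
    }
}

# substitute bases until no hexamer of `signals` occurs with its start in
# sense offsets [fromOff, toOff - 5] around `site`
eraseSignals <- function(chars, strand, site, fromOff, toOff, signals,
                         protect = integer()) {
    rx <- paste0("(", paste(signals, collapse = "|"), ")")
    repeat {
        ctx <- readSenseSeq(chars, strand, site, fromOff, toOff)
        m <- regexpr(rx, ctx)
        if (m == -1L) return(chars)
        offs <- fromOff + (as.integer(m) - 1L) + 0:5
        cand <- setdiff(offs, protect)
        chars <- writeSenseSeq(chars, strand, site,
                               cand[ceiling(length(cand) / 2)], "C")
    }
}

#' Plant true poly(A) sites and internal-priming artifacts
#'
#' For every gene, 1--3 cleavage sites are placed downstream of the
#' annotated 3' end, at least 60 nt apart. Each true site receives the
#' canonical polyadenylation signal \code{AATAAA} written on the sense
#' strand at offset -21, and any accidental run of >= 7 A within sense
#' offsets -30..+10 is broken by base substitution, so that every true
#' site passes both downstream sequence filters by construction. One
#' internal-priming artifact site per gene is placed inside the gene body:
#' it sits on a written run of 7 A (sense offsets 0..+6) and any
#' polyadenylation signal within its -30..0 window is erased, so that it
#' fails the internal-priming filter by construction.
#'
#' Planted switch genes (half class I, half class II, drawn among genes
#' with >= 2 PASs) have balanced baseline usage of their proximal/distal
#' pair; the low-temperature group shifts usage by \code{switchDelta}
#' towards the distal site (class I) or the proximal site (class II).
#' Planted DE genes receive a log2 expression shift of alternating sign.
#'
#' @param genome,annotation output of [simulateGenome()].
#' @param cfg the same [ApaSimConfig-class].
#' @return list with \code{genome} (sequences after planting) and
#'   \code{truth} (an [ApaSimTruth-class]).
#' @export
plantPasAndArtifacts <- function(genome, annotation, cfg) {
    stopifnot(is(cfg, "ApaSimConfig"))
    signals <- pasSignalSet()
    withSeed(deriveSeed(cfg@seed, 2L), {
        charsList <- lapply(as.character(genome), function(s)
            strsplit(s, "", fixed = TRUE)[[1L]])
        n <- length(annotation)
        pasList <- vector("list", n)

        nPas <- if (n) sample(seq(cfg@pasPerGeneRange[1L],
                                  cfg@pasPerGeneRange[2L]),
                              n, replace = TRUE) else integer()
        # switch genes need >= 2 PASs
        multi <- which(nPas >= 2L)
        nSwitch <- min(round(cfg@switchFraction * n), length(multi))
        nSwitch <- 2L * (nSwitch %/% 2L)   # even split over classes I/II
        switchIdx <- if (nSwitch) sort(sample(multi, nSwitch)) else integer()
        switchClass <- rep(c("I", "II"), length.out = length(switchIdx))
        nDe <- round(cfg@deFraction * n)
        deIdx <- if (nDe) sort(sample(setdiff(seq_len(n), switchIdx),
                                      min(nDe, n - length(switchIdx))))
                 else integer()
        deShift <- rep(c(1, -1), length.out = length(deIdx)) * cfg@deLog2fc

        artSite <- integer(n)
        for (i in seq_len(n)) {
            g <- annotation[i]
            chrom <- as.character(GenomicRanges::seqnames(g))
            strand <- as.character(GenomicRanges::strand(g))
            a3p <- g$annotated3p
            k <- nPas[i]
            offs <- cumsum(c(sample(40:80, 1L),
                             if (k > 1L) sample(60:120, k - 1L,
                                                replace = TRUE)))
            sites <- if (strand == "+") a3p + offs else a3p - offs
            ch <- charsList[[chrom]]
            for (s in sites) {
                ch <- writeSenseSeq(ch, strand, s, -21L, "AATAAA")
                ch <- breakARuns(ch, strand, s, -30L, 10L, 7L,
                                 protect = -21:-16)
            }
            # artifact inside the gene body, >= 60 nt from every true PAS
            art <- if (strand == "+") a3p - 140L else a3p + 140L
            ch <- writeSenseSeq(ch, strand, art, 0L, "AAAAAAA")
            ch <- eraseSignals(ch, strand, art, -30L, 0L, signals,
                               protect = 0:6)
            charsList[[chrom]] <- ch
            artSite[i] <- art

            base <- if (i %in% switchIdx) {
                if (k == 2L) c(0.5, 0.5) else c(0.4, 0.2, 0.4)
            } else {
                p <- stats::rgamma(k, shape = 5)
                p / sum(p)
            }
            low <- base
            if (i %in% switchIdx) {
                cls <- switchClass[match(i, switchIdx)]
                d <- cfg@switchDelta
                if (cls == "I") {        # distal preferred at low temp
                    low[1L] <- low[1L] - d; low[k] <- low[k] + d
                } else {
                    low[1L] <- low[1L] + d; low[k] <- low[k] - d
                }
            }
            pasList[[i]] <- data.frame(
                chrom = chrom, strand = strand, site = sites,
                gene_id = g$gene_id, pas_index = seq_len(k) - 1L,
                usage_low = low, usage_high = base)
        }

        pasTab <- if (n) do.call(rbind, pasList) else
            data.frame(chrom = character(), strand = character(),
                       site = integer(), gene_id = character(),
                       pas_index = integer(), usage_low = numeric(),
                       usage_high = numeric())
        lv <- names(genome)
        truePas <- GRanges(
            seqnames = factor(pasTab$chrom, levels = lv),
            ranges = IRanges(start = pasTab$site, width = 1L),
            strand = pasTab$strand,
            gene_id = pasTab$gene_id, pas_index = pasTab$pas_index,
            usage_low = pasTab$usage_low, usage_high = pasTab$usage_high)
        artifacts <- GRanges(
            seqnames = factor(as.character(
                GenomicRanges::seqnames(annotation)), levels = lv),
            ranges = IRanges(start = artSite, width = 1L),
            strand = GenomicRanges::strand(annotation),
            gene_id = annotation$gene_id)
        truth <- new("ApaSimTruth",
            truePas = truePas,
            artifactSites = artifacts,
            switchGenes = S4Vectors::DataFrame(
                gene_id = annotation$gene_id[switchIdx],
                class = switchClass),
            deGenes = S4Vectors::DataFrame(
                gene_id = annotation$gene_id[deIdx],
                log2_shift = deShift))
        genome2 <- DNAStringSet(vapply(charsList, paste, character(1L),
                                       collapse = ""))
        names(genome2) <- names(genome)
        list(genome = genome2, truth = truth)
    })
}

# draw signed jitter from a discretized double-geometric (p = 0.5)
# truncated at +/- scale
sampleJitter <- function(n, scale) {
    if (scale == 0L || n == 0L) return(integer(n))
    j <- c(-(scale:1), 0L, 1:scale)
    w <- 0.5^abs(j)
    sample(j, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate per-sample read 3' end positions
#'
#' Per sample, each gene's read total is drawn from a negative binomial
#' with mean \code{geneMean} (times \code{2^log2_shift} in the low group
#' for planted DE genes) and dispersion \code{geneDispersion}. An
#' \code{artifactFraction} binomial share of the gene's reads is emitted
#' exactly at the gene's internal-priming site; the remainder is split
#' multinomially over the gene's true PASs using the group's usage
#' proportions, and each of those reads records its cleavage position as
#' the true site plus a signed jitter drawn from a symmetric discretized
#' double-geometric distribution truncated at \code{+/- jitterScale},
#' reflecting the imprecision of cleavage and polyadenylation.
#'
#' @param genome planted genome (used only for bounds checking).
#' @param truth an [ApaSimTruth-class].
#' @param cfg the same [ApaSimConfig-class].
#' @return named \code{list} of width-1 \code{GRanges} (one per sample,
#'   one range per read); sample names are \code{<group>_<replicate>}.
#' @export
simulateReads <- function(genome, truth, cfg) {
    stopifnot(is(cfg, "ApaSimConfig"), is(truth, "ApaSimTruth"))
    tp <- truePas(truth)
    art <- artifactSites(truth)
    de <- deGenes(truth)
    geneIds <- unique(tp$gene_id)
    lowLabel <- cfg@groups[1L]
    samples <- paste(rep(cfg@groups, each = cfg@nReplicates),
                     rep(seq_len(cfg@nReplicates), length(cfg@groups)),
                     sep = "_")
    groupOf <- rep(cfg@groups, each = cfg@nReplicates)

    byGene <- split(seq_along(tp), tp$gene_id)
    artOf <- stats::setNames(seq_along(art), art$gene_id)
    shiftOf <- stats::setNames(rep(0, length(geneIds)), geneIds)
    if (nrow(de)) shiftOf[de$gene_id] <- de$log2_shift

    withSeed(deriveSeed(cfg@seed, 3L), {
        out <- vector("list", length(samples))
        names(out) <- samples
        for (si in seq_along(samples)) {
            grp <- groupOf[si]
            usageCol <- if (grp == lowLabel) "usage_low" else "usage_high"
            chromV <- strandV <- character(0)
            posV <- integer(0)
            chromL <- list(); strandL <- list(); posL <- list()
            for (g in geneIds) {
                rows <- byGene[[g]]
                mu <- cfg@geneMean *
                    if (grp == lowLabel) 2^shiftOf[[g]] else 1
                total <- stats::rnbinom(1L, mu = mu,
                                        size = 1 / cfg@geneDispersion)
                if (total == 0L) next
                nArt <- stats::rbinom(1L, total, cfg@artifactFraction)
                nTrue <- total - nArt
                counts <- if (nTrue)
                    as.integer(stats::rmultinom(
                        1L, nTrue,
                        S4Vectors::mcols(tp)[rows, usageCol]))
                    else integer(length(rows))
                sites <- rep(GenomicRanges::start(tp)[rows], counts)
                jit <- sampleJitter(length(sites), cfg@jitterScale)
                pos <- sites + jit
                if (nArt) {
                    ai <- artOf[[g]]
                    pos <- c(pos, rep(GenomicRanges::start(art)[ai], nArt))
                }
                chromL[[g]] <- rep(as.character(
                    GenomicRanges::seqnames(tp))[rows[1L]], length(pos))
                strandL[[g]] <- rep(as.character(
                    GenomicRanges::strand(tp))[rows[1L]], length(pos))
                posL[[g]] <- pos
            }
            chromV <- unlist(chromL, use.names = FALSE)
            strandV <- unlist(strandL, use.names = FALSE)
            posV <- unlist(posL, use.names = FALSE)
            gr <- GRanges(
                seqnames = factor(if (length(chromV)) chromV
                                  else character(), levels = names(genome)),
                ranges = IRanges(start = if (length(posV)) posV
                                 else integer(), width = 1L),
                strand = if (length(strandV)) strandV else character())
            gr$sample <- rep(samples[si], length(gr))
            out[[si]] <- gr
        }
        out
    })
}

#' Generate a complete synthetic APA dataset
#'
#' Convenience wrapper running [simulateGenome()],
#' [plantPasAndArtifacts()] and [simulateReads()] under one seed.
#'
#' @param cfg an [ApaSimConfig-class].
#' @return list with \code{genome}, \code{annotation}, \code{truth},
#'   \code{events} (named list of per-sample \code{GRanges}) and
#'   \code{sampleSheet} (data.frame: sample, group, replicate).
#' @examples
#' sim <- simulateApaDataset(ApaSimConfig(nGenes = 10, seed = 2))
#' lengths(sim$events)
#' @export
simulateApaDataset <- function(cfg) {
    g <- simulateGenome(cfg)
    pl <- plantPasAndArtifacts(g$genome, g$annotation, cfg)
    ev <- simulateReads(pl$genome, pl$truth, cfg)
    sheet <- data.frame(
        sample = names(ev),
        group = sub("_[0-9]+$", "", names(ev)),
        replicate = as.integer(sub("^.*_", "", names(ev))),
        stringsAsFactors = FALSE)
    list(genome = pl$genome, annotation = g$annotation, truth = pl$truth,
         events = ev, sampleSheet = sheet)
}

#' Write a simulated dataset to disk
#'
#' Writes the genome as FASTA, the annotation as a 0-based half-open TSV
#' (gene_id, chrom, start, end, strand, annotated_3p_end), one BED6 file
#' of read 3' ends per sample (name = sample id, score = 1), the truth
#' tables as TSV, and a sample sheet TSV with file paths.
#'
#' @param sim output of [simulateApaDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the sample sheet.
#' @importFrom Biostrings writeXStringSet
#' @importFrom utils write.table
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    ann <- sim$annotation
    annTab <- data.frame(
        gene_id = ann$gene_id,
        chrom = as.character(GenomicRanges::seqnames(ann)),
        start = GenomicRanges::start(ann) - 1L,
        end = GenomicRanges::end(ann),
        strand = as.character(GenomicRanges::strand(ann)),
        annotated_3p_end = ann$annotated3p - 1L)
    write.table(annTab, file.path(dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- character(length(sim$events))
    for (i in seq_along(sim$events)) {
        s <- names(sim$events)[i]
        paths[i] <- file.path(dir, paste0(s, ".bed"))
        gr <- sim$events[[i]]
        bed <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::start(gr),
            name = s, score = 1L,
            strand = as.character(GenomicRanges::strand(gr)))
        write.table(bed, paths[i], sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    sheet <- sim$sampleSheet
    sheet$path <- paths
    write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tp <- truePas(sim$truth)
    write.table(data.frame(
        gene_id = tp$gene_id,
        chrom = as.character(GenomicRanges::seqnames(tp)),
        strand = as.character(GenomicRanges::strand(tp)),
        site = GenomicRanges::start(tp) - 1L,
        pas_index = tp$pas_index,
        usage_low = tp$usage_low, usage_high = tp$usage_high),
        file.path(dir, "truth_pas.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    art <- artifactSites(sim$truth)
    write.table(data.frame(
        gene_id = art$gene_id,
        chrom = as.character(GenomicRanges::seqnames(art)),
        strand = as.character(GenomicRanges::strand(art)),
        site = GenomicRanges::start(art) - 1L),
        file.path(dir, "truth_artifacts.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    write.table(as.data.frame(switchGenes(sim$truth)),
        file.path(dir, "truth_switches.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    write.table(as.data.frame(deGenes(sim$truth)),
        file.path(dir, "truth_de.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(file.path(dir, "samples.tsv"))
}
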