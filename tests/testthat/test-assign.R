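# two-gene annotation with a controlled sense-strand gap d between the
# first gene's annotated 3' end and the downstream gene's start
gapAnnotation <- function(d, strand = "+", chromLen = 3e6L) {
    if (strand == "+") {
        a3p <- 1000L
        g <- GenomicRanges::GRanges("c",
            IRanges::IRanges(start = c(1L, a3p + d + 1L),
                             end = c(a3p, a3p + d + 500L)),
            strand = strand, gene_id = c("a", "b"),
            annotated3p = c(a3p, a3p + d + 500L))
    } else {
        a3p <- chromLen - 1000L
        g <- GenomicRanges::GRanges("c",
            IRanges::IRanges(start = c(a3p, a3p - d - 500L),
                             end = c(chromLen, a3p - d - 1L)),
            strand = strand, gene_id = c("a", "b"),
            annotated3p = c(a3p, a3p - d - 500L))
    }
    GenomeInfoDb::seqlengths(g) <- c(c = chromLen)
    g
}

test_that("3' extension is min(cap, floor(d/2)) towards a downstream gene", {
    for (strand in c("+", "-")) {
        for (d in c(0L, 1L, 2L, 9999L, 10000L, 10001L, 1000000L)) {
            ext <- extendThreePrime(gapAnnotation(d, strand))
            expect_equal(ext$extension[1L], min(5000L, d %/% 2L),
                         info = paste("strand", strand, "d", d))
        }
    }
    # worked example: 3' end 1000 (+), next gene starts at 4000 (0-based)
    ext <- extendThreePrime(gapAnnotation(3000L, "+"))
    expect_equal(ext$extension[1L], 1500L)
    expect_equal(ext$extended3p[1L], 2500L)
})

test_that("without a downstream gene the chromosome end caps the extension", {
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(1L, 1000L),
                                strand = "+", gene_id = "a",
                                annotated3p = 1000L)
    GenomeInfoDb::seqlengths(g) <- c(c = 10000L)
    expect_equal(extendThreePrime(g)$extension, 5000L)
    GenomeInfoDb::seqlengths(g) <- c(c = 1200L)
    expect_equal(extendThreePrime(g)$extension, 200L)
})

test_that("PASs are assigned inside and only inside the extended span", {
    ext <- extendThreePrime(gapAnnotation(3000L, "+"))  # gene a ends 2500
    pas <- GenomicRanges::GRanges("c",
        IRanges::IRanges(c(2400L, 2600L), width = 1L), strand = "+",
        pas_id = c("in", "out"))
    asn <- assignPas(pas, ext)
    expect_equal(asn$gene_id, c("a", NA))

    # strand mismatch is never assigned
    pasM <- GenomicRanges::GRanges("c", IRanges::IRanges(2400L, 2400L),
                                   strand = "-", pas_id = "m")
    expect_true(is.na(assignPas(pasM, ext)$gene_id))
})

test_that("overlapping regions resolve to the nearest annotated 3' end", {
    g <- GenomicRanges::GRanges("c",
        IRanges::IRanges(start = c(1L, 150L), end = c(100L, 260L)),
        strand = "+", gene_id = c("b_far", "a_near"),
        annotated3p = c(100L, 260L))
    GenomeInfoDb::seqlengths(g) <- c(c = 100000L)
    ext <- extendThreePrime(g)
    # site 290: inside both extensions; distances 190 vs 30
    pas <- GenomicRanges::GRanges("c", IRanges::IRanges(290L, 290L),
                                  strand = "+", pas_id = "p")
    expect_equal(assignPas(pas, ext)$gene_id, "a_near")

    # exact tie in distance -> lexicographically smallest gene_id
    gTie <- GenomicRanges::GRanges("c",
        IRanges::IRanges(start = c(1L, 200L), end = c(100L, 300L)),
        strand = "+", gene_id = c("zed", "abc"),
        annotated3p = c(100L, 300L))
    GenomeInfoDb::seqlengths(gTie) <- c(c = 100000L)
    extTie <- extendThreePrime(gTie)
    pasTie <- GenomicRanges::GRanges("c", IRanges::IRanges(200L, 200L),
                                     strand = "+", pas_id = "p")
    expect_equal(assignPas(pasTie, extTie)$gene_id, "abc")
})

test_that("proximal/distal ranks follow the direction of transcription", {
    mk <- function(strand) {
        gr <- GenomicRanges::GRanges("c",
            IRanges::IRanges(c(1200L, 1500L), width = 1L),
            strand = strand, pas_id = c("p1200", "p1500"),
            gene_id = "g")
        rankPas(gr)
    }
    plus <- mk("+")
    expect_equal(plus$rank[plus$pas_id == "p1200"], 0L)
    minus <- mk("-")
    expect_equal(minus$rank[minus$pas_id == "p1500"], 0L)

    # rank is a bijection 0..k-1 per gene on simulated data
    sim <- tinySim()
    cl <- clusterEvents(sim$events, w = 25)
    pe <- buildCountMatrix(cl, sim$sampleSheet)
    kept <- filterPas(pe, sim$genome)$kept
    kept <- rankPas(assignPas(kept, extendThreePrime(sim$annotation)))
    rr <- SummarizedExperiment::rowRanges(kept)
    for (g in unique(rr$gene_id[!is.na(rr$gene_id)]))
        expect_setequal(rr$rank[which(rr$gene_id == g)],
                        seq_len(sum(rr$gene_id == g, na.rm = TRUE)) - 1L)
})

test_that("true PASs map back to their planting gene", {
    sim <- tinySim()
    cl <- clusterEvents(sim$events, w = 25)
    pe <- buildCountMatrix(cl, sim$sampleSheet)
    kept <- filterPas(pe, sim$genome)$kept
    kept <- rankPas(assignPas(kept, extendThreePrime(sim$annotation)))
    rr <- SummarizedExperiment::rowRanges(kept)
    tp <- truePas(sim$truth)
    hits <- GenomicRanges::findOverlaps(tp, rr, maxgap = 8L)
    got <- rr$gene_id[S4Vectors::subjectHits(hits)]
    want <- tp$gene_id[S4Vectors::queryHits(hits)]
    expect_gte(mean(got == want, na.rm = TRUE), 0.99)
    # single-PAS genes are not APA genes
    tab <- table(tp$gene_id)
    expect_false(any(names(tab)[tab == 1L] %in% apaGenes(kept)))
})
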