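test_that("generator is deterministic and degenerate-safe", {
    cfg <- ApaSimConfig(nGenes = 15, seed = 7)
    a <- simulateApaDataset(cfg)
    b <- simulateApaDataset(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$annotation, b$annotation)
    expect_identical(lapply(a$events, GenomicRanges::start),
                     lapply(b$events, GenomicRanges::start))

    empty <- simulateGenome(ApaSimConfig(nGenes = 0, seed = 1))
    expect_length(empty$annotation, 0L)
    expect_gt(sum(Biostrings::width(empty$genome)), 0L)

    expect_error(simulateGenome(ApaSimConfig(nGenes = 50, seed = 1),
                                chromLength = 1000),
                 "too short")
})

test_that("genes never overlap on the same strand", {
    g <- simulateGenome(ApaSimConfig(nGenes = 50, seed = 3))
    ann <- g$annotation
    hits <- GenomicRanges::findOverlaps(ann, ann, ignore.strand = FALSE)
    expect_true(all(S4Vectors::queryHits(hits) ==
                    S4Vectors::subjectHits(hits)))
    expect_equal(length(ann), 50L)
})

test_that("planted truth satisfies its own sequence contracts", {
    sim <- tinySim()
    tp <- truePas(sim$truth)
    art <- artifactSites(sim$truth)

    # PASs of one gene are >= 60 nt apart
    for (g in unique(tp$gene_id)) {
        pos <- sort(GenomicRanges::start(tp)[tp$gene_id == g])
        if (length(pos) > 1L) expect_true(all(diff(pos) >= 60L))
    }

    # signal planted in -30..0, no A-run >= 7 in -30..+10, for true PASs
    ctxSig <- senseContext(sim$genome,
        as.character(GenomicRanges::seqnames(tp)),
        as.character(GenomicRanges::strand(tp)),
        GenomicRanges::start(tp), -30L, 0L)
    expect_true(all(grepl("AATAAA", ctxSig)))
    ctxIp <- senseContext(sim$genome,
        as.character(GenomicRanges::seqnames(tp)),
        as.character(GenomicRanges::strand(tp)),
        GenomicRanges::start(tp), -30L, 10L)
    expect_false(any(grepl("A{7,}", ctxIp)))

    # artifact sites sit on an A-run >= 7 and lack any signal in -30..0
    ctxArt <- senseContext(sim$genome,
        as.character(GenomicRanges::seqnames(art)),
        as.character(GenomicRanges::strand(art)),
        GenomicRanges::start(art), -30L, 10L)
    expect_true(all(grepl("A{7,}", ctxArt)))
    expect_false(any(hasPolyASignal(sim$genome, art)))

    # usage proportions sum to one per gene and group (validity check)
    expect_true(validObject(sim$truth))
})

test_that("reads land on planted sites and respect jitter bounds", {
    cfg0 <- ApaSimConfig(nGenes = 12, jitterScale = 0L,
                         artifactFraction = 0, seed = 21)
    sim0 <- simulateApaDataset(cfg0)
    sites <- GenomicRanges::start(truePas(sim0$truth))
    for (ev in sim0$events)
        expect_true(all(GenomicRanges::start(ev) %in% sites))

    sim <- tinySim()
    sites <- GenomicRanges::start(truePas(sim$truth))
    artPos <- GenomicRanges::start(artifactSites(sim$truth))
    for (ev in sim$events) {
        p <- GenomicRanges::start(ev)
        dTrue <- vapply(p, function(x) min(abs(x - sites)), numeric(1))
        ok <- dTrue <= 8 | p %in% artPos
        expect_true(all(ok))
    }
})

test_that("planted class I switches prefer the distal PAS at low temperature", {
    cfg <- ApaSimConfig(nGenes = 30, pasPerGeneRange = c(2L, 2L),
                        switchFraction = 0.4, deFraction = 0, seed = 5)
    sim <- simulateApaDataset(cfg)
    tp <- truePas(sim$truth)
    sw <- as.data.frame(switchGenes(sim$truth))
    grp <- sim$sampleSheet$group
    pooled <- function(g) Reduce(`+`, lapply(which(grp == g), function(i) {
        ev <- sim$events[[i]]
        vapply(seq_along(tp), function(j)
            sum(abs(GenomicRanges::start(ev) -
                    GenomicRanges::start(tp)[j]) <= 8 &
                as.character(GenomicRanges::seqnames(ev)) ==
                as.character(GenomicRanges::seqnames(tp))[j]),
            numeric(1))
    }))
    lowC <- pooled("low"); highC <- pooled("high")
    for (g in sw$gene_id[sw$class == "I"]) {
        idx <- which(tp$gene_id == g)
        distal <- idx[which.max(tp$pas_index[idx])]
        shareLow <- lowC[distal] / sum(lowC[idx])
        shareHigh <- highC[distal] / sum(highC[idx])
        expect_gt(shareLow, shareHigh)
    }
})

test_that("without planted switches per-gene usage is equal between groups", {
    cfg <- ApaSimConfig(nGenes = 200, switchFraction = 0, deFraction = 0,
                        artifactFraction = 0, jitterScale = 0L, seed = 17)
    sim <- simulateApaDataset(cfg)
    tp <- truePas(sim$truth)
    grp <- sim$sampleSheet$group
    key <- paste(as.character(GenomicRanges::seqnames(tp)),
                 GenomicRanges::start(tp))
    countAt <- function(i) {
        ev <- sim$events[[i]]
        evKey <- paste(as.character(GenomicRanges::seqnames(ev)),
                       GenomicRanges::start(ev))
        as.numeric(table(factor(evKey, levels = key)))
    }
    lowC <- Reduce(`+`, lapply(which(grp == "low"), countAt))
    highC <- Reduce(`+`, lapply(which(grp == "high"), countAt))
    pvals <- vapply(unique(tp$gene_id), function(g) {
        idx <- which(tp$gene_id == g)
        if (length(idx) < 2L) return(NA_real_)
        m <- rbind(lowC[idx], highC[idx])
        if (any(colSums(m) == 0)) return(NA_real_)
        suppressWarnings(stats::chisq.test(m)$p.value)
    }, numeric(1))
    pvals <- pvals[!is.na(pvals)]
    expect_gte(mean(pvals >= 0.01), 0.95)
})
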