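makePE <- function(counts, groups = c("low", "low", "high", "high")) {
    n <- nrow(counts)
    rownames(counts) <- paste0("p", seq_len(n))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    rr <- GenomicRanges::GRanges("c", IRanges::IRanges(seq_len(n) * 100L,
                                                       width = 1L),
                                 strand = "+")
    rr$pas_id <- rownames(counts)
    PasExperiment(counts, rr,
                  data.frame(group = groups,
                             replicate = ave(seq_along(groups), groups,
                                             FUN = seq_along),
                             row.names = colnames(counts)))
}

test_that("CPM normalization identities hold", {
    pe <- makePE(rbind(c(10L, 30L, 50L, 70L), c(90L, 270L, 450L, 630L)))
    cpm <- SummarizedExperiment::assay(cpmNormalize(pe), "cpm")
    expect_equal(unname(cpm[, 1L]), c(1e5, 9e5))
    expect_equal(unname(colSums(cpm)), rep(1e6, 4), tolerance = 1e-9)

    # scaling one sample's counts x3 leaves its CPM column unchanged
    m <- matrix(rpois(40, 50) + 1L, nrow = 10)
    pe1 <- makePE(m)
    m2 <- m; m2[, 2L] <- m2[, 2L] * 3L
    pe2 <- makePE(m2)
    expect_equal(SummarizedExperiment::assay(cpmNormalize(pe1), "cpm")[, 2L],
                 SummarizedExperiment::assay(cpmNormalize(pe2), "cpm")[, 2L])

    pe0 <- makePE(rbind(c(0L, 1L, 1L, 1L)))
    expect_error(cpmNormalize(pe0), "zero library total")
})

test_that("the NB Wald test is null-centred and BH-adjusted", {
    pe <- makePE(matrix(20L, nrow = 4, ncol = 6),
                 groups = rep(c("low", "high"), each = 3))
    res <- nbTest(pe)
    expect_equal(res$log2fc, rep(0, 4))
    expect_equal(res$p, rep(1, 4))

    expect_error(nbTest(makePE(matrix(20L, 2, 2),
                               groups = c("low", "high"))),
                 ">= 2 replicates")

    # padj equals a hand-rolled BH step-up on the returned p-values
    withr::local_seed(8)
    m <- matrix(rnbinom(600, mu = 100, size = 10), ncol = 6)
    res <- nbTest(makePE(m, groups = rep(c("low", "high"), each = 3)))
    p <- res$p
    n <- length(p)
    o <- order(p)
    stepUp <- rep(NA_real_, n)
    running <- 1
    for (i in rev(seq_len(n))) {
        running <- min(running, p[o[i]] * n / i)
        stepUp[o[i]] <- running
    }
    expect_equal(res$padj, stepUp)
    expect_true(all(res$padj >= res$p - 1e-12) && all(res$padj <= 1))
})

test_that("pooled moment dispersion recovers the simulated value", {
    withr::local_seed(31)
    phi <- 0.1
    m <- matrix(rnbinom(3000 * 6, mu = 200, size = 1 / phi), ncol = 6)
    keep <- rowSums(m) >= 10
    libs <- colSums(m[keep, ])
    res <- nbTest(makePE(m, groups = rep(c("low", "high"), each = 3)))
    # back out the dispersion from a fixed-dispersion rerun matching se
    resFixed <- nbTest(makePE(m, groups = rep(c("low", "high"), each = 3)),
                       dispersion = phi)
    expect_equal(stats::median(res$se / resFixed$se), 1, tolerance = 0.1)
})

test_that("switch-pair selection reproduces the worked tier examples", {
    tab <- data.frame(pas_id = c("a", "b", "c"), gene_id = "g",
                      rank = 0:2, baseMean = c(100, 100, 100),
                      log2fc = c(1.0, -0.5, 0.2),
                      padj = c(0.01, 0.04, 0.30))
    call <- selectSwitchPair(tab)
    expect_equal(call$tier, "both_significant")
    expect_equal(call$proximal_pas, "a")
    expect_equal(call$distal_pas, "b")
    expect_equal(call$pair_delta, 1.5)
    expect_equal(call$label, "enhanced")
    expect_equal(call$apa_class, "II")

    sameSign <- data.frame(pas_id = c("a", "b"), gene_id = "g",
                           rank = 0:1, baseMean = c(100, 100),
                           log2fc = c(1.0, 0.8), padj = c(0.01, 0.02))
    expect_null(selectSwitchPair(sameSign))

    tierC <- data.frame(pas_id = c("a", "b"), gene_id = "g",
                        rank = 0:1, baseMean = c(500, 400),
                        log2fc = c(-0.2, 0.3), padj = c(0.60, 0.40))
    call <- selectSwitchPair(tierC)
    expect_equal(call$tier, "none_significant")
    expect_equal(call$label, "repressed")
    expect_equal(call$apa_class, "I")
    expect_equal(call$pair_delta, 0.5)

    expect_error(selectSwitchPair(tab[1L, ]), ">= 2")
})

test_that("pair selection agrees with literal tier enumeration", {
    withr::local_seed(77)
    for (rep in 1:300) {
        tab <- randomGeneTable(sample(2:5, 1))
        got <- selectSwitchPair(tab)
        want <- switchPairOracle(tab)
        if (is.null(want)) {
            expect_null(got)
        } else {
            expect_false(is.null(got))
            expect_equal(got$proximal_pas, want$proximal)
            expect_equal(got$distal_pas, want$distal)
            expect_equal(got$label, want$label)
            expect_equal(got$apa_class, want$class)
        }
    }
})

test_that("strand flip swaps classes but preserves the pair distance", {
    withr::local_seed(13)
    for (rep in 1:50) {
        tab <- randomGeneTable(sample(2:4, 1))
        flip <- tab
        flip$rank <- max(tab$rank) - tab$rank
        a <- selectSwitchPair(tab)
        b <- selectSwitchPair(flip)
        if (is.null(a)) {
            expect_null(b)
        } else {
            expect_equal(b$pair_delta, a$pair_delta)
            expect_equal(b$apa_class, setNames(c("II", "I"),
                                               c("I", "II"))[[a$apa_class]])
            expect_equal(sort(c(a$label, b$label)),
                         c("enhanced", "repressed"))
        }
    }
})

test_that("switch calls require a significant PAS by default", {
    res <- rbind(
        data.frame(pas_id = c("a1", "a2"), gene_id = "gSig", rank = 0:1,
                   baseMean = 100, log2fc = c(-1, 1),
                   padj = c(0.001, 0.002)),
        data.frame(pas_id = c("b1", "b2"), gene_id = "gNoise", rank = 0:1,
                   baseMean = 100, log2fc = c(-0.2, 0.2),
                   padj = c(0.8, 0.9)))
    calls <- callApaSwitches(res)
    expect_equal(calls$gene_id, "gSig")
    all3 <- callApaSwitches(res, tiers = c("both_significant",
                                           "one_significant",
                                           "none_significant"))
    expect_setequal(all3$gene_id, c("gSig", "gNoise"))
    # single-PAS genes never appear
    res1 <- rbind(res, data.frame(pas_id = "c1", gene_id = "gSingle",
                                  rank = 0, baseMean = 5, log2fc = 3,
                                  padj = 1e-6))
    expect_false("gSingle" %in% callApaSwitches(res1)$gene_id)
})

test_that("top2 mode pairs the two strongest PASs", {
    tab <- data.frame(pas_id = c("a", "b", "c"), gene_id = "g",
                      rank = 0:2, baseMean = c(50, 900, 800),
                      log2fc = c(2.0, -0.4, 0.6),
                      padj = c(0.001, 0.02, 0.4))
    call <- selectSwitchPair(tab, mode = "top2")
    expect_equal(call$proximal_pas, "b")
    expect_equal(call$distal_pas, "c")
    expect_equal(call$tier, "top2")
    # same-sign top2 -> no call even with significance elsewhere
    tab$log2fc <- c(2.0, 0.4, 0.6)
    expect_null(selectSwitchPair(tab, mode = "top2"))
})

test_that("DE categories apply the fold-change and FDR thresholds", {
    # strong planted shift: gene A up at low, gene B flat
    withr::local_seed(41)
    mkGene <- function(muLow, muHigh, n = 30) {
        cbind(matrix(rnbinom(3 * n, mu = muLow, size = 50), ncol = 3),
              matrix(rnbinom(3 * n, mu = muHigh, size = 50), ncol = 3))
    }
    counts <- rbind(mkGene(800, 100, 1), mkGene(200, 200, 29))
    pe <- makePE(counts, groups = rep(c("low", "high"), each = 3))
    SummarizedExperiment::rowRanges(pe)$gene_id <-
        paste0("g", seq_len(nrow(counts)))
    de <- callDeGenes(pe)
    expect_equal(de$category[de$gene_id == "g1"], "CoolUp")
    expect_true(all(de$category[de$gene_id != "g1"] == "NotDE"))

    # a significant but sub-threshold fold change stays NotDE
    counts2 <- rbind(mkGene(280, 200, 1), mkGene(200, 200, 29))
    pe2 <- makePE(counts2, groups = rep(c("low", "high"), each = 3))
    SummarizedExperiment::rowRanges(pe2)$gene_id <-
        paste0("g", seq_len(nrow(counts2)))
    de2 <- callDeGenes(pe2)
    expect_equal(de2$category[de2$gene_id == "g1"], "NotDE")
})

test_that("planted DE genes are recovered at the rate a power oracle predicts", {
    cfg <- ApaSimConfig(nGenes = 150, switchFraction = 0, deFraction = 0.2,
                        seed = 61)
    sim <- simulateApaDataset(cfg)
    cl <- clusterEvents(sim$events, w = 25)
    pe <- buildCountMatrix(cl, sim$sampleSheet)
    kept <- rankPas(assignPas(filterPas(pe, sim$genome)$kept,
                              extendThreePrime(sim$annotation)))
    de <- callDeGenes(kept)
    truthDe <- as.data.frame(deGenes(sim$truth))
    m <- merge(de, truthDe, by = "gene_id")
    sens <- mean(m$category != "NotDE")

    # categories are consistent with their own fold change and padj
    up <- de$category == "CoolUp"
    down <- de$category == "CoolDown"
    expect_true(all(de$log2fc[up] >= 1 & de$padj[up] < 0.01))
    expect_true(all(de$log2fc[down] <= -1 & de$padj[down] < 0.01))
    expect_false(any(!up & !down &
                     abs(de$log2fc) >= 1 & de$padj < 0.01))

    # effect-size recovery: mean observed log2FC of planted genes equals
    # the planted shift minus the CPM library-composition offset
    # (planted effects change the low-group library total)
    shifts <- truthDe$log2_shift
    compShift <- log2((150 - nrow(truthDe) + sum(2^shifts)) / 150)
    for (s in c(1, -1)) {
        obs <- mean(m$log2fc[sign(m$log2_shift) == s])
        expect_lt(abs(obs - (s * log2(2.5) - compShift)), 0.35)
    }

    # detected planted genes far exceed the background false-call rate
    fpr <- mean(de$category != "NotDE" &
                !(de$gene_id %in% truthDe$gene_id))
    expect_lte(fpr, 0.02)
    expect_gt(sens, fpr + 0.1)
    # no planted gene is called in the wrong direction
    wrong <- (m$log2_shift > 0 & m$category == "CoolDown") |
             (m$log2_shift < 0 & m$category == "CoolUp")
    expect_false(any(wrong))
})
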