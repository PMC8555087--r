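# Independent reference implementations used to validate the package's
# algorithms, coded deliberately differently from the package internals.

# Brute-force greedy clustering for one (chrom, strand): at every step
# re-scan all unassigned positions for the highest total count (ties to
# the smallest coordinate), then absorb everything within +/- w.
greedyClusterOracle <- function(pos, total, w) {
    remaining <- seq_along(pos)
    seeds <- integer(0)
    members <- list()
    while (length(remaining)) {
        best <- remaining[1L]
        for (i in remaining) {
            if (total[i] > total[best] ||
                (total[i] == total[best] && pos[i] < pos[best]))
                best <- i
        }
        grab <- remaining[abs(pos[remaining] - pos[best]) <= w]
        seeds <- c(seeds, pos[best])
        members[[length(members) + 1L]] <- grab
        remaining <- setdiff(remaining, grab)
    }
    o <- order(seeds)
    list(seeds = seeds[o],
         totals = vapply(members[o], function(m) sum(total[m]), numeric(1)))
}

# Literal tier-rule enumeration for one gene's PAS test table.
# tab: data.frame(pas_id, rank, baseMean, log2fc, padj)
switchPairOracle <- function(tab, alpha = 0.05) {
    k <- nrow(tab)
    describe <- function(i, j) {
        pr <- if (tab$rank[i] < tab$rank[j]) i else j
        di <- if (pr == i) j else i
        list(prox = pr, dist = di,
             delta = abs(tab$log2fc[pr] - tab$log2fc[di]),
             diff = tab$log2fc[pr] - tab$log2fc[di],
             opposite = tab$log2fc[pr] * tab$log2fc[di] < 0)
    }
    byCount <- function(idx) {   # highest baseMean, ties to smaller rank
        idx[order(-tab$baseMean[idx], tab$rank[idx])]
    }
    sig <- which(tab$padj < alpha)
    cand <- list()
    if (length(sig) >= 2L) {
        for (i in sig) for (j in sig) if (i < j) {
            d <- describe(i, j)
            if (d$opposite) cand[[length(cand) + 1L]] <- d
        }
    } else if (length(sig) == 1L) {
        partner <- byCount(setdiff(seq_len(k), sig))[1L]
        cand <- list(describe(sig, partner))
    } else {
        top <- byCount(seq_len(k))[1:2]
        cand <- list(describe(top[1L], top[2L]))
    }
    if (!length(cand)) return(NULL)
    best <- NULL
    for (d in cand) {
        if (is.null(best) || d$delta > best$delta ||
            (d$delta == best$delta &&
             (tab$rank[d$prox] < tab$rank[best$prox] ||
              (tab$rank[d$prox] == tab$rank[best$prox] &&
               tab$rank[d$dist] < tab$rank[best$dist]))))
            best <- d
    }
    if (!best$opposite) return(NULL)
    list(proximal = tab$pas_id[best$prox], distal = tab$pas_id[best$dist],
         delta = best$delta,
         label = if (best$diff > 0) "enhanced" else "repressed",
         class = if (best$diff > 0) "II" else "I")
}

# random per-gene PAS test table for the pair-selection property tests
randomGeneTable <- function(k, gene = "g1") {
    data.frame(pas_id = paste0("p", seq_len(k)),
               gene_id = gene,
               rank = sample(seq_len(k)) - 1L,
               baseMean = round(stats::runif(k, 10, 1000)),
               log2fc = round(stats::rnorm(k, 0, 1), 2),
               padj = round(stats::runif(k)^2, 3),
               stringsAsFactors = FALSE)
}

# build a width-1 GRanges of events from positions (recycled over counts)
eventGR <- function(pos, counts = 1L, chrom = "chr1", strand = "+",
                    sample = "s1") {
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(rep(pos, counts), width = 1L),
        strand = strand)
    gr$sample <- rep_len(sample, length(gr))
    gr
}

# tiny shared simulated dataset (built once per test run)
tinySim <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateApaDataset(ApaSimConfig(nGenes = 40,
                                                      seed = 404))
        cache
    }
})
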