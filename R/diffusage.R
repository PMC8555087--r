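#' Counts-per-million normalization
#'
#' Scales each sample's counts by its library total times one million
#' (the \code{cpm} function of edgeR, without compositional normalization
#' factors), and stores the result as the \code{"cpm"} assay. Every CPM
#' column sums to 1e6, and uniformly scaling one sample's counts leaves
#' its CPM column unchanged.
#'
#' @param x a [PasExperiment-class] with a \code{"counts"} assay.
#' @return \code{x} with an added \code{"cpm"} assay.
#' @export
cpmNormalize <- function(x) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    if (any(colSums(cnt) == 0))
        stop("zero library total for sample(s): ",
             paste(colnames(cnt)[colSums(cnt) == 0], collapse = ", "))
    SummarizedExperiment::assays(x)$cpm <- edgeR::cpm(cnt)
    x
}

# NB Wald test on a count matrix; the core behind nbTest()/callDeGenes().
# Dispersion is a single method-of-moments estimate pooled across all
# tested features: per feature, the pooled within-group variance of the
# normalized values is compared with the value expected under Poisson
# noise, and the excesses are combined as a ratio of sums, then floored.
nbWaldTable <- function(counts, group, minCount = 10L,
                        dispersion = NULL, lowLabel = "low") {
    stopifnot(is.matrix(counts))
    group <- as.character(group)
    labs <- unique(group)
    if (length(labs) != 2L)
        stop("exactly two condition groups are required")
    if (!lowLabel %in% labs)
        stop("group label '", lowLabel, "' not found")
    highLabel <- setdiff(labs, lowLabel)
    iL <- which(group == lowLabel)
    iH <- which(group == highLabel)
    if (length(iL) < 2L || length(iH) < 2L)
        stop("each group needs >= 2 replicates")
    keep <- rowSums(counts) >= minCount
    counts <- counts[keep, , drop = FALSE]
    if (!nrow(counts))
        return(data.frame(pas_id = character(), baseMean = numeric(),
                          log2fc = numeric(), se = numeric(),
                          stat = numeric(), p = numeric(),
                          padj = numeric()))
    libs <- colSums(counts)
    sf <- 1e6 / libs                       # CPM scale factors
    y <- t(t(counts) * sf)
    mL <- rowMeans(y[, iL, drop = FALSE])
    mH <- rowMeans(y[, iH, drop = FALSE])
    vL <- apply(y[, iL, drop = FALSE], 1L, stats::var)
    vH <- apply(y[, iH, drop = FALSE], 1L, stats::var)
    dfL <- length(iL) - 1L
    dfH <- length(iH) - 1L
    s2 <- (dfL * vL + dfH * vH) / (dfL + dfH)
    mAll <- rowMeans(y)
    if (is.null(dispersion)) {
        # Var(cpm) ~ sbar * mu + phi * mu^2, sbar = mean scale factor
        sbar <- mean(sf)
        dispersion <- max(sum(s2 - sbar * mAll) / sum(mAll^2), 1e-8)
    }
    sbarL <- mean(sf[iL]); sbarH <- mean(sf[iH])
    varL <- (sbarL * mL + dispersion * mL^2) / length(iL)
    varH <- (sbarH * mH + dispersion * mH^2) / length(iH)
    log2fc <- log2((mL + 0.5) / (mH + 0.5))
    se <- sqrt(varL / (mL + 0.5)^2 + varH / (mH + 0.5)^2) / log(2)
    stat <- ifelse(se > 0, log2fc / se, 0)
    p <- 2 * stats::pnorm(-abs(stat))
    p[log2fc == 0] <- 1
    data.frame(pas_id = rownames(counts),
               baseMean = rowMeans(y),
               log2fc = log2fc, se = se, stat = stat, p = p,
               padj = stats::p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Negative-binomial differential PAS usage test
#'
#' Tests every PAS passing the minimum-count filter for differential
#' usage between the pooled low- and high-temperature groups. The effect
#' size is \code{log2fc = log2((mean CPM low + 0.5) / (mean CPM high +
#' 0.5))}; its standard error comes from the NB variance \code{mu + phi
#' mu^2} propagated through the log by the delta method, with the
#' dispersion \code{phi} estimated once by method of moments pooled
#' across all tested PASs (at three replicates per group a per-feature
#' estimate is far too noisy for a calibrated Wald test). Two-sided
#' p-values use the normal reference and are Benjamini-Hochberg adjusted
#' over all tested PASs.
#'
#' @param x a [PasExperiment-class]; rows carrying \code{gene_id}/
#'   \code{rank} metadata propagate them into the result.
#' @param minCount minimum summed count across samples for a PAS to be
#'   tested (default 10).
#' @param dispersion optional fixed NB dispersion, bypassing estimation.
#' @param lowLabel the \code{colData} group label treated as numerator
#'   of the fold change (default \code{"low"}).
#' @return data.frame with pas_id, gene_id, rank, baseMean, log2fc, se,
#'   stat, p, padj.
#' @export
nbTest <- function(x, minCount = 10L, dispersion = NULL,
                   lowLabel = "low") {
    cnt <- SummarizedExperiment::assay(x, "counts")
    res <- nbWaldTable(cnt, sampleGroups(x), minCount = minCount,
                       dispersion = dispersion, lowLabel = lowLabel)
    rr <- SummarizedExperiment::rowRanges(x)
    idx <- match(res$pas_id, rownames(x))
    res$gene_id <- if (!is.null(rr$gene_id)) rr$gene_id[idx]
                   else NA_character_
    res$rank <- if (!is.null(rr$rank)) rr$rank[idx] else NA_integer_
    res[, c("pas_id", "gene_id", "rank", "baseMean", "log2fc", "se",
            "stat", "p", "padj")]
}

# order a candidate pair as (proximal, distal) and score it
pairRow <- function(res, i, j) {
    if (res$rank[i] > res$rank[j]) { k <- i; i <- j; j <- k }
    diff <- res$log2fc[i] - res$log2fc[j]
    data.frame(proximal_pas = res$pas_id[i], distal_pas = res$pas_id[j],
               proximal_rank = res$rank[i], distal_rank = res$rank[j],
               lfc_proximal = res$log2fc[i], lfc_distal = res$log2fc[j],
               pair_delta = abs(diff), diff = diff,
               opposite = (res$log2fc[i] * res$log2fc[j]) < 0,
               stringsAsFactors = FALSE)
}

#' Select a gene's most divergent proximal/distal PAS pair
#'
#' Tiered candidate construction over one gene's tested PASs
#' (\code{alpha} applied to BH-adjusted p-values):
#' \itemize{
#'   \item \strong{both_significant}: two or more PASs significant ->
#'     candidates are all pairs of significant PASs whose fold changes
#'     have opposite signs;
#'   \item \strong{one_significant}: exactly one significant -> the single
#'     pair of that PAS with the highest-\code{baseMean} other PAS;
#'   \item \strong{none_significant}: the single pair of the two
#'     highest-\code{baseMean} PASs.
#' }
#' Among candidates the pair with the greatest fold-change distance
#' \code{|log2fc(proximal) - log2fc(distal)|} wins (ties towards the
#' smaller proximal rank, then smaller distal rank). A call is returned
#' only when the chosen pair's fold changes have opposite signs; it is
#' labelled \code{enhanced} (class II, proximal preferred at low
#' temperature) when \code{log2fc(proximal) - log2fc(distal) > 0} and
#' \code{repressed} (class I, distal preferred at low temperature)
#' otherwise.
#'
#' With \code{mode = "top2"} the candidate set is instead the single pair
#' of the two highest-\code{baseMean} PASs regardless of significance,
#' called when the fold changes are of opposite sign and at least one
#' adjusted p-value is below \code{alpha}.
#'
#' @param geneRes rows of an [nbTest()] result for one gene (>= 2 PASs,
#'   with distinct ranks).
#' @param alpha FDR threshold (default 0.05).
#' @param mode \code{"tiered"} (default) or \code{"top2"}.
#' @return one-row data.frame (gene_id, proximal_pas, distal_pas,
#'   lfc_proximal, lfc_distal, pair_delta, label, apa_class, tier) or
#'   \code{NULL} when no pair qualifies.
#' @export
selectSwitchPair <- function(geneRes, alpha = 0.05,
                             mode = c("tiered", "top2")) {
    mode <- match.arg(mode)
    res <- as.data.frame(geneRes)
    if (nrow(res) < 2L)
        stop("a gene needs >= 2 tested PASs for pair selection")
    # deterministic base ordering for baseMean ties: smaller rank first
    res <- res[order(-res$baseMean, res$rank), , drop = FALSE]
    sig <- which(res$padj < alpha)

    if (mode == "top2") {
        tier <- "top2"
        chosen <- pairRow(res, 1L, 2L)
        if (!chosen$opposite || !any(res$padj[1:2] < alpha)) return(NULL)
    } else if (length(sig) >= 2L) {
        tier <- "both_significant"
        cand <- list()
        for (a in seq_along(sig)[-length(sig)])
            for (b in (a + 1L):length(sig)) {
                pr <- pairRow(res, sig[a], sig[b])
                if (pr$opposite) cand[[length(cand) + 1L]] <- pr
            }
        if (!length(cand)) return(NULL)
        tab <- do.call(rbind, cand)
        tab <- tab[order(-tab$pair_delta, tab$proximal_rank,
                         tab$distal_rank), , drop = FALSE]
        chosen <- tab[1L, , drop = FALSE]
    } else if (length(sig) == 1L) {
        tier <- "one_significant"
        partner <- setdiff(seq_len(nrow(res)), sig)[1L]  # max baseMean
        chosen <- pairRow(res, sig, partner)
        if (!chosen$opposite) return(NULL)
    } else {
        tier <- "none_significant"
        chosen <- pairRow(res, 1L, 2L)                   # top-2 baseMean
        if (!chosen$opposite) return(NULL)
    }
    if (chosen$diff == 0) return(NULL)
    data.frame(gene_id = res$gene_id[1L],
               proximal_pas = chosen$proximal_pas,
               distal_pas = chosen$distal_pas,
               lfc_proximal = chosen$lfc_proximal,
               lfc_distal = chosen$lfc_distal,
               pair_delta = chosen$pair_delta,
               label = if (chosen$diff > 0) "enhanced" else "repressed",
               apa_class = if (chosen$diff > 0) "II" else "I",
               tier = tier, stringsAsFactors = FALSE)
}

#' Call APA switches over all APA genes
#'
#' Applies [selectSwitchPair()] to every gene with at least two tested
#' PASs and collects the calls. Class I marks genes whose distal PAS is
#' preferred at low temperature, class II the proximal; single-PAS genes
#' never appear.
#'
#' A temperature-dependent APA switch is a \emph{significant} usage change
#' in opposite directions, so by default only pairs from tiers with at
#' least one significant PAS (\code{both_significant},
#' \code{one_significant}) count as switch calls; \code{none_significant}
#' pair selections describe a gene's most divergently used PAS pair
#' without evidence of regulation and would otherwise be called for about
#' half of all unregulated APA genes (any gene whose two fold-change
#' signs happen to differ). Pass them in \code{tiers} to keep them.
#'
#' @param results an [nbTest()] data.frame with gene_id and rank set.
#' @param alpha FDR threshold for the pair tiers (default 0.05).
#' @param mode see [selectSwitchPair()].
#' @param tiers selection tiers retained as switch calls.
#' @return data.frame of calls (possibly zero rows) with a
#'   \code{"classCounts"} attribute: named counts of class I/II calls.
#' @export
callApaSwitches <- function(results, alpha = 0.05,
                            mode = c("tiered", "top2"),
                            tiers = c("both_significant",
                                      "one_significant", "top2")) {
    mode <- match.arg(mode)
    res <- as.data.frame(results)
    res <- res[!is.na(res$gene_id) & !is.na(res$rank), , drop = FALSE]
    calls <- list()
    for (g in unique(res$gene_id)) {
        sub <- res[res$gene_id == g, , drop = FALSE]
        if (nrow(sub) < 2L) next
        call <- selectSwitchPair(sub, alpha = alpha, mode = mode)
        if (!is.null(call) && call$tier %in% tiers)
            calls[[length(calls) + 1L]] <- call
    }
    out <- if (length(calls)) do.call(rbind, calls) else
        data.frame(gene_id = character(), proximal_pas = character(),
                   distal_pas = character(), lfc_proximal = numeric(),
                   lfc_distal = numeric(), pair_delta = numeric(),
                   label = character(), apa_class = character(),
                   tier = character(), stringsAsFactors = FALSE)
    attr(out, "classCounts") <- c(I = sum(out$apa_class == "I"),
                                  II = sum(out$apa_class == "II"))
    out
}

#' Call differentially expressed genes (CoolUp / CoolDown)
#'
#' Aggregates assigned PAS counts to gene level, runs the NB Wald test
#' between the pooled low- and high-temperature groups, and categorizes:
#' \code{CoolUp} when \code{log2fc >= log2(fc)} and \code{padj < fdr},
#' \code{CoolDown} when \code{log2fc <= -log2(fc)} and \code{padj < fdr},
#' otherwise \code{NotDE}. Defaults follow the usual fold change >= 2 at
#' FDR < 0.01 convention for calling temperature-responsive genes.
#'
#' @param x a [PasExperiment-class] with \code{gene_id} assigned.
#' @param fdr adjusted-p threshold (default 0.01).
#' @param fc fold-change threshold on the natural scale (default 2).
#' @param minCount minimum summed gene count for testing.
#' @param lowLabel numerator group label.
#' @return data.frame: gene_id, baseMean, log2fc, p, padj, category.
#' @export
callDeGenes <- function(x, fdr = 0.01, fc = 2, minCount = 10L,
                        lowLabel = "low") {
    gid <- SummarizedExperiment::rowRanges(x)$gene_id
    if (is.null(gid)) stop("run assignPas() first")
    keep <- !is.na(gid)
    cnt <- SummarizedExperiment::assay(x, "counts")[keep, , drop = FALSE]
    geneCounts <- rowsum(cnt, group = gid[keep])
    res <- nbWaldTable(geneCounts, sampleGroups(x), minCount = minCount,
                       lowLabel = lowLabel)
    names(res)[names(res) == "pas_id"] <- "gene_id"
    lfcCut <- log2(fc)
    res$category <- ifelse(
        res$padj < fdr & res$log2fc >= lfcCut, "CoolUp",
        ifelse(res$padj < fdr & res$log2fc <= -lfcCut, "CoolDown",
               "NotDE"))
    res[, c("gene_id", "baseMean", "log2fc", "p", "padj", "category")]
}
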