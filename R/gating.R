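#' Read a flow-cytometry event table
#'
#' CSV with one row per event and columns \code{red} and \code{green}
#' (post-compensation linear intensities).
#'
#' @param path CSV file.
#' @return data.frame with columns red, green.
#' @importFrom utils read.csv
#' @export
readFlowTable <- function(path) {
    tab <- read.csv(path)
    if (!all(c("red", "green") %in% colnames(tab)))
        stop("flow table must have 'red' and 'green' columns")
    if (nrow(tab) && (any(!is.finite(tab$red)) || any(!is.finite(tab$green))))
        stop("intensities must be finite")
    if (nrow(tab) && (any(tab$red < 0) || any(tab$green < 0)))
        stop("intensities must be non-negative")
    tab[, c("red", "green")]
}

#' Fit flow-cytometry gates from negative controls
#'
#' The mRuby-negative gate boundary \code{redMax} is set at the
#' \code{q}-quantile of the red intensity of a red-negative control
#' (parental cells without the red marker). The GFP-positive/negative
#' split \code{greenSplit} is the \code{q}-quantile of the green
#' intensity among the mRuby-negative events of a green-negative control
#' (cells after cassette exchange with an inactive fragment, which
#' contains no GFP-positive population). The published gates were drawn
#' interactively; a high quantile of the named negative control is the
#' reproducible equivalent and is configurable.
#'
#' @param negRedControl data.frame (red, green): red-negative control.
#' @param negGreenControl data.frame (red, green): GFP-negative control.
#' @param q quantile for both thresholds (default 0.99).
#' @param minEvents minimum gate-2 occupancy passed through to the
#'   [GateSet-class] (default 100).
#' @return a [GateSet-class].
#' @export
fitGates <- function(negRedControl, negGreenControl, q = 0.99,
                     minEvents = 100L) {
    if (!nrow(negRedControl)) stop("empty red-negative control")
    if (!nrow(negGreenControl)) stop("empty green-negative control")
    redMax <- stats::quantile(negRedControl$red, q, names = FALSE)
    neg <- negGreenControl[negGreenControl$red < redMax, , drop = FALSE]
    if (!nrow(neg))
        stop("green-negative control has no mRuby-negative events")
    greenSplit <- stats::quantile(neg$green, q, names = FALSE)
    GateSet(redMax = redMax, greenSplit = greenSplit,
            minEvents = minEvents)
}

#' Background-corrected enhancer activity of a sample
#'
#' Restricts to mRuby-negative events (red below \code{redMax}), splits
#' them into GFP-positive events (gate 2, green at or above
#' \code{greenSplit}) and GFP-negative events (gate 3, below), and
#' returns \code{median(green | gate 2) - median(green | gate 3)}: the
#' gate-3 median measures background fluorescence and is subtracted from
#' the gate-2 median. When gate 2 holds fewer than \code{minEvents}
#' events the sample has no GFP-positive population and the activity is 0
#' with flag \code{NO_POSITIVE_POPULATION}; a thin gate 3 is flagged
#' \code{LOW_BACKGROUND} (activity still computed when possible).
#'
#' @param events data.frame (red, green), one row per cell.
#' @param gates a [GateSet-class] from [fitGates()].
#' @return list: \code{activity}, \code{n_gate2}, \code{n_gate3},
#'   \code{flags} (character, possibly empty).
#' @export
enhancerActivity <- function(events, gates) {
    stopifnot(is(gates, "GateSet"))
    if (!nrow(events)) stop("empty event table")
    neg <- events[events$red < redMax(gates), , drop = FALSE]
    g2 <- neg$green[neg$green >= greenSplit(gates)]
    g3 <- neg$green[neg$green < greenSplit(gates)]
    flags <- character()
    if (length(g2) < minEvents(gates)) {
        return(list(activity = 0, n_gate2 = length(g2),
                    n_gate3 = length(g3),
                    flags = "NO_POSITIVE_POPULATION"))
    }
    if (length(g3) < minEvents(gates)) flags <- c(flags, "LOW_BACKGROUND")
    bg <- if (length(g3)) stats::median(g3) else 0
    list(activity = stats::median(g2) - bg,
         n_gate2 = length(g2), n_gate3 = length(g3), flags = flags)
}
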