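#' Linear-time farthest-first (maximin) selection
#'
#' Selects representative items from a set given a distance oracle, in
#' farthest-first order: the first item is the one farthest from a random
#' (seeded) pivot; every subsequent pick maximises the minimum distance to
#' the items already selected. The minimum-distance array is updated
#' incrementally, so at most `k * n` distance evaluations are performed and
#' the novelty sequence (min distance to the previous picks) is
#' non-increasing. Ties are broken by the lexicographically smallest item
#' id.
#'
#' @param items character vector of distinct item ids.
#' @param distFun function `(a, b) -> distance` in \[0, 1\] with
#'   `distFun(a, a) == 0`; assumed symmetric.
#' @param k number of items to select (defaults to all).
#' @param stopNovelty stop before a pick whose novelty would fall below
#'   this threshold (e.g. `1 - maxIdentity`).
#' @param seed RNG seed for the pivot choice.
#' @return a [SampleTrace-class]; the first item carries the sentinel
#'   novelty 1.
#' @examples
#' pts <- c(a = 0, b = 1, c = 10)
#' d <- function(x, y) abs(pts[x] - pts[y]) / 10
#' ficlinSelect(names(pts), d, k = 3, seed = 1)
#' @export
ficlinSelect <- function(items, distFun, k = length(items),
                         stopNovelty = NULL, seed = 1L) {
    items <- as.character(items)
    n <- length(items)
    if (n == 0L) stop("cannot sample from an empty item set")
    if (is.null(k)) k <- n
    if (k <= 0L) stop("k must be positive")
    k <- min(k, n)
    if (anyDuplicated(items)) stop("item ids must be distinct")

    nCalls <- 0L
    dVec <- function(a, rest) {
        nCalls <<- nCalls + length(rest)
        vapply(rest, function(b) distFun(a, b), numeric(1))
    }

    pivot <- items[withSeed(seed, sample.int(n, 1L))]
    dPivot <- dVec(pivot, items)
    first <- items[orderPick(dPivot, items)]

    sel <- character(0)
    nov <- numeric(0)
    minDist <- rep(Inf, n)
    names(minDist) <- items
    pick <- first
    pickNov <- 1.0
    repeat {
        if (!is.null(stopNovelty) && length(sel) > 0L &&
            pickNov < stopNovelty) break
        sel <- c(sel, pick)
        nov <- c(nov, pickNov)
        if (length(sel) >= k) break
        rest <- setdiff(items, sel)
        d <- dVec(pick, rest)
        minDist[rest] <- pmin(minDist[rest], d)
        i <- orderPick(minDist[rest], rest)
        pick <- rest[i]
        pickNov <- minDist[pick]
    }
    new("SampleTrace",
        trace = data.frame(item = unname(sel), order = seq_along(sel),
                           novelty = unname(nov)),
        nDistCalls = nCalls)
}

# index of the maximal value, ties broken by smallest id
orderPick <- function(vals, ids) {
    mx <- max(vals)
    cand <- which(vals >= mx - 1e-12)
    cand[order(ids[cand])][1]
}

#' @describeIn ficlinSelect the trace data.frame of a SampleTrace
#' @param object a [SampleTrace-class].
#' @export
sampleTrace <- function(object) object@trace

#' @describeIn ficlinSelect number of distance evaluations used
#' @export
nDistCalls <- function(object) object@nDistCalls
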