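#' @include AllClasses.R AllGenerics.R
NULL

#' Geometric mean
#'
#' Computed as \code{exp(mean(log(x)))} so that long vectors of small
#' proportions do not underflow.
#'
#' @param x numeric vector of strictly positive values.
#' @return the geometric mean, a positive scalar.
#' @examples
#' geometricMean(c(1, 4)) # 2
#' @export
geometricMean <- function(x) {
    if (length(x) < 1L || !is.numeric(x))
        stop("'x' must be a non-empty numeric vector")
    if (any(!is.finite(x)) || any(x <= 0))
        stop("geometric mean requires strictly positive finite values")
    exp(mean(log(x)))
}

#' Replace zeros with a pseudocount
#'
#' If the table contains any zero, a pseudocount is added to every entry
#' (default 1e-5); otherwise the table is returned unchanged. A message is
#' emitted when the replacement is triggered, since some users may prefer a
#' model-based zero correction applied upstream.
#'
#' @param x a \linkS4class{CompositionTable} or numeric matrix.
#' @param pseudocount positive value added to all entries when zeros are
#'   present.
#' @return an object of the same class, strictly positive.
#' @examples
#' replaceZeros(CompositionTable(rbind(c(0, 2, 2))))
#' @export
setMethod("replaceZeros", "CompositionTable", function(x, pseudocount = 1e-5) {
    v <- replaceZeros(x@values, pseudocount)
    methods::initialize(x, values = v)
})

#' @rdname replaceZeros-CompositionTable-method
#' @export
setMethod("replaceZeros", "matrix", function(x, pseudocount = 1e-5) {
    if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
        pseudocount <= 0)
        stop("'pseudocount' must be a positive scalar")
    if (any(x < 0)) stop("abundances must be non-negative")
    if (!any(x == 0)) return(x)
    message("zeros detected: adding pseudocount ", format(pseudocount),
            " to all entries")
    x + pseudocount
})

#' Closure (total-sum normalisation)
#'
#' Divides each sample row by its total so the table lies on the simplex
#' (rows sum to one). Idempotent and scale-invariant per row.
#'
#' @param x a \linkS4class{CompositionTable} or numeric matrix.
#' @return the closed object; rows sum to 1.
#' @examples
#' closure(CompositionTable(rbind(c(1, 1, 2))))
#' @export
setMethod("closure", "CompositionTable", function(x) {
    methods::initialize(x, values = closure(x@values))
})

#' @rdname closure-CompositionTable-method
#' @export
setMethod("closure", "matrix", function(x) {
    rs <- rowSums(x)
    if (any(rs == 0)) {
        bad <- which(rs == 0)[1]
        stop("sample row ", if (!is.null(rownames(x))) rownames(x)[bad] else bad,
             " sums to zero and cannot be closed")
    }
    x / rs
})

#' Balance between two groups of parts
#'
#' The scaled isometric-log-ratio balance of two disjoint groups of parts of
#' a composition:
#' \deqn{b = \sqrt{rs/(r+s)} \, \ln\left( g(x_R)/g(x_S) \right)}
#' where r and s are the group sizes and g is the geometric mean. The
#' set-enrichment statistic (\code{\link{cbeaStatistic}}) is the special case
#' where the second group is the complement of the first.
#'
#' @param row numeric vector of strictly positive parts (one sample).
#' @param groupR,groupS disjoint, non-empty index vectors into \code{row}.
#' @return the balance, a real scalar.
#' @examples
#' balance(c(0.4, 0.2, 0.3, 0.1), 1:2, 3:4)
#' @export
balance <- function(row, groupR, groupS) {
    groupR <- as.integer(groupR); groupS <- as.integer(groupS)
    if (length(groupR) == 0L || length(groupS) == 0L)
        stop("both groups must be non-empty")
    if (length(intersect(groupR, groupS)))
        stop("groups must be disjoint")
    if (min(groupR, groupS) < 1L || max(groupR, groupS) > length(row))
        stop("group indices out of range")
    if (any(!is.finite(row)) || any(row <= 0))
        stop("'row' must be strictly positive and finite")
    r <- length(groupR); s <- length(groupS)
    lx <- log(row)
    sqrt(r * s / (r + s)) * (mean(lx[groupR]) - mean(lx[groupS]))
}

#' Per-sample competitive enrichment statistic for one taxon set
#'
#' The scaled log-ratio of the geometric mean of within-set parts to the
#' geometric mean of the complement:
#' \deqn{M = \sqrt{K(p-K)/p}\,\ln\left( g(x_{set}) / g(x_{set^c}) \right)}
#' with K the set size and p the number of taxa. Identical to
#' \code{balance(row, set, complement)}: the coefficient
#' \eqn{\sqrt{K(p-K)/p}} equals \eqn{\sqrt{rs/(r+s)}} with r = K,
#' s = p - K.
#'
#' @param row numeric vector of strictly positive parts (one sample).
#' @param setIdx indices of the taxa in the set; must be a non-empty proper
#'   subset (1 <= K <= p - 1), otherwise the complement geometric mean is
#'   undefined.
#' @return the enrichment statistic, a real scalar.
#' @examples
#' cbeaStatistic(c(0.4, 0.2, 0.3, 0.1), 1:2)
#' @export
cbeaStatistic <- function(row, setIdx) {
    setIdx <- as.integer(setIdx)
    p <- length(row)
    if (length(setIdx) < 1L || length(setIdx) >= p)
        stop("the set must be a non-empty proper subset of the taxa ",
             "(complement geometric mean undefined otherwise)")
    balance(row, setIdx, setdiff(seq_len(p), setIdx))
}

## shared scoring kernel: logX is n x p log-abundances, mem is p x m 0/1.
## Per-set score = sqrt(K(p-K)/p) * (mean log in-set - mean log out-of-set).
.scoreKernel <- function(logX, mem) {
    p <- ncol(logX)
    K <- colSums(mem)
    inSums <- logX %*% mem                       # n x m
    tot <- rowSums(logX)
    meanIn <- sweep(inSums, 2, K, "/")
    meanOut <- sweep(-inSums, 1, tot, "+")
    meanOut <- sweep(meanOut, 2, p - K, "/")
    sweep(meanIn - meanOut, 2, sqrt(K * (p - K) / p), "*")
}

#' Raw enrichment score matrix
#'
#' Applies \code{\link{cbeaStatistic}} to every sample and every set; columns
#' follow the set order of the collection. The table and the collection must
#' share an identical taxon universe (same ids, same order).
#'
#' @param table a strictly positive \linkS4class{CompositionTable} (apply
#'   \code{\link{replaceZeros}} and \code{\link{closure}} first; scores are
#'   invariant to the closure but require positivity).
#' @param sets a \linkS4class{SetCollection} aligned to the table.
#' @return numeric matrix, samples x sets, all values finite.
#' @examples
#' tab <- closure(CompositionTable(rbind(s1 = c(4, 2, 3, 1)),
#'                transpose = FALSE))
#' sets <- SetCollection(list(top = c("taxon1", "taxon2")), taxonIds(tab))
#' scoreMatrix(tab, sets)
#' @export
scoreMatrix <- function(table, sets) {
    stopifnot(methods::is(table, "CompositionTable"),
              methods::is(sets, "SetCollection"))
    if (!identical(taxonIds(table), taxonIds(sets)))
        stop("taxon identifiers of the table and the set collection disagree; ",
             "align them first (same ids, same order)")
    v <- table@values
    if (any(v <= 0))
        stop("scoring requires strictly positive abundances; ",
             "run replaceZeros() first")
    out <- .scoreKernel(log(v), sets@membership)
    dimnames(out) <- list(rownames(v), colnames(sets@membership))
    out
}
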