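#' @include AllClasses.R AllGenerics.R composition.R null-model.R
NULL

#' Competitive balance enrichment analysis, end to end
#'
#' Runs the full single-sample taxon-set enrichment pipeline:
#' zero replacement, closure, raw balance scores, empirical-null estimation
#' by taxa permutation, and the requested output transform. With
#' \code{outputType = "raw"} no permutation is performed and the raw score
#' matrix is returned as-is.
#'
#' @param table a \linkS4class{CompositionTable}, or a numeric matrix /
#'   data.frame of counts or relative abundances (samples x taxa).
#' @param sets a \linkS4class{SetCollection}, or a named list of taxon-id
#'   vectors (converted against the table's taxa).
#' @param family null family, "mixture2" (default; the variant with reliable
#'   sample-level type-I error control) or "normal".
#' @param adjust apply the inter-taxa correlation adjustment (default FALSE;
#'   adjusted nulls are conservative for mean-inflated sets but guard against
#'   flagging merely correlated sets).
#' @param outputType "cdf" (default), "zscore", "pval" or "raw".
#' @param nPerm taxa permutations pooled into the null (default 100).
#' @param pseudocount added to all entries when zeros are present
#'   (default 1e-5).
#' @param seed optional integer; the run is reproducible given it.
#' @param maxIter,tol EM control for the mixture fit.
#' @return an \linkS4class{EnrichmentResult} (samples x sets).
#' @examples
#' set.seed(1)
#' counts <- matrix(rnbinom(50 * 30, mu = 100, size = 1), 50, 30)
#' res <- cbea(counts, list(block = paste0("taxon", 1:10)),
#'             outputType = "pval", nPerm = 20, seed = 7)
#' head(scores(res))
#' @export
cbea <- function(table, sets, family = c("mixture2", "normal"),
                 adjust = FALSE,
                 outputType = c("cdf", "zscore", "pval", "raw"),
                 nPerm = 100L, pseudocount = 1e-5, seed = NULL,
                 maxIter = 1000L, tol = 1e-6) {
    family <- match.arg(family)
    outputType <- match.arg(outputType)
    if (!methods::is(table, "CompositionTable"))
        table <- CompositionTable(table)
    if (!methods::is(sets, "SetCollection")) {
        if (!is.list(sets))
            stop("'sets' must be a SetCollection or a named list of taxon ids")
        sets <- SetCollection(sets, universe = taxonIds(table))
    }
    if (!identical(taxonIds(table), taxonIds(sets))) {
        if (!setequal(taxonIds(table), taxonIds(sets)))
            stop("taxon identifiers of the table and the set collection disagree")
        sets <- methods::new("SetCollection",
            membership = sets@membership[taxonIds(table), , drop = FALSE])
    }
    comp <- closure(replaceZeros(table, pseudocount))
    raw <- scoreMatrix(comp, sets)
    if (outputType == "raw")
        return(transformScores(raw, outputType = "raw"))
    null <- buildNull(comp, sets, family = family, adjust = adjust,
                      nPerm = nPerm, seed = seed, maxIter = maxIter,
                      tol = tol)
    transformScores(raw, null, outputType)
}
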