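#' CompositionTable: a samples-by-taxa abundance matrix
#'
#' Container for a taxonomic abundance table with unique sample and taxon
#' identifiers. Rows are samples, columns are taxa. Values may be raw counts
#' or relative abundances: every enrichment score downstream is invariant to
#' row scaling, so no normalisation flag is needed (closure is always applied
#' internally before scoring).
#'
#' @slot values numeric matrix, n samples x p taxa, non-negative, with unique
#'   rownames (sample ids) and colnames (taxon ids).
#'
#' @export
setClass("CompositionTable", representation(values = "matrix"))

setValidity("CompositionTable", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 1L || ncol(v) < 2L)
        return("need at least 1 sample and 2 taxa")
    if (anyNA(v) || any(!is.finite(v)))
        return("abundances must be finite and non-missing")
    if (any(v < 0)) return("abundances must be non-negative")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("sample and taxon identifiers are required (dimnames)")
    if (anyDuplicated(rownames(v))) return("duplicate sample identifiers")
    if (anyDuplicated(colnames(v))) return("duplicate taxon identifiers")
    TRUE
})

#' Construct a CompositionTable
#'
#' @param x numeric matrix or data.frame, samples in rows and taxa in columns
#'   (use \code{transpose = TRUE} for taxa-in-rows dialects). Missing dimnames
#'   are filled with \code{sample<i>} / \code{taxon<j>}.
#' @param transpose logical; transpose \code{x} before interpreting rows as
#'   samples.
#' @return A \linkS4class{CompositionTable}.
#' @examples
#' tab <- CompositionTable(matrix(1:6, nrow = 2))
#' abundances(tab)
#' @export
CompositionTable <- function(x, transpose = FALSE) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x)) stop("'x' must be a matrix or data.frame")
    if (transpose) x <- t(x)
    if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("taxon", seq_len(ncol(x)))
    methods::new("CompositionTable", values = x)
}

#' SetCollection: binary taxon-set membership
#'
#' Membership of p taxa in m named sets, aligned to the taxon universe of a
#' \linkS4class{CompositionTable}. Every set must be a non-empty proper
#' subset of the universe (1 <= size <= p - 1).
#'
#' @slot membership numeric 0/1 matrix, p taxa x m sets, rownames = taxon ids,
#'   colnames = set names.
#'
#' @export
setClass("SetCollection", representation(membership = "matrix"))

setValidity("SetCollection", function(object) {
    m <- object@membership
    if (!is.numeric(m)) return("'membership' must be numeric")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("taxon ids (rownames) and set names (colnames) are required")
    if (anyDuplicated(rownames(m))) return("duplicate taxon identifiers")
    if (anyDuplicated(colnames(m))) return("duplicate set names")
    if (!all(m %in% c(0, 1))) return("membership entries must be 0 or 1")
    sz <- colSums(m)
    if (any(sz < 1))
        return("every set must contain at least one taxon")
    if (any(sz > nrow(m) - 1L))
        return("a set covering the whole taxon universe is not a proper subset")
    TRUE
})

#' Construct a SetCollection from a named list of taxa
#'
#' @param sets named list; each element is a character vector of taxon ids.
#' @param universe character vector of all taxon ids (typically
#'   \code{taxonIds(table)}). Taxa listed in a set but absent from the
#'   universe are dropped with a message; sets that become empty are dropped
#'   with a warning.
#' @return A \linkS4class{SetCollection}.
#' @examples
#' SetCollection(list(aerobes = c("t1", "t2")), universe = c("t1", "t2", "t3"))
#' @export
SetCollection <- function(sets, universe) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("'sets' must be a uniquely named list")
    universe <- as.character(universe)
    dropped <- sum(vapply(sets, function(s) sum(!s %in% universe), 0L))
    if (dropped > 0)
        message(dropped, " set member(s) absent from the taxon universe; dropped")
    sets <- lapply(sets, intersect, universe)
    empty <- vapply(sets, length, 0L) == 0L
    if (any(empty)) {
        warning("dropping empty set(s) after intersection with universe: ",
                paste(names(sets)[empty], collapse = ", "))
        sets <- sets[!empty]
    }
    if (length(sets) == 0L) stop("no non-empty sets remain")
    m <- vapply(sets, function(s) as.numeric(universe %in% s),
                numeric(length(universe)))
    m <- matrix(m, nrow = length(universe),
                dimnames = list(universe, names(sets)))
    methods::new("SetCollection", membership = m)
}

#' NullModel: per-set empirical null distribution of the enrichment statistic
#'
#' Parametric fits (normal or two-component Gaussian mixture) to taxa-permuted
#' enrichment scores, one fit per set, with optional correlation adjustment
#' (the spread re-estimated from unpermuted scores).
#'
#' @slot family "normal" or "mixture2".
#' @slot adjusted logical; was the correlation adjustment applied.
#' @slot nPerm number of taxa permutations pooled into the null.
#' @slot parameters data.frame, one row per set. Normal: \code{set, mu,
#'   sigma}. Mixture: \code{set, w1, mu1, sigma1, w2, mu2, sigma2} with
#'   components ordered by ascending mean.
#' @slot diagnostics data.frame: per-set convergence flag, log-likelihood and
#'   whether a degenerate mixture fit fell back to the normal.
#'
#' @export
setClass("NullModel", representation(
    family = "character", adjusted = "logical", nPerm = "integer",
    parameters = "data.frame", diagnostics = "data.frame"))

setValidity("NullModel", function(object) {
    if (!object@family %in% c("normal", "mixture2"))
        return("family must be 'normal' or 'mixture2'")
    p <- object@parameters
    if (object@family == "normal") {
        if (!all(c("set", "mu", "sigma") %in% names(p)))
            return("normal parameters need columns set, mu, sigma")
        if (any(p$sigma <= 0)) return("sigma must be positive")
    } else {
        need <- c("set", "w1", "mu1", "sigma1", "w2", "mu2", "sigma2")
        if (!all(need %in% names(p)))
            return("mixture parameters need columns set, w1, mu1, sigma1, w2, mu2, sigma2")
        if (any(p$sigma1 <= 0) || any(p$sigma2 <= 0))
            return("component sigmas must be positive")
        if (any(abs(p$w1 + p$w2 - 1) > 1e-9))
            return("component weights must sum to 1")
        if (any(p$w1 < 0 | p$w1 > 1)) return("weights must lie in [0, 1]")
        if (any(p$mu1 > p$mu2 + 1e-12))
            return("mixture components must be ordered by ascending mean")
    }
    TRUE
})

#' EnrichmentResult: samples-by-sets enrichment scores
#'
#' Output of \code{\link{cbea}} / \code{\link{transformScores}}: a numeric
#' matrix of per-sample, per-set values on one of four scales ("raw", "cdf",
#' "zscore", "pval"), with the fitted \linkS4class{NullModel} attached for
#' the transformed scales.
#'
#' @slot scores numeric matrix, samples x sets.
#' @slot outputType "raw", "cdf", "zscore" or "pval".
#' @slot nullModel the \linkS4class{NullModel} used (NULL for raw output).
#'
#' @export
setClass("EnrichmentResult", representation(
    scores = "matrix", outputType = "character", nullModel = "ANY"))

setValidity("EnrichmentResult", function(object) {
    if (!object@outputType %in% c("raw", "cdf", "zscore", "pval"))
        return("outputType must be raw, cdf, zscore or pval")
    if (any(!is.finite(object@scores)))
        return("scores must be finite")
    if (object@outputType %in% c("cdf", "pval") &&
        (any(object@scores < 0) || any(object@scores > 1)))
        return("cdf/pval scores must lie in [0, 1]")
    if (object@outputType != "raw" && !methods::is(object@nullModel, "NullModel"))
        return("transformed output requires a NullModel")
    TRUE
})

#' SimulationConfig: parameters of the synthetic count generator
#'
#' Describes a zero-inflated negative-binomial (ZINB) taxonomic count table
#' with disjoint taxon-set blocks, optional block-exchangeable correlation
#' inside designated sets, and mean-inflated enrichment for those sets.
#'
#' @slot nSamples,nTaxa,setSize,nSets integers; \code{setSize * nSets} must
#'   not exceed \code{nTaxa}.
#' @slot nbMean,nbDispersion negative-binomial mean and size (variance =
#'   mu + mu^2 / size).
#' @slot zeroProb probability of a structural zero (sparsity), in [0, 1).
#' @slot rho latent exchangeable correlation within designated sets, in [0, 1).
#' @slot foldChange mean inflation (>= 1) for taxa in designated sets;
#'   1 means the global null.
#' @slot enrichedSets integer indices of the designated sets (receive rho and,
#'   when foldChange > 1, the mean inflation).
#'
#' @export
setClass("SimulationConfig", representation(
    nSamples = "integer", nTaxa = "integer", setSize = "integer",
    nSets = "integer", nbMean = "numeric", nbDispersion = "numeric",
    zeroProb = "numeric", rho = "numeric", foldChange = "numeric",
    enrichedSets = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nSamples < 1L) return("nSamples must be >= 1")
    if (object@setSize < 1L || object@nSets < 1L)
        return("setSize and nSets must be >= 1")
    if (object@setSize * object@nSets > object@nTaxa)
        return("setSize * nSets exceeds nTaxa: blocks must fit in the taxon universe")
    if (object@nbMean <= 0 || object@nbDispersion <= 0)
        return("nbMean and nbDispersion must be positive")
    if (object@zeroProb < 0 || object@zeroProb >= 1)
        return("zeroProb must lie in [0, 1)")
    if (object@rho < 0 || object@rho >= 1)
        return("rho must lie in [0, 1)")
    if (object@foldChange < 1) return("foldChange must be >= 1")
    if (length(object@enrichedSets) &&
        (min(object@enrichedSets) < 1L ||
         max(object@enrichedSets) > object@nSets))
        return("enrichedSets indices out of range")
    TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSamples,nTaxa,setSize,nSets dimensions of the simulated table.
#' @param nbMean,nbDispersion NB mean and size parameter.
#' @param zeroProb structural zero probability (sparsity).
#' @param rho within-set latent exchangeable correlation.
#' @param foldChange mean inflation for enriched taxa (1 = global null).
#' @param enrichedSets indices of designated sets.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' simConfig(nSamples = 50, nTaxa = 100, setSize = 20, nSets = 5)
#' @export
simConfig <- function(nSamples, nTaxa, setSize = 20L, nSets = 1L,
                      nbMean = 100, nbDispersion = 1, zeroProb = 0,
                      rho = 0, foldChange = 1, enrichedSets = integer(0)) {
    methods::new("SimulationConfig",
        nSamples = as.integer(nSamples), nTaxa = as.integer(nTaxa),
        setSize = as.integer(setSize), nSets = as.integer(nSets),
        nbMean = as.numeric(nbMean), nbDispersion = as.numeric(nbDispersion),
        zeroProb = as.numeric(zeroProb), rho = as.numeric(rho),
        foldChange = as.numeric(foldChange),
        enrichedSets = as.integer(enrichedSets))
}

#' SimulatedDataset: a synthetic count table with ground truth
#'
#' @slot counts integer-valued \linkS4class{CompositionTable}.
#' @slot sets the block \linkS4class{SetCollection}.
#' @slot truth named logical: is each set truly enriched.
#' @slot groups character: "case"/"control" per sample, or length 0 for
#'   single-group designs.
#' @slot config the generating \linkS4class{SimulationConfig}.
#'
#' @export
setClass("SimulatedDataset", representation(
    counts = "CompositionTable", sets = "SetCollection", truth = "logical",
    groups = "character", config = "SimulationConfig"))

setValidity("SimulatedDataset", function(object) {
    if (length(object@truth) != ncol(object@sets@membership))
        return("truth labels must align with sets")
    if (length(object@groups) &&
        length(object@groups) != nrow(object@counts@values))
        return("group labels must align with samples")
    if (any(object@counts@values %% 1 != 0))
        return("counts must be integers")
    TRUE
})
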