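#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn CompositionTable the abundance matrix (samples x taxa)
#' @param x,object a CompositionTable
#' @export
setMethod("abundances", "CompositionTable", function(x) x@values)

#' @describeIn CompositionTable sample identifiers
#' @export
setMethod("sampleIds", "CompositionTable", function(x) rownames(x@values))

#' @describeIn CompositionTable taxon identifiers
#' @export
setMethod("taxonIds", "CompositionTable", function(x) colnames(x@values))

#' @describeIn CompositionTable dimensions (samples, taxa)
#' @export
setMethod("dim", "CompositionTable", function(x) dim(x@values))

#' @describeIn CompositionTable brief display
#' @export
setMethod("show", "CompositionTable", function(object) {
    v <- object@values
    cat("CompositionTable:", nrow(v), "samples x", ncol(v), "taxa\n")
    cat("  zeros:", sum(v == 0), sprintf("(%.1f%%)", 100 * mean(v == 0)),
        " row sums:", paste(signif(range(rowSums(v)), 4), collapse = " - "),
        "\n")
})

#' @describeIn SetCollection the 0/1 membership matrix (taxa x sets)
#' @param x,object a SetCollection
#' @export
setMethod("membership", "SetCollection", function(x) x@membership)

#' @describeIn SetCollection taxon universe
#' @export
setMethod("taxonIds", "SetCollection", function(x) rownames(x@membership))

#' @describeIn SetCollection number of sets
#' @export
setMethod("length", "SetCollection", function(x) ncol(x@membership))

#' @describeIn SetCollection set names
#' @export
setMethod("names", "SetCollection", function(x) colnames(x@membership))

#' @describeIn SetCollection taxa per set
#' @export
setMethod("setSizes", "SetCollection", function(x) {
    stats::setNames(as.integer(colSums(x@membership)), colnames(x@membership))
})

#' @describeIn SetCollection membership as a named list of taxon ids
#' @export
setMethod("setMembers", "SetCollection", function(x) {
    apply(x@membership > 0, 2, function(i) rownames(x@membership)[i],
          simplify = FALSE)
})

#' @describeIn SetCollection subset by set name or index
#' @param i set names or indices
#' @param j,drop,... unused
#' @export
setMethod("[", "SetCollection", function(x, i, j, ..., drop = FALSE) {
    methods::new("SetCollection",
                 membership = x@membership[, i, drop = FALSE])
})

#' @describeIn SetCollection brief display
#' @export
setMethod("show", "SetCollection", function(object) {
    m <- object@membership
    cat("SetCollection:", ncol(m), "sets over", nrow(m), "taxa\n")
    cat("  set sizes:", paste(utils::head(colSums(m), 8), collapse = ", "),
        if (ncol(m) > 8) "..." else "", "\n")
})

#' @describeIn NullModel distribution family ("normal" or "mixture2")
#' @param x,object a NullModel
#' @export
setMethod("nullFamily", "NullModel", function(x) x@family)

#' @describeIn NullModel was the correlation adjustment applied
#' @export
setMethod("isAdjusted", "NullModel", function(x) x@adjusted)

#' @describeIn NullModel per-set fitted parameters
#' @export
setMethod("nullParameters", "NullModel", function(x) x@parameters)

#' @describeIn NullModel per-set convergence diagnostics
#' @export
setMethod("nullDiagnostics", "NullModel", function(x) x@diagnostics)

#' @describeIn NullModel brief display
#' @export
setMethod("show", "NullModel", function(object) {
    cat("NullModel:", object@family,
        if (object@adjusted) "(correlation-adjusted)" else "(unadjusted)",
        "\n  sets:", nrow(object@parameters),
        " permutations pooled:", object@nPerm, "\n")
    if (any(object@diagnostics$fallbackNormal))
        cat("  ", sum(object@diagnostics$fallbackNormal),
            "set(s) fell back to the normal fit (degenerate mixture)\n")
})

#' @describeIn EnrichmentResult the score matrix (samples x sets)
#' @param x,object an EnrichmentResult
#' @export
setMethod("scores", "EnrichmentResult", function(x) x@scores)

#' @describeIn EnrichmentResult scale of the scores
#' @export
setMethod("outputType", "EnrichmentResult", function(x) x@outputType)

#' @describeIn EnrichmentResult the fitted null model (NULL for raw)
#' @export
setMethod("nullModel", "EnrichmentResult", function(x) x@nullModel)

#' @describeIn EnrichmentResult dimensions (samples, sets)
#' @export
setMethod("dim", "EnrichmentResult", function(x) dim(x@scores))

#' @describeIn EnrichmentResult brief display
#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult (", object@outputType, "): ",
        nrow(object@scores), " samples x ", ncol(object@scores), " sets\n",
        sep = "")
    if (methods::is(object@nullModel, "NullModel"))
        cat("  null:", object@nullModel@family,
            if (object@nullModel@adjusted) "adjusted" else "unadjusted", "\n")
})

#' @describeIn SimulatedDataset the simulated count table
#' @param x,object a SimulatedDataset
#' @export
setMethod("simCounts", "SimulatedDataset", function(x) x@counts)

#' @describeIn SimulatedDataset the block set collection
#' @export
setMethod("simSets", "SimulatedDataset", function(x) x@sets)

#' @describeIn SimulatedDataset named logical vector of true enrichment
#' @export
setMethod("truthLabels", "SimulatedDataset", function(x) x@truth)

#' @describeIn SimulatedDataset case/control labels (may be empty)
#' @export
setMethod("groupLabels", "SimulatedDataset", function(x) x@groups)

#' @describeIn SimulatedDataset brief display
#' @export
setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset:", nrow(object@counts@values), "samples x",
        ncol(object@counts@values), "taxa;",
        ncol(object@sets@membership), "sets (",
        sum(object@truth), "enriched )\n")
    if (length(object@groups))
        cat("  groups:", sum(object@groups == "case"), "cases /",
            sum(object@groups == "control"), "controls\n")
})

#' @describeIn SimulationConfig brief display
#' @param object a SimulationConfig
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSamples, "samples x", object@nTaxa,
        "taxa;", object@nSets, "sets of", object@setSize, "\n")
    cat(sprintf("  NB(mean %.3g, size %.3g), zeroProb %.2f, rho %.2f, fold %.2f\n",
                object@nbMean, object@nbDispersion, object@zeroProb,
                object@rho, object@foldChange))
    if (length(object@enrichedSets))
        cat("  designated sets:",
            paste(object@enrichedSets, collapse = ", "), "\n")
})
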