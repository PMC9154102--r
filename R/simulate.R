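#' @include AllClasses.R AllGenerics.R
NULL

## latent Gaussian draw with exchangeable correlation rho inside the
## designated taxon blocks and independence elsewhere; n x p
.latentGaussian <- function(n, p, blocks, rho) {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
        for (idx in blocks) {
            shared <- stats::rnorm(n)
            z[, idx] <- sqrt(rho) * shared +
                sqrt(1 - rho) * matrix(stats::rnorm(n * length(idx)),
                                       n, length(idx))
        }
    }
    z
}

.blockIndices <- function(config) {
    lapply(seq_len(config@nSets), function(i)
        (i - 1L) * config@setSize + seq_len(config@setSize))
}

## core generator: caseMask marks the samples in which enriched taxa get the
## fold-change; length-n logical
.simulateCore <- function(config, caseMask) {
    n <- config@nSamples; p <- config@nTaxa
    blocks <- .blockIndices(config)
    marked <- blocks[config@enrichedSets]
    z <- .latentGaussian(n, p, marked, config@rho)
    u <- stats::pnorm(z)
    mu <- matrix(config@nbMean, n, p)
    if (config@foldChange > 1 && length(marked) && any(caseMask)) {
        enrichedTaxa <- unlist(marked)
        mu[caseMask, enrichedTaxa] <- config@nbMean * config@foldChange
    }
    counts <- stats::qnbinom(u, size = config@nbDispersion, mu = mu)
    if (config@zeroProb > 0) {
        mask <- matrix(stats::runif(n * p) < config@zeroProb, n, p)
        counts[mask] <- 0L
    }
    counts <- matrix(as.numeric(counts), n, p, dimnames = list(
        sprintf("sample%04d", seq_len(n)), sprintf("taxon%04d", seq_len(p))))
    setsL <- stats::setNames(
        lapply(blocks, function(idx) colnames(counts)[idx]),
        sprintf("set%02d", seq_len(config@nSets)))
    sets <- SetCollection(setsL, universe = colnames(counts))
    truth <- stats::setNames(seq_len(config@nSets) %in% config@enrichedSets &
                                 config@foldChange > 1, names(setsL))
    list(counts = CompositionTable(counts), sets = sets, truth = truth)
}

#' Simulate a ZINB taxonomic count table with block structure
#'
#' Draws a latent multivariate normal with exchangeable correlation
#' \code{rho} inside the designated set blocks (independent elsewhere), maps
#' each margin through the negative-binomial quantile function (a Gaussian
#' copula; mean \code{nbMean}, times \code{foldChange} for taxa in designated
#' sets, same dispersion), and finally applies independent
#' Bernoulli(\code{zeroProb}) structural-zero masking. Taxa are partitioned
#' into \code{nSets} disjoint blocks of \code{setSize} (taxa beyond the
#' blocks belong to no set). \code{rho} is specified on the latent normal
#' scale; the induced count-scale correlation is attenuated.
#'
#' In this single-group design the fold change applies to all samples;
#' use \code{\link{simulateTwoGroups}} for case/control enrichment.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional integer; the dataset is deterministic given it.
#' @return a \linkS4class{SimulatedDataset}.
#' @examples
#' sim <- simulateCounts(simConfig(nSamples = 20, nTaxa = 60, nSets = 3),
#'                       seed = 1)
#' simCounts(sim)
#' @export
simulateCounts <- function(config, seed = NULL) {
    stopifnot(methods::is(config, "SimulationConfig"))
    gen <- function() .simulateCore(config, rep(TRUE, config@nSamples))
    parts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
    methods::new("SimulatedDataset", counts = parts$counts,
                 sets = parts$sets, truth = parts$truth,
                 groups = character(0), config = config)
}

#' Simulate a case/control table with set enrichment in cases only
#'
#' Same generator as \code{\link{simulateCounts}}, but the fold change on
#' designated taxa applies only to case samples; control samples share the
#' baseline mean. The first \code{nCases} samples are cases.
#'
#' @param config a \linkS4class{SimulationConfig} with
#'   \code{nSamples = nCases + nControls}.
#' @param nCases,nControls group sizes.
#' @param seed optional integer seed.
#' @return a \linkS4class{SimulatedDataset} with \code{groupLabels} set.
#' @export
simulateTwoGroups <- function(config, nCases, nControls, seed = NULL) {
    stopifnot(methods::is(config, "SimulationConfig"))
    nCases <- as.integer(nCases); nControls <- as.integer(nControls)
    if (nCases + nControls != config@nSamples)
        stop("nCases + nControls must equal config nSamples")
    caseMask <- seq_len(config@nSamples) <= nCases
    gen <- function() .simulateCore(config, caseMask)
    parts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
    methods::new("SimulatedDataset", counts = parts$counts,
                 sets = parts$sets, truth = parts$truth,
                 groups = ifelse(caseMask, "case", "control"),
                 config = config)
}
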