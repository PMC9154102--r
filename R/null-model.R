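#' @include AllClasses.R AllGenerics.R composition.R
NULL

#' Permute taxa columns of a table
#'
#' Applies one uniform random permutation of the taxa columns, identical for
#' all samples, while keeping the taxon identifiers in their original
#' positions. This breaks the taxon-to-set assignment (the competitive null)
#' without altering any sample's composition: scoring a fixed set on the
#' permuted table equals scoring the correspondingly permuted set on the
#' original table.
#'
#' @param table a \linkS4class{CompositionTable}.
#' @param seed optional integer; when given, the permutation is drawn under
#'   this seed without disturbing the caller's RNG state.
#' @return a \linkS4class{CompositionTable} with shuffled columns.
#' @export
permuteTaxa <- function(table, seed = NULL) {
    stopifnot(methods::is(table, "CompositionTable"))
    p <- ncol(table@values)
    perm <- if (is.null(seed)) sample.int(p)
            else withr::with_seed(seed, sample.int(p))
    v <- table@values[, perm, drop = FALSE]
    colnames(v) <- colnames(table@values)
    methods::initialize(table, values = v)
}

#' Maximum-likelihood normal fit
#'
#' @param x numeric vector, length >= 2, finite.
#' @return list with \code{mu} (sample mean), \code{sigma} (ML standard
#'   deviation, i.e. divisor N) and \code{loglik}.
#' @examples
#' fitNormal(c(-1, 1)) # mu 0, sigma 1
#' @export
fitNormal <- function(x) {
    if (length(x) < 2L || any(!is.finite(x)))
        stop("'x' must be >= 2 finite values")
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma < 1e-12)
        stop("degenerate fit: all scores identical (sigma = 0)")
    list(mu = mu, sigma = sigma,
         loglik = sum(stats::dnorm(x, mu, sigma, log = TRUE)))
}

## two-component mixture density / cdf on a parameter list
## par: w1, mu1, sigma1, w2, mu2, sigma2
.dmix2 <- function(x, par) {
    par$w1 * stats::dnorm(x, par$mu1, par$sigma1) +
        par$w2 * stats::dnorm(x, par$mu2, par$sigma2)
}

.pmix2 <- function(q, par) {
    par$w1 * stats::pnorm(q, par$mu1, par$sigma1) +
        par$w2 * stats::pnorm(q, par$mu2, par$sigma2)
}

## one EM run from a given parameter list; compiled inner loop
.emRun <- function(x, par, maxIter, tol) {
    f <- .emMix2Cpp(x, par$w1, par$mu1, par$sigma1,
                    par$w2, par$mu2, par$sigma2,
                    as.integer(maxIter), tol)
    list(par = f[c("w1", "mu1", "sigma1", "w2", "mu2", "sigma2")],
         loglik = f$loglik, converged = f$converged, iter = f$iter)
}

.mixInitQuantile <- function(x) {
    lo <- x[x <= stats::median(x)]
    hi <- x[x > stats::median(x)]
    if (!length(hi)) { # heavy ties at the median
        hi <- lo
    }
    list(w1 = 0.5, mu1 = mean(lo), sigma1 = max(stats::sd(x) / 2, 1e-6),
         w2 = 0.5, mu2 = mean(hi), sigma2 = max(stats::sd(x) / 2, 1e-6))
}

.mixInitRandom <- function(x) {
    z <- sample(c(TRUE, FALSE), length(x), replace = TRUE)
    if (!any(z) || all(z)) z[1] <- !z[1]
    list(w1 = 0.5, mu1 = mean(x[z]), sigma1 = max(stats::sd(x), 1e-6),
         w2 = 0.5, mu2 = mean(x[!z]), sigma2 = max(stats::sd(x), 1e-6))
}

#' Two-component Gaussian mixture fit by EM
#'
#' Univariate expectation-maximisation with a deterministic quantile-split
#' initialisation (below/above the median) plus seeded random restarts. Each
#' start runs a short burn-in and only the best-likelihood start is run to
#' convergence; convergence is declared when the log-likelihood improves by
#' less than \code{tol}. Components are returned ordered by ascending mean,
#' which also makes the fit invariant to label swaps in the initialisation.
#'
#' A fit is flagged \code{degenerate} when a component collapses (weight
#' < 0.01 or sigma < 1e-8); callers such as \code{\link{buildNull}} fall back
#' to the normal fit in that case. Non-convergence within \code{maxIter} is
#' flagged, not fatal: with heavily overlapping components EM is known to
#' converge slowly.
#'
#' @param x numeric vector, length >= 10, finite.
#' @param maxIter,tol EM stopping rule (default 1000 iterations, 1e-6
#'   log-likelihood change).
#' @param nStart number of initialisations (1 quantile split +
#'   \code{nStart - 1} random).
#' @param seed optional integer seed for the random restarts.
#' @return list: \code{w1, mu1, sigma1, w2, mu2, sigma2} (ascending means),
#'   \code{loglik}, \code{converged}, \code{degenerate}, \code{iter}.
#' @export
fitMixture2 <- function(x, maxIter = 1000L, tol = 1e-6, nStart = 3L,
                        seed = NULL) {
    if (any(!is.finite(x)))
        stop("'x' must be finite (no NA/NaN/Inf)")
    if (length(x) < 10L)
        stop("need at least 10 observations to fit a 2-component mixture")
    run <- function() {
        inits <- c(list(.mixInitQuantile(x)),
                   replicate(max(nStart - 1L, 0L), .mixInitRandom(x),
                             simplify = FALSE))
        burn <- lapply(inits, function(p0) .emRun(x, p0, maxIter = 25L,
                                                  tol = tol))
        best <- burn[[which.max(vapply(burn, `[[`, 0, "loglik"))]]
        if (!best$converged)
            best <- .emRun(x, best$par, maxIter = maxIter, tol = tol)
        best
    }
    fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    par <- fit$par
    if (par$mu1 > par$mu2) {   # order components by ascending mean
        par <- list(w1 = par$w2, mu1 = par$mu2, sigma1 = par$sigma2,
                    w2 = par$w1, mu2 = par$mu1, sigma2 = par$sigma1)
    }
    degenerate <- min(par$w1, par$w2) < 0.01 ||
        min(par$sigma1, par$sigma2) < 1e-8
    c(par, list(loglik = fit$loglik, converged = fit$converged,
                degenerate = degenerate, iter = fit$iter))
}

## fit one family to a score vector, with the mixture falling back to the
## normal when degenerate; returns a one-row parameter df + diagnostics
.fitNullOne <- function(x, family, maxIter, tol, seed) {
    if (family == "normal") {
        f <- fitNormal(x)
        return(list(par = data.frame(mu = f$mu, sigma = f$sigma),
                    diag = data.frame(converged = TRUE, loglik = f$loglik,
                                      fallbackNormal = FALSE)))
    }
    f <- tryCatch(fitMixture2(x, maxIter = maxIter, tol = tol, seed = seed),
                  error = function(e) NULL)
    if (is.null(f) || f$degenerate) {
        g <- fitNormal(x)
        return(list(par = data.frame(w1 = 1, mu1 = g$mu, sigma1 = g$sigma,
                                     w2 = 0, mu2 = g$mu, sigma2 = g$sigma),
                    diag = data.frame(converged = TRUE, loglik = g$loglik,
                                      fallbackNormal = TRUE)))
    }
    list(par = data.frame(w1 = f$w1, mu1 = f$mu1, sigma1 = f$sigma1,
                          w2 = f$w2, mu2 = f$mu2, sigma2 = f$sigma2),
         diag = data.frame(converged = f$converged, loglik = f$loglik,
                           fallbackNormal = FALSE))
}

#' Estimate the per-set empirical null by taxa permutation
#'
#' For each set, pools the enrichment scores of \code{nPerm} independent
#' taxa permutations (one shared column permutation per replicate, applied to
#' all samples and all sets) — \code{n * nPerm} null draws per set — and fits
#' the chosen family by maximum likelihood (normal) or EM (mixture).
#'
#' With \code{adjust = TRUE}, the same family is also fitted to the set's
#' unpermuted scores and the spread parameters of the permuted fit are
#' replaced by those of the unpermuted fit (normal: sigma; mixture: both
#' component sigmas, matched by ascending mean), keeping the permuted
#' location (and mixture weights). Taxa permutation destroys inter-taxa
#' correlation and with it the variance inflation correlated sets carry; the
#' swap restores that spread so correlated-but-not-enriched sets are not
#' flagged.
#'
#' @param table strictly positive \linkS4class{CompositionTable} (zeros
#'   already replaced; closure optional — scores are scale-invariant).
#' @param sets aligned \linkS4class{SetCollection}.
#' @param family "mixture2" (default) or "normal".
#' @param adjust apply the correlation adjustment (default FALSE).
#' @param nPerm number of taxa permutations pooled (default 100).
#' @param seed optional integer seed; the whole estimation is deterministic
#'   given it.
#' @param maxIter,tol EM control, see \code{\link{fitMixture2}}.
#' @return a \linkS4class{NullModel}.
#' @export
buildNull <- function(table, sets, family = c("mixture2", "normal"),
                      adjust = FALSE, nPerm = 100L, seed = NULL,
                      maxIter = 1000L, tol = 1e-6) {
    family <- match.arg(family)
    stopifnot(methods::is(table, "CompositionTable"),
              methods::is(sets, "SetCollection"))
    if (!identical(taxonIds(table), taxonIds(sets)))
        stop("taxon identifiers of the table and the set collection disagree")
    nPerm <- as.integer(nPerm)
    if (nPerm < 1L) stop("'nPerm' must be >= 1")
    v <- table@values
    if (any(v <= 0)) stop("strictly positive abundances required")
    logX <- log(v)
    mem <- sets@membership
    p <- nrow(mem); m <- ncol(mem); n <- nrow(v)

    doBuild <- function() {
        ## permuting the table's columns while keeping taxon ids in place is
        ## the same as permuting the membership rows
        pooled <- matrix(NA_real_, n * nPerm, m)
        for (b in seq_len(nPerm)) {
            perm <- sample.int(p)
            pooled[(b - 1L) * n + seq_len(n), ] <-
                .scoreKernel(logX, mem[perm, , drop = FALSE])
        }
        unperm <- if (adjust) .scoreKernel(logX, mem) else NULL
        parL <- vector("list", m); diagL <- vector("list", m)
        for (k in seq_len(m)) {
            fitSeed <- sample.int(.Machine$integer.max, 1L)
            fit <- .fitNullOne(pooled[, k], family, maxIter, tol, fitSeed)
            if (adjust) {
                ufit <- .fitNullOne(unperm[, k], family, maxIter, tol,
                                    sample.int(.Machine$integer.max, 1L))
                if (family == "normal") {
                    fit$par$sigma <- ufit$par$sigma
                } else {
                    ## components already ascending-mean ordered in both fits
                    fit$par$sigma1 <- ufit$par$sigma1
                    fit$par$sigma2 <- ufit$par$sigma2
                }
                fit$diag$adjustFallbackNormal <- ufit$diag$fallbackNormal
            }
            parL[[k]] <- fit$par; diagL[[k]] <- fit$diag
        }
        pars <- cbind(data.frame(set = colnames(mem),
                                 stringsAsFactors = FALSE),
                      do.call(rbind, parL))
        diags <- cbind(data.frame(set = colnames(mem),
                                  stringsAsFactors = FALSE),
                       do.call(rbind, diagL))
        rownames(pars) <- rownames(diags) <- NULL
        methods::new("NullModel", family = family, adjusted = adjust,
                     nPerm = nPerm, parameters = pars, diagnostics = diags)
    }
    if (is.null(seed)) doBuild() else withr::with_seed(seed, doBuild())
}

## CDF of the fitted null of set k (row of the parameter table)
.nullCdfRow <- function(q, par, family) {
    if (family == "normal") stats::pnorm(q, par$mu, par$sigma)
    else .pmix2(q, par)
}

#' Transform raw scores against a fitted null
#'
#' \describe{
#'   \item{cdf}{the fitted null CDF evaluated at each raw score}
#'   \item{pval}{one minus the CDF (upper-tail enrichment p-value)}
#'   \item{zscore}{(x - mu)/sigma under the normal null; the probit of the
#'     CDF under the mixture null, which preserves the CDF's ranking and
#'     reduces to the former in the one-component case}
#'   \item{raw}{pass-through (no null model needed)}
#' }
#'
#' @param raw numeric matrix of raw scores, samples x sets (as returned by
#'   \code{\link{scoreMatrix}}).
#' @param null a \linkS4class{NullModel} whose sets cover the columns of
#'   \code{raw} (required unless \code{outputType = "raw"}).
#' @param outputType "cdf", "zscore", "pval" or "raw".
#' @return an \linkS4class{EnrichmentResult}.
#' @export
transformScores <- function(raw, null = NULL,
                            outputType = c("cdf", "zscore", "pval", "raw")) {
    outputType <- match.arg(outputType)
    stopifnot(is.matrix(raw), is.numeric(raw))
    if (outputType == "raw")
        return(methods::new("EnrichmentResult", scores = raw,
                            outputType = "raw", nullModel = NULL))
    if (!methods::is(null, "NullModel"))
        stop("outputType '", outputType, "' requires a fitted NullModel")
    pars <- null@parameters
    idx <- match(colnames(raw), pars$set)
    if (anyNA(idx))
        stop("sets missing from the null model: ",
             paste(colnames(raw)[is.na(idx)], collapse = ", "))
    out <- raw
    for (j in seq_len(ncol(raw))) {
        par <- pars[idx[j], , drop = FALSE]
        cdf <- .nullCdfRow(raw[, j], par, null@family)
        out[, j] <- switch(outputType,
            cdf = cdf,
            pval = 1 - cdf,
            zscore = if (null@family == "normal")
                         (raw[, j] - par$mu) / par$sigma
                     else stats::qnorm(pmin(pmax(cdf, 1e-300), 1 - 1e-16)))
    }
    methods::new("EnrichmentResult", scores = out, outputType = outputType,
                 nullModel = null)
}
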