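#' @include AllClasses.R AllGenerics.R cbea.R
NULL

## Agresti-Coull interval for a proportion
.agrestiCoull <- function(phat, n, conf = 0.95) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    nt <- n + z^2
    pt <- (phat * n + z^2 / 2) / nt
    half <- z * sqrt(pt * (1 - pt) / nt)
    c(lower = max(0, pt - half), upper = min(1, pt + half))
}

.calibrationReport <- function(df, method, alpha, reps, seed) {
    structure(df, class = c("CalibrationReport", "data.frame"),
              method = method, alpha = alpha, reps = reps, seed = seed)
}

#' Within-sample Wilcoxon rank-sum baseline
#'
#' Two-sided rank-sum test comparing the abundances of in-set taxa against
#' the remainder taxa within a single sample — the standard non-parametric
#' baseline for the competitive set null. An all-tied sample is reported as
#' p = 1 with a message (no evidence either way).
#'
#' @param row numeric abundance vector for one sample.
#' @param setIdx indices of the in-set taxa (non-empty, proper subset).
#' @return two-sided p-value.
#' @export
wilcoxonBaseline <- function(row, setIdx) {
    setIdx <- as.integer(setIdx)
    p <- length(row)
    if (length(setIdx) < 1L || length(setIdx) >= p)
        stop("the set must be a non-empty proper subset of the taxa")
    inSet <- row[setIdx]; outSet <- row[-setIdx]
    if (length(unique(row)) == 1L) {
        message("all abundances tied; returning p = 1")
        return(1)
    }
    suppressWarnings(
        stats::wilcox.test(inSet, outSet, alternative = "two.sided")$p.value)
}

#' Sample-level type-I error by random taxon sets
#'
#' Repeatedly draws a uniform random taxon set of each requested size, scores
#' it on the (fixed) table with the chosen method, and records the fraction
#' of samples rejected at \code{alpha}. Random sets match the competitive
#' null — within a sample, randomly drawn taxa should not be enriched over
#' the background — so the mean rejection fraction estimates type-I error.
#'
#' @param table \linkS4class{CompositionTable} or matrix (counts or
#'   proportions).
#' @param setSizes integer vector of set sizes to test.
#' @param nReps random sets drawn per size (default 100).
#' @param alpha significance level (default 0.05).
#' @param method "cbea" or "wilcoxon" (the rank-sum baseline).
#' @param family,adjust,nPerm,pseudocount,maxIter,tol passed to
#'   \code{\link{cbea}} for \code{method = "cbea"}.
#' @param seed optional integer; governs the random sets (and the method's
#'   permutations).
#' @return a CalibrationReport data.frame: one row per set size with the
#'   mean rejection fraction (\code{estimate}), its standard error across
#'   replicates (\code{se}) and an Agresti-Coull interval.
#' @export
type1SampleLevel <- function(table, setSizes = c(20L, 50L), nReps = 100L,
                             alpha = 0.05, method = c("cbea", "wilcoxon"),
                             family = "mixture2", adjust = FALSE,
                             nPerm = 100L, pseudocount = 1e-5,
                             maxIter = 1000L, tol = 1e-6, seed = NULL) {
    method <- match.arg(method)
    if (!methods::is(table, "CompositionTable"))
        table <- CompositionTable(table)
    p <- ncol(table@values)
    if (any(setSizes > p - 1L)) stop("set sizes must be <= p - 1")
    runAll <- function() {
        comp <- closure(replaceZeros(table, pseudocount))
        rows <- lapply(setSizes, function(K) {
            rej <- vapply(seq_len(nReps), function(r) {
                idx <- sample.int(p, K)
                if (method == "cbea") {
                    sets <- methods::new("SetCollection", membership = matrix(
                        as.numeric(seq_len(p) %in% idx),
                        dimnames = list(taxonIds(table), "random")))
                    res <- cbea(comp, sets, family = family, adjust = adjust,
                                outputType = "pval", nPerm = nPerm,
                                pseudocount = pseudocount,
                                seed = sample.int(.Machine$integer.max, 1L),
                                maxIter = maxIter, tol = tol)
                    mean(scores(res)[, 1] < alpha)
                } else {
                    pv <- apply(abundances(comp), 1, wilcoxonBaseline, idx)
                    mean(pv < alpha)
                }
            }, 0)
            ci <- .agrestiCoull(mean(rej), nReps)
            data.frame(setSize = K, estimate = mean(rej),
                       se = stats::sd(rej) / sqrt(nReps),
                       lower = ci[["lower"]], upper = ci[["upper"]],
                       reps = nReps)
        })
        do.call(rbind, rows)
    }
    df <- if (is.null(seed)) runAll() else withr::with_seed(seed, runAll())
    .calibrationReport(df, method = paste0(method,
        if (method == "cbea") paste0("/", family,
            if (adjust) "/adjusted" else "/unadjusted") else ""),
        alpha = alpha, reps = nReps, seed = seed)
}

#' Population-level type-I error by label permutation
#'
#' Computes the method's per-set scores once, then repeatedly assigns
#' uniformly random binary case/control labels to the samples and applies a
#' per-set Welch's t-test; the fraction of sets rejected at \code{alpha},
#' averaged over label draws, estimates population-level type-I error. Sets
#' with (near-)constant scores in a replicate are excluded with a
#' diagnostic count rather than counted either way.
#'
#' @param table \linkS4class{CompositionTable} or matrix.
#' @param sets \linkS4class{SetCollection} or named list of taxon ids.
#' @param nLabelPerms number of random label assignments (default 100).
#' @param alpha significance level.
#' @param outputType score scale fed to the t-test (default "raw"; raw
#'   scores need no null estimation and are the recommended population-level
#'   variant).
#' @param family,adjust,nPerm,pseudocount passed to \code{\link{cbea}} when
#'   \code{outputType != "raw"}.
#' @param seed optional integer seed.
#' @return a CalibrationReport data.frame (single row) with the mean
#'   rejection fraction, its SE across label draws, an Agresti-Coull
#'   interval, and the count of excluded degenerate set-replicates.
#' @export
type1Population <- function(table, sets, nLabelPerms = 100L, alpha = 0.05,
                            outputType = "raw", family = "mixture2",
                            adjust = FALSE, nPerm = 100L,
                            pseudocount = 1e-5, seed = NULL) {
    run <- function() {
        res <- cbea(table, sets, family = family, adjust = adjust,
                    outputType = outputType, nPerm = nPerm,
                    pseudocount = pseudocount,
                    seed = sample.int(.Machine$integer.max, 1L))
        sc <- scores(res)
        n <- nrow(sc)
        if (n < 4L) stop("need at least 4 samples for label permutation")
        excluded <- 0L
        rej <- vapply(seq_len(nLabelPerms), function(r) {
            repeat {   # resample until both classes have >= 2 samples
                lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
                if (sum(lab) >= 2L && sum(!lab) >= 2L) break
            }
            pv <- apply(sc, 2, function(x) {
                if (stats::sd(x[lab]) < 1e-12 && stats::sd(x[!lab]) < 1e-12)
                    return(NA_real_)
                stats::t.test(x[lab], x[!lab])$p.value
            })
            excluded <<- excluded + sum(is.na(pv))
            mean(pv < alpha, na.rm = TRUE)
        }, 0)
        ci <- .agrestiCoull(mean(rej), nLabelPerms)
        data.frame(estimate = mean(rej),
                   se = stats::sd(rej) / sqrt(nLabelPerms),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   reps = nLabelPerms, excluded = excluded)
    }
    df <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    .calibrationReport(df, method = paste0("welch-t/", outputType),
                       alpha = alpha, reps = nLabelPerms, seed = seed)
}

## rank-statistic AUROC (Mann-Whitney form); ties handled by midranks
.aurocRank <- function(score, positive) {
    nPos <- sum(positive); nNeg <- sum(!positive)
    if (nPos == 0L || nNeg == 0L)
        stop("AUROC undefined: need both positive and negative samples")
    r <- rank(score)
    (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Power and score-ranking AUROC on a simulated dataset
#'
#' For each truly enriched set: power is the fraction of relevant samples
#' (case samples when group labels exist, all samples otherwise) whose
#' enrichment p-value falls below \code{alpha}; AUROC measures how well the
#' set's scores rank case samples above controls, with a DeLong confidence
#' interval. Scoring never inspects the truth labels — they enter only in
#' this final tally.
#'
#' @param dataset a \linkS4class{SimulatedDataset} with at least one truly
#'   enriched set; AUROC additionally requires case/control labels.
#' @param alpha significance level for power.
#' @param family,adjust,nPerm,pseudocount,seed passed to \code{\link{cbea}}.
#' @return list with \code{power} (CalibrationReport rows per enriched set)
#'   and \code{auroc} (data.frame per enriched set: auc, DeLong CI), or
#'   \code{auroc = NULL} without group labels.
#' @export
powerAndAuroc <- function(dataset, alpha = 0.05, family = "mixture2",
                          adjust = FALSE, nPerm = 100L, pseudocount = 1e-5,
                          seed = NULL) {
    stopifnot(methods::is(dataset, "SimulatedDataset"))
    truth <- truthLabels(dataset)
    if (!any(truth))
        stop("no truly enriched set in the dataset: power/AUROC undefined")
    res <- cbea(simCounts(dataset), simSets(dataset), family = family,
                adjust = adjust, outputType = "pval", nPerm = nPerm,
                pseudocount = pseudocount, seed = seed)
    pv <- scores(res)
    groups <- groupLabels(dataset)
    relevant <- if (length(groups)) groups == "case"
                else rep(TRUE, nrow(pv))
    enriched <- names(truth)[truth]
    powRows <- lapply(enriched, function(s) {
        rej <- pv[relevant, s] < alpha
        ci <- .agrestiCoull(mean(rej), sum(relevant))
        data.frame(set = s, power = mean(rej),
                   se = sqrt(mean(rej) * (1 - mean(rej)) / sum(relevant)),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   n = sum(relevant))
    })
    power <- .calibrationReport(do.call(rbind, powRows), method = "cbea",
                                alpha = alpha, reps = sum(relevant),
                                seed = seed)
    auroc <- NULL
    if (length(groups)) {
        rawScores <- scores(transformScores(
            scoreMatrix(closure(replaceZeros(simCounts(dataset),
                                             pseudocount)),
                        simSets(dataset)), outputType = "raw"))
        aurRows <- lapply(enriched, function(s) {
            r <- pROC::roc(response = factor(groups,
                                             levels = c("control", "case")),
                           predictor = rawScores[, s], quiet = TRUE,
                           direction = "<")
            ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
            data.frame(set = s, auc = as.numeric(pROC::auc(r)),
                       lower = ci[1], upper = ci[3])
        })
        auroc <- do.call(rbind, aurRows)
    }
    list(power = power, auroc = auroc)
}
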