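test_that("taxa permutation preserves compositions and only relabels columns", {
    tab <- closure(randomTable(5, 6, seed = 2))

    # a seed whose permutation is the identity leaves the table unchanged
    idSeed <- NULL
    for (s in 1:500) {
        if (identical(withr::with_seed(s, sample.int(6)), 1:6)) {
            idSeed <- s
            break
        }
    }
    expect_false(is.null(idSeed))
    expect_identical(abundances(permuteTaxa(tab, seed = idSeed)),
                     abundances(tab))

    permuted <- permuteTaxa(tab, seed = 99)
    expect_equal(rowSums(abundances(permuted)), rowSums(abundances(tab)))
    expect_identical(taxonIds(permuted), taxonIds(tab))

    # scoring a fixed set on permuted data equals scoring the
    # correspondingly permuted set on the original data
    perm <- withr::with_seed(99, sample.int(6))
    idx <- c(1, 3)
    onPermuted <- scoreMatrix(permuted, indexSet(tab, idx))
    onOriginal <- scoreMatrix(tab, indexSet(tab, perm[idx]))
    expect_equal(unname(onPermuted), unname(onOriginal), tolerance = 1e-12)
})

test_that("normal MLE fit: closed form, equivariance, Monte-Carlo recovery", {
    f <- fitNormal(c(-1, 1))
    expect_equal(f$mu, 0)
    expect_equal(f$sigma, 1)

    x <- withr::with_seed(1, stats::rnorm(200, 5, 2))
    f1 <- fitNormal(x); f2 <- fitNormal(x + 3)
    expect_equal(f2$mu, f1$mu + 3)
    expect_equal(f2$sigma, f1$sigma)

    y <- withr::with_seed(2, stats::rnorm(10000, 2, 3))
    g <- fitNormal(y)
    expect_lt(abs(g$mu - 2), 3 * 3 / sqrt(10000))
    expect_lt(abs(g$sigma - 3), 3 * 3 / sqrt(2 * 10000))

    expect_error(fitNormal(rep(1, 5)), "degenerate")
    expect_error(fitNormal(c(1, NA)), "finite")
})

test_that("mixture EM approximates a single Gaussian when the truth has one component", {
    x <- withr::with_seed(3, stats::rnorm(5000, 1, 2))
    f <- fitMixture2(x, seed = 1)
    grid <- seq(-7, 9, length.out = 400)
    mixCdf <- cbea:::.pmix2(grid, f)
    expect_lt(max(abs(mixCdf - stats::pnorm(grid, 1, 2))), 0.02)
})

test_that("mixture EM recovers well-separated components, any seed, ordered by mean", {
    x <- withr::with_seed(4, c(stats::rnorm(2500, -3, 1), stats::rnorm(2500, 3, 1)))
    f <- fitMixture2(x, seed = 10)
    expect_lt(abs(f$mu1 - (-3)), 0.2)
    expect_lt(abs(f$mu2 - 3), 0.2)
    expect_lt(abs(f$w1 - 0.5), 0.05)
    expect_lte(f$mu1, f$mu2)

    g <- fitMixture2(x, seed = 77)
    expect_equal(unlist(f[c("w1", "mu1", "sigma1", "w2", "mu2", "sigma2")]),
                 unlist(g[c("w1", "mu1", "sigma1", "w2", "mu2", "sigma2")]),
                 tolerance = 1e-3)
    expect_error(fitMixture2(c(x, Inf)), "finite")
    expect_error(fitMixture2(stats::rnorm(5)), "at least 10")
})

test_that("mixture EM agrees with an independent reference fit", {
    skip_if_not_installed("mclust")
    withr::local_package("mclust")
    x <- withr::with_seed(5, c(stats::rnorm(1500, -2, 0.8), stats::rnorm(3500, 1, 1.5)))
    f <- fitMixture2(x, seed = 1)
    ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    refMu <- sort(ref$parameters$mean)
    expect_equal(c(f$mu1, f$mu2), unname(refMu), tolerance = 0.05)
    # log-likelihood at least as good as the reference within slack
    expect_gt(f$loglik, ref$loglik - 1)
})

test_that("the unadjusted normal null equals the normal fit of pooled permuted scores", {
    tab <- closure(randomTable(8, 12, seed = 6))
    sets <- indexSet(tab, c(2, 3, 7), name = "s1")
    nPerm <- 5L
    null <- buildNull(tab, sets, family = "normal", nPerm = nPerm, seed = 123)

    pooled <- withr::with_seed(123, {
        unlist(lapply(seq_len(nPerm), function(b) {
            perm <- sample.int(12)
            mem <- membership(sets)[perm, , drop = FALSE]
            rownames(mem) <- taxonIds(tab)   # reposition, not relabel
            scoreMatrix(tab, new("SetCollection", membership = mem))[, 1]
        }))
    })
    ref <- fitNormal(pooled)
    pars <- nullParameters(null)
    expect_equal(pars$mu, ref$mu, tolerance = 1e-12)
    expect_equal(pars$sigma, ref$sigma, tolerance = 1e-12)
})

test_that("correlation adjustment inflates the null spread only under correlation", {
    # independent taxa: adjusted and unadjusted sigmas agree within MC error
    cfgInd <- simConfig(nSamples = 400, nTaxa = 100, setSize = 30, nSets = 1,
                        rho = 0, enrichedSets = 1L)
    tabInd <- suppressMessages(closure(replaceZeros(
        simCounts(simulateCounts(cfgInd, seed = 21)))))
    setsInd <- simSets(simulateCounts(cfgInd, seed = 21))
    unadj <- buildNull(tabInd, setsInd, family = "normal", adjust = FALSE,
                       nPerm = 50, seed = 1)
    adj <- buildNull(tabInd, setsInd, family = "normal", adjust = TRUE,
                     nPerm = 50, seed = 1)
    ratio <- nullParameters(adj)$sigma / nullParameters(unadj)$sigma
    expect_lt(abs(ratio - 1), 0.15)

    # strong within-set correlation: adjusted sigma strictly larger
    cfgCor <- simConfig(nSamples = 400, nTaxa = 100, setSize = 30, nSets = 1,
                        rho = 0.5, enrichedSets = 1L)
    simCor <- simulateCounts(cfgCor, seed = 22)
    tabCor <- suppressMessages(closure(replaceZeros(simCounts(simCor))))
    unadjC <- buildNull(tabCor, simSets(simCor), family = "normal",
                        adjust = FALSE, nPerm = 50, seed = 1)
    adjC <- buildNull(tabCor, simSets(simCor), family = "normal",
                      adjust = TRUE, nPerm = 50, seed = 1)
    expect_gt(nullParameters(adjC)$sigma, nullParameters(unadjC)$sigma)
})

test_that("transforms respect the null: symmetry point, complement rule, monotonicity", {
    pars <- data.frame(set = "s", mu = 1.5, sigma = 0.7)
    null <- new("NullModel", family = "normal", adjusted = FALSE,
                nPerm = 1L, parameters = pars,
                diagnostics = data.frame(set = "s", converged = TRUE,
                                         loglik = 0, fallbackNormal = FALSE))
    raw <- matrix(c(1.5, 0.3, 2.8), 3, 1,
                  dimnames = list(paste0("s", 1:3), "s"))
    cdf <- scores(transformScores(raw, null, "cdf"))
    z <- scores(transformScores(raw, null, "zscore"))
    pv <- scores(transformScores(raw, null, "pval"))
    expect_equal(cdf[1, 1], 0.5)
    expect_equal(z[1, 1], 0)
    expect_equal(pv[1, 1], 0.5)
    expect_equal(pv + cdf, matrix(1, 3, 1, dimnames = dimnames(raw)))
    # strictly monotone in the raw score
    expect_true(all(diff(cdf[order(raw[, 1]), 1]) > 0))
    expect_error(transformScores(raw, NULL, "cdf"), "requires")

    # all output scales agree in how they rank samples within a set
    tab <- closure(randomTable(20, 15, seed = 8))
    sets <- indexSet(tab, 1:4)
    res <- lapply(c("raw", "cdf", "zscore", "pval"), function(ot)
        scores(cbea(tab, sets, outputType = ot, nPerm = 10, seed = 5))[, 1])
    expect_equal(order(res[[1]]), order(res[[2]]))
    expect_equal(order(res[[2]]), order(res[[3]]))
    expect_equal(order(res[[4]]), rev(order(res[[1]])))
})

test_that("draws from a fitted null push through its own CDF to uniformity", {
    tab <- closure(randomTable(100, 60, seed = 13))
    sets <- indexSet(tab, 1:15)
    null <- buildNull(tab, sets, family = "mixture2", nPerm = 20, seed = 3)
    par <- nullParameters(null)[1, ]
    u <- withr::with_seed(9, cbea:::.pmix2(rmix2(5000, par), par))
    expect_lt(ksDistance(u, identity), 0.03)
})

test_that("the end-to-end run is deterministic and raw output skips the null", {
    tab <- randomTable(10, 12, seed = 14)
    sets <- list(a = paste0("taxon", 1:3), b = paste0("taxon", c(5, 8, 11)))
    raw <- cbea(tab, sets, outputType = "raw")
    expect_null(nullModel(raw))
    direct <- scoreMatrix(closure(tab),
                          SetCollection(sets, taxonIds(tab)))
    expect_identical(scores(raw), direct)

    r1 <- cbea(tab, sets, outputType = "pval", nPerm = 15, seed = 42)
    r2 <- cbea(tab, sets, outputType = "pval", nPerm = 15, seed = 42)
    expect_identical(scores(r1), scores(r2))
})
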