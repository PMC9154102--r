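test_that("geometric mean matches closed forms and rejects bad input", {
    expect_equal(geometricMean(c(5, 5, 5)), 5)
    expect_equal(geometricMean(c(1, 4)), 2)
    # frozen arbitrary-precision value of sqrt(0.4 * 0.2)
    expect_equal(geometricMean(c(0.4, 0.2)), 0.282842712474619, tolerance = 1e-12)
    expect_error(geometricMean(c(1, 0)), "positive")
    expect_error(geometricMean(numeric(0)))
})

test_that("zero replacement adds the pseudocount to every entry only when needed", {
    clean <- CompositionTable(rbind(c(1, 2, 3)))
    expect_identical(abundances(replaceZeros(clean)), abundances(clean))
    withZero <- rbind(c(0, 2, 2))
    expect_message(out <- replaceZeros(withZero, 1e-5), "pseudocount")
    expect_equal(unname(out), rbind(c(1e-5, 2.00001, 2.00001)))
    allZero <- rbind(c(0, 0, 0))
    expect_equal(unname(suppressMessages(replaceZeros(allZero))),
                 rbind(rep(1e-5, 3)))
    expect_error(replaceZeros(rbind(c(-1, 2, 0))), "non-negative")
    expect_error(replaceZeros(rbind(c(0, 1, 2)), pseudocount = 0), "positive")
})

test_that("closure normalises rows to the simplex and is idempotent and scale-free", {
    expect_equal(unname(closure(rbind(c(1, 1, 2)))), rbind(c(0.25, 0.25, 0.5)))
    closed <- rbind(c(0.25, 0.25, 0.5))
    expect_equal(closure(closed), closed)
    expect_equal(closure(rbind(c(10, 10, 20))), closure(rbind(c(1, 1, 2))))
    tab <- randomTable(5, 4)
    expect_equal(unname(rowSums(abundances(closure(tab)))), rep(1, 5),
                 tolerance = 1e-9)
    expect_error(closure(rbind(c(0, 0, 0))), "sums to zero")
})

test_that("balance matches the frozen oracle and is antisymmetric", {
    row <- c(0.4, 0.2, 0.3, 0.1)
    # frozen: sqrt(2*2/(2+2)) * ln(sqrt(.4*.2)/sqrt(.3*.1)), mpmath 30 dps
    expect_equal(balance(row, 1:2, 3:4), 0.490414626505863, tolerance = 1e-12)
    expect_equal(balance(row, 3:4, 1:2), -balance(row, 1:2, 3:4))
    expect_equal(balance(rep(0.25, 4), c(1, 3), c(2, 4)), 0)
    expect_error(balance(row, 1:2, 2:3), "disjoint")
    expect_error(balance(row, integer(0), 1:2), "non-empty")
})

test_that("the set statistic equals the balance against the complement", {
    row <- c(0.4, 0.2, 0.3, 0.1)
    expect_equal(cbeaStatistic(row, 1:2), 0.490414626505863, tolerance = 1e-12)
    expect_identical(cbeaStatistic(row, 1:2), balance(row, 1:2, 3:4))
    p <- 7
    expect_equal(cbeaStatistic(rep(1 / p, p), c(2, 5)), 0)
    # symmetric subcompositions cancel: set and complement share (0.4, 0.1)
    expect_equal(cbeaStatistic(c(0.4, 0.1, 0.4, 0.1), c(1, 2)), 0)
    expect_error(cbeaStatistic(row, 1:4), "proper subset")
    expect_error(cbeaStatistic(row, integer(0)), "proper subset")
})

test_that("two algebraic forms of the statistic agree on random compositions", {
    # coefficient-times-log-ratio-of-geometric-means versus
    # coefficient-times-difference-of-mean-logs, 1000 random rows and sets
    withr::with_seed(42, {
        for (i in 1:1000) {
            p <- sample(3:40, 1)
            row <- stats::rgamma(p, 2) + 1e-4
            K <- sample(p - 1, 1)
            idx <- sample(p, K)
            viaGm <- sqrt(K * (p - K) / p) *
                log(geometricMean(row[idx]) / geometricMean(row[-idx]))
            viaLogs <- sqrt(K * (p - K) / p) *
                (mean(log(row[idx])) - mean(log(row[-idx])))
            expect_equal(cbeaStatistic(row, idx), viaGm, tolerance = 1e-10)
            expect_equal(viaGm, viaLogs, tolerance = 1e-10)
        }
    })
})

test_that("the statistic is scale-invariant and antisymmetric in set/complement", {
    withr::with_seed(7, {
        for (i in 1:50) {
            p <- sample(4:30, 1)
            row <- stats::rgamma(p, 2) + 1e-4
            idx <- sample(p, sample(p - 1, 1))
            cc <- stats::runif(1, 1e-3, 1e3)
            expect_equal(cbeaStatistic(cc * row, idx), cbeaStatistic(row, idx),
                         tolerance = 1e-10)
            expect_equal(cbeaStatistic(row, idx),
                         -cbeaStatistic(row, setdiff(seq_len(p), idx)),
                         tolerance = 1e-10)
        }
    })
})

test_that("scoreMatrix reproduces the per-row statistic and its symmetries", {
    tab <- closure(randomTable(6, 8, seed = 3))
    idx <- c(2, 5, 7)
    sets <- indexSet(tab, idx)
    sm <- scoreMatrix(tab, sets)
    expect_equal(dim(sm), c(6, 1))
    manual <- apply(abundances(tab), 1, cbeaStatistic, idx)
    expect_equal(unname(sm[, 1]), unname(manual), tolerance = 1e-12)

    # scaling one raw sample before closure leaves its scores unchanged
    raw <- abundances(randomTable(4, 8, seed = 9))
    scaled <- raw; scaled[2, ] <- scaled[2, ] * 1000
    s1 <- scoreMatrix(closure(CompositionTable(raw)), indexSet(tab, idx))
    s2 <- scoreMatrix(closure(CompositionTable(scaled)), indexSet(tab, idx))
    expect_equal(s1, s2, tolerance = 1e-10)

    # complementary sets give mirrored columns
    comp <- setdiff(1:8, idx)
    m2 <- cbind(as.numeric(1:8 %in% idx), as.numeric(1:8 %in% comp))
    dimnames(m2) <- list(taxonIds(tab), c("k", "kc"))
    both <- scoreMatrix(tab, new("SetCollection", membership = m2))
    expect_equal(both[, "k"], -both[, "kc"], tolerance = 1e-10)
})

test_that("scores are invariant to a consistent relabelling of taxa", {
    tab <- closure(randomTable(5, 10, seed = 4))
    idx <- c(1, 4, 6)
    sets <- indexSet(tab, idx)
    perm <- withr::with_seed(11, sample(10))
    vPerm <- abundances(tab)[, perm]
    mPerm <- membership(sets)[perm, , drop = FALSE]
    relabelled <- scoreMatrix(CompositionTable(vPerm),
                              new("SetCollection", membership = mPerm))
    expect_equal(unname(relabelled), unname(scoreMatrix(tab, sets)),
                 tolerance = 1e-12)
})

test_that("scoring a zeroed table after replacement is bit-identical across runs", {
    withr::with_seed(5, {
        raw <- matrix(stats::rpois(60, 3), 6, 10)
    })
    run <- function() {
        tab <- suppressMessages(closure(replaceZeros(CompositionTable(raw),
                                                     1e-5)))
        scoreMatrix(tab, indexSet(tab, 1:3))
    }
    expect_identical(run(), run())
})

test_that("scoreMatrix validates alignment and positivity", {
    tab <- closure(randomTable(3, 5))
    other <- new("SetCollection", membership = matrix(
        c(1, 0, 1, 0, 0), dimnames = list(paste0("x", 1:5), "s")))
    expect_error(scoreMatrix(tab, other), "disagree")
    withZero <- CompositionTable(rbind(c(0, 1, 2, 3, 4)))
    expect_error(scoreMatrix(withZero, indexSet(withZero, 1:2)), "positive")
})
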