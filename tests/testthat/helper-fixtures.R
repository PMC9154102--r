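# shared fixture builders; everything is generated in code, under fixed seeds

# strictly positive random composition table
randomTable <- function(n, p, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(stats::rgamma(n * p, shape = 2, rate = 1) + 1e-3, n, p)
        CompositionTable(m)
    })
}

# single-column SetCollection over the table's taxa from plain indices
indexSet <- function(table, idx, name = "set") {
    p <- length(taxonIds(table))
    m <- matrix(as.numeric(seq_len(p) %in% idx),
                dimnames = list(taxonIds(table), name))
    new("SetCollection", membership = m)
}

# draw from a fitted two-component mixture parameter row
rmix2 <- function(n, par) {
    pick <- stats::rbinom(n, 1, par$w2)
    ifelse(pick == 1, stats::rnorm(n, par$mu2, par$sigma2),
           stats::rnorm(n, par$mu1, par$sigma1))
}

# sup distance between a fitted null CDF and the empirical CDF of x
ksDistance <- function(x, cdfFun) {
    x <- sort(x)
    n <- length(x)
    Fx <- cdfFun(x)
    max(pmax(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n)))
}

# global-null NB table matching the calibration study conditions
globalNullTable <- function(n, p, seed, mu = 100, size = 1, zeroProb = 0) {
    cfg <- simConfig(nSamples = n, nTaxa = p, setSize = min(20L, p),
                     nSets = 1L, nbMean = mu, nbDispersion = size,
                     zeroProb = zeroProb)
    simCounts(simulateCounts(cfg, seed = seed))
}
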