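# Small in-code fixtures shared across test files.

tinyBetaMatrix <- function() {
    m <- matrix(c(0.1, 0.9, 0.5,
                  0.4, 0.0, 1.0), nrow = 3,
                dimnames = list(c("cgA", "cgB", "cgC"), c("s1", "s2")))
    BetaMatrix(m)
}

toyClockModel <- function() {
    ClockModel(intercept = 7,
               weights = c(cgA = 2, cgB = -1, cgC = 0.5),
               alpha = 0.5, lambda = 0.1, lambdaRule = "1se")
}

writeTempTSV <- function(lines) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

# toy manifest: two short "chromosomes" so distances are easy to reason about
toyManifest <- function() {
    lens <- c(chrA = 10000000L, chrB = 1000L)
    gr <- GenomicRanges::GRanges(
        seqnames = factor(c("chrA", "chrA", "chrB"),
                          levels = names(lens)),
        ranges = IRanges::IRanges(start = c(1L, 5000000L, 1000L),
                                  width = 1L))
    names(gr) <- c("cgStart", "cgMid", "cgEnd")
    GenomeInfoDb::seqlengths(gr) <- lens
    gr
}

# independent brute-force hypergeometric upper tail via choose()
enumHyperUpper <- function(k, n, K, N) {
    support <- max(0, n - (N - K)):min(K, n)
    probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
    sum(probs[support >= k])
}
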