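## Hypergeometric enrichment of clock CpGs near chromosome ends and
## against arbitrary CpG annotation sets (e.g. cis-mQTL lists).

#' Distance from each probe to the nearest chromosome end
#'
#' With 1-based fully-closed coordinates the distance is
#' \code{min(position, chromosome_length - position + 1)}, so both the
#' first and the last base of a chromosome are at distance 1.  A probe is
#' "sub-telomeric at D Mb" when its distance is at most \code{D * 1e6}.
#'
#' @param manifest a width-1 \link[GenomicRanges]{GRanges} named by probe
#'   id with \code{seqlengths} set.
#' @return named numeric vector of distances in bp.
#' @export
distanceToChromosomeEnd <- function(manifest) {
    stopifnot(is(manifest, "GRanges"))
    lens <- GenomeInfoDb::seqlengths(manifest)
    chrom <- as.character(GenomicRanges::seqnames(manifest))
    if (anyNA(lens[chrom]))
        stop("unknown chromosome length for: ",
             paste(unique(chrom[is.na(lens[chrom])]), collapse = ", "))
    pos <- GenomicRanges::start(manifest)
    setNames(pmin(pos, lens[chrom] - pos + 1), names(manifest))
}

#' Sub-telomeric enrichment of a clock's CpGs
#'
#' Hypergeometric upper-tail test of whether the clock's CpGs fall within
#' \code{window_mb} megabases of a chromosome end more often than expected
#' from the background manifest: population N = background size, successes
#' K = background probes within the window, draws n = clock size, overlap
#' k = clock probes within the window.
#'
#' @param clockProbes character vector of clock probe ids; must all be
#'   present in the manifest.
#' @param manifest background \link[GenomicRanges]{GRanges} (named,
#'   seqlengths set).
#' @param window_mb sub-telomeric window(s) in Mb; several values give a
#'   sensitivity analysis, one row each.
#' @return a \code{data.frame} with columns \code{window_mb}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{p_upper}.
#' @export
subtelomericEnrichment <- function(clockProbes, manifest, window_mb = 3) {
    absent <- setdiff(clockProbes, names(manifest))
    if (length(absent))
        stop("clock probe(s) absent from manifest: ",
             paste(absent, collapse = ", "))
    d <- distanceToChromosomeEnd(manifest)
    res <- lapply(window_mb, function(w) {
        inWin <- d <= w * 1e6
        k <- sum(inWin[clockProbes])
        out <- setOverlapTest(k = k, n = length(clockProbes),
                              K = sum(inWin), N = length(manifest))
        out$window_mb <- w
        out
    })
    do.call(rbind, res)
}

#' Exact hypergeometric set-overlap test
#'
#' Upper-tail probability \eqn{P(X \ge k)} of drawing at least \code{k}
#' annotated items when \code{n} items are drawn without replacement from
#' a population of \code{N} of which \code{K} are annotated.  The tail is
#' accumulated in log space (log probabilities combined by
#' log-sum-exp) so that extreme enrichment p-values remain accurate.
#'
#' @param k observed overlap.
#' @param n draws (e.g. clock size).
#' @param K annotated items in the population (e.g. cis-mQTL CpGs).
#' @param N population size (e.g. all CpGs shared by both array
#'   platforms).
#' @return a one-row \code{data.frame}: \code{N}, \code{K}, \code{n},
#'   \code{k}, \code{p_upper}.
#' @examples
#' setOverlapTest(k = 4, n = 4, K = 5, N = 10)   # 5/210
#' @export
setOverlapTest <- function(k, n, K, N) {
    for (v in list(k = k, n = n, K = K, N = N))
        stopifnot(length(v) == 1L, is.finite(v), v == round(v))
    if (N < 0 || K < 0 || n < 0 || k < 0 || K > N || n > N ||
        k > min(K, n))
        stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
    lo <- max(0L, n - (N - K))
    hi <- min(K, n)
    p_upper <- if (k <= lo) 1 else {
        lp <- stats::dhyper(seq(k, hi), m = K, n = N - K, k = n,
                            log = TRUE)
        mx <- max(lp)
        exp(mx + log(sum(exp(lp - mx))))
    }
    data.frame(N = N, K = K, n = n, k = k,
               p_upper = min(1, p_upper))
}
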