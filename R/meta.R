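## Cross-cohort combination rules: inverse-variance fixed effects with
## Cochran Q heterogeneity, and Stouffer's sqrt(n)-weighted z method.

.metaResult <- function(method, estimate = NA_real_, se = NA_real_,
                        z, p, k, n_total = NA_real_, Q = NA_real_,
                        het_df = NA_real_, het_p = NA_real_) {
    data.frame(method = method, estimate = estimate, se = se, z = z,
               p = p, k = k, n_total = n_total, Q = Q, het_df = het_df,
               het_p = het_p, stringsAsFactors = FALSE)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-study estimates with weights \eqn{w_i = 1/se_i^2}:
#' pooled \eqn{= \sum w_i b_i / \sum w_i}, SE \eqn{= 1/\sqrt{\sum w_i}},
#' \eqn{z =} pooled/SE, and Cochran heterogeneity
#' \eqn{Q = \sum w_i (b_i - pooled)^2} referred to a chi-square with
#' \eqn{k - 1} degrees of freedom (the "Het. P").
#'
#' @param estimates per-study estimates (same scale across studies).
#' @param ses per-study standard errors, all positive.
#' @param n optional per-study sample sizes (reported as their sum).
#' @return a one-row \code{data.frame}: method, pooled estimate, SE, z,
#'   two-sided p, k, total n, Q, het_df, het_p.
#' @export
fixedEffectMeta <- function(estimates, ses, n = NULL) {
    k <- length(estimates)
    if (k < 1) stop("need at least one study")
    if (length(ses) != k) stop("estimates and ses must have equal length")
    if (any(ses <= 0)) stop("all standard errors must be positive")
    w <- 1 / ses^2
    pooled <- sum(w * estimates) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- pooled / se
    Q <- sum(w * (estimates - pooled)^2)
    het_df <- k - 1
    het_p <- if (het_df == 0) 1 else
        pchisq(Q, df = het_df, lower.tail = FALSE)
    .metaResult("fixed_effect", estimate = pooled, se = se, z = z,
                p = 2 * pnorm(-abs(z)), k = k,
                n_total = if (is.null(n)) NA_real_ else sum(n),
                Q = Q, het_df = het_df, het_p = het_p)
}

#' Stouffer's sqrt(n)-weighted z combination
#'
#' Combines per-study z scores as
#' \eqn{Z = \sum_i \sqrt{n_i} z_i / \sqrt{\sum_i n_i}} with two-sided
#' \eqn{p = 2\Phi(-|Z|)}.  Per-cohort t statistics are consumed directly
#' as z scores by default (the convention under which the combined smoking
#' statistics reproduce published values exactly); set
#' \code{tToZ = TRUE} with per-study degrees of freedom to convert each t
#' to an exact normal quantile first.
#'
#' @param z per-study z (or t) statistics.
#' @param n per-study sample sizes, all positive.
#' @param tToZ convert t statistics to z via their tail probabilities.
#' @param df per-study degrees of freedom, required when \code{tToZ}.
#' @return a one-row \code{data.frame}: method, combined Z, two-sided p,
#'   k, total n.
#' @export
stoufferMeta <- function(z, n, tToZ = FALSE, df = NULL) {
    k <- length(z)
    if (k < 1) stop("need at least one study")
    if (length(n) != k) stop("z and n must have equal length")
    if (any(n <= 0)) stop("all sample sizes must be positive")
    if (tToZ) {
        if (is.null(df) || length(df) != k)
            stop("tToZ requires per-study df")
        z <- sign(z) * stats::qnorm(pt(-abs(z), df), lower.tail = FALSE)
    }
    Z <- sum(sqrt(n) * z) / sqrt(sum(n))
    .metaResult("stouffer_sqrt_n", z = Z, p = 2 * pnorm(-abs(Z)), k = k,
                n_total = sum(n))
}
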