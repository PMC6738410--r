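## Per-cohort association statistics: biweight midcorrelation, ordinary
## and cluster-robust linear models, the smoking harness, and Cox
## proportional hazards with Huber sandwich standard errors.

.assocStat <- function(estimate, se, statistic, p, n, df = NA_real_,
                       n_events = NA_integer_, model = "", exposure = "") {
    data.frame(exposure = exposure, estimate = estimate, se = se,
               statistic = statistic, p = p, n = n, df = df,
               n_events = n_events, model = model,
               stringsAsFactors = FALSE)
}

#' Biweight midcorrelation
#'
#' Robust correlation built from median/MAD-based Tukey biweights:
#' \eqn{u_i = (x_i - med(x)) / (9\,MAD(x))} with the unscaled median
#' absolute deviation, weight \eqn{a_i = (1-u_i^2)^2 I(|u_i|<1)}, and
#' \deqn{bicor(x,y)=\frac{\sum_i a_i b_i (x_i-med\,x)(y_i-med\,y)}
#'  {\sqrt{\sum_i [a_i(x_i-med\,x)]^2}\sqrt{\sum_i [b_i(y_i-med\,y)]^2}}.}
#' A variable with zero MAD falls back to Pearson-style terms (mean
#' centring, unit weights) for that variable.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return the correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("bicor needs at least 3 observations")
    if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
    term <- function(v) {
        med <- median(v)
        madv <- median(abs(v - med))
        if (madv == 0) {                 # Pearson fallback for this variable
            if (sd(v) == 0) return(NULL)
            return(v - mean(v))
        }
        u <- (v - med) / (9 * madv)
        w <- (1 - u^2)^2 * (abs(u) < 1)
        (v - med) * w
    }
    a <- term(x)
    b <- term(y)
    if (is.null(a) || is.null(b))
        stop("undefined correlation: a variable has zero variance")
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0)
        stop("undefined correlation: zero weighted variance")
    sum(a * b) / den
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of \code{outcome} on \code{exposure} plus
#' covariates, with Wald t tests on the exposure coefficient.  When
#' \code{cluster} is given, cluster-robust (sandwich) standard errors are
#' used, the implementable common denominator for pedigree or
#' repeated-measure correlation.
#'
#' @param data a \code{data.frame}.
#' @param outcome,exposure column names.
#' @param covariates character vector of covariate column names.
#' @param cluster optional column name of cluster ids.
#' @return a one-row association \code{data.frame}: exposure label,
#'   estimate (outcome units per unit exposure), SE, t statistic,
#'   two-sided p, n, residual df, model label.
#' @export
linearAssoc <- function(data, outcome, exposure, covariates = character(),
                        cluster = NULL) {
    cols <- c(outcome, exposure, covariates, cluster)
    miss <- setdiff(cols, names(data))
    if (length(miss))
        stop("column(s) not found: ", paste(miss, collapse = ", "))
    d <- data[stats::complete.cases(data[, c(outcome, exposure,
                                             covariates)]), , drop = FALSE]
    rhs <- paste(c(exposure, covariates), collapse = " + ")
    fit <- lm(stats::as.formula(paste(outcome, "~", rhs)), data = d)
    cf <- coef(fit)
    if (anyNA(cf)) {
        aliased <- names(cf)[is.na(cf)]
        stop("aliased (collinear) term(s) dropped from the design: ",
             paste(aliased, collapse = ", "))
    }
    expTerm <- .termFor(fit, exposure)
    vc <- if (is.null(cluster)) stats::vcov(fit) else
        sandwich::vcovCL(fit, cluster = d[[cluster]])
    est <- cf[[expTerm]]
    se <- sqrt(vc[expTerm, expTerm])
    tstat <- est / se
    df <- fit$df.residual
    .assocStat(estimate = est, se = se, statistic = tstat,
               p = 2 * pt(-abs(tstat), df), n = nrow(d), df = df,
               model = if (is.null(cluster)) "ols" else "ols_cluster",
               exposure = expTerm)
}

## first design-matrix term generated by a model column (handles factors)
.termFor <- function(fit, column) {
    cn <- names(coef(fit))
    hit <- cn[cn == column | startsWith(cn, column)]
    if (!length(hit))
        stop("exposure '", column, "' not found among model terms")
    hit[1L]
}

#' Smoking association harness
#'
#' Relates a telomere-length measure to smoking within one cohort:
#' pack-years when available (continuous), otherwise ever- versus
#' never-smoker, adjusting for age and, when present with variation, sex
#' and ethnicity.  The returned t statistic is the per-cohort input to the
#' Stouffer combination across cohorts.
#'
#' @param samples sample table (data.frame) with smoking columns
#'   \code{pack_years} and/or \code{ever_smoker}, plus \code{age} and
#'   optionally \code{sex}, \code{ethnicity}.
#' @param tl numeric telomere-length measure, one value per row of
#'   \code{samples}.
#' @param variablePolicy \code{"auto"} prefers pack-years;
#'   \code{"pack_years"} or \code{"ever_smoker"} force the choice.
#' @param cluster optional cluster-id column name.
#' @return a one-row association \code{data.frame}; the exposure label is
#'   \code{"Pack years"} or \code{"Smoker"}.
#' @export
smokingAssoc <- function(samples, tl,
                         variablePolicy = c("auto", "pack_years",
                                            "ever_smoker"),
                         cluster = NULL) {
    variablePolicy <- match.arg(variablePolicy)
    stopifnot(nrow(samples) == length(tl))
    hasPY <- "pack_years" %in% names(samples) &&
        any(!is.na(samples$pack_years))
    hasES <- "ever_smoker" %in% names(samples) &&
        any(!is.na(samples$ever_smoker))
    use <- switch(variablePolicy,
        auto = if (hasPY) "pack_years" else if (hasES) "ever_smoker" else
            stop("no smoking data available"),
        pack_years = if (hasPY) "pack_years" else
            stop("pack_years not available"),
        ever_smoker = if (hasES) "ever_smoker" else
            stop("ever_smoker not available"))
    d <- samples
    d$.tl <- tl
    if (use == "ever_smoker") d$ever_smoker <- as.numeric(d$ever_smoker)
    if (var(d[[use]], na.rm = TRUE) == 0)
        stop("no variance in smoking exposure '", use, "'")
    covs <- "age"
    for (cc in c("sex", "ethnicity")) {
        if (cc %in% names(d) && length(unique(d[[cc]])) > 1)
            covs <- c(covs, cc)
    }
    out <- linearAssoc(d, outcome = ".tl", exposure = use,
                       covariates = covs, cluster = cluster)
    out$exposure <- if (use == "pack_years") "Pack years" else "Smoker"
    out
}

#' Cox proportional-hazards association
#'
#' Maximises the Cox partial likelihood (Efron tie handling) for the
#' exposure plus covariates and reports the log hazard ratio per unit
#' exposure with its hazard ratio.  With \code{cluster} (or
#' \code{robust = TRUE}) standard errors are the Huber sandwich estimator,
#' grouped on the cluster id when supplied.
#'
#' @param data a \code{data.frame}.
#' @param time,event column names: follow-up time (years) and event
#'   indicator (0/1).
#' @param exposure,covariates column names.
#' @param cluster optional cluster-id column name.
#' @param robust force sandwich SEs without clustering.
#' @return a one-row association \code{data.frame} with an extra
#'   \code{hr} column (\code{exp(estimate)} per unit exposure).
#' @export
coxAssoc <- function(data, time, event, exposure,
                     covariates = character(), cluster = NULL,
                     robust = !is.null(cluster)) {
    cols <- c(time, event, exposure, covariates, cluster)
    miss <- setdiff(cols, names(data))
    if (length(miss))
        stop("column(s) not found: ", paste(miss, collapse = ", "))
    d <- data[stats::complete.cases(data[, cols, drop = FALSE]), ,
              drop = FALSE]
    nEvents <- sum(d[[event]] > 0)
    if (nEvents < 1) stop("no events: partial likelihood undefined")
    if (var(d[[exposure]]) == 0)
        stop("constant exposure: no partial-likelihood information")
    rhs <- paste(c(exposure, covariates), collapse = " + ")
    fml <- stats::as.formula(
        paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs))
    fit <- if (is.null(cluster))
        survival::coxph(fml, data = d, ties = "efron", robust = robust)
    else
        survival::coxph(fml, data = d, ties = "efron", robust = TRUE,
                        cluster = d[[cluster]])
    if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
        stop("Cox model failed to converge: ", fit$info$message)
    expTerm <- .termFor(fit, exposure)
    sm <- summary(fit)$coefficients
    seCol <- if ("robust se" %in% colnames(sm)) "robust se" else "se(coef)"
    est <- sm[expTerm, "coef"]
    se <- sm[expTerm, seCol]
    z <- est / se
    out <- .assocStat(estimate = est, se = se, statistic = z,
                      p = 2 * pnorm(-abs(z)), n = nrow(d),
                      n_events = nEvents,
                      model = if (robust || !is.null(cluster))
                          "cox_sandwich" else "cox",
                      exposure = expTerm)
    out$hr <- exp(est)
    out
}
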