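## Elastic-net clock training, application of coefficient tables to beta
## matrices, and age adjustment of the resulting estimates.

.asBetaValues <- function(betas) {
    if (is(betas, "BetaMatrix")) betaValues(betas)
    else as.matrix(betas)
}

#' Train a linear CpG clock by penalised regression
#'
#' Fits the elastic net
#' \deqn{\min_{\beta_0,\beta} \frac{1}{2n}\sum_i (y_i-\beta_0-x_i'\beta)^2
#'   + \lambda\left[\alpha\|\beta\|_1 +
#'   \frac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' on column-standardised predictors (population 1/n variance) over a
#' 100-point log-spaced lambda grid from \eqn{\lambda_{max}} down to
#' \eqn{\lambda_{max} r}, with \eqn{r = 0.01} when the number of probes is
#' at least the number of samples and \eqn{10^{-4}} otherwise.
#' Cross-validated error is the mean squared error averaged over folds; its
#' standard error is the SD of per-fold errors divided by the square root
#' of the number of folds.  Rule \code{"1se"} selects the largest lambda
#' whose CV error is within one standard error of the minimum (the rule
#' used to build kilobase-scale telomere clocks); \code{"min"} selects the
#' CV minimiser; \code{"fixed"} uses the supplied \code{lambda}.
#' Coefficients are refit on all data at the chosen lambda and reported on
#' the original beta scale.
#'
#' @param betas a \linkS4class{BetaMatrix} or probes-by-samples matrix;
#'   missing values are an error (impute upstream).
#' @param target numeric, one value (kb) per sample.
#' @param alpha elastic-net mixing parameter; 0.5 is the convention for
#'   this family of clocks.
#' @param nFolds number of CV folds (>= 2).
#' @param rule \code{"1se"}, \code{"min"} or \code{"fixed"}.
#' @param lambda penalty for rule \code{"fixed"}.
#' @param seed integer; fold assignment is a seeded random permutation into
#'   nearly equal blocks and is recorded in the returned path.
#' @return a list with \code{model} (\linkS4class{ClockModel}, with
#'   training probe means stored for later imputation) and \code{cv}
#'   (\linkS4class{CVPath}, or NULL for rule \code{"fixed"} or a constant
#'   target).
#' @export
trainClock <- function(betas, target, alpha = 0.5, nFolds = 10,
                       rule = c("1se", "min", "fixed"), lambda = NULL,
                       seed = 1L) {
    rule <- match.arg(rule)
    b <- .asBetaValues(betas)
    if (anyNA(b))
        stop("missing beta values among training probes; impute upstream")
    x <- t(b)                      # samples x probes for the solver
    y <- as.numeric(target)
    n <- nrow(x)
    if (length(y) != n) stop("target length must equal number of samples")
    if (!all(is.finite(y))) stop("target must be finite")
    if (rule != "fixed" && (nFolds < 2 || n < nFolds))
        stop("need n_samples >= nFolds >= 2")

    probeMeans <- setNames(colMeans(x), colnames(x))
    if (var(y) == 0) {
        warning("constant target: returning intercept-only model")
        model <- ClockModel(intercept = mean(y),
                            weights = setNames(numeric(ncol(x)),
                                               colnames(x)),
                            alpha = alpha, lambda = NA_real_,
                            lambdaRule = rule,
                            trainingMeans = probeMeans)
        return(list(model = model, cv = NULL))
    }

    fit <- glmnet::glmnet(x, y, alpha = alpha, nlambda = 100,
                          standardize = TRUE)
    cvpath <- NULL
    if (rule == "fixed") {
        if (is.null(lambda)) stop("rule 'fixed' requires a lambda")
        chosen <- lambda
        # refit a dedicated path ending exactly at the requested lambda,
        # at tight convergence, so off-grid penalties are solved rather
        # than interpolated
        top <- fit$lambda[1L]
        lamSeq <- if (chosen >= top) c(chosen * 1.5, chosen) else
            exp(seq(log(top), log(chosen), length.out = 100L))
        fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = lamSeq,
                              standardize = TRUE, thresh = 1e-12)
    } else {
        foldid <- withr::with_seed(seed,
            sample(rep(seq_len(nFolds), length.out = n)))
        cvfit <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                                   type.measure = "mse",
                                   lambda = fit$lambda)
        chosen <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
        cvpath <- new("CVPath", lambda = cvfit$lambda, cvm = cvfit$cvm,
                      cvsd = cvfit$cvsd, foldid = as.integer(foldid),
                      lambdaMin = cvfit$lambda.min,
                      lambda1se = cvfit$lambda.1se)
    }
    co <- as.matrix(coef(fit, s = chosen))[, 1L]
    w <- co[-1L]
    # coefficients below solver precision are numerically zero (kb scale)
    w[abs(w) < 1e-9 * sd(y)] <- 0
    model <- ClockModel(intercept = unname(co[1L]),
                        weights = w[w != 0],
                        alpha = alpha, lambda = chosen, lambdaRule = rule,
                        trainingMeans = probeMeans)
    list(model = model, cv = cvpath)
}

#' Apply a clock coefficient table to a beta matrix
#'
#' Computes, per sample, \code{intercept + sum_j weight_j * beta_js} in
#' kilobases.  Probes that are absent from the matrix, or missing for a
#' sample, are an error under the default policy; under
#' \code{"mean_impute"} they are replaced with the training-set means
#' stored in the model (an error if the model carries none).  Rescaling
#' over the probes that happen to be present is deliberately not offered:
#' it silently changes the estimator.
#'
#' @param model a \linkS4class{ClockModel}.
#' @param betas a \linkS4class{BetaMatrix} or probes-by-samples matrix.
#' @param missingPolicy \code{"error"} or \code{"mean_impute"}.
#' @return a \code{data.frame} (one row per sample): \code{sample_id},
#'   \code{dnamtl} (kb), \code{n_probes_used}, \code{n_probes_imputed}.
#' @examples
#' m <- ClockModel(7, c(cgA = 2, cgB = -1, cgC = 0.5))
#' b <- BetaMatrix(matrix(c(0.5, 0.2, 0.8), 3,
#'                 dimnames = list(c("cgA", "cgB", "cgC"), "s1")))
#' applyClock(m, b)   # 7 + 1.0 - 0.2 + 0.4 = 8.2 kb
#' @export
applyClock <- function(model, betas,
                       missingPolicy = c("error", "mean_impute")) {
    missingPolicy <- match.arg(missingPolicy)
    stopifnot(is(model, "ClockModel"))
    b <- .asBetaValues(betas)
    if (is.null(colnames(b)))
        colnames(b) <- paste0("s", seq_len(ncol(b)))
    need <- names(model@weights)
    absent <- setdiff(need, rownames(b))
    sub <- matrix(NA_real_, nrow = length(need), ncol = ncol(b),
                  dimnames = list(need, colnames(b)))
    present <- intersect(need, rownames(b))
    sub[present, ] <- b[present, , drop = FALSE]
    nMissing <- colSums(is.na(sub))
    if (missingPolicy == "error") {
        if (length(absent))
            stop("probes required by the clock are absent: ",
                 paste(absent, collapse = ", "))
        if (any(nMissing > 0)) {
            bad <- which(is.na(sub), arr.ind = TRUE)[1L, ]
            stop("missing beta value at probe '", need[bad[1L]],
                 "', sample '", colnames(sub)[bad[2L]],
                 "'; use missingPolicy = 'mean_impute' or impute upstream")
        }
    } else {
        tm <- model@trainingMeans
        noMean <- need[is.na(match(need, names(tm))) &
                       rowSums(is.na(sub)) > 0]
        if (length(noMean))
            stop("no training mean stored for probe(s): ",
                 paste(noMean, collapse = ", "))
        for (pr in need) {
            miss <- is.na(sub[pr, ])
            if (any(miss)) sub[pr, miss] <- tm[[pr]]
        }
    }
    tl <- model@intercept + drop(crossprod(sub, model@weights))
    data.frame(sample_id = colnames(b),
               dnamtl = unname(tl),
               n_probes_used = length(need),
               n_probes_imputed = unname(nMissing),
               stringsAsFactors = FALSE)
}

#' Age-adjust telomere-length estimates
#'
#' Regresses the estimate on chronological age by ordinary least squares
#' (within each group when a grouping is given, e.g. per cohort) and
#' returns the raw residuals.  A negative residual marks a sample whose
#' estimate is shorter than expected based on age; a positive one the
#' opposite.  Residuals have zero mean and are orthogonal to age within
#' each group.
#'
#' @param tl numeric estimates in kb (names preserved).
#' @param age numeric ages in years, same length.
#' @param group optional grouping factor (e.g. cohort id); adjustment is
#'   performed within each level.
#' @return numeric residuals, kb, in input order.
#' @export
adjustForAge <- function(tl, age, group = NULL) {
    stopifnot(length(tl) == length(age))
    if (is.null(group)) group <- rep.int(1L, length(tl))
    res <- numeric(length(tl))
    for (g in unique(group)) {
        idx <- which(group == g)
        if (length(idx) < 3)
            stop("age adjustment needs >= 3 samples per group (group '",
                 g, "')")
        if (var(age[idx]) == 0)
            stop("zero age variance in group '", g,
                 "': residualisation undefined")
        res[idx] <- residuals(lm(tl[idx] ~ age[idx]))
    }
    names(res) <- names(tl)
    res
}
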