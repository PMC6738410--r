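#' @import methods
#' @importFrom stats coef cor lm median pchisq pnorm pt quantile residuals
#'   rnorm runif sd setNames var
NULL

#' BetaMatrix: CpG methylation fractions for a set of samples
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding a single
#' assay named \code{"beta"}: a probes-by-samples matrix of methylation
#' fractions in \[0, 1\] (Illumina orientation).  Missing values are stored
#' as \code{NA} and never imputed at construction time; downstream
#' operations declare their own missing-data policy.
#'
#' @slot ... inherits all slots from \code{SummarizedExperiment}.
#' @export
setClass("BetaMatrix", contains = "SummarizedExperiment")

.validBetaMatrix <- function(object) {
    msg <- character()
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (!is.numeric(b))
            msg <- c(msg, "beta values must be numeric")
        bad <- which(!is.na(b) & (b < 0 | b > 1))
        if (length(bad)) {
            ij <- arrayInd(bad[1L], dim(b))
            msg <- c(msg, sprintf(
                "beta value %.4g outside [0, 1] at probe '%s', sample '%s'",
                b[bad[1L]], rownames(b)[ij[1L]], colnames(b)[ij[2L]]))
        }
        if (anyDuplicated(rownames(b)))
            msg <- c(msg, "duplicate probe ids")
        if (anyDuplicated(colnames(b)))
            msg <- c(msg, "duplicate sample ids")
        if (is.null(rownames(b)) || is.null(colnames(b)))
            msg <- c(msg, "probe and sample ids are required")
    }
    if (length(msg)) msg else TRUE
}

setValidity("BetaMatrix", .validBetaMatrix)

#' Construct a BetaMatrix
#'
#' @param values numeric matrix of methylation fractions, probes in rows and
#'   samples in columns; dimnames supply the ids unless given explicitly.
#' @param probeIds,sampleIds optional character vectors overriding the
#'   dimnames of \code{values}.
#' @param sampleData optional \code{data.frame} of per-sample covariates,
#'   stored as \code{colData}.
#' @return a validated \linkS4class{BetaMatrix}.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2,
#'             dimnames = list(c("cgA", "cgB"), c("s1", "s2")))
#' BetaMatrix(m)
#' @export
BetaMatrix <- function(values, probeIds = NULL, sampleIds = NULL,
                       sampleData = NULL) {
    values <- as.matrix(values)
    if (!is.null(probeIds)) rownames(values) <- probeIds
    if (!is.null(sampleIds)) colnames(values) <- sampleIds
    args <- list(assays = list(beta = values))
    if (!is.null(sampleData))
        args$colData <- S4Vectors::DataFrame(sampleData,
                                             row.names = colnames(values))
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("BetaMatrix", se)
}

#' ClockModel: a linear CpG clock in kilobase units
#'
#' Stores the intercept (kb) and sparse CpG weights (kb per unit beta) of a
#' linear telomere-length clock, together with the elastic-net training
#' metadata (mixing parameter alpha, penalty lambda and the rule used to
#' select it) and, optionally, the training-set probe means needed for
#' mean-imputation at application time.
#'
#' @slot intercept numeric(1), kilobases.
#' @slot weights named numeric, kilobases per unit beta value.
#' @slot alpha numeric(1), elastic-net mixing parameter in \[0, 1\].
#' @slot lambda numeric(1), penalty at which the model was fit.
#' @slot lambdaRule character(1), one of \code{"1se"}, \code{"min"},
#'   \code{"fixed"}.
#' @slot nNonzero integer(1), number of weights with nonzero value.
#' @slot trainingMeans named numeric, per-probe training means (may be
#'   empty).
#' @export
setClass("ClockModel",
    representation(intercept = "numeric", weights = "numeric",
                   alpha = "numeric", lambda = "numeric",
                   lambdaRule = "character", nNonzero = "integer",
                   trainingMeans = "numeric"))

.validClockModel <- function(object) {
    msg <- character()
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        msg <- c(msg, "intercept must be a single finite number")
    w <- object@weights
    if (length(w) && (is.null(names(w)) || any(!nzchar(names(w)))))
        msg <- c(msg, "weights must be named by probe id")
    if (anyDuplicated(names(w)))
        msg <- c(msg, "duplicate probe ids among weights")
    if (object@nNonzero != sum(w != 0))
        msg <- c(msg, "nNonzero must equal the number of nonzero weights")
    if (length(object@alpha) == 1L && !is.na(object@alpha) &&
        (object@alpha < 0 || object@alpha > 1))
        msg <- c(msg, "alpha must lie in [0, 1]")
    if (!object@lambdaRule %in% c("1se", "min", "fixed"))
        msg <- c(msg, "lambdaRule must be one of '1se', 'min', 'fixed'")
    if (length(msg)) msg else TRUE
}

setValidity("ClockModel", .validClockModel)

#' Construct a ClockModel
#'
#' @param intercept intercept in kilobases.
#' @param weights named numeric vector of CpG weights (kb per unit beta).
#' @param alpha elastic-net mixing parameter used in training (NA if
#'   unknown, e.g. for a model loaded from file without metadata).
#' @param lambda penalty at which the model was fit (NA if unknown).
#' @param lambdaRule how lambda was chosen: \code{"1se"}, \code{"min"} or
#'   \code{"fixed"}.
#' @param trainingMeans optional named numeric vector of training-set probe
#'   means, used by the \code{"mean_impute"} application policy.
#' @return a validated \linkS4class{ClockModel}.
#' @examples
#' ClockModel(7, c(cgA = 2, cgB = -1))
#' @export
ClockModel <- function(intercept, weights = numeric(0), alpha = NA_real_,
                       lambda = NA_real_, lambdaRule = "fixed",
                       trainingMeans = numeric(0)) {
    new("ClockModel", intercept = as.numeric(intercept),
        weights = weights, alpha = as.numeric(alpha),
        lambda = as.numeric(lambda), lambdaRule = lambdaRule,
        nNonzero = sum(weights != 0), trainingMeans = trainingMeans)
}

#' CVPath: the cross-validation path of an elastic-net fit
#'
#' @slot lambda numeric, the descending penalty grid.
#' @slot cvm numeric, mean cross-validated squared error (kb^2) per lambda.
#' @slot cvsd numeric, standard error of the CV error per lambda.
#' @slot foldid integer, the fold assignment used.
#' @slot lambdaMin numeric(1), penalty minimising the CV error.
#' @slot lambda1se numeric(1), largest penalty with CV error within one
#'   standard error of the minimum.
#' @export
setClass("CVPath",
    representation(lambda = "numeric", cvm = "numeric", cvsd = "numeric",
                   foldid = "integer", lambdaMin = "numeric",
                   lambda1se = "numeric"))

setValidity("CVPath", function(object) {
    msg <- character()
    if (is.unsorted(rev(object@lambda)))
        msg <- c(msg, "lambda grid must be descending")
    if (any(object@cvm < 0) || any(object@cvsd < 0))
        msg <- c(msg, "CV error and its SE must be nonnegative")
    if (length(object@lambda) != length(object@cvm) ||
        length(object@lambda) != length(object@cvsd))
        msg <- c(msg, "lambda, cvm and cvsd must have equal length")
    if (object@lambda1se < object@lambdaMin)
        msg <- c(msg, "lambda1se must be >= lambdaMin")
    if (length(msg)) msg else TRUE
})

#' @describeIn ClockModel accessor for the intercept (kb).
#' @param object,x a \code{ClockModel}.
#' @export
clockIntercept <- function(object) object@intercept

#' @describeIn ClockModel accessor for the named weight vector.
#' @export
clockWeights <- function(object) object@weights

#' @describeIn ClockModel number of nonzero weights.
#' @export
nNonzero <- function(object) object@nNonzero

#' Accessors for BetaMatrix
#'
#' @param x a \linkS4class{BetaMatrix}.
#' @return \code{betaValues} returns the probes-by-samples numeric matrix;
#'   \code{probeIds} and \code{sampleIds} its dimnames;
#'   \code{missingMask} a logical matrix marking missing cells.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @rdname betaValues
#' @export
probeIds <- function(x) rownames(x)

#' @rdname betaValues
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname betaValues
#' @export
missingMask <- function(x) is.na(betaValues(x))

setMethod("show", "ClockModel", function(object) {
    cat("ClockModel:", length(object@weights), "CpG weights (",
        object@nNonzero, "nonzero ),",
        sum(object@weights < 0), "negative /",
        sum(object@weights > 0), "positive\n")
    cat("  intercept:", format(object@intercept, digits = 4), "kb\n")
    cat("  alpha:", object@alpha, " lambda:",
        format(object@lambda, digits = 4),
        " rule:", object@lambdaRule, "\n")
    if (length(object@trainingMeans))
        cat("  training means stored for", length(object@trainingMeans),
            "probes\n")
})

setMethod("show", "CVPath", function(object) {
    cat("CVPath over", length(object@lambda), "lambda values\n")
    cat("  lambda.min:", format(object@lambdaMin, digits = 4),
        " lambda.1se:", format(object@lambda1se, digits = 4), "\n")
    cat("  folds:", length(unique(object@foldid)), "\n")
})
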