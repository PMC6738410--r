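# Training uses a 50 x 5 full-rank problem where the unpenalised solution
# is known in closed form, plus seeded synthetic cohorts for recovery.

fullRankProblem <- function(seed = 21) {
    withr::with_seed(seed, {
        x <- matrix(runif(50 * 5, 0.1, 0.9), nrow = 50,
                    dimnames = list(NULL, paste0("cg", 1:5)))
        beta <- c(1.5, -2, 0.7, 0, 3)
        y <- 6 + drop(x %*% beta) + rnorm(50, 0, 0.05)
        list(betas = t(x), y = y)
    })
}

test_that("a constant target yields an intercept-only model", {
    pr <- fullRankProblem()
    expect_warning(
        res <- trainClock(pr$betas, rep(7, 50), seed = 1),
        "constant target")
    expect_equal(clockIntercept(res$model), 7)
    expect_equal(nNonzero(res$model), 0L)
    tl <- applyClock(res$model, pr$betas)
    expect_equal(tl$dnamtl, rep(7, 50))
})

test_that("negligible penalty reproduces the normal-equations solution", {
    pr <- fullRankProblem()
    ols <- lm(pr$y ~ t(pr$betas))
    fit <- glmnet::glmnet(t(pr$betas), pr$y, alpha = 0.5)
    res <- trainClock(pr$betas, pr$y, alpha = 0.5, rule = "fixed",
                      lambda = fit$lambda[1] * 1e-7, seed = 1)
    w <- clockWeights(res$model)
    expect_equal(unname(w[paste0("cg", 1:5)]),
                 unname(coef(ols)[-1]), tolerance = 1e-4)
    expect_equal(clockIntercept(res$model), unname(coef(ols)[1]),
                 tolerance = 1e-4)
})

test_that("at lambda >= lambda_max every weight is exactly zero", {
    pr <- fullRankProblem()
    x <- t(pr$betas)
    y <- pr$y
    # lambda_max from the standardized-predictor correlation bound
    n <- nrow(x)
    xs <- scale(x, center = TRUE,
                scale = sqrt(apply(x, 2, function(v)
                    sum((v - mean(v))^2) / n)))
    lambdaMax <- max(abs(crossprod(xs, y - mean(y)))) / (n * 0.5)
    res <- trainClock(pr$betas, y, alpha = 0.5, rule = "fixed",
                      lambda = lambdaMax, seed = 1)
    expect_equal(nNonzero(res$model), 0L)
    expect_identical(unname(clockWeights(res$model)), numeric(0))
    # and the top of the automatic grid is that lambda
    fit <- glmnet::glmnet(x, y, alpha = 0.5)
    expect_equal(fit$lambda[1], lambdaMax, tolerance = 1e-6)
})

test_that("support size is near-monotone along the descending lambda path", {
    sim <- simulateCohort(simConfig(n_samples = 120, n_cpgs = 300,
                                    n_causal = 15, seed = 6))
    fit <- glmnet::glmnet(t(betaValues(sim$betas)), sim$truth$tl,
                          alpha = 0.5)
    nz <- fit$df
    steps <- diff(nz)
    expect_gte(mean(steps >= 0), 0.95)
})

test_that("cross-validated training beats the intercept-only model in-sample", {
    sim <- simulateCohort(simConfig(n_samples = 150, n_cpgs = 200,
                                    n_causal = 20, seed = 13))
    res <- trainClock(sim$betas, sim$truth$tl, nFolds = 5, rule = "min",
                      seed = 2)
    expect_s4_class(res$cv, "CVPath")
    expect_gte(res$cv@lambda1se, res$cv@lambdaMin)
    tl <- applyClock(res$model, sim$betas)$dnamtl
    mseModel <- mean((sim$truth$tl - tl)^2)
    mseNull <- mean((sim$truth$tl - mean(sim$truth$tl))^2)
    expect_lte(mseModel, mseNull)
})

test_that("missing training values are an explicit error", {
    pr <- fullRankProblem()
    pr$betas[1, 1] <- NA
    expect_error(trainClock(pr$betas, pr$y, seed = 1), "impute upstream")
})

test_that("applyClock computes the weighted sum in kilobases", {
    tl <- applyClock(toyClockModel(), tinyBetaMatrix())
    # s1: 7 + 2*0.1 - 1*0.9 + 0.5*0.5 = 6.55 ; s2: 7 + 0.8 - 0 + 0.5 = 8.3
    expect_equal(tl$dnamtl, c(6.55, 8.3), tolerance = 1e-12)
    expect_equal(tl$n_probes_used, c(3L, 3L))
    expect_equal(tl$n_probes_imputed, c(0L, 0L))

    b <- BetaMatrix(matrix(c(0.5, 0.2, 0.8), 3,
                    dimnames = list(c("cgA", "cgB", "cgC"), "s1")))
    m <- ClockModel(7, c(cgA = 2, cgB = -1, cgC = 0.5))
    expect_equal(applyClock(m, b)$dnamtl, 8.2, tolerance = 1e-12)
})

test_that("clock application is linear in the beta rows", {
    m <- toyClockModel()
    x <- c(cgA = 0.2, cgB = 0.6, cgC = 0.1)
    y <- c(cgA = 0.8, cgB = 0.2, cgC = 0.9)
    b <- BetaMatrix(cbind(s1 = x, s2 = y, s3 = (x + y) / 2))
    tl <- applyClock(m, b)$dnamtl
    expect_equal(tl[3], mean(tl[1:2]), tolerance = 1e-12)
})

test_that("missing probes follow the declared policy", {
    m <- toyClockModel()
    b <- BetaMatrix(matrix(c(0.5, 0.2), 2,
                    dimnames = list(c("cgA", "cgB"), "s1")))
    expect_error(applyClock(m, b), "absent: cgC")

    m2 <- ClockModel(7, c(cgA = 2, cgB = -1, cgC = 0.5),
                     trainingMeans = c(cgA = 0.5, cgB = 0.5, cgC = 0.4))
    tl <- applyClock(m2, b, missingPolicy = "mean_impute")
    expect_equal(tl$dnamtl, 7 + 1 - 0.2 + 0.5 * 0.4, tolerance = 1e-12)
    expect_equal(tl$n_probes_imputed, 1L)

    m3 <- ClockModel(7, c(cgA = 2, cgB = -1, cgC = 0.5))
    expect_error(applyClock(m3, b, missingPolicy = "mean_impute"),
                 "no training mean")
})

test_that("age adjustment returns centred, age-orthogonal raw residuals", {
    # exact line: tl = 9 - 0.02 * age -> all residuals zero
    age <- c(30, 45, 60, 75)
    tl <- 9 - 0.02 * age
    expect_equal(unname(adjustForAge(tl, age)), rep(0, 4),
                 tolerance = 1e-12)

    withr::with_seed(3, {
        age <- runif(100, 20, 90)
        tl <- 9 - 0.02 * age + rnorm(100, 0, 0.5)
    })
    r <- adjustForAge(tl, age)
    expect_equal(mean(r), 0, tolerance = 1e-9)
    expect_equal(sum(r * (age - mean(age))), 0, tolerance = 1e-8)

    # slope-0 generator: residuals are tl minus its fitted (flat-ish) line
    withr::with_seed(4, {
        tl0 <- rnorm(50, 7, 0.3)
        age0 <- runif(50, 20, 90)
    })
    r0 <- adjustForAge(tl0, age0)
    expect_equal(unname(r0), unname(residuals(lm(tl0 ~ age0))),
                 tolerance = 1e-12)
})

test_that("age adjustment respects grouping and rejects degenerate groups", {
    age <- c(30, 50, 70, 30, 50, 70)
    tl <- c(8, 7.5, 7, 9, 8.7, 8.4)
    grp <- rep(c("A", "B"), each = 3)
    r <- adjustForAge(tl, age, group = grp)
    expect_equal(mean(r[grp == "A"]), 0, tolerance = 1e-9)
    expect_equal(mean(r[grp == "B"]), 0, tolerance = 1e-9)

    expect_error(adjustForAge(c(8, 7, 6), c(50, 50, 50)),
                 "zero age variance")
    expect_error(adjustForAge(c(8, 7), c(40, 50)), ">= 3 samples")
})
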