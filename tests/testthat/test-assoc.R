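test_that("bicor matches its definition computed by brute force", {
    withr::with_seed(11, {
        x <- rnorm(1000)
        y <- 0.5 * x + rnorm(1000)
    })
    # independent evaluation of the weighted-midcovariance definition
    bruteForce <- function(x, y) {
        num <- 0; dx <- 0; dy <- 0
        medx <- median(x); madx <- median(abs(x - medx))
        medy <- median(y); mady <- median(abs(y - medy))
        for (i in seq_along(x)) {
            ux <- (x[i] - medx) / (9 * madx)
            uy <- (y[i] - medy) / (9 * mady)
            ai <- if (abs(ux) < 1) (1 - ux^2)^2 else 0
            bi <- if (abs(uy) < 1) (1 - uy^2)^2 else 0
            num <- num + ai * bi * (x[i] - medx) * (y[i] - medy)
            dx <- dx + (ai * (x[i] - medx))^2
            dy <- dy + (bi * (y[i] - medy))^2
        }
        num / sqrt(dx * dy)
    }
    expect_equal(bicor(x, y), bruteForce(x, y), tolerance = 1e-12)
    expect_equal(bicor(x, y), cor(x, y), tolerance = 0.05)
})

test_that("bicor is a correlation: self, antisymmetry, bounds, affine", {
    withr::with_seed(12, x <- rnorm(50))
    expect_equal(bicor(x, x), 1, tolerance = 1e-12)
    expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
    withr::with_seed(13, y <- rnorm(50))
    r <- bicor(x, y)
    expect_true(r >= -1 && r <= 1)
    expect_equal(bicor(3 * x + 5, y), r, tolerance = 1e-12)
    expect_equal(bicor(x, 0.1 * y - 2), r, tolerance = 1e-12)
})

test_that("bicor degenerates gracefully", {
    # zero MAD but positive variance: Pearson fallback for that variable
    x <- c(rep(1, 8), 0, 2)
    withr::with_seed(14, y <- rnorm(10))
    expect_equal(bicor(x, y),
                 {
                     a <- x - mean(x)
                     med <- median(y); madv <- median(abs(y - med))
                     u <- (y - med) / (9 * madv)
                     b <- (y - med) * (1 - u^2)^2 * (abs(u) < 1)
                     sum(a * b) / sqrt(sum(a^2) * sum(b^2))
                 }, tolerance = 1e-12)
    expect_error(bicor(rep(1, 5), rnorm(5)), "zero variance")
    expect_error(bicor(1:2, 1:2), "at least 3")
    expect_error(bicor(1:4, 1:5), "equal length")
})

test_that("simple regression reproduces the closed-form slope", {
    withr::with_seed(15, {
        x <- runif(80)
        y <- 2 - 3 * x + rnorm(80, 0, 0.3)
    })
    d <- data.frame(y = y, x = x)
    a <- linearAssoc(d, "y", "x")
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(a$estimate, slope, tolerance = 1e-10)
    expect_equal(a$statistic, a$estimate / a$se, tolerance = 1e-9)
    s <- summary(lm(y ~ x))$coefficients
    expect_equal(a$p, s["x", 4], tolerance = 1e-12)
})

test_that("the planted age slope is recovered within 2 SE", {
    sim <- simulateCohort(simConfig(n_samples = 5000, n_cpgs = 2,
                                    n_causal = 0, seed = 17))
    d <- sim$samples
    d$tl_true <- sim$truth$tl
    a <- linearAssoc(d, "tl_true", "age",
                     covariates = c("sex", "ethnicity", "bmi",
                                    "pack_years"))
    expect_lt(abs(a$estimate - (-0.022)), 2 * a$se)
})

test_that("perfect collinearity raises an aliasing error", {
    d <- data.frame(y = rnorm(20), x = rnorm(20))
    d$x2 <- d$x
    expect_error(linearAssoc(d, "y", "x", covariates = "x2"),
                 "aliased")
})

test_that("cluster-robust SEs differ from naive under clustering", {
    withr::with_seed(18, {
        fam <- rep(1:30, each = 4)
        u <- rnorm(30)[fam]
        x <- rnorm(120)
        y <- 0.5 * x + u + rnorm(120, 0, 0.3)
    })
    d <- data.frame(y = y, x = x, fam = fam)
    naive <- linearAssoc(d, "y", "x")
    clust <- linearAssoc(d, "y", "x", cluster = "fam")
    expect_equal(clust$estimate, naive$estimate, tolerance = 1e-12)
    expect_false(isTRUE(all.equal(clust$se, naive$se)))
    expect_equal(clust$model, "ols_cluster")
})

test_that("smoking harness prefers pack-years, falls back to binary", {
    sim <- simulateCohort(simConfig(n_samples = 1500, n_cpgs = 2,
                                    n_causal = 0, seed = 19))
    s <- sim$samples
    a <- smokingAssoc(s, sim$truth$tl)
    expect_equal(a$exposure, "Pack years")

    # unbiasedness: mean standardized deviation from the planted slope
    # over independent cohorts is ~N(0, 1/R)
    zdev <- vapply(1:12, function(i) {
        si <- simulateCohort(simConfig(n_samples = 500, n_cpgs = 2,
                                       n_causal = 0, seed = 500 + i))
        ai <- smokingAssoc(si$samples, si$truth$tl)
        (ai$estimate - (-0.022)) / ai$se
    }, numeric(1))
    expect_lt(abs(mean(zdev)), 3 / sqrt(12))

    sBin <- s[, setdiff(names(s), "pack_years")]
    b <- smokingAssoc(sBin, sim$truth$tl)
    expect_equal(b$exposure, "Smoker")
    expect_lt(b$estimate, 0)

    sNone <- s[, setdiff(names(s), c("pack_years", "ever_smoker"))]
    expect_error(smokingAssoc(sNone, sim$truth$tl), "no smoking data")

    sNever <- s
    sNever$pack_years <- 0
    sNever$ever_smoker <- FALSE
    expect_error(smokingAssoc(sNever, sim$truth$tl), "no variance")
})

test_that("smoking association is calibrated under the null", {
    # null cohorts: zero pack-year effect; nominal 0.05 rejection rate
    nRep <- 1000
    rej <- withr::with_seed(20, {
        vapply(seq_len(nRep), function(i) {
            n <- 120
            age <- runif(n, 22, 93)
            ever <- runif(n) < 0.45
            py <- ifelse(ever, rgamma(n, 2, scale = 7.5), 0)
            tl <- 8.4 - 0.022 * age + rnorm(n, 0, 1)
            d <- data.frame(sample_id = seq_len(n), age = age,
                            pack_years = py, ever_smoker = ever)
            smokingAssoc(d, tl)$p < 0.05
        }, logical(1))
    })
    expect_gte(mean(rej), 0.035)
    expect_lte(mean(rej), 0.065)
})

test_that("Cox association recovers the planted mortality hazard", {
    sim <- simulateCohort(simConfig(n_samples = 2000, n_cpgs = 2,
                                    n_causal = 0, seed = 23))
    d <- sim$samples
    d$tladj <- sim$truth$tl_adj_age
    a <- coxAssoc(d, "time", "event", "tladj", covariates = "age")
    expect_lt(abs(a$estimate - log(0.37)), 2 * a$se)
    expect_equal(a$hr, exp(a$estimate), tolerance = 1e-12)
    expect_equal(a$statistic, a$estimate / a$se, tolerance = 1e-9)
})

test_that("null-hazard Cox confidence intervals cover 1", {
    # Wald CIs are asymptotic: assessed at ~120 events per replicate
    covered <- vapply(1:200, function(s) {
        sim <- simulateCohort(simConfig(n_samples = 400, n_cpgs = 2,
                                        n_causal = 0, log_hr_per_kb = 0,
                                        seed = 3000 + s))
        d <- sim$samples
        d$tladj <- sim$truth$tl_adj_age
        a <- coxAssoc(d, "time", "event", "tladj")
        abs(a$estimate) < 1.96 * a$se
    }, logical(1))
    expect_gte(mean(covered), 0.93)
})

test_that("Cox degenerate inputs error", {
    d <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0),
                    x = c(1, 2, 3))
    expect_error(coxAssoc(d, "time", "event", "x"), "no events")
    d2 <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0),
                     x = c(1, 1, 1))
    expect_error(coxAssoc(d2, "time", "event", "x"), "constant exposure")
})

test_that("Cox on uncensored exponential data matches the closed form", {
    # with log-hazard b*x and no censoring, the exponential-regression MLE
    # is the large-n truth; at n = 5000 the Cox estimate sits on it
    withr::with_seed(24, {
        x <- rnorm(5000)
        tt <- rexp(5000, rate = 0.1 * exp(0.4 * x))
    })
    d <- data.frame(time = tt, event = 1L, x = x)
    a <- coxAssoc(d, "time", "event", "x")
    expect_lt(abs(a$estimate - 0.4), 3 * a$se)
})
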