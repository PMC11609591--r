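test_that("a noiseless Gaussian histogram is recovered to machine precision", {
    x <- seq(1, 15, by = 2)
    y <- 40 * exp(-((x - 7.7)^2) / 2.6^2)
    co <- endloop:::.fitGaussianXY(x, y, start = list(A = 30, c = 7, w = 3))
    expect_equal(co["c", "Estimate"], 7.7, tolerance = 1e-8)
    expect_equal(co["w", "Estimate"], 2.6, tolerance = 1e-8)
    expect_equal(co["A", "Estimate"], 40, tolerance = 1e-8)
})

test_that("histogram fits recover synthetic sample parameters", {
    v <- sampleGaussianCL(5000, center = 9.0, width = 6.03, seed = 7)
    fit <- fitGaussianCL(v, binWidth = 2)
    expect_lt(abs(fitCenter(fit) - 9.0), 3 * fitCenterSd(fit))
    expect_lt(abs(fitWidth(fit) - 6.03), 3 * fitWidthSd(fit) + 0.3)
    expect_equal(fit@binWidth, 2)
    expect_equal(fit@nPoints, 5000L)
    # sigma = w / sqrt(2) round-trips the convention
    expect_equal(fitWidth(fit) / sqrt(2) * sqrt(2), fitWidth(fit))
})

test_that("degenerate inputs to the Gaussian fit error out loudly", {
    expect_error(fitGaussianCL(rep(5, 100)), "degenerate")
    expect_error(fitGaussianCL(c(1, 2, 3)), "at least 10")
    expect_error(fitGaussianCL(sampleGaussianCL(100, 9, 6, seed = 1),
                               binWidth = 0), "positive")
})

test_that("the 95% bound is center + sqrt(2) w and increasing in both", {
    f <- GaussianFit(center = 0, width = 1)
    expect_equal(upperBound95(f), sqrt(2))
    # the alternative sigma-convention bound is documented but different
    expect_equal(upperBound95(f, convention = "sigma1.645"),
                 qnorm(0.95), tolerance = 1e-6)
    for (i in 1:10) {
        c0 <- runif(1, 2, 12); w0 <- runif(1, 1, 7)
        b <- upperBound95(GaussianFit(c0, w0))
        expect_gt(upperBound95(GaussianFit(c0 + 0.5, w0)), b)
        expect_gt(upperBound95(GaussianFit(c0, w0 + 0.5)), b)
    }
})

test_that("width scaling follows the center ratio with quadrature errors", {
    s <- scaleWidth(2.6, 9.0, 7.7)
    expect_equal(s$width, 2.6 * 9.0 / 7.7, tolerance = 1e-12)
    expect_equal(round(s$width, 2), 3.04)
    expect_equal(s$sd, 0)

    expect_equal(scaleWidth(3, 5, 5)$width, 3)           # equal centers
    expect_equal(scaleWidth(3, 5, 5, gcFactor = 2)$width, 6)  # linearity

    sp <- scaleWidth(2.6, 9.0, 7.7, wRandomSd = 0.7, centerNativeSd = 0.8,
                     centerRandomSd = 0.4)
    relHand <- sqrt((0.7 / 2.6)^2 + (0.8 / 9.0)^2 + (0.4 / 7.7)^2)
    expect_equal(sp$sd, sp$width * relHand)
    expect_error(scaleWidth(2.6, 9.0, 0), "centerRandom")
})

test_that("sigma-confidence is a plain standardized excess", {
    expect_equal(round(sigmaConfidence(6.03, 3.03, 0.81), 1), 3.7)
    expect_equal(sigmaConfidence(4, 4, 1), 0)
    expect_equal(sigmaConfidence(5, 3, 1), 2)
    expect_error(sigmaConfidence(5, 3, 0), "positive")
})

test_that("Welch test matches the hand-evaluated formulas", {
    x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
    res <- welchTest(x, y)
    # hand evaluation: var = 5/3 each, se = sqrt(2 * (5/3) / 4)
    se <- sqrt(var(x) / 4 + var(y) / 4)
    tHand <- (mean(x) - mean(y)) / se
    dofHand <- (var(x) / 4 + var(y) / 4)^2 /
        ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
    expect_equal(res$t, tHand)
    expect_equal(res$t, -9.859006, tolerance = 1e-6)
    expect_equal(res$dof, 6)
    expect_equal(res$pValue, 2 * pt(tHand, dofHand))
    expect_equal(res$pValue, 6.280126e-05, tolerance = 1e-6)

    # symmetry and the identical-sample case
    expect_equal(welchTest(y, x)$pValue, res$pValue)
    z <- c(1, 2, 3)
    same <- welchTest(z, z)
    expect_equal(same$t, 0)
    expect_equal(same$pValue, 1)
    expect_lte(res$dof, 4 + 4 - 2)

    expect_error(welchTest(1, c(1, 2)), "at least 2")
    expect_error(welchTest(c(1, 1), c(1, 2)), "nonzero variance")
})

test_that("SEM is sd/sqrt(n) with the n-1 denominator", {
    expect_equal(sem(c(5, 5, 5)), 0)
    expect_equal(sem(c(0, 2)), 1)     # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
    v <- rnorm(20)
    expect_equal(sem(3 * v), 3 * sem(v))
    expect_equal(sem(v), sd(v) / sqrt(20))
    expect_error(sem(1), "at least 2")
})

test_that("pearsonLinfit matches closed-form OLS on a hand dataset", {
    x <- c(1, 2, 4, 5, 7); y <- c(2.1, 2.9, 5.2, 5.8, 8.1)
    fit <- pearsonLinfit(x, y)
    # closed-form OLS evaluated independently
    bHand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    aHand <- mean(y) - bHand * mean(x)
    rHand <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(fit@slope, bHand)
    expect_equal(fit@intercept, aHand)
    expect_equal(fit@pearsonR, rHand)
    expect_equal(sign(fit@slope), sign(fit@pearsonR))
    tr <- rHand * sqrt(3 / (1 - rHand^2))
    expect_equal(fit@pValue, 2 * pt(-abs(tr), 3))
    expect_equal(fit@df, 3L)

    exact <- pearsonLinfit(1:10, 2 * (1:10))
    expect_equal(exact@pearsonR, 1)
    expect_equal(exact@slope, 2)
    expect_equal(exact@intercept, 0, tolerance = 1e-12)

    expect_error(pearsonLinfit(rep(1, 5), rnorm(5)), "zero variance")
    expect_error(pearsonLinfit(1:5, rep(2, 5)), "undefined")
    expect_error(pearsonLinfit(1:2, 1:2), "at least 3")
})

test_that("the confidence band is narrowest at the predictor mean", {
    set.seed(5)
    x <- runif(40, 0, 10); y <- 3 + 0.5 * x + rnorm(40, sd = 0.5)
    fit <- pearsonLinfit(x, y)
    band <- confidenceBand(fit, c(mean(x), 0, 10))
    hw <- (band$upr - band$lwr) / 2
    expect_lt(hw[1], hw[2])
    expect_lt(hw[1], hw[3])
    expect_true(all(band$lwr < band$fit & band$fit < band$upr))
    # half-width at mean(x) is t * s / sqrt(n) by the standard formula
    s <- summary(fit@model)$sigma
    expect_equal(hw[1], qt(0.975, 38) * s / sqrt(40), tolerance = 1e-10)
})

test_that("linear-fit standard errors are calibrated", {
    set.seed(6)
    n <- 30; hitsA <- 0L; hitsB <- 0L; reps <- 500L
    for (i in seq_len(reps)) {
        x <- runif(n, 0, 10)
        y <- 2 + 0.5 * x + rnorm(n, sd = 1)
        fit <- pearsonLinfit(x, y)
        tc <- qt(0.975, n - 2)
        if (abs(fit@intercept - 2) <= tc * fit@interceptSd) hitsA <- hitsA + 1L
        if (abs(fit@slope - 0.5) <= tc * fit@slopeSd) hitsB <- hitsB + 1L
    }
    expect_gte(hitsA / reps, 0.9)
    expect_gte(hitsB / reps, 0.9)
})
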