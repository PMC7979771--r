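test_that("the empirical survival curve is the complementary ECDF", {
    sc <- empiricalSurvival(c(1, 2, 3))
    expect_equal(survProb(sc), c(2, 1, 0) / 3)
    expect_true(all(diff(survProb(sc)) <= 0))
    d <- sampleTwoPhase(TwoPhaseSpec(n_bouts = 200, seed = 2))
    expect_true(all(d > 0))                     # P(X > 0) = 1
    expect_error(empiricalSurvival(numeric(0)), "no durations")
})

test_that("the active index MLE recovers a pure Pareto survival exponent", {
    set.seed(8)
    u <- runif(1e5)
    d <- 3 * u^(-1 / 0.8)                       # survival exponent 0.8
    f <- fitActiveIndex(d, xmin = 3)
    expect_true(f$beta > 0.78 && f$beta < 0.82) # within ~2.5 MLE SE
    expect_equal(f$se, 0.8 / sqrt(1e5), tolerance = 0.05)
    expect_error(fitActiveIndex(c(1, 2), xmin = 3), "below")
    expect_error(fitActiveIndex(rep(5, 4), xmin = 3), "too few")
})

test_that("the truncated head fit matches the printed light-phase active index", {
    # durations generated with the male light-phase parameters; the
    # pipeline should recover the generating exponent within 3 SE
    d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.73, K = 200, lam = 1000,
                                     xmin = 1, n_bouts = 5000, seed = 77))
    f <- fitActiveIndex(d, xmin = 3, K = 200)
    expect_lt(abs(f$beta - 0.73), 3 * f$se)
})

test_that("the head fit is invariant under rescaling durations and xmin", {
    set.seed(15)
    d <- 3 * runif(5000)^(-1 / 0.85)
    b1 <- fitActiveIndex(d, xmin = 3)$beta
    b2 <- fitActiveIndex(7.3 * d, xmin = 7.3 * 3)$beta
    expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("the latency scan accepts a shifted exponential at the first candidate", {
    set.seed(4)
    d <- 50 + rexp(2000, 1 / 600)
    fl <- findSleepLatency(d)
    expect_equal(fl$K, 50)
    expect_true(fl$accepted)
    expect_lt(abs(fl$lam - 600), 3 * 600 / sqrt(2000))
    expect_equal(fl$N, sum(d > 50))
    expect_error(findSleepLatency(c(rep(10, 50), 60, 70, 80, 90, 95)),
                 "too few")
})

test_that("the latency scan returns the smallest accepted candidate", {
    d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000,
                                     xmin = 3, n_bouts = 3000, seed = 19))
    fl <- findSleepLatency(d)
    # exhaustive oracle over the same data-driven grid
    cand <- unique(c(50, sort(unique(d[d >= 50]))))
    for (K in cand) {
        e <- d[d > K] - K
        if (length(e) < 10) break
        p <- suppressWarnings(ks.test(e, "pexp", rate = 1 / mean(e),
                                      exact = FALSE)$p.value)
        if (p >= 0.10) {
            expect_equal(fl$K, K)
            break
        }
        expect_gt(fl$K, K)
    }
})

test_that("a latency scan with no acceptable candidate is flagged, not silent", {
    # two point masses above the scan start: no tail is ever exponential
    d <- c(runif(300, 1, 40), rep(60, 100), rep(1000, 100))
    expect_warning(fl <- findSleepLatency(d, min_tail = 30), "exhausted")
    expect_false(fl$accepted)
    expect_true(is.na(fl$K))
})

test_that("the KS scan recovers the printed day-phase latency scale", {
    d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000,
                                     xmin = 3, n_bouts = 5000, seed = 23))
    fl <- findSleepLatency(d)
    expect_true(fl$K >= 150 && fl$K <= 250)     # within 25% of 200 s
})

test_that("the tail AIC comparison identifies the generating tail model", {
    set.seed(26)
    d_exp <- c(runif(200, 3, 50), 50 + rexp(1000, 1 / 500))
    expect_gt(tailAICCompare(d_exp, 50), 0)
    d_gauss <- c(runif(200, 3, 50), 50 + abs(rnorm(1000, 0, 400)))
    expect_lt(tailAICCompare(d_gauss, 50), 0)
    expect_error(tailAICCompare(c(1, 2, 60), 50), "too few")
})

test_that("the switch rate follows beta/t below K and 1/lambda above", {
    p <- list(beta = 0.8, K = 200, lam = 500)
    expect_equal(switchRate(100, p), 0.008)
    expect_equal(switchRate(300, p), 0.002)
    expect_equal(switchRate(c(10, 1000), p), c(0.08, 0.002))
    expect_error(switchRate(0, p), "> 0")
})

test_that("the fitted five-parameter signature is internally consistent", {
    d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000,
                                     xmin = 3, n_bouts = 5000, seed = 31))
    f <- fitSleepModel(d)
    expect_identical(f@total, f@N * f@lam)
    expect_identical(f@N, f@n_tail)
    expect_gt(f@delta_aic_gauss_minus_exp, 0)
    # a fixed latency above every duration gives zero sleep
    f0 <- fitSleepModel(d, K = max(d) + 1)
    expect_equal(f0@N, 0)
    expect_equal(f0@total, 0)
})

test_that("per-phase fitting records failures without stopping other phases", {
    d_day <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 150, lam = 800,
                                         xmin = 3, n_bouts = 3000, seed = 41))
    bouts <- data.frame(
        duration_s = c(d_day, runif(40, 1, 30)),
        phase = c(rep("day", 3000), rep("night", 40)))
    tab <- suppressWarnings(sleepParameters(bouts))
    expect_equal(nrow(tab), 2)
    day <- tab[tab$phase == "day", ]
    night <- tab[tab$phase == "night", ]
    expect_true(is.na(day$error))
    expect_equal(day$total_s, day$N * day$lambda_s)
    expect_false(is.na(night$error))            # nothing above scan start
})

test_that("parameters are recovered across random two-phase scenarios", {
    # pipeline recovery over random (beta, K, lambda); replicate count
    # chosen large enough that the sample medians are stable
    set.seed(1)
    res <- t(sapply(1:150, function(r) {
        beta <- runif(1, 0.7, 1)
        K <- runif(1, 100, 400)
        lam <- runif(1, 300, 2000)
        d <- sampleTwoPhase(TwoPhaseSpec(beta = beta, K = K, lam = lam,
                                         xmin = 3, n_bouts = 5000,
                                         seed = r * 13))
        f <- tryCatch(fitSleepModel(d, xmin = 3), error = function(e) NULL)
        if (is.null(f)) return(c(NA, NA, NA))
        c(abs(f@beta - beta), abs(f@K - K) / K, abs(f@lam - lam) / lam)
    }))
    expect_lt(mean(is.na(res[, 1])), 0.05)
    expect_lte(median(res[, 1], na.rm = TRUE), 0.03)
    expect_lte(median(res[, 2], na.rm = TRUE), 0.25)
    expect_lte(median(res[, 3], na.rm = TRUE), 0.10)
})
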