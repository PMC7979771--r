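# Two-phase survival model fitting: empirical survival curves, the
# truncated power-law MLE for the active index, the KS changepoint scan for
# the sleep latency, the gaussian-vs-exponential tail comparison, and the
# per-fly five-parameter summary.

#' Empirical complementary cumulative probability
#'
#' \eqn{P(X > t)} evaluated at the sorted unique observed durations.
#'
#' @param durations numeric vector of rest durations (s).
#' @return A [SurvivalCurve-class].
#' @examples
#' sc <- empiricalSurvival(c(1, 2, 3))
#' survProb(sc)   # 2/3, 1/3, 0
#' @export
empiricalSurvival <- function(durations) {
    if (length(durations) == 0L) stop("no durations supplied")
    stopifnot(is.numeric(durations), all(is.finite(durations)))
    t <- sort(unique(durations))
    n <- length(durations)
    # durations > t for each unique t: complement of the running count <= t
    p <- 1 - cumsum(tabulate(match(sort(durations), t), nbins = length(t))) / n
    new("SurvivalCurve", t = t, p = p, n = as.numeric(n))
}

#' Fit the active index (power-law survival exponent)
#'
#' Continuous maximum-likelihood fit of the power-law head of the duration
#' distribution on \code{[xmin, K]}. The likelihood is that of a Pareto
#' density \eqn{\propto t^{-(\beta+1)}} truncated to \code{[xmin, K]}; with
#' \code{K = Inf} it reduces to the closed-form Hill/Clauset estimator.
#' Note the convention: the reported \code{beta} is the \emph{survival}
#' exponent (the active index), i.e. the density exponent minus 1.
#' Off-the-shelf power-law fitters report the density exponent.
#'
#' @param durations rest durations (s).
#' @param xmin lower bound of power-law behavior (s); the conventional
#'   choice is 3 s.
#' @param K upper truncation (the sleep latency); \code{Inf} pools all
#'   durations >= xmin.
#' @param min_head minimum number of head samples required.
#' @return list with \code{beta}, \code{se} (MLE standard error),
#'   \code{n_head}, and \code{loglik}.
#' @examples
#' d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000,
#'                                  n_bouts = 5000, seed = 1))
#' fitActiveIndex(d, xmin = 3, K = 200)$beta
#' @export
fitActiveIndex <- function(durations, xmin = 3.0, K = Inf, min_head = 10) {
    stopifnot(is.numeric(durations), xmin > 0, K > xmin)
    if (all(durations < xmin))
        stop("all durations are below 'xmin'")
    x <- durations[durations >= xmin & durations <= K]
    n <- length(x)
    if (n < min_head)
        stop(sprintf("too few head samples (%d < %d)", n, min_head))
    slx <- sum(log(x / xmin))
    if (!is.finite(K)) {
        beta <- n / slx          # alpha - 1 with alpha = 1 + n / sum log
        se <- beta / sqrt(n)
        ll <- n * log(beta) + n * beta * log(xmin) - (beta + 1) * sum(log(x))
        return(list(beta = beta, se = se, n_head = n, loglik = ll))
    }
    lr <- log(K / xmin)
    # log-likelihood of the truncated Pareto in the survival exponent beta
    negll <- function(b) {
        -(n * log(b) - n * (log(xmin) * -b + log1p(-exp(-b * lr))) -
              (b + 1) * sum(log(x)))
    }
    opt <- optimize(negll, interval = c(1e-6, 50))
    beta <- opt$minimum
    h <- 1e-4 * max(beta, 1)
    d2 <- (negll(beta + h) - 2 * negll(beta) + negll(beta - h)) / h^2
    se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
    list(beta = beta, se = se, n_head = n, loglik = -opt$objective)
}

#' Locate the sleep latency by a Kolmogorov-Smirnov scan
#'
#' Scans candidate changepoints K upward from \code{scan_start}. For each
#' candidate the excesses \eqn{X - K} of the durations above it are tested
#' (one-sample KS, asymptotic p-value) against an exponential distribution
#' with mean estimated from the same excesses. The sleep latency is the
#' smallest candidate at which the test fails to reject at level
#' \code{alpha}. The candidate grid is \code{scan_start} followed by the
#' sorted unique observed durations above it, so each step changes the tail
#' set; the scan stops when fewer than \code{min_tail} excesses remain.
#'
#' Estimating the exponential mean from the tested sample makes the
#' asymptotic KS test conservative (the Lilliefors effect); this mirrors the
#' published procedure and is deliberately not corrected.
#'
#' @param durations rest durations (s).
#' @param scan_start first candidate latency (s).
#' @param alpha KS significance level of the scan.
#' @param min_tail minimum tail sample size.
#' @return list with \code{K}, \code{lam} (mean excess at K), \code{N}
#'   (tail count at K), \code{ks_p_at_K}, \code{accepted} (FALSE when the
#'   grid was exhausted), and \code{scan} (data.frame of all candidates
#'   tried with their \code{lam}, \code{n_tail} and \code{p}).
#' @examples
#' d <- 50 + rexp(2000, 1 / 600)
#' findSleepLatency(d)$K   # 50: the first candidate is already exponential
#' @export
findSleepLatency <- function(durations, scan_start = 50, alpha = 0.10,
                             min_tail = 10) {
    stopifnot(is.numeric(durations), scan_start > 0)
    if (sum(durations > scan_start) < min_tail)
        stop(sprintf("too few durations above 'scan_start' (%d < %d)",
                     sum(durations > scan_start), min_tail))
    cand <- c(scan_start, sort(unique(durations[durations >= scan_start])))
    cand <- unique(cand)
    scan <- list()
    res <- NULL
    for (K in cand) {
        e <- durations[durations > K] - K
        if (length(e) < min_tail) break
        lam <- mean(e)
        p <- suppressWarnings(
            ks.test(e, "pexp", rate = 1 / lam, exact = FALSE)$p.value)
        scan[[length(scan) + 1L]] <- c(K = K, lam = lam,
                                       n_tail = length(e), p = p)
        if (p >= alpha) {
            res <- list(K = K, lam = lam, N = as.numeric(length(e)),
                        ks_p_at_K = p, accepted = TRUE)
            break
        }
    }
    scan <- as.data.frame(do.call(rbind, scan))
    if (is.null(res)) {
        warning("no candidate latency accepted before the grid was exhausted")
        res <- list(K = NA_real_, lam = NA_real_, N = NA_real_,
                    ks_p_at_K = NA_real_, accepted = FALSE)
    }
    res$scan <- scan
    res
}

#' Compare gaussian and exponential models of the sleep-phase tail
#'
#' Fits the tail excesses \eqn{X - K | X > K} by maximum likelihood under
#' (a) an exponential density and (b) a half-gaussian density (a gaussian
#' decay law \eqn{\propto e^{-t^2/2\sigma^2}} on positive excesses), one
#' free parameter each, and returns AIC(gaussian) - AIC(exponential).
#' Positive values favor the exponential (memoryless) sleep phase.
#'
#' @param durations rest durations (s).
#' @param K sleep latency (s).
#' @param min_tail minimum number of excesses.
#' @return \code{delta_aic_gauss_minus_exp} (numeric scalar).
#' @export
tailAICCompare <- function(durations, K, min_tail = 10) {
    e <- durations[durations > K] - K
    n <- length(e)
    if (n < min_tail)
        stop(sprintf("too few tail excesses (%d < %d)", n, min_tail))
    lam <- mean(e)
    ll_exp <- -n * log(lam) - n
    s2 <- mean(e^2)              # MLE scale of the half-gaussian
    ll_gauss <- n / 2 * log(2 / (pi * s2)) - n / 2
    2 * (ll_exp - ll_gauss)      # (2 - 2 ll_g) - (2 - 2 ll_e)
}

#' Rest-to-move switch rate of the two-phase model
#'
#' The hazard implied by the two-phase survival law: \eqn{\beta/t} while in
#' the sleep latency phase (\eqn{t \le K}) and the constant \eqn{1/\lambda}
#' in the sleep phase.
#'
#' @param t time since rest onset (s, > 0); vectorized.
#' @param params a [SleepParams-class], or any list/object with fields
#'   \code{beta}, \code{K}, \code{lam}.
#' @return Switch rate (1/s) for each \code{t}.
#' @examples
#' switchRate(100, list(beta = 0.8, K = 200, lam = 500))  # 0.008
#' switchRate(300, list(beta = 0.8, K = 200, lam = 500))  # 0.002
#' @export
switchRate <- function(t, params) {
    if (is(params, "SleepParams")) {
        beta <- params@beta; K <- params@K; lam <- params@lam
    } else {
        beta <- params$beta; K <- params$K; lam <- params$lam
    }
    stopifnot(is.numeric(t))
    if (any(t <= 0)) stop("'t' must be > 0")
    ifelse(t <= K, beta / t, 1 / lam)
}

#' Fit the full two-phase sleep model to one duration sample
#'
#' Orchestrates the fit for one fly and phase: the KS scan locates the
#' sleep latency K and sleep duration lambda, the truncated power-law MLE
#' on \code{[xmin, K]} estimates the active index beta, N counts the bouts
#' above K, and Total = N x lambda estimates total sleep time (latency time
#' excluded). Durations quantized to a frame grid can be dequantized by
#' adding uniform noise on one frame interval before the continuous
#' MLE/KS machinery (on by default; a no-op when \code{dt = 0}).
#'
#' @param durations rest durations (s) of one fly in one phase.
#' @param xmin lower bound of the power-law head (s).
#' @param scan_start,alpha,min_tail see [findSleepLatency()].
#' @param min_head see [fitActiveIndex()].
#' @param head_mode "truncated" fits beta on \code{[xmin, K]} (default);
#'   "pooled" fits all durations >= xmin, for sensitivity checks.
#' @param dequantize add U(0, dt) to break frame-grid ties before fitting.
#' @param dt frame interval (s), typically \code{1/fps}; 0 disables
#'   dequantization.
#' @param K optional fixed sleep latency (s). When given the KS scan is
#'   skipped: N counts the bouts above this K (possibly 0, with
#'   \code{total = 0}) and lambda is their mean excess.
#' @param phase optional phase label stored in the result.
#' @return A [SleepParams-class].
#' @examples
#' d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000,
#'                                  n_bouts = 5000, seed = 1))
#' fitSleepModel(d)
#' @export
fitSleepModel <- function(durations, xmin = 3.0, scan_start = 50,
                          alpha = 0.10, min_tail = 10, min_head = 10,
                          head_mode = c("truncated", "pooled"),
                          dequantize = TRUE, dt = 0, K = NULL, phase = "") {
    head_mode <- match.arg(head_mode)
    stopifnot(is.numeric(durations), length(durations) > 0)
    if (dequantize && dt > 0 && anyDuplicated(durations))
        durations <- durations + runif(length(durations), 0, dt)
    if (is.null(K)) {
        lat <- findSleepLatency(durations, scan_start = scan_start,
                                alpha = alpha, min_tail = min_tail)
        if (!lat$accepted)
            stop("sleep latency scan failed: no candidate accepted")
    } else {
        e <- durations[durations > K] - K
        lat <- list(K = K, lam = if (length(e)) mean(e) else NA_real_,
                    N = as.numeric(length(e)), ks_p_at_K = NA_real_)
    }
    Kup <- if (head_mode == "truncated") lat$K else Inf
    head <- fitActiveIndex(durations, xmin = xmin, K = Kup,
                           min_head = min_head)
    daic <- tryCatch(tailAICCompare(durations, lat$K, min_tail = min_tail),
                     error = function(e) NA_real_)
    total <- if (lat$N > 0) lat$N * lat$lam else 0
    new("SleepParams", beta = head$beta, K = lat$K, lam = lat$lam,
        N = lat$N, total = total, xmin = xmin,
        ks_p_at_K = lat$ks_p_at_K, n_head = head$n_head, n_tail = lat$N,
        beta_se = head$se, delta_aic_gauss_minus_exp = daic, phase = phase)
}

#' Five sleep parameters per fly and phase
#'
#' Applies [fitSleepModel()] to each fly x phase group of a bout table.
#' A failed fit in one group (e.g. a latency scan that rejects every
#' candidate) is recorded in the \code{error} column and does not stop the
#' other groups.
#'
#' @param bouts data.frame with \code{duration_s} and \code{phase} columns,
#'   optionally \code{fly_id}; typically from [extractRestBouts()].
#' @param ... passed to [fitSleepModel()].
#' @param dt frame interval for dequantization; defaults to \code{1/fps}
#'   when the bout table carries an \code{fps} attribute.
#' @return data.frame, one row per fly and phase: \code{fly_id},
#'   \code{phase}, \code{beta}, \code{K_s}, \code{lambda_s}, \code{N},
#'   \code{total_s}, \code{ks_p}, \code{delta_aic}, \code{beta_se},
#'   \code{n_head}, \code{error}.
#' @export
sleepParameters <- function(bouts, ..., dt = NULL) {
    stopifnot(is.data.frame(bouts), "duration_s" %in% names(bouts))
    if (is.null(dt)) {
        fps <- attr(bouts, "fps")
        dt <- if (!is.null(fps) && is.finite(fps)) 1 / fps else 0
    }
    if (is.null(bouts$fly_id)) bouts$fly_id <- "fly1"
    if (is.null(bouts$phase) || all(is.na(bouts$phase))) bouts$phase <- "all"
    groups <- split(bouts, list(bouts$fly_id, bouts$phase), drop = TRUE)
    rows <- lapply(groups, function(g) {
        fit <- tryCatch(fitSleepModel(g$duration_s, ..., dt = dt,
                                      phase = g$phase[1L]),
                        error = function(e) e)
        if (inherits(fit, "error")) {
            data.frame(fly_id = g$fly_id[1L], phase = g$phase[1L],
                       beta = NA_real_, K_s = NA_real_, lambda_s = NA_real_,
                       N = NA_real_, total_s = NA_real_, ks_p = NA_real_,
                       delta_aic = NA_real_, beta_se = NA_real_,
                       n_head = NA_real_, error = conditionMessage(fit))
        } else {
            data.frame(fly_id = g$fly_id[1L], phase = g$phase[1L],
                       beta = fit@beta, K_s = fit@K, lambda_s = fit@lam,
                       N = fit@N, total_s = fit@total, ks_p = fit@ks_p_at_K,
                       delta_aic = fit@delta_aic_gauss_minus_exp,
                       beta_se = fit@beta_se, n_head = fit@n_head,
                       error = NA_character_)
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
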