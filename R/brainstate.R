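# Two-hemisphere brain-state random-walk model: simulation, exact
# first-passage oracle, and the (a, w) parameter sweep.

#' Dwell-time scale of a brain state
#'
#' Mean residence time \eqn{\theta = (i^2 + j^2)^{a/2}} of the joint brain
#' state (i, j): quieter (deeper) states are slower to leave. Dwell times
#' are exponential with this mean, the switch being a Poisson process.
#'
#' @param i,j hemisphere state coordinates (>= 0); vectorized.
#' @param a dwell-time exponent.
#' @return \eqn{\theta} (s).
#' @examples
#' dwellTimeScale(3, 4, 1)   # 5
#' @export
dwellTimeScale <- function(i, j, a) {
    stopifnot(all(i >= 0), all(j >= 0))
    (i^2 + j^2)^(a / 2)
}

#' Simulate rest bouts from the brain-state walk
#'
#' Simulates \code{n_bouts} independent bouts of the two-hemisphere walk
#' described in [BrainStateModel-class]. Reproducible under the model's
#' seed.
#'
#' @param model a [BrainStateModel-class].
#' @return A [SimResult-class].
#' @export
simulateBouts <- function(model) {
    validObject(model)
    res <- .withSeed(model@seed,
        simulate_bouts_cpp(as.integer(model@L), model@a, model@w_thresh,
                           model@epsilon, as.integer(model@start_state[1L]),
                           as.integer(model@start_state[2L]),
                           as.integer(model@n_bouts),
                           model@sleep_dynamics == "continue",
                           model@threshold_metric == "euclidean"))
    new("SimResult", durations = res$durations, slept = res$slept,
        latency_component = res$latency, model = model)
}

#' Simulate a single rest bout
#'
#' @param model a [BrainStateModel-class]; its \code{n_bouts} and seed are
#'   ignored, the current RNG state is used.
#' @return list with \code{duration}, \code{slept},
#'   \code{latency_component}.
#' @export
simulateRestBout <- function(model) {
    validObject(model)
    res <- simulate_bouts_cpp(as.integer(model@L), model@a, model@w_thresh,
                              model@epsilon,
                              as.integer(model@start_state[1L]),
                              as.integer(model@start_state[2L]), 1L,
                              model@sleep_dynamics == "continue",
                              model@threshold_metric == "euclidean")
    list(duration = res$durations[1L], slept = res$slept[1L],
         latency_component = res$latency[1L])
}

#' Exact mean first-passage time to the wake boundary
#'
#' Solves the linear system for the expected time the walker started at
#' \code{start} needs to reach the wake boundary (i = 0 or j = 0), with the
#' dwell means \eqn{(i^2+j^2)^{a/2}} and no sleep-phase wake clock. Serves
#' as the independent oracle for the Monte-Carlo simulator on small
#' lattices (dense solve over the L x L interior).
#'
#' @param L states per hemisphere (<= \code{max_L}).
#' @param a dwell-time exponent.
#' @param start integer vector (i, j).
#' @param theta_scale global multiplier of all dwell means (a change of
#'   time unit; expectations scale linearly with it).
#' @param max_L guard for the dense solve.
#' @return list with \code{mean} (expected bout duration from \code{start})
#'   and \code{E} (L x L matrix of expectations from every interior state).
#' @examples
#' meanFirstPassageOracle(1, 0)$mean   # 1: one unit-mean dwell, then out
#' @export
meanFirstPassageOracle <- function(L, a, start = c(1, 1), theta_scale = 1,
                                   max_L = 12) {
    L <- as.integer(L)
    if (L > max_L)
        stop(sprintf("L = %d too large for the dense solve (max %d)", L, max_L))
    stopifnot(L >= 1, length(start) == 2, all(start >= 1), all(start <= L))
    id <- function(i, j) (i - 1L) * L + j
    n <- L * L
    A <- diag(n)
    theta <- numeric(n)
    for (i in seq_len(L)) for (j in seq_len(L)) {
        s <- id(i, j)
        theta[s] <- theta_scale * (i^2 + j^2)^(a / 2)
        ni <- c(i - 1L, i + 1L, i, i)
        nj <- c(j, j, j - 1L, j + 1L)
        adm <- ni <= L & nj <= L            # reflecting at L
        ni <- ni[adm]; nj <- nj[adm]
        pr <- 1 / sum(adm)
        for (k in seq_along(ni))
            if (ni[k] >= 1L && nj[k] >= 1L)  # boundary states contribute 0
                A[s, id(ni[k], nj[k])] <- A[s, id(ni[k], nj[k])] - pr
    }
    E <- solve(A, theta)
    list(mean = E[id(start[1L], start[2L])],
         E = matrix(E, nrow = L, ncol = L, byrow = TRUE,
                    dimnames = list(i = seq_len(L), j = seq_len(L))))
}

#' Sweep the (a, w) plane of the brain-state model
#'
#' For every combination of dwell exponent \code{a} and sleep threshold
#' \code{w}, simulates bouts, fits the two-phase sleep model to the
#' simulated durations, and records the fitted active index, sleep latency
#' and sleep duration. Cells whose fitted latency falls in
#' \code{feasible_range} (the experimentally observed 80-300 s band) are
#' flagged feasible; per-cell fit failures are recorded and do not stop the
#' sweep.
#'
#' @param a_grid,w_grid numeric grids of dwell exponents and thresholds.
#' @param L states per hemisphere.
#' @param epsilon sleep-phase wake rate (1/s).
#' @param n_bouts bouts simulated per cell.
#' @param seed RNG seed; each cell derives a child seed.
#' @param feasible_range latency band defining feasibility (s).
#' @param xmin,scan_start,alpha passed to [fitSleepModel()].
#' @return data.frame with one row per (a, w) cell: \code{a}, \code{w},
#'   \code{beta_hat}, \code{K_hat}, \code{lambda_hat}, \code{frac_slept},
#'   \code{feasible}, \code{error}.
#' @export
sweepParameters <- function(a_grid, w_grid, L = 50, epsilon = 1e-3,
                            n_bouts = 2000, seed = NA,
                            feasible_range = c(80, 300), xmin = 3,
                            scan_start = 50, alpha = 0.10) {
    stopifnot(length(a_grid) >= 1, length(w_grid) >= 1)
    grid <- expand.grid(a = a_grid, w = w_grid, KEEP.OUT.ATTRS = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(g) {
        m <- BrainStateModel(L = L, a = grid$a[g], w_thresh = grid$w[g],
                             epsilon = epsilon, n_bouts = n_bouts,
                             seed = .childSeed(seed, g))
        sim <- simulateBouts(m)
        fit <- tryCatch(
            fitSleepModel(sim@durations, xmin = xmin, scan_start = scan_start,
                          alpha = alpha, dequantize = FALSE),
            error = function(e) e)
        if (inherits(fit, "error")) {
            data.frame(a = grid$a[g], w = grid$w[g], beta_hat = NA_real_,
                       K_hat = NA_real_, lambda_hat = NA_real_,
                       frac_slept = mean(sim@slept), feasible = FALSE,
                       error = conditionMessage(fit))
        } else {
            data.frame(a = grid$a[g], w = grid$w[g], beta_hat = fit@beta,
                       K_hat = fit@K, lambda_hat = fit@lam,
                       frac_slept = mean(sim@slept),
                       feasible = fit@K >= feasible_range[1L] &
                           fit@K <= feasible_range[2L],
                       error = NA_character_)
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
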