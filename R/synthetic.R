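# Synthetic data with the statistical structure the analysis assumes:
# two-phase rest durations, alternating move/rest trajectories, and rendered
# grayscale frame stacks.

# Evaluate expr under a local seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (is.na(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed) %% .Machine$integer.max)
    expr
}

# Deterministic child seed from a parent seed (NA propagates).
.childSeed <- function(seed, k) {
    if (is.na(seed)) return(NA_real_)
    (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

#' Two-phase survival, quantile and sampling functions
#'
#' The two-phase bout-duration law has survival function
#' \deqn{P(X>t) = (t/x_{min})^{-\beta}, \quad x_{min} \le t \le K,}
#' glued continuously at the sleep latency \eqn{K} to an exponential tail
#' \deqn{P(X>t) = (K/x_{min})^{-\beta} e^{-(t-K)/\lambda}, \quad t > K.}
#' This is the law whose rest-to-move switch rate is exactly \eqn{\beta/t}
#' in the latency phase and \eqn{1/\lambda} in the sleep phase; its density
#' jumps at \eqn{K} unless \eqn{\lambda = K/\beta}. The alternative
#' \code{continuity = "density"} glues the \emph{density}
#' (\eqn{\propto t^{-\beta-1}} then \eqn{\propto e^{-t/\lambda}})
#' continuously at \eqn{K} instead; its head survival is then a power law
#' plus an additive constant, which is kept only for sensitivity checks.
#'
#' @param t,q duration(s), s.
#' @param p survival level(s) in (0, 1].
#' @param beta survival power-law exponent (> 0).
#' @param K sleep latency (s), \code{K > xmin}.
#' @param lam mean exponential excess beyond \code{K} (s).
#' @param xmin lower support bound (s).
#' @param continuity which quantity is continuous at \code{K}.
#' @return \code{twoPhaseSurvival}: \eqn{P(X>t)}; \code{twoPhaseQuantile}:
#'   the duration \eqn{t} with \eqn{P(X>t) = p}.
#' @seealso [sampleTwoPhase()]
#' @export
twoPhaseSurvival <- function(t, beta, K, lam, xmin = 1,
                             continuity = c("survival", "density")) {
    continuity <- match.arg(continuity)
    stopifnot(beta > 0, lam > 0, K > xmin, xmin > 0)
    out <- numeric(length(t))
    head <- t >= xmin & t <= K
    tail <- t > K
    if (continuity == "survival") {
        SK <- (K / xmin)^(-beta)
        out[t < xmin] <- 1
        out[head] <- (t[head] / xmin)^(-beta)
        out[tail] <- SK * exp(-(t[tail] - K) / lam)
    } else {
        # density-continuous mixture: f ~ C t^-(beta+1) then C2 e^(-t/lam)
        M <- (xmin^(-beta) - K^(-beta)) / beta + lam * K^(-(beta + 1))
        Cn <- 1 / M
        p_tail <- Cn * lam * K^(-(beta + 1))
        out[t < xmin] <- 1
        out[head] <- Cn * (t[head]^(-beta) - K^(-beta)) / beta + p_tail
        out[tail] <- p_tail * exp(-(t[tail] - K) / lam)
    }
    out
}

#' @rdname twoPhaseSurvival
#' @export
twoPhaseQuantile <- function(p, beta, K, lam, xmin = 1,
                             continuity = c("survival", "density")) {
    continuity <- match.arg(continuity)
    stopifnot(all(p > 0), all(p <= 1), beta > 0, lam > 0, K > xmin, xmin > 0)
    out <- numeric(length(p))
    if (continuity == "survival") {
        SK <- (K / xmin)^(-beta)
        hd <- p >= SK
        out[hd] <- xmin * p[hd]^(-1 / beta)
        out[!hd] <- K - lam * log(p[!hd] / SK)
    } else {
        M <- (xmin^(-beta) - K^(-beta)) / beta + lam * K^(-(beta + 1))
        Cn <- 1 / M
        p_tail <- Cn * lam * K^(-(beta + 1))
        hd <- p > p_tail
        out[hd] <- (K^(-beta) + beta * (p[hd] - p_tail) / Cn)^(-1 / beta)
        out[!hd] <- K - lam * log(p[!hd] / p_tail)
    }
    out
}

#' Sample rest-bout durations from the two-phase law
#'
#' Inverse-CDF sampling of i.i.d. durations from the two-phase distribution
#' described in [twoPhaseSurvival()]. Reproducible under the spec's seed.
#'
#' @param spec a [TwoPhaseSpec-class].
#' @param continuity see [twoPhaseSurvival()].
#' @return Numeric vector of \code{spec@n_bouts} durations (s).
#' @examples
#' d <- sampleTwoPhase(TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000,
#'                                  n_bouts = 1000, seed = 1))
#' mean(d > 200)   # fraction of sleep bouts
#' @export
sampleTwoPhase <- function(spec, continuity = c("survival", "density")) {
    validObject(spec)
    continuity <- match.arg(continuity)
    .withSeed(spec@seed, {
        u <- runif(spec@n_bouts)
        twoPhaseQuantile(u, spec@beta, spec@K, spec@lam, spec@xmin,
                         continuity = continuity)
    })
}

# Uniform point in the chamber interior, in px (0-based), margin from walls.
.chamberDraw <- function(chamber, margin = 1) {
    W <- chamber@width_mm * chamber@px_per_mm
    Lg <- chamber@length_mm * chamber@px_per_mm
    if (chamber@type == "1D") {
        c(runif(1, margin, W - 1 - margin), runif(1, margin, Lg - 1 - margin))
    } else {
        ax <- (W - 1) / 2 - margin
        ay <- (Lg - 1) / 2 - margin
        cx <- (W - 1) / 2
        cy <- (Lg - 1) / 2
        repeat {
            p <- c(runif(1, -ax, ax), runif(1, -ay, ay))
            if ((p[1] / ax)^2 + (p[2] / ay)^2 <= 1)
                return(c(cx + p[1], cy + p[2]))
        }
    }
}

.insideChamber <- function(chamber, x, y, margin = 1) {
    W <- chamber@width_mm * chamber@px_per_mm
    Lg <- chamber@length_mm * chamber@px_per_mm
    if (chamber@type == "1D") {
        x >= margin & x <= W - 1 - margin & y >= margin & y <= Lg - 1 - margin
    } else {
        ax <- (W - 1) / 2 - margin
        ay <- (Lg - 1) / 2 - margin
        ((x - (W - 1) / 2) / ax)^2 + ((y - (Lg - 1) / 2) / ay)^2 <= 1
    }
}

#' Generate a synthetic fly trajectory
#'
#' Builds an alternating move/rest trajectory on the frame grid. Movement is
#' waypoint walking: the fly heads toward a uniformly drawn interior target
#' at \code{move_speed_px_s}, picking a new target on arrival, for a
#' log-normal active-bout duration. Rest segments hold the current position,
#' perturbed by independent per-frame noise uniform in a disk of radius
#' \code{jitter_px}, for a duration drawn from the two-phase law. The planted
#' rest bouts are returned as ground truth in the \code{bouts_truth} slot
#' (onset, duration quantized to the frame grid, anchor location).
#'
#' @param spec a [TrajectorySpec-class].
#' @return A [Trajectory-class] whose \code{bouts_truth} holds the planted
#'   bouts.
#' @examples
#' sp <- TrajectorySpec(duration_s = 120,
#'                      rest_spec = TwoPhaseSpec(beta = 0.8, K = 30, lam = 60,
#'                                               xmin = 1, n_bouts = 1),
#'                      seed = 1)
#' traj <- makeTrajectory(sp)
#' @export
makeTrajectory <- function(spec) {
    validObject(spec)
    fps <- spec@fps
    n_frames <- floor(spec@duration_s * fps)
    if (n_frames < 2L)
        stop("'duration_s' too short: fewer than 2 frames")
    .withSeed(spec@seed, {
        rs <- spec@rest_spec
        # pre-draw generous batches of rest and move durations
        n_guess <- max(16L, ceiling(spec@duration_s /
                                    max(1, rs@xmin + exp(spec@move_meanlog))))
        draw_rests <- function(n) {
            s2 <- rs; s2@n_bouts <- n; s2@seed <- NA_real_
            sampleTwoPhase(s2)
        }
        rests <- draw_rests(n_guess)
        moves <- rlnorm(n_guess, spec@move_meanlog, spec@move_sdlog)
        x <- numeric(n_frames); y <- numeric(n_frames)
        truth <- list()
        pos <- .chamberDraw(spec@chamber)
        target <- .chamberDraw(spec@chamber)
        step <- spec@move_speed_px_s / fps
        f <- 1L; k_rest <- 0L; k_move <- 0L
        moving <- TRUE
        while (f <= n_frames) {
            if (moving) {
                k_move <- k_move + 1L
                if (k_move > length(moves))
                    moves <- c(moves, rlnorm(n_guess, spec@move_meanlog,
                                             spec@move_sdlog))
                nf <- max(2L, round(moves[k_move] * fps))
                for (i in seq_len(min(nf, n_frames - f + 1L))) {
                    d <- target - pos
                    dl <- sqrt(sum(d^2))
                    if (dl <= step) {
                        pos <- target
                        target <- .chamberDraw(spec@chamber)
                    } else {
                        pos <- pos + d / dl * step
                    }
                    x[f] <- pos[1]; y[f] <- pos[2]
                    f <- f + 1L
                }
            } else {
                k_rest <- k_rest + 1L
                if (k_rest > length(rests)) rests <- c(rests, draw_rests(n_guess))
                nf <- round(rests[k_rest] * fps) + 1L
                if (f + nf - 1L > n_frames) {
                    # truncated trailing rest: fill as movement instead so the
                    # planted list contains only complete bouts
                    moving <- TRUE
                    next
                }
                # stop one stride beyond the last walking frame, so the rest
                # anchor is a genuinely new location
                d <- target - pos
                dl <- sqrt(sum(d^2))
                if (dl > step) {
                    pos <- pos + d / dl * step
                } else {
                    pos <- target
                    target <- .chamberDraw(spec@chamber)
                }
                if (spec@jitter_px > 0) {
                    r <- spec@jitter_px * sqrt(runif(nf))
                    th <- runif(nf, 0, 2 * pi)
                    x[f:(f + nf - 1L)] <- pos[1] + r * cos(th)
                    y[f:(f + nf - 1L)] <- pos[2] + r * sin(th)
                } else {
                    x[f:(f + nf - 1L)] <- pos[1]
                    y[f:(f + nf - 1L)] <- pos[2]
                }
                truth[[length(truth) + 1L]] <-
                    data.frame(onset_s = (f - 1L) / fps,
                               duration_s = (nf - 1L) / fps,
                               x_px = pos[1], y_px = pos[2])
                f <- f + nf
            }
            moving <- !moving
        }
        if (length(truth) == 0L)
            stop("'duration_s' too short to contain one complete rest bout")
        truth <- do.call(rbind, truth)
        Trajectory(times = (seq_len(n_frames) - 1) / fps, x = x, y = y,
                   fps = fps, chamber = spec@chamber, schedule = spec@schedule,
                   bouts_truth = truth)
    })
}

# Chamber interior mask on the rendered frame grid (logical matrix, row = y).
.chamberMask <- function(chamber, ny, nx, margin) {
    W <- chamber@width_mm * chamber@px_per_mm
    Lg <- chamber@length_mm * chamber@px_per_mm
    xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
    ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
    if (chamber@type == "1D") {
        xs >= margin & xs <= margin + W - 1 & ys >= margin & ys <= margin + Lg - 1
    } else {
        ((xs - margin - (W - 1) / 2) / (W / 2))^2 +
            ((ys - margin - (Lg - 1) / 2) / (Lg / 2))^2 <= 1
    }
}

#' Render a trajectory to a grayscale frame stack
#'
#' Draws the fly as a bright disk at each trajectory position on a dark
#' chamber interior surrounded by a brighter rim, so that background
#' subtraction and morphological chamber masking behave as on real
#' recordings. Optional Gaussian pixel noise emulates sensor noise.
#'
#' @param traj a [Trajectory-class].
#' @param fly_radius_px fly disk radius (px, >= 1).
#' @param fly_intensity,bg_intensity,surround_intensity gray levels of the
#'   fly, chamber interior and surround; the fly must be brighter than the
#'   interior.
#' @param margin_px pixels of surround around the chamber.
#' @param noise_sd per-pixel Gaussian noise SD (gray levels, 0 = noiseless).
#' @param seed RNG seed for the noise.
#' @return A [FrameStack-class].
#' @export
renderFrames <- function(traj, fly_radius_px = 2, fly_intensity = 200,
                         bg_intensity = 30, surround_intensity = 120,
                         margin_px = 4, noise_sd = 0, seed = NA) {
    stopifnot(is(traj, "Trajectory"))
    if (fly_radius_px < 1) stop("'fly_radius_px' must be >= 1")
    if (fly_intensity <= bg_intensity)
        stop("'fly_intensity' must exceed 'bg_intensity'")
    ch <- traj@chamber
    W <- ch@width_mm * ch@px_per_mm
    Lg <- ch@length_mm * ch@px_per_mm
    nx <- ceiling(W) + 2 * margin_px
    ny <- ceiling(Lg) + 2 * margin_px
    xs <- traj@x + margin_px
    ys <- traj@y + margin_px
    r <- fly_radius_px
    if (any(xs < r | xs > nx - 1 - r | ys < r | ys > ny - 1 - r))
        stop("trajectory leaves the frame bounds at the given fly radius")
    mask <- .chamberMask(ch, ny, nx, margin_px)
    bg <- matrix(surround_intensity, ny, nx)
    bg[mask] <- bg_intensity
    n <- length(xs)
    frames <- array(bg, dim = c(ny, nx, n))
    # disk stencil offsets around the rounded center
    off <- expand.grid(dy = -(r + 1):(r + 1), dx = -(r + 1):(r + 1))
    .withSeed(seed, {
        for (k in seq_len(n)) {
            cy <- ys[k]; cx <- xs[k]
            py <- round(cy) + off$dy; px <- round(cx) + off$dx
            keep <- (py - cy)^2 + (px - cx)^2 <= r^2 &
                py >= 0 & py < ny & px >= 0 & px < nx
            frames[cbind(py[keep] + 1L, px[keep] + 1L, k)] <- fly_intensity
        }
        if (noise_sd > 0)
            frames <- frames + array(rnorm(length(frames), 0, noise_sd),
                                     dim = dim(frames))
    })
    new("FrameStack", frames = frames, fps = traj@fps, chamber_mask = mask,
        schedule = traj@schedule)
}
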