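# Independent oracles and small constructors shared across tests.

# Rejection sampler for the two-phase law (survival-continuous form):
# head by rejection from a uniform proposal under the Pareto density,
# tail by direct exponential draws. Independent of the inverse-CDF path.
rejectionTwoPhase <- function(n, beta, K, lam, xmin) {
    SK <- (K / xmin)^(-beta)
    n_tail <- rbinom(1, n, SK)
    tail <- K + rexp(n_tail, rate = 1 / lam)
    n_head <- n - n_tail
    head <- numeric(0)
    fmax <- xmin^(-1)                      # t^-(b+1) max at xmin, up to scale
    while (length(head) < n_head) {
        m <- 4 * (n_head - length(head)) * ceiling((K - xmin) * beta / xmin)
        m <- min(m, 5e6)
        t <- runif(m, xmin, K)
        acc <- runif(m) < (t / xmin)^(-(beta + 1))
        head <- c(head, t[acc])
    }
    sample(c(head[seq_len(n_head)], tail))
}

# Disk of radius r (px) stamped onto matrix m at 0-based center (cx, cy).
stampDisk <- function(m, cx, cy, r, value) {
    ny <- nrow(m); nx <- ncol(m)
    for (py in max(0, floor(cy - r)):min(ny - 1, ceiling(cy + r)))
        for (px in max(0, floor(cx - r)):min(nx - 1, ceiling(cx + r)))
            if ((py - cy)^2 + (px - cx)^2 <= r^2)
                m[py + 1, px + 1] <- value
    m
}

# A short synthetic video spec used by tracking round-trip tests.
roundTripSpec <- function(duration_s = 600, seed = 11, jitter_px = 0.5) {
    TrajectorySpec(duration_s = duration_s, fps = 10, move_speed_px_s = 40,
                   jitter_px = jitter_px,
                   rest_spec = TwoPhaseSpec(beta = 0.8, K = 60, lam = 120,
                                            xmin = 2, n_bouts = 1),
                   seed = seed)
}

# A short clip with brief rests, for rendering/masking tests where only a
# valid trajectory is needed.
shortClipSpec <- function(duration_s = 20, fps = 10, seed = 2) {
    TrajectorySpec(duration_s = duration_s, fps = fps, move_speed_px_s = 30,
                   move_meanlog = log(1.5), move_sdlog = 0.4,
                   rest_spec = TwoPhaseSpec(beta = 0.8, K = 3, lam = 3,
                                            xmin = 1, n_bouts = 1),
                   seed = seed)
}

# Trajectory with explicitly planted frame-level rest segments.
# segs: list of list(pos = c(x, y), frames = k) alternating move/rest is up
# to the caller; returns a Trajectory at the given fps.
manualTrajectory <- function(xy, fps = 25, chamber = Chamber(),
                             schedule = LightSchedule()) {
    Trajectory(times = (seq_len(nrow(xy)) - 1) / fps, x = xy[, 1],
               y = xy[, 2], fps = fps, chamber = chamber, schedule = schedule)
}
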