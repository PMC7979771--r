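# Rest-bout extraction from trajectories and circadian phase labeling.

#' Extract rest bouts from a trajectory
#'
#' A rest bout is a maximal run of frames whose positions stay within
#' \code{tol_px} of the run's anchor location (the first frame of the run)
#' and whose span reaches \code{min_rest_s}. Duration is measured on the
#' frame grid, between the first and last stationary frame. Bouts are
#' disjoint and ordered by onset.
#'
#' @param traj a [Trajectory-class], or a data.frame with columns
#'   \code{t_s}, \code{x_px}, \code{y_px} (then \code{fps} is required).
#' @param min_rest_s minimum bout duration (s); rests shorter than this are
#'   treated as part of activity.
#' @param tol_px "same location" tolerance from the anchor (px). With
#'   sub-pixel centroid flutter of radius j, any \code{tol_px >= 2 j} keeps
#'   a bout in one piece.
#' @param fps frame rate, only for data.frame input.
#' @param schedule optional [LightSchedule-class] used to label phases;
#'   defaults to the trajectory's schedule.
#' @return data.frame with \code{onset_s}, \code{duration_s}, \code{phase},
#'   \code{x_px}, \code{y_px}; the frame rate is attached as attribute
#'   \code{"fps"}.
#' @examples
#' sp <- TrajectorySpec(duration_s = 300, jitter_px = 0, seed = 2,
#'                      rest_spec = TwoPhaseSpec(K = 20, lam = 40, n_bouts = 1))
#' traj <- makeTrajectory(sp)
#' b <- extractRestBouts(traj, tol_px = 0)
#' @export
extractRestBouts <- function(traj, min_rest_s = 1.0, tol_px = 1.0, fps = NULL,
                             schedule = NULL) {
    if (is(traj, "Trajectory")) {
        times <- traj@times; x <- traj@x; y <- traj@y
        fps <- traj@fps
        if (is.null(schedule)) schedule <- traj@schedule
    } else {
        stopifnot(is.data.frame(traj),
                  all(c("t_s", "x_px", "y_px") %in% names(traj)))
        if (is.null(fps)) stop("'fps' is required for data.frame input")
        times <- traj$t_s; x <- traj$x_px; y <- traj$y_px
    }
    n <- length(times)
    if (n == 0L) stop("empty trajectory")
    if (n > 1L && any(diff(times) <= 0))
        stop("trajectory times must be strictly increasing")
    tol2 <- tol_px^2
    out <- list()
    a <- 1L
    while (a <= n) {
        # find the first frame farther than tol from the anchor, scanning in
        # doubling windows so short (movement) runs stay cheap
        brk <- NA_integer_
        lo <- a + 1L; win <- 64L
        while (lo <= n) {
            hi <- min(n, lo + win - 1L)
            seg <- lo:hi
            far <- (x[seg] - x[a])^2 + (y[seg] - y[a])^2 > tol2
            if (any(far)) {
                brk <- seg[which(far)[1L]]
                break
            }
            lo <- hi + 1L
            win <- win * 2L
        }
        last <- if (is.na(brk)) n else brk - 1L
        dur <- times[last] - times[a]
        if (dur >= min_rest_s)
            out[[length(out) + 1L]] <- c(times[a], dur, x[a], y[a])
        a <- if (is.na(brk)) n + 1L else brk
    }
    if (length(out)) {
        m <- do.call(rbind, out)
        bouts <- data.frame(onset_s = m[, 1L], duration_s = m[, 2L],
                            phase = NA_character_, x_px = m[, 3L],
                            y_px = m[, 4L])
    } else {
        bouts <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                            phase = character(0), x_px = numeric(0),
                            y_px = numeric(0))
    }
    if (!is.null(schedule)) bouts <- assignPhase(bouts, schedule)
    attr(bouts, "fps") <- fps
    bouts
}

#' Label bouts with circadian phase
#'
#' Labels each bout "day" or "night" by the Zeitgeber time of its onset.
#' Bouts spanning a light transition keep their onset label. Under constant
#' darkness (DD) the labels follow the hypothetical light-dark schedule the
#' flies were entrained to, so "day" still means the ZT window in which the
#' lights would be on.
#'
#' @param bouts data.frame with an \code{onset_s} column.
#' @param schedule a [LightSchedule-class].
#' @return The bouts data.frame with its \code{phase} column filled.
#' @export
assignPhase <- function(bouts, schedule) {
    stopifnot(is(schedule, "LightSchedule"))
    validObject(schedule)
    fps <- attr(bouts, "fps")
    zt <- (schedule@t0_zt + bouts$onset_s / 3600) %% 24
    bouts$phase <- ifelse(.isLight(zt, schedule), "day", "night")
    attr(bouts, "fps") <- fps
    bouts
}
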