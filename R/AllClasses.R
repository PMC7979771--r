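#' @import methods
#' @importFrom stats runif rnorm rexp rlnorm ks.test t.test cor optimize
#'   quantile sd complete.cases hclust as.dist setNames
NULL

.checkScalar <- function(x, name, positive = FALSE, integerish = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        return(sprintf("'%s' must be a single finite number", name))
    if (positive && x <= 0)
        return(sprintf("'%s' must be > 0", name))
    if (integerish && abs(x - round(x)) > 1e-8)
        return(sprintf("'%s' must be a whole number", name))
    NULL
}

#' Two-phase rest-bout duration law
#'
#' Parameter container for the two-phase bout-duration distribution: the
#' survival function is a power law \eqn{P(X>t) = (t/x_{min})^{-\beta}} on
#' \eqn{[x_{min}, K]} glued continuously at the sleep latency \eqn{K} to an
#' exponential tail with mean excess \eqn{\lambda}. \code{beta} is the
#' survival exponent (the active index), so the head density exponent is
#' \code{beta + 1}.
#'
#' @slot beta survival power-law exponent (dimensionless, > 0).
#' @slot K sleep latency, the changepoint between the two phases (s).
#' @slot lam mean of the exponential excess beyond \code{K} (s).
#' @slot xmin lower support bound (s); \code{0 < xmin < K}.
#' @slot n_bouts number of bouts to draw.
#' @slot seed integer RNG seed, or \code{NA} to use the current RNG state.
#'
#' @seealso [sampleTwoPhase()], [TwoPhaseSpec()]
#' @export
setClass("TwoPhaseSpec",
    representation(beta = "numeric", K = "numeric", lam = "numeric",
                   xmin = "numeric", n_bouts = "numeric", seed = "numeric"),
    prototype(beta = 0.8, K = 200, lam = 1000, xmin = 1, n_bouts = 1000,
              seed = NA_real_))

setValidity("TwoPhaseSpec", function(object) {
    msgs <- c(
        .checkScalar(object@beta, "beta", positive = TRUE),
        .checkScalar(object@K, "K", positive = TRUE),
        .checkScalar(object@lam, "lam", positive = TRUE),
        .checkScalar(object@xmin, "xmin", positive = TRUE),
        .checkScalar(object@n_bouts, "n_bouts", integerish = TRUE))
    if (is.null(msgs) || length(msgs) == 0L) {
        if (object@K <= object@xmin)
            msgs <- c(msgs, "'K' must exceed 'xmin'")
        if (object@n_bouts < 1)
            msgs <- c(msgs, "'n_bouts' must be >= 1")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a TwoPhaseSpec
#'
#' @param beta,K,lam,xmin,n_bouts,seed see the class slots.
#' @return A validated [TwoPhaseSpec-class] object.
#' @examples
#' spec <- TwoPhaseSpec(beta = 0.8, K = 200, lam = 1000, n_bouts = 500, seed = 1)
#' d <- sampleTwoPhase(spec)
#' @export
TwoPhaseSpec <- function(beta = 0.8, K = 200, lam = 1000, xmin = 1,
                         n_bouts = 1000, seed = NA) {
    new("TwoPhaseSpec", beta = as.numeric(beta), K = as.numeric(K),
        lam = as.numeric(lam), xmin = as.numeric(xmin),
        n_bouts = as.numeric(n_bouts), seed = as.numeric(seed))
}

#' Observation chamber geometry
#'
#' @slot type "1D" (tubular) or "2D" (elliptic). The y axis is the chamber's
#'   long axis in both cases.
#' @slot length_mm extent of the long (y) axis in mm.
#' @slot width_mm extent of the short (x) axis in mm.
#' @slot px_per_mm pixel scale of the rendered/recorded image.
#' @export
setClass("Chamber",
    representation(type = "character", length_mm = "numeric",
                   width_mm = "numeric", px_per_mm = "numeric"),
    prototype(type = "1D", length_mm = 78, width_mm = 5, px_per_mm = 1.25))

setValidity("Chamber", function(object) {
    msgs <- character()
    if (!object@type %in% c("1D", "2D"))
        msgs <- c(msgs, "'type' must be \"1D\" or \"2D\"")
    for (s in c("length_mm", "width_mm", "px_per_mm")) {
        m <- .checkScalar(slot(object, s), s, positive = TRUE)
        if (!is.null(m)) msgs <- c(msgs, m)
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a Chamber
#'
#' Defaults are the tubular chamber (5 x 78 mm); use
#' \code{Chamber("2D", length_mm = 50, width_mm = 30)} for the elliptic arena.
#'
#' @param type,length_mm,width_mm,px_per_mm see the class slots.
#' @export
Chamber <- function(type = c("1D", "2D"), length_mm = NULL, width_mm = NULL,
                    px_per_mm = 1.25) {
    type <- match.arg(type)
    if (is.null(length_mm)) length_mm <- if (type == "1D") 78 else 50
    if (is.null(width_mm))  width_mm  <- if (type == "1D") 5  else 30
    new("Chamber", type = type, length_mm = as.numeric(length_mm),
        width_mm = as.numeric(width_mm), px_per_mm = as.numeric(px_per_mm))
}

#' Light schedule
#'
#' Zeitgeber-time bookkeeping for a recording. Under constant darkness
#' (\code{condition = "DD"}) phase labels follow the hypothetical light-dark
#' schedule the flies were entrained to.
#'
#' @slot condition "LD" or "DD".
#' @slot lights_on_zt,lights_off_zt ZT hours of lights-on / lights-off.
#' @slot t0_zt ZT hour of the first recorded frame.
#' @export
setClass("LightSchedule",
    representation(condition = "character", lights_on_zt = "numeric",
                   lights_off_zt = "numeric", t0_zt = "numeric"),
    prototype(condition = "LD", lights_on_zt = 0, lights_off_zt = 12,
              t0_zt = 0))

setValidity("LightSchedule", function(object) {
    msgs <- character()
    if (!object@condition %in% c("LD", "DD"))
        msgs <- c(msgs, "'condition' must be \"LD\" or \"DD\"")
    for (s in c("lights_on_zt", "lights_off_zt", "t0_zt")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v < 0 || v >= 24)
            msgs <- c(msgs, sprintf("'%s' must be in [0, 24)", s))
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a LightSchedule
#' @param condition,lights_on_zt,lights_off_zt,t0_zt see the class slots.
#' @export
LightSchedule <- function(condition = c("LD", "DD"), lights_on_zt = 0,
                          lights_off_zt = 12, t0_zt = 0) {
    new("LightSchedule", condition = match.arg(condition),
        lights_on_zt = as.numeric(lights_on_zt),
        lights_off_zt = as.numeric(lights_off_zt), t0_zt = as.numeric(t0_zt))
}

#' Synthetic trajectory specification
#'
#' Describes an alternating move/rest trajectory: rest durations are drawn
#' from the two-phase law, movement bouts from a log-normal (movement bouts
#' are spacers, not part of the fitted model), and movement is a bounded
#' random walk inside the chamber at the given speed.
#'
#' @slot chamber a [Chamber-class].
#' @slot fps frame rate (frames/s).
#' @slot duration_s recording length (s).
#' @slot move_speed_px_s walking speed while active (px/s).
#' @slot rest_spec a [TwoPhaseSpec-class] for rest-bout durations.
#' @slot move_meanlog,move_sdlog log-normal parameters of active-bout
#'   durations (s).
#' @slot jitter_px half-width of the uniform positional noise applied to
#'   resting frames (sub-pixel centroid flutter).
#' @slot schedule a [LightSchedule-class].
#' @slot seed RNG seed or NA.
#' @export
setClass("TrajectorySpec",
    representation(chamber = "Chamber", fps = "numeric", duration_s = "numeric",
                   move_speed_px_s = "numeric", rest_spec = "TwoPhaseSpec",
                   move_meanlog = "numeric", move_sdlog = "numeric",
                   jitter_px = "numeric", schedule = "LightSchedule",
                   seed = "numeric"))

setValidity("TrajectorySpec", function(object) {
    msgs <- c(
        .checkScalar(object@fps, "fps", positive = TRUE),
        .checkScalar(object@duration_s, "duration_s", positive = TRUE),
        .checkScalar(object@move_speed_px_s, "move_speed_px_s", positive = TRUE))
    if (length(object@jitter_px) != 1L || object@jitter_px < 0)
        msgs <- c(msgs, "'jitter_px' must be a single number >= 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a TrajectorySpec
#' @param chamber,fps,duration_s,move_speed_px_s,rest_spec,move_meanlog,move_sdlog,jitter_px,schedule,seed
#'   see the class slots.
#' @export
TrajectorySpec <- function(chamber = Chamber(), fps = 25, duration_s = 3600,
                           move_speed_px_s = 10,
                           rest_spec = TwoPhaseSpec(),
                           move_meanlog = log(5), move_sdlog = 0.6,
                           jitter_px = 0.5, schedule = LightSchedule(),
                           seed = NA) {
    new("TrajectorySpec", chamber = chamber, fps = as.numeric(fps),
        duration_s = as.numeric(duration_s),
        move_speed_px_s = as.numeric(move_speed_px_s), rest_spec = rest_spec,
        move_meanlog = as.numeric(move_meanlog),
        move_sdlog = as.numeric(move_sdlog), jitter_px = as.numeric(jitter_px),
        schedule = schedule, seed = as.numeric(seed))
}

#' Fly trajectory
#'
#' Per-frame fly locations. \code{y} runs along the chamber's long axis;
#' coordinates are 0-based pixel centers.
#'
#' @slot times time of each frame (s from recording start), strictly
#'   increasing.
#' @slot x,y per-frame coordinates (px).
#' @slot fps nominal frame rate (frames/s).
#' @slot chamber the [Chamber-class] the fly was recorded in.
#' @slot schedule the [LightSchedule-class] of the recording.
#' @slot bouts_truth for synthetic trajectories, the planted rest-bout table
#'   (ground truth); empty data.frame otherwise.
#' @export
setClass("Trajectory",
    representation(times = "numeric", x = "numeric", y = "numeric",
                   fps = "numeric", chamber = "Chamber",
                   schedule = "LightSchedule", bouts_truth = "data.frame"),
    prototype(bouts_truth = data.frame()))

setValidity("Trajectory", function(object) {
    msgs <- character()
    n <- length(object@times)
    if (length(object@x) != n || length(object@y) != n)
        msgs <- c(msgs, "'times', 'x' and 'y' must have equal length")
    if (n > 1 && any(diff(object@times) <= 0))
        msgs <- c(msgs, "'times' must be strictly increasing")
    if (!is.null(.checkScalar(object@fps, "fps", positive = TRUE)))
        msgs <- c(msgs, "'fps' must be a single number > 0")
    if (length(msgs)) msgs else TRUE
})

#' Construct a Trajectory
#' @param times,x,y,fps,chamber,schedule,bouts_truth see the class slots.
#' @export
Trajectory <- function(times, x, y, fps, chamber = Chamber(),
                       schedule = LightSchedule(),
                       bouts_truth = data.frame()) {
    new("Trajectory", times = as.numeric(times), x = as.numeric(x),
        y = as.numeric(y), fps = as.numeric(fps), chamber = chamber,
        schedule = schedule, bouts_truth = bouts_truth)
}

#' Rendered frame stack
#'
#' A grayscale video as a 3-D array (rows = y, cols = x, slices = frames),
#' plus the renderer's ground-truth chamber mask used by round-trip tests.
#'
#' @slot frames numeric array \code{[ny, nx, nframes]}.
#' @slot fps frame rate.
#' @slot chamber_mask logical matrix marking the chamber interior.
#' @slot schedule the recording's [LightSchedule-class].
#' @export
setClass("FrameStack",
    representation(frames = "array", fps = "numeric",
                   chamber_mask = "matrix", schedule = "LightSchedule"))

setValidity("FrameStack", function(object) {
    msgs <- character()
    if (length(dim(object@frames)) != 3L)
        msgs <- c(msgs, "'frames' must be a 3-D array")
    else if (!all(dim(object@frames)[1:2] == dim(object@chamber_mask)))
        msgs <- c(msgs, "'chamber_mask' must match the frame shape")
    if (length(msgs)) msgs else TRUE
})

#' Fitted sleep parameters for one fly and phase
#'
#' The five-parameter sleep signature plus fit diagnostics. \code{beta} is
#' the survival power-law exponent of short rests (active index), \code{K}
#' the sleep latency located by the KS changepoint scan, \code{lam} the mean
#' exponential sleep duration, \code{N} the number of sleep bouts
#' (rests longer than \code{K}) and \code{total = N * lam} the estimated
#' total sleep time, which excludes time spent in the latency phase.
#'
#' @slot beta,K,lam,N,total the five parameters (see Description).
#' @slot xmin lower bound of the power-law fit (s).
#' @slot ks_p_at_K KS p-value at the accepted latency.
#' @slot n_head,n_tail sample sizes of head and tail fits (\code{N == n_tail}).
#' @slot beta_se MLE standard error of \code{beta}.
#' @slot delta_aic_gauss_minus_exp AIC(half-gaussian) - AIC(exponential) on
#'   the tail excesses; positive favors the exponential sleep phase.
#' @slot phase phase label ("day", "night" or "" when unlabeled).
#' @export
setClass("SleepParams",
    representation(beta = "numeric", K = "numeric", lam = "numeric",
                   N = "numeric", total = "numeric", xmin = "numeric",
                   ks_p_at_K = "numeric", n_head = "numeric",
                   n_tail = "numeric", beta_se = "numeric",
                   delta_aic_gauss_minus_exp = "numeric", phase = "character"),
    prototype(phase = "", delta_aic_gauss_minus_exp = NA_real_,
              beta_se = NA_real_))

setValidity("SleepParams", function(object) {
    msgs <- character()
    if (is.finite(object@beta) && object@beta <= 0)
        msgs <- c(msgs, "'beta' must be > 0")
    if (is.finite(object@lam) && object@lam <= 0)
        msgs <- c(msgs, "'lam' must be > 0")
    if (is.finite(object@total) && is.finite(object@N) && is.finite(object@lam) &&
        !isTRUE(all.equal(object@total, object@N * object@lam)))
        msgs <- c(msgs, "'total' must equal N * lam")
    if (is.finite(object@N) && is.finite(object@n_tail) &&
        object@N != object@n_tail)
        msgs <- c(msgs, "'N' must equal 'n_tail'")
    if (length(msgs)) msgs else TRUE
})

#' Empirical survival curve
#'
#' Complementary cumulative probability \eqn{P(X > t)} evaluated at the
#' sorted unique observed durations.
#'
#' @slot t sorted unique durations (s).
#' @slot p survival probabilities, non-increasing in \code{[0, 1]}.
#' @slot n sample size.
#' @export
setClass("SurvivalCurve",
    representation(t = "numeric", p = "numeric", n = "numeric"))

setValidity("SurvivalCurve", function(object) {
    msgs <- character()
    if (length(object@t) != length(object@p))
        msgs <- c(msgs, "'t' and 'p' must have equal length")
    if (any(diff(object@t) <= 0))
        msgs <- c(msgs, "'t' must be strictly increasing")
    if (any(object@p < 0) || any(object@p > 1))
        msgs <- c(msgs, "'p' must lie in [0, 1]")
    if (any(diff(object@p) > 1e-12))
        msgs <- c(msgs, "'p' must be non-increasing")
    if (length(msgs)) msgs else TRUE
})

#' Brain-state random-walk model parameters
#'
#' Configuration of the two-hemisphere brain-state walk: each hemisphere
#' occupies one of \code{L} quietness states; the joint state (i, j)
#' performs a nearest-neighbor random walk with exponential dwell times of
#' mean \eqn{\theta = (i^2+j^2)^{a/2}}; the bout ends when either hemisphere
#' reaches state 0 (wake boundary). Past the distance threshold
#' \code{w_thresh} the fly is asleep and additionally wakes at constant rate
#' \code{epsilon}.
#'
#' @slot L states per hemisphere.
#' @slot a dwell-time exponent (quieter states are slower to leave).
#' @slot w_thresh sleep threshold distance from the origin (state units).
#' @slot epsilon wake rate in the sleep phase (1/s).
#' @slot start_state integer vector (i, j), the state entered at rest onset.
#' @slot n_bouts bouts to simulate.
#' @slot seed RNG seed or NA.
#' @slot sleep_dynamics "continue" (walk continues past the threshold while
#'   an independent epsilon wake clock runs inside the sleep region) or
#'   "absorb" (bout ends at threshold crossing plus an Exp(1/epsilon) sleep
#'   time).
#' @slot threshold_metric "euclidean" (distance from origin) or "manhattan"
#'   (i + j).
#' @export
setClass("BrainStateModel",
    representation(L = "numeric", a = "numeric", w_thresh = "numeric",
                   epsilon = "numeric", start_state = "numeric",
                   n_bouts = "numeric", seed = "numeric",
                   sleep_dynamics = "character", threshold_metric = "character"),
    prototype(L = 50, a = 1, w_thresh = 20, epsilon = 1e-3,
              start_state = c(1, 1), n_bouts = 1000, seed = NA_real_,
              sleep_dynamics = "continue", threshold_metric = "euclidean"))

setValidity("BrainStateModel", function(object) {
    msgs <- c(
        .checkScalar(object@L, "L", positive = TRUE, integerish = TRUE),
        .checkScalar(object@epsilon, "epsilon", positive = TRUE),
        .checkScalar(object@w_thresh, "w_thresh", positive = TRUE),
        .checkScalar(object@n_bouts, "n_bouts", positive = TRUE,
                     integerish = TRUE))
    if (length(msgs) == 0L) {
        if (object@w_thresh > sqrt(2) * object@L)
            msgs <- c(msgs, "'w_thresh' must be <= sqrt(2) * L")
        if (length(object@start_state) != 2L ||
            any(object@start_state < 1) || any(object@start_state > object@L))
            msgs <- c(msgs, "'start_state' must be two coordinates in [1, L]")
        if (!object@sleep_dynamics %in% c("continue", "absorb"))
            msgs <- c(msgs, "'sleep_dynamics' must be \"continue\" or \"absorb\"")
        if (!object@threshold_metric %in% c("euclidean", "manhattan"))
            msgs <- c(msgs, "'threshold_metric' must be \"euclidean\" or \"manhattan\"")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a BrainStateModel
#' @param L,a,w_thresh,epsilon,start_state,n_bouts,seed,sleep_dynamics,threshold_metric
#'   see the class slots.
#' @examples
#' m <- BrainStateModel(L = 10, a = 1, w_thresh = 6, epsilon = 0.01,
#'                      n_bouts = 200, seed = 7)
#' res <- simulateBouts(m)
#' @export
BrainStateModel <- function(L = 50, a = 1, w_thresh = 20, epsilon = 1e-3,
                            start_state = c(1, 1), n_bouts = 1000, seed = NA,
                            sleep_dynamics = c("continue", "absorb"),
                            threshold_metric = c("euclidean", "manhattan")) {
    new("BrainStateModel", L = as.numeric(L), a = as.numeric(a),
        w_thresh = as.numeric(w_thresh), epsilon = as.numeric(epsilon),
        start_state = as.numeric(start_state), n_bouts = as.numeric(n_bouts),
        seed = as.numeric(seed), sleep_dynamics = match.arg(sleep_dynamics),
        threshold_metric = match.arg(threshold_metric))
}

#' Brain-state simulation result
#'
#' @slot durations simulated rest-bout durations (s).
#' @slot slept whether each bout crossed the sleep threshold.
#' @slot latency_component time from bout onset to the first threshold
#'   crossing (s); NA for bouts that never slept.
#' @slot model the generating [BrainStateModel-class].
#' @export
setClass("SimResult",
    representation(durations = "numeric", slept = "logical",
                   latency_component = "numeric", model = "BrainStateModel"))

setValidity("SimResult", function(object) {
    msgs <- character()
    n <- length(object@durations)
    if (length(object@slept) != n || length(object@latency_component) != n)
        msgs <- c(msgs, "fields must have equal length")
    if (any(object@durations <= 0))
        msgs <- c(msgs, "'durations' must be positive")
    ok <- object@slept & is.finite(object@latency_component)
    if (any(object@latency_component[ok] > object@durations[ok] + 1e-9))
        msgs <- c(msgs, "'latency_component' must not exceed 'duration'")
    if (length(msgs)) msgs else TRUE
})
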