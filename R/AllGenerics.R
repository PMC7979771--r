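#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: frame times and
#' coordinates of a [Trajectory-class], the five fitted sleep parameters of
#' a [SleepParams-class], the grid of a [SurvivalCurve-class] and the
#' simulated durations of a [SimResult-class].
#'
#' @param object an object of the documented class.
#' @return The requested slot value (numeric unless stated otherwise).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("coordX", function(object) standardGeneric("coordX"))
#' @rdname accessors
#' @export
setGeneric("coordY", function(object) standardGeneric("coordY"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("activeIndex", function(object) standardGeneric("activeIndex"))
#' @rdname accessors
#' @export
setGeneric("sleepLatency", function(object) standardGeneric("sleepLatency"))
#' @rdname accessors
#' @export
setGeneric("sleepDuration", function(object) standardGeneric("sleepDuration"))
#' @rdname accessors
#' @export
setGeneric("nSleepBouts", function(object) standardGeneric("nSleepBouts"))
#' @rdname accessors
#' @export
setGeneric("totalSleep", function(object) standardGeneric("totalSleep"))
#' @rdname accessors
#' @export
setGeneric("survTimes", function(object) standardGeneric("survTimes"))
#' @rdname accessors
#' @export
setGeneric("survProb", function(object) standardGeneric("survProb"))
#' @rdname accessors
#' @export
setGeneric("boutDurations", function(object) standardGeneric("boutDurations"))

#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(object) object@times)
#' @rdname accessors
setMethod("coordX", "Trajectory", function(object) object@x)
#' @rdname accessors
setMethod("coordY", "Trajectory", function(object) object@y)
#' @rdname accessors
setMethod("frameRate", "Trajectory", function(object) object@fps)
#' @rdname accessors
setMethod("frameRate", "FrameStack", function(object) object@fps)
#' @rdname accessors
setMethod("activeIndex", "SleepParams", function(object) object@beta)
#' @rdname accessors
setMethod("sleepLatency", "SleepParams", function(object) object@K)
#' @rdname accessors
setMethod("sleepDuration", "SleepParams", function(object) object@lam)
#' @rdname accessors
setMethod("nSleepBouts", "SleepParams", function(object) object@N)
#' @rdname accessors
setMethod("totalSleep", "SleepParams", function(object) object@total)
#' @rdname accessors
setMethod("survTimes", "SurvivalCurve", function(object) object@t)
#' @rdname accessors
setMethod("survProb", "SurvivalCurve", function(object) object@p)
#' @rdname accessors
setMethod("boutDurations", "SimResult", function(object) object@durations)
#' @rdname accessors
setMethod("boutDurations", "Trajectory", function(object) object@bouts_truth)

setMethod("show", "Trajectory", function(object) {
    n <- length(object@times)
    cat(sprintf("Trajectory: %d frames @ %g fps (%.1f s), %s chamber\n",
                n, object@fps, if (n) diff(range(object@times)) else 0,
                object@chamber@type))
    if (nrow(object@bouts_truth))
        cat(sprintf("  planted rest bouts: %d\n", nrow(object@bouts_truth)))
})

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("FrameStack: %d frames of %d x %d px @ %g fps\n",
                d[3], d[1], d[2], object@fps))
})

setMethod("show", "SleepParams", function(object) {
    cat(sprintf("SleepParams%s\n",
        if (nzchar(object@phase)) sprintf(" [%s]", object@phase) else ""))
    cat(sprintf("  beta (active index): %.3f (SE %.3f, n_head = %d)\n",
                object@beta, object@beta_se, as.integer(object@n_head)))
    cat(sprintf("  K (sleep latency):   %.1f s (KS p = %.3f)\n",
                object@K, object@ks_p_at_K))
    cat(sprintf("  lambda (sleep dur.): %.1f s\n", object@lam))
    cat(sprintf("  N (sleep bouts):     %d\n", as.integer(object@N)))
    cat(sprintf("  Total (N x lambda):  %.1f s\n", object@total))
})

setMethod("show", "SurvivalCurve", function(object) {
    cat(sprintf("SurvivalCurve: %d support points, n = %d, t in [%g, %g] s\n",
                length(object@t), as.integer(object@n),
                min(object@t), max(object@t)))
})

setMethod("show", "SimResult", function(object) {
    cat(sprintf(
        "SimResult: %d bouts (%.1f%% slept), mean duration %.1f s\n",
        length(object@durations), 100 * mean(object@slept),
        mean(object@durations)))
})

setMethod("show", "TwoPhaseSpec", function(object) {
    cat(sprintf(
        "TwoPhaseSpec: beta = %g, K = %g s, lambda = %g s, xmin = %g s, n = %d\n",
        object@beta, object@K, object@lam, object@xmin,
        as.integer(object@n_bouts)))
})
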