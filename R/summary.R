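# Descriptive and comparative outputs: activity/sleep profiles on the
# 30-min Zeitgeber grid, Spearman parameter correlations with hierarchical
# clustering, group tests, and the sleep-history independence check.

# Split the interval [start, end) (seconds on the unfolded ZT clock) over a
# bin grid of width `bw`, fold to one 24 h day, and accumulate seconds per
# folded bin. Returns a vector of length 86400/bw.
.foldIntervals <- function(start, end, bw) {
    nb <- as.integer(86400 / bw)
    acc <- numeric(nb)
    for (k in seq_along(start)) {
        s <- start[k]
        while (s < end[k]) {
            e <- min(end[k], (floor(s / bw) + 1) * bw)
            b <- (floor(s / bw) %% nb) + 1
            acc[b] <- acc[b] + (e - s)
            s <- e
        }
    }
    acc
}

#' Sleep profile on the 30-min Zeitgeber grid
#'
#' Minutes asleep per 30-min ZT bin, averaged across recording days. A
#' bout qualifies as sleep when its duration exceeds \code{threshold_s}
#' (the fly's fitted sleep latency K, or 300 s for the legacy 5-min
#' convention); qualifying bouts contribute their full span, split
#' proportionally across the bins they cover.
#'
#' @param bouts bout table from [extractRestBouts()].
#' @param threshold_s sleep threshold (s).
#' @param schedule a [LightSchedule-class].
#' @param recording_s total recording length (s), used to count days.
#' @param bin_minutes bin width (min).
#' @return data.frame with \code{bin_start_zt} (h), \code{minutes}
#'   (per-day average, in [0, bin_minutes]) and \code{is_light}.
#' @export
sleepProfile <- function(bouts, threshold_s, schedule, recording_s,
                         bin_minutes = 30) {
    stopifnot(threshold_s > 0, recording_s > 0)
    bw <- bin_minutes * 60
    q <- bouts[bouts$duration_s > threshold_s, , drop = FALSE]
    t0 <- schedule@t0_zt * 3600
    acc <- .foldIntervals(t0 + q$onset_s, t0 + q$onset_s + q$duration_s, bw)
    n_days <- recording_s / 86400
    zt <- seq(0, 24 - bin_minutes / 60, by = bin_minutes / 60)
    data.frame(bin_start_zt = zt, minutes = acc / 60 / n_days,
               is_light = .isLight(zt, schedule))
}

#' Activity profile on the 30-min Zeitgeber grid
#'
#' Beam crossings per 30-min ZT bin (DAMS emulation), averaged across
#' recording days.
#'
#' @param x a [Trajectory-class], or the crossings data.frame from
#'   [virtualBeamCrossings()].
#' @param schedule a [LightSchedule-class]; taken from the trajectory when
#'   omitted.
#' @param recording_s recording length (s); inferred from a trajectory.
#' @param bin_minutes bin width (min).
#' @return data.frame with \code{bin_start_zt}, \code{crossings} (per-day
#'   average) and \code{is_light}.
#' @export
activityProfile <- function(x, schedule = NULL, recording_s = NULL,
                            bin_minutes = 30) {
    if (is(x, "Trajectory")) {
        if (is.null(schedule)) schedule <- x@schedule
        if (is.null(recording_s)) recording_s <- max(x@times)
        x <- virtualBeamCrossings(x, bin_minutes = bin_minutes)
    }
    stopifnot(is.data.frame(x), all(c("bin_start_s", "crossings") %in% names(x)))
    if (is.null(schedule) || is.null(recording_s))
        stop("'schedule' and 'recording_s' are required for data.frame input")
    bw <- bin_minutes * 60
    nb <- as.integer(86400 / bw)
    zt_bin <- (floor(schedule@t0_zt * 3600 / bw) + x$bin_start_s / bw) %% nb
    acc <- vapply(seq_len(nb) - 1L,
                  function(b) sum(x$crossings[zt_bin == b]), numeric(1))
    n_days <- recording_s / 86400
    zt <- (seq_len(nb) - 1L) * bin_minutes / 60
    data.frame(bin_start_zt = zt, crossings = acc / n_days,
               is_light = .isLight(zt, schedule))
}

#' Spearman correlation structure of the sleep parameters
#'
#' Pairwise Spearman rank correlations (tie-corrected) between the ten
#' per-fly parameters (five per phase), and average-linkage hierarchical
#' clustering on the distance 1 - rho. Constant columns, whose rank
#' correlation is undefined, are flagged and their pairs set to NA (treated
#' as maximally distant in the clustering).
#'
#' @param param_table data.frame or matrix of per-fly parameters (>= 5
#'   rows; columns are parameters such as beta_day, ..., total_night).
#' @return list with \code{rho} (correlation matrix), \code{hclust},
#'   \code{order} (leaf order), \code{flagged_constant} (column names).
#' @export
parameterCorrelations <- function(param_table) {
    m <- as.matrix(param_table)
    stopifnot(is.numeric(m))
    if (nrow(m) < 5) stop("need at least 5 flies")
    const <- apply(m, 2, function(v) {
        v <- v[is.finite(v)]
        length(v) < 2 || diff(range(v)) == 0
    })
    rho <- suppressWarnings(cor(m, method = "spearman",
                                use = "pairwise.complete.obs"))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
    diag(rho) <- 1
    d <- 1 - rho
    d[is.na(d)] <- 2                      # maximal 1 - rho distance
    hc <- hclust(as.dist(d), method = "average")
    list(rho = rho, hclust = hc, order = hc$order,
         flagged_constant = colnames(m)[const])
}

#' Two-group comparison of a sleep parameter
#'
#' Two-tailed two-sample t test: Student's (equal variances) or Welch's
#' (default), following the 5% reporting convention.
#'
#' @param sample_a,sample_b numeric vectors (n >= 2 each).
#' @param equal_var assume equal variances (Student) instead of Welch.
#' @return list with \code{statistic}, \code{p_value}, \code{df},
#'   \code{mean_a}, \code{mean_b}, \code{method}.
#' @export
groupCompare <- function(sample_a, sample_b, equal_var = FALSE) {
    sample_a <- sample_a[is.finite(sample_a)]
    sample_b <- sample_b[is.finite(sample_b)]
    if (length(sample_a) < 2 || length(sample_b) < 2)
        stop("each group needs at least 2 finite observations")
    tt <- t.test(sample_a, sample_b, var.equal = equal_var)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), mean_a = mean(sample_a),
         mean_b = mean(sample_b), method = tt$method)
}

#' Does sleep history predict the next sleep bout?
#'
#' Spearman correlation between each sleep bout's duration in the sleep
#' phase (duration minus the latency K) and the total sleep accumulated
#' before its onset, plus the cross-correlations between consecutive
#' day/night sleep totals. Under the memoryless sleep phase all three
#' should be near zero.
#'
#' @param bouts bout table with \code{onset_s} and \code{duration_s}.
#' @param K sleep latency threshold (s).
#' @param schedule optional [LightSchedule-class]; required for the
#'   day/night cross-correlations.
#' @param min_bouts minimum number of sleep bouts.
#' @return list with \code{rho_history}, \code{p_history},
#'   \code{n_sleep_bouts}, and (when a schedule is given)
#'   \code{rho_day_to_night}, \code{rho_night_to_day}.
#' @export
sleepHistoryCorrelation <- function(bouts, K, schedule = NULL,
                                    min_bouts = 5) {
    sl <- bouts[bouts$duration_s > K, , drop = FALSE]
    sl <- sl[order(sl$onset_s), , drop = FALSE]
    n <- nrow(sl)
    if (n < min_bouts)
        stop(sprintf("too few sleep bouts (%d < %d)", n, min_bouts))
    s <- sl$duration_s - K
    prior <- c(0, cumsum(s)[-n])
    ct <- suppressWarnings(
        stats::cor.test(s, prior, method = "spearman", exact = FALSE))
    out <- list(rho_history = unname(ct$estimate),
                p_history = ct$p.value, n_sleep_bouts = n)
    if (!is.null(schedule)) {
        # totals per consecutive 12 h ZT half-day block
        zt_s <- schedule@t0_zt * 3600 + sl$onset_s
        block <- floor(zt_s / 43200)
        tot <- tapply(s, block, sum)
        blk <- as.numeric(names(tot))
        is_day <- (blk %% 2) == (if (schedule@lights_on_zt == 0) 0 else 1)
        day_next <- match(blk + 1, blk)
        pair_dn <- which(is_day & !is.na(day_next))
        pair_nd <- which(!is_day & !is.na(day_next))
        sp <- function(i) {
            if (length(i) < 3) return(NA_real_)
            suppressWarnings(cor(tot[i], tot[day_next[i]],
                                 method = "spearman"))
        }
        out$rho_day_to_night <- unname(sp(pair_dn))
        out$rho_night_to_day <- unname(sp(pair_nd))
    }
    out
}
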