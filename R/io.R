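# Plain-text interchange: trajectory and bout tables as CSV.

#' Read and write trajectory and bout tables
#'
#' Trajectories are exchanged as CSV with columns
#' \code{frame,t_s,x_px,y_px}; bout tables as CSV with columns
#' \code{onset_s,duration_s,phase,x_px,y_px}. Rest-duration samples are a
#' single \code{duration_s} column.
#'
#' @param traj a [Trajectory-class].
#' @param bouts a bout data.frame from [extractRestBouts()].
#' @param file path to a CSV file.
#' @param fps,chamber,schedule metadata for the reconstructed
#'   [Trajectory-class].
#' @return The readers return a [Trajectory-class] / data.frame; the
#'   writers return the file path invisibly.
#' @name flysleep-io
NULL

#' @rdname flysleep-io
#' @export
writeTrajectoryCsv <- function(traj, file) {
    stopifnot(is(traj, "Trajectory"))
    df <- data.frame(frame = seq_along(traj@times) - 1L, t_s = traj@times,
                     x_px = traj@x, y_px = traj@y)
    utils::write.csv(df, file, row.names = FALSE)
    invisible(file)
}

#' @rdname flysleep-io
#' @export
readTrajectoryCsv <- function(file, fps, chamber = Chamber(),
                              schedule = LightSchedule()) {
    df <- utils::read.csv(file)
    stopifnot(all(c("t_s", "x_px", "y_px") %in% names(df)))
    Trajectory(times = df$t_s, x = df$x_px, y = df$y_px, fps = fps,
               chamber = chamber, schedule = schedule)
}

#' @rdname flysleep-io
#' @export
writeBoutsCsv <- function(bouts, file) {
    utils::write.csv(bouts, file, row.names = FALSE)
    invisible(file)
}

#' @rdname flysleep-io
#' @export
readBoutsCsv <- function(file) {
    df <- utils::read.csv(file)
    stopifnot("duration_s" %in% names(df))
    df
}
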