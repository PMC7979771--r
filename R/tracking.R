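# Background-difference tracking: background reconstruction from hourly
# first frames, morphological chamber masking, top-difference-pixel fly
# detection, and a virtual midline beam emulating the DAMS counter.

.asFrameArray <- function(frames) {
    if (is(frames, "FrameStack")) return(frames@frames)
    if (is.matrix(frames)) return(array(frames, dim = c(dim(frames), 1L)))
    if (is.array(frames) && length(dim(frames)) == 3L) return(frames)
    stop("'frames' must be a FrameStack, a matrix or a 3-D array")
}

#' Reconstruct the background image
#'
#' Pixel-wise mean of the supplied frames. On real recordings these are the
#' first frames of each hour within one light phase (12 frames per phase),
#' so that a fly contaminates each pixel by at most its intensity excess
#' divided by the number of frames.
#'
#' @param frames a [FrameStack-class], 3-D array, or list of matrices of
#'   identical shape.
#' @return Numeric matrix, the mean image.
#' @export
reconstructBackground <- function(frames) {
    if (is.list(frames) && !is(frames, "FrameStack")) {
        if (length(frames) == 0L) stop("no frames supplied")
        d <- dim(frames[[1L]])
        if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
            stop("frame shape mismatch")
        frames <- array(unlist(frames), dim = c(d, length(frames)))
    } else {
        frames <- .asFrameArray(frames)
    }
    if (dim(frames)[3L] == 0L) stop("no frames supplied")
    rowMeans(frames, dims = 2)
}

#' Locate the chamber interior by morphological opening
#'
#' Grayscale morphological opening (disc structuring element) removes
#' small bright blobs such as residual fly traces from the background; the
#' chamber, being darker than its surround, is then the largest connected
#' dark region below the mid-range threshold.
#'
#' @param background numeric matrix from [reconstructBackground()].
#' @param opening_radius_px disc radius of the structuring element (px,
#'   >= 1); choose it larger than the fly radius.
#' @return Logical matrix marking the chamber interior (the moving area).
#' @export
movingAreaMask <- function(background, opening_radius_px = 3) {
    stopifnot(is.matrix(background))
    if (opening_radius_px < 1) stop("'opening_radius_px' must be >= 1")
    rng <- range(background)
    if (diff(rng) < 1e-8)
        stop("chamber not found: background image is uniform")
    opened <- .grayOpen(background, floor(opening_radius_px))
    dark <- opened < mean(rng)
    if (!any(dark)) stop("chamber not found: no dark region below threshold")
    lab <- EBImage::bwlabel(dark)
    counts <- tabulate(lab[lab > 0])
    mask <- lab == which.max(counts)
    dim(mask) <- dim(background)
    mask
}

# Grayscale erosion (min filter) / dilation (max filter) over a disc of
# radius r, by shifted-matrix reduction; borders use the available pixels.
.grayFilter <- function(m, r, fun, fill) {
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dy^2 + off$dx^2 <= r^2, ]
    ny <- nrow(m); nx <- ncol(m)
    out <- matrix(fill, ny, nx)
    for (k in seq_len(nrow(off))) {
        dy <- off$dy[k]; dx <- off$dx[k]
        ys <- max(1, 1 + dy):min(ny, ny + dy)
        xs <- max(1, 1 + dx):min(nx, nx + dx)
        sh <- matrix(fill, ny, nx)
        sh[ys - dy, xs - dx] <- m[ys, xs]
        out <- fun(out, sh)
    }
    out
}

.grayOpen <- function(m, r) {
    .grayFilter(.grayFilter(m, r, pmin, Inf), r, pmax, -Inf)
}

# 8-connected components over a small set of pixel coordinates
# (union-find over the vectorized adjacency). Returns the rows of
# `coords` (row, col) in the largest component.
.largestComponent8 <- function(coords) {
    n <- nrow(coords)
    if (n == 1L) return(coords)
    adj <- abs(outer(coords[, 1L], coords[, 1L], "-")) <= 1L &
           abs(outer(coords[, 2L], coords[, 2L], "-")) <= 1L
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (e in seq_len(nrow(edges))) {
        a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
        if (a != b) parent[b] <- a
    }
    root <- vapply(seq_len(n), find, integer(1))
    big <- names(which.max(table(root)))
    coords[root == as.integer(big), , drop = FALSE]
}

#' Detect the fly in one frame
#'
#' Among in-mask pixels, takes the \code{n_top} largest positive
#' frame-minus-background differences (ties at the cutoff value are all
#' included), binarizes them, finds the largest 8-connected component and
#' returns its centroid. If the maximum difference is below
#' \code{noise_floor} the fly is flagged missing.
#'
#' @param frame,background numeric matrices of identical shape.
#' @param mask logical matrix (the moving area); defaults to all pixels.
#' @param n_top number of top difference pixels to keep.
#' @param noise_floor gray-level difference below which no detection is
#'   reported.
#' @return Named numeric \code{c(x =, y =)} in 0-based pixel coordinates,
#'   or \code{c(x = NA, y = NA)} when missing.
#' @export
detectFly <- function(frame, background, mask = NULL, n_top = 100,
                      noise_floor = 5) {
    stopifnot(identical(dim(frame), dim(background)))
    if (is.null(mask)) mask <- matrix(TRUE, nrow(frame), ncol(frame))
    stopifnot(identical(dim(mask), dim(frame)))
    d <- frame - background
    d[!mask] <- -Inf
    mx <- max(d)
    if (!is.finite(mx) || mx < noise_floor)
        return(c(x = NA_real_, y = NA_real_))
    pos <- which(d > 0)
    v <- d[pos]
    if (length(pos) > n_top) {
        cutoff <- sort(v, decreasing = TRUE)[n_top]
        keep <- v >= cutoff        # include ties at the cutoff
        pos <- pos[keep]
    }
    ny <- nrow(frame)
    coords <- cbind(row = (pos - 1L) %% ny + 1L, col = (pos - 1L) %/% ny + 1L)
    comp <- .largestComponent8(coords)
    c(x = mean(comp[, "col"]) - 1, y = mean(comp[, "row"]) - 1)
}

# frame indices of the first frame of each `every_s` interval
.bgSampleIdx <- function(idx, times, every_s) {
    bins <- floor(times[idx] / every_s)
    idx[!duplicated(bins)]
}

#' Track a video into a trajectory
#'
#' Runs [detectFly()] on every frame. The background is reconstructed per
#' light phase from the first frame of each \code{bg_sample_s} interval
#' (hourly on full-length recordings), unless an explicit background is
#' supplied. Missing detections are filled by carrying the last known
#' location forward (a stationary undetectable fly accumulates rest time);
#' leading missing frames are back-filled from the first detection.
#'
#' @param frames a [FrameStack-class] or 3-D array.
#' @param fps frame rate; taken from the FrameStack when available.
#' @param schedule optional [LightSchedule-class]; phases get separate
#'   backgrounds. Defaults to the FrameStack's schedule.
#' @param background optional explicit background matrix (skips
#'   reconstruction; single phase).
#' @param bg_sample_s spacing of background sample frames (s).
#' @param opening_radius_px passed to [movingAreaMask()].
#' @param n_top,noise_floor passed to [detectFly()].
#' @param chamber chamber geometry attached to the output trajectory.
#' @return A [Trajectory-class] (coordinates relative to the frame, 0-based).
#' @export
trackVideo <- function(frames, fps = NULL, schedule = NULL, background = NULL,
                       bg_sample_s = 3600, opening_radius_px = 3, n_top = 100,
                       noise_floor = 5, chamber = Chamber()) {
    if (is(frames, "FrameStack")) {
        if (is.null(fps)) fps <- frames@fps
        if (is.null(schedule)) schedule <- frames@schedule
    }
    arr <- .asFrameArray(frames)
    n <- dim(arr)[3L]
    if (n < 2L) stop("need at least 2 frames to track")
    if (is.null(fps)) stop("'fps' must be given for array input")
    if (is.null(schedule)) schedule <- LightSchedule()
    times <- (seq_len(n) - 1) / fps
    zt <- (schedule@t0_zt + times / 3600) %% 24
    light <- .isLight(zt, schedule)
    x <- rep(NA_real_, n); y <- rep(NA_real_, n)
    for (ph in unique(light)) {
        idx <- which(light == ph)
        if (is.null(background)) {
            bgi <- .bgSampleIdx(idx, times, bg_sample_s)
            bg <- reconstructBackground(arr[, , bgi, drop = FALSE])
        } else {
            bg <- background
        }
        mask <- movingAreaMask(bg, opening_radius_px)
        for (k in idx) {
            p <- detectFly(arr[, , k], bg, mask, n_top = n_top,
                           noise_floor = noise_floor)
            x[k] <- p[["x"]]; y[k] <- p[["y"]]
        }
    }
    if (all(is.na(x))) stop("no frame yielded a detection")
    # carry last known location forward; back-fill the leading gap
    filled <- .locf(x)
    x <- filled; y <- .locf(y)
    Trajectory(times = times, x = x, y = y, fps = fps, chamber = chamber,
               schedule = schedule)
}

.locf <- function(v) {
    ok <- !is.na(v)
    first <- which(ok)[1L]
    if (first > 1L) v[seq_len(first - 1L)] <- v[first]
    ok <- !is.na(v)
    idx <- cummax(ifelse(ok, seq_along(v), 0L))
    v[idx]
}

.isLight <- function(zt, schedule) {
    on <- schedule@lights_on_zt; off <- schedule@lights_off_zt
    if (on < off) zt >= on & zt < off else zt >= on | zt < off
}

#' Virtual midline beam crossings
#'
#' Emulates the DAMS infrared beam: counts, per time bin, the sign changes
#' of \code{y - midline}, where the midline is the midpoint of the
#' chamber's long (y) axis. Frames exactly on the midline are ignored for
#' the sign sequence, so a slow traverse still counts once.
#'
#' @param traj a [Trajectory-class].
#' @param bin_minutes bin width (min).
#' @param midline beam position (px); default is the midpoint of the
#'   chamber's y extent.
#' @return data.frame with \code{bin_start_s}, \code{bin_start_zt} and
#'   \code{crossings}, covering every bin of the recording.
#' @export
virtualBeamCrossings <- function(traj, bin_minutes = 30, midline = NULL) {
    stopifnot(is(traj, "Trajectory"))
    n <- length(traj@times)
    if (n == 0L) stop("empty trajectory")
    if (is.null(midline)) {
        Lg <- traj@chamber@length_mm * traj@chamber@px_per_mm
        midline <- (Lg - 1) / 2
    }
    s <- sign(traj@y - midline)
    nz <- which(s != 0)
    cross_t <- numeric(0)
    if (length(nz) > 1L) {
        sw <- which(s[nz[-1L]] != s[nz[-length(nz)]])
        cross_t <- traj@times[nz[sw + 1L]]
    }
    bw <- bin_minutes * 60
    total <- max(traj@times)
    starts <- seq(0, total, by = bw)
    cnt <- tabulate(findInterval(cross_t, starts), nbins = length(starts))
    data.frame(bin_start_s = starts,
               bin_start_zt = (traj@schedule@t0_zt + starts / 3600) %% 24,
               crossings = cnt)
}
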