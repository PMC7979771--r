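test_that("background reconstruction is the pixel-wise mean", {
    f <- matrix(50, 20, 10)
    expect_equal(reconstructBackground(replicate(12, f, simplify = FALSE)), f)
    # a fly of excess intensity D visiting 12 distinct spots contaminates
    # each visited pixel by D / 12
    D <- 120
    stack <- lapply(1:12, function(k) stampDisk(f, 2 + (k - 1) %% 5 * 2,
                                                2 + (k - 1) %/% 5 * 6,
                                                0.8, 50 + D))
    bg <- reconstructBackground(stack)
    touched <- bg > 50
    expect_true(any(touched))
    expect_equal(unique(round(bg[touched] - 50, 9)), D / 12)
    expect_error(reconstructBackground(list()), "no frames")
    expect_error(reconstructBackground(list(f, matrix(0, 3, 3))), "mismatch")
})

test_that("the moving-area mask covers the eroded chamber and ignores the fly", {
    sp <- shortClipSpec(duration_s = 20, fps = 5, seed = 2)
    traj <- makeTrajectory(sp)
    fs <- renderFrames(traj)
    bg <- matrix(120, nrow(fs@chamber_mask), ncol(fs@chamber_mask))
    bg[fs@chamber_mask] <- 30
    m <- movingAreaMask(bg, opening_radius_px = 3)
    eroded <- EBImage::erode(fs@chamber_mask + 0, EBImage::makeBrush(7, "disc")) > 0
    expect_true(all(m[eroded]))
    expect_true(all(!m[!fs@chamber_mask]))   # excludes the bright surround
    # opening removes a fly disk smaller than the structuring element
    # (fly kept off the chamber wall, where it would merge with the rim)
    withfly <- stampDisk(bg, 6.6, 50, 2, 200)
    expect_equal(movingAreaMask(withfly, 3), m)
    expect_error(movingAreaMask(matrix(7, 5, 5)), "uniform")
})

test_that("fly detection finds the planted disk and prefers the larger of two", {
    bg <- matrix(20, 60, 60)
    fr <- stampDisk(bg, 30.3, 40.7, 6.2, 150)       # area > 100 px
    p <- detectFly(fr, bg)
    expect_lt(abs(p[["x"]] - 30.3), 1)
    expect_lt(abs(p[["y"]] - 40.7), 1)
    # two equal-intensity disks, areas ~120 and ~60: the larger connected
    # component wins
    fr2 <- stampDisk(stampDisk(bg, 15, 15, 6.2, 150), 45, 45, 4.3, 150)
    p2 <- detectFly(fr2, bg)
    expect_lt(abs(p2[["x"]] - 15), 1)
    expect_lt(abs(p2[["y"]] - 15), 1)
    # no difference -> missing flag, not an error
    expect_true(all(is.na(detectFly(bg, bg))))
})

test_that("fly detection is translation-equivariant", {
    bg <- matrix(20, 50, 50)
    fr <- stampDisk(bg, 20.5, 22.5, 3, 150)
    frs <- stampDisk(bg, 20.5 + 7, 22.5 + 9, 3, 150)
    p <- detectFly(fr, bg)
    ps <- detectFly(frs, bg)
    expect_equal(ps[["x"]] - p[["x"]], 7)
    expect_equal(ps[["y"]] - p[["y"]], 9)
})

test_that("video tracking recovers the planted trajectory within one pixel RMS", {
    sp <- roundTripSpec(duration_s = 120, seed = 31)
    traj <- makeTrajectory(sp)
    fs <- renderFrames(traj)
    tr <- trackVideo(fs, bg_sample_s = 30, chamber = traj@chamber)
    expect_equal(length(frameTimes(tr)), dim(fs@frames)[3])
    err <- sqrt((coordX(tr) - (coordX(traj) + 4))^2 +
                (coordY(tr) - (coordY(traj) + 4))^2)
    expect_lt(sqrt(mean(err^2)), 1)
    expect_error(trackVideo(fs@frames[, , 1, drop = FALSE], fps = 10),
                 "at least 2")
})

test_that("missing detections are filled by the last known location", {
    sp <- roundTripSpec(duration_s = 30, seed = 5)
    traj <- makeTrajectory(sp)
    fs <- renderFrames(traj)
    bg <- matrix(120, nrow(fs@chamber_mask), ncol(fs@chamber_mask))
    bg[fs@chamber_mask] <- 30
    arr <- fs@frames
    arr[, , 50:60] <- array(bg, dim = c(dim(bg), 11))   # fly vanishes
    tr <- trackVideo(arr, fps = 10, background = bg, chamber = traj@chamber)
    expect_equal(length(frameTimes(tr)), dim(arr)[3])
    expect_false(any(is.na(coordX(tr))))
    expect_equal(coordX(tr)[55], coordX(tr)[49])
})

test_that("virtual beam counts match analytic crossing counts", {
    ch <- Chamber()
    mid <- (78 * 1.25 - 1) / 2
    # monotone traverse: exactly one crossing
    xy <- cbind(rep(3, 50), seq(10, 80, length.out = 50))
    expect_equal(sum(virtualBeamCrossings(manualTrajectory(xy))$crossings), 1)
    # confined to one half: none
    xy2 <- cbind(rep(3, 50), seq(5, 20, length.out = 50))
    expect_equal(sum(virtualBeamCrossings(manualTrajectory(xy2))$crossings), 0)
    # sinusoid about the midline: 2 f T crossings
    fps <- 50; T <- 10; f <- 1
    t <- seq(0, T, by = 1 / fps)
    xy3 <- cbind(rep(3, length(t)), mid + 20 * sin(2 * pi * f * t + 0.1))
    expect_equal(sum(virtualBeamCrossings(manualTrajectory(xy3, fps))$crossings),
                 2 * f * T)
})

test_that("beam counts are invariant under reflection about the midline", {
    set.seed(6)
    mid <- 40
    y <- cumsum(rnorm(500))
    y <- mid + 30 * (y - min(y)) / diff(range(y)) - 15
    tr <- manualTrajectory(cbind(rep(2, 500), y))
    tr2 <- manualTrajectory(cbind(rep(2, 500), 2 * mid - y))
    expect_equal(virtualBeamCrossings(tr, midline = mid)$crossings,
                 virtualBeamCrossings(tr2, midline = mid)$crossings)
})
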