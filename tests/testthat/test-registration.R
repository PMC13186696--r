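# a persistent jittered emitter plus optional sparse clutter
fiducial_table <- function(fid_xy, n_frames = 1000L, jitter = 2,
                           clutter = NULL, seed = 1) {
  withr::local_seed(seed, .local_envir = parent.frame())
  frame <- x <- y <- NULL
  for (i in seq_len(nrow(fid_xy))) {
    frame <- c(frame, 0:(n_frames - 1L))
    x <- c(x, fid_xy[i, 1] + rnorm(n_frames, 0, jitter))
    y <- c(y, fid_xy[i, 2] + rnorm(n_frames, 0, jitter))
  }
  if (!is.null(clutter)) {
    frame <- c(frame, clutter$frame); x <- c(x, clutter$x); y <- c(y, clutter$y)
  }
  loc_table(frame, x, y, n_frames = n_frames)
}

test_that("a planted persistent fiducial yields one near-complete track", {
  t <- fiducial_table(cbind(3000, 4000), n_frames = 1000L)
  tracks <- detect_fiducials(t)
  expect_length(tracks, 1)
  expect_gte(nrow(tracks[[1]]), 990)
})

test_that("sparse blinking sites do not form tracks", {
  withr::local_seed(8)
  n_frames <- 2000L
  t <- loc_table(sample.int(n_frames, 10) - 1L, rnorm(10, 500, 2),
                 rnorm(10, 500, 2), n_frames = n_frames)
  expect_length(detect_fiducials(t, min_presence_fraction = 0.5), 0)
})

test_that("two well-separated fiducials give two disjoint tracks", {
  t <- fiducial_table(rbind(c(1000, 1000), c(6000, 1000)), n_frames = 1000L)
  tracks <- detect_fiducials(t)
  expect_length(tracks, 2)
  mx <- sort(vapply(tracks, function(tr) mean(tr$x_nm), numeric(1)))
  expect_equal(mx, c(1000, 6000), tolerance = 1e-2)
})

test_that("estimate_drift reproduces exact linear drift after re-centering", {
  n <- 1000L
  f <- 0:(n - 1L)
  tr <- structure(data.frame(frame = f, x_nm = 100 + 0.01 * f, y_nm = 200),
                  class = c("fiducial_track", "data.frame"))
  trace <- estimate_drift(list(tr), n)
  expected <- 0.01 * f - mean(0.01 * f)
  expect_equal(trace$dx_nm, expected, tolerance = 1e-9)
  expect_equal(trace$dy_nm, rep(0, n), tolerance = 1e-9)
  expect_lt(abs(mean(trace$dx_nm)), 1e-6)
})

test_that("static tracks give an all-zero trace; zero tracks error", {
  tr <- structure(data.frame(frame = 0:9, x_nm = 5, y_nm = 7),
                  class = c("fiducial_track", "data.frame"))
  trace <- estimate_drift(list(tr), 10L)
  expect_equal(trace$dx_nm, rep(0, 10))
  expect_error(estimate_drift(list(), 10L), "no fiducial tracks")
})

test_that("averaging two noisy tracks reduces residual drift error", {
  withr::local_seed(9)
  n <- 2000L
  f <- 0:(n - 1L)
  drift <- 0.01 * f
  mk <- function(x0, y0) structure(
    data.frame(frame = f, x_nm = x0 + drift + rnorm(n, 0, 2),
               y_nm = y0 + rnorm(n, 0, 2)),
    class = c("fiducial_track", "data.frame"))
  trace <- estimate_drift(list(mk(0, 0), mk(5000, 3000)), n)
  resid <- trace$dx_nm - (drift - mean(drift))
  expect_lt(sqrt(mean(resid^2)), 2)  # ~ sigma / sqrt(2)
})

test_that("apply_drift is invertible and exact on planted drift", {
  withr::local_seed(10)
  n <- 500L
  t0 <- loc_table(sample.int(n, 300, replace = TRUE) - 1L,
                  runif(300, 0, 5000), runif(300, 0, 5000), n_frames = n)
  trace <- data.frame(frame = 0:(n - 1L), dx_nm = sin(1:n / 50),
                      dy_nm = cos(1:n / 50))
  t1 <- apply_drift(t0, trace)
  inv <- transform(trace, dx_nm = -dx_nm, dy_nm = -dy_nm)
  t2 <- apply_drift(t1, inv)
  expect_equal(t2$x_nm, t0$x_nm, tolerance = 1e-9)
  zero <- transform(trace, dx_nm = 0, dy_nm = 0)
  expect_equal(apply_drift(t0, zero)$x_nm, t0$x_nm)
  expect_error(apply_drift(loc_table(600L, 0, 0, n_frames = 1000L), trace),
               "cover")
})

test_that("drift correction restores a drifted fiducial to its jitter scale", {
  withr::local_seed(12)
  n <- 2000L
  f <- 0:(n - 1L)
  jitter <- 2
  t <- loc_table(rep(f, 2),
                 c(1000 + 0.05 * f + rnorm(n, 0, jitter),
                   8000 + 0.05 * f + rnorm(n, 0, jitter)),
                 c(1000 + rnorm(n, 0, jitter), 8000 + rnorm(n, 0, jitter)),
                 n_frames = n)
  tracks <- detect_fiducials(t)
  expect_length(tracks, 2)
  corrected <- apply_drift(t, estimate_drift(tracks, n))
  sdx <- sd(corrected$x_nm[corrected$x_nm < 5000])
  expect_lte(sdx, jitter * 1.2)
})

test_that("translation alignment recovers a planted shift exactly", {
  mk_tracks <- function(shift = c(0, 0)) {
    lapply(list(c(1000, 1000), c(5000, 2000), c(3000, 6000)), function(p)
      structure(data.frame(frame = 0:99, x_nm = p[1] + shift[1],
                           y_nm = p[2] + shift[2]),
                class = c("fiducial_track", "data.frame")))
  }
  ref <- mk_tracks()
  tf <- align_channels(ref, mk_tracks(shift = c(-10, 5)))
  expect_equal(c(tf$tx_nm, tf$ty_nm), c(10, -5), tolerance = 1e-6)
  expect_equal(tf$theta, 0)
  id <- align_channels(ref, ref)
  expect_equal(c(id$tx_nm, id$ty_nm, id$theta), c(0, 0, 0), tolerance = 1e-9)
  expect_error(align_channels(ref, mk_tracks(shift = c(5000, 5000))),
               "0 matched")
})

test_that("rigid alignment recovers a planted rotation (Procrustes oracle)", {
  pts <- rbind(c(1000, 1000), c(5000, 2000), c(3000, 6000))
  th <- 0.5 * pi / 180
  ctr <- colMeans(pts)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + c(20, -30), "+")
  as_tracks <- function(m) lapply(seq_len(nrow(m)), function(i)
    structure(data.frame(frame = 0:9, x_nm = m[i, 1], y_nm = m[i, 2]),
              class = c("fiducial_track", "data.frame")))
  # moving -> reference must invert the planted motion
  tf <- align_channels(as_tracks(pts), as_tracks(moved), mode = "rigid",
                       pairing_radius_nm = 500)
  expect_equal(tf$theta, -th, tolerance = 1e-3)
  back <- apply_transform(make_sites(moved[, 1], moved[, 2]), tf)
  expect_equal(back$x_nm, pts[, 1], tolerance = 1e-3)
  expect_equal(back$y_nm, pts[, 2], tolerance = 1e-3)
  expect_lt(tf$rmse_nm, 1e-6)
})

test_that("channel transforms preserve pairwise distances", {
  withr::local_seed(13)
  s <- make_sites(runif(50, 0, 1000), runif(50, 0, 1000))
  tf <- structure(list(theta = 0.3, tx_nm = 123, ty_nm = -77), class = "channel_transform")
  s2 <- apply_transform(s, tf)
  d0 <- dist(cbind(s$x_nm, s$y_nm))
  d1 <- dist(cbind(s2$x_nm, s2$y_nm))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
})

test_that("fiducial localizations are excluded from downstream signal", {
  t <- fiducial_table(cbind(2000, 2000), n_frames = 500L,
                      clutter = data.frame(frame = 0:9, x = 4000, y = 4000))
  tracks <- detect_fiducials(t)
  clean <- remove_fiducials(t, tracks)
  expect_equal(nrow(clean), 10)  # only the clutter far from the bead remains
  expect_gte(attr(clean, "n_excluded"), 500)
})
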