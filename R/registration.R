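#' Detect gold-fiducial tracks in a localization table
#'
#' Gold nanoparticles are bright and blink continuously, so a fiducial shows
#' up as a spatially compact spot present in nearly every frame. Detection
#' bins the field on a `link_radius_nm` grid, keeps regions whose distinct-
#' frame presence is compatible with a persistent emitter, and then links per
#' frame the localization nearest to the region centroid (at most one
#' position per frame). Only tracks present in at least
#' `min_presence_fraction` of all frames are returned.
#'
#' @param table A [loc_table()].
#' @param min_presence_fraction Minimum fraction of frames a track must cover
#'   (fiducials blink continuously; default 0.5).
#' @param link_radius_nm Spatial linking scale in nm (default 500; gold beads
#'   are sparse so a generous radius is safe).
#' @return A list of `fiducial_track` data.frames (`frame`, `x_nm`, `y_nm`)
#'   with attribute `id`; possibly empty.
#' @export
detect_fiducials <- function(table, min_presence_fraction = 0.5,
                             link_radius_nm = 500) {
  stopifnot(nrow(table) > 0, min_presence_fraction > 0,
            min_presence_fraction <= 1, link_radius_nm > 0)
  n_frames <- attr(table, "n_frames")

  cx <- floor(table$x_nm / link_radius_nm)
  cy <- floor(table$y_nm / link_radius_nm)
  cell <- paste(cx, cy)
  presence <- tapply(table$frame, cell, function(f) length(unique(f)))
  # candidate cells: a fiducial straddling a cell border still leaves
  # a large per-cell presence; ordinary blinking sites do not
  cand <- names(presence)[presence >= 0.25 * min_presence_fraction * n_frames]
  if (length(cand) == 0) return(list())

  # merge adjacent candidate cells into regions
  cc <- do.call(rbind, strsplit(cand, " "))
  ccx <- as.numeric(cc[, 1]); ccy <- as.numeric(cc[, 2])
  lab <- cpp_radius_components(ccx, ccy, 1.5)  # 8-neighbourhood in cell units

  tracks <- list()
  for (g in unique(lab)) {
    in_region <- cell %in% cand[lab == g]
    idx <- which(in_region)
    centx <- mean(table$x_nm[idx]); centy <- mean(table$y_nm[idx])
    # one position per frame: nearest localization to the region centroid
    d2 <- (table$x_nm[idx] - centx)^2 + (table$y_nm[idx] - centy)^2
    keep_near <- d2 <= (2 * link_radius_nm)^2
    idx <- idx[keep_near]; d2 <- d2[keep_near]
    if (length(idx) == 0) next
    ord <- order(table$frame[idx], d2)
    idx <- idx[ord]
    first <- !duplicated(table$frame[idx])
    idx <- idx[first]
    if (length(idx) < min_presence_fraction * n_frames) next
    tr <- data.frame(frame = table$frame[idx], x_nm = table$x_nm[idx],
                     y_nm = table$y_nm[idx])
    tr <- tr[order(tr$frame), , drop = FALSE]
    rownames(tr) <- NULL
    tracks[[length(tracks) + 1L]] <- structure(tr,
      class = c("fiducial_track", "data.frame"), id = length(tracks) + 1L)
  }
  tracks
}

#' Estimate a per-frame drift trace from fiducial tracks
#'
#' Each track's per-frame displacement from its own mean position is linearly
#' interpolated onto every frame (end values held constant beyond a track's
#' coverage) and averaged across tracks; the trace is re-centred so its mean
#' displacement over frames is zero.
#'
#' @param tracks Non-empty list of fiducial tracks from [detect_fiducials()].
#' @param n_frames Total frame count the trace must cover.
#' @return A `drift_trace` data.frame with columns `frame` (0-based, all
#'   frames), `dx_nm`, `dy_nm`.
#' @export
estimate_drift <- function(tracks, n_frames) {
  if (length(tracks) == 0)
    stop("drift unavailable: no fiducial tracks", call. = FALSE)
  frames <- 0:(n_frames - 1L)
  dx <- matrix(NA_real_, n_frames, length(tracks))
  dy <- matrix(NA_real_, n_frames, length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    ox <- tr$x_nm - mean(tr$x_nm)
    oy <- tr$y_nm - mean(tr$y_nm)
    if (nrow(tr) == 1) {
      dx[, k] <- ox; dy[, k] <- oy
    } else {
      dx[, k] <- approx(tr$frame, ox, xout = frames, rule = 2)$y
      dy[, k] <- approx(tr$frame, oy, xout = frames, rule = 2)$y
    }
  }
  trace <- data.frame(frame = frames,
                      dx_nm = rowMeans(dx), dy_nm = rowMeans(dy))
  trace$dx_nm <- trace$dx_nm - mean(trace$dx_nm)
  trace$dy_nm <- trace$dy_nm - mean(trace$dy_nm)
  structure(trace, class = c("drift_trace", "data.frame"))
}

#' Subtract a drift trace from a localization table
#'
#' @param table A [loc_table()].
#' @param trace A [estimate_drift()] trace covering every frame in `table`.
#' @return The drift-corrected [loc_table()]; record count unchanged.
#' @export
apply_drift <- function(table, trace) {
  idx <- match(table$frame, trace$frame)
  if (anyNA(idx))
    stop("drift trace does not cover all frames in the table", call. = FALSE)
  loc_table(table$frame, table$x_nm - trace$dx_nm[idx],
            table$y_nm - trace$dy_nm[idx], table$photons,
            channel = attr(table, "channel"),
            n_frames = attr(table, "n_frames"),
            pixel_size_nm = attr(table, "pixel_size_nm"))
}

track_means <- function(tracks) {
  t(vapply(tracks, function(tr) c(mean(tr$x_nm), mean(tr$y_nm)), numeric(2)))
}

# greedy one-to-one matching of point sets by ascending distance
match_points <- function(a, b, radius) {
  if (nrow(a) == 0 || nrow(b) == 0) return(cbind(integer(0), integer(0)))
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  pairs <- which(d <= radius^2, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(cbind(integer(0), integer(0)))
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Rigid channel alignment from matched fiducials
#'
#' Matches fiducial track means between a reference and a moving channel by
#' proximity and fits the least-squares transform mapping moving onto
#' reference fiducials: a pure translation (default; sequential single-
#' objective imaging has negligible rotation) or a rigid
#' rotation + translation via 2D Procrustes/Kabsch.
#'
#' @param reference_tracks,moving_tracks Lists of fiducial tracks.
#' @param mode `"translation"` (>= 1 matched fiducial) or `"rigid"`
#'   (>= 2 matched fiducials).
#' @param pairing_radius_nm Maximum distance between track means for a match
#'   (default 500 nm).
#' @return A `channel_transform`: list with `theta` (radians), `tx_nm`,
#'   `ty_nm` (such that `x' = R x + t`), `rmse_nm` and `n_matched`.
#' @export
align_channels <- function(reference_tracks, moving_tracks,
                           mode = c("translation", "rigid"),
                           pairing_radius_nm = 500) {
  mode <- match.arg(mode)
  ref <- track_means(reference_tracks)
  mov <- track_means(moving_tracks)
  m <- match_points(mov, ref, pairing_radius_nm)
  need <- if (mode == "translation") 1L else 2L
  if (nrow(m) < need)
    stop(sprintf("alignment error: %d matched fiducial(s), need >= %d for %s",
                 nrow(m), need, mode), call. = FALSE)
  P <- mov[m[, 1], , drop = FALSE]  # moving
  Q <- ref[m[, 2], , drop = FALSE]  # reference
  if (mode == "translation") {
    theta <- 0
    t_vec <- colMeans(Q) - colMeans(P)
  } else {
    cp <- colMeans(P); cq <- colMeans(Q)
    Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
    H <- t(Pc) %*% Qc
    sv <- svd(H)
    D <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    theta <- atan2(R[2, 1], R[1, 1])
    t_vec <- cq - as.vector(R %*% cp)
  }
  R <- rot2(theta)
  resid <- Q - (P %*% t(R) + matrix(t_vec, nrow(P), 2, byrow = TRUE))
  structure(list(theta = theta, tx_nm = t_vec[1], ty_nm = t_vec[2],
                 rmse_nm = sqrt(mean(rowSums(resid^2))), n_matched = nrow(m)),
            class = "channel_transform")
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' @export
print.channel_transform <- function(x, ...) {
  cat(sprintf(
    "<channel_transform> rotation %.4g rad, translation (%.3f, %.3f) nm, RMS %.3f nm (%d fiducials)\n",
    x$theta, x$tx_nm, x$ty_nm, x$rmse_nm, x$n_matched))
  invisible(x)
}

#' Apply a rigid channel transform to a localization table or site set
#'
#' @param obj A [loc_table()] or `binding_sites` object.
#' @param tf A `channel_transform` from [align_channels()].
#' @return The transformed object (distances preserved).
#' @export
apply_transform <- function(obj, tf) {
  R <- rot2(tf$theta)
  xy <- cbind(obj$x_nm, obj$y_nm) %*% t(R)
  obj$x_nm <- xy[, 1] + tf$tx_nm
  obj$y_nm <- xy[, 2] + tf$ty_nm
  obj
}

#' Remove fiducial localizations from a table
#'
#' Gold beads are not glycan signal: every localization within
#' `exclusion_radius_nm` of a track (inflated by the track's own spatial
#' spread, which includes residual drift) is dropped before analysis.
#'
#' @param table A [loc_table()].
#' @param tracks Fiducial tracks from [detect_fiducials()].
#' @param exclusion_radius_nm Base exclusion radius (default 200 nm).
#' @return The filtered [loc_table()] with attribute `n_excluded`.
#' @export
remove_fiducials <- function(table, tracks, exclusion_radius_nm = 200) {
  if (length(tracks) == 0) return(table)
  drop <- logical(nrow(table))
  for (tr in tracks) {
    cx <- mean(tr$x_nm); cy <- mean(tr$y_nm)
    spread <- sqrt(max((tr$x_nm - cx)^2 + (tr$y_nm - cy)^2))
    r2 <- (exclusion_radius_nm + spread)^2
    drop <- drop | ((table$x_nm - cx)^2 + (table$y_nm - cy)^2 <= r2)
  }
  out <- loc_table_like(table, !drop)
  attr(out, "n_excluded") <- sum(drop)
  out
}
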