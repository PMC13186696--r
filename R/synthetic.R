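#' Specification of a synthetic DNA-PAINT scene
#'
#' Describes a multi-channel acquisition the way the real experiment is run:
#' a field imaged for `n_frames` (default 20,000 frames at 100 ms), sparse
#' blinking with a Poisson number of events per docking site spread uniformly
#' over the stack, isotropic Gaussian localization noise, optional stage
#' drift, persistent gold fiducials and unspecific sticking artifacts.
#' Glycan structure is planted as class motifs: groups of sites from a
#' channel multiset placed within `motif_radius_nm` of a common anchor
#' (default 4 nm, inside the 5-nm GlyCo cut-off so planted classes are
#' recoverable by construction).
#'
#' @param field_nm Field size `c(width, height)` in nm (default 10 x 10 um).
#' @param roi An [roi_polygon()]; `NULL` means the full field.
#' @param channels Channel label panel (default the five-lectin panel).
#' @param site_density_per_um2 Per-channel binding-site density (recycled
#'   across channels; default 20 um^-2).
#' @param motifs List of motifs, each `list(channels = c(...), weight = w)`;
#'   weights are normalized internally.
#' @param motif_fraction Fraction of all sites that belong to motifs
#'   (default 0).
#' @param motif_radius_nm Maximum member distance from the motif anchor;
#'   member distances are uniform in `[1, motif_radius_nm]` (default 4).
#' @param n_frames Stack length in frames (default 20000).
#' @param mean_events Poisson mean of blinking events per site (default 10).
#' @param mean_event_frames Mean duration of one binding event in frames
#'   (default 1: one localization per event). Values > 1 emulate imager
#'   bright times longer than the frame time (a 100-ms frame and a few
#'   hundred ms bright time give 2-4), producing the adjacent-frame repeats
#'   that NeNA precision estimation relies on; one localization is emitted
#'   per frame of the event.
#' @param sigma_nm Per-channel localization precision in nm (recycled;
#'   default 5).
#' @param drift `list(mode = "none")`, `list(mode = "linear", velocity_nm_per_frame
#'   = c(vx, vy))` or `list(mode = "random_walk", step_nm = s)`.
#' @param n_fiducials Number of gold fiducials (default 0).
#' @param fiducial_jitter_nm Fiducial localization jitter (default 2 nm).
#' @param sticking_rate_per_um2 Density of sticking artifacts per channel
#'   (default 0).
#' @param sticking_window_frames Length of the window confining a sticking
#'   artifact's events (default 200 frames). Windows are aligned to the
#'   anchored partition of the stack into `sticking_window_frames` bins —
#'   the canonical signature the temporal filter is designed to reject.
#' @param sticking_events_mean Poisson mean of events per sticking artifact
#'   (default 30).
#' @param min_separation_nm Minimum distance enforced between planted
#'   anchors/background sites (default 0 = pure CSR).
#' @param seed Random seed; the same seed reproduces the scene exactly.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(field_nm = c(10000, 10000), roi = NULL,
                       channels = c("WGA", "SNA", "PHA-L", "AAL", "PSA"),
                       site_density_per_um2 = 20,
                       motifs = list(), motif_fraction = 0,
                       motif_radius_nm = 4,
                       n_frames = 20000L, mean_events = 10,
                       mean_event_frames = 1,
                       sigma_nm = 5, drift = list(mode = "none"),
                       n_fiducials = 0L, fiducial_jitter_nm = 2,
                       sticking_rate_per_um2 = 0,
                       sticking_window_frames = 200L,
                       sticking_events_mean = 30,
                       min_separation_nm = 0, seed = 1L) {
  stopifnot(all(field_nm > 0), all(site_density_per_um2 >= 0),
            motif_fraction >= 0, motif_fraction <= 1, motif_radius_nm >= 1,
            n_frames >= 1, mean_events > 0, mean_event_frames >= 1,
            all(sigma_nm >= 0),
            n_fiducials >= 0, sticking_rate_per_um2 >= 0,
            min_separation_nm >= 0)
  for (m in motifs) {
    if (!all(m$channels %in% channels))
      stop("spec error: motif channel(s) not in panel: ",
           paste(setdiff(m$channels, channels), collapse = ", "), call. = FALSE)
    if (length(m$channels) < 2)
      stop("spec error: a motif needs >= 2 members", call. = FALSE)
  }
  if (motif_fraction > 0 && length(motifs) == 0)
    stop("spec error: motif_fraction > 0 but no motifs given", call. = FALSE)
  if (is.null(roi))
    roi <- roi_polygon(c(0, field_nm[1], field_nm[1], 0),
                       c(0, 0, field_nm[2], field_nm[2]), label = "field")
  structure(list(field_nm = field_nm, roi = roi, channels = channels,
                 site_density_per_um2 = rep_len(site_density_per_um2,
                                                length(channels)),
                 motifs = motifs, motif_fraction = motif_fraction,
                 motif_radius_nm = motif_radius_nm,
                 n_frames = as.integer(n_frames), mean_events = mean_events,
                 mean_event_frames = mean_event_frames,
                 sigma_nm = rep_len(sigma_nm, length(channels)),
                 drift = drift, n_fiducials = as.integer(n_fiducials),
                 fiducial_jitter_nm = fiducial_jitter_nm,
                 sticking_rate_per_um2 = sticking_rate_per_um2,
                 sticking_window_frames = as.integer(sticking_window_frames),
                 sticking_events_mean = sticking_events_mean,
                 min_separation_nm = min_separation_nm,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# uniform points inside the ROI polygon (rejection from its bounding box)
runif_in_roi <- function(n, roi) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  bx <- range(roi$x_nm); by <- range(roi$y_nm)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    px <- runif(m, bx[1], bx[2]); py <- runif(m, by[1], by[2])
    ok <- pracma::inpolygon(px, py, roi$x_nm, roi$y_nm, boundary = TRUE)
    take <- min(sum(ok), n - got)
    if (take > 0) {
      out[got + seq_len(take), ] <- cbind(px[ok][seq_len(take)],
                                          py[ok][seq_len(take)])
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

# sequential placement with a minimum pairwise separation (grid-checked)
place_separated <- function(n, roi, min_sep) {
  if (min_sep <= 0) return(runif_in_roi(n, roi))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  attempts <- 0L
  while (got < n && attempts < 200L * n) {
    p <- runif_in_roi(1, roi)
    attempts <- attempts + 1L
    if (got == 0L ||
        min((out[seq_len(got), 1] - p[1])^2 +
              (out[seq_len(got), 2] - p[2])^2) >= min_sep^2) {
      got <- got + 1L
      out[got, ] <- p
    }
  }
  if (got < n)
    stop("cannot place ", n, " sites at min separation ", min_sep, " nm",
         call. = FALSE)
  colnames(out) <- c("x", "y")
  out
}

drift_trace_from_spec <- function(spec) {
  f <- 0:(spec$n_frames - 1L)
  d <- spec$drift
  if (is.null(d$mode) || d$mode == "none") {
    dx <- dy <- numeric(spec$n_frames)
  } else if (d$mode == "linear") {
    v <- d$velocity_nm_per_frame
    dx <- v[1] * f; dy <- v[2] * f
  } else if (d$mode == "random_walk") {
    dx <- cumsum(rnorm(spec$n_frames, 0, d$step_nm))
    dy <- cumsum(rnorm(spec$n_frames, 0, d$step_nm))
  } else stop("unknown drift mode: ", d$mode, call. = FALSE)
  data.frame(frame = f, dx_nm = dx, dy_nm = dy)
}

#' Generate a synthetic multi-channel DNA-PAINT scene
#'
#' Places binding sites (motif members jointly within the motif radius, the
#' remainder completely spatially random per channel), draws a Poisson
#' number of blinking events per site at uniformly random frames with
#' isotropic Gaussian localization offsets, adds cumulative drift by frame,
#' persistent fiducial tracks with small jitter, and sticking artifacts
#' whose events are confined to one short window. The same seed yields
#' bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @return List with `channels` (a [channel_set()] of [loc_table()]s) and
#'   `truth` (list: `sites` data.frame with `channel`, `x_nm`, `y_nm`,
#'   `motif`, `instance`; `fiducials`; `drift`; `sticking`; `spec`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  K <- length(spec$channels)
  area <- roi_area_um2(spec$roi)

  n_bg <- rpois(K, spec$site_density_per_um2 * area)
  n_total <- sum(n_bg)

  # motif instances: carve motif members out of the per-channel budgets
  inst_motif <- integer(0)
  if (spec$motif_fraction > 0 && n_total > 0) {
    w <- vapply(spec$motifs, function(m) m$weight %||% 1, numeric(1))
    w <- w / sum(w)
    sizes <- vapply(spec$motifs, function(m) length(m$channels), integer(1))
    n_motif_sites <- round(spec$motif_fraction * n_total)
    n_inst <- max(0L, round(n_motif_sites / sum(w * sizes)))
    if (n_inst > 0)
      inst_motif <- sample.int(length(spec$motifs), n_inst, replace = TRUE,
                               prob = w)
  }

  # anchors: motif anchors first, then per-channel background sites
  n_anchor <- length(inst_motif)
  motif_members <- unlist(lapply(inst_motif,
                                 function(i) spec$motifs[[i]]$channels))
  for (k in seq_len(K)) {
    used <- sum(motif_members == spec$channels[k])
    n_bg[k] <- max(0L, n_bg[k] - used)
  }
  pos <- place_separated(n_anchor + sum(n_bg), spec$roi,
                         spec$min_separation_nm)

  sites <- vector("list", 0)
  row <- 0L
  for (j in seq_along(inst_motif)) {
    row <- row + 1L
    m <- spec$motifs[[inst_motif[j]]]
    nm <- length(m$channels)
    r <- runif(nm - 1L, 1, spec$motif_radius_nm)
    th <- runif(nm - 1L, 0, 2 * pi)
    sites[[length(sites) + 1L]] <- data.frame(
      channel = m$channels,
      x_nm = pos[row, 1] + c(0, r * cos(th)),
      y_nm = pos[row, 2] + c(0, r * sin(th)),
      motif = glyco_label(m$channels), instance = j)
  }
  for (k in seq_len(K)) {
    if (n_bg[k] == 0) next
    idx <- row + seq_len(n_bg[k])
    row <- row + n_bg[k]
    sites[[length(sites) + 1L]] <- data.frame(
      channel = spec$channels[k], x_nm = pos[idx, 1], y_nm = pos[idx, 2],
      motif = NA_character_, instance = NA_integer_)
  }
  sites <- if (length(sites)) do.call(rbind, sites)
           else data.frame(channel = character(0), x_nm = numeric(0),
                           y_nm = numeric(0), motif = character(0),
                           instance = integer(0))
  rownames(sites) <- NULL

  drift <- drift_trace_from_spec(spec)

  # fiducials: uniform over the field, kept out of the ROI when possible
  fid <- NULL
  if (spec$n_fiducials > 0) {
    fx <- numeric(0); fy <- numeric(0)
    full_field <- isTRUE(all.equal(area, prod(spec$field_nm) / 1e6))
    for (i in seq_len(spec$n_fiducials)) {
      for (att in 1:200) {
        px <- runif(1, 0, spec$field_nm[1]); py <- runif(1, 0, spec$field_nm[2])
        if (full_field ||
            !pracma::inpolygon(px, py, spec$roi$x_nm, spec$roi$y_nm,
                               boundary = TRUE)) break
      }
      fx <- c(fx, px); fy <- c(fy, py)
    }
    fid <- data.frame(id = seq_len(spec$n_fiducials), x_nm = fx, y_nm = fy)
  }

  sticking_all <- vector("list", 0)
  tables <- vector("list", K)
  for (k in seq_len(K)) {
    ch <- spec$channels[k]
    s <- sites[sites$channel == ch, , drop = FALSE]
    n_sites <- nrow(s)
    ev <- if (n_sites) rpois(n_sites, spec$mean_events) else integer(0)
    n_ev <- sum(ev)
    starts <- if (n_ev) sample.int(spec$n_frames, n_ev, replace = TRUE) - 1L else integer(0)
    dur <- if (spec$mean_event_frames > 1)
      1L + rpois(n_ev, spec$mean_event_frames - 1) else rep(1L, n_ev)
    site_of_ev <- rep(seq_len(n_sites), ev)
    frame <- unlist(lapply(seq_len(n_ev), function(e)
      starts[e]:min(starts[e] + dur[e] - 1L, spec$n_frames - 1L)),
      use.names = FALSE)
    if (is.null(frame)) frame <- integer(0)
    site_of_loc <- rep(site_of_ev, pmin(dur, spec$n_frames - starts))
    tot <- length(frame)
    sx <- s$x_nm[site_of_loc] + rnorm(tot, 0, spec$sigma_nm[k])
    sy <- s$y_nm[site_of_loc] + rnorm(tot, 0, spec$sigma_nm[k])

    # sticking artifacts: many events confined to one short window
    n_stick <- rpois(1, spec$sticking_rate_per_um2 * area)
    if (n_stick > 0) {
      sp <- runif_in_roi(n_stick, spec$roi)
      for (i in seq_len(n_stick)) {
        ne <- max(2L, rpois(1, spec$sticking_events_mean))
        n_windows <- max(1L, spec$n_frames %/% spec$sticking_window_frames)
        w0 <- spec$sticking_window_frames * (sample.int(n_windows, 1) - 1L)
        sf <- w0 + sample.int(spec$sticking_window_frames, ne, replace = TRUE) - 1L
        frame <- c(frame, sf)
        sx <- c(sx, sp[i, 1] + rnorm(ne, 0, spec$sigma_nm[k]))
        sy <- c(sy, sp[i, 2] + rnorm(ne, 0, spec$sigma_nm[k]))
      }
      sticking_all[[length(sticking_all) + 1L]] <-
        data.frame(channel = ch, x_nm = sp[, 1], y_nm = sp[, 2])
    }

    # fiducials blink continuously: one localization every frame
    if (!is.null(fid)) {
      for (i in seq_len(nrow(fid))) {
        frame <- c(frame, 0:(spec$n_frames - 1L))
        sx <- c(sx, fid$x_nm[i] + rnorm(spec$n_frames, 0, spec$fiducial_jitter_nm))
        sy <- c(sy, fid$y_nm[i] + rnorm(spec$n_frames, 0, spec$fiducial_jitter_nm))
      }
    }

    # cumulative stage drift by frame
    sx <- sx + drift$dx_nm[frame + 1L]
    sy <- sy + drift$dy_nm[frame + 1L]

    ord <- order(frame)
    tables[[k]] <- loc_table(frame[ord], sx[ord], sy[ord],
                             channel = ch, n_frames = spec$n_frames)
  }

  sticking <- if (length(sticking_all)) do.call(rbind, sticking_all)
              else data.frame(channel = character(0), x_nm = numeric(0),
                              y_nm = numeric(0))
  list(channels = channel_set(tables),
       truth = list(sites = sites, fiducials = fid, drift = drift,
                    sticking = sticking, spec = spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match called sites against ground truth
#'
#' Greedy one-to-one matching by ascending distance within
#' `match_radius_nm`, then standard detection metrics.
#'
#' @param sites_called A `binding_sites` object.
#' @param truth_sites Data.frame of true positions (`x_nm`, `y_nm`), e.g. one
#'   channel's slice of `truth$sites`.
#' @param match_radius_nm Maximum distance for a match (default 10 nm).
#' @return List with `recall`, `precision`, `rmse_nm`, `n_matched`.
#' @export
truth_match <- function(sites_called, truth_sites, match_radius_nm = 10) {
  a <- cbind(sites_called$x_nm, sites_called$y_nm)
  b <- cbind(truth_sites$x_nm, truth_sites$y_nm)
  m <- match_points(a, b, match_radius_nm)
  n_matched <- nrow(m)
  rmse <- if (n_matched)
    sqrt(mean((a[m[, 1], 1] - b[m[, 2], 1])^2 +
                (a[m[, 1], 2] - b[m[, 2], 2])^2)) else NaN
  list(recall = if (nrow(b)) n_matched / nrow(b) else NaN,
       precision = if (nrow(a)) n_matched / nrow(a) else NaN,
       rmse_nm = rmse, n_matched = n_matched)
}
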