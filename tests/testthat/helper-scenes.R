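# writes a small two-condition scene set to disk and returns a run_config
write_demo_run <- function(dir, n_per_condition = 2, base_seed = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- list()
  i <- 0L
  for (cond in c("control", "treated")) {
    for (r in seq_len(n_per_condition)) {
      i <- i + 1L
      motif_frac <- if (cond == "control") 0.1 else 0.3
      spec <- scene_spec(
        field_nm = c(4000, 4000), site_density_per_um2 = 25,
        motifs = list(list(channels = c("SNA", "WGA"), weight = 1)),
        motif_fraction = motif_frac, mean_events = 8, mean_event_frames = 3,
        n_frames = 5000L, seed = base_seed + i)
      sc <- generate_scene(spec)
      id <- sprintf("%s_%d", cond, r)
      sdir <- file.path(dir, id)
      dir.create(sdir, showWarnings = FALSE)
      paths <- vapply(names(sc$channels), function(lab) {
        p <- file.path(sdir, paste0(lab, ".csv"))
        t <- sc$channels[[lab]]
        attr(t, "pixel_size_nm") <- 130  # store in camera pixels on disk
        write_localizations(t, p)
        p
      }, character(1))
      samples[[i]] <- list(id = id, condition = cond, channels = paths)
    }
  }
  run_config(samples, pixel_size_nm = 130, detect_fiducials = FALSE,
             cluster = list(radius_nm = 10))
}

# the two synthetic cellular states used for end-to-end separation checks.
# Cellular state remodelling shifts several glycan channels at once (no
# single alteration explains a state change), so condition B differs from A
# by a collective set of density/spacing changes: the SNA+WGA class density
# doubles, WGA intra-channel spacing stretches by 1.5 (density / 1.5^2),
# PSA density rises 1.4x and PHA-L falls to 0.7x. The 100-um^2 field at
# 50 sites/um^2 keeps per-sample peak and class-density estimates stable
# (~5,000 sites per channel), comparable to the dense experimental fields.
state_panel_spec <- function(condition, seed) {
  dens <- c(WGA = 50, SNA = 50, `PHA-L` = 50, AAL = 50, PSA = 50)
  motif_frac <- 0.15
  if (condition == "B") {
    dens["WGA"] <- 50 / 1.5^2
    dens["PSA"] <- 50 * 1.4
    dens["PHA-L"] <- 50 * 0.7
    motif_frac <- 0.30
  }
  scene_spec(field_nm = c(10000, 10000), channels = names(dens),
             site_density_per_um2 = unname(dens),
             motifs = list(list(channels = c("SNA", "WGA"), weight = 1)),
             motif_fraction = motif_frac, motif_radius_nm = 4,
             mean_events = 10, sigma_nm = 5, seed = seed)
}

# peak finding uses a 21-bin smoothing window here: at ~5,000 sites/channel
# the 1-nm-binned NN histogram carries ~50 counts/bin near its (flat-topped)
# mode, and a ~20-nm window is needed for a stable mode estimate; the small
# bias it introduces is common to all samples and drops out of the embedding
analyse_state_sample <- function(spec) {
  sc <- generate_scene(spec)
  sites <- lapply(names(sc$channels), function(l)
    call_sites(sc$channels[[l]], sigma_nm = 5))
  names(sites) <- names(sc$channels)
  hset <- nn_histogram_set(sites, smooth_window_bins = 21)
  list(peaks = peak_matrix(hset),
       glyco = glyco_classes(sites, roi_area_um2(spec$roi), 5))
}
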