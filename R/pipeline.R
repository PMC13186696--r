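#' Build a run configuration
#'
#' Defaults reproduce the standard postprocessing settings: 130-nm effective
#' pixel size, clustering radius of twice the per-channel NeNA precision,
#' minimum 2 localizations per cluster, temporal bins of 1% of the stack
#' with a 90% rejection threshold, 5-nm GlyCo cut-off and a K x K NN peak
#' matrix.
#'
#' @param samples List of samples, each
#'   `list(id =, condition =, channels = c(label = path, ...), roi = path or
#'   roi_polygon)`.
#' @param pixel_size_nm Camera pixel size (default 130 nm).
#' @param detect_fiducials Run fiducial detection / drift correction /
#'   channel alignment (default TRUE).
#' @param alignment_mode `"translation"` (default) or `"rigid"`.
#' @param cluster ClusterParams overrides:
#'   `list(radius_nm = NULL, min_locs = 2, time_bin_frames = NULL,
#'   max_bin_fraction = 0.9)`; `radius_nm = NULL` uses `2 * sigma_nena`.
#' @param fallback_sigma_nm Precision used when the NeNA fit fails or is
#'   unreliable (default 5 nm).
#' @param nn `list(bin_nm = 1, range_nm = 200, smooth_window_bins = 5)`.
#' @param glyco_cutoff_nm GlyCo grouping cut-off (default 5 nm).
#' @param feature_modes Feature modes to embed (default
#'   `c("nn_peaks", "glyco")`).
#' @param n_components PCA components (default 2).
#' @param seed Root seed echoed into the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(samples, pixel_size_nm = 130,
                       detect_fiducials = TRUE,
                       alignment_mode = "translation",
                       cluster = list(), fallback_sigma_nm = 5,
                       nn = list(), glyco_cutoff_nm = 5,
                       feature_modes = c("nn_peaks", "glyco"),
                       n_components = 2, seed = 1L) {
  cl <- utils::modifyList(list(radius_nm = NULL, min_locs = 2L,
                               time_bin_frames = NULL,
                               max_bin_fraction = 0.9), cluster)
  nn <- utils::modifyList(list(bin_nm = 1, range_nm = 200,
                               smooth_window_bins = 5), nn)
  structure(list(samples = samples, pixel_size_nm = pixel_size_nm,
                 detect_fiducials = detect_fiducials,
                 alignment_mode = alignment_mode, cluster = cl,
                 fallback_sigma_nm = fallback_sigma_nm, nn = nn,
                 glyco_cutoff_nm = glyco_cutoff_nm,
                 feature_modes = feature_modes,
                 n_components = n_components, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$samples <- lapply(y$samples, function(s) {
    s$channels <- unlist(s$channels)
    s
  })
  do.call(run_config, y)
}

process_sample_channels <- function(tables, config, roi = NULL) {
  # registration: per-channel residual drift, then alignment to channel 1
  tracks_by_channel <- NULL
  if (isTRUE(config$detect_fiducials)) {
    tracks_by_channel <- lapply(tables, detect_fiducials)
    for (k in seq_along(tables)) {
      trk <- tracks_by_channel[[k]]
      if (length(trk) > 0) {
        trace <- estimate_drift(trk, attr(tables[[k]], "n_frames"))
        tables[[k]] <- apply_drift(tables[[k]], trace)
        # re-detect on the corrected table for alignment and exclusion
        tracks_by_channel[[k]] <- detect_fiducials(tables[[k]])
      }
    }
    ref <- tracks_by_channel[[1]]
    for (k in seq_along(tables)[-1]) {
      if (length(ref) > 0 && length(tracks_by_channel[[k]]) > 0) {
        tf <- align_channels(ref, tracks_by_channel[[k]],
                             mode = config$alignment_mode)
        tables[[k]] <- apply_transform(tables[[k]], tf)
        tracks_by_channel[[k]] <- detect_fiducials(tables[[k]])
      }
    }
    for (k in seq_along(tables))
      tables[[k]] <- remove_fiducials(tables[[k]], tracks_by_channel[[k]])
  }
  if (!is.null(roi))
    tables <- lapply(tables, clip_to_roi, roi = roi)
  tables
}

analyse_sample <- function(tables, config, roi_area) {
  precisions <- lapply(tables, function(t) {
    est <- tryCatch(nena_precision(t, min_pairs = 200), error = function(e) NULL)
    if (is.null(est) || !est$reliable) {
      list(sigma_nm = config$fallback_sigma_nm, fallback = TRUE,
           estimate = est)
    } else list(sigma_nm = est$sigma_nm, fallback = FALSE, estimate = est)
  })
  sites <- lapply(seq_along(tables), function(k) {
    radius <- config$cluster$radius_nm
    if (is.null(radius)) radius <- 2 * precisions[[k]]$sigma_nm
    params <- cluster_params(radius, config$cluster$min_locs,
                             config$cluster$time_bin_frames,
                             config$cluster$max_bin_fraction)
    call_sites(tables[[k]], params)
  })
  names(sites) <- names(tables)
  hset <- nn_histogram_set(sites, config$nn$bin_nm, config$nn$range_nm,
                           config$nn$smooth_window_bins)
  list(precisions = precisions, sites = sites, hset = hset,
       peaks = peak_matrix(hset),
       glyco = glyco_classes(sites, roi_area, config$glyco_cutoff_nm))
}

#' Run the full glycan-atlassing pipeline
#'
#' Orchestrates, per sample: load channels, fiducial drift correction and
#' channel alignment, ROI segmentation, NeNA precision, binding-site calling
#' with the temporal sticking filter, NN histogram/peak-matrix analysis and
#' GlyCo class construction; then, across samples, feature assembly and PCA
#' for each requested feature mode. All stage outputs are written under
#' `out_dir`; the run is deterministic given inputs and config.
#'
#' @param config A [run_config()] (or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return The results manifest (also written as `manifest.yaml`): per-stage
#'   output paths, parameter echo, per-channel counts, precision estimates
#'   and software version.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = as.character(packageVersion("glycoatlas")),
                   parameters = config[setdiff(names(config), "samples")],
                   samples = list())

  results <- list()
  for (s in config$samples) {
    stage <- paste0("sample '", s$id, "'")
    tables <- list()
    for (lab in names(s$channels)) {
      path <- s$channels[[lab]]
      if (!file.exists(path))
        stop(stage, ": missing channel file for '", lab, "': ", path,
             call. = FALSE)
      t <- read_localizations(path, config$pixel_size_nm)
      attr(t, "channel") <- lab
      tables[[lab]] <- t
    }
    roi <- s$roi
    if (is.character(roi)) roi <- read_roi(roi)[[1]]
    tables <- process_sample_channels(tables, config, roi)
    roi_area <- if (!is.null(roi)) roi_area_um2(roi) else {
      fx <- range(unlist(lapply(tables, `[[`, "x_nm")))
      fy <- range(unlist(lapply(tables, `[[`, "y_nm")))
      diff(fx) * diff(fy) / 1e6
    }
    res <- analyse_sample(tables, config, roi_area)
    results[[s$id]] <- res

    sdir <- file.path(out_dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    for (lab in names(res$sites))
      write_sites(res$sites[[lab]], file.path(sdir, paste0("sites_", lab, ".csv")))
    write_nn_csv(res$peaks, file.path(sdir, "nn_peak_matrix.csv"))
    write_nn_csv(res$hset, file.path(sdir, "nn_histograms.csv"))
    write_glyco_csv(res$glyco, file.path(sdir, "glyco_classes.csv"),
                    file.path(sdir, "glyco_instances.csv"))

    manifest$samples[[s$id]] <- list(
      condition = s$condition, roi_area_um2 = roi_area,
      outputs = file.path(s$id, c(paste0("sites_", names(res$sites), ".csv"),
                                  "nn_peak_matrix.csv", "nn_histograms.csv",
                                  "glyco_classes.csv", "glyco_instances.csv")),
      channels = lapply(stats::setNames(names(res$sites), names(res$sites)),
        function(lab) {
          rep <- attr(res$sites[[lab]], "report")
          pr <- res$precisions[[lab]]
          list(n_localizations = nrow(tables[[lab]]),
               sigma_nena_nm = pr$sigma_nm,
               sigma_fallback = pr$fallback,
               n_clusters_raw = rep$n_clusters_raw,
               n_rejected_temporal = rep$n_rejected_temporal,
               n_sites = rep$n_sites)
        }))
  }

  # cross-sample embeddings
  ids <- vapply(config$samples, `[[`, character(1), "id")
  conds <- vapply(config$samples, `[[`, character(1), "condition")
  if (length(results) >= 2) {
    for (mode in config$feature_modes) {
      obj <- switch(mode,
        nn_peaks = lapply(results, `[[`, "peaks"),
        glyco = lapply(results, `[[`, "glyco"),
        nn_full = lapply(results, `[[`, "hset"),
        stop("unknown feature mode: ", mode, call. = FALSE))
      fm <- assemble_features(unname(obj), mode, ids, conds)
      emb <- run_pca(fm, config$n_components)
      write_embedding_csv(emb,
        file.path(out_dir, paste0("pca_scores_", mode, ".csv")),
        file.path(out_dir, paste0("pca_loadings_", mode, ".csv")),
        file.path(out_dir, paste0("pca_variance_", mode, ".csv")))
      sil <- if (sum(table(conds) >= 2) >= 2)
        tryCatch(separation_score(emb), error = function(e) NA_real_)
      else NA_real_
      manifest[[paste0("embedding_", mode)]] <- list(
        explained_variance_ratio = as.numeric(emb$explained_variance_ratio),
        silhouette = sil)
    }
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
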