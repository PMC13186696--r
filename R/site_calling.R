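#' Clustering parameters for binding-site calling
#'
#' Defaults reproduce the standard postprocessing values for a 20,000-frame
#' stack: radius = 2x the NeNA precision (supplied by the caller), minimum 2
#' localizations per cluster, temporal bins of 1% of the stack (200 frames)
#' and rejection when one bin holds more than 90% of a cluster's events.
#'
#' @param radius_nm Linking radius in nm; conventionally `2 * sigma_nena`.
#' @param min_locs Minimum localizations per cluster (default 2).
#' @param time_bin_frames Temporal bin length in frames; `NULL` resolves to
#'   `round(0.01 * n_frames)` at filter time.
#' @param max_bin_fraction A cluster is rejected when one bin holds more than
#'   this fraction of its events (default 0.9).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(radius_nm, min_locs = 2L, time_bin_frames = NULL,
                           max_bin_fraction = 0.9) {
  stopifnot(radius_nm > 0, min_locs >= 2, max_bin_fraction > 0,
            max_bin_fraction <= 1)
  if (!is.null(time_bin_frames)) stopifnot(time_bin_frames >= 1)
  structure(list(radius_nm = radius_nm, min_locs = as.integer(min_locs),
                 time_bin_frames = time_bin_frames,
                 max_bin_fraction = max_bin_fraction),
            class = "cluster_params")
}

resolve_time_bin <- function(params, n_frames) {
  tb <- params$time_bin_frames
  if (is.null(tb)) tb <- max(1L, as.integer(round(0.01 * n_frames)))
  as.integer(tb)
}

#' Cluster localizations into candidate binding sites
#'
#' Groups repeated localizations of one docking strand: clusters are the
#' connected components of the graph linking localizations at distance
#' <= `radius_nm` (single linkage; equivalent to DBSCAN with `min_samples = 2`
#' where every point is core). Components with fewer than `min_locs` members
#' are discarded.
#'
#' @param table A [loc_table()] in nm units.
#' @param params A [cluster_params()].
#' @return List of integer vectors of member row indices into `table`;
#'   every localization belongs to at most one cluster.
#' @export
cluster_localizations <- function(table, params) {
  if (nrow(table) == 0) return(list())
  lab <- cpp_radius_components(table$x_nm, table$y_nm, params$radius_nm)
  cl <- split(seq_len(nrow(table)), lab)
  unname(cl[lengths(cl) >= params$min_locs])
}

#' Temporal sticking filter for one cluster
#'
#' Unspecific sticking events produce many localizations confined to a short
#' time window. Frames are partitioned into consecutive non-overlapping bins
#' of `time_bin_frames` anchored at frame 0 (the last bin may be short); the
#' cluster is rejected iff any bin holds more than `max_bin_fraction` of its
#' events.
#'
#' @param frames Integer vector of the cluster's member frames (0-based).
#' @param n_frames Total stack length.
#' @param params A [cluster_params()].
#' @return `TRUE` to keep the cluster, `FALSE` to reject it.
#' @export
temporal_filter <- function(frames, n_frames, params) {
  stopifnot(length(frames) > 0)
  tb <- resolve_time_bin(params, n_frames)
  stopifnot(n_frames >= tb)
  bins <- frames %/% tb
  max(tabulate(bins + 1L)) <= params$max_bin_fraction * length(frames)
}

#' Binding-site centres from surviving clusters
#'
#' The centre of each cluster (unweighted arithmetic mean of its member
#' coordinates) is taken as the location of one glycan target, the "lectin
#' binding site".
#'
#' @param table The clustered [loc_table()].
#' @param clusters List of member-index vectors (after filtering).
#' @return A `binding_sites` data.frame (`x_nm`, `y_nm`, `n_locs`,
#'   `first_frame`, `last_frame`) with attribute `channel`.
#' @export
site_centres <- function(table, clusters) {
  out <- data.frame(
    x_nm = vapply(clusters, function(i) mean(table$x_nm[i]), numeric(1)),
    y_nm = vapply(clusters, function(i) mean(table$y_nm[i]), numeric(1)),
    n_locs = vapply(clusters, length, integer(1)),
    first_frame = vapply(clusters, function(i) min(table$frame[i]), integer(1)),
    last_frame = vapply(clusters, function(i) max(table$frame[i]), integer(1)))
  structure(out, class = c("binding_sites", "data.frame"),
            channel = attr(table, "channel"))
}

#' @export
print.binding_sites <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("<binding_sites> channel %s: %d sites\n",
              attr(x, "channel"), nrow(x)))
  if (!is.null(rep))
    cat(sprintf("  clusters raw %d, rejected by temporal filter %d\n",
                rep$n_clusters_raw, rep$n_rejected_temporal))
  invisible(x)
}

#' Call lectin binding sites for one channel
#'
#' Full site-calling stage: fixed-radius clustering, temporal sticking
#' filter, cluster centres. The clustering radius is `params$radius_nm` when
#' given, otherwise `2 * sigma_nm`.
#'
#' @param table A [loc_table()].
#' @param params A [cluster_params()], or `NULL` to build one from `sigma_nm`.
#' @param sigma_nm NeNA precision used for the default `2 * sigma` radius.
#' @return A `binding_sites` object with attribute `report`
#'   (`n_clusters_raw`, `n_rejected_temporal`, `n_sites`).
#' @export
call_sites <- function(table, params = NULL, sigma_nm = NULL) {
  if (is.null(params)) {
    if (is.null(sigma_nm)) stop("need params or sigma_nm", call. = FALSE)
    params <- cluster_params(radius_nm = 2 * sigma_nm)
  }
  n_frames <- attr(table, "n_frames")
  clusters <- cluster_localizations(table, params)
  keep <- vapply(clusters, function(i)
    temporal_filter(table$frame[i], n_frames, params), logical(1))
  sites <- site_centres(table, clusters[keep])
  attr(sites, "report") <- list(n_clusters_raw = length(clusters),
                                n_rejected_temporal = sum(!keep),
                                n_sites = sum(keep))
  sites
}

#' Export binding sites as CSV
#'
#' @param sites A `binding_sites` object.
#' @param path Output CSV path.
#' @export
write_sites <- function(sites, path) {
  df <- cbind(channel = attr(sites, "channel"), as.data.frame(sites))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binding sites from CSV
#'
#' @param path CSV written by [write_sites()].
#' @return A `binding_sites` object.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ch <- if (nrow(df)) df$channel[1] else NA_character_
  structure(df[, c("x_nm", "y_nm", "n_locs", "first_frame", "last_frame")],
            class = c("binding_sites", "data.frame"), channel = ch)
}
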