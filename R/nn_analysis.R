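#' First-nearest-neighbour distances between two site sets
#'
#' For each source site, the Euclidean distance to the nearest target site;
#' when source and target are the same channel each site's own entry is
#' excluded.
#'
#' @param source,target `binding_sites` objects (or data.frames with `x_nm`,
#'   `y_nm`).
#' @param same_channel `TRUE` when `source` and `target` are the same set.
#' @return Numeric vector of distances (one per source site).
#' @export
nn_distances <- function(source, target, same_channel = FALSE) {
  if (nrow(target) == 0 || (same_channel && nrow(target) < 2))
    stop("undefined-pair error: target ",
         if (nrow(target) == 0) "is empty" else "has < 2 sites for a self pair",
         call. = FALSE)
  if (same_channel && nrow(source) != nrow(target))
    stop("same_channel requires source == target", call. = FALSE)
  as.numeric(cpp_nn_dist(source$x_nm, source$y_nm, target$x_nm, target$y_nm,
                         same_channel))
}

smooth_counts <- function(counts, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(counts[lo:hi])  # truncated at the edges
  }, numeric(1))
}

#' Histogram of first-NN distances with peak finding
#'
#' Uniform bins on `[0, range_nm)`. For peak finding only, counts are
#' smoothed by a centred moving average of `smooth_window_bins` (truncated at
#' the edges); raw counts are stored. The peak is the centre of the
#' global-maximum smoothed bin; among tied smoothed maxima, the bin with the
#' larger raw count wins, then the smaller distance.
#'
#' @param distances Numeric NN distances in nm (>= 1 value within range).
#' @param bin_nm Bin width (default 1 nm).
#' @param range_nm Histogram range (default 200 nm).
#' @param smooth_window_bins Odd moving-average window (default 5).
#' @param source,target Channel labels carried along for bookkeeping.
#' @return An `nn_histogram`: list with `source`, `target`, `bin_edges_nm`,
#'   `counts`, `smoothed`, `peak_nm`, `bin_nm`, `range_nm`.
#' @export
nn_histogram <- function(distances, bin_nm = 1, range_nm = 200,
                         smooth_window_bins = 5,
                         source = NA_character_, target = NA_character_) {
  stopifnot(bin_nm > 0, range_nm > bin_nm)
  distances <- distances[is.finite(distances)]
  stopifnot(length(distances) >= 1)
  inr <- distances >= 0 & distances < range_nm
  if (!any(inr))
    stop("empty-histogram error: all distances outside [0, ", range_nm, ") nm",
         call. = FALSE)
  edges <- seq(0, range_nm, by = bin_nm)
  nb <- length(edges) - 1L
  counts <- tabulate(floor(distances[inr] / bin_nm) + 1L, nbins = nb)
  sm <- smooth_counts(counts, smooth_window_bins)
  best <- which(sm == max(sm))
  if (length(best) > 1) {
    best <- best[counts[best] == max(counts[best])]
    best <- best[1]  # smallest distance among remaining ties
  }
  structure(list(source = source, target = target, bin_edges_nm = edges,
                 counts = counts, smoothed = sm,
                 peak_nm = edges[best] + bin_nm / 2,
                 bin_nm = bin_nm, range_nm = range_nm),
            class = "nn_histogram")
}

#' @export
print.nn_histogram <- function(x, ...) {
  cat(sprintf("<nn_histogram> %s -> %s: %d distances, peak %.1f nm\n",
              x$source, x$target, sum(x$counts), x$peak_nm))
  invisible(x)
}

#' All K^2 first-NN histograms of a channel panel
#'
#' Computes the NN histogram for every ordered (source, target) channel pair,
#' including self pairs. Pairs that are undefined (empty target, or a
#' singleton self pair) are flagged missing rather than failing the panel.
#'
#' @param sites_by_channel Named list of `binding_sites`, one per channel.
#' @inheritParams nn_histogram
#' @return An `nn_histogram_set`: list with `channels`, `histograms`
#'   (length-K^2 list, `NULL` where missing, named `"src->tgt"`) and
#'   `missing` (logical K x K matrix).
#' @export
nn_histogram_set <- function(sites_by_channel, bin_nm = 1, range_nm = 200,
                             smooth_window_bins = 5) {
  labels <- names(sites_by_channel)
  if (is.null(labels))
    labels <- vapply(sites_by_channel, function(s) attr(s, "channel"), character(1))
  K <- length(labels)
  hists <- vector("list", K * K)
  names(hists) <- as.vector(t(outer(labels, labels, paste, sep = "->")))
  missing <- matrix(FALSE, K, K, dimnames = list(labels, labels))
  k <- 0L
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      k <- k + 1L
      h <- tryCatch({
        d <- nn_distances(sites_by_channel[[i]], sites_by_channel[[j]],
                          same_channel = i == j)
        nn_histogram(d, bin_nm, range_nm, smooth_window_bins,
                     source = labels[i], target = labels[j])
      }, error = function(e) NULL)
      if (is.null(h)) missing[i, j] <- TRUE
      hists[k] <- list(h)
    }
  }
  structure(list(channels = labels, histograms = hists, missing = missing,
                 bin_nm = bin_nm, range_nm = range_nm),
            class = "nn_histogram_set")
}

#' K x K NN peak-distance matrix
#'
#' Entry (i, j) is the peak (mode) of the first-NN distance histogram from
#' channel i sites to channel j sites — the 5 x 5 matrix of a five-lectin
#' panel, 6 x 6 when the DBCO metabolic channel is included. Missing pairs
#' are `NA`.
#'
#' @param x An `nn_histogram_set`, or a named list of `binding_sites` (then
#'   histograms are computed first with `...` passed to
#'   [nn_histogram_set()]).
#' @param ... Histogram parameters for the site-set input form.
#' @return An `nn_peak_matrix`: K x K numeric matrix (rows = source channel,
#'   columns = target) with attribute `missing`.
#' @export
peak_matrix <- function(x, ...) {
  if (!inherits(x, "nn_histogram_set")) x <- nn_histogram_set(x, ...)
  K <- length(x$channels)
  peaks <- matrix(NA_real_, K, K, dimnames = list(x$channels, x$channels))
  k <- 0L
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      k <- k + 1L
      if (!is.null(x$histograms[[k]])) peaks[i, j] <- x$histograms[[k]]$peak_nm
    }
  }
  structure(peaks, class = c("nn_peak_matrix", "matrix", "array"),
            missing = x$missing)
}

#' Full NN-distribution feature vector
#'
#' Concatenates the raw counts of all K^2 histograms, each normalized to sum
#' 1, in fixed (source, target) channel order — the input for PCA on full NN
#' distance distributions rather than their peaks alone.
#'
#' @param hset An `nn_histogram_set` with no missing pairs and consistent
#'   binning.
#' @return Named numeric vector of length `K^2 * n_bins`.
#' @export
full_distribution_features <- function(hset) {
  stopifnot(inherits(hset, "nn_histogram_set"))
  if (any(hset$missing))
    stop("missing histograms: cannot build full-distribution features",
         call. = FALSE)
  nb <- vapply(hset$histograms, function(h) length(h$counts), integer(1))
  bw <- vapply(hset$histograms, function(h) h$bin_nm, numeric(1))
  if (length(unique(nb)) != 1 || length(unique(bw)) != 1)
    stop("parameter error: inconsistent histogram binning", call. = FALSE)
  segs <- lapply(hset$histograms, function(h) h$counts / sum(h$counts))
  out <- unlist(segs, use.names = FALSE)
  centres <- hset$histograms[[1]]$bin_edges_nm[-1] - bw[1] / 2
  names(out) <- as.vector(vapply(names(hset$histograms), function(nm)
    paste0(nm, "@", centres), character(nb[1])))
  out
}

#' Export a peak matrix or histogram set as CSV
#'
#' The peak matrix is written as a labelled K x K table; histograms in long
#' format (`source`, `target`, `bin_centre_nm`, `count`).
#'
#' @param x An `nn_peak_matrix` or `nn_histogram_set`.
#' @param path Output CSV path.
#' @export
write_nn_csv <- function(x, path) {
  if (inherits(x, "nn_peak_matrix")) {
    df <- data.frame(channel = rownames(x), unclass(x), check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "nn_histogram_set")) {
    rows <- lapply(x$histograms[!vapply(x$histograms, is.null, logical(1))],
      function(h) data.frame(source = h$source, target = h$target,
        bin_centre_nm = h$bin_edges_nm[-1] - h$bin_nm / 2, count = h$counts))
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}
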