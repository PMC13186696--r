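#' Assemble a per-sample feature matrix
#'
#' Builds the samples x features matrix fed into PCA from one of the three
#' per-sample summaries:
#' \describe{
#'   \item{`"nn_peaks"`}{K x K NN peak matrices, flattened row-major into K^2
#'     columns named `"src->tgt"`. Missing (NA) entries are imputed by the
#'     per-feature cross-sample mean and masked.}
#'   \item{`"glyco"`}{GlyCo class densities per um^2 over the union of class
#'     labels across samples; a class absent from a sample contributes 0.}
#'   \item{`"nn_full"`}{concatenated normalized NN distance histograms
#'     (see [full_distribution_features()]).}
#' }
#'
#' @param samples List (one element per sample) of `nn_peak_matrix`,
#'   `glyco_table` or `nn_histogram_set` objects matching `mode`.
#' @param mode `"nn_peaks"`, `"glyco"` or `"nn_full"`.
#' @param sample_ids Character vector of sample identifiers.
#' @param conditions Character vector of condition labels per sample.
#' @return A `feature_matrix`: list with `values` (samples x features),
#'   `sample_ids`, `conditions`, `feature_names`, `mask` (logical matrix,
#'   `TRUE` where a value was imputed) and `mode`.
#' @export
assemble_features <- function(samples, mode = c("nn_peaks", "glyco", "nn_full"),
                              sample_ids = NULL, conditions = NULL) {
  mode <- match.arg(mode)
  n <- length(samples)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(conditions)) conditions <- rep(NA_character_, n)
  stopifnot(length(sample_ids) == n, length(conditions) == n)

  if (mode == "nn_peaks") {
    panels <- lapply(samples, function(s) {
      if (!inherits(s, "nn_peak_matrix")) stop("schema error: expected nn_peak_matrix", call. = FALSE)
      rownames(s)
    })
    if (length(unique(vapply(panels, paste, character(1), collapse = ","))) != 1)
      stop("schema error: inconsistent channel panels across samples", call. = FALSE)
    labels <- panels[[1]]
    fn <- as.vector(t(outer(labels, labels, paste, sep = "->")))
    values <- t(vapply(samples, function(s) as.vector(t(unclass(s))),
                       numeric(length(fn))))
  } else if (mode == "glyco") {
    for (s in samples) if (!inherits(s, "glyco_table"))
      stop("schema error: expected glyco_table", call. = FALSE)
    fn <- sort(unique(unlist(lapply(samples, function(s) s$classes$label))))
    if (length(fn) == 0) stop("schema error: no classes in any sample", call. = FALSE)
    values <- t(vapply(samples, function(s) {
      v <- stats::setNames(rep(0, length(fn)), fn)
      v[s$classes$label] <- s$classes$density_per_um2
      v
    }, numeric(length(fn))))
  } else {
    vecs <- lapply(samples, function(s) {
      if (!inherits(s, "nn_histogram_set")) stop("schema error: expected nn_histogram_set", call. = FALSE)
      full_distribution_features(s)
    })
    fn <- names(vecs[[1]])
    for (v in vecs) if (!identical(names(v), fn))
      stop("schema error: inconsistent histogram features across samples", call. = FALSE)
    values <- do.call(rbind, vecs)
  }

  colnames(values) <- fn
  rownames(values) <- sample_ids
  mask <- is.na(values)
  if (any(mask)) {
    for (j in which(colSums(mask) > 0)) {
      mu <- mean(values[, j], na.rm = TRUE)
      if (!is.finite(mu)) mu <- 0
      values[mask[, j], j] <- mu
    }
  }
  structure(list(values = values, sample_ids = sample_ids,
                 conditions = conditions, feature_names = fn,
                 mask = mask, mode = mode),
            class = "feature_matrix")
}

#' PCA state embedding of a feature matrix
#'
#' Features are z-scored across samples (zero-variance columns dropped
#' first), then decomposed by singular value decomposition. Loadings are
#' reported as the correlation between each standardized feature and each PC
#' score, so high absolute loadings flag the glycan features driving the
#' separation. The sign of each component is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param features A [assemble_features()] result.
#' @param n_components Number of components to keep (default 2, the plotted
#'   PC1/PC2); capped at `min(samples - 1, features, rank)`.
#' @return A `state_embedding`: list with `scores` (samples x components),
#'   `explained_variance_ratio`, `loadings` (features x components),
#'   `sample_ids`, `conditions`, `feature_names`, `dropped_features`.
#' @export
run_pca <- function(features, n_components = 2) {
  X <- features$values
  if (nrow(X) < 2) stop("need >= 2 samples for PCA", call. = FALSE)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("all features have zero variance", call. = FALSE)
  Xs <- scale(X)

  p <- prcomp(Xs, center = FALSE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-9)
  k <- min(n_components, nrow(X) - 1L, ncol(X), rank)
  scores <- p$x[, seq_len(k), drop = FALSE]
  evr <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  loadings <- cor(Xs, scores)
  for (c_ in seq_len(k)) {
    i <- which.max(abs(loadings[, c_]))
    if (loadings[i, c_] < 0) {
      loadings[, c_] <- -loadings[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- features$sample_ids
  structure(list(scores = scores, explained_variance_ratio = evr,
                 loadings = loadings, sample_ids = features$sample_ids,
                 conditions = features$conditions,
                 feature_names = colnames(X), dropped_features = dropped),
            class = "state_embedding")
}

#' @export
print.state_embedding <- function(x, ...) {
  cat(sprintf("<state_embedding> %d samples, %d components (EVR: %s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Ranked loading report per principal component
#'
#' For each component, features sorted by absolute loading (descending; ties
#' broken lexicographically). High absolute loadings indicate a strong
#' contribution of that glycan feature to the component.
#'
#' @param embedding A [run_pca()] result.
#' @param top_n Number of features to report per component (default all).
#' @return Named list (one data.frame per component: `feature`, `loading`,
#'   `rank`).
#' @export
loadings_report <- function(embedding, top_n = Inf) {
  lapply(stats::setNames(seq_len(ncol(embedding$loadings)),
                         colnames(embedding$loadings)), function(c_) {
    l <- embedding$loadings[, c_]
    ord <- order(-abs(l), names(l))
    out <- data.frame(feature = names(l)[ord], loading = unname(l[ord]),
                      rank = seq_along(l))
    head(out, top_n)
  })
}

#' Condition-separation score of an embedding
#'
#' Mean silhouette width of the condition labels over the first two PC
#' scores (Euclidean distance): near 1 for well-separated tight condition
#' clusters, near 0 for no structure. Conditions with a single sample are
#' excluded with a warning.
#'
#' @param embedding A [run_pca()] result.
#' @param condition_labels Labels per sample; defaults to the embedding's
#'   stored conditions.
#' @return Silhouette score in \[-1, 1\].
#' @export
separation_score <- function(embedding, condition_labels = NULL) {
  if (is.null(condition_labels)) condition_labels <- embedding$conditions
  stopifnot(length(condition_labels) == nrow(embedding$scores))
  tab <- table(condition_labels)
  small <- names(tab)[tab < 2]
  keep <- !(condition_labels %in% small)
  if (length(small))
    warning("excluding condition(s) with a single sample: ",
            paste(small, collapse = ", "))
  labs <- condition_labels[keep]
  if (length(unique(labs)) < 2)
    stop("need >= 2 conditions with >= 2 samples each", call. = FALSE)
  S <- embedding$scores[keep, seq_len(min(2L, ncol(embedding$scores))),
                        drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labs)), dist(S))
  w <- sil[, "sil_width"]
  w[!is.finite(w)] <- 0
  mean(w)
}

#' Export an embedding as CSV files
#'
#' @param embedding A [run_pca()] result.
#' @param scores_path,loadings_path,variance_path Output CSV paths (NULL to
#'   skip).
#' @export
write_embedding_csv <- function(embedding, scores_path = NULL,
                                loadings_path = NULL, variance_path = NULL) {
  if (!is.null(scores_path))
    write.csv(data.frame(sample_id = embedding$sample_ids,
                         condition = embedding$conditions,
                         embedding$scores, check.names = FALSE),
              scores_path, row.names = FALSE, quote = FALSE)
  if (!is.null(loadings_path))
    write.csv(data.frame(feature = rownames(embedding$loadings),
                         embedding$loadings, check.names = FALSE),
              loadings_path, row.names = FALSE, quote = FALSE)
  if (!is.null(variance_path))
    write.csv(data.frame(component = colnames(embedding$scores),
                         explained_variance_ratio = embedding$explained_variance_ratio),
              variance_path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
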