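#' Group binding sites at the GlyCo cut-off
#'
#' Pools the binding sites of all channels into one aligned frame and forms
#' the connected components of the graph with edges between sites at
#' distance <= `cutoff_nm` (single linkage: a site joins a group via any
#' member within the cut-off). Same-channel and cross-channel pairs both
#' count. At or below the 5-nm default, grouped sites are assumed to belong
#' to the same glycan (sub)structure.
#'
#' @param sites_by_channel Named list of `binding_sites` in one aligned
#'   coordinate frame.
#' @param cutoff_nm Grouping cut-off in nm (default 5).
#' @return A `site_groups` data.frame: one row per site with `channel`,
#'   `x_nm`, `y_nm`, `component`.
#' @export
group_sites <- function(sites_by_channel, cutoff_nm = 5) {
  stopifnot(cutoff_nm >= 0)
  labels <- names(sites_by_channel)
  if (is.null(labels))
    labels <- vapply(sites_by_channel, function(s) attr(s, "channel"), character(1))
  pooled <- do.call(rbind, lapply(seq_along(sites_by_channel), function(i) {
    s <- sites_by_channel[[i]]
    if (nrow(s) == 0) return(NULL)
    data.frame(channel = labels[i], x_nm = s$x_nm, y_nm = s$y_nm)
  }))
  if (is.null(pooled))
    pooled <- data.frame(channel = character(0), x_nm = numeric(0),
                         y_nm = numeric(0))
  pooled$component <- if (nrow(pooled))
    cpp_radius_components(pooled$x_nm, pooled$y_nm, cutoff_nm) else integer(0)
  structure(pooled, class = c("site_groups", "data.frame"),
            cutoff_nm = cutoff_nm)
}

#' Canonical GlyCo class label
#'
#' Member channel labels sorted alphabetically and joined by `"+"`, repeats
#' kept (e.g. `"AAL+WGA+WGA"`), so the label is independent of member order.
#'
#' @param channels Character vector of member channel labels.
#' @return Canonical label string.
#' @export
glyco_label <- function(channels) {
  paste(sort(channels), collapse = "+")
}

#' Build the GlyCo class table from site groups
#'
#' Every component of two or more sites becomes an instance of the class
#' identified by the multiset of its member channels; singleton components
#' carry no class and are only counted. Densities are per square micrometre
#' of the analysis ROI.
#'
#' @param groups A `site_groups` object from [group_sites()].
#' @param roi_area_um2 ROI area in um^2 (> 0), the density normalizer.
#' @return A `glyco_table`: list with `classes` (data.frame `label`, `size`,
#'   `count`, `density_per_um2`), `instances` (data.frame `label`,
#'   `centroid_x_nm`, `centroid_y_nm`, `members`), `roi_area_um2`,
#'   `n_singletons`, `n_sites`.
#' @export
classify_groups <- function(groups, roi_area_um2) {
  if (!is.numeric(roi_area_um2) || roi_area_um2 <= 0)
    stop("parameter error: roi_area_um2 must be > 0", call. = FALSE)
  comp <- split(seq_len(nrow(groups)), groups$component)
  sizes <- lengths(comp)
  multi <- comp[sizes >= 2]
  n_singletons <- sum(sizes == 1)
  if (length(multi)) {
    instances <- do.call(rbind, lapply(multi, function(i) {
      data.frame(label = glyco_label(groups$channel[i]),
                 centroid_x_nm = mean(groups$x_nm[i]),
                 centroid_y_nm = mean(groups$y_nm[i]),
                 members = paste(sort(groups$channel[i]), collapse = ","),
                 size = length(i))
    }))
    rownames(instances) <- NULL
    agg <- aggregate(cbind(count = rep(1L, nrow(instances))) ~ label + size,
                     data = instances, FUN = sum)
    agg <- agg[order(agg$label), c("label", "size", "count")]
    agg$density_per_um2 <- agg$count / roi_area_um2
    rownames(agg) <- NULL
  } else {
    instances <- data.frame(label = character(0), centroid_x_nm = numeric(0),
                            centroid_y_nm = numeric(0), members = character(0),
                            size = integer(0))
    agg <- data.frame(label = character(0), size = integer(0),
                      count = integer(0), density_per_um2 = numeric(0))
  }
  structure(list(classes = agg,
                 instances = instances[, c("label", "centroid_x_nm",
                                           "centroid_y_nm", "members")],
                 roi_area_um2 = roi_area_um2,
                 n_singletons = n_singletons,
                 n_sites = nrow(groups)),
            class = "glyco_table")
}

#' @export
print.glyco_table <- function(x, ...) {
  cat(sprintf("<glyco_table> %d classes, %d instances, %d singleton sites (%.2f um^2)\n",
              nrow(x$classes), nrow(x$instances), x$n_singletons,
              x$roi_area_um2))
  if (nrow(x$classes)) print(head(top_classes(x, 5), 5))
  invisible(x)
}

#' GlyCo classes for a channel panel
#'
#' Convenience wrapper: [group_sites()] then [classify_groups()], taking the
#' density normalizer from an [roi_polygon()] or a numeric area.
#'
#' @inheritParams group_sites
#' @param roi An [roi_polygon()] or the ROI area in um^2.
#' @param cutoff_nm Grouping cut-off in nm (default 5).
#' @return A `glyco_table` (see [classify_groups()]).
#' @export
glyco_classes <- function(sites_by_channel, roi, cutoff_nm = 5) {
  area <- if (inherits(roi, "roi_polygon")) roi_area_um2(roi) else roi
  classify_groups(group_sites(sites_by_channel, cutoff_nm), area)
}

#' Most frequent GlyCo classes
#'
#' Classes sorted by count (descending), ties broken by label in
#' lexicographic order; the ten most frequent classes are the standard
#' display.
#'
#' @param table A `glyco_table`.
#' @param n Number of classes to return (default 10; fewer when not
#'   available).
#' @return A data.frame slice of `table$classes` in rank order.
#' @export
top_classes <- function(table, n = 10) {
  stopifnot(n >= 1)
  cl <- table$classes
  cl <- cl[order(-cl$count, cl$label), , drop = FALSE]
  rownames(cl) <- NULL
  head(cl, n)
}

#' Spatial class map
#'
#' One point layer (data.frame of instance centroids) per class, for mapping
#' the cellular location of classes.
#'
#' @param table A `glyco_table`.
#' @return Named list of data.frames (`centroid_x_nm`, `centroid_y_nm`), one
#'   per class label; layers partition the instances.
#' @export
class_map <- function(table) {
  ins <- table$instances
  lapply(split(ins[, c("centroid_x_nm", "centroid_y_nm")], ins$label),
         function(d) { rownames(d) <- NULL; d })
}

#' Export a GlyCo table as CSV
#'
#' Writes the class table (`label`, `size`, `count`, `density_per_um2`) and,
#' optionally, the instance table with centroids.
#'
#' @param table A `glyco_table`.
#' @param path Class-table CSV path.
#' @param instances_path Optional instance CSV path.
#' @export
write_glyco_csv <- function(table, path, instances_path = NULL) {
  write.csv(table$classes, path, row.names = FALSE, quote = FALSE)
  if (!is.null(instances_path))
    write.csv(table$instances, instances_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
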