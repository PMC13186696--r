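#' Construct a polygon region of interest
#'
#' Manual polygon picks delimit the cell so that no extracellular signal
#' enters the analysis. Vertices are in nanometres; the polygon must be
#' simple (non-self-intersecting) with positive area.
#'
#' @param x_nm,y_nm Numeric vertex coordinates (>= 3 vertices, any winding).
#' @param label Polygon label (several labelled polygons per dataset are
#'   allowed, e.g. one per cell).
#' @return An `roi_polygon` object.
#' @export
roi_polygon <- function(x_nm, y_nm, label = "ROI") {
  stopifnot(length(x_nm) == length(y_nm))
  if (length(x_nm) < 3) stop("geometry error: polygon needs >= 3 vertices", call. = FALSE)
  if (any(!is.finite(x_nm)) || any(!is.finite(y_nm)))
    stop("geometry error: non-finite vertex", call. = FALSE)
  out <- structure(list(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                        label = label), class = "roi_polygon")
  if (shoelace_nm2(out) <= 0)
    stop("geometry error: degenerate polygon (zero area)", call. = FALSE)
  if (polygon_self_intersects(out))
    stop("geometry error: self-intersecting polygon", call. = FALSE)
  out
}

shoelace_nm2 <- function(roi) {
  x <- roi$x_nm; y <- roi$y_nm
  j <- c(seq_along(x)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# O(V^2) segment intersection test over non-adjacent edges; V is small for
# manual picks so this is never a bottleneck
polygon_self_intersects <- function(roi) {
  n <- length(roi$x_nm)
  px <- c(roi$x_nm, roi$x_nm[1]); py <- c(roi$y_nm, roi$y_nm[1])
  seg_int <- function(i, j) {
    d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- d(px[i], py[i], px[i + 1], py[i + 1], px[j], py[j])
    d2 <- d(px[i], py[i], px[i + 1], py[i + 1], px[j + 1], py[j + 1])
    d3 <- d(px[j], py[j], px[j + 1], py[j + 1], px[i], py[i])
    d4 <- d(px[j], py[j], px[j + 1], py[j + 1], px[i + 1], py[i + 1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n < 4) return(FALSE)
  for (i in 1:(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # closing edge is adjacent to the first
      if (seg_int(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> '%s': %d vertices, %.3f um^2\n",
              x$label, length(x$x_nm), roi_area_um2(x)))
  invisible(x)
}

#' Polygon area in square micrometres
#'
#' Shoelace area of the polygon, converted from nm^2; this is the normalizer
#' for class densities per square micrometre.
#'
#' @param roi An [roi_polygon()].
#' @return Area in um^2 (> 0).
#' @export
roi_area_um2 <- function(roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  shoelace_nm2(roi) / 1e6
}

#' Clip localizations or binding sites to a polygon ROI
#'
#' Points strictly inside or on the boundary are retained (closed-region
#' semantics); record order is preserved.
#'
#' @param obj A [loc_table()] or `binding_sites` data.frame with `x_nm`,
#'   `y_nm` columns.
#' @param roi An [roi_polygon()].
#' @return Object of the same type containing only in-ROI points.
#' @export
clip_to_roi <- function(obj, roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  inside <- pracma::inpolygon(obj$x_nm, obj$y_nm, roi$x_nm, roi$y_nm,
                              boundary = TRUE)
  if (inherits(obj, "loc_table")) {
    loc_table_like(obj, inside)
  } else {
    out <- obj[inside, , drop = FALSE]
    rownames(out) <- NULL
    for (a in c("channel", "report")) attr(out, a) <- attr(obj, a)
    out
  }
}

#' Read/write ROI polygons as CSV
#'
#' File format: columns `label`, `vertex_index`, `x_nm`, `y_nm`; one row per
#' vertex, vertices ordered within each label.
#'
#' @param path CSV path.
#' @return `read_roi()`: a named list of [roi_polygon()] objects.
#' @export
read_roi <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (fld in c("label", "vertex_index", "x_nm", "y_nm"))
    if (!fld %in% names(df))
      stop("ROI format error: missing field '", fld, "'", call. = FALSE)
  out <- lapply(split(df, df$label), function(d) {
    d <- d[order(d$vertex_index), ]
    roi_polygon(d$x_nm, d$y_nm, label = d$label[1])
  })
  out[unique(df$label)]
}

#' @rdname read_roi
#' @param rois List of [roi_polygon()] objects.
#' @export
write_roi <- function(rois, path) {
  if (inherits(rois, "roi_polygon")) rois <- list(rois)
  rows <- lapply(rois, function(r) {
    data.frame(label = r$label, vertex_index = seq_along(r$x_nm),
               x_nm = r$x_nm, y_nm = r$y_nm)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
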