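#' Construct a localization table
#'
#' One channel's single-molecule localizations. Coordinates are stored in
#' nanometres (image convention: origin at the upper-left of the camera ROI,
#' y increasing downward); frames are 0-based.
#'
#' @param frame Integer vector of 0-based frame indices.
#' @param x_nm,y_nm Numeric coordinates in nanometres.
#' @param photons Numeric photon counts (>= 0); defaults to 0 when unknown.
#' @param channel Channel label, e.g. `"WGA"`.
#' @param n_frames Total number of frames in the acquisition stack
#'   (default 20000, one 100-ms frame stack).
#' @param pixel_size_nm Camera pixel size used at load time; retained so the
#'   table can be written back in pixel units.
#' @return A `loc_table`: a data.frame with columns `frame`, `x_nm`, `y_nm`,
#'   `photons` and attributes `channel`, `n_frames`, `pixel_size_nm`,
#'   `units = "nm"`.
#' @export
loc_table <- function(frame, x_nm, y_nm, photons = NULL, channel = "ch1",
                      n_frames = 20000L, pixel_size_nm = 1) {
  n <- length(frame)
  if (is.null(photons)) photons <- numeric(n)
  stopifnot(length(x_nm) == n, length(y_nm) == n, length(photons) == n)
  df <- data.frame(frame = as.integer(frame), x_nm = as.numeric(x_nm),
                   y_nm = as.numeric(y_nm), photons = as.numeric(photons))
  out <- structure(df, class = c("loc_table", "data.frame"),
                   channel = channel, n_frames = as.integer(n_frames),
                   pixel_size_nm = pixel_size_nm, units = "nm")
  validate_loc_table(out)
  out
}

validate_loc_table <- function(x) {
  if (nrow(x) > 0) {
    if (any(!is.finite(x$x_nm)) || any(!is.finite(x$y_nm)))
      stop("loc_table: non-finite coordinates", call. = FALSE)
    if (any(x$frame < 0L))
      stop("loc_table: negative frame index", call. = FALSE)
    if (any(x$frame >= attr(x, "n_frames")))
      stop("loc_table: frame index >= n_frames (", attr(x, "n_frames"), ")",
           call. = FALSE)
    if (any(x$photons < 0))
      stop("loc_table: negative photon count", call. = FALSE)
  }
  invisible(x)
}

# carry loc_table attributes through a row subset
loc_table_like <- function(template, rows) {
  loc_table(template$frame[rows], template$x_nm[rows], template$y_nm[rows],
            template$photons[rows], channel = attr(template, "channel"),
            n_frames = attr(template, "n_frames"),
            pixel_size_nm = attr(template, "pixel_size_nm"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> channel %s: %d localizations over %d frames (nm units)\n",
              attr(x, "channel"), nrow(x), attr(x, "n_frames")))
  if (nrow(x) > 0) print(head(as.data.frame(x), 5))
  invisible(x)
}

#' Assemble a multi-channel panel
#'
#' @param tables List of [loc_table()] objects with unique channel labels;
#'   panels of 5 (lectins only) or 6 (with the DBCO metabolic channel)
#'   channels are typical.
#' @return A named list of class `channel_set`.
#' @export
channel_set <- function(tables) {
  labels <- vapply(tables, function(t) attr(t, "channel"), character(1))
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  names(tables) <- labels
  structure(tables, class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> K = %d channels: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

locs_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

#' Read a localization table (CSV + YAML sidecar)
#'
#' Reads a comma-separated localization table with mandatory columns
#' `frame`, `x`, `y`, `photons`; `x`/`y` are camera-pixel coordinates and are
#' converted to nanometres on load. A YAML sidecar (same basename, `.yaml`)
#' supplies `n_frames`, `channel` and `pixel_size_nm` metadata.
#'
#' @param path CSV file path.
#' @param pixel_size_nm Conversion constant in nm per pixel; `NULL` takes the
#'   sidecar value (130 nm is the typical effective pixel size after 2x2
#'   binning).
#' @param strict If `TRUE`, a record with a non-finite coordinate is a hard
#'   error; otherwise such records are dropped with a message and counted in
#'   attribute `n_rejected`.
#' @return A [loc_table()] in nanometre units.
#' @export
read_localizations <- function(path, pixel_size_nm = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("localization file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (fld in c("frame", "x", "y", "photons")) {
    if (!fld %in% names(df))
      stop("localization format error: missing mandatory field '", fld, "'",
           call. = FALSE)
  }
  meta <- list()
  sp <- locs_sidecar_path(path)
  if (file.exists(sp)) meta <- yaml::read_yaml(sp)
  if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
  if (is.null(pixel_size_nm))
    stop("pixel size unknown: pass pixel_size_nm or provide a sidecar", call. = FALSE)
  stopifnot(pixel_size_nm > 0)

  bad <- !is.finite(df$x) | !is.finite(df$y)
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    if (strict) stop("non-finite coordinate in ", path, " (strict mode)", call. = FALSE)
    message(n_rejected, " record(s) with non-finite coordinates rejected")
    df <- df[!bad, , drop = FALSE]
  }

  n_frames <- meta$n_frames
  if (is.null(n_frames)) n_frames <- if (nrow(df)) max(df$frame) + 1L else 1L
  channel <- if (!is.null(meta$channel)) meta$channel
             else tools::file_path_sans_ext(basename(path))
  out <- loc_table(df$frame, df$x * pixel_size_nm, df$y * pixel_size_nm,
                   df$photons, channel = channel, n_frames = n_frames,
                   pixel_size_nm = pixel_size_nm)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a localization table (CSV + YAML sidecar)
#'
#' Inverse of [read_localizations()]: coordinates are written back in camera
#' pixels using the table's `pixel_size_nm` attribute, and metadata
#' (`n_frames`, `channel`, `pixel_size_nm`) go to the YAML sidecar so a
#' round-trip reproduces the table.
#'
#' @param table A [loc_table()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return Invisibly, `path`.
#' @export
write_localizations <- function(table, path) {
  validate_loc_table(table)
  px <- attr(table, "pixel_size_nm")
  df <- data.frame(frame = table$frame,
                   x = sprintf("%.17g", table$x_nm / px),
                   y = sprintf("%.17g", table$y_nm / px),
                   photons = sprintf("%.17g", table$photons))
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write localization file: ", path, call. = FALSE)
  yaml::write_yaml(list(n_frames = attr(table, "n_frames"),
                        channel = attr(table, "channel"),
                        pixel_size_nm = px,
                        n_records = nrow(table)),
                   locs_sidecar_path(path))
  invisible(path)
}

#' Render a 2D localization count image
#'
#' Quality-control rendering: localizations are binned on a square grid
#' anchored at the origin. The sum of the image equals the number of
#' localizations with non-negative coordinates (points at negative
#' coordinates fall outside the image).
#'
#' @param table A [loc_table()].
#' @param bin_nm Bin (pixel) size of the rendering in nm; must be > 0.
#' @return An integer matrix of counts; rows index y bins, columns x bins.
#' @export
render_histogram_image <- function(table, bin_nm) {
  if (!is.numeric(bin_nm) || length(bin_nm) != 1 || bin_nm <= 0)
    stop("bin_nm must be a single positive number", call. = FALSE)
  keep <- table$x_nm >= 0 & table$y_nm >= 0
  x <- table$x_nm[keep]; y <- table$y_nm[keep]
  if (length(x) == 0) return(matrix(0L, 1, 1))
  ix <- floor(x / bin_nm) + 1L
  iy <- floor(y / bin_nm) + 1L
  img <- matrix(0L, nrow = max(iy), ncol = max(ix))
  for (k in seq_along(ix)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 1L
  img
}
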