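#' Adjacent-frame nearest-neighbour distances
#'
#' For every localization in frame t, the distance to its nearest
#' localization in frame t+1, kept when below `max_d_nm`. Because a DNA-PAINT
#' blink typically spans adjacent frames, these pairs are dominated by
#' repeated localizations of the same molecule, whose displacement reflects
#' the localization precision.
#'
#' @param table A [loc_table()] spanning at least two occupied frames.
#' @param max_d_nm Pairing cut-off in nm (default 100: far above plausible
#'   precision, below typical inter-site spacing).
#' @return Numeric vector of distances in nm.
#' @export
adjacent_frame_nn_distances <- function(table, max_d_nm = 100) {
  stopifnot(max_d_nm > 0)
  by_frame <- split(seq_len(nrow(table)), table$frame)
  if (length(by_frame) < 2)
    stop("insufficient data: need localizations in >= 2 frames", call. = FALSE)
  frames <- as.integer(names(by_frame))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    nxt <- match(frames[k] + 1L, frames)
    if (is.na(nxt)) next
    i <- by_frame[[k]]; j <- by_frame[[nxt]]
    d <- cpp_nn_dist(table$x_nm[i], table$y_nm[i],
                     table$x_nm[j], table$y_nm[j], FALSE)
    out[[k]] <- d[!is.na(d) & d <= max_d_nm]
  }
  unlist(out, use.names = FALSE)
}

# same-molecule displacement density: Rayleigh in the pair distance with
# per-localization precision sigma (difference of two sigma-precise fits)
nena_signal_density <- function(d, sigma) {
  d / (2 * sigma^2) * exp(-d^2 / (4 * sigma^2))
}

#' Fit the NeNA localization-precision model
#'
#' Nonlinear least-squares fit on the 1-nm-binned histogram of adjacent-frame
#' NN distances. The model is a two-component mixture: the same-molecule
#' component `d/(2 sigma^2) exp(-d^2/(4 sigma^2))` (the distance between two
#' independent localizations of one molecule, each with precision `sigma`)
#' plus a linearly rising background `2 d / max_d^2` from unrelated
#' neighbours, with a fitted mixture weight.
#'
#' @param distances Adjacent-frame NN distances in nm
#'   (see [adjacent_frame_nn_distances()]).
#' @param max_d_nm Upper support of the distances / background component.
#' @param min_pairs Minimum number of distances required (default 500).
#' @param channel Optional channel label carried into the estimate.
#' @return A `precision_estimate`: list with `sigma_nm`, `n_pairs`,
#'   `fit_rmse`, `background_fraction`, `reliable` (FALSE when the fit failed
#'   or the background dominates) and `channel`.
#' @export
fit_nena <- function(distances, max_d_nm = 100, min_pairs = 500,
                     channel = NA_character_) {
  distances <- distances[is.finite(distances) & distances >= 0 &
                           distances <= max_d_nm]
  n <- length(distances)
  if (n < min_pairs)
    stop("estimation error: ", n, " distances, need >= ", min_pairs, call. = FALSE)
  bw <- 1
  edges <- seq(0, max_d_nm, by = bw)
  counts <- tabulate(pmin(floor(distances / bw), length(edges) - 2L) + 1L,
                     nbins = length(edges) - 1L)
  centres <- edges[-length(edges)] + bw / 2

  sigma0 <- max(centres[which.max(counts)] / sqrt(2), 1)
  sigma0 <- min(sigma0, max_d_nm / 2 - 1e-6)
  df <- data.frame(d = centres, cnt = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cnt ~ n * bw * (w * nena_signal_density(d, sigma) +
                        (1 - w) * 2 * d / max_d_nm^2),
      data = df, start = list(sigma = sigma0, w = 0.8),
      lower = c(sigma = 1e-3, w = 0), upper = c(sigma = max_d_nm / 2, w = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("estimation error: NeNA fit did not converge (n_pairs = ", n, ")",
         call. = FALSE)
  cf <- coef(fit)
  est <- structure(list(
    sigma_nm = unname(cf["sigma"]),
    n_pairs = n,
    fit_rmse = sqrt(mean(resid(fit)^2)),
    background_fraction = unname(1 - cf["w"]),
    reliable = unname(cf["w"]) >= 0.5,
    channel = channel), class = "precision_estimate")
  est
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "<precision_estimate>%s sigma = %.2f nm (n = %d pairs, background %.0f%%%s)\n",
    if (is.na(x$channel)) "" else paste0(" ", x$channel), x$sigma_nm,
    x$n_pairs, 100 * x$background_fraction,
    if (x$reliable) "" else "; UNRELIABLE"))
  invisible(x)
}

#' Estimate experimental localization precision for one channel
#'
#' Convenience wrapper: adjacent-frame NN distances followed by the NeNA
#' histogram fit. The clustering radius used downstream is two times this
#' precision.
#'
#' @inheritParams adjacent_frame_nn_distances
#' @inheritParams fit_nena
#' @return A `precision_estimate` (see [fit_nena()]).
#' @export
nena_precision <- function(table, max_d_nm = 100, min_pairs = 500) {
  d <- adjacent_frame_nn_distances(table, max_d_nm)
  fit_nena(d, max_d_nm, min_pairs, channel = attr(table, "channel"))
}
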