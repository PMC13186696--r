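# Independent brute-force oracles; deliberately O(n^2)/O(nm) and written
# without the package's neighbour kernels.

# connected components at distance <= r via repeated label propagation over
# the full pairwise distance matrix
oracle_components <- function(x, y, r) {
  n <- length(x)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(cbind(x, y))) <= r
  lab <- seq_len(n)
  repeat {
    new_lab <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), numeric(1))
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  lab
}

# canonical form of a partition: labels renumbered by first appearance
canonical_partition <- function(lab) {
  match(lab, unique(lab))
}

# O(n*m) first-NN scan
oracle_nn <- function(sx, sy, tx, ty, same_set = FALSE) {
  vapply(seq_along(sx), function(i) {
    d2 <- (tx - sx[i])^2 + (ty - sy[i])^2
    if (same_set) d2[i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
}

# distances drawn from the NeNA same-molecule component for precision sigma
r_nena_signal <- function(n, sigma) {
  sigma * sqrt(-4 * log(runif(n)))
}

# linearly rising background on [0, max_d] (NN distances of unrelated CSR
# neighbours at small d)
r_nena_background <- function(n, max_d) {
  max_d * sqrt(runif(n))
}

make_sites <- function(x, y, channel = "ch") {
  n <- length(x)
  structure(data.frame(x_nm = x, y_nm = y, n_locs = rep(2L, n),
                       first_frame = rep(0L, n), last_frame = rep(0L, n)),
            class = c("binding_sites", "data.frame"), channel = channel)
}

# binding_sites views of a generated scene's ground-truth positions
truth_as_sites <- function(truth, channels) {
  out <- lapply(channels, function(ch) {
    s <- truth$sites[truth$sites$channel == ch, , drop = FALSE]
    make_sites(s$x_nm, s$y_nm, ch)
  })
  names(out) <- channels
  out
}
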