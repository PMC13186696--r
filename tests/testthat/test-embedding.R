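fake_peaks <- function(m, labels = c("A", "B")) {
  structure(m, dimnames = list(labels, labels),
            class = c("nn_peak_matrix", "matrix", "array"),
            missing = is.na(m))
}

test_that("feature assembly has the contracted shapes", {
  withr::local_seed(71)
  pk <- replicate(3, fake_peaks(matrix(runif(25, 10, 100), 5, 5,
                                       dimnames = NULL), LETTERS[1:5]),
                  simplify = FALSE)
  fm <- assemble_features(pk, "nn_peaks")
  expect_equal(dim(fm$values), c(3, 25))
  expect_equal(fm$feature_names[2], "A->B")
  expect_equal(fm$values[1, "A->B"], unclass(pk[[1]])["A", "B"])
})

test_that("nn_peaks missing entries are mean-imputed and masked", {
  m1 <- matrix(c(1, 2, 3, 4), 2, 2); m2 <- matrix(c(5, NA, 7, 8), 2, 2)
  fm <- assemble_features(list(fake_peaks(m1), fake_peaks(m2)), "nn_peaks")
  # row-major flattening: feature 3 is B->A
  expect_equal(fm$values[2, "B->A"], 2)  # imputed with the other sample's value
  expect_true(fm$mask[2, "B->A"])
  expect_false(any(is.na(fm$values)))
})

test_that("glyco features union class labels with absent classes at zero", {
  mk_tab <- function(labels, dens) {
    structure(list(classes = data.frame(label = labels, size = 2L,
                                        count = seq_along(labels),
                                        density_per_um2 = dens)),
              class = "glyco_table")
  }
  fm <- assemble_features(list(mk_tab(c("SNA+WGA", "AAL+PSA"), c(1.5, 0.2)),
                               mk_tab("AAL+PSA", 0.4)), "glyco")
  expect_setequal(fm$feature_names, c("SNA+WGA", "AAL+PSA"))
  expect_equal(fm$values[2, "SNA+WGA"], 0)
  expect_equal(fm$values[1, "SNA+WGA"], 1.5)
})

test_that("nn_full features concatenate K^2 normalized histograms", {
  spec1 <- scene_spec(field_nm = c(3000, 3000), channels = c("WGA", "SNA"),
                      site_density_per_um2 = 60, seed = 72)
  spec2 <- scene_spec(field_nm = c(3000, 3000), channels = c("WGA", "SNA"),
                      site_density_per_um2 = 60, seed = 73)
  hs <- lapply(list(spec1, spec2), function(sp)
    nn_histogram_set(truth_as_sites(generate_scene(sp)$truth, sp$channels)))
  fm <- assemble_features(hs, "nn_full")
  expect_equal(ncol(fm$values), 4 * 200)
  expect_equal(unname(rowSums(fm$values)), c(4, 4))
})

test_that("collinear samples load on a single component", {
  t <- seq(0, 1, length.out = 6)
  fm <- list(values = cbind(f1 = 1 + 2 * t, f2 = 3 - t, f3 = t),
             sample_ids = paste0("s", 1:6), conditions = rep("c", 6),
             feature_names = c("f1", "f2", "f3"),
             mask = matrix(FALSE, 6, 3), mode = "nn_peaks")
  class(fm) <- "feature_matrix"
  emb <- run_pca(fm, 2)
  expect_equal(emb$explained_variance_ratio[1], 1.0, tolerance = 1e-9)
})

test_that("a separating feature gets the top PC1 loading and rank", {
  withr::local_seed(74)
  n <- 40
  g <- rep(c(0, 1), each = n / 2)
  # the cluster split drives `sep` strongly and the rest weakly, so the
  # separation axis is PC1 and `sep` carries its largest loading
  sep <- 10 * g + rnorm(n, 0, 0.1)
  noise <- 0.5 * g + matrix(rnorm(n * 4), n)
  vals <- cbind(sep = sep, noise)
  colnames(vals) <- c("sep", paste0("n", 1:4))
  fm <- structure(list(values = vals, sample_ids = paste0("s", 1:n),
                       conditions = rep(c("a", "b"), each = n / 2),
                       feature_names = colnames(vals),
                       mask = matrix(FALSE, n, 5), mode = "nn_peaks"),
                  class = "feature_matrix")
  emb <- run_pca(fm, 2)
  expect_equal(which.max(abs(emb$loadings[, "PC1"])),
               c(sep = 1L))
  rep1 <- loadings_report(emb, top_n = 3)
  expect_equal(rep1$PC1$feature[1], "sep")
  expect_true(all(abs(emb$loadings) <= 1 + 1e-9))
  expect_true(all(diff(emb$explained_variance_ratio) <= 0))
})

test_that("scores reconstruct the standardized data up to residual variance", {
  withr::local_seed(75)
  vals <- matrix(rnorm(8 * 6), 8, 6,
                 dimnames = list(NULL, paste0("f", 1:6)))
  fm <- structure(list(values = vals, sample_ids = paste0("s", 1:8),
                       conditions = rep("c", 8), feature_names = colnames(vals),
                       mask = matrix(FALSE, 8, 6), mode = "nn_peaks"),
                  class = "feature_matrix")
  emb <- run_pca(fm, 2)
  Xs <- scale(vals)
  V <- sweep(emb$loadings, 2, apply(emb$scores, 2, sd), "/")
  resid <- Xs - emb$scores %*% t(V)
  expect_equal(sum(resid^2) / (nrow(vals) - 1),
               (1 - sum(emb$explained_variance_ratio)) * ncol(vals),
               tolerance = 1e-8)
})

test_that("the embedding is invariant to sample order and feature scaling", {
  withr::local_seed(76)
  vals <- matrix(runif(6 * 4), 6, 4, dimnames = list(NULL, paste0("f", 1:4)))
  mk <- function(v, ids = paste0("s", 1:6)) structure(
    list(values = v, sample_ids = ids, conditions = rep(c("a", "b"), 3),
         feature_names = colnames(v), mask = matrix(FALSE, 6, 4),
         mode = "nn_peaks"), class = "feature_matrix")
  emb <- run_pca(mk(vals))
  # scaling a raw feature column is absorbed by z-scoring
  v2 <- vals; v2[, 2] <- v2[, 2] * 1000
  emb2 <- run_pca(mk(v2))
  expect_equal(emb2$scores, emb$scores, tolerance = 1e-9)
  # permuting samples permutes scores identically
  perm <- c(3, 1, 6, 2, 5, 4)
  emb3 <- run_pca(mk(vals[perm, ], paste0("s", 1:6)[perm]))
  expect_equal(unname(emb3$scores), unname(emb$scores[perm, ]), tolerance = 1e-9)
  expect_equal(emb3$explained_variance_ratio, emb$explained_variance_ratio)
})

test_that("silhouette separates planted clusters and degrades under permutation", {
  withr::local_seed(77)
  n <- 12
  scores <- rbind(matrix(rnorm(n, 0, 0.1), n / 2, 2),
                  matrix(rnorm(n, 20, 0.1), n / 2, 2))
  emb <- structure(list(scores = scores,
                        conditions = rep(c("a", "b"), each = n / 2)),
                   class = "state_embedding")
  expect_gt(separation_score(emb), 0.9)
  hits <- vapply(1:100, function(i) {
    abs(separation_score(emb, sample(emb$conditions))) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.5)  # permuted labels rarely separate
  # identical points in both conditions: no separation
  emb0 <- structure(list(scores = matrix(0, 6, 2),
                         conditions = rep(c("a", "b"), 3)),
                    class = "state_embedding")
  expect_lte(separation_score(emb0), 0)
  # singleton conditions are excluded with a warning
  emb1 <- structure(list(scores = scores,
                         conditions = c(rep(c("a", "b"), each = 5), "c", "a")),
                    class = "state_embedding")
  expect_warning(separation_score(emb1), "single sample")
})
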