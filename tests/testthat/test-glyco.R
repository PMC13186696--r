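pair_sites <- function(d, cutoff = 5) {
  group_sites(list(WGA = make_sites(0, 0, "WGA"),
                   SNA = make_sites(d, 0, "SNA")), cutoff)
}

test_that("the 5-nm cut-off groups pairs and respects the threshold", {
  g <- pair_sites(3)
  expect_equal(max(g$component), 1)
  g2 <- pair_sites(6)
  expect_equal(max(g2$component), 2)  # two singletons, no class
  expect_equal(nrow(classify_groups(g2, 1)$classes), 0)
  expect_equal(classify_groups(g2, 1)$n_singletons, 2)
})

test_that("grouping is transitive (single-linkage chain)", {
  ch <- c("WGA", "SNA", "WGA", "AAL", "PHA-L")
  sites <- lapply(unique(ch), function(l) {
    i <- which(ch == l)
    make_sites(4 * (i - 1), rep(0, length(i)), l)
  })
  names(sites) <- unique(ch)
  g <- group_sites(sites, 5)
  expect_equal(length(unique(g$component)), 1)
  tab <- classify_groups(g, 1)
  expect_equal(tab$classes$label, "AAL+PHA-L+SNA+WGA+WGA")
  expect_equal(tab$classes$size, 5L)
})

test_that("class labels are canonical multisets with correct arithmetic", {
  sites <- list(
    WGA = make_sites(c(0, 100, 203), c(0, 0, 0), "WGA"),
    SNA = make_sites(c(3, 97), c(0, 0), "SNA"))
  # groups: {W,S}, {S,W}, {W,W}? build the W+W pair explicitly
  sites$WGA <- make_sites(c(0, 100, 203, 206), c(0, 0, 0, 0), "WGA")
  tab <- glyco_classes(sites, 2, cutoff_nm = 5)
  cl <- tab$classes
  expect_setequal(cl$label, c("SNA+WGA", "WGA+WGA"))
  expect_equal(cl$count[cl$label == "SNA+WGA"], 2L)
  expect_equal(cl$density_per_um2[cl$label == "SNA+WGA"], 1.0)
  expect_equal(cl$count[cl$label == "WGA+WGA"], 1L)
  expect_equal(cl$density_per_um2[cl$label == "WGA+WGA"], 0.5)
  # conservation: sum(count * size) + singletons = total sites
  expect_equal(sum(cl$count * cl$size) + tab$n_singletons, 6)
})

test_that("grouping equals the brute-force union-find oracle", {
  withr::local_seed(61)
  for (rep in 1:5) {
    n <- 400
    labs <- sample(c("WGA", "SNA", "AAL"), n, replace = TRUE)
    x <- runif(n, 0, 600); y <- runif(n, 0, 600)
    sites <- lapply(unique(labs), function(l)
      make_sites(x[labs == l], y[labs == l], l))
    names(sites) <- unique(labs)
    g <- group_sites(sites, 5)
    # oracle over the same pooled order
    want <- oracle_components(g$x_nm, g$y_nm, 5)
    expect_equal(canonical_partition(g$component), canonical_partition(want))
  }
})

test_that("components are monotone in the cut-off and vanish as it -> 0", {
  withr::local_seed(62)
  sites <- list(A = make_sites(runif(200, 0, 300), runif(200, 0, 300), "A"),
                B = make_sites(runif(200, 0, 300), runif(200, 0, 300), "B"))
  cuts <- c(0.001, 2, 5, 10, 25)
  ncomp <- vapply(cuts, function(cc) max(group_sites(sites, cc)$component),
                  numeric(1))
  expect_true(all(diff(ncomp) <= 0))
  g0 <- group_sites(sites, 1e-9)
  expect_equal(max(g0$component), 400)  # all singletons
  expect_equal(nrow(classify_groups(g0, 1)$classes), 0)
})

test_that("relabelling channels permutes labels but preserves counts", {
  spec <- scene_spec(field_nm = c(3000, 3000), site_density_per_um2 = 60,
                     channels = c("WGA", "SNA"), seed = 63)
  sites <- truth_as_sites(generate_scene(spec)$truth, c("WGA", "SNA"))
  tab1 <- glyco_classes(sites, 9, 5)
  swapped <- list(WGA = make_sites(sites$SNA$x_nm, sites$SNA$y_nm, "WGA"),
                  SNA = make_sites(sites$WGA$x_nm, sites$WGA$y_nm, "SNA"))
  tab2 <- glyco_classes(swapped, 9, 5)
  expect_equal(sort(tab1$classes$count), sort(tab2$classes$count))
  expect_equal(tab1$n_singletons, tab2$n_singletons)
})

test_that("planted motif mixture is recovered with correct proportions", {
  spec <- scene_spec(field_nm = c(10000, 10000), site_density_per_um2 = 12,
                     motifs = list(list(channels = c("SNA", "WGA"), weight = 0.6),
                                   list(channels = c("AAL", "PSA", "WGA"), weight = 0.4)),
                     motif_fraction = 0.35, motif_radius_nm = 4,
                     min_separation_nm = 50, seed = 64)
  sc <- generate_scene(spec)
  sites <- truth_as_sites(sc$truth, spec$channels)
  tab <- glyco_classes(sites, roi_area_um2(spec$roi), 5)
  cl <- tab$classes
  main <- cl[cl$label %in% c("SNA+WGA", "AAL+PSA+WGA"), ]
  prop <- main$count / sum(main$count)
  names(prop) <- main$label
  expect_lt(abs(prop["SNA+WGA"] - 0.6), 0.05)
  # no spurious class above 1% of instances
  spurious <- cl[!cl$label %in% c("SNA+WGA", "AAL+PSA+WGA"), ]
  expect_true(all(spurious$count <= 0.01 * sum(cl$count)))
})

test_that("top_classes ranks by count with lexicographic ties", {
  tab <- list(classes = data.frame(
    label = c("A+B", "A+C", "B+C"), size = 2L,
    count = c(5L, 3L, 3L), density_per_um2 = c(5, 3, 3) / 2))
  top <- top_classes(tab, 2)
  expect_equal(top$label, c("A+B", "A+C"))
  expect_equal(nrow(top_classes(tab, 50)), 3)
  withr::local_seed(65)
  counts <- sample.int(100, 20, replace = TRUE)
  tab2 <- list(classes = data.frame(label = sprintf("C%02d+X", 1:20), size = 2L,
                                    count = counts, density_per_um2 = counts))
  got <- top_classes(tab2, 20)
  ord <- order(-tab2$classes$count, tab2$classes$label)
  expect_equal(got$label, tab2$classes$label[ord])
})

test_that("class maps partition instances and preserve planted geometry", {
  # left half carries SNA+WGA pairs, right half only distant singletons
  sites <- list(WGA = make_sites(c(1:20 * 30, 9000 + 1:20 * 30), rep(0, 40), "WGA"),
                SNA = make_sites(c(1:20 * 30 + 3, 9000 + 1:20 * 30 + 500.5),
                                 rep(0, 40), "SNA"))
  tab <- glyco_classes(sites, 10, 5)
  layers <- class_map(tab)
  expect_equal(sum(vapply(layers, nrow, integer(1))), sum(tab$classes$count))
  expect_true(all(layers[["SNA+WGA"]]$centroid_x_nm < 9000))
})
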