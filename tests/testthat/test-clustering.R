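test_that("Pearson distance matches the explicit covariance formula", {
  set.seed(2)
  m <- matrix(rnorm(5 * 10), 5, 10)
  e <- make_expr(m, sample_names = design_names(c("AM", "CS"), stages = 1:3,
                                                reps = c("A", "B", "C"))[1:10])
  d <- pearson_distance_matrix(e, "samples")
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j], 1 - oracle_pearson(m[, i], m[, j]), tolerance = 1e-12)
  }
  expect_equal(diag(d), rep(0, 10), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # identical samples -> 0; anti-correlated -> 2
  m2 <- cbind(1:5, 1:5, 5:1)
  e2 <- make_expr(m2, sample_names = c("AM081", "CS081", "MN081"))
  d2 <- pearson_distance_matrix(e2)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 2)
  # zero-variance vector is an error naming it
  e3 <- make_expr(cbind(rep(1, 4), rnorm(4)), sample_names = c("AM081", "CS081"))
  expect_error(pearson_distance_matrix(e3), "AM081")
})

test_that("1 - r distance is invariant to per-gene affine rescaling", {
  set.seed(6)
  m <- matrix(rnorm(8 * 6), 8, 6)
  nms <- c("AM081", "AM082", "AM083", "CS081", "CS082", "CS083")
  d1 <- pearson_distance_matrix(make_expr(m, sample_names = nms), "genes")
  m2 <- m * 3.7 - 11
  d2 <- pearson_distance_matrix(make_expr(m2, sample_names = nms), "genes")
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("dendrogram merges match a brute-force agglomeration oracle", {
  # two leaves: single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_dendrogram(d2)
  expect_equal(hc2$height, 0.3)
  # 4-leaf toy with hand-set distances, average and complete linkage
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4[upper.tri(d4)] <- c(0.1, 0.4, 0.5, 0.45, 0.55, 0.2)
  d4 <- d4 + t(d4)
  for (linkage in c("average", "complete")) {
    hc <- hierarchical_dendrogram(d4, linkage)
    expect_equal(sort(hc$height), sort(oracle_agglomerate(d4, linkage)),
                 tolerance = 1e-12)
  }
})

test_that("dendrogram heights are invariant to leaf input order", {
  set.seed(8)
  m <- matrix(rnorm(30 * 6), 30, 6)
  nms <- c("AM081", "AM082", "AM083", "CS081", "CS082", "CS083")
  e <- make_expr(m, sample_names = nms)
  hc1 <- hierarchical_dendrogram(pearson_distance_matrix(e), "average")
  perm <- c(3, 6, 1, 5, 2, 4)
  e2 <- expr_subset(e, samples = nms[perm])
  hc2 <- hierarchical_dendrogram(pearson_distance_matrix(e2), "average")
  expect_equal(sort(hc1$height), sort(hc2$height), tolerance = 1e-12)
})

test_that("Newick export reproduces leaf labels and parses with ape", {
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4[upper.tri(d4)] <- c(0.1, 0.4, 0.5, 0.45, 0.55, 0.2)
  d4 <- d4 + t(d4)
  hc <- hierarchical_dendrogram(d4, "average")
  nwk <- dendrogram_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, letters[1:4])
})

test_that("profile k-means separates identical-profile groups perfectly", {
  nms <- design_names("AM", stages = 1:3, reps = c("A", "B", "C"))
  up <- rep(c(1, 5, 9), each = 3)
  down <- rep(c(9, 5, 1), each = 3)
  m <- rbind(matrix(rep(up, 5), 5, byrow = TRUE),
             matrix(rep(down, 5), 5, byrow = TRUE))
  m <- m + matrix(rnorm(90, 0, 1e-6), 10)  # break exact ties only
  e <- make_expr(m, sample_names = nms)
  pc <- kmeans_profiles(e, k = 2, seed = 1)
  cl <- pc$assignment$cluster
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_true(cl[1] != cl[6])
  expect_lt(pc$tot_withinss, 1e-6)
  # monotonicity labels from centroid stage means
  info <- tidy(pc)
  expect_equal(unique(info$monotonicity[1:5]), "up")
  expect_equal(unique(info$monotonicity[6:10]), "down")
})

test_that("planted monotone-up genes land in up-labelled clusters", {
  sp <- synthetic_spec(n_vineyards = 6, n_constitutive = 0, n_marker_up = 60,
                       n_marker_down = 60, n_plastic = 0, n_year_effect = 0,
                       n_bimodal_low = 0, n_background = 80)
  d <- generate_dataset(sp, seed = 15)
  avg <- average_replicates(d$expr)
  pc <- kmeans_profiles(avg, k = 6, seed = 2)
  lab <- tidy(pc)
  up_true <- d$truth$gene_id[d$truth$class == "marker_up"]
  up_called <- lab$gene_id[lab$monotonicity == "up"]
  expect_gte(mean(up_true %in% up_called), 0.95)
  down_true <- d$truth$gene_id[d$truth$class == "marker_down"]
  expect_length(intersect(down_true, up_called), 0)
})

test_that("k-means is deterministic under a fixed seed", {
  set.seed(3)
  nms <- design_names(c("AM", "CS"), stages = 1:3, reps = "A")
  m <- matrix(rnorm(40 * 6), 40, 6)
  e <- make_expr(m, sample_names = nms)
  p1 <- kmeans_profiles(e, k = 3, seed = 9)
  p2 <- kmeans_profiles(e, k = 3, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
})
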