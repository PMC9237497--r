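test_that("population_means averages cells and reports missing ones", {
  d <- tiny_design(lines = 3, reps = 2, treatments = default_treatments(1))
  tab <- simulate_trait_table(d, tiny_params(), "M2", seed = 4)
  mm <- population_means(tab, "V1", "M2")
  expect_setequal(names(mm), c("treatment", "y", "PY"))
  hand <- tab |>
    dplyr::filter(treatment == "G1", trait == "y") |>
    dplyr::pull(value) |> mean()
  expect_equal(mm$y[mm$treatment == "G1"], hand)
  expect_error(population_means(dplyr::filter(tab, !(treatment == "G1" &
                                                       trait == "y")),
                                "V1", "M2"),
               "missing cells: G1/y")
  # single observation per cell: matrix equals the raw values
  one <- tibble::tibble(variety = "V", generation = "M2",
                        treatment = c("A", "B"), line = "L1", replicate = 1L,
                        trait = "t", value = c(3.5, 4.5))
  expect_equal(population_means(one, "V", "M2")$t, c(3.5, 4.5))
})

test_that("euclidean distances satisfy metric axioms and printed-table anchors", {
  mm <- reference_mean_matrix("Gomati VU-89", "M2")
  d <- euclidean_matrix(mm)
  dm <- as.matrix(d)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  # triangle inequality, exhaustive over all triples (13 populations)
  n <- nrow(dm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
  # the most similar pair of the printed matrix
  expect_equal(dm["G1+S1", "S3"], 2.67, tolerance = 0.005)
  # two populations, one trait -> absolute difference
  m2 <- tibble::tibble(treatment = c("A", "B"), t = c(3, 7.5))
  expect_equal(as.vector(euclidean_matrix(m2)), 4.5)
  # identical rows at distance zero
  m3 <- tibble::tibble(treatment = c("A", "B"), t1 = c(1, 1), t2 = c(2, 2))
  expect_equal(as.vector(euclidean_matrix(m3)), 0)
  # standardization flag and its zero-variance guard
  expect_s3_class(euclidean_matrix(mm, standardize = TRUE), "dist")
  expect_error(euclidean_matrix(m3, standardize = TRUE), "zero-variance")
})

test_that("upgma reproduces the hand-worked toy and keeps heights monotone", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma(dm)
  expect_equal(h$height, c(2, 4))
  expect_setequal(h$labels[-h$merge[1, ]], c("A", "B"))
  expect_error(upgma(dm[1, 1, drop = FALSE]), "at least 2")
  # all-equal distances: equal heights, deterministic output
  de <- matrix(3, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  h1 <- upgma(de); h2 <- upgma(de)
  expect_equal(h1$height, rep(3, 3))
  expect_identical(h1$merge, h2$merge)
  # label order invariance: shuffling rows gives the same heights
  set.seed(10)
  x <- matrix(rnorm(60), 6)
  rownames(x) <- paste0("P", 1:6)
  d1 <- dist(x)
  perm <- sample(6)
  d2 <- dist(x[perm, ])
  expect_equal(upgma(d1)$height, upgma(d2)$height, tolerance = 1e-12)
})

test_that("adding a constant to all off-diagonal distances shifts UPGMA heights by it", {
  set.seed(12)
  for (i in 1:10) {
    x <- matrix(rnorm(36), 6)
    rownames(x) <- paste0("P", 1:6)
    d0 <- dist(x)
    shift <- runif(1, 0.5, 3)
    d1 <- stats::as.dist(as.matrix(d0) + shift * (1 - diag(6)))
    expect_equal(upgma(d1)$height, upgma(d0)$height + shift,
                 tolerance = 1e-10)
    expect_true(all(diff(upgma(d0)$height) >= -1e-12))
  }
})

test_that("flat clusters recover construction and collapse at the limits", {
  # two well-separated pairs
  mm <- tibble::tibble(treatment = c("A1", "A2", "B1", "B2"),
                       t1 = c(0, 0.5, 10, 10.5), t2 = c(0, 0.2, 9.8, 10))
  d <- euclidean_matrix(mm)
  h <- upgma(d)
  cp <- cluster_profiles(h, 2, mm, d)
  grp <- split(cp$membership$treatment, cp$membership$cluster)
  expect_true(setequal(grp[[1]], c("A1", "A2")) ||
                setequal(grp[[1]], c("B1", "B2")))
  # brute-force: the chosen 2-split minimizes within-cluster mean distance
  dm <- as.matrix(d)
  splits <- list(c("A1", "A2"), c("A1", "B1"), c("A1", "B2"))
  within <- vapply(splits, function(s) {
    o <- setdiff(mm$treatment, s)
    mean(c(dm[s, s][upper.tri(dm[s, s])], dm[o, o][upper.tri(dm[o, o])]))
  }, 0)
  expect_true(setequal(grp[[1]], splits[[which.min(within)]]) ||
                setequal(grp[[2]], splits[[which.min(within)]]))
  # k = n: profiles equal the mean matrix rows
  cpn <- cluster_profiles(h, 4, mm, d)
  expect_equal(nrow(cpn$profiles), 4)
  expect_setequal(cpn$profiles$t1, mm$t1)
  # k = 1: column means
  cp1 <- cluster_profiles(h, 1, mm, d)
  expect_equal(cp1$profiles$t1, mean(mm$t1))
  expect_error(cluster_profiles(h, 9, mm, d), "k")
  # inter-cluster distance = average of member pair distances
  expect_equal(cp$intercluster[1, 2],
               mean(dm[grp[[1]], grp[[2]]]))
})

test_that("an outlying population isolates in a singleton cluster and extreme PC1 score", {
  mm <- reference_mean_matrix("Gomati VU-89", "M2")
  far <- mm
  far[far$treatment == "G4+S4", -1] <- far[far$treatment == "G4+S4", -1] + 400
  d <- euclidean_matrix(far)
  cp <- cluster_profiles(upgma(d), 2, far, d)
  sizes <- table(cp$membership$cluster)
  singleton <- cp$membership$treatment[
    cp$membership$cluster == names(sizes)[sizes == 1]]
  expect_equal(singleton, "G4+S4")
  pc <- pca_populations(far)
  sc <- pc$scores$PC1
  expect_equal(far$treatment[which.max(abs(sc))], "G4+S4")
})

test_that("correlation PCA satisfies its closed-form and spectral identities", {
  # two traits with correlation rho: eigenvalues (1 + rho, 1 - rho)
  set.seed(21)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40, 0, 0.6)
  mm <- tibble::tibble(treatment = paste0("P", 1:40), a = x, b = y)
  rho <- cor(x, y)
  pc <- pca_populations(mm)
  expect_equal(pc$eigenvalues, c(1 + rho, 1 - rho), tolerance = 1e-10)
  expect_equal(pc$pct_variance[1], 100 * (1 + rho) / 2, tolerance = 1e-10)
  # general identities on the reference matrix
  ref <- pca_populations(reference_mean_matrix())
  expect_equal(sum(ref$eigenvalues), 10, tolerance = 1e-10)
  expect_equal(unname(rowSums(ref$cos2)), rep(1, 10), tolerance = 1e-10)
  expect_equal(unname(colSums(ref$contrib)), rep(100, 10), tolerance = 1e-10)
  # sign convention: the largest |loading| per component is positive
  for (j in seq_len(ncol(ref$loadings))) {
    expect_gte(ref$loadings[which.max(abs(ref$loadings[, j])), j], 0)
  }
  expect_error(pca_populations(tibble::tibble(treatment = c("A", "B"),
                                              t1 = c(1, 1), t2 = c(1, 2))),
               "zero-variance")
})

test_that("PCA matches an independent power-iteration eigensolver", {
  set.seed(33)
  for (i in 1:5) {
    x <- matrix(rnorm(13 * 10), 13)
    mm <- tibble::as_tibble(x, .name_repair = ~paste0("t", 1:10)) |>
      dplyr::mutate(treatment = paste0("P", 1:13), .before = 1)
    pc <- pca_populations(mm)
    oracle <- power_eigen(cor(x))
    expect_equal(pc$eigenvalues, oracle$values, tolerance = 1e-8)
    for (j in 1:10) {
      # eigenvectors agree up to sign
      expect_lt(min(sum(abs(pc$loadings[, j] - oracle$vectors[, j])),
                    sum(abs(pc$loadings[, j] + oracle$vectors[, j]))), 1e-6)
    }
  }
})

test_that("permuting population rows permutes scores and preserves variance fractions", {
  mm <- reference_mean_matrix()
  pc1 <- pca_populations(mm)
  perm <- c(5:13, 1:4)
  pc2 <- pca_populations(mm[perm, ])
  expect_equal(pc2$pct_variance, pc1$pct_variance, tolerance = 1e-12)
  s1 <- pc1$scores[match(pc2$scores$treatment, pc1$scores$treatment), ]
  expect_equal(as.matrix(s1[, -1]), as.matrix(pc2$scores[, -1]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("dendrograms round-trip to Newick", {
  mm <- reference_mean_matrix()
  h <- upgma(euclidean_matrix(mm))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(h, tf)
  phy <- ape::read.tree(tf)
  expect_setequal(phy$tip.label, mm$treatment)
  expect_equal(ape::Ntip(phy), 13)
})
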