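test_that("haplotype distance matrices match their definitions", {
  m <- rbind(c(14, 13, 16), c(14, 13, 16), c(14, 15, 16))
  h <- as_num_haps(m)
  d_sq <- haplotype_distance_matrix(h, "sumsq")
  d_ct <- haplotype_distance_matrix(h, "count")
  expect_equal(d_sq[1, 2], 0)
  expect_equal(d_sq[1, 3], 4)   # single locus differing by 2 repeats
  expect_equal(d_ct[1, 3], 1)
  expect_equal(d_sq, t(d_sq))

  # brute-force double loop on random data
  set.seed(9)
  h2 <- random_haps(10)
  d <- haplotype_distance_matrix(h2, "sumsq")
  for (i in 1:10) for (j in 1:10)
    expect_equal(d[i, j], sum((unclass(h2)[i, ] - unclass(h2)[j, ])^2))

  h3 <- as_num_haps(rbind(c(1, NA), c(NA, 1)))
  expect_error(haplotype_distance_matrix(h3), "no shared")
})

test_that("PhiST is 1 for fixed differences and matches the 8-individual oracle", {
  # two groups each fixed for its own haplotype: no within-group variance
  h <- as_num_haps(rbind(matrix(14, 4, 15), matrix(16, 4, 15)))
  ph <- amova_phist(h, rep(c("A", "B"), each = 4), n_perm = 99, seed = 1)
  expect_equal(ph$estimate["A", "B"], 1)

  # 8-individual toy case: values frozen from a spreadsheet-style
  # evaluation of the sum-of-squares decomposition
  x <- rbind(c(10, 10, 10), c(10, 10, 11), c(10, 11, 10), c(10, 10, 10),
             c(12, 10, 10), c(12, 10, 11), c(12, 11, 10), c(12, 10, 12))
  h8 <- as_num_haps(x)
  g <- rep(c("g1", "g2"), each = 4)
  d2 <- haplotype_distance_matrix(h8)
  ss <- ygeo:::amova_ss(d2, g)
  expect_equal(unname(ss), c(13.5, 5, 8.5))
  comp <- ygeo:::phist_from_ss(ss, c(4, 4))
  expect_equal(comp$ms_among, 8.5)
  expect_equal(comp$ms_within, 5 / 6, tolerance = 1e-12)
  expect_equal(comp$n_prime, 4)
  expect_equal(comp$phist, 0.696969696969697, tolerance = 1e-12)
  ph8 <- amova_phist(h8, g, n_perm = 99, seed = 1)
  expect_equal(ph8$estimate["g1", "g2"], 0.696969696969697,
               tolerance = 1e-12)
})

test_that("PhiST is invariant under relabelling and distance scaling", {
  set.seed(21)
  h <- random_haps(14)
  g <- rep(c("A", "B"), each = 7)
  d2 <- haplotype_distance_matrix(h)
  base <- ygeo:::phist_two_groups(d2, 7)
  expect_equal(ygeo:::phist_two_groups(d2 * 3.7, 7), base,
               tolerance = 1e-12)
  # reordering within groups leaves PhiST fixed
  p <- c(sample(1:7), sample(8:14))
  expect_equal(ygeo:::phist_two_groups(d2[p, p], 7), base,
               tolerance = 1e-12)
  # relabelling haplotype values (adding a constant) leaves PhiST fixed
  h2 <- as_num_haps(unclass(h) + 5)
  expect_equal(ygeo:::phist_two_groups(haplotype_distance_matrix(h2), 7),
               base, tolerance = 1e-12)
})

test_that("permutation P is uniform under the null", {
  set.seed(1234)
  n_rep <- 200
  hits <- 0L
  for (r in seq_len(n_rep)) {
    h <- random_haps(16)
    ph <- amova_phist(h, rep(c("A", "B"), each = 8), n_perm = 99)
    if (ph$p_value["A", "B"] <= 0.05) hits <- hits + 1L
  }
  # 99% binomial bounds around 5% of 200
  expect_gte(hits, 3)
  expect_lte(hits, 17)
})

test_that("Shannon mutual information hits its closed-form anchors", {
  h_same <- as_num_haps(rbind(matrix(10, 4, 15), matrix(11, 4, 15),
                              matrix(10, 4, 15), matrix(11, 4, 15)))
  g <- rep(c("A", "B"), each = 8)
  expect_equal(shannon_mutual_information(h_same, g), 0)

  # disjoint haplotype sets in equal halves attain ln 2
  h_disj <- as_num_haps(rbind(matrix(10, 6, 15), matrix(20, 6, 15)))
  expect_equal(shannon_mutual_information(h_disj,
                                          rep(c("A", "B"), each = 6)),
               log(2))

  # plug-in entropy oracle on a small mixed case
  hA <- as_num_haps(rbind(matrix(1, 3, 2), matrix(2, 1, 2)))
  hB <- as_num_haps(rbind(matrix(1, 1, 2), matrix(2, 3, 2)))
  h <- rbind(unclass(hA), unclass(hB))
  gg <- rep(c("A", "B"), each = 4)
  hp <- -sum(c(0.5, 0.5) * log(c(0.5, 0.5)))
  hw <- -sum(c(0.75, 0.25) * log(c(0.75, 0.25)))
  expect_equal(shannon_mutual_information(as_num_haps(h), gg), hp - hw,
               tolerance = 1e-12)
  expect_gte(shannon_mutual_information(as_num_haps(h), gg), 0)
  expect_error(shannon_mutual_information(hA, rep("A", 4)), "2 groups")
})

test_that("PCoA reconstructs Euclidean configurations", {
  # collinear points: one positive axis carries all variance
  d <- as.matrix(dist(cbind(c(0, 1, 2), 0)))
  pc <- pcoa(d)
  expect_equal(pc$variance_fraction[1], 1)

  # equilateral triangle: two equal eigenvalues at 50% each
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  pc3 <- pcoa(d3)
  expect_equal(pc3$variance_fraction, c(0.5, 0.5), tolerance = 1e-9)

  # random planar configuration: distances reproduced to 1e-8 and
  # coordinates agree with the reference implementation
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2)
  d10 <- as.matrix(dist(pts))
  pc10 <- pcoa(d10)
  rec <- as.matrix(dist(pc10$coordinates))
  expect_lt(max(abs(rec - d10)), 1e-8)
  ref <- stats::cmdscale(d10, k = 2, eig = TRUE)
  expect_equal(abs(pc10$coordinates[, 1:2]), abs(ref$points),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(pc10$variance_fraction), 1, tolerance = 1e-12)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
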