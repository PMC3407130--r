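test_that("DYS389b derivation subtracts the embedded repeat count", {
  rec <- make_records(n = 2)
  rec$DYS389I <- c("13", NA)
  rec$DYS389II <- c("29", "30")
  out <- derive_dys389b(rec)
  expect_identical(out$DYS389b, c("16", NA))
  expect_identical(out$DYS389I, c("13", NA))  # retained

  bad <- make_records(n = 1)
  bad$DYS389I <- "30"; bad$DYS389II <- "29"
  expect_error(derive_dys389b(bad), "non-positive")

  # inverse identity on random valid pairs
  set.seed(3)
  i <- sample(10:16, 50, replace = TRUE)
  b <- sample(14:18, 50, replace = TRUE)
  rec2 <- make_records(n = 50)
  rec2$DYS389I <- as.character(i)
  rec2$DYS389II <- as.character(i + b)
  out2 <- derive_dys389b(rec2)
  expect_equal(as.numeric(out2$DYS389I) + as.numeric(out2$DYS389b),
               as.numeric(out2$DYS389II))
})

test_that("numeric conversion applies the partial-repeat fraction rule", {
  rec <- make_records(n = 1)
  rec$DYS458 <- "17.2"          # tetranucleotide
  rec$DYS392 <- "11.1"          # trinucleotide
  rec <- derive_dys389b(rec)
  h <- numeric_haplotypes(rec)
  expect_equal(ncol(h), 15)
  expect_equal(unname(h[1, "DYS458"]), 17.5)
  expect_equal(unname(h[1, "DYS392"]), 11 + 1 / 3)
  expect_equal(unname(h[1, "DYS19"]), 14)  # integers unchanged
  expect_null(attr(h, "dys385"))

  rec$DYS458 <- "17.5"  # suffix not below unit length
  expect_error(numeric_haplotypes(derive_dys389b(rec)), "repeat unit")

  # duplicated singleton locus is masked missing
  rec2 <- make_records(n = 1)
  rec2$DYS19 <- "15-16"
  h2 <- numeric_haplotypes(derive_dys389b(rec2))
  expect_true(is.na(h2[1, "DYS19"]))

  # 17-locus mode carries the sorted DYS385 pair
  rec3 <- make_records(n = 1, dys385 = "14-11")
  h3 <- numeric_haplotypes(derive_dys389b(rec3), drop_dys385 = FALSE)
  expect_equal(unname(attr(h3, "dys385")[1, ]), c(11, 14))
})

test_that("pairwise difference counts follow locus and multiset rules", {
  a <- as_num_haps(matrix(c(14, 13, 16, 24, 11), 1))
  b <- as_num_haps(matrix(c(14, 14, 16, 26, 12), 1))
  expect_equal(pairwise_allele_differences(a, a), 0L)
  expect_equal(pairwise_allele_differences(a, b), 3L)
  expect_equal(multistep_neighbor_count(a, b), 1L)  # only the 2-step

  # missing loci are excluded without rescaling
  b2 <- b; b2[1, 2] <- NA
  expect_equal(pairwise_allele_differences(a, as_num_haps(unclass(b2))), 2L)

  # DYS385 multiset: one shared allele counts one difference
  m <- matrix(14, 2, 15)
  h_ab <- as_num_haps(m, dys385 = rbind(c(11, 14), c(11, 15)))
  expect_equal(pairwise_allele_differences(subset_hap(h_ab, 1),
                                           subset_hap(h_ab, 2)), 1L)
  h_cd <- as_num_haps(m, dys385 = rbind(c(11, 14), c(12, 15)))
  expect_equal(pairwise_allele_differences(subset_hap(h_cd, 1),
                                           subset_hap(h_cd, 2)), 2L)
  h_ef <- as_num_haps(m, dys385 = rbind(c(11, 14), c(14, 15)))
  expect_equal(pairwise_allele_differences(subset_hap(h_ef, 1),
                                           subset_hap(h_ef, 2)), 1L)

  expect_error(pairwise_allele_differences(a, h_ab), "panel mismatch")
})

test_that("group pairwise means match the brute-force double loop", {
  set.seed(11)
  h <- random_haps(12)
  m <- unclass(h)
  m[sample(length(m), 8)] <- NA  # some missing entries
  h <- as_num_haps(m)
  for (stat in c("diff", "multistep")) {
    got <- ygeo:::allele_diff_matrix(h, stat)
    want <- oracle_pair_diff(m, multistep = (stat == "multistep"))
    expect_equal(unname(got), unname(want))
  }
  # multistep never exceeds the difference count
  expect_true(all(ygeo:::allele_diff_matrix(h, "multistep") <=
                    ygeo:::allele_diff_matrix(h, "diff")))
})

test_that("diversity statistics match the Nei formula", {
  # all identical
  h1 <- as_num_haps(matrix(14, 6, 15))
  d1 <- diversity_stats(h1)
  expect_equal(d1$H, 0)
  expect_equal(d1$D, 1 / 6)
  expect_equal(d1$n_pairs, 15)

  # all distinct
  h2 <- as_num_haps(matrix(seq_len(90), 6, 15))
  d2 <- diversity_stats(h2)
  expect_equal(d2$H, 1)
  expect_equal(d2$D, 1)

  # mixed sample against the hand-applied formula: 5 copies of one
  # haplotype, 3 of another, 2 singletons (n = 10)
  m <- rbind(matrix(10, 5, 15), matrix(11, 3, 15),
             matrix(12, 1, 15), matrix(13, 1, 15))
  d3 <- diversity_stats(as_num_haps(m))
  p <- c(5, 3, 1, 1) / 10
  expect_equal(d3$H, 10 * (1 - sum(p^2)) / 9)
  expect_equal(d3$k, 4)
  expect_error(diversity_stats(as_num_haps(matrix(1, 1, 15))), "n >= 2")

  # a 41-member group yields 820 pairwise comparisons
  expect_equal(diversity_stats(random_haps(41))$n_pairs, 820)
})

test_that("dispersion comparison behaves at the extremes", {
  set.seed(5)
  base <- random_haps(8)
  # identical groups: delta is zero, P is 1
  cd <- compare_dispersion(base, base, "diff", n_perm = 200, seed = 1)
  expect_equal(cd$delta, 0)
  expect_equal(cd$p_value, 1, tolerance = 0.05)
  expect_equal(cd$n_pairs_a, 28)

  # strongly separated dispersion: one group monomorphic, the other wild
  tight <- as_num_haps(matrix(14, 10, 15))
  wild <- random_haps(10)
  cd2 <- compare_dispersion(tight, wild, "diff", n_perm = 400, seed = 2)
  expect_lte(cd2$p_value, 3 / 401)

  # the t-test route agrees on direction
  cd3 <- compare_dispersion(tight, wild, "diff", method = "t.test")
  expect_lt(cd3$p_value, 0.001)
  expect_error(compare_dispersion(subset_hap(base, 1), base), "n >= 2")
})
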