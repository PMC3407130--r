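test_that("paternal-relative dedup keeps one record per matching group", {
  rec <- make_records(n = 3, haplogroup = c("R-M17", "R-M17", "R-M17"),
                      descent_group = c("f1", "f1", "f2"))
  dd <- dedup_paternal_relatives(rec)
  expect_equal(nrow(dd$kept), 2)
  expect_equal(nrow(dd$removed), 1)
  expect_true("S001" %in% dd$kept$id)  # lexicographically smallest kept

  # identical genotypes but distinct descent groups are all kept
  rec2 <- make_records(n = 2, haplogroup = c("R-M17", "R-M17"),
                       descent_group = c("f1", "f2"))
  expect_equal(nrow(dedup_paternal_relatives(rec2)$kept), 2)

  # differing STR profile blocks grouping
  m <- matrix(rep(c(14, 13, 29, 24, 11, 13, 13, 15, 12, 12, 19, 15, 17,
                    23, 12), each = 2), nrow = 2,
              dimnames = list(NULL, yf_singletons))
  m[2, "DYS19"] <- 15
  rec3 <- make_records(str = m, haplogroup = c("R-M17", "R-M17"),
                       descent_group = c("f1", "f1"))
  expect_equal(nrow(dedup_paternal_relatives(rec3)$kept), 2)

  # idempotence
  dd2 <- dedup_paternal_relatives(dd$kept)
  expect_identical(dd2$kept, dd$kept)
})

test_that("haplogroup frequency tables reproduce count arithmetic and CIs", {
  labels <- c(rep("R-M173", 152), rep("other", 270 - 152))
  fr <- haplogroup_frequencies(data.frame(haplogroup = labels))
  r1 <- fr[fr$haplogroup == "R-M173", ]
  expect_equal(r1$count, 152)
  expect_equal(r1$percent, 56.3)
  expect_true(r1$informative)

  # frequencies sum to one per group
  set.seed(1)
  lab2 <- sample(letters[1:6], 100, replace = TRUE)
  grp <- rep(c("A", "B"), 50)
  fr2 <- haplogroup_frequencies(data.frame(haplogroup = lab2), grp)
  sums <- tapply(fr2$frequency, fr2$group, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
  # CIs contain the point estimate after clamping
  expect_true(all(fr2$ci_lower <= fr2$frequency + 1e-12))
  expect_true(all(fr2$ci_upper >= fr2$frequency - 1e-12))
  expect_error(haplogroup_frequencies(data.frame(haplogroup = "x")[0, ,
                                                 drop = FALSE]),
               "empty group")
})

test_that("modified-Wald CI matches its defining formula and clamps", {
  ci <- modified_wald_ci(38, 270)
  pt <- (38 + 2) / (270 + 4)
  hw <- 1.96 * sqrt(pt * (1 - pt) / (270 + 4))
  expect_equal(unname(ci[1, "lower"]), pt - hw, tolerance = 1e-12)
  expect_equal(unname(ci[1, "upper"]), pt + hw, tolerance = 1e-12)

  ci0 <- modified_wald_ci(0, 20)
  expect_identical(unname(ci0[1, "lower"]), 0)
  ci1 <- modified_wald_ci(20, 20)
  expect_identical(unname(ci1[1, "upper"]), 1)
})

test_that("Fisher exact matches closed forms and enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 3), 2)), "margin")

  # random small tables against the choose()-based enumeration oracle
  # and against the standard reference implementation
  set.seed(42)
  for (rep in 1:200) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact_2x2(tab)$p_value
    expect_equal(mine, oracle_fisher_p(tab), tolerance = 1e-12)
    expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("multiple-testing adjustment follows the step-up definitions", {
  expect_equal(adjust_pvalues(0.03, "BH")$adjusted, 0.03)
  a <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH", alpha = 0.05)
  expect_true(all(a$significant))
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(adjust_pvalues(p, "BH")$adjusted, oracle_bh(p),
                 tolerance = 1e-12)
    # BY inflates BH elementwise
    expect_true(all(adjust_pvalues(p, "BY")$adjusted >=
                      adjust_pvalues(p, "BH")$adjusted - 1e-12))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(adjust_pvalues(rep(0.01, 5))$bonferroni_critical, 0.01)
})
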