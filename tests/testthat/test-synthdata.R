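small_cfg <- function(seed = 1, ...) {
  mun <- data.frame(municipality = c("a1", "a2", "b1", "b2", "b3", "b4"),
                    x_km = c(5, 10, 25, 30, 35, 40),
                    y_km = c(5, 8, 15, 20, 15, 25),
                    region = c("A", "A", "B", "B", "B", "B"),
                    n = c(5, 5, 15, 15, 10, 10),
                    stringsAsFactors = FALSE)
  sim_config(seed = seed, municipalities = mun, n_duplicates = 3, ...)
}

test_that("zero mutation pressure reproduces founders exactly", {
  for (cfg in list(small_cfg(generations = 0),
                   small_cfg(mu = 1e-9))) {
    sim <- simulate_population(cfg)
    rec <- derive_dys389b(sim$records)
    h <- numeric_haplotypes(rec, drop_dys385 = FALSE)
    founders <- sim$truth$founders
    ids <- rec$id
    truth_hg <- sim$truth$haplogroup[sub("R$", "", ids)]
    for (i in seq_len(nrow(rec))) {
      f <- founders[truth_hg[i], ]
      expect_equal(unname(unclass(h)[i, "DYS19"]), unname(f["DYS19"]))
      expect_equal(unname(unclass(h)[i, "DYS389b"]), unname(f["DYS389b"]))
      expect_equal(unname(attr(h, "dys385")[i, ]),
                   unname(sort(f[c("DYS385.a", "DYS385.b")])))
    }
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_population(small_cfg(seed = 5))
  s2 <- simulate_population(small_cfg(seed = 5))
  expect_identical(s1$records, s2$records)
  p1 <- simulate_pasture_points(small_cfg(seed = 5))
  p2 <- simulate_pasture_points(small_cfg(seed = 5))
  expect_identical(p1, p2)
  s3 <- simulate_population(small_cfg(seed = 6))
  expect_false(identical(s1$records, s3$records))
})

test_that("planted relative duplicates are removed by dedup (287 -> 270 shape)", {
  cfg <- sim_config(seed = 11)  # study-scale defaults
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$records), 287)
  rec <- call_haplogroups(sim$records)
  dd <- dedup_paternal_relatives(rec)
  expect_equal(nrow(dd$kept), 270)
  expect_equal(nrow(dd$removed), 17)
})

test_that("haplogroup calls on simulated SNP profiles recover the truth", {
  sim <- simulate_population(small_cfg(seed = 9))
  rec <- call_haplogroups(sim$records)
  node <- sub("\\*$", "", sub("^[A-Z]+-", "", rec$haplogroup))
  truth <- sim$truth$haplogroup[sub("R$", "", rec$id)]
  expect_equal(unname(node), unname(truth))
})

test_that("the region-restricted clade is absent in region A lineages", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_population(cfg)
  hg <- sim$truth$haplogroup
  lr <- sim$truth$lineage_region[names(hg)]
  expect_equal(sum(hg[lr == "A"] == "M17"), 0)
  expect_gt(mean(hg[lr == "B"] == "M17"), 0.10)
})

test_that("pasture point clouds honor counts and cluster geometry", {
  cfg <- sim_config(seed = 17)
  pts <- simulate_pasture_points(cfg)
  expect_equal(nrow(pts), 853)
  comp <- etymon_composition(pts)
  expect_equal(comp$count, c(606, 145, 102))

  # zero spread collapses points onto the configured centers
  cl <- cfg$pasture_clusters
  cl$Romance$sd_km <- 0
  cfg0 <- sim_config(seed = 17, pasture_clusters = cl)
  p0 <- simulate_pasture_points(cfg0)
  rom <- p0[p0$etymon_class == "Romance", ]
  expect_true(all(paste(rom$x_km, rom$y_km) %in%
                    paste(cl$Romance$centers[, 1], cl$Romance$centers[, 2])))

  # empirical class centroids sit within 3 SE of the mixture mean
  sla <- pts[pts$etymon_class == "Slavic", ]
  ctr <- cfg$pasture_clusters$Slavic
  mx <- sum(ctr$weights * ctr$centers[, 1])
  spread_x <- sqrt(sum(ctr$weights * (ctr$centers[, 1]^2 + ctr$sd_km^2)) -
                     mx^2)
  expect_lt(abs(mean(sla$x_km) - mx), 3 * spread_x / sqrt(nrow(sla)))
})

test_that("PhiST is monotone nondecreasing in divergence generations", {
  # two populations whose founders split `gen` generations ago: the B
  # founder is the A founder evolved under the same stepwise model,
  # while within-population depth is held fixed
  phist_at <- function(gen, seed) {
    mun <- data.frame(municipality = c("a1", "b1"), x_km = c(0, 30),
                      y_km = c(0, 0), region = c("A", "B"),
                      n = c(40, 40), stringsAsFactors = FALSE)
    freq <- list(A = c("U106/S21" = 1), B = c("M17" = 1))
    base <- ygeo:::founder_haplotypes(c("M17", "U106/S21"))
    base["M17", ] <- base["U106/S21", ]   # common ancestor
    set.seed(seed + gen)
    drift <- vapply(seq_len(ncol(base)), function(j)
      ygeo:::stepwise_displacement(1, gen, 0.02), integer(1))
    base["M17", ] <- base["M17", ] + drift
    cfg <- sim_config(seed = seed, municipalities = mun, hg_freq = freq,
                      generations = 25, mu = 0.02, founders = base,
                      migration_prob = 0, n_duplicates = 0)
    sim <- simulate_population(cfg)
    h <- numeric_haplotypes(derive_dys389b(sim$records))
    reg <- substr(sim$records$municipality_proband, 1, 1)
    amova_phist(h, reg, n_perm = 9)$estimate[1, 2]
  }
  grid <- c(0, 50, 200, 800)
  ph <- rowMeans(vapply(1:3, function(s)
    vapply(grid, phist_at, numeric(1), seed = 100 * s), numeric(4)))
  expect_lt(abs(ph[1]), 0.1)              # common founder: no structure
  expect_true(all(diff(ph) > -0.05))      # nondecreasing within MC slack
  expect_gt(ph[4], ph[1] + 0.2)
})
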