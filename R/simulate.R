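# default synthetic municipality layout: 29 municipalities in a ~55 x 40
# km alpine box; region A (former Romance settlement) in the southwest,
# region B elsewhere, with a dominant central hub municipality.  Sample
# sizes total 270 retained probands: 35 in region A, 235 in region B.
default_municipalities <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
municipality x_km y_km region n
A01  6  6 A 5
A02 10  5 A 5
A03 14  6 A 5
A04 18  5 A 4
A05 22  6 A 4
A06  9 10 A 4
A07 14 11 A 4
A08 19 10 A 4
B01 28 14 B 99
B02 31 16 B 19
B03 26 18 B 12
B04 24 22 B 10
B05 27 26 B 9
B06 30 30 B 8
B07 33 34 B 7
B08 35 20 B 7
B09 39 22 B 7
B10 43 24 B 6
B11 47 26 B 6
B12 51 28 B 6
B13 33 12 B 5
B14 38 13 B 5
B15 43 14 B 5
B16 48 15 B 5
B17 22 27 B 4
B18 25 31 B 4
B19 36 28 B 5
B20 40 31 B 3
B21 44 34 B 3
")
  stopifnot(sum(df$n) == 270, sum(df$n[df$region == "A"]) == 35)
  df
}

# per-region haplogroup founder frequencies (tree node names); anchored
# to the printed regional pattern: the R1a clade (M17) absent in region A
# but at 16% in region B, the R1b clade totalling 68.6% (A) vs 37.9% (B),
# I1 / J / G2a at similar frequencies in both regions.
default_hg_freq <- function() {
  a <- c("U106/S21" = 0.200, "U152/S28" = 0.230, "M412/S167" = 0.143,
         "L23/S141" = 0.057, "M269" = 0.029, "M343" = 0.027,
         "M96" = 0.057, "M253" = 0.086, "M304" = 0.057, "P15" = 0.057,
         "P37.2" = 0.029, "M9" = 0.028)
  b <- c("U106/S21" = 0.187, "U152/S28" = 0.115, "M412/S167" = 0.030,
         "S116" = 0.026, "L23/S141" = 0.011, "M269" = 0.010,
         "M17" = 0.160, "M253" = 0.166, "M304" = 0.094, "P15" = 0.077,
         "M78" = 0.021, "M96" = 0.004, "P37.2" = 0.021, "M223" = 0.017,
         "M242" = 0.013, "M9" = 0.013, "M70" = 0.009, "M89" = 0.009,
         "M20" = 0.004, "M170" = 0.013)
  stopifnot(abs(sum(a) - 1) < 1e-9, abs(sum(b) - 1) < 1e-9)
  list(A = a, B = b)
}

# deterministic founder haplotypes: a modal 17-allele profile shifted by
# small haplogroup-specific offsets so that between-haplogroup distances
# dominate within-haplogroup mutation noise.  DYS389 is simulated as
# DYS389I and the non-overlapping block DYS389b; the concatenated
# DYS389II designation is emitted as their sum.
founder_haplotypes <- function(hg_names) {
  loci <- c("DYS19", "DYS389I", "DYS389b", "DYS390", "DYS391", "DYS392",
            "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
            "DYS458", "DYS635", "YGATAH4", "DYS385.a", "DYS385.b")
  modal <- c(14, 13, 16, 24, 11, 13, 13, 15, 12, 12, 19, 15, 17, 23, 12,
             11, 14)
  hg_names <- sort(hg_names)
  f <- t(vapply(seq_along(hg_names), function(k) {
    modal + ((k * 7 + seq_along(loci) * 3) %% 5) - 2
  }, numeric(length(loci))))
  dimnames(f) <- list(hg_names, loci)
  f
}

# default pasture-point cluster layout: Slavic names focused in the east
# and north, Romance in the southwest, Germanic evenly spread; counts
# 606/145/102 give the 71/17/12% composition of the 853-name corpus.
default_pasture_clusters <- function() {
  list(
    Germanic = list(n = 606, uniform = TRUE,
                    bbox = c(0, 55, 0, 40)),
    Slavic = list(n = 145, uniform = FALSE,
                  centers = matrix(c(26, 20, 30, 29, 42, 26, 45, 14),
                                   ncol = 2, byrow = TRUE),
                  weights = c(30, 35, 40, 40) / 145, sd_km = 4),
    Romance = list(n = 102, uniform = FALSE,
                   centers = matrix(c(10, 7, 18, 8), ncol = 2,
                                    byrow = TRUE),
                   weights = c(60, 42) / 102, sd_km = 4))
}

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: 29 municipalities with
#' 270 retained probands (35 region A, 235 region B) plus 17 planted
#' paternal-relative duplicates (287 raw samples), region-structured
#' haplogroup founder frequencies with a region-restricted R1a clade,
#' symmetric single-step stepwise Y-STR mutation at mu = 2e-3 per locus
#' per generation over 120 generations since the haplogroup founders,
#' patrilocal three-generation residence histories, road distances
#' inflated 1.4x over Euclidean, and an 853-point pasture-name corpus at
#' 71/17/12\% Germanic/Slavic/Romance composition.
#'
#' @param seed integer seed.
#' @param municipalities data.frame with `municipality`, `x_km`, `y_km`,
#'   `region`, `n` (sample size).
#' @param hg_freq list with elements `A` and `B`: named founder
#'   frequencies over marker-tree node names, each summing to 1.
#' @param generations generations since the haplogroup founders.
#' @param mu per-locus per-generation stepwise mutation rate, in
#'   (0, 0.1).
#' @param multistep_prob probability that a mutation jumps 2 repeats
#'   instead of 1 (default 0; set e.g. 0.05 to exercise multi-step
#'   statistics).
#' @param migration_prob probability per generation step that the
#'   lineage moved municipality.
#' @param stay_region_prob probability that a migration stays within the
#'   region.
#' @param p_father_known probability the father's municipality is
#'   recorded.
#' @param p_grandfather_known probability the grandfather's municipality
#'   is recorded given the father's is.
#' @param founders optional matrix of founder haplotypes (rows named by
#'   haplogroup node, columns the 17 allele slots including `DYS389b`
#'   and the `DYS385.a`/`DYS385.b` pair); default a deterministic
#'   modal-plus-offset table covering all configured haplogroups.
#' @param n_duplicates planted paternal-relative duplicates.
#' @param road_inflation road distance = Euclidean x this factor.
#' @param pasture_clusters per-class point cluster parameters, see
#'   source of `default_pasture_clusters`.
#' @param tree marker tree used for canonical SNP profiles.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       municipalities = default_municipalities(),
                       hg_freq = default_hg_freq(),
                       generations = 120, mu = 2e-3,
                       multistep_prob = 0,
                       migration_prob = 0.33, stay_region_prob = 0.9,
                       p_father_known = 0.759,
                       p_grandfather_known = 0.687,
                       founders = NULL,
                       n_duplicates = 17, road_inflation = 1.4,
                       pasture_clusters = default_pasture_clusters(),
                       tree = ygeo_tree()) {
  if (mu <= 0 || mu >= 0.1) stop("mu must lie in (0, 0.1)")
  if (generations < 0) stop("generations must be >= 0")
  for (r in names(hg_freq)) {
    if (abs(sum(hg_freq[[r]]) - 1) > 1e-6)
      stop("founder frequencies for region ", r, " must sum to 1")
    bad <- setdiff(names(hg_freq[[r]]), tree$marker)
    if (length(bad) > 0)
      stop("founder frequency node(s) not in tree: ",
           paste(bad, collapse = ", "))
  }
  if (any(municipalities$n < 0)) stop("sample sizes must be nonnegative")
  cfg <- list(seed = as.integer(seed), municipalities = municipalities,
              hg_freq = hg_freq, generations = as.integer(generations),
              mu = mu, multistep_prob = multistep_prob,
              migration_prob = migration_prob,
              stay_region_prob = stay_region_prob,
              p_father_known = p_father_known,
              p_grandfather_known = p_grandfather_known,
              founders = founders,
              n_duplicates = as.integer(n_duplicates),
              road_inflation = road_inflation,
              pasture_clusters = pasture_clusters, tree = tree)
  class(cfg) <- "sim_config"
  cfg
}

# net repeat displacement after `gen` generations of stepwise mutation
# for `n` independent lineages at one locus
stepwise_displacement <- function(n, gen, mu, multistep_prob = 0) {
  if (gen == 0 || n == 0) return(integer(n))
  k <- stats::rbinom(n, gen, mu)
  vapply(k, function(ki) {
    if (ki == 0) return(0L)
    steps <- sample(c(-1L, 1L), ki, replace = TRUE)
    if (multistep_prob > 0) {
      big <- stats::runif(ki) < multistep_prob
      steps[big] <- steps[big] * 2L
    }
    sum(steps)
  }, integer(1))
}

#' Simulate a genotyped, geolocated population sample
#'
#' Draws each individual's haplogroup from its ancestral region's
#' founder frequencies, evolves the founder Y-STR haplotype forward
#' under the symmetric single-step stepwise mutation model, writes the
#' noiseless canonical SNP profile of the drawn haplogroup, generates a
#' patrilocal three-generation municipality history with the migration
#' kernel, and plants paternal-relative duplicates (identical genotypes,
#' shared descent group).
#'
#' @param cfg a [sim_config()].
#' @return list with `records` (records data.frame of
#'   `270 + n_duplicates` rows under the default sizes) and `truth`
#'   (list: `region` named by municipality, `haplogroup` named by id,
#'   `founders`, `config`).
#' @export
simulate_population <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  mun <- cfg$municipalities
  tree <- cfg$tree
  hg_all <- sort(unique(unlist(lapply(cfg$hg_freq, names))))
  founders <- cfg$founders %||% founder_haplotypes(hg_all)
  if (!all(hg_all %in% rownames(founders)))
    stop("founder table lacks haplogroup(s): ",
         paste(setdiff(hg_all, rownames(founders)), collapse = ", "))
  region_of <- stats::setNames(mun$region, mun$municipality)
  n_total <- sum(mun$n)
  proband_mun <- rep(mun$municipality, mun$n)

  # backward residence history: proband municipality is where the sample
  # was placed; father and grandfather follow the (reversed) migration
  # kernel, staying put with probability 1 - migration_prob per step
  migrate_from <- function(m) {
    if (stats::runif(1) >= cfg$migration_prob) return(m)
    same_region <- stats::runif(1) < cfg$stay_region_prob
    pool <- mun$municipality[if (same_region)
      mun$region == region_of[[m]] else mun$region != region_of[[m]]]
    pool <- setdiff(pool, m)
    if (length(pool) == 0) m else sample(pool, 1)
  }
  father_mun <- vapply(proband_mun, migrate_from, character(1))
  grandf_mun <- vapply(father_mun, migrate_from, character(1))

  # lineage region (drives the haplogroup draw) is the ancestral one
  lineage_region <- region_of[grandf_mun]
  hg <- vapply(lineage_region, function(r) {
    f <- cfg$hg_freq[[r]]
    sample(names(f), 1, prob = f)
  }, character(1))

  # Y-STR haplotypes: founder + stepwise mutation, per locus
  loci17 <- colnames(founders)
  hap <- founders[hg, , drop = FALSE]
  for (j in seq_along(loci17))
    hap[, j] <- hap[, j] + stepwise_displacement(n_total, cfg$generations,
                                                 cfg$mu,
                                                 cfg$multistep_prob)
  hap[hap < 5] <- 5  # floor: allele designations stay positive

  ids <- sprintf("ET%04d", seq_len(n_total))
  by_p <- sprintf("%d", sample(1945:1985, n_total, replace = TRUE))
  by_f <- sprintf("%d", as.integer(by_p) - sample(25:35, n_total, TRUE))
  by_g <- sprintf("%d", as.integer(by_f) - sample(25:35, n_total, TRUE))
  f_known <- stats::runif(n_total) < cfg$p_father_known
  g_known <- f_known & stats::runif(n_total) < cfg$p_grandfather_known

  rec <- data.frame(id = ids,
                    municipality_proband = proband_mun,
                    municipality_father = ifelse(f_known, father_mun, NA),
                    municipality_grandfather = ifelse(g_known, grandf_mun,
                                                      NA),
                    birth_year_proband = by_p, birth_year_father = by_f,
                    birth_year_grandfather = by_g,
                    surname_etymon_class = "Germanic",
                    descent_group = paste0("fam", seq_len(n_total)),
                    stringsAsFactors = FALSE)
  for (loc in c("DYS19", "DYS390", "DYS391", "DYS392", "DYS393", "DYS437",
                "DYS438", "DYS439", "DYS448", "DYS456", "DYS458",
                "DYS635", "YGATAH4"))
    rec[[loc]] <- as.character(hap[, loc])
  rec$DYS389I <- as.character(hap[, "DYS389I"])
  rec$DYS389II <- as.character(hap[, "DYS389I"] + hap[, "DYS389b"])
  d385 <- cbind(pmin(hap[, "DYS385.a"], hap[, "DYS385.b"]),
                pmax(hap[, "DYS385.a"], hap[, "DYS385.b"]))
  rec$DYS385 <- paste(d385[, 1], d385[, 2], sep = "-")

  # noiseless canonical SNP profile of the drawn haplogroup
  canon <- t(vapply(hg_all, function(h)
    unname(canonical_profile(tree, h)), character(n_markers(tree))))
  colnames(canon) <- tree$marker
  canon <- ifelse(canon == "derived", "D", "A")
  for (m in tree$marker) rec[[paste0("snp.", m)]] <- canon[hg, m]

  # plant paternal-relative duplicates: copies sharing descent group and
  # all genotype data
  if (cfg$n_duplicates > 0) {
    src <- sample.int(n_total, cfg$n_duplicates, replace = FALSE)
    dup <- rec[src, , drop = FALSE]
    dup$id <- sprintf("ET%04dR", src)
    rec <- rbind(rec, dup)
    rec <- rec[order(rec$id), , drop = FALSE]
    rownames(rec) <- NULL
  }

  truth <- list(region = region_of,
                haplogroup = stats::setNames(hg, ids),
                lineage_region = stats::setNames(unname(lineage_region),
                                                 ids),
                founders = founders, config = cfg)
  list(records = rec, truth = truth)
}

#' Simulate etymon-classified pasture-name points
#'
#' Gaussian-mixture point clouds for the Slavic and Romance classes and
#' a uniform scatter over the study box for the Germanic class; class
#' counts are honored exactly.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override (default `cfg$seed + 1`).
#' @return data.frame with `x_km`, `y_km`, `etymon_class`.
#' @export
simulate_pasture_points <- function(cfg = sim_config(), seed = NULL) {
  set.seed(seed %||% (cfg$seed + 1L))
  out <- list()
  for (cl in names(cfg$pasture_clusters)) {
    p <- cfg$pasture_clusters[[cl]]
    if (isTRUE(p$uniform)) {
      x <- stats::runif(p$n, p$bbox[1], p$bbox[2])
      y <- stats::runif(p$n, p$bbox[3], p$bbox[4])
    } else {
      comp <- sample.int(nrow(p$centers), p$n, replace = TRUE,
                         prob = p$weights)
      x <- stats::rnorm(p$n, p$centers[comp, 1], p$sd_km)
      y <- stats::rnorm(p$n, p$centers[comp, 2], p$sd_km)
    }
    out[[cl]] <- data.frame(x_km = x, y_km = y, etymon_class = cl,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Road-distance matrix of a simulated geography
#'
#' Euclidean municipality distances inflated by the configured factor,
#' emulating valley road networks without a road graph.
#'
#' @param cfg a [sim_config()].
#' @return symmetric km matrix with zero diagonal.
#' @export
simulate_road_distances <- function(cfg = sim_config()) {
  m <- cfg$municipalities
  d <- as.matrix(stats::dist(cbind(m$x_km, m$y_km))) * cfg$road_inflation
  dimnames(d) <- list(m$municipality, m$municipality)
  d
}

#' Write a complete synthetic input bundle
#'
#' Emits the three input files consumed by [run_pipeline()]
#' (population, geo + distances, pasture points) plus a ground-truth
#' table, all as delimited text.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_population(cfg)
  pts <- simulate_pasture_points(cfg)
  geo <- cfg$municipalities[, c("municipality", "x_km", "y_km", "region")]
  paths <- c(population = file.path(dir, "population.tsv"),
             geo = file.path(dir, "geo.tsv"),
             distances = file.path(dir, "distances.tsv"),
             points = file.path(dir, "points.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_population_table(sim$records, paths["population"])
  write_delim_tsv(geo, paths["geo"])
  write_square_matrix(simulate_road_distances(cfg), paths["distances"])
  write_delim_tsv(pts, paths["points"])
  write_delim_tsv(data.frame(id = names(sim$truth$haplogroup),
                             haplogroup = unname(sim$truth$haplogroup),
                             lineage_region =
                               unname(sim$truth$lineage_region)),
                  paths["truth"])
  invisible(paths)
}
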