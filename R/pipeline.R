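#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow: read inputs, call haplogroups,
#' remove paternal-relative duplicates, derive toponym-density regions,
#' place individuals at the configured generation level, compute
#' haplogroup frequency tables with region contrasts, Y-STR diversity
#' and dispersion statistics, region-level PhiST and Shannon mutual
#' information, municipality-level distance matrices, spatial
#' autocorrelograms against road distances, and principal coordinates,
#' and write every artifact to `out_dir`.  The run is deterministic
#' given the config seed.
#'
#' @param config an [analysis_config()].
#' @param inputs named list/vector of paths: `population`, `geo`,
#'   `distances`, `points`.
#' @param out_dir output directory (created if needed).
#' @param tree marker tree (default the packaged canonical tree).
#' @return invisibly, a list with all stage results, the stage `log`
#'   (data.frame of record counts in/out) and `paths` of written files.
#' @export
run_pipeline <- function(config, inputs, out_dir, tree = ygeo_tree()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1]] <<- data.frame(stage = stage, n_in = n_in,
                                          n_out = n_out, detail = detail,
                                          stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- load -----------------------------------------------------------
  records <- run_stage("read_population",
                       read_population_table(inputs[["population"]]))
  gd <- run_stage("read_geo",
                  read_geo_and_distances(inputs[["geo"]],
                                         inputs[["distances"]]))
  points <- run_stage("read_points", read_pasture_points(inputs[["points"]]))
  note("read_population", NA, nrow(records))

  ## --- haplogroup calling and deduplication ---------------------------
  records <- run_stage("call_haplogroups", call_haplogroups(records, tree))
  dd <- run_stage("dedup", dedup_paternal_relatives(records))
  note("dedup_paternal_relatives", nrow(records), nrow(dd$kept),
       paste0(nrow(dd$removed), " paternal-relative duplicates removed"))
  records <- dd$kept

  ## --- toponym density and regionalization ----------------------------
  if (nrow(points) == 0)
    run_stage("density", stop("no pasture points supplied"))
  bbox <- c(range(points$x_km), range(points$y_km))
  grids <- run_stage("density", lapply(
    stats::setNames(nm = c("Germanic", "Slavic", "Romance")),
    function(cl) point_density(points[points$etymon_class == cl, ],
                               cell_km = config$density_cell_km,
                               radius_km = config$density_radius_km,
                               bbox = bbox)))
  fallback <- NULL
  if ("region" %in% names(gd$geo) && !all(is.na(gd$geo$region)))
    fallback <- stats::setNames(gd$geo$region, gd$geo$municipality)
  regions <- run_stage("classify_regions",
                       classify_regions(grids$Romance, grids$Slavic,
                                        gd$geo, margin = 0,
                                        fallback = fallback))
  region_of <- stats::setNames(regions$region, regions$municipality)
  note("classify_regions", nrow(gd$geo), sum(!is.na(regions$region)),
       paste0(sum(regions$provenance == "unresolved"), " unresolved"))

  ## --- generation-level placement -------------------------------------
  mun_col <- paste0("municipality_", config$generation_level)
  placed <- !is.na(records[[mun_col]])
  note("generation_placement", nrow(records), sum(placed),
       paste0("level=", config$generation_level, "; ",
              sum(!placed), " without municipality excluded"))
  spatial_records <- records[placed, , drop = FALSE]
  spatial_records$municipality <- spatial_records[[mun_col]]
  spatial_records$region <- region_of[spatial_records$municipality]
  has_region <- !is.na(spatial_records$region)
  if (any(!has_region))
    note("region_placement", nrow(spatial_records), sum(has_region),
         "individuals in unresolved municipalities excluded")
  spatial_records <- spatial_records[has_region, , drop = FALSE]

  ## --- haplogroup frequencies and region contrasts --------------------
  freq_all <- run_stage("frequencies",
                        haplogroup_frequencies(
                          records, "all",
                          informative_threshold =
                            config$informative_threshold))
  freq_region <- run_stage("frequencies_region",
                           haplogroup_frequencies(
                             spatial_records, spatial_records$region,
                             informative_threshold =
                               config$informative_threshold))
  contrasts <- run_stage("fisher_contrasts",
                         region_contrasts(spatial_records,
                                          method = config$p_adjust_method))

  ## --- Y-STR preparation and diversity --------------------------------
  records <- run_stage("derive_dys389b", derive_dys389b(records))
  spatial_records <- derive_dys389b(spatial_records)
  haps_all <- run_stage("to_numeric", numeric_haplotypes(records))
  haps_sp <- numeric_haplotypes(spatial_records)
  div <- run_stage("diversity", rbind(
    cbind(group = "all", as.data.frame(diversity_stats(haps_all))),
    do.call(rbind, lapply(sort(unique(spatial_records$region)),
                          function(r) {
      cbind(group = r, as.data.frame(
        diversity_stats(subset_hap(haps_sp,
                                   which(spatial_records$region == r)))))
    }))))

  ## --- dispersion contrasts within haplogroups ------------------------
  disp <- run_stage("dispersion",
                    dispersion_contrasts(spatial_records, haps_sp,
                                         n_perm = config$permutations_fst,
                                         seed = config$seed + 11L))

  ## --- region-level distances -----------------------------------------
  d2_sp <- run_stage("distance_matrix", haplotype_distance_matrix(haps_sp))
  phist_region <- run_stage("phist_region",
                            amova_phist(haps_sp, spatial_records$region,
                                        n_perm = config$permutations_fst,
                                        seed = config$seed + 21L,
                                        d2 = d2_sp))
  shua_region <- run_stage("shua_region",
                           shua_matrix(haps_sp, spatial_records$region,
                                       n_perm = 0))
  shua_region_locus <- shua_matrix(haps_sp, spatial_records$region,
                                   per_locus = TRUE, n_perm = 0)

  ## --- municipality-level distances, correlograms, PCoA ---------------
  mun_n <- table(spatial_records$municipality)
  keep_mun <- names(mun_n)[mun_n >= 2]
  note("municipal_subset", length(mun_n), length(keep_mun),
       "municipalities with n >= 2 retained for spatial analysis")
  in_mun <- spatial_records$municipality %in% keep_mun
  haps_mun <- subset_hap(haps_sp, which(in_mun))
  mun_labels <- spatial_records$municipality[in_mun]
  phist_mun <- run_stage("phist_municipal",
                         amova_phist(haps_mun, mun_labels,
                                     n_perm = config$permutations_fst,
                                     seed = config$seed + 31L,
                                     d2 = d2_sp[in_mun, in_mun]))
  shua_mun <- run_stage("shua_municipal",
                        shua_matrix(haps_mun, mun_labels, n_perm = 0))
  road <- gd$dist[phist_mun$labels, phist_mun$labels]
  classes <- run_stage("distance_classes",
                       build_distance_classes(road, "even",
                                              k = config$n_distance_classes))
  cg <- list()
  for (metric in c("phist", "shua")) {
    est <- if (metric == "phist") pmax(phist_mun$estimate, 0)
           else shua_mun$estimate
    cg[[metric]] <- run_stage(paste0("autocorr_", metric),
                              autocorrelogram(gower_center(est^2), classes,
                                              n_perm =
                                                config$permutations_autocorr,
                                              n_boot = config$bootstraps,
                                              seed = config$seed + 41L))
  }
  pc <- run_stage("pcoa", list(
    phist = pcoa(pmax(phist_mun$estimate, 0)),
    shua = pcoa(shua_mun$estimate)))

  ## --- write artifacts -------------------------------------------------
  log_df <- do.call(rbind, log)
  paths <- write_pipeline_outputs(out_dir, records, freq_all, freq_region,
                                  contrasts, div, disp, phist_region,
                                  shua_region, shua_region_locus,
                                  phist_mun, shua_mun, cg, pc, grids,
                                  regions, log_df, config)
  res <- list(records = records, spatial_records = spatial_records,
              frequencies = freq_all, frequencies_region = freq_region,
              contrasts = contrasts, diversity = div, dispersion = disp,
              phist_region = phist_region, shua_region = shua_region,
              shua_region_locus = shua_region_locus,
              phist_municipal = phist_mun, shua_municipal = shua_mun,
              correlograms = cg, pcoa = pc, density = grids,
              regions = regions, log = log_df, paths = paths)
  invisible(res)
}

# Fisher exact region contrast per haplogroup (region A vs B counts),
# with multiple-testing adjustment
region_contrasts <- function(spatial_records, method = "BY",
                             alpha = 0.05) {
  regs <- sort(unique(spatial_records$region))
  if (length(regs) != 2) stop("need exactly two regions, got ",
                              length(regs))
  nA <- sum(spatial_records$region == regs[1])
  nB <- sum(spatial_records$region == regs[2])
  hgs <- sort(unique(spatial_records$haplogroup))
  rows <- lapply(hgs, function(h) {
    xA <- sum(spatial_records$haplogroup == h &
                spatial_records$region == regs[1])
    xB <- sum(spatial_records$haplogroup == h &
                spatial_records$region == regs[2])
    ft <- fisher_exact_2x2(matrix(c(xA, nA - xA, xB, nB - xB), 2,
                                  byrow = FALSE))
    data.frame(haplogroup = h, count_a = xA, n_a = nA, count_b = xB,
               n_b = nB, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p_value, method = method, alpha = alpha)
  out$p_adjusted <- adj$adjusted
  out$significant <- adj$significant
  attr(out, "bonferroni_critical") <- adj$bonferroni_critical
  attr(out, "method") <- adj$method
  out
}

# within-haplogroup dispersion contrasts between the two regions, for
# haplogroups with at least 3 members in each region
dispersion_contrasts <- function(spatial_records, haps, n_perm = 5000,
                                 seed = 1L, min_n = 3) {
  regs <- sort(unique(spatial_records$region))
  hgs <- sort(unique(spatial_records$haplogroup))
  out <- list()
  for (h in hgs) {
    ia <- which(spatial_records$haplogroup == h &
                  spatial_records$region == regs[1])
    ib <- which(spatial_records$haplogroup == h &
                  spatial_records$region == regs[2])
    if (length(ia) < min_n || length(ib) < min_n) next
    for (stat in c("diff", "multistep")) {
      cd <- compare_dispersion(subset_hap(haps, ia), subset_hap(haps, ib),
                               statistic = stat, n_perm = n_perm,
                               seed = seed)
      out[[paste(h, stat)]] <-
        data.frame(haplogroup = h, statistic = stat,
                   mean_a = cd$mean_a, mean_b = cd$mean_b,
                   n_pairs_a = cd$n_pairs_a, n_pairs_b = cd$n_pairs_b,
                   p_value = cd$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell_km=%g radius_km=%g x0=%g y0=%g",
                     grid$cell_km, grid$radius_km, grid$x[1], grid$y[1]),
             con)
  m <- grid$density
  dimnames(m) <- list(sprintf("x%g", grid$x), sprintf("y%g", grid$y))
  utils::write.table(data.frame(label = rownames(m), m,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_pipeline_outputs <- function(out_dir, records, freq_all, freq_region,
                                   contrasts, div, disp, phist_region,
                                   shua_region, shua_region_locus,
                                   phist_mun, shua_mun, cg, pc, grids,
                                   regions, log_df, config) {
  p <- function(f) file.path(out_dir, f)
  paths <- c()
  add <- function(name, path) paths[[name]] <<- path
  write_population_table(records, p("records_kept.tsv"))
  add("records", p("records_kept.tsv"))
  write_delim_tsv(rbind(freq_all, freq_region), p("haplogroup_frequencies.tsv"))
  add("frequencies", p("haplogroup_frequencies.tsv"))
  write_delim_tsv(contrasts, p("fisher_contrasts.tsv"))
  add("contrasts", p("fisher_contrasts.tsv"))
  write_delim_tsv(div, p("diversity.tsv"))
  add("diversity", p("diversity.tsv"))
  if (!is.null(disp)) {
    write_delim_tsv(disp, p("dispersion.tsv"))
    add("dispersion", p("dispersion.tsv"))
  }
  write_square_matrix(phist_mun$estimate, p("phist_municipal.tsv"))
  add("phist_municipal", p("phist_municipal.tsv"))
  write_square_matrix(phist_mun$p_value, p("phist_municipal_p.tsv"))
  add("phist_municipal_p", p("phist_municipal_p.tsv"))
  write_square_matrix(shua_mun$estimate, p("shua_municipal.tsv"))
  add("shua_municipal", p("shua_municipal.tsv"))
  for (m in names(cg)) {
    f <- paste0("correlogram_", m, ".tsv")
    write_delim_tsv(cg[[m]]$table, p(f))
    add(paste0("correlogram_", m), p(f))
  }
  for (m in names(pc)) {
    f <- paste0("pcoa_", m, ".tsv")
    con <- file(p(f), "w")
    writeLines(paste0("# eigenvalues\t",
                      paste(format(pc[[m]]$eigenvalues, digits = 10),
                            collapse = "\t")), con)
    utils::write.table(data.frame(label = rownames(pc[[m]]$coordinates),
                                  pc[[m]]$coordinates,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    add(paste0("pcoa_", m), p(f))
  }
  for (cl in names(grids)) {
    f <- paste0("density_", tolower(cl), ".tsv")
    write_density_grid(grids[[cl]], p(f))
    add(paste0("density_", cl), p(f))
  }
  write_delim_tsv(regions, p("regions.tsv"))
  add("regions", p("regions.tsv"))
  write_delim_tsv(log_df, p("pipeline_log.tsv"))
  add("log", p("pipeline_log.tsv"))
  summary <- list(
    config = unclass(config),
    n_records_kept = nrow(records),
    regions = stats::setNames(as.list(regions$region),
                              regions$municipality),
    phist_region = list(estimate = phist_region$estimate[1, 2],
                        p_value = phist_region$p_value[1, 2]),
    shua_region = shua_region$estimate[1, 2],
    shua_region_per_locus = shua_region_locus$estimate[1, 2],
    correlogram_overall_p = lapply(cg, function(x) x$omega_p),
    pcoa_axis_fractions = lapply(pc, function(x)
      x$variance_fraction[seq_len(min(3, length(x$variance_fraction)))]),
    log = log_df)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add("summary", p("summary.json"))
  paths
}
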