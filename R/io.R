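# metadata columns of a records table, in canonical order
record_meta_cols <- function() {
  c("id", "municipality_proband", "municipality_father",
    "municipality_grandfather", "birth_year_proband", "birth_year_father",
    "birth_year_grandfather", "surname_etymon_class", "descent_group")
}

# locus-name synonyms accepted on input
locus_synonyms <- c("Y-GATA-H4" = "YGATAH4", "Y_GATA_H4" = "YGATAH4",
                    "GATA-H4" = "YGATAH4", "GATA_H4" = "YGATAH4")

#' Read a per-individual population table
#'
#' Reads a delimited text table (comma or tab, auto-detected from the
#' header) with one row per individual: identifiers, three-generation
#' municipality assignments, birth years, surname etymon class, descent
#' group, the 17-allele Yfiler Y-STR profile, and binary Y-SNP states in
#' columns named `snp.<marker>`.  DYS385 is accepted as an `"a-b"` /
#' `"a,b"` pair in one column or as separate `DYS385a`/`DYS385b`
#' columns and is stored as a sorted unordered pair.  Missing values are
#' empty cells or `NA` -- never 0 -- and are kept missing.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping canonical
#'   column names to the file's column names (e.g.
#'   `c(id = "SampleID")`).
#' @param panel locus panel, see [yfiler_panel()].
#' @return a records data.frame (character columns; STR designations
#'   verbatim except DYS385 normalization).
#' @export
read_population_table <- function(path, dialect = NULL,
                                  panel = yfiler_panel()) {
  df <- read_delim_auto(path)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      hit <- which(names(df) == dialect[[std]])
      if (length(hit) == 1) names(df)[hit] <- std
    }
  }
  for (syn in names(locus_synonyms)) {
    hit <- which(names(df) == syn)
    if (length(hit) == 1) names(df)[hit] <- locus_synonyms[[syn]]
  }
  # combine split DYS385a/b columns
  if (all(c("DYS385a", "DYS385b") %in% names(df)) &&
      !"DYS385" %in% names(df)) {
    df$DYS385 <- ifelse(is.na(df$DYS385a) | is.na(df$DYS385b), NA,
                        paste(df$DYS385a, df$DYS385b, sep = "-"))
    df$DYS385a <- df$DYS385b <- NULL
  }
  loci <- c(singleton_loci(panel), "DYS385")
  # any column that looks like a Y-STR locus must be a known one
  str_like <- grepl("^(DYS|YGATA|Y-GATA)", names(df))
  unknown <- names(df)[str_like & !names(df) %in% loci]
  if (length(unknown) > 0)
    stop("unknown locus column: ", unknown[1])
  miss <- setdiff(loci, names(df))
  if (length(miss) > 0)
    stop("population table lacks Yfiler locus column(s): ",
         paste(miss, collapse = ", "))
  if (!"id" %in% names(df)) stop("population table lacks an 'id' column")
  if (anyDuplicated(df$id))
    stop("duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (mc in setdiff(record_meta_cols(), names(df)))
    df[[mc]] <- rep(NA_character_, nrow(df))
  units <- stats::setNames(panel$repeat_unit, panel$locus)
  # validate allele designations row-wise so errors carry the row index
  for (loc in loci) {
    for (i in seq_len(nrow(df))) {
      v <- df[[loc]][i]
      if (is.na(v) || v == "") next
      parts <- strsplit(v, "[-,]")[[1]]
      ok <- tryCatch({
        parse_allele(parts, units[[loc]]); TRUE
      }, error = function(e) FALSE)
      if (!ok || length(parts) > 2 ||
          (loc == "DYS385" && length(parts) != 2))
        stop("invalid allele '", v, "' at locus ", loc, ", row ", i)
    }
    # normalize pair separators and DYS385 order
    has <- !is.na(df[[loc]]) & grepl("[-,]", df[[loc]])
    df[[loc]][has] <- vapply(df[[loc]][has], function(v) {
      parts <- strsplit(v, "[-,]")[[1]]
      paste(parts[order(as.numeric(parts))], collapse = "-")
    }, character(1))
  }
  snp_cols <- grep("^snp\\.", names(df), value = TRUE)
  out <- df[, c(intersect(record_meta_cols(), names(df)), loci, snp_cols,
                setdiff(names(df), c(record_meta_cols(), loci, snp_cols))),
            drop = FALSE]
  out
}

#' Write a records table
#'
#' Tab-delimited, missing values as empty cells; read-write-read is the
#' identity.
#'
#' @param records records data.frame.
#' @param path output path.
#' @export
write_population_table <- function(records, path) {
  write_delim_tsv(records, path)
  invisible(path)
}

#' Read municipality geography and the road-distance matrix
#'
#' The geo table has columns `municipality`, `x_km`, `y_km` (planar,
#' pre-projected km) and optional `valley` and `region` columns.  The
#' distance file is a labelled square matrix; its labels must match the
#' geo keys.  Asymmetries up to `tol` km are averaged away; larger ones
#' are an error.  Road distances need not satisfy the triangle
#' inequality.
#'
#' @param geo_path path of the geo table.
#' @param dist_path path of the labelled square distance matrix.
#' @param tol symmetry tolerance in km (default 1e-3).
#' @return list with `geo` (data.frame) and `dist` (symmetric matrix,
#'   zero diagonal, km).
#' @export
read_geo_and_distances <- function(geo_path, dist_path, tol = 1e-3) {
  geo <- read_delim_auto(geo_path)
  need <- c("municipality", "x_km", "y_km")
  miss <- setdiff(need, names(geo))
  if (length(miss) > 0)
    stop("geo table lacks column(s): ", paste(miss, collapse = ", "))
  geo$x_km <- as_num(geo$x_km); geo$y_km <- as_num(geo$y_km)
  if (!all(is.finite(geo$x_km)) || !all(is.finite(geo$y_km)))
    stop("geo coordinates must be finite")
  if (anyDuplicated(geo$municipality))
    stop("duplicate municipality keys")
  d <- read_square_matrix(dist_path)
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  missing_keys <- setdiff(geo$municipality, rownames(d))
  extra_keys <- setdiff(rownames(d), geo$municipality)
  if (length(missing_keys) > 0 || length(extra_keys) > 0)
    stop("distance labels do not match geo keys; missing: ",
         paste(missing_keys, collapse = ", "), "; extra: ",
         paste(extra_keys, collapse = ", "))
  d <- d[geo$municipality, geo$municipality]
  asym <- abs(d - t(d))
  if (max(asym) > tol)
    stop("distance matrix asymmetric beyond tolerance (max ",
         format(max(asym)), " km)")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (any(d < 0)) stop("negative road distance")
  list(geo = geo, dist = d)
}

#' Analysis configuration
#'
#' Bundles the analysis settings: generation level at which individuals
#' are placed, permutation and bootstrap counts, density radius and cell
#' size, the informativeness threshold, the multiple-testing method, and
#' the random seed.
#'
#' @param generation_level `"proband"`, `"father"` or `"grandfather"`.
#' @param permutations_fst permutations for PhiST P values (default
#'   5000).
#' @param permutations_autocorr permutations for the correlogram
#'   (default 9999).
#' @param bootstraps bootstrap resamples for correlogram CIs (default
#'   9999).
#' @param density_radius_km circular-neighborhood radius (default 10).
#' @param density_cell_km grid cell size (default 1).
#' @param informative_threshold relative-frequency threshold (default
#'   0.05).
#' @param p_adjust_method `"BY"`, `"BH"` or `"bonferroni"`.
#' @param n_distance_classes correlogram distance classes (default 6,
#'   even pair counts).
#' @param seed integer random seed.
#' @return object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(generation_level = c("proband", "father",
                                                 "grandfather"),
                            permutations_fst = 5000,
                            permutations_autocorr = 9999,
                            bootstraps = 9999,
                            density_radius_km = 10,
                            density_cell_km = 1,
                            informative_threshold = 0.05,
                            p_adjust_method = c("BY", "BH", "bonferroni"),
                            n_distance_classes = 6,
                            seed = 1L) {
  cfg <- list(generation_level = match.arg(generation_level),
              permutations_fst = as.integer(permutations_fst),
              permutations_autocorr = as.integer(permutations_autocorr),
              bootstraps = as.integer(bootstraps),
              density_radius_km = as.numeric(density_radius_km),
              density_cell_km = as.numeric(density_cell_km),
              informative_threshold = as.numeric(informative_threshold),
              p_adjust_method = match.arg(p_adjust_method),
              n_distance_classes = as.integer(n_distance_classes),
              seed = as.integer(seed))
  counts <- c(cfg$permutations_fst, cfg$permutations_autocorr,
              cfg$bootstraps, cfg$n_distance_classes)
  if (any(counts <= 0)) stop("counts must be positive")
  if (cfg$density_radius_km <= 0 || cfg$density_cell_km <= 0)
    stop("density radius and cell size must be positive")
  if (cfg$informative_threshold <= 0 || cfg$informative_threshold >= 1)
    stop("informative threshold must lie in (0, 1)")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment.  Keys are the arguments of [analysis_config()].
#'
#' @param path config file path.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'")
  args <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1,
                                                      FUN.VALUE = ""))
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  num <- setdiff(known, c("generation_level", "p_adjust_method"))
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  do.call(analysis_config, args)
}
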