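#' The Yfiler Y-STR locus panel
#'
#' Returns the packaged locus table for the 17-allele Yfiler panel:
#' 15 singleton loci plus the duplicated locus DYS385, with repeat unit
#' lengths used to convert partial-repeat allele designations (e.g. 17.2
#' at a tetranucleotide becomes 17.5).  Custom panels in the same format
#' can be loaded with `read_delim_auto`-compatible files via `path`.
#'
#' @param path optional path to an alternative panel table with columns
#'   `locus`, `repeat_unit`, `duplicated`.
#' @return data.frame with columns `locus`, `repeat_unit` (integer),
#'   `duplicated` (logical).
#' @export
yfiler_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "yfiler_panel.tsv", package = "ygeo",
                        mustWork = TRUE)
  df <- read_delim_auto(path)
  df$repeat_unit <- as.integer(df$repeat_unit)
  df$duplicated <- as.logical(df$duplicated)
  df
}

# singleton locus names in canonical order (DYS389II position later
# replaced by DYS389b in the numeric 15-locus panel)
singleton_loci <- function(panel = yfiler_panel()) {
  panel$locus[!panel$duplicated]
}

# the 15-locus numeric panel: DYS389b replaces DYS389II, DYS385 dropped
numeric_loci <- function(panel = yfiler_panel()) {
  loci <- singleton_loci(panel)
  replace(loci, loci == "DYS389II", "DYS389b")
}

# parse one raw allele designation ("17", "17.2"); returns numeric repeat
# block length, NA for missing. unit = repeat unit length of the locus.
parse_allele <- function(x, unit) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x != ""
  if (!any(ok)) return(out)
  xs <- x[ok]
  bad <- !grepl("^[0-9]+(\\.[0-9]+)?$", xs)
  if (any(bad)) stop("non-numeric allele designation: '", xs[bad][1], "'")
  whole <- as.numeric(sub("\\..*$", "", xs))
  frac <- rep(0, length(xs))
  has_frac <- grepl("\\.", xs)
  frac[has_frac] <- as.numeric(sub("^[0-9]+\\.", "", xs[has_frac]))
  if (any(frac >= unit))
    stop("partial-repeat suffix ", frac[frac >= unit][1],
         " not below repeat unit length ", unit)
  out[ok] <- whole + frac / unit
  out
}

#' Derive DYS389b from the nested DYS389I/II alleles
#'
#' DYS389II is a concatenated designation that embeds DYS389I; the
#' non-overlapping repeat block DYS389b is DYS389II minus DYS389I.
#' DYS389I is retained.  A missing value at either locus propagates to
#' DYS389b; a non-positive difference is biologically impossible and is
#' an error.
#'
#' @param records a records data.frame (see [read_population_table()])
#'   carrying `DYS389I` and `DYS389II` columns.
#' @return `records` with a `DYS389b` character column added.
#' @export
derive_dys389b <- function(records) {
  if (!all(c("DYS389I", "DYS389II") %in% names(records)))
    stop("records lack DYS389I/DYS389II columns")
  i <- parse_allele(records$DYS389I, 4L)
  ii <- parse_allele(records$DYS389II, 4L)
  b <- ii - i
  if (any(!is.na(b) & b <= 0))
    stop("DYS389II - DYS389I non-positive at row ",
         which(!is.na(b) & b <= 0)[1])
  records$DYS389b <- ifelse(is.na(b), NA_character_,
                            format_allele(b))
  records
}

# inverse of parse_allele for integral/half-repeat values: store numeric
# repeat counts back as designation strings (integers without decimals)
format_allele <- function(x) {
  ifelse(is.na(x), NA_character_,
         sub("\\.?0+$", "", formatC(x, format = "f", digits = 3)))
}

#' Convert raw Yfiler profiles to numeric haplotypes
#'
#' Converts repeat-designation strings to inferred repeat block lengths
#' (partial repeat `x.y` at a locus with unit length `u` becomes
#' `x + y/u`), masks duplicated singleton loci as missing, and by default
#' drops the duplicated locus DYS385 to produce the 15-locus numeric
#' panel (DYS389b in place of DYS389II).  Requires [derive_dys389b()] to
#' have been applied.
#'
#' @param records records data.frame with raw STR columns (plus
#'   `DYS389b`).  A singleton-locus cell containing two designations
#'   separated by `-` or `,` marks a locus duplication and is masked.
#' @param drop_dys385 drop DYS385 from the comparison panel (default
#'   TRUE).  When FALSE the DYS385 allele pair is carried along as an
#'   attribute for 17-locus comparisons.
#' @param panel locus panel table, see [yfiler_panel()].
#' @return object of class `num_haplotypes`: numeric matrix (rows =
#'   individuals, columns = 15 loci, NA = missing) with attributes
#'   `dys385` (n x 2 sorted numeric matrix, or NULL when dropped) and
#'   `panel_size` (15 or 17).
#' @export
numeric_haplotypes <- function(records, drop_dys385 = TRUE,
                               panel = yfiler_panel()) {
  if (!"DYS389b" %in% names(records))
    stop("derive_dys389b() must be applied before numeric conversion")
  loci <- numeric_loci(panel)
  units <- stats::setNames(panel$repeat_unit, panel$locus)
  units["DYS389b"] <- units[["DYS389II"]]
  n <- nrow(records)
  m <- matrix(NA_real_, n, length(loci), dimnames = list(records$id, loci))
  for (loc in loci) {
    raw <- records[[loc]]
    if (is.null(raw)) stop("records lack locus column ", loc)
    dup <- !is.na(raw) & grepl("[-,]", raw)
    raw[dup] <- NA  # duplicated singleton locus treated as missing
    m[, loc] <- parse_allele(raw, units[[loc]])
  }
  d385 <- NULL
  if (!drop_dys385) {
    raw <- records[["DYS385"]]
    if (is.null(raw)) stop("records lack locus column DYS385")
    d385 <- t(vapply(raw, function(v) {
      if (is.na(v) || v == "") return(c(NA_real_, NA_real_))
      parts <- strsplit(v, "[-,]")[[1]]
      if (length(parts) != 2)
        stop("DYS385 must hold an allele pair, got '", v, "'")
      sort(parse_allele(parts, units[["DYS385"]]))
    }, numeric(2)))
    dimnames(d385) <- list(records$id, c("DYS385.a", "DYS385.b"))
  }
  structure(m, dys385 = d385, panel_size = if (drop_dys385) 15L else 17L,
            class = c("num_haplotypes", "matrix", "array"))
}

#' @export
print.num_haplotypes <- function(x, ...) {
  cat("numeric Y-STR haplotypes:", nrow(x), "individuals,",
      attr(x, "panel_size"), "locus panel\n")
  invisible(x)
}

check_same_panel <- function(a, b) {
  pa <- attr(a, "panel_size") %||% ncol(a)
  pb <- attr(b, "panel_size") %||% ncol(b)
  if (!identical(pa, pb))
    stop("panel mismatch: ", pa, " vs ", pb, " loci")
}

# multiset comparison of two sorted DYS385 pairs: number of non-shared
# elements of one pair (0, 1, or 2); NA if either pair incomplete
dys385_diff <- function(p, q, multistep = FALSE) {
  if (anyNA(p) || anyNA(q)) return(NA_integer_)
  if (!multistep) {
    # multiset intersection size for 2-element multisets
    lev <- union(p, q)
    inter <- sum(pmin(table(factor(p, levels = lev)),
                      table(factor(q, levels = lev))))
    return(2L - as.integer(inter))
  }
  # multistep: best of the two matchings, count matched pairs >= 2 apart
  m1 <- sum(abs(p - q) >= 2)
  m2 <- sum(abs(p - rev(q)) >= 2)
  as.integer(min(m1, m2))
}

#' Count of differing alleles between two haplotypes
#'
#' Number of compared loci with unequal repeat block lengths.  Loci
#' missing in either haplotype are excluded without rescaling.  For the
#' 17-locus panel the DYS385 allele pairs are compared as multisets:
#' each non-shared element counts one difference.
#'
#' @param a,b single-row `num_haplotypes` objects (or 1-row subsets) on a
#'   common panel.
#' @return integer count.
#' @export
pairwise_allele_differences <- function(a, b) {
  check_same_panel(a, b)
  va <- a[1, ]; vb <- b[1, ]
  ok <- !is.na(va) & !is.na(vb)
  d <- sum(va[ok] != vb[ok])
  if (identical(attr(a, "panel_size"), 17L)) {
    dd <- dys385_diff(attr(a, "dys385")[1, ], attr(b, "dys385")[1, ])
    if (!is.na(dd)) d <- d + dd
  }
  as.integer(d)
}

#' Count of multi-step neighbor alleles between two haplotypes
#'
#' Number of compared loci where the absolute repeat difference is at
#' least `threshold` (default 2) repeat units.
#'
#' @inheritParams pairwise_allele_differences
#' @param threshold minimum absolute repeat difference (default 2).
#' @return integer count.
#' @export
multistep_neighbor_count <- function(a, b, threshold = 2) {
  check_same_panel(a, b)
  va <- a[1, ]; vb <- b[1, ]
  ok <- !is.na(va) & !is.na(vb)
  d <- sum(abs(va[ok] - vb[ok]) >= threshold)
  if (identical(attr(a, "panel_size"), 17L)) {
    dd <- dys385_diff(attr(a, "dys385")[1, ], attr(b, "dys385")[1, ],
                      multistep = TRUE)
    if (!is.na(dd)) d <- d + dd
  }
  as.integer(d)
}

# full n x n matrix of a pairwise comparison statistic, vectorized per
# locus; DYS385 pairs (17-locus panel) are compared as 2-element
# multisets via the better of the two matchings
allele_diff_matrix <- function(h, stat = c("diff", "multistep"),
                               threshold = 2) {
  stat <- match.arg(stat)
  m <- unclass(h)
  n <- nrow(m)
  D <- matrix(0L, n, n)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- outer(!is.na(v), !is.na(v), "&")
    dd <- abs(outer(v, v, "-"))
    hit <- if (stat == "diff") dd > 0 else dd >= threshold
    D <- D + (hit & ok)
  }
  d385 <- attr(h, "dys385")
  if (identical(attr(h, "panel_size"), 17L) && !is.null(d385)) {
    p1 <- d385[, 1]; p2 <- d385[, 2]
    ok <- outer(!is.na(p1), !is.na(p1), "&")
    if (stat == "diff") {
      straight <- (outer(p1, p1, "!=")) + (outer(p2, p2, "!="))
      crossed <- (outer(p1, p2, "!=")) + (outer(p2, p1, "!="))
    } else {
      straight <- (abs(outer(p1, p1, "-")) >= threshold) +
        (abs(outer(p2, p2, "-")) >= threshold)
      crossed <- (abs(outer(p1, p2, "-")) >= threshold) +
        (abs(outer(p2, p1, "-")) >= threshold)
    }
    extra <- pmin(straight, crossed)
    extra[!ok] <- 0L
    D <- D + extra
  }
  D
}

# condensed vector (length choose(n,2), pair order (1,2),(1,3),...) of a
# pairwise statistic over all haplotype pairs
pairwise_stat_vector <- function(h, stat = c("diff", "multistep"),
                                 threshold = 2) {
  D <- allele_diff_matrix(h, stat, threshold)
  as.integer(t(D)[lower.tri(D)])
}

#' Row subset of a numeric haplotype object
#'
#' Keeps the DYS385 attribute and panel bookkeeping intact.
#' @param h a `num_haplotypes` object.
#' @param i row indices.
#' @return a `num_haplotypes` object with the selected rows.
#' @export
subset_hap <- function(h, i) {
  structure(h[i, , drop = FALSE],
            dys385 = if (!is.null(attr(h, "dys385")))
              attr(h, "dys385")[i, , drop = FALSE],
            panel_size = attr(h, "panel_size"),
            class = class(h))
}

hap_keys <- function(h) {
  keys <- apply(unclass(h), 1, paste, collapse = "|")
  d385 <- attr(h, "dys385")
  if (!is.null(d385))
    keys <- paste(keys, apply(d385, 1, paste, collapse = "|"), sep = "|")
  keys
}

#' Haplotype diversity and dispersion statistics for one sample
#'
#' Haplotype diversity is Nei's unbiased estimator
#' H = n (1 - sum p_i^2) / (n - 1) over haplotype frequencies p_i;
#' discrimination capacity D is the number of distinct haplotypes divided
#' by the sample size.  Pairwise dispersion statistics (mean and SD of
#' the number of differing alleles, mean multi-step neighbor count) are
#' computed over all choose(n, 2) haplotype pairs.
#'
#' @param h a `num_haplotypes` object with n >= 2 rows.
#' @return list with `n`, `k` (distinct haplotypes), `H`, `D`,
#'   `mean_pairwise_diff`, `sd_pairwise_diff`, `mean_multistep`,
#'   `n_pairs`.
#' @export
diversity_stats <- function(h) {
  n <- nrow(h)
  if (n < 2) stop("diversity statistics require n >= 2")
  keys <- hap_keys(h)
  p <- table(keys) / n
  H <- n * (1 - sum(p^2)) / (n - 1)
  dv <- pairwise_stat_vector(h, "diff")
  mv <- pairwise_stat_vector(h, "multistep")
  list(n = n, k = length(p), H = H, D = length(p) / n,
       mean_pairwise_diff = mean(dv), sd_pairwise_diff = stats::sd(dv),
       mean_multistep = mean(mv), n_pairs = choose(n, 2))
}

#' Compare pairwise dispersion between two groups
#'
#' Tests whether two groups differ in the mean of a within-group pairwise
#' haplotype statistic (number of differing alleles, or multi-step
#' neighbor count).  The default is a label-permutation test: individuals
#' are shuffled between the groups (sizes preserved) and the two-sided P
#' is the fraction of permutations with an absolute difference of group
#' means at least as large as observed, with the +1 correction.  A
#' two-sample t test on the pairwise values is available for comparison
#' (it ignores the dependence among pairs sharing an individual).
#'
#' @param a,b `num_haplotypes` objects (same panel), each n >= 2.
#' @param statistic `"diff"` or `"multistep"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param method `"permutation"` (default) or `"t.test"`.
#' @return list with `mean_a`, `mean_b`, `delta`, `p_value`, `n_pairs_a`,
#'   `n_pairs_b`, `method`.
#' @export
compare_dispersion <- function(a, b, statistic = c("diff", "multistep"),
                               n_perm = 5000, seed = NULL,
                               method = c("permutation", "t.test")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  check_same_panel(a, b)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("both groups must have n >= 2")
  pooled <- rbind_hap(a, b)
  va <- pairwise_stat_vector(a, statistic)
  vb <- pairwise_stat_vector(b, statistic)
  obs <- mean(va) - mean(vb)
  if (method == "t.test") {
    tt <- stats::t.test(va, vb)
    return(list(mean_a = mean(va), mean_b = mean(vb), delta = obs,
                p_value = tt$p.value, n_pairs_a = length(va),
                n_pairs_b = length(vb), method = "t.test"))
  }
  if (!is.null(seed)) set.seed(seed)
  # precompute the full pairwise matrix once; permutations only re-index
  n <- na + nb
  full <- allele_diff_matrix(pooled, statistic)
  ut_a <- upper.tri(matrix(0, na, na))
  ut_b <- upper.tri(matrix(0, nb, nb))
  stat_for <- function(ia) {
    ib <- setdiff(seq_len(n), ia)
    mean(full[ia, ia][ut_a]) - mean(full[ib, ib][ut_b])
  }
  hits <- 0L
  for (r in seq_len(n_perm)) {
    ia <- sample.int(n, na)
    if (abs(stat_for(ia)) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  list(mean_a = mean(va), mean_b = mean(vb), delta = obs,
       p_value = perm_pvalue(hits, n_perm), n_pairs_a = length(va),
       n_pairs_b = length(vb), method = "permutation")
}

rbind_hap <- function(a, b) {
  m <- rbind(unclass(a), unclass(b))
  d385 <- NULL
  if (!is.null(attr(a, "dys385")))
    d385 <- rbind(attr(a, "dys385"), attr(b, "dys385"))
  structure(m, dys385 = d385, panel_size = attr(a, "panel_size"),
            class = class(a))
}
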