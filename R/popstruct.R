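#' Squared inter-individual haplotype distance matrix
#'
#' Computes the squared molecular distance between all pairs of numeric
#' haplotypes.  The default metric is the sum of squared repeat-block
#' differences over the shared non-missing loci; `"count"` instead counts
#' the number of differing loci.  Loci missing in either member of a pair
#' are excluded without rescaling; a pair with no shared non-missing
#' locus is an error.
#'
#' @param h a `num_haplotypes` matrix (15-locus panel).
#' @param metric `"sumsq"` (sum of squared repeat differences, default)
#'   or `"count"` (number of differing loci).
#' @return symmetric n x n numeric matrix with zero diagonal.
#' @export
haplotype_distance_matrix <- function(h, metric = c("sumsq", "count")) {
  metric <- match.arg(metric)
  m <- unclass(h)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok))
        stop("pair (", i, ", ", j, ") has no shared non-missing locus")
      diff <- m[i, ok] - m[j, ok]
      d[i, j] <- d[j, i] <-
        if (metric == "sumsq") sum(diff^2) else sum(diff != 0)
    }
  }
  d
}

# sums of squared-distance blocks used by the AMOVA decomposition
amova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

phist_from_ss <- function(ss, sizes) {
  K <- length(sizes); N <- sum(sizes)
  ms_among <- ss[["among"]] / (K - 1)
  ms_within <- ss[["within"]] / (N - K)
  n_prime <- (N - sum(sizes^2) / N) / (K - 1)
  sigma_a <- (ms_among - ms_within) / n_prime
  list(phist = sigma_a / (sigma_a + ms_within), sigma_a = sigma_a,
       ms_among = ms_among, ms_within = ms_within, n_prime = n_prime)
}

phist_two_groups <- function(d2, na) {
  # fast path for two groups given pooled squared distances; group A is
  # rows 1..na.  Used by the permutation loop.
  n <- nrow(d2)
  ia <- seq_len(na)
  s_a <- sum(d2[ia, ia])
  s_b <- sum(d2[-ia, -ia])
  ss_total <- sum(d2) / (2 * n)
  ss_within <- s_a / (2 * na) + s_b / (2 * (n - na))
  phist_from_ss(c(total = ss_total, within = ss_within,
                  among = ss_total - ss_within), c(na, n - na))$phist
}

#' Pairwise AMOVA-based PhiST with permutation P values
#'
#' Two-level analysis of molecular variance on squared inter-haplotype
#' distances for every pair of population samples.  The sums of squares
#' are SS_total = sum(d^2)/(2N) over the pooled pair and
#' SS_within = sum_k sum(d^2 within k)/(2 n_k); mean squares use K - 1
#' and N - K degrees of freedom, the among-group variance component is
#' (MS_among - MS_within)/n' with n' = (N - sum n_k^2 / N)/(K - 1), and
#' PhiST = sigma_a^2 / (sigma_a^2 + MS_within).  The P value is the
#' fraction of permutations (individuals shuffled between the two
#' groups) with PhiST at least the observed value, with the +1
#' correction in numerator and denominator.  Negative estimates are
#' reported as computed unless `clamp = TRUE`.
#'
#' @param haps a `num_haplotypes` object for all individuals pooled.
#' @param groups group label per row of `haps` (>= 2 groups, each n >= 2).
#' @param metric distance metric, see [haplotype_distance_matrix()].
#' @param n_perm permutations per pair (default 5000).
#' @param seed RNG seed.
#' @param clamp clamp negative PhiST estimates to zero for display.
#' @param d2 optionally, a precomputed squared distance matrix over all
#'   rows of `haps` (skips recomputation).
#' @return object of class `pairwise_dist`: list with `labels`,
#'   `estimate` (symmetric matrix), `p_value` (symmetric matrix, NA
#'   diagonal), `n_perm`, `metric`, `sizes`.
#' @export
amova_phist <- function(haps, groups, metric = c("sumsq", "count"),
                        n_perm = 5000, seed = NULL, clamp = FALSE,
                        d2 = NULL) {
  metric <- match.arg(metric)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("every group needs n >= 2; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  labs <- names(sizes)
  if (is.null(d2)) d2 <- haplotype_distance_matrix(haps, metric)
  if (!is.null(seed)) set.seed(seed)
  K <- length(labs)
  est <- matrix(0, K, K, dimnames = list(labs, labs))
  pv <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      idx <- c(which(groups == labs[i]), which(groups == labs[j]))
      na <- sizes[[labs[i]]]
      dd <- d2[idx, idx]
      obs <- phist_two_groups(dd, na)
      # permutation: only the within-A block sum changes, and the
      # within-B sum follows from fixed totals and row sums
      n <- length(idx)
      nb <- n - na
      ns <- min(na, nb)   # sample the smaller side: cost ns^2 per draw
      total <- sum(dd)
      rs <- rowSums(dd)
      ss_total <- total / (2 * n)
      hits <- 0L
      for (r in seq_len(n_perm)) {
        ii <- sample.int(n, ns)
        s_s <- sum(dd[ii, ii])
        s_o <- total - 2 * sum(rs[ii]) + s_s
        ss_within <- s_s / (2 * ns) + s_o / (2 * (n - ns))
        ph <- phist_from_ss(c(total = ss_total, within = ss_within,
                              among = ss_total - ss_within),
                            c(ns, n - ns))$phist
        if (ph >= obs - 1e-12) hits <- hits + 1L
      }
      est[i, j] <- est[j, i] <- if (clamp) max(obs, 0) else obs
      pv[i, j] <- pv[j, i] <- perm_pvalue(hits, n_perm)
    }
  }
  structure(list(labels = labs, estimate = est, p_value = pv,
                 n_perm = n_perm, metric = metric,
                 sizes = as.integer(sizes)),
            class = "pairwise_dist")
}

#' @export
print.pairwise_dist <- function(x, ...) {
  cat("pairwise population distances (", x$metric, " metric, ",
      x$n_perm, " permutations)\n", sep = "")
  print(round(x$estimate, 4))
  invisible(x)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon mutual information between population and haplotype
#'
#' The mutual information I = H_pooled - sum_k (n_k / N) H_k, with
#' Shannon entropies H = -sum p ln p (natural log) over haplotype
#' frequencies.  The default treats the whole haplotype as a single
#' allele; `per_locus = TRUE` averages per-locus mutual information over
#' the panel instead (the convention of some population-genetics
#' software).  I is nonnegative and zero exactly when the empirical
#' haplotype distributions of all groups are identical.
#'
#' @param haps a `num_haplotypes` object.
#' @param groups group label per row (>= 2 groups, each n >= 1).
#' @param per_locus average per-locus mutual information instead of
#'   whole-haplotype mode.
#' @return numeric scalar (nats).
#' @export
shannon_mutual_information <- function(haps, groups, per_locus = FALSE) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 1)) stop("empty group: ",
                           paste(names(sizes)[sizes < 1], collapse = ", "))
  N <- nrow(haps)
  one_mode <- function(keys) {
    hp <- shannon_entropy(table(keys) / N)
    hw <- sum(vapply(names(sizes), function(g) {
      k <- keys[groups == g]
      (length(k) / N) * shannon_entropy(table(k) / length(k))
    }, numeric(1)))
    max(hp - hw, 0)  # guard tiny negative rounding
  }
  if (!per_locus) return(one_mode(hap_keys(haps)))
  m <- unclass(haps)
  mean(vapply(seq_len(ncol(m)), function(j) one_mode(m[, j]), numeric(1)))
}

#' Pairwise Shannon mutual information matrix
#'
#' [shannon_mutual_information()] evaluated for every pair of groups,
#' optionally with a permutation P value (individuals shuffled between
#' the pair).
#'
#' @inheritParams shannon_mutual_information
#' @param n_perm permutations per pair; 0 skips P values.
#' @param seed RNG seed.
#' @return a `pairwise_dist` object (metric `"shua"`).
#' @export
shua_matrix <- function(haps, groups, per_locus = FALSE, n_perm = 0,
                        seed = NULL) {
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  K <- length(labs)
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(0, K, K, dimnames = list(labs, labs))
  pv <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    idx <- which(groups %in% labs[c(i, j)])
    g <- groups[idx]
    hh <- subset_hap(haps, idx)
    obs <- shannon_mutual_information(hh, g, per_locus)
    est[i, j] <- est[j, i] <- obs
    if (n_perm > 0) {
      hits <- 0L
      for (r in seq_len(n_perm)) {
        if (shannon_mutual_information(hh, sample(g), per_locus) >=
            obs - 1e-12) hits <- hits + 1L
      }
      pv[i, j] <- pv[j, i] <- perm_pvalue(hits, n_perm)
    }
  }
  structure(list(labels = labs, estimate = est, p_value = pv,
                 n_perm = n_perm, metric = "shua",
                 sizes = as.integer(table(groups)[labs])),
            class = "pairwise_dist")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are Gower
#' double-centered (see [gower_center()]), the centered matrix is
#' eigendecomposed, and coordinates are eigenvectors scaled by the
#' square root of their (positive) eigenvalues.  Negative eigenvalues
#' (possible for non-Euclidean inputs such as PhiST matrices) are
#' reported but excluded from the variance fractions, which are relative
#' to the sum of positive eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal (not squared).
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (n x n_positive matrix), `eigenvalues` (all, decreasing),
#'   `variance_fraction` (per positive axis).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  C <- gower_center(d^2)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * 1e-9
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 variance_fraction = e$values[keep] / sum(e$values[keep])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3, length(x$variance_fraction))
  cat("PCoA:", nrow(x$coordinates), "points;",
      length(x$variance_fraction), "positive axes; first", k, "axes carry",
      paste0(round(100 * x$variance_fraction[seq_len(k)], 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}
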