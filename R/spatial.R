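#' Gower double-centering of a squared distance matrix
#'
#' Transforms squared distances into the covariance-analog matrix
#' c_xy = -1/2 (d2_xy - rowmean_x - colmean_y + grandmean).  For
#' Euclidean squared distances of centered points this recovers the Gram
#' matrix; row and column sums of the result are zero.
#'
#' @param d2 symmetric matrix of squared distances, zero diagonal.
#' @return symmetric matrix of the same dimension.
#' @export
gower_center <- function(d2) {
  d2 <- as.matrix(d2)
  if (!isTRUE(all.equal(d2, t(d2), tolerance = 1e-8)))
    stop("matrix must be symmetric")
  rm <- rowMeans(d2)
  gm <- mean(d2)
  -0.5 * (sweep(sweep(d2, 1, rm), 2, rm) + gm)
}

#' Assign unit pairs to geographic distance classes
#'
#' Pairs of units (upper triangle, stable order by row then column) are
#' binned either by fixed km edges or into `k` classes of (near-)equal
#' pair counts ("even sample sizes"): pairs are sorted by distance with
#' stable tie order and split so that the first `P mod k` classes hold
#' one extra pair (larger classes first).
#'
#' @param geo symmetric matrix of geographic (road) distances in km.
#' @param scheme `"even"` (equal pair counts, default) or `"fixed"`.
#' @param k number of classes for the even scheme.
#' @param edges breaks in km for the fixed scheme (length k + 1,
#'   intervals closed on the right).
#' @return object of class `dist_classes`: list with `pair_i`, `pair_j`,
#'   `distance`, `class` (integer per pair), `k`, `edges` (data.frame of
#'   per-class min/max distance and pair count), `scheme`.
#' @export
build_distance_classes <- function(geo, scheme = c("even", "fixed"),
                                   k = 6, edges = NULL) {
  scheme <- match.arg(scheme)
  geo <- as.matrix(geo)
  n <- nrow(geo)
  if (n < 2) stop("need at least two units")
  ut <- which(upper.tri(geo), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  d <- geo[ut]
  P <- length(d)
  if (scheme == "even") {
    ord <- order(d)  # stable: ties keep pair order
    base <- P %/% k
    extra <- P %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    if (any(sizes == 0)) stop("class ", which(sizes == 0)[1], " is empty")
    cls <- integer(P)
    cls[ord] <- rep(seq_len(k), times = sizes)
  } else {
    if (is.null(edges)) stop("fixed scheme requires 'edges'")
    cls <- as.integer(cut(d, breaks = edges, include.lowest = TRUE))
    if (anyNA(cls)) stop("pair distance outside supplied edges")
    k <- length(edges) - 1
    empty <- setdiff(seq_len(k), unique(cls))
    if (length(empty) > 0) stop("class ", empty[1], " is empty")
  }
  edge_df <- do.call(rbind, lapply(seq_len(k), function(h) {
    dh <- d[cls == h]
    data.frame(class = h, d_min = min(dh), d_max = max(dh),
               n_pairs = length(dh))
  }))
  structure(list(pair_i = ut[, 1], pair_j = ut[, 2], distance = d,
                 class = cls, k = k, edges = edge_df, scheme = scheme),
            class = "dist_classes")
}

# observed per-class r given centered matrix C and a unit permutation p
class_r <- function(C, dg, classes, p = NULL) {
  xi <- classes$pair_i; yi <- classes$pair_j
  if (!is.null(p)) { xi <- p[xi]; yi <- p[yi] }
  num <- 2 * C[cbind(xi, yi)]
  den <- dg[xi] + dg[yi]
  nh <- rowsum(num, classes$class)
  dh <- rowsum(den, classes$class)
  as.numeric(nh / dh)
}

#' Multivariate spatial autocorrelation correlogram
#'
#' Smouse-Peakall autocorrelation of a genetic covariance-analog matrix
#' (from [gower_center()] of squared genetic distances) against
#' geographic distance classes.  For class h,
#' r(h) = sum over class pairs of c_xy / sum_x m_x(h) c_xx, where m_x(h)
#' counts the class-h pairs involving unit x.  The permutation null
#' shuffles units over locations and yields a 95\% envelope (2.5/97.5
#' percentiles) and a one-sided P per class (fraction of permuted r at
#' least the observed value for positive r, mirrored for negative, +1
#' corrected).  Bootstrap resampling of pairs within each class gives a
#' 95\% CI for r.  Permutation replicates are retained for the overall
#' (omega) test.
#'
#' @param C centered genetic covariance-analog matrix (units x units).
#' @param classes a [build_distance_classes()] object on the same units.
#' @param n_perm permutations (default 9999).
#' @param n_boot bootstrap resamples (default 9999).
#' @param seed RNG seed.
#' @return object of class `correlogram`: list with `table` (per-class
#'   data.frame: class, d_min, d_max, n_pairs, r, env_lo, env_hi, ci_lo,
#'   ci_hi, p), `omega`, `omega_p`, `perm_r` (n_perm x k matrix),
#'   `n_perm`, `n_boot`, `seed`.
#' @export
autocorrelogram <- function(C, classes, n_perm = 9999, n_boot = 9999,
                            seed = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (max(classes$pair_j) > n) stop("classes refer to units beyond C")
  if (!is.null(seed)) set.seed(seed)
  dg <- diag(C)
  k <- classes$k
  obs <- class_r(C, dg, classes)
  perm_r <- matrix(NA_real_, n_perm, k)
  for (b in seq_len(n_perm))
    perm_r[b, ] <- class_r(C, dg, classes, sample.int(n))
  # order-statistic envelope: with m replicates the bounds are the
  # floor(0.025 (m+1))-th and ceiling(0.975 (m+1))-th order statistics,
  # giving at most 5% two-sided exceedance under the null
  lo_i <- max(1L, floor(0.025 * (n_perm + 1)))
  hi_i <- min(n_perm, ceiling(0.975 * (n_perm + 1)))
  env <- apply(perm_r, 2, function(v) sort(v)[c(lo_i, hi_i)])
  pval <- vapply(seq_len(k), function(h) {
    if (obs[h] >= 0) perm_pvalue(sum(perm_r[, h] >= obs[h] - 1e-12), n_perm)
    else perm_pvalue(sum(perm_r[, h] <= obs[h] + 1e-12), n_perm)
  }, numeric(1))
  ci <- matrix(NA_real_, 2, k)
  for (h in seq_len(k)) {
    sel <- classes$class == h
    num <- 2 * C[cbind(classes$pair_i[sel], classes$pair_j[sel])]
    den <- dg[classes$pair_i[sel]] + dg[classes$pair_j[sel]]
    m <- length(num)
    idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), m)
    rb <- colSums(matrix(num[idx], m)) / colSums(matrix(den[idx], m))
    ci[, h] <- stats::quantile(rb, c(0.025, 0.975), names = FALSE)
  }
  omega <- sum(obs^2)
  omega_perm <- rowSums(perm_r^2)
  omega_p <- perm_pvalue(sum(omega_perm >= omega - 1e-12), n_perm)
  tab <- cbind(classes$edges,
               data.frame(r = obs, env_lo = env[1, ], env_hi = env[2, ],
                          ci_lo = ci[1, ], ci_hi = ci[2, ], p = pval))
  structure(list(table = tab, omega = omega, omega_p = omega_p,
                 perm_r = perm_r, n_perm = n_perm, n_boot = n_boot,
                 seed = seed),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("spatial autocorrelogram (", x$n_perm, " permutations, ",
      x$n_boot, " bootstraps); overall P = ",
      format(x$omega_p, digits = 3), "\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot method for correlograms
#'
#' Draws r per distance class with the permutation envelope (dashed) and
#' bootstrap CIs (bars).
#' @param x a `correlogram`.
#' @param ... passed to [plot()].
#' @export
plot.correlogram <- function(x, ...) {
  t <- x$table
  mid <- (t$d_min + t$d_max) / 2
  ylim <- range(t$r, t$env_lo, t$env_hi, t$ci_lo, t$ci_hi, 0)
  plot(mid, t$r, type = "b", pch = 16, ylim = ylim,
       xlab = "distance class midpoint (km)", ylab = "r", ...)
  graphics::lines(mid, t$env_lo, lty = 2)
  graphics::lines(mid, t$env_hi, lty = 2)
  graphics::arrows(mid, t$ci_lo, mid, t$ci_hi, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Overall (omega) significance test of a correlogram
#'
#' The omega statistic is the sum over classes of squared r.  Its P
#' value is the fraction of permutation replicates with omega at least
#' the observed value (+1 corrected), recomputed from the replicate
#' matrix stored in the correlogram.
#'
#' @param cg a [autocorrelogram()] result.
#' @return list with `omega` and `p_value`.
#' @export
omega_overall_test <- function(cg) {
  if (is.null(cg$perm_r)) stop("correlogram lacks permutation replicates")
  obs <- sum(cg$table$r^2)
  reps <- rowSums(cg$perm_r^2)
  list(omega = obs, p_value = perm_pvalue(sum(reps >= obs - 1e-12),
                                          nrow(cg$perm_r)))
}
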