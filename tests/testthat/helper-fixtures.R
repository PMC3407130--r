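# shared fixture builders and independent brute-force oracles

yf_singletons <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391",
                   "DYS392", "DYS393", "DYS437", "DYS438", "DYS439",
                   "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4")

# minimal records data.frame from a matrix of singleton designations
# (rows = individuals) and a DYS385 vector of "a-b" strings
make_records <- function(str = NULL, dys385 = NULL, n = NULL,
                         id = NULL, haplogroup = NULL,
                         descent_group = NULL) {
  if (is.null(n)) n <- if (!is.null(str)) nrow(str) else length(haplogroup)
  base <- c(14, 13, 29, 24, 11, 13, 13, 15, 12, 12, 19, 15, 17, 23, 12)
  if (is.null(str))
    str <- matrix(rep(base, each = n), nrow = n,
                  dimnames = list(NULL, yf_singletons))
  df <- data.frame(id = id %||% sprintf("S%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (j in seq_along(yf_singletons))
    df[[yf_singletons[j]]] <- as.character(str[, j])
  df$DYS385 <- dys385 %||% rep("11-14", n)
  if (!is.null(haplogroup)) df$haplogroup <- haplogroup
  if (!is.null(descent_group)) df$descent_group <- descent_group
  df$descent_group <- df$descent_group %||% NA_character_
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a num_haplotypes object directly from a numeric matrix
as_num_haps <- function(m, dys385 = NULL) {
  structure(m, dys385 = dys385,
            panel_size = if (is.null(dys385)) 15L else 17L,
            class = c("num_haplotypes", "matrix", "array"))
}

# random 15-locus haplotype matrix with (nearly) no ties across rows
random_haps <- function(n, n_loci = 15, lo = 8, hi = 30) {
  as_num_haps(matrix(sample(lo:hi, n * n_loci, replace = TRUE), n,
                     dimnames = list(NULL, paste0("L", seq_len(n_loci)))))
}

# --- independent oracles -------------------------------------------------

# naive per-pair difference count (scalar double loop, no vectorization)
oracle_pair_diff <- function(m, multistep = FALSE, threshold = 2) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cnt <- 0
    for (l in seq_len(ncol(m))) {
      a <- m[i, l]; b <- m[j, l]
      if (is.na(a) || is.na(b)) next
      if (multistep) { if (abs(a - b) >= threshold) cnt <- cnt + 1 }
      else if (a != b) cnt <- cnt + 1
    }
    out[i, j] <- cnt
  }
  out
}

# two-sided Fisher exact P by explicit enumeration over tables with the
# observed margins, with probabilities from products of choose()
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- pr[support == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# BH step-up from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m / i * p[o[i]])
    adj[o[i]] <- min(run, 1)
  }
  adj
}

# brute-force per-cell circular neighborhood density
oracle_density <- function(points, xs, ys, radius) {
  out <- matrix(0, length(xs), length(ys))
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    cnt <- 0
    for (k in seq_len(nrow(points))) {
      if ((points$x_km[k] - xs[i])^2 + (points$y_km[k] - ys[j])^2 <=
          radius^2) cnt <- cnt + 1
    }
    out[i, j] <- cnt / (pi * radius^2)
  }
  out
}

# random marker tree: each node's parent is ROOT or an earlier node
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  nm <- paste0("M", seq_len(n_nodes))
  parent <- c("ROOT", vapply(seq_len(n_nodes - 1), function(i)
    sample(c("ROOT", nm[seq_len(i)]), 1), character(1)))
  marker_tree(nm, parent, rep("X", n_nodes))
}

# all phylogenetically consistent fully typed profiles of a tree: the
# derived set of a single Y lineage is exactly one root path (possibly
# empty).  Bitmask enumeration filtered independently of the package's
# own path helpers.
oracle_consistent_profiles <- function(tree) {
  n <- length(tree$marker)
  walk_up <- function(m) {
    p <- character(0)
    while (m != "ROOT") { p <- c(p, m); m <- tree$parent[[m]] }
    p
  }
  keep <- list()
  for (mask in 0:(2^n - 1)) {
    der <- tree$marker[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(der) > 0) {
      deepest <- der[which.max(vapply(der, function(m)
        length(walk_up(m)), integer(1)))]
      if (!setequal(der, walk_up(deepest))) next
    }
    st <- stats::setNames(rep("ancestral", n), tree$marker)
    st[der] <- "derived"
    keep[[length(keep) + 1]] <- st
  }
  keep
}
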