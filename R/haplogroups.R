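#' Call haplogroups for a table of records
#'
#' Applies [assign_haplogroup()] to the SNP profile of every record
#' (columns prefixed `snp.`) and adds/overwrites a `haplogroup` column.
#'
#' @param records records data.frame (see [read_population_table()]).
#' @param tree a [marker_tree()]; default the packaged canonical tree.
#' @return `records` with a `haplogroup` character column.
#' @export
call_haplogroups <- function(records, tree = ygeo_tree()) {
  snp_cols <- grep("^snp\\.", names(records), value = TRUE)
  if (length(snp_cols) == 0) stop("records carry no snp.* columns")
  markers <- sub("^snp\\.", "", snp_cols)
  unknown <- setdiff(markers, tree$marker)
  if (length(unknown) > 0)
    stop("SNP column(s) not in marker tree: ",
         paste(unknown, collapse = ", "))
  records$haplogroup <- vapply(seq_len(nrow(records)), function(i) {
    g <- stats::setNames(as.character(records[i, snp_cols]), markers)
    assign_haplogroup(g, tree)$label
  }, character(1))
  records
}

#' Remove paternal-relative duplicates
#'
#' Records form a paternal-relative group when they share an identical
#' haplogroup call AND an identical full STR profile AND the same
#' (non-missing) descent group.  Exactly one member per group is kept:
#' the one with the lexicographically smallest id.  Records with a
#' missing descent group are never grouped.
#'
#' @param records records data.frame with `haplogroup`, STR columns and
#'   `descent_group`.
#' @return list with `kept` and `removed` records data.frames.
#' @export
dedup_paternal_relatives <- function(records) {
  if (!"haplogroup" %in% names(records))
    stop("records lack a haplogroup column; run call_haplogroups() first")
  str_cols <- intersect(c(singleton_loci(), "DYS385"), names(records))
  prof <- apply(records[, str_cols, drop = FALSE], 1, paste,
                collapse = "|")
  key <- ifelse(is.na(records$descent_group), NA,
                paste(records$haplogroup, prof, records$descent_group,
                      sep = "||"))
  keep <- rep(TRUE, nrow(records))
  for (k in unique(key[!is.na(key) & duplicated(key)])) {
    idx <- which(!is.na(key) & key == k)
    keep[idx] <- FALSE
    keep[idx[order(records$id[idx])[1]]] <- TRUE
  }
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Modified-Wald (add 2 successes / 2 failures) binomial CI
#'
#' p-tilde = (x + 2)/(n + 4); the interval is p-tilde +/- z *
#' sqrt(p-tilde (1 - p-tilde)/(n + 4)), clamped to [0, 1].
#'
#' @param x successes, `n` trials (vectorized).
#' @param n trials.
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @return matrix with columns `lower`, `upper`.
#' @export
modified_wald_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (abs(conf_level - 0.95) < 1e-9) z <- 1.96  # reporting convention
  pt <- (x + 2) / (n + 4)
  hw <- z * sqrt(pt * (1 - pt) / (n + 4))
  cbind(lower = pmax(pt - hw, 0), upper = pmin(pt + hw, 1))
}

#' Haplogroup frequency table per group
#'
#' Counts and relative frequencies of haplogroup calls per group, with
#' modified-Wald 95\% confidence intervals and an informativeness flag
#' (relative frequency at or above the threshold; frequencies below 5\%
#' are conventionally reported as non-informative).
#'
#' @param records records data.frame with a `haplogroup` column.
#' @param groups group label per record (e.g. region or generation-level
#'   placement); a single label for the combined sample.
#' @param informative_threshold relative-frequency threshold
#'   (default 0.05).
#' @param conf_level CI level (default 0.95).
#' @param haplogroup_levels optional label set fixing table rows (e.g.
#'   [enumerate_haplogroups()] output); default the observed labels.
#' @return data.frame with `group`, `haplogroup`, `count`, `n`,
#'   `frequency`, `percent` (one-decimal, half away from zero),
#'   `ci_lower`, `ci_upper`, `informative`.  Frequencies sum to 1 within
#'   each group.
#' @export
haplogroup_frequencies <- function(records, groups = "all",
                                   informative_threshold = 0.05,
                                   conf_level = 0.95,
                                   haplogroup_levels = NULL) {
  if (!"haplogroup" %in% names(records))
    stop("records lack a haplogroup column")
  if (nrow(records) == 0)
    stop("empty group: ", paste(unique(as.character(groups)),
                                collapse = ", "))
  groups <- rep_len(as.character(groups), nrow(records))
  if (is.null(haplogroup_levels))
    haplogroup_levels <- sort(unique(records$haplogroup))
  out <- list()
  for (g in unique(groups)) {
    sub <- records$haplogroup[groups == g]
    n <- length(sub)
    if (n == 0) stop("empty group: ", g)
    cnt <- table(factor(sub, levels = haplogroup_levels))
    ci <- modified_wald_ci(as.integer(cnt), n, conf_level)
    freq <- as.numeric(cnt) / n
    out[[g]] <- data.frame(group = g, haplogroup = names(cnt),
                           count = as.integer(cnt), n = n,
                           frequency = freq,
                           percent = round_half_away(100 * freq, 1),
                           ci_lower = ci[, "lower"],
                           ci_upper = ci[, "upper"],
                           informative = freq >= informative_threshold,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided P by summing, over the hypergeometric distribution
#' fixed by the margins, the probabilities of all tables at most as
#' probable as the observed one (probabilities within a 1e-7 relative
#' tolerance of the observed are counted as ties, the standard
#' convention).  The odds ratio is the sample cross-product ratio.
#'
#' @param tab 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("table must be 2 x 2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  m <- sum(tab[1, ])          # row-1 total
  n <- sum(tab[2, ])          # row-2 total
  k <- sum(tab[, 1])          # column-1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = p)
}

#' Multiple-testing adjustment with significance flags
#'
#' Adjusts raw P values by the Benjamini-Yekutieli step-up (default: the
#' FDR variant with the harmonic-sum inflation, robust under
#' dependence), Benjamini-Hochberg, or Bonferroni method, and flags
#' significance at `alpha`.  The Bonferroni critical value alpha/m is
#' reported alongside.
#'
#' @param p numeric vector of raw P values in [0, 1].
#' @param method `"BY"` (default), `"BH"` or `"bonferroni"`.
#' @param alpha significance level (default 0.05).
#' @return list with `adjusted`, `significant` (logical),
#'   `bonferroni_critical` (alpha/m), `method`, `alpha`.
#' @export
adjust_pvalues <- function(p, method = c("BY", "BH", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("P values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  list(adjusted = adj, significant = adj <= alpha,
       bonferroni_critical = alpha / length(p), method = method,
       alpha = alpha)
}
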