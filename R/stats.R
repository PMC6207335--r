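#' Two-sided Mann-Whitney U test
#'
#' Tests whether two samples come from the same distribution using the rank
#' sum statistic. The exact null distribution is used when both samples have
#' at most 8 observations and no ties are present; otherwise the normal
#' approximation with tie and continuity correction applies. When every
#' value in both samples is identical the p-value is 1 by convention.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with \code{statistic} (U for \code{x}), \code{p_value},
#'   \code{method} (\code{"exact"} or \code{"normal_approx"}).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate"))
  ties <- any(duplicated(pooled))
  exact <- max(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic),
       p_value = min(1, wt$p.value),
       method = if (exact) "exact" else "normal_approx")
}

#' Dunn's test with Bonferroni correction
#'
#' Pairwise post-hoc comparison of two or more groups on joint mid-ranks,
#' with tie-corrected variance. For each pair the two-sided normal p-value
#' of the rank-mean difference is multiplied by the number of pairwise
#' comparisons and clipped at 1. With two groups the Bonferroni factor is 1
#' and the result reduces to a rank-sum z-test.
#'
#' @param groups List of numeric samples (each non-empty, total n >= 5).
#' @return Data frame with one row per pair: \code{group_i}, \code{group_j},
#'   \code{z}, \code{p_value} (Bonferroni-corrected).
#' @export
dunn_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be non-empty")
  N <- sum(sizes)
  if (N < 5) stop("total sample size must be at least 5")

  values <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_along(groups), sizes)
  r <- rank(values)  # mid-ranks
  rbar <- tapply(r, grp, mean)

  # tie correction: sum over tie groups of (t^3 - t)
  tt <- table(values)
  tie_sum <- sum(tt^3 - tt)
  var_term <- (N * (N + 1) / 12) - tie_sum / (12 * (N - 1))

  k <- length(groups)
  m <- k * (k - 1) / 2
  labels <- if (!is.null(names(groups))) names(groups)
            else as.character(seq_len(k))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(var_term * (1 / sizes[i] + 1 / sizes[j]))
      z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
      p <- min(1, 2 * stats::pnorm(-abs(z)) * m)
      rows[[length(rows) + 1]] <- data.frame(
        group_i = labels[i], group_j = labels[j], z = z, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# feature columns treated as counts (routed to the Dunn test); everything
# else is treated as continuous (Mann-Whitney U)
COUNT_FEATURES <- c("contacts_total", "contacts_local", "contacts_tertiary",
                    "distinct_neighborhood_count", "n_hbond",
                    "n_hydrophobic")

#' Compare a feature between residue groups
#'
#' Splits the residue feature table by \code{folding_class} (EARLY vs LATE)
#' or \code{functional} (TRUE vs FALSE) and reports group means and standard
#' deviations over all residues, together with two p-values: \code{p_all}
#' over all residues and \code{p_buried} over the buried subset (RASA below
#' the burial threshold). Early folding residues concentrate in the buried
#' core while functional residues sit at the surface, so the buried-subset
#' p-value is the one used to call significance: below 0.05 for the
#' Mann-Whitney U test (continuous features) or below 0.025 for the Dunn
#' test (count features).
#'
#' @param table Residue feature table (see \code{\link{featurize}}).
#' @param feature Name of the feature column.
#' @param grouping \code{"folding_class"} or \code{"functional"}.
#' @return List of class \code{group_comparison}: feature, grouping, per
#'   group \code{n}, \code{mean}, \code{sd}, plus \code{p_all},
#'   \code{p_buried}, \code{test}, \code{significant}.
#' @export
compare_feature <- function(table, feature,
                            grouping = c("folding_class", "functional")) {
  grouping <- match.arg(grouping)
  stopifnot(feature %in% names(table), "buried" %in% names(table))
  g <- if (grouping == "folding_class") {
    factor(table$folding_class, levels = c("EARLY", "LATE"))
  } else {
    factor(ifelse(table$functional, "FUNCTIONAL", "NON_FUNCTIONAL"),
           levels = c("FUNCTIONAL", "NON_FUNCTIONAL"))
  }
  v <- table[[feature]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep]); buried <- table$buried[keep]
  if (nlevels(g) < 2)
    stop("grouping '", grouping, "' has an empty group: only level(s) ",
         paste(levels(g), collapse = ", "), " present")

  split_all <- split(v, g)
  split_bur <- split(v[buried %in% TRUE], droplevels(g[buried %in% TRUE]))
  test <- if (feature %in% COUNT_FEATURES) "dunn" else "mann_whitney"

  run_test <- function(parts) {
    if (length(parts) < 2 || any(lengths(parts) == 0)) return(NA_real_)
    if (test == "dunn") dunn_bonferroni(parts)$p_value[1]
    else mann_whitney_u(parts[[1]], parts[[2]])$p_value
  }
  p_all <- run_test(split_all)
  p_buried <- run_test(split_bur)
  alpha <- if (test == "dunn") 0.025 else 0.05

  out <- list(
    feature = feature, grouping = grouping,
    groups = data.frame(
      group = names(split_all), n = lengths(split_all),
      mean = vapply(split_all, mean, numeric(1)),
      sd = vapply(split_all, stats::sd, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    p_all = p_all, p_buried = p_buried, test = test,
    alpha = alpha,
    significant = !is.na(p_buried) && p_buried < alpha,
    p_buried_defined = !is.na(p_buried)
  )
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Feature '", x$feature, "' by ", x$grouping, " (", x$test, "):\n",
      sep = "")
  print(x$groups, row.names = FALSE)
  cat("p_all = ", format(x$p_all, digits = 4), ", p_buried = ",
      format(x$p_buried, digits = 4),
      if (isTRUE(x$significant)) " *" else "", "\n", sep = "")
  invisible(x)
}

#' Observed-versus-expected overlap shift of two binary label sets
#'
#' For \code{N} positions carrying \code{n_A} labels of one kind, \code{n_B}
#' of another and \code{n_obs} positions carrying both, compares the
#' observed joint probability \code{n_obs / N} against the product of the
#' marginals \code{(n_A / N) (n_B / N)}. The shift (in percentage points)
#' is negative when the sets overlap less than independent labels would,
#' positive when co-occurrence is enriched.
#'
#' @param n_obs Number of positions carrying both labels.
#' @param n_A,n_B Label counts.
#' @param N Total positions considered (> 0).
#' @return List of class \code{overlap_result}: \code{N}, \code{n_A},
#'   \code{n_B}, \code{n_obs}, \code{observed_pct}, \code{expected_pct},
#'   \code{shift_pct} (exact, unrounded).
#' @export
overlap_shift <- function(n_obs, n_A, n_B, N) {
  if (N <= 0) stop("N must be positive")
  stopifnot(n_obs >= 0, n_obs <= min(n_A, n_B), max(n_A, n_B) <= N)
  observed <- 100 * n_obs / N
  expected <- 100 * (n_A / N) * (n_B / N)
  structure(list(N = N, n_A = n_A, n_B = n_B, n_obs = n_obs,
                 observed_pct = observed, expected_pct = expected,
                 shift_pct = observed - expected),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d/%d obs both (A=%d, B=%d); observed %.2f%%, expected %.2f%%, shift %+.2f%%\n",
              x$n_obs, x$N, x$n_A, x$n_B, x$observed_pct, x$expected_pct,
              x$shift_pct))
  invisible(x)
}

#' Contingency summary of folding class versus functional relevance
#'
#' Cross-tabulates the EARLY/LATE and functional/non-functional labels of a
#' residue feature table and reports the observed percentage of residues
#' carrying both labels next to the percentage expected under independence
#' (product of the marginal fractions). Structures without any functional
#' annotation should be excluded before calling (see
#' \code{\link{overlap_table}}).
#'
#' @param table Residue feature table with \code{folding_class} and
#'   \code{functional} columns, or a named vector/list of four counts
#'   \code{early_functional}, \code{early_nonfunctional},
#'   \code{late_functional}, \code{late_nonfunctional}.
#' @return List of class \code{contingency_summary} with the four counts,
#'   \code{total}, \code{observed_pct}, \code{expected_pct}.
#' @export
contingency_summary <- function(table) {
  if (is.data.frame(table)) {
    early <- table$folding_class == "EARLY"
    fun <- table$functional
    counts <- c(early_functional = sum(early & fun),
                early_nonfunctional = sum(early & !fun),
                late_functional = sum(!early & fun),
                late_nonfunctional = sum(!early & !fun))
  } else {
    counts <- unlist(table)
    stopifnot(all(c("early_functional", "early_nonfunctional",
                    "late_functional", "late_nonfunctional") %in%
                  names(counts)))
    counts <- counts[c("early_functional", "early_nonfunctional",
                       "late_functional", "late_nonfunctional")]
  }
  total <- sum(counts)
  if (total == 0) stop("empty contingency table")
  p_early <- (counts[["early_functional"]] +
              counts[["early_nonfunctional"]]) / total
  p_fun <- (counts[["early_functional"]] +
            counts[["late_functional"]]) / total
  structure(list(counts = counts, total = total,
                 observed_pct = 100 * counts[["early_functional"]] / total,
                 expected_pct = 100 * p_early * p_fun),
            class = "contingency_summary")
}

#' @export
print.contingency_summary <- function(x, ...) {
  m <- matrix(x$counts, 2, 2, byrow = TRUE,
              dimnames = list(c("early", "late"),
                              c("functional", "non-functional")))
  print(m)
  cat(sprintf("observed joint %.1f%%, expected %.1f%% (of %d residues)\n",
              x$observed_pct, x$expected_pct, x$total))
  invisible(x)
}

#' Notched-boxplot summary of a sample
#'
#' Median with the conventional 95 percent notch interval
#' \code{median +/- 1.57 IQR / sqrt(n)} (McGill, Tukey and Larsen
#' convention). Non-overlapping notches of two boxes indicate substantially
#' different medians.
#'
#' @param sample Numeric sample (n >= 1).
#' @return List with \code{median}, \code{lower}, \code{upper}, \code{n}.
#' @export
notch_bounds <- function(sample) {
  stopifnot(length(sample) >= 1, all(is.finite(sample)))
  m <- stats::median(sample)
  half <- 1.57 * stats::IQR(sample) / sqrt(length(sample))
  list(median = m, lower = m - half, upper = m + half, n = length(sample))
}
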