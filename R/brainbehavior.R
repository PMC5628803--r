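#' Select scores showing a deficit in one group
#'
#' Returns the neurocognitive scores whose mean in `group_a` is lower than
#' in `group_b` with an unadjusted two-sample t p-value below `alpha` -
#' one comparison per score, direction required (a score that is higher in
#' `group_a` is never selected, whatever its p). Scores with fewer than
#' two observations in either group are skipped with a warning.
#'
#' @param cohort Cohort data frame (columns `subject_id`, `group`, `age`,
#'   `wmh_count`, plus one column per score).
#' @param group_a Deficit group (default `"SCD"`).
#' @param group_b Reference group (default `"CTL"`).
#' @param alpha Selection level (default 0.05).
#' @param var_equal Pooled (default) or Welch t.
#' @return Character vector of selected score names.
#' @export
select_deficit_scores <- function(cohort, group_a = "SCD", group_b = "CTL",
                                  alpha = 0.05, var_equal = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  for (gp in c(group_a, group_b)) if (!any(cohort$group == gp))
    stop(sprintf("group '%s' absent from cohort", gp), call. = FALSE)
  scores <- setdiff(names(cohort), c("subject_id", "group", "age", "wmh_count"))
  sel <- character(0)
  for (nm in scores) {
    xa <- cohort[[nm]][cohort$group == group_a]
    xb <- cohort[[nm]][cohort$group == group_b]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      warning(sprintf("score '%s' has < 2 observations per group; skipped", nm))
      next
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    if (mean(xa) < mean(xb) && tt$p.value < alpha) sel <- c(sel, nm)
  }
  sel
}

#' Pearson correlation with two-sided p
#'
#' Sample Pearson correlation of paired complete observations, with the
#' two-sided p-value from the t transform `t = r sqrt((n-2)/(1-r^2))`,
#' `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return `list(r, p, n)`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p_(i) = min_{j >= i} m p_(j) / j`, clipped
#' at 1) in the input order, plus rejection flags at level `q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)` (default 0.05).
#' @return `list(adjusted, reject)`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  adjusted <- p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Correlate regional ALFF with neurocognitive scores
#'
#' Pearson correlation of every (cluster, score) pair across all subjects
#' pooled, with Benjamini-Hochberg adjustment over the full cluster-by-
#' score family. Missing scores are handled pairwise-complete; the n used
#' is reported per row.
#'
#' @param cohort Cohort data frame; rows must align with `regional_alff`.
#' @param regional_alff Subjects x clusters matrix (see
#'   [regional_alff_matrix()]).
#' @param scores Character vector of score column names to test (e.g. from
#'   [select_deficit_scores()]).
#' @param q FDR level (default 0.05).
#' @return A data frame sorted by adjusted p with columns `cluster`,
#'   `score`, `r`, `p`, `p_adj`, `n`, `significant`.
#' @export
correlate_clusters_scores <- function(cohort, regional_alff, scores,
                                      q = 0.05) {
  regional_alff <- as.matrix(regional_alff)
  if (nrow(regional_alff) != nrow(cohort))
    stop("regional_alff rows must align with cohort rows", call. = FALSE)
  cl_names <- colnames(regional_alff) %||%
    paste0("cluster", seq_len(ncol(regional_alff)))
  if (!ncol(regional_alff) || !length(scores)) {
    warning("empty cluster or score set; returning empty table")
    return(data.frame(cluster = character(0), score = character(0),
                      r = numeric(0), p = numeric(0), p_adj = numeric(0),
                      n = integer(0), significant = logical(0)))
  }
  rows <- list()
  for (ci in seq_len(ncol(regional_alff))) {
    for (nm in scores) {
      pr <- pearson_r(regional_alff[, ci], cohort[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl_names[ci], score = nm, r = pr$r, p = pr$p, n = pr$n,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  fdr <- bh_fdr(tab$p, q)
  tab$p_adj <- fdr$adjusted
  tab$significant <- fdr$reject
  tab <- tab[order(tab$p_adj, tab$p), c("cluster", "score", "r", "p",
                                        "p_adj", "n", "significant")]
  rownames(tab) <- NULL
  tab
}

#' Pathological white-matter lesion load
#'
#' Flags a lesion count as pathological when it exceeds one lesion per
#' decade of age - strictly: `n_lesions > age / 10`, so a boundary count
#' (e.g. 4 lesions at age 40) is not pathological.
#'
#' @param n_lesions Lesion count(s), non-negative.
#' @param age Age(s) in years, positive.
#' @return Logical vector.
#' @export
classify_wmh_pathological <- function(n_lesions, age) {
  if (any(n_lesions < 0)) stop("n_lesions must be >= 0", call. = FALSE)
  if (any(age <= 0)) stop("age must be > 0", call. = FALSE)
  n_lesions > age / 10
}
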