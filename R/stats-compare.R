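## Inferential statistics on amplitude tables: paired t-test, one-way ANOVA
## with Tukey's HSD. Implemented from the textbook formulas (the test suite
## checks them against R's stats:: reference implementations on random
## data).

#' Paired Student's t-test
#'
#' Classical two-sided paired t-test on the within-cell differences.
#' Pairs with a missing value on either side are dropped listwise.
#'
#' @param x,y equal-length paired measurement vectors (e.g. first and
#'   second stimulation amplitudes of the same cells).
#' @param labels condition labels (length 2).
#' @return list of class `paired_comparison`: `t`, `df`, `p_value`,
#'   `mean_difference`, `n_pairs`, `flags`.
#' @export
paired_t_test <- function(x, y, labels = c("first", "second")) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2) stop("need >= 2 complete pairs")
  flags <- character(0)
  md <- mean(d); sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(md) * Inf; p <- 0
      flags <- "zero_variance"
    }
  } else {
    tstat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  }
  structure(list(labels = labels, t = tstat, df = n - 1L, p_value = p,
                 mean_difference = md, n_pairs = n, flags = flags),
            class = "paired_comparison")
}

#' Significance stars for an adjusted p-value
#'
#' Threshold ladder is configurable; the default is the conventional
#' 0.05 / 0.01 / 0.001 / 0.0001 ladder.
#'
#' @param p p-value(s).
#' @param thresholds decreasing vector of 4 thresholds.
#' @return character vector of "ns", "*", "**", "***" or "****".
#' @export
p_stars <- function(p, thresholds = c(0.05, 0.01, 0.001, 0.0001)) {
  stopifnot(length(thresholds) == 4, all(diff(thresholds) < 0))
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < thresholds[4]) "****"
    else if (pp < thresholds[3]) "***"
    else if (pp < thresholds[2]) "**"
    else if (pp < thresholds[1]) "*"
    else "ns"
  }, character(1))
}

#' One-way ANOVA with Tukey's multiple-comparison test
#'
#' Computes the one-way ANOVA F statistic and p-value, then all pairwise
#' comparisons with Tukey-HSD adjusted p-values from the studentized-range
#' distribution. Groups with fewer than 2 observations are excluded with a
#' warning.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   `value`/`group` columns.
#' @param tukey compute the pairwise Tukey table (default TRUE; turn off
#'   for speed in large simulations that only need F and p).
#' @param thresholds star-annotation thresholds, see [p_stars()].
#' @return list of class `anova_tukey`: `F`, `df_between`, `df_within`,
#'   `p_value`, `group_means`, `pairwise` (data.frame with `group1`,
#'   `group2`, `mean_difference`, `p_unadjusted`, `p_adjusted`, `stars`).
#' @export
anova_tukey <- function(groups, tukey = TRUE,
                        thresholds = c(0.05, 0.01, 0.001, 0.0001)) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(groups)[sizes < 2], collapse = ", "))
    groups <- groups[sizes >= 2]
  }
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups with n >= 2")
  ni <- lengths(groups)
  N <- sum(ni)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ni * means) / N
  ss_between <- sum(ni * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1L; df_w <- N - k
  ms_w <- ss_within / df_w
  Fstat <- if (ms_w == 0) {
    if (ss_between == 0) 0 else Inf
  } else (ss_between / df_b) / ms_w
  p <- if (is.infinite(Fstat)) 0 else
    stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  if (ms_w == 0 && ss_between == 0) p <- 1
  pairwise <- NULL
  if (tukey) {
    cmb <- utils::combn(names(groups), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      g1 <- cmb[1, j]; g2 <- cmb[2, j]
      diff <- means[[g2]] - means[[g1]]
      se <- sqrt(ms_w / 2 * (1 / ni[[g1]] + 1 / ni[[g2]]))
      if (se == 0) {
        q <- if (diff == 0) 0 else Inf
      } else q <- abs(diff) / se
      p_adj <- if (is.infinite(q)) 0 else
        stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
      if (q == 0) p_adj <- 1
      ## unadjusted two-sample comparison on the pooled within-group
      ## variance (the q/sqrt(2) identity links it to the Tukey statistic)
      tt <- q / sqrt(2)
      p_un <- if (is.infinite(tt)) 0 else
        2 * stats::pt(tt, df = df_w, lower.tail = FALSE)
      if (q == 0) p_un <- 1
      data.frame(group1 = g1, group2 = g2, mean_difference = diff,
                 p_unadjusted = p_un, p_adjusted = p_adj,
                 stars = p_stars(p_adj, thresholds),
                 stringsAsFactors = FALSE)
    }))
    rownames(pairwise) <- NULL
  }
  structure(list(F = Fstat, df_between = df_b, df_within = df_w,
                 p_value = p, group_means = means, group_n = ni,
                 pairwise = pairwise),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g %s\n",
              x$df_between, x$df_within, x$F, x$p_value,
              p_stars(x$p_value)))
  if (!is.null(x$pairwise)) {
    cat("Tukey multiple comparisons:\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}
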