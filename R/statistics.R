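# Statistical analysis layer: normality screening, Spearman correlation
# with Fisher-z confidence intervals, and shows-vs-no-shows group
# comparisons of the area features.

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of normality. The default `"lilliefors"` variant
#' plugs the sample mean and SD into the reference normal (the composite
#' test appropriate when the parameters are estimated; `nortest`'s
#' Dallal-Wilkinson p-value). `"ks"` runs the fixed-parameter KS test
#' against the normal with the sample moments (its p is conservative for
#' estimated parameters).
#'
#' @param x Numeric sample, `n >= 3` (for `"lilliefors"`, `n >= 4`).
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return List with `statistic` (max |ECDF - CDF|), `p`, `n`, `method`.
#' @export
ks_normality <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < 3L) {
    stop_mtm("ks_normality needs at least 3 finite values",
             "mtmpose_insufficient_n_error")
  }
  if (stats::sd(x) == 0) {
    stop_mtm("ks_normality is undefined for a constant sample",
             "mtmpose_degenerate_error")
  }
  ht <- if (method == "lilliefors") {
    nortest::lillie.test(x)
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       n = length(x), method = method)
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the two-sided
#' p-value uses the t approximation with `n - 2` degrees of freedom and the
#' confidence interval the Fisher z transform ([fisher_ci()]).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3` after removing pairs
#'   with missing values.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `mtm_correlation`: `r`, `p`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
spearman_cor <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_mtm("`x` and `y` must have equal length", "mtmpose_schema_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop_mtm("spearman_cor needs at least 3 complete pairs",
             "mtmpose_insufficient_n_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_mtm("correlation undefined for a constant vector",
             "mtmpose_degenerate_error")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  r <- unname(ht$estimate)
  ci <- if (n >= 4L && abs(r) < 1) {
    fisher_ci(r, n, conf_level = conf_level)
  } else {
    c(ci_low = NA_real_, ci_high = NA_real_)
  }
  structure(list(r = r, p = unname(ht$p.value),
                 ci_low = unname(ci[1L]), ci_high = unname(ci[2L]), n = n),
            class = "mtm_correlation")
}

#' @export
print.mtm_correlation <- function(x, ...) {
  cat(sprintf("Spearman r = %.3f (95%% CI %.3f, %.3f), p = %.4g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' `tanh(atanh(r) +/- z_(1-alpha/2) / sqrt(n - 3))`: the correlation is
#' mapped through the Fisher z transform, whose sampling distribution is
#' approximately normal with SD `1 / sqrt(n - 3)`, and the symmetric normal
#' interval is mapped back.
#'
#' @param r Correlation in (-1, 1).
#' @param n Sample size, at least 4.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric `c(ci_low, ci_high)`; the bounds always bracket
#'   `r` and lie in (-1, 1).
#' @examples
#' fisher_ci(0.315, 94)
#' @export
fisher_ci <- function(r, n, conf_level = 0.95) {
  stopifnot(length(r) == 1L, length(n) == 1L)
  if (!is.finite(r) || abs(r) >= 1) {
    stop_mtm("`r` must lie strictly inside (-1, 1)", "mtmpose_degenerate_error")
  }
  if (n < 4L) {
    stop_mtm("fisher_ci needs n >= 4", "mtmpose_insufficient_n_error")
  }
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - half), ci_high = tanh(z + half))
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. `U` is the number of
#' pairs `(a_i, b_j)` with `a_i > b_j` (ties count one half), so identical
#' distributions give `U` near `n_a * n_b / 2` and `a` stochastically larger
#' gives `U` near `n_a * n_b`. The default p-value is the tie-corrected
#' normal approximation with continuity correction; `exact = TRUE` requests
#' exact enumeration (available without ties, sensible for small samples).
#'
#' @param a,b Numeric samples, both nonempty.
#' @param exact Logical; exact p instead of the normal approximation.
#' @param correct Continuity correction for the normal approximation.
#' @return List with `U`, `p`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, exact = FALSE, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop_mtm("mann_whitney needs two nonempty samples",
             "mtmpose_insufficient_n_error")
  }
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = correct)
  )
  list(U = unname(ht$statistic), p = unname(ht$p.value),
       n_a = length(a), n_b = length(b))
}

#' Two-sample independent t-test
#'
#' Student's pooled-variance two-sample t-test, two-sided, by default (the
#' classic "independent t-test"); set `var_equal = FALSE` for the Welch
#' variant.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `p`, `df`, `n_a`, `n_b`.
#' @export
independent_t <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_mtm("independent_t needs at least 2 values per group",
             "mtmpose_insufficient_n_error")
  }
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    stop_mtm("independent_t undefined: zero within-group variance",
             "mtmpose_degenerate_error")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter), n_a = length(a), n_b = length(b))
}

#' Distance-feature / MTM-score correlation table
#'
#' For each of the four mean signed limb distances (Dlm15, Dlm16, Dlm27,
#' Dlm28) against each MTM observation value (occurrence percentage and the
#' lower, upper and total per-minute rates), computes the Spearman
#' correlation with its Fisher-z confidence interval. Cells are flagged
#' significant at `sig_level` (default 0.01, the table-footnote convention).
#'
#' @param features Per-video feature summaries ([summarize_video()] rows).
#' @param scores Per-video MTM scores ([score_videos()]).
#' @param conf_level Confidence level of the intervals (default 0.95).
#' @param sig_level Per-cell significance flag threshold (default 0.01).
#' @return A `data.frame` with one row per (landmark, metric) cell:
#'   `landmark`, `metric`, `r`, `p`, `ci_low`, `ci_high`, `n`, `significant`.
#' @export
correlate_features <- function(features, scores, conf_level = 0.95,
                               sig_level = 0.01) {
  m <- merge(features, scores, by = "video_id")
  if (nrow(m) < 4L) {
    stop_mtm("correlate_features needs at least 4 matched videos",
             "mtmpose_insufficient_n_error")
  }
  dists <- c(Dlm15 = "mean_dlm15", Dlm16 = "mean_dlm16",
             Dlm27 = "mean_dlm27", Dlm28 = "mean_dlm28")
  metrics <- c(occurrence_percentage = "occurrence_percentage",
               rate_lower = "rate_lower", rate_upper = "rate_upper",
               rate_total = "rate_total")
  out <- vector("list", length(dists) * length(metrics))
  k <- 0L
  for (i in seq_along(dists)) for (j in seq_along(metrics)) {
    # A constant metric (e.g. no video shows a group) leaves that cell
    # undefined rather than aborting the whole table.
    ct <- tryCatch(
      spearman_cor(m[[dists[i]]], m[[metrics[j]]], conf_level = conf_level),
      mtmpose_degenerate_error = function(e) {
        list(r = NA_real_, p = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, n = nrow(m))
      }
    )
    k <- k + 1L
    out[[k]] <- data.frame(
      landmark = names(dists)[i], metric = names(metrics)[j],
      r = ct$r, p = ct$p, ci_low = ct$ci_low, ci_high = ct$ci_high,
      n = ct$n, significant = ct$p < sig_level
    )
  }
  do.call(rbind, out)
}

#' Area comparisons between videos showing and not showing MTM
#'
#' For each MTM category (Total, Lower, Upper), compares the three mean
#' normalized areas between videos that show the category and videos that
#' do not: the whole area with the independent t-test, the upper- and
#' lower-part areas with the Mann-Whitney U test. Locations reported are
#' group means for the t-test and medians for the U test. A category with
#' an empty group is skipped with a warning.
#'
#' @inheritParams correlate_features
#' @param var_equal Passed to [independent_t()] for the whole-area test.
#' @return A `data.frame` with columns `category`, `measure`, `test`,
#'   `statistic`, `p`, `n_show`, `n_noshow`, `location_show`,
#'   `location_noshow`.
#' @export
compare_mtm_groups <- function(features, scores, var_equal = TRUE) {
  m <- merge(features, scores, by = "video_id")
  if (nrow(m) < 4L) {
    stop_mtm("compare_mtm_groups needs at least 4 matched videos",
             "mtmpose_insufficient_n_error")
  }
  cats <- c(Total = "shows_total", Lower = "shows_lower",
            Upper = "shows_upper")
  measures <- c(whole = "mean_area_whole", upper = "mean_area_upper",
                lower = "mean_area_lower")
  out <- list()
  for (ci in seq_along(cats)) {
    flag <- m[[cats[ci]]]
    if (sum(flag) == 0L || sum(!flag) == 0L) {
      warning(sprintf(
        "category %s skipped: one of the shows/no-shows groups is empty",
        names(cats)[ci]
      ), call. = FALSE)
      next
    }
    for (mi in seq_along(measures)) {
      show <- m[[measures[mi]]][flag]
      noshow <- m[[measures[mi]]][!flag]
      if (names(measures)[mi] == "whole") {
        # a one-video group or zero variance leaves the cell undefined
        ht <- tryCatch(
          independent_t(show, noshow, var_equal = var_equal),
          mtmpose_degenerate_error = function(e) list(t = NA_real_,
                                                      p = NA_real_),
          mtmpose_insufficient_n_error = function(e) list(t = NA_real_,
                                                          p = NA_real_)
        )
        row <- data.frame(test = "t_test", statistic = ht$t, p = ht$p,
                          location_show = mean(show),
                          location_noshow = mean(noshow))
      } else {
        ht <- mann_whitney(show, noshow)
        row <- data.frame(test = "mann_whitney", statistic = ht$U, p = ht$p,
                          location_show = stats::median(show),
                          location_noshow = stats::median(noshow))
      }
      out[[length(out) + 1L]] <- cbind(
        data.frame(category = names(cats)[ci], measure = names(measures)[mi]),
        row[c("test", "statistic", "p")],
        data.frame(n_show = sum(flag), n_noshow = sum(!flag)),
        row[c("location_show", "location_noshow")]
      )
    }
  }
  if (length(out) == 0L) {
    stop_mtm("no category had both groups nonempty",
             "mtmpose_insufficient_n_error")
  }
  do.call(rbind, out)
}
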