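test_that("fisher_ci brackets r and shrinks monotonically with n", {
  set.seed(51)
  for (i in 1:25) {
    r <- runif(1, -0.95, 0.95)
    ns <- c(5, 10, 20, 50, 100, 500)
    widths <- sapply(ns, function(n) {
      ci <- fisher_ci(r, n)
      expect_lte(ci[["ci_low"]], r)
      expect_gte(ci[["ci_high"]], r)
      expect_true(all(abs(ci) < 1))
      ci[["ci_high"]] - ci[["ci_low"]]
    })
    expect_true(all(diff(widths) < 0))
  }
  # r = 0 gives an interval symmetric about 0
  ci <- fisher_ci(0, 30)
  expect_equal(ci[["ci_low"]], -ci[["ci_high"]])
  expect_error(fisher_ci(0.5, 3), class = "mtmpose_insufficient_n_error")
  expect_error(fisher_ci(1, 30), class = "mtmpose_degenerate_error")
})

test_that("spearman correlation equals the mid-rank Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, exp(x))$r, 1)
  expect_equal(spearman_cor(x, -x)$r, -1)
  # n = 6 with ties: hand-computed mid-ranks, Pearson by sums
  x6 <- c(1, 2, 2, 3, 4, 4)
  y6 <- c(5, 3, 4, 4, 1, 2)
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x6); ry <- midrank(y6)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  ct <- spearman_cor(x6, y6)
  expect_equal(ct$r, oracle, tolerance = 1e-12)
  # p from the t approximation with n - 2 df
  tstat <- oracle * sqrt((6 - 2) / (1 - oracle^2))
  expect_equal(ct$p, 2 * stats::pt(-abs(tstat), df = 4), tolerance = 1e-12)
  # invariant under strictly monotone transforms of either variable
  set.seed(52)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    r0 <- spearman_cor(a, b)$r
    expect_equal(spearman_cor(exp(a), b)$r, r0)
    expect_equal(spearman_cor(a, b^3)$r, r0)
  }
  expect_error(spearman_cor(rep(1, 5), rnorm(5)),
               class = "mtmpose_degenerate_error")
})

test_that("spearman CI arithmetic is internally consistent", {
  set.seed(53)
  x <- rnorm(30); y <- x + rnorm(30)
  ct <- spearman_cor(x, y)
  ci <- fisher_ci(ct$r, ct$n)
  expect_equal(c(ct$ci_low, ct$ci_high), unname(ci))
})

test_that("Mann-Whitney U has the documented conventions and exact oracle", {
  # identical multisets: U = n_a * n_b / 2
  a <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(a, a)$U, 8)
  # a entirely above b: U = n_a * n_b
  expect_equal(mann_whitney(c(10, 11, 12), c(1, 2))$U, 6)
  # exact p equals full enumeration at n = 5/5
  set.seed(54)
  a5 <- c(0.11, 0.52, 0.93, 1.34, 2.01)
  b5 <- c(0.45, 0.78, 1.62, 2.35, 2.88)
  expect_equal(mann_whitney(a5, b5, exact = TRUE)$p,
               mwu_exact_oracle(a5, b5), tolerance = 1e-12)
  # normal approximation close to enumeration even at n = 5/5
  expect_lt(abs(mann_whitney(a5, b5)$p - mwu_exact_oracle(a5, b5)), 0.05)
})

test_that("independent t matches the hand-computed pooled formula", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  ht <- independent_t(a, b)
  sp2 <- ((4 - 1) * var(a) + (5 - 1) * var(b)) / (4 + 5 - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 5))
  expect_equal(ht$t, t_oracle, tolerance = 1e-12)
  expect_equal(ht$df, 7)
  # same values -> t = 0, p = 1
  ht0 <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ht0$t, 0)
  expect_equal(ht0$p, 1)
  # a clear shift at large n gives a small p
  set.seed(55)
  expect_lt(independent_t(rnorm(100), rnorm(100) + 1)$p, 1e-6)
  expect_error(independent_t(c(1, 1), c(1, 1)),
               class = "mtmpose_degenerate_error")
})

test_that("KS normality statistic equals the brute-force ECDF oracle", {
  x <- c(0.3, -1.2, 0.8, 2.0, -0.4, 1.1, 0.05, -0.7)
  ks <- ks_normality(x)
  xs <- sort(x)
  n <- length(xs)
  z <- stats::pnorm(xs, mean(xs), sd(xs))
  d_oracle <- max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1) / n))
  expect_equal(ks$statistic, d_oracle, tolerance = 1e-12)
  # fixed-parameter variant has the same statistic here by construction
  expect_equal(ks_normality(x, method = "ks")$statistic, d_oracle,
               tolerance = 1e-12)
  # statistic shrinks for a large truly normal sample
  set.seed(56)
  expect_lt(ks_normality(rnorm(5000))$statistic, 0.02)
  expect_error(ks_normality(c(0, 0, 0)), class = "mtmpose_degenerate_error")
  expect_error(ks_normality(c(1, 2)), class = "mtmpose_insufficient_n_error")
})

make_fake_cohort_tables <- function(n, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  features <- data.frame(
    video_id = ids,
    mean_dlm15 = rnorm(n), mean_dlm16 = rnorm(n),
    mean_dlm27 = rnorm(n), mean_dlm28 = rnorm(n),
    mean_area_whole = rnorm(n, 10), mean_area_upper = rnorm(n, 3),
    mean_area_lower = rnorm(n, 5),
    n_valid_frames = 3600L, n_frames = 3600L, usable = TRUE
  )
  rate_lower <- ifelse(runif(n) < 0.4, 0, round(runif(n, 0.5, 10), 1))
  rate_upper <- ifelse(runif(n) < 0.3, 0, round(runif(n, 0.5, 10), 1))
  scores <- data.frame(
    video_id = ids,
    occurrence_percentage = (rate_lower + rate_upper) * 2,
    rate_total = rate_lower + rate_upper,
    rate_lower = rate_lower, rate_upper = rate_upper,
    shows_total = rate_lower + rate_upper > 0,
    shows_lower = rate_lower > 0, shows_upper = rate_upper > 0
  )
  list(features = features, scores = scores)
}

test_that("the correlation table recovers a perfect monotone coupling", {
  tb <- make_fake_cohort_tables(20, seed = 57)
  tb$features$mean_dlm16 <- -tb$scores$rate_total
  tab <- correlate_features(tb$features, tb$scores)
  cell <- tab[tab$landmark == "Dlm16" & tab$metric == "rate_total", ]
  expect_equal(cell$r, -1)
  expect_equal(cell$n, 20L)
  # each cell's CI re-derives from fisher_ci(r, n)
  ok <- !is.na(tab$r) & abs(tab$r) < 1
  for (i in which(ok)) {
    ci <- fisher_ci(tab$r[i], tab$n[i])
    expect_equal(c(tab$ci_low[i], tab$ci_high[i]), unname(ci))
  }
})

test_that("a decoupled cohort yields a null correlation table", {
  tb <- make_fake_cohort_tables(100, seed = 58)
  tab <- correlate_features(tb$features, tb$scores)
  expect_true(all(abs(tab$r) < 0.35))
  expect_lte(sum(tab$significant, na.rm = TRUE), 1)
})

test_that("group comparisons use the documented test per measure", {
  tb <- make_fake_cohort_tables(60, seed = 59)
  # push the lower area down by 2 SD where lower MTM is shown
  shift <- ifelse(tb$scores$shows_lower, -2, 0)
  tb$features$mean_area_lower <- rnorm(60, 5) + shift
  cmp <- compare_mtm_groups(tb$features, tb$scores)
  expect_setequal(unique(cmp$test[cmp$measure == "whole"]), "t_test")
  expect_setequal(unique(cmp$test[cmp$measure != "whole"]), "mann_whitney")
  low <- cmp[cmp$category == "Lower" & cmp$measure == "lower", ]
  expect_lt(low$p, 0.05)
  expect_lt(low$location_show, low$location_noshow)
  expect_equal(low$n_show + low$n_noshow, 60L)
})

test_that("a category with an empty group is skipped with a warning", {
  tb <- make_fake_cohort_tables(20, seed = 60)
  tb$scores$shows_total <- TRUE  # no-shows group empty for Total
  expect_warning(cmp <- compare_mtm_groups(tb$features, tb$scores),
                 "Total")
  expect_false("Total" %in% cmp$category)
  expect_true(all(c("Lower", "Upper") %in% cmp$category))
})

test_that("the Mann-Whitney comparison holds its nominal level under label shuffling", {
  set.seed(61)
  n <- 60
  area <- rnorm(n, 5)
  labels <- rep(c(TRUE, FALSE), c(24, 36))
  rej <- 0L
  reps <- 1000L
  for (i in seq_len(reps)) {
    lab <- sample(labels)
    p <- mann_whitney(area[lab], area[!lab])$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})
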