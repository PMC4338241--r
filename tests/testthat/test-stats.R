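make_two_group <- function(y1, y2) {
  tibble::tibble(g = rep(c("a", "b"), c(length(y1), length(y2))),
                 D = c(y1, y2))
}

test_that("exhaustive permutation p matches brute-force enumeration", {
  y1 <- c(1.2, 1.9, 1.4)
  y2 <- c(2.8, 2.2, 3.1)
  df <- make_two_group(y1, y2)
  fit <- permanova(df, "D", "g", transform = "none", n_perm = 10000, seed = 1)
  expect_true(fit$exhaustive)

  # oracle: enumerate all 20 assignments of 3-vs-3 labels
  y <- c(y1, y2)
  fstat <- function(idx) {
    a <- y[idx]; b <- y[-idx]
    ssb <- 3 * (mean(a) - mean(y))^2 + 3 * (mean(b) - mean(y))^2
    ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    (ssb / 1) / (ssw / 4)
  }
  fobs <- fstat(1:3)
  all_f <- apply(combn(6, 3), 2, fstat)
  p_oracle <- mean(all_f >= fobs - 1e-12)
  expect_equal(fit$table$p_perm[1], p_oracle, tolerance = 1e-12)
})

test_that("constant responses give SS_total = 0 and an undefined test", {
  df <- make_two_group(rep(2, 4), rep(2, 4))
  fit <- permanova(df, "D", "g", transform = "none", n_perm = 99)
  expect_true(fit$degenerate)
  expect_true(all(is.na(fit$table$p_perm)))
})

test_that("univariate Euclidean PERMANOVA reproduces classical ANOVA exactly", {
  set.seed(10)
  df <- tibble::tibble(g = factor(rep(letters[1:3], each = 5)),
                       D = rnorm(15, mean = rep(c(0, 0.5, 1), each = 5)))
  fit <- permanova(df, "D", "g", transform = "none", n_perm = 99, seed = 2)
  a <- anova(stats::aov(D ~ g, df))
  expect_equal(fit$table$SS[1], a$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(fit$table$SS[2], a$`Sum Sq`[2], tolerance = 1e-10)
  expect_equal(fit$table$pseudo_F[1], a$`F value`[1], tolerance = 1e-10)
})

test_that("balanced crossed designs decompose additively with mixed-model F ratios", {
  set.seed(11)
  des <- expand.grid(technique = letters[1:4], operator = c("o1", "o2", "o3"),
                     session = c("s1", "s2"), rep = 1:3)
  des$D <- rnorm(nrow(des)) +
    0.8 * as.numeric(des$technique) + 0.2 * (des$session == "s2")
  fit <- permanova(des, "D", c("technique", "operator", "session"),
                   random = "operator", transform = "none", n_perm = 49, seed = 3)
  tab <- fit$table
  tot <- tab$SS[tab$source == "Total"]
  expect_equal(sum(tab$SS[!(tab$source %in% "Total")]), tot, tolerance = 1e-9)

  # classical SS agree with aov
  a <- anova(stats::aov(D ~ technique * operator * session, des))
  for (src in c("technique", "operator", "session", "technique:operator")) {
    expect_equal(tab$SS[tab$source == src], a[src, "Sum Sq"], tolerance = 1e-9)
  }
  # expected-mean-square denominators: fixed terms vs their interaction with
  # the random factor; random-containing terms vs residual
  ms <- setNames(tab$MS, tab$source)
  expect_equal(tab$pseudo_F[tab$source == "technique"],
               ms["technique"] / ms["technique:operator"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(tab$pseudo_F[tab$source == "session"],
               ms["session"] / ms["operator:session"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(tab$pseudo_F[tab$source == "operator"],
               ms["operator"] / ms["Residual"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(tab$pseudo_F[tab$source == "technique:operator:session"],
               ms["technique:operator:session"] / ms["Residual"],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("unbalanced designs are rejected", {
  df <- make_two_group(rnorm(3), rnorm(5))
  expect_error(permanova(df, "D", "g", transform = "none"), "balanced")
})

test_that("permutation p is stable across seeds within binomial error", {
  set.seed(12)
  df <- make_two_group(rnorm(8), rnorm(8, mean = 0.9))
  p1 <- permanova(df, "D", "g", transform = "none", n_perm = 999, seed = 1)$table$p_perm[1]
  p2 <- permanova(df, "D", "g", transform = "none", n_perm = 999, seed = 2)$table$p_perm[1]
  expect_lt(abs(p1 - p2), 3 * sqrt(p1 * (1 - p1) / 999) + 1e-6)
})

test_that("pairwise posthoc: identical levels give p 1; Bonferroni arithmetic holds", {
  df <- tibble::tibble(g = rep(letters[1:2], each = 5), D = rep(c(1, 2, 3, 4, 5), 2))
  out <- pairwise_posthoc(df, "D", "g", transform = "none", n_perm = 99)
  expect_equal(out$p_adj, 1)

  set.seed(13)
  df5 <- tibble::tibble(g = rep(letters[1:5], each = 4), D = rnorm(20))
  out5 <- pairwise_posthoc(df5, "D", "g", transform = "none", n_perm = 99, seed = 4)
  expect_identical(nrow(out5), 10L)
  expect_equal(out5$p_adj, pmin(1, 10 * out5$p_raw))
  expect_true(all(out5$p_adj >= out5$p_raw))
})

test_that("pairwise posthoc detects a 10-sigma separation at the 0.005 level", {
  set.seed(14)
  df <- tibble::tibble(g = rep(c("a", "b"), each = 12),
                       D = c(rnorm(12, 0, 1), rnorm(12, 10, 1)))
  out <- pairwise_posthoc(df, "D", "g", transform = "none", n_perm = 4999, seed = 5)
  expect_lte(out$p_adj, 0.005)
})

test_that("permdisp: identical groups give F = 0; dispersion difference is detected", {
  df <- make_two_group(c(1, 2, 3, 4), c(1, 2, 3, 4))
  fit <- permdisp(df, "D", "g", transform = "none", n_perm = 99)
  expect_equal(fit$F, 0)

  set.seed(15)
  hits <- 0
  for (i in 1:100) {
    d2 <- tibble::tibble(g = rep(c("a", "b"), each = 20),
                         D = c(rnorm(20, 5, 1), rnorm(20, 5, 5)))
    f <- permdisp(d2, "D", "g", transform = "none", n_perm = 199, seed = i)
    if (f$p_perm < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 80)
})

test_that("permdisp F agrees with the independent dispersion implementation in vegan", {
  set.seed(33)
  y <- c(rnorm(10, 0, 1), rnorm(10, 0, 3))
  g <- factor(rep(c("a", "b"), each = 10))
  bd <- vegan::betadisper(dist(y), g, type = "median")
  f_vegan <- anova(bd)$`F value`[1]
  fit <- permdisp(data.frame(g = g, D = y), "D", "g", transform = "none",
                  n_perm = 99)
  expect_equal(fit$F, f_vegan, tolerance = 1e-10)
})

test_that("permdisp is calibrated under location-only differences", {
  set.seed(16)
  ps <- numeric(200)
  for (i in 1:200) {
    df <- tibble::tibble(g = rep(c("a", "b"), each = 10),
                         D = c(rnorm(10, 0, 1), rnorm(10, 3, 1)))
    ps[i] <- permdisp(df, "D", "g", transform = "none", n_perm = 99,
                      seed = i)$p_perm
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bland-Altman summaries follow the documented quantile rules", {
  ref <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$median, 0)
  expect_equal(unname(ba0$iqr), c(0, 0))

  ba1 <- bland_altman(ref, ref + 0.5)
  expect_equal(ba1$median, 0.5)
  expect_equal(diff(ba1$iqr), 0, ignore_attr = TRUE)

  # hand-computable example under the mean-of-order-statistics quantile rule
  alt <- ref + c(-0.3, -0.2, -0.1, 0, 0.1)
  ba <- bland_altman(ref, alt)
  expect_equal(ba$median, -0.1)
  expect_equal(unname(ba$iqr), c(-0.25, 0.05))
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("tidiers return well-formed tibbles", {
  set.seed(17)
  df <- make_two_group(rnorm(6), rnorm(6, 1))
  fit <- permanova(df, "D", "g", transform = "none", n_perm = 99)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(glance(fit)$n_permutations, fit$n_permutations)
  ba <- bland_altman(rnorm(10), rnorm(10))
  expect_s3_class(tidy(ba), "tbl_df")
  expect_identical(nrow(glance(ba)), 1L)
  pd <- permdisp(df, "D", "g", transform = "none", n_perm = 99)
  expect_s3_class(tidy(pd), "tbl_df")
})
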