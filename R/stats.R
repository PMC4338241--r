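#' Permutational MANOVA for balanced crossed designs
#'
#' Distance-based (non-parametric) MANOVA partitioning the total sum of
#' squares of the (transformed) responses among crossed factors and all
#' their interactions, with a pseudo-F statistic per source and a p-value
#' from unrestricted permutation of the raw data rows. With the Euclidean
#' distance on a single response this reproduces classical ANOVA sums of
#' squares exactly.
#'
#' With one random factor (`random`), pseudo-F denominators follow
#' classical expected-mean-square rules for a mixed model: a source not
#' containing the random factor is tested against its interaction with the
#' random factor (if present in the model), every other source against the
#' residual.
#'
#' When the number of distinct permutations is small, a Monte Carlo
#' asymptotic p-value (`p_mc`, from a moment-matched Pearson type III fit
#' to the permutation distribution) is more reliable than the raw
#' permutation p; both are always reported. When all row permutations can
#' be enumerated within `n_perm`, the permutation p is exact.
#'
#' @param data Data frame with factor columns and response columns.
#' @param response Character vector of response column names (e.g. `"D"`).
#' @param factors Character vector of factor column names; all interactions
#'   are included.
#' @param random Optional name of one random factor.
#' @param transform `"log10"` (default; zeros are floored at `log_floor`
#'   first), `"fourth_root"` or `"none"`.
#' @param log_floor Floor applied before log10 (default 1e-4 mm), needed
#'   because perfectly registered duplicate controls produce deviations
#'   numerically equal to zero.
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `cr_permanova`; see [tidy.cr_permanova()].
#' @export
permanova <- function(data, response, factors, random = NULL,
                      transform = c("log10", "fourth_root", "none"),
                      log_floor = 1e-4, n_perm = 9999, seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(all(response %in% names(data)), all(factors %in% names(data)))
  if (!is.null(random)) stopifnot(random %in% factors)
  df <- as.data.frame(data)
  for (f in factors) df[[f]] <- factor(df[[f]])

  counts <- table(df[factors])
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    stop("unsupported design: the factor crossing must be balanced", call. = FALSE)
  }

  Y <- as.matrix(df[response])
  Y <- transform_responses(Y, transform, log_floor)
  n <- nrow(Y)

  eng <- permanova_engine(df, factors, Y)
  if (eng$ss_total <= 1e-12 * n) {
    tab <- tibble::tibble(source = c(eng$term_labels, "Residual", "Total"),
                          df = c(eng$term_df, eng$df_res, n - 1),
                          SS = 0, MS = NA_real_, pseudo_F = NA_real_,
                          p_perm = NA_real_, p_mc = NA_real_)
    return(structure(list(table = tab, n_permutations = 0L, seed = seed,
                          degenerate = TRUE),
                     class = "cr_permanova"))
  }

  obs <- permanova_stats(eng, Y, random)

  set.seed(seed)
  exhaustive <- n <= 8 && factorial(n) <= n_perm
  perms <- if (exhaustive) all_permutations(n) else
    t(replicate(n_perm, sample.int(n)))
  np <- nrow(perms)
  Fperm <- matrix(NA_real_, nrow = np, ncol = length(obs$F))
  for (b in seq_len(np)) {
    Fperm[b, ] <- permanova_stats(eng, Y[perms[b, ], , drop = FALSE], random)$F
  }
  # ties between permuted and observed statistics are counted as >=, with a
  # small relative slack so equivalent permutations are not split by
  # floating-point noise
  thr <- obs$F - 1e-8 * (1 + abs(obs$F))
  count_ge <- colSums(sweep(Fperm, 2, thr, `>=`), na.rm = TRUE)
  p_perm <- if (exhaustive) count_ge / np else (count_ge + 1) / (np + 1)
  p_perm[!is.finite(obs$F)] <- NA_real_
  p_mc <- vapply(seq_along(obs$F), function(j) {
    if (!is.finite(obs$F[j])) return(NA_real_)
    pearson3_tail(Fperm[, j], obs$F[j])
  }, numeric(1))

  tab <- tibble::tibble(
    source = c(eng$term_labels, "Residual", "Total"),
    df = c(eng$term_df, eng$df_res, n - 1),
    SS = c(obs$SS, obs$ss_res, eng$ss_total),
    MS = c(obs$SS / eng$term_df, obs$ss_res / eng$df_res, NA_real_),
    pseudo_F = c(obs$F, NA_real_, NA_real_),
    p_perm = c(p_perm, NA_real_, NA_real_),
    p_mc = c(p_mc, NA_real_, NA_real_)
  )
  structure(list(table = tab, n_permutations = np, seed = seed,
                 exhaustive = exhaustive, degenerate = FALSE,
                 transform = transform, response = response,
                 random = random),
            class = "cr_permanova")
}

transform_responses <- function(Y, transform, log_floor) {
  switch(transform,
         log10 = log10(pmax(Y, log_floor)),
         fourth_root = sign(Y) * abs(Y)^0.25,
         none = Y)
}

# precompute orthonormal bases per model term (balanced crossing with sum
# contrasts makes term blocks mutually orthogonal)
permanova_engine <- function(df, factors, Y) {
  fml <- stats::as.formula(paste("~", paste(factors, collapse = "*")))
  contr <- setNames(rep(list("contr.sum"), length(factors)), factors)
  X <- stats::model.matrix(fml, df, contrasts.arg = contr)
  asg <- attr(X, "assign")
  tl <- attr(stats::terms(fml), "term.labels")
  Qs <- lapply(seq_along(tl), function(k) {
    Xk <- X[, asg == k, drop = FALSE]
    Xk <- sweep(Xk, 2, colMeans(Xk))
    qr.Q(qr(Xk))[, seq_len(qr(Xk)$rank), drop = FALSE]
  })
  term_df <- vapply(Qs, ncol, integer(1))
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_total <- sum(Yc^2)
  list(Qs = Qs, term_labels = tl, term_df = term_df,
       df_res = n - 1 - sum(term_df), ss_total = ss_total, n = n)
}

permanova_stats <- function(eng, Y, random) {
  Yc <- sweep(Y, 2, colMeans(Y))
  SS <- vapply(eng$Qs, function(Q) sum(crossprod(Q, Yc)^2), numeric(1))
  ss_res <- max(eng$ss_total - sum(SS), 0)
  MS <- SS / eng$term_df
  ms_res <- ss_res / eng$df_res
  tl <- eng$term_labels
  denom <- vapply(seq_along(tl), function(k) {
    parts <- strsplit(tl[k], ":", fixed = TRUE)[[1]]
    if (!is.null(random) && !(random %in% parts)) {
      target <- sort(c(parts, random))
      hit <- which(vapply(tl, function(t2)
        identical(sort(strsplit(t2, ":", fixed = TRUE)[[1]]), target), logical(1)))
      if (length(hit) == 1) return(MS[hit])
    }
    ms_res
  }, numeric(1))
  list(SS = SS, F = MS / denom, ss_res = ss_res)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(blk)
    r <- r + nrow(sub)
  }
  out
}

# upper-tail probability of x under a Pearson type III (shifted gamma)
# moment fit to the sample
pearson3_tail <- function(sample, x) {
  sample <- sample[is.finite(sample)]
  m <- mean(sample)
  s <- sd(sample)
  if (!is.finite(s) || s < 1e-12) return(if (x > m) 0 else 1)
  g1 <- mean((sample - m)^3) / s^3
  if (abs(g1) < 1e-3) return(stats::pnorm(x, m, s, lower.tail = FALSE))
  shape <- 4 / g1^2
  scale <- s * g1 / 2
  loc <- m - 2 * s / g1
  if (g1 > 0) {
    stats::pgamma(pmax(x - loc, 0), shape = shape, scale = scale, lower.tail = FALSE)
  } else {
    stats::pgamma(pmax(loc - x, 0), shape = shape, scale = -scale, lower.tail = TRUE)
  }
}

#' @export
print.cr_permanova <- function(x, ...) {
  cat(sprintf("Permutational MANOVA (%d permutations%s)\n", x$n_permutations,
              if (isTRUE(x$exhaustive)) ", exhaustive" else ""))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidiers for fitted objects
#'
#' `tidy()` returns the source table (or per-pair/per-case table) as a
#' tibble; `glance()` returns a one-row model summary.
#'
#' @param x A fitted object from [permanova()], [permdisp()] or
#'   [bland_altman()].
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.cr_permanova <- function(x, ...) x$table

#' @rdname tidiers
#' @export
glance.cr_permanova <- function(x, ...) {
  tab <- x$table
  main <- tab$source[1]
  tibble::tibble(n_permutations = x$n_permutations,
                 ss_total = tab$SS[tab$source == "Total"],
                 r2_first_term = tab$SS[1] / tab$SS[tab$source == "Total"],
                 p_first_term = tab$p_perm[1],
                 first_term = main)
}

#' Pairwise a posteriori permutation t-tests
#'
#' For each pair of levels of `factor_name`, a two-sample t statistic on
#' the transformed response with a permutation p-value (relabelling the
#' pooled observations), Bonferroni-adjusted by the number of pairs.
#'
#' @inheritParams permanova
#' @param factor_name Factor whose levels are compared (other design
#'   factors are ignored, matching the pooled pairwise convention).
#' @return Tibble with one row per pair: `t`, `p_raw`, `p_mc`, `p_adj`
#'   (Bonferroni of `p_raw`, capped at 1).
#' @export
pairwise_posthoc <- function(data, response, factor_name,
                             transform = c("log10", "fourth_root", "none"),
                             log_floor = 1e-4, n_perm = 9999, seed = 1L) {
  transform <- match.arg(transform)
  df <- as.data.frame(data)
  g <- factor(df[[factor_name]])
  if (nlevels(g) < 2) stop("need at least 2 levels", call. = FALSE)
  y <- transform_responses(as.matrix(df[response]), transform, log_floor)
  lv <- levels(g)
  if (any(table(g) < 2)) stop("every level needs at least 2 observations", call. = FALSE)
  pairs <- combn(lv, 2)
  npairs <- ncol(pairs)
  set.seed(seed)
  rows <- lapply(seq_len(npairs), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ya <- y[g == a, , drop = FALSE]
    yb <- y[g == b, , drop = FALSE]
    tobs <- pooled_t(ya, yb)
    yy <- rbind(ya, yb)
    na <- nrow(ya)
    tperm <- replicate(n_perm, {
      idx <- sample.int(nrow(yy))
      pooled_t(yy[idx[seq_len(na)], , drop = FALSE],
               yy[idx[-seq_len(na)], , drop = FALSE])
    })
    p_raw <- (sum(abs(tperm) >= abs(tobs)) + 1) / (n_perm + 1)
    p_mc <- 2 * min(pearson3_tail(abs(tperm), abs(tobs)), 0.5)
    tibble::tibble(level_1 = a, level_2 = b, t = tobs,
                   p_raw = p_raw, p_mc = p_mc,
                   p_adj = min(1, npairs * p_raw))
  })
  dplyr::bind_rows(rows)
}

# multivariate pooled t: ratio of between-centroid distance to its pooled SE
pooled_t <- function(ya, yb) {
  na <- nrow(ya); nb <- nrow(yb)
  dvec <- colMeans(ya) - colMeans(yb)
  sp2 <- (sum(sweep(ya, 2, colMeans(ya))^2) + sum(sweep(yb, 2, colMeans(yb))^2)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se < 1e-300) return(0)
  sqrt(sum(dvec^2)) * sign_first(dvec) / se
}

sign_first <- function(v) if (length(v) == 1) sign_or_one(v) else 1

#' Permutation test of multivariate dispersion homogeneity
#'
#' Tests whether groups differ in spread: each observation's distance to
#' its group spatial median in the transformed response space is computed,
#' a classical one-way ANOVA F is formed on those distances, and its
#' p-value is obtained by permuting the distances among groups. Identical
#' groups give F = 0; groups differing only in location leave the test
#' null-calibrated.
#'
#' @inheritParams pairwise_posthoc
#' @return Object of class `cr_permdisp` with fields `F`, `df`, `p_perm`,
#'   `distances`.
#' @export
permdisp <- function(data, response, factor_name,
                     transform = c("log10", "fourth_root", "none"),
                     log_floor = 1e-4, n_perm = 9999, seed = 1L) {
  transform <- match.arg(transform)
  df <- as.data.frame(data)
  g <- factor(df[[factor_name]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations", call. = FALSE)
  y <- transform_responses(as.matrix(df[response]), transform, log_floor)
  z <- numeric(nrow(y))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    med <- spatial_median(y[idx, , drop = FALSE])
    z[idx] <- sqrt(rowSums(sweep(y[idx, , drop = FALSE], 2, med)^2))
  }
  f_of <- function(zz) {
    msb <- sum(tapply(zz, g, function(v) length(v) * (mean(v) - mean(zz))^2)) /
      (nlevels(g) - 1)
    msw <- sum(tapply(zz, g, function(v) sum((v - mean(v))^2))) /
      (length(zz) - nlevels(g))
    if (msw < 1e-300) return(if (msb < 1e-300) 0 else Inf)
    msb / msw
  }
  Fobs <- f_of(z)
  set.seed(seed)
  Fperm <- replicate(n_perm, f_of(z[sample.int(length(z))]))
  p <- (sum(Fperm >= Fobs) + 1) / (n_perm + 1)
  structure(list(F = Fobs, df = c(nlevels(g) - 1, length(z) - nlevels(g)),
                 p_perm = p, distances = tibble::tibble(group = g, distance = z),
                 n_permutations = n_perm, seed = seed),
            class = "cr_permdisp")
}

# geometric (spatial) median by Weiszfeld iteration; marginal median start
spatial_median <- function(Y, tol = 1e-10, max_iter = 200) {
  if (ncol(Y) == 1) return(median(Y[, 1]))
  m <- apply(Y, 2, median)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(Y, 2, m)^2))
    if (any(d < 1e-12)) return(m)
    w <- 1 / d
    m2 <- colSums(Y * w) / sum(w)
    if (sqrt(sum((m2 - m)^2)) < tol) return(m2)
    m <- m2
  }
  m
}

#' @export
print.cr_permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.4g on df (%d, %d), permutation p = %.4g (%d permutations)\n",
              x$F, x$df[1], x$df[2], x$p_perm, x$n_permutations))
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.cr_permdisp <- function(x, ...) {
  tibble::tibble(statistic = x$F, df = x$df[1], df_residual = x$df[2],
                 p_perm = x$p_perm, n_permutations = x$n_permutations)
}

#' @rdname tidiers
#' @export
tidy.cr_permdisp <- function(x, ...) x$distances

#' Bland-Altman agreement summary
#'
#' Agreement between an alternative measurement method and a reference
#' (gold standard) on paired cases: per-case differences (alternative minus
#' reference), summarised by their median, interquartile range and a 95%
#' confidence interval for the median from binomial order statistics.
#' Quantiles use the mean-of-order-statistics rule (type 6), the convention
#' of mainstream clinical statistics software. A rank correlation of
#' difference against pair mean is reported (not tested) as a trend flag.
#'
#' @param reference_values,alternative_values Equal-length numeric vectors,
#'   paired by case.
#' @param labels Optional case labels.
#' @return Object of class `cr_bland_altman`.
#' @export
bland_altman <- function(reference_values, alternative_values, labels = NULL) {
  stopifnot(length(reference_values) == length(alternative_values),
            length(reference_values) >= 2)
  if (is.null(labels)) labels <- as.character(seq_along(reference_values))
  d <- alternative_values - reference_values
  mid <- (alternative_values + reference_values) / 2
  n <- length(d)
  s <- sort(d)
  l <- qbinom(0.025, n, 0.5)
  l <- max(l, 1)
  u <- min(n + 1 - l, n)
  iqr <- quantile(d, c(0.25, 0.75), type = 6, names = FALSE)
  trend <- if (sd(d) < 1e-300 || sd(mid) < 1e-300) 0 else
    cor(mid, d, method = "spearman")
  structure(list(
    cases = tibble::tibble(label = labels, reference = reference_values,
                           alternative = alternative_values,
                           mean = mid, difference = d),
    median = median(d), iqr = iqr, ci95_median = c(s[l], s[u]),
    trend_rank_correlation = trend, n = n
  ), class = "cr_bland_altman")
}

#' @export
print.cr_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: n = %d, median difference %.3f (IQR %.3f, %.3f; 95%% CI of median %.3f, %.3f)\n",
              x$n, x$median, x$iqr[1], x$iqr[2], x$ci95_median[1], x$ci95_median[2]))
  cat(sprintf("  rank correlation of difference vs mean: %.3f\n",
              x$trend_rank_correlation))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.cr_bland_altman <- function(x, ...) x$cases

#' @rdname tidiers
#' @export
glance.cr_bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, median = x$median, iqr_low = x$iqr[1],
                 iqr_high = x$iqr[2], ci95_low = x$ci95_median[1],
                 ci95_high = x$ci95_median[2],
                 trend_rank_correlation = x$trend_rank_correlation)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
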