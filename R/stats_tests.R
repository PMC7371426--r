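#' Descriptive summary: mean +/- SEM and quartiles
#'
#' SEM uses the sample SD (n - 1 denominator); percentiles use linear
#' interpolation (type-7 convention).
#'
#' @param values numeric vector, n >= 1.
#' @param units unit label carried through to reports.
#' @return list of class `pf_summary`: `n`, `mean`, `sem`, `q1`, `median`,
#'   `q3`, `units`.
#' @export
summarize_group <- function(values, units = "") {
  assert_that(length(values) >= 1, "pf_empty_input", "no values")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sem <- if (length(values) > 1) stats::sd(values) / sqrt(length(values))
         else 0
  structure(list(n = length(values), mean = mean(values), sem = sem,
                 q1 = qs[1], median = qs[2], q3 = qs[3], units = units),
            class = "pf_summary")
}

pf_test <- function(test, statistic, p_value, comparison = NA_character_,
                    family = NA_character_, ...) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 comparison = comparison, family = family, ...),
            class = "pf_test")
}

#' @export
print.pf_test <- function(x, ...) {
  cat(sprintf("<pf_test %s> statistic = %.4g, p = %.4g%s\n", x$test,
              x$statistic, x$p_value,
              if (is.na(x$comparison)) "" else paste0(" (", x$comparison, ")")))
  invisible(x)
}

# Exact two-sided Mann-Whitney p by enumeration over which of the N ranks
# belong to the first sample. Feasible for small samples only.
mw_exact_p <- function(a, b, U_obs) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  combos <- utils::combn(N, n1)
  U_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # two-sided by symmetry of the null distribution around n1 n2 / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U is computed from rank sums with midranks for ties. The two-sided
#' p-value is exact (full enumeration of rank assignments) when
#' `min(n1, n2) <= exact_max` and enumeration is feasible, otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. All-tied data are handled (p = 1), not rejected.
#'
#' @param a,b numeric samples.
#' @param exact_max largest `min(n1, n2)` for which enumeration is tried.
#' @return `pf_test` with fields `U` (min of U1, U2), `U1`, `U2`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  assert_that(length(a) >= 1 && length(b) >= 1, "pf_empty_input",
              "both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  ties <- any(duplicated(c(a, b)))
  if (min(n1, n2) <= exact_max && choose(N, n1) <= 5e5) {
    p <- mw_exact_p(a, b, U1)
    method <- "exact_enumeration"
  } else {
    tie_tab <- table(c(a, b))
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  pf_test("mann_whitney", statistic = min(U1, U2), p_value = p,
          U = min(U1, U2), U1 = U1, U2 = U2, method = method,
          ties = ties)
}

#' Two-sample unpaired comparison
#'
#' Nonparametric route ([mann_whitney()]; the default for firing-probability
#' data) or a two-sided unpaired t-test (pooled variance by default, Welch
#' optional).
#'
#' @param a,b numeric samples.
#' @param mode `"mann_whitney"` or `"t_test"`.
#' @param var_equal pooled-variance t (conventional unpaired t-test) when
#'   TRUE, Welch when FALSE.
#' @return a `pf_test`.
#' @export
compare_two_unpaired <- function(a, b, mode = c("mann_whitney", "t_test"),
                                 var_equal = TRUE) {
  mode <- match.arg(mode)
  if (mode == "mann_whitney") return(mann_whitney(a, b))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  pf_test("t_test", statistic = unname(tt$statistic),
          p_value = tt$p.value, df = unname(tt$parameter))
}

kruskal_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie_tab <- table(x)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  H / C
}

dunn_pairs <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  labs <- names(groups) %||% as.character(seq_along(groups))
  out <- vector("list", m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i1] + 1 / n[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    out[[j]] <- pf_test("dunn", statistic = unname(z),
                        p_value = min(1, p_raw * m),
                        comparison = paste(labs[i1], "vs", labs[i2]),
                        family = "dunn_bonferroni",
                        p_unadjusted = p_raw)
  }
  out
}

oneway_anova <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  k <- length(groups)
  gm <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ss_b <- sum(n * (means - gm)^2)
  ss_w <- sum(vapply(groups, function(gr) sum((gr - mean(gr))^2),
                     numeric(1)))
  mse <- ss_w / (N - k)
  Fv <- (ss_b / (k - 1)) / mse
  list(F = Fv, df1 = k - 1, df2 = N - k, mse = mse, means = means, n = n,
       p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Multi-group comparison with post-hoc tests
#'
#' Omnibus test plus pairwise post-hoc p-values adjusted by the named
#' procedure: Kruskal-Wallis (tie-corrected H, chi-squared p) with Dunn's
#' Bonferroni-adjusted z tests; one-way ANOVA with Tukey HSD (studentized
#' range) or with pairwise t tests under Sidak adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, all nonempty).
#' @param mode `"kruskal_dunn"`, `"anova_tukey"` or `"anova_sidak"`.
#' @return list: `omnibus` (a `pf_test`), `pairwise` (list of `pf_test`).
#' @export
compare_many <- function(groups, mode = c("kruskal_dunn", "anova_tukey",
                                          "anova_sidak")) {
  mode <- match.arg(mode)
  assert_that(length(groups) >= 2, "pf_empty_input", "need >= 2 groups")
  assert_that(all(lengths(groups) >= 1), "pf_empty_input",
              "all groups must be nonempty")
  labs <- names(groups) %||% as.character(seq_along(groups))
  names(groups) <- labs
  if (mode == "kruskal_dunn") {
    H <- kruskal_H(groups)
    omnibus <- pf_test("kruskal_wallis", statistic = H,
                       p_value = stats::pchisq(H, length(groups) - 1,
                                               lower.tail = FALSE),
                       df = length(groups) - 1)
    return(list(omnibus = omnibus, pairwise = dunn_pairs(groups)))
  }
  av <- oneway_anova(groups)
  omnibus <- pf_test("anova_F", statistic = av$F, p_value = av$p,
                     df1 = av$df1, df2 = av$df2)
  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  pairwise <- vector("list", m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- av$means[i1] - av$means[i2]
    se <- sqrt(av$mse * (1 / av$n[i1] + 1 / av$n[i2]))
    cmp <- paste(labs[i1], "vs", labs[i2])
    if (mode == "anova_tukey") {
      q <- abs(diff) / (se / sqrt(2))
      p <- stats::ptukey(q, length(groups), av$df2, lower.tail = FALSE)
      pairwise[[j]] <- pf_test("tukey", statistic = q, p_value = p,
                               comparison = cmp, family = "tukey_hsd")
    } else {
      tv <- diff / se
      p_raw <- 2 * stats::pt(-abs(tv), av$df2)
      pairwise[[j]] <- pf_test("sidak_t", statistic = tv,
                               p_value = 1 - (1 - p_raw)^m,
                               comparison = cmp, family = "sidak",
                               p_unadjusted = p_raw)
    }
  }
  list(omnibus = omnibus, pairwise = pairwise)
}

gg_epsilon <- function(S) {
  T_ <- nrow(S)
  C <- qr.Q(qr(stats::contr.helmert(T_)))  # T x (T-1), orthonormal columns
  D <- t(C) %*% S %*% C
  (sum(diag(D)))^2 / ((T_ - 1) * sum(D^2))
}

#' Repeated-measures (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' One balanced within-subject factor (every subject measured at the same
#' time points / sessions) and an optional between-subject grouping factor.
#' Sums of squares follow the classical split-plot decomposition; the
#' within-factor and interaction tests are reported both uncorrected and
#' with Greenhouse-Geisser sphericity-corrected degrees of freedom (epsilon
#' from the pooled within-group covariance of the subject-by-time matrix).
#'
#' @param values numeric matrix, subjects x time points (no missing cells).
#' @param between optional vector of group labels, one per subject.
#' @return list of `pf_test`: `within` (time), `interaction` (when grouped),
#'   `between` (when grouped); each within-type test carries `epsilon`,
#'   `df1_gg`, `df2_gg`, `p_gg`.
#' @export
repeated_measures_anova <- function(values, between = NULL) {
  X <- as.matrix(values)
  assert_that(all(is.finite(X)), "pf_missing_cells",
              "design must be complete (no missing cells)")
  N <- nrow(X); T_ <- ncol(X)
  assert_that(N >= 2 && T_ >= 2, "pf_empty_input",
              "need >= 2 subjects and >= 2 time points")
  g <- if (is.null(between)) factor(rep("all", N)) else factor(between)
  k <- nlevels(g)
  M <- mean(X)
  Ms <- rowMeans(X)
  Mt <- colMeans(X)
  ss_total <- sum((X - M)^2)
  ss_subj <- T_ * sum((Ms - M)^2)
  Mg <- as.vector(tapply(Ms, g, mean))  # in levels(g) order
  ng <- as.vector(table(g))
  ss_group <- T_ * sum(ng * (Mg - M)^2)
  ss_err_b <- ss_subj - ss_group
  ss_time <- N * sum((Mt - M)^2)
  cell <- do.call(rbind, lapply(levels(g), function(lv)
    colMeans(X[g == lv, , drop = FALSE])))
  ss_gxt <- sum(ng * (cell - Mg - matrix(Mt, k, T_, byrow = TRUE) + M)^2)
  ss_res <- ss_total - ss_subj - ss_time - ss_gxt
  df_res <- (N - k) * (T_ - 1)
  ms_res <- ss_res / df_res
  # pooled within-group covariance across time points
  Xc <- X
  for (lv in levels(g))
    Xc[g == lv, ] <- scale(X[g == lv, , drop = FALSE], scale = FALSE)
  S <- crossprod(Xc) / (N - k)
  eps <- gg_epsilon(S)
  within_test <- function(name, ss, df1) {
    Fv <- (ss / df1) / ms_res
    pf_test(name, statistic = Fv,
            p_value = stats::pf(Fv, df1, df_res, lower.tail = FALSE),
            df1 = df1, df2 = df_res, epsilon = eps,
            df1_gg = eps * df1, df2_gg = eps * df_res,
            p_gg = stats::pf(Fv, eps * df1, eps * df_res,
                             lower.tail = FALSE))
  }
  out <- list(within = within_test("rm_anova_time", ss_time, T_ - 1))
  if (k > 1) {
    out$interaction <- within_test("rm_anova_group_x_time", ss_gxt,
                                   (k - 1) * (T_ - 1))
    Fb <- (ss_group / (k - 1)) / (ss_err_b / (N - k))
    out$between <- pf_test("rm_anova_group", statistic = Fb,
                           p_value = stats::pf(Fb, k - 1, N - k,
                                               lower.tail = FALSE),
                           df1 = k - 1, df2 = N - k)
  }
  out
}

#' Pearson correlation with two-sided p from the t transform
#' @param x,y numeric vectors, n >= 3, finite, nonzero variance.
#' @return `pf_test` with fields `r`, `df`.
#' @export
pearson_cor <- function(x, y) {
  assert_that(length(x) == length(y), "pf_length_mismatch",
              "x and y lengths differ")
  assert_that(length(x) >= 3 && all(is.finite(x)) && all(is.finite(y)),
              "pf_empty_input", "need >= 3 finite pairs")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0, "pf_zero_variance",
              "zero variance in x or y")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tv), n - 2)
  }
  pf_test("pearson", statistic = r, p_value = p, r = r, df = n - 2)
}
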