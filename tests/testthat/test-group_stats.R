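test_that("summaries match hand values and the sort-based oracle", {
  s1 <- summarize_group(c(1, 1, 1))
  expect_equal(s1$mean, 1)
  expect_equal(s1$sem, 0)
  s2 <- summarize_group(c(0, 1))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$sem, 0.5)
  set.seed(1)
  for (i in 1:15) {
    x <- rnorm(sample(3:40, 1))
    s <- summarize_group(x)
    expect_equal(s$sem, sd(x) / sqrt(length(x)))
    expect_equal(s$q1, bf_percentile(x, 0.25))
    expect_equal(s$q3, bf_percentile(x, 0.75))
    expect_true(s$q1 <= s$median && s$median <= s$q3)
  }
})

test_that("Mann-Whitney: U and exact p match enumeration and wilcox.test", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)          # 2/20 arrangements as extreme

  # identical samples: U at its mean, p in the 1 region
  ri <- mann_whitney(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(ri$U1, ri$U2)
  expect_gte(ri$p_value, 0.99)

  # permutation invariance within groups
  set.seed(2)
  a <- rnorm(6); b <- rnorm(7)
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(sample(a), sample(b))$p_value)

  # oracle: wilcox.test exact p for tie-free small samples
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    mine <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(min(mine$U1, mine$U2),
                 min(ref$statistic, n1 * n2 - ref$statistic),
                 ignore_attr = TRUE)
  }

  # large-sample route against wilcox.test normal approximation
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(25); b <- rnorm(30, 0.3)
    mine <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }

  # all-tied data: documented handling, not an exception
  expect_equal(mann_whitney(rep(1, 10), rep(1, 12))$p_value, 1)
})

test_that("Kruskal-Wallis H matches kruskal.test; Dunn p adjusted upward", {
  set.seed(4)
  for (i in 1:15) {
    groups <- lapply(1:3, function(j) round(rnorm(sample(4:9, 1), j / 3), 1))
    names(groups) <- c("g1", "g2", "g3")
    res <- compare_many(groups, "kruskal_dunn")
    ref <- stats::kruskal.test(groups)
    expect_equal(res$omnibus$statistic, unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(res$omnibus$p_value, ref$p.value, tolerance = 1e-12)
    for (pw in res$pairwise)
      expect_gte(pw$p_value, pw$p_unadjusted - 1e-12)
  }

  # identical groups: omnibus p ~ 1, no post-hoc significance
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  rs <- compare_many(same, "kruskal_dunn")
  expect_gte(rs$omnibus$p_value, 0.99)
  expect_true(all(vapply(rs$pairwise, function(p) p$p_value, numeric(1)) > 0.9))

  # one strongly shifted group dominates the pairwise comparisons
  sh <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 100)
  rsh <- compare_many(sh, "kruskal_dunn")
  ps <- vapply(rsh$pairwise, function(p) p$p_value, numeric(1))
  labs <- vapply(rsh$pairwise, function(p) p$comparison, character(1))
  expect_true(all(ps[grepl("c", labs)] < ps[!grepl("c", labs)]))
})

test_that("ANOVA F and Tukey/Sidak post-hocs match base-R oracles", {
  set.seed(5)
  for (i in 1:10) {
    groups <- lapply(1:4, function(j) rnorm(sample(5:9, 1), j / 4))
    names(groups) <- paste0("g", 1:4)
    res <- compare_many(groups, "anova_tukey")
    x <- unlist(groups); f <- factor(rep(names(groups), lengths(groups)))
    av <- stats::aov(x ~ f)
    ref_F <- summary(av)[[1]]$`F value`[1]
    expect_equal(res$omnibus$statistic, ref_F, tolerance = 1e-10)
    tk <- stats::TukeyHSD(av)$f[, "p adj"]
    mine <- vapply(res$pairwise, function(p) p$p_value, numeric(1))
    expect_equal(sort(unname(mine)), sort(unname(tk)), tolerance = 1e-7)

    rs <- compare_many(groups, "anova_sidak")
    for (pw in rs$pairwise) {
      expect_gte(pw$p_value, pw$p_unadjusted - 1e-12)
      expect_equal(pw$p_value, 1 - (1 - pw$p_unadjusted)^6,
                   tolerance = 1e-12)
    }
  }
})

test_that("repeated-measures ANOVA matches aov and corrects sphericity", {
  set.seed(6)
  # oracle: aov split-plot stratified F tests, unbalanced groups
  for (i in 1:5) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1); T_ <- 4
    X <- matrix(rnorm((n1 + n2) * T_), n1 + n2, T_)
    X[seq_len(n1), ] <- X[seq_len(n1), ] + outer(rep(1, n1), seq_len(T_)) / 3
    grp <- rep(c("a", "b"), c(n1, n2))
    res <- repeated_measures_anova(X, grp)
    df <- data.frame(y = as.vector(t(X)),
                     time = factor(rep(seq_len(T_), n1 + n2)),
                     subj = factor(rep(seq_len(n1 + n2), each = T_)),
                     grp = factor(rep(grp, each = T_)))
    av <- summary(stats::aov(y ~ grp * time + Error(subj), data = df))
    within_tab <- av[["Error: Within"]][[1]]
    expect_equal(res$within$statistic, within_tab["time", "F value"],
                 tolerance = 1e-8)
    expect_equal(res$interaction$statistic,
                 within_tab["grp:time", "F value"], tolerance = 1e-8)
    between_tab <- av[["Error: subj"]][[1]]
    expect_equal(res$between$statistic, between_tab["grp", "F value"],
                 tolerance = 1e-8)
    expect_true(res$within$epsilon <= 1 + 1e-9 &&
                  res$within$epsilon >= 1 / (T_ - 1) - 1e-9)
    expect_equal(res$within$df1_gg, res$within$epsilon * (T_ - 1))
  }

  # deterministic linear growth: overwhelming within-factor effect
  Xg <- outer(rep(1, 8), 1:5) + matrix(rnorm(40, 0, 0.05), 8, 5)
  rg <- repeated_measures_anova(Xg)
  expect_lt(rg$within$p_gg, 1e-6)

  # duplicated groups: between-factor F = 0
  Xd <- matrix(rnorm(40), 8, 5)
  rd <- repeated_measures_anova(rbind(Xd, Xd),
                                rep(c("a", "b"), each = 8))
  expect_lt(rd$between$statistic, 1e-20)

  expect_error(repeated_measures_anova(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "pf_missing_cells")
})

test_that("Pearson r matches hand computation and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  r <- pearson_cor(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$p_value, 0)

  # hand-computable 4-point set
  xh <- c(1, 2, 3, 4); yh <- c(2, 1, 4, 3)
  # cov = 1, sd = 1.290994..., r = 1/ (5/3) = 0.6
  r2 <- pearson_cor(xh, yh)
  expect_equal(r2$r, 0.6, tolerance = 1e-12)
  ref <- stats::cor.test(xh, yh)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)),
               class = "pf_zero_variance")
})

test_that("type-I error sits near 0.05 for the implemented tests (small sim)", {
  # reduced replicate counts; the full 10^4-rep calibration runs in the
  # acceptance suite
  set.seed(7)
  n_rep <- 400
  rej <- replicate(n_rep, {
    c(mw = mann_whitney(rnorm(10), rnorm(12))$p_value < 0.05,
      pe = pearson_cor(rnorm(15), rnorm(15))$p_value < 0.05)
  })
  for (nm in rownames(rej)) {
    rate <- mean(rej[nm, ])
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
  }
})

test_that("report bundle is deterministic with one row per cell/group", {
  g <- tiny_cohort(seed = 91, n_cells = 2, with_behavior = TRUE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- build_report(g$cohort, out_dir = d1)
  r2 <- build_report(g$cohort, out_dir = d2)
  expect_equal(nrow(r1$per_cell), 2)
  expect_true(all(c("probability", "mAHP", "adp_peak") %in%
                    names(r1$per_cell)))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))

  # empty cohort: empty tables with headers, no error
  r0 <- build_report(pf_cohort())
  expect_equal(nrow(r0$per_cell), 0)
  expect_true(all(c("cell_id", "group") %in% names(r0$per_cell)))
})
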