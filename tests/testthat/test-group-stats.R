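test_that("one-way ANOVA matches the sum-of-squares formula and t^2 identity", {
  # identical groups: F = 0
  df0 <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                    y = rep(c(1, 2, 3), 3))
  expect_equal(glance(one_way_anova(df0, "y", "g"))$F, 0)
  # two groups: F = t^2 from the pooled t-test
  set.seed(5)
  df2 <- data.frame(g = rep(c("a", "b"), each = 6),
                    y = c(rnorm(6), rnorm(6, 0.8)))
  fit <- one_way_anova(df2, "y", "g")
  tt <- stats::t.test(y ~ g, df2, var.equal = TRUE)
  expect_equal(glance(fit)$F, unname(tt$statistic^2))
  expect_equal(glance(fit)$p, tt$p.value)
  # fixed dataset against the brute-force decomposition
  df3 <- data.frame(g = rep(c("a", "b", "c"), times = c(4, 5, 3)),
                    y = c(5.1, 4.8, 5.6, 5.0, 6.2, 6.0, 5.8, 6.5, 6.1,
                          4.2, 4.0, 4.6))
  gm <- mean(df3$y)
  means <- tapply(df3$y, df3$g, mean)
  ns <- table(df3$g)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((df3$y - means[df3$g])^2)
  F_hand <- (ss_b / 2) / (ss_w / 9)
  expect_equal(glance(one_way_anova(df3, "y", "g"))$F, F_hand)
})

test_that("Tukey HSD returns all pairs with valid adjusted p-values", {
  set.seed(6)
  df <- data.frame(g = rep(c("CT", "4Hz", "10Hz", "40Hz"), each = 5),
                   y = c(rnorm(5, 533, 50), rnorm(5, 921, 50),
                         rnorm(5, 1120, 50), rnorm(5, 829, 50)))
  tk <- tidy(one_way_anova(df, "y", "g"))
  expect_equal(nrow(tk), choose(4, 2))
  expect_true(all(tk$adj_p >= 0 & tk$adj_p <= 1))
  # the largest contrast (CT vs 10Hz) should be significant at these n
  big <- tk[grepl("CT", tk$contrast) & grepl("10Hz", tk$contrast), ]
  expect_lt(min(big$adj_p), 0.05)
})

test_that("ANOVA rejects degenerate inputs", {
  expect_error(one_way_anova(data.frame(g = c("a", "a", "b"), y = 1:3),
                             "y", "g"), "n >= 2")
  expect_error(one_way_anova(data.frame(g = rep(c("a", "b"), each = 3),
                                        y = rep(5, 6)), "y", "g"),
               "degenerate|variance")
})

test_that("BH step-up reproduces the hand-worked example and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), adj[perm])
})

test_that("volcano table handles planted, null and degenerate compounds", {
  # zero-variance separation: log2FC = 1, p collapses to the smallest double
  m <- metabolite_matrix(
    cbind(a = c(10, 10, 20, 20), b = c(5, 6, 5, 6)),
    sample_groups = c("CT", "CT", "ES", "ES"))
  v <- volcano_table(m, "CT", "ES")
  expect_equal(v$log2_fold_change[v$compound_id == "a"], 1)
  expect_equal(v$raw_p[v$compound_id == "a"], .Machine$double.xmin)
  expect_equal(v$log2_fold_change[v$compound_id == "b"], 0)
  expect_equal(v$raw_p[v$compound_id == "b"], 1)
  expect_true(all(v$fdr_adjusted_p >= v$raw_p))
})

test_that("volcano t-test agrees with stats::t.test per compound", {
  mat <- generate_metabolome(n_per_group = 5, compounds = 12, effects = NULL,
                             seed = 17, groups = c("CT", "10Hz"))
  v <- volcano_table(mat, "CT", "10Hz")
  for (j in c(1, 5, 12)) {
    ref <- stats::t.test(mat$intensities[mat$sample_groups == "10Hz", j],
                         mat$intensities[mat$sample_groups == "CT", j],
                         var.equal = TRUE)
    expect_equal(v$raw_p[j], ref$p.value)
    expect_equal(v$t[j], unname(ref$statistic))
  }
  vw <- volcano_table(mat, "CT", "10Hz", var_equal = FALSE)
  refw <- stats::t.test(mat$intensities[mat$sample_groups == "10Hz", 3],
                        mat$intensities[mat$sample_groups == "CT", 3])
  expect_equal(vw$raw_p[3], refw$p.value)
})

test_that("planted two-fold compounds are detected reproducibly", {
  detected <- vapply(1:8, function(s) {
    folds <- data.frame(compound = paste0("hit_", 1:5), group = "ES",
                        fold = 2)
    mat <- generate_metabolome(n_per_group = 5, compounds = 100,
                               effects = folds, sigma_log = 0.2,
                               seed = 400 + s, groups = c("CT", "ES"))
    v <- volcano_table(mat, "CT", "ES")
    sum(v$fdr_adjusted_p < 0.05 & startsWith(v$compound_id, "hit_"))
  }, numeric(1))
  expect_gt(mean(detected), 3)          # most planted hits found
  expect_lt(stats::sd(detected), 2.5)   # stable across seeds
})

test_that("compound identification applies all three acceptance rules strictly", {
  rec <- compound_record("kynurenic acid", 189.04259, 300)
  near <- feature_record("kynurenic acid",
                         189.04259 * (1 + 4.9e-6), 329, 91)
  expect_true(match_compound(near, rec)$accepted)
  mass_out <- feature_record("kynurenic acid",
                             189.04259 * (1 + 5.1e-6), 329, 91)
  expect_false(match_compound(mass_out, rec)$accepted)
  rt_out <- feature_record("kynurenic acid", 189.04259, 331, 95)
  expect_false(match_compound(rt_out, rec)$accepted)
  iso_out <- feature_record("kynurenic acid", 189.04259, 300, 90)
  expect_false(match_compound(iso_out, rec)$accepted)   # boundary: > 90 required
  exact <- feature_record("kynurenic acid", 189.04259, 300, 100)
  expect_true(match_compound(exact, rec)$accepted)
})

test_that("group z-score table standardises per compound", {
  mat <- generate_metabolome(n_per_group = 4, compounds = 6, effects = NULL,
                             seed = 23, groups = c("CT", "4Hz", "10Hz"))
  z <- group_zscore_table(mat)
  expect_equal(nrow(z), ncol(mat$intensities))
  zm <- as.matrix(z[, -1])
  expect_true(all(abs(rowMeans(zm)) < 1e-12))
  expect_equal(unname(apply(zm, 1, stats::sd)), rep(1, nrow(z)))
})
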