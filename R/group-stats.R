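#' One-way ANOVA with Tukey HSD post hoc test
#'
#' Classical between/within variance decomposition across groups followed by
#' Tukey's honestly-significant-difference test on all pairwise contrasts
#' (studentized-range distribution), the standard analysis for structural
#' and functional index comparisons across stimulation groups.
#'
#' @param data A data frame with one observation per row.
#' @param value Column name (string) of the response.
#' @param group Column name (string) of the group factor.
#' @return A `capillary_anova` object; use [tidy()] for the Tukey pairs and
#'   [glance()] for the F test.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 4),
#'                  y = c(1, 2, 3, 4, 3, 4, 5, 6))
#' glance(one_way_anova(df, "y", "g"))
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  data <- as.data.frame(data)
  if (!all(c(value, group) %in% names(data))) {
    abort("`value` and `group` must name columns of `data`")
  }
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("every group needs n >= 2")
  if (var(y) == 0) abort("total variance is zero: ANOVA is degenerate")
  within_var <- sum(tapply(y, g, var) * (table(g) - 1))
  if (within_var == 0 && length(unique(tapply(y, g, mean))) == 1) {
    abort("zero within-group variance with equal means: degenerate ANOVA")
  }
  fit <- aov(y ~ g, data = data.frame(y = y, g = g))
  s <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  structure(
    list(
      F = s[["F value"]][1L],
      df = c(between = s[["Df"]][1L], within = s[["Df"]][2L]),
      p = s[["Pr(>F)"]][1L],
      tukey = tibble(
        contrast = rownames(tk),
        difference = tk[, "diff"],
        conf_low = tk[, "lwr"],
        conf_high = tk[, "upr"],
        adj_p = tk[, "p adj"]
      ),
      group_means = tibble(group = levels(g),
                           mean = as.numeric(tapply(y, g, mean)),
                           n = as.integer(table(g)))
    ),
    class = "capillary_anova"
  )
}

#' @export
print.capillary_anova <- function(x, ...) {
  cat(sprintf("<capillary_anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  invisible(x)
}

#' @describeIn one_way_anova Tukey HSD pairwise table (one row per
#'   contrast: difference, confidence limits, adjusted p).
#' @param x A `capillary_anova`.
#' @param ... Unused.
#' @export
tidy.capillary_anova <- function(x, ...) x$tukey

#' @describeIn one_way_anova One-row F-test summary.
#' @export
glance.capillary_anova <- function(x, ...) {
  tibble(F = x$F, df_between = x$df[[1L]], df_within = x$df[[2L]], p = x$p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: sort the m p-values ascending,
#' set `adj_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and return in
#' the original input order. Validates the input range, then delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must be numeric in [0, 1] with no missing values")
  }
  p.adjust(p_values, method = "BH")
}

# Vectorised equal-variance two-sample t-test over the columns of two
# matrices (samples x compounds). Returns list(t, df, p). Zero pooled
# variance with distinct means gives p = 0 (reported as the smallest
# representable double by the caller).
rowwise_t_test <- function(a, b, var_equal = TRUE) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, var); vb <- apply(b, 2L, var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- unname((mb - ma) / se)
  p <- 2 * pt(-abs(t), unname(df))
  # exact group equality -> t = 0/0; no evidence against the null
  p[se == 0 & mb == ma] <- 1
  # distinct means with zero variance -> infinitely strong evidence
  p[se == 0 & mb != ma] <- .Machine$double.xmin
  t[se == 0] <- ifelse(mb[se == 0] == ma[se == 0], 0,
                       sign(mb[se == 0] - ma[se == 0]) * Inf)
  list(t = t, df = df, p = p)
}

#' Volcano table: fold change, t-test and FDR per compound
#'
#' For every compound, the log2 fold change of raw-intensity group means
#' (`b` over `a`), a two-sample Student's t-test (equal-variance pooled by
#' default; Welch behind `var_equal = FALSE`), and Benjamini-Hochberg FDR
#' adjustment across compounds. Compounds with a zero group-`a` mean get an
#' undefined fold change and are flagged, not dropped.
#'
#' @param mat A [metabolite_matrix()].
#' @param group_a,group_b Group labels to contrast (`a` is the reference,
#'   e.g. the unstimulated control).
#' @param var_equal Use the pooled-variance Student's t-test (default) or
#'   Welch's.
#' @return A tibble with one row per compound: `compound_id`,
#'   `mean_a`, `mean_b`, `log2_fold_change`, `t`, `raw_p`,
#'   `fdr_adjusted_p`, `fold_change_defined`.
#' @export
volcano_table <- function(mat, group_a, group_b, var_equal = TRUE) {
  stopifnot(inherits(mat, "metabolite_matrix"))
  ia <- mat$sample_groups == group_a
  ib <- mat$sample_groups == group_b
  if (sum(ia) < 2 || sum(ib) < 2) {
    abort("both groups must be present with n >= 2")
  }
  a <- mat$intensities[ia, , drop = FALSE]
  b <- mat$intensities[ib, , drop = FALSE]
  ma <- colMeans(a); mb <- colMeans(b)
  defined <- ma > 0 & mb > 0
  l2fc <- ifelse(defined, log2(mb / ma), NA_real_)
  tt <- rowwise_t_test(a, b, var_equal = var_equal)
  tibble(
    compound_id = colnames(mat$intensities),
    mean_a = unname(ma), mean_b = unname(mb),
    log2_fold_change = unname(l2fc),
    t = tt$t, raw_p = tt$p,
    fdr_adjusted_p = bh_fdr(tt$p),
    fold_change_defined = unname(defined)
  )
}

#' Compound-identification acceptance filter
#'
#' Accepts a measured feature as an identification of a library compound
#' only when all of: mass accuracy within `mass_ppm` parts per million of
#' the theoretical mass, retention time within `rt_tol_s` seconds of the
#' authenticated standard, and isotope-pattern match above `isotope_min`
#' percent. Defaults: < 5 ppm, < 30 s, > 90% (all strict inequalities).
#'
#' @param features Tibble of [feature_record()] rows (`measured_mass`,
#'   `retention_time`, `isotope_match`).
#' @param records Tibble of [compound_record()] rows (`theoretical_mass`,
#'   `retention_time`), matched row-by-row to `features` (recycled if one
#'   row).
#' @param mass_ppm,rt_tol_s,isotope_min Acceptance tolerances.
#' @return Tibble: the feature/record pairs with `mass_ppm_diff`,
#'   `rt_diff_s`, `isotope_match` and logical `accepted`.
#' @export
match_compound <- function(features, records, mass_ppm = 5, rt_tol_s = 30,
                           isotope_min = 90) {
  features <- as_tibble(features)
  records <- as_tibble(records)
  if (nrow(records) == 1L && nrow(features) > 1L) {
    records <- records[rep(1L, nrow(features)), ]
  }
  if (nrow(records) != nrow(features)) {
    abort("`features` and `records` must align row-by-row")
  }
  ppm <- 1e6 * abs(features$measured_mass - records$theoretical_mass) /
    records$theoretical_mass
  drt <- abs(features$retention_time - records$retention_time)
  tibble(
    compound_id = records$compound_id %||% features$compound_id,
    mass_ppm_diff = ppm,
    rt_diff_s = drt,
    isotope_match = features$isotope_match,
    accepted = ppm < mass_ppm & drt < rt_tol_s &
      features$isotope_match > isotope_min
  )
}

#' Group-mean z-score table
#'
#' Per-compound group means standardised across groups (mean 0, SD 1 within
#' each compound) — a plain-text stand-in for heatmap presentations of
#' significantly changed metabolites.
#'
#' @param mat A [metabolite_matrix()].
#' @return Tibble: `compound_id`, one column per group with the z-scored
#'   group mean.
#' @export
group_zscore_table <- function(mat) {
  stopifnot(inherits(mat, "metabolite_matrix"))
  groups <- unique(mat$sample_groups)
  gm <- vapply(groups, function(g) {
    colMeans(mat$intensities[mat$sample_groups == g, , drop = FALSE])
  }, numeric(ncol(mat$intensities)))
  z <- t(scale(t(gm)))
  dplyr::bind_cols(tibble(compound_id = colnames(mat$intensities)),
                   as_tibble(z))
}
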