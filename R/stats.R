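paired_diffs <- function(data, x, y) {
  xv <- pull(data, {{ x }})
  yv <- pull(data, {{ y }})
  if (length(xv) != length(yv)) abort("paired samples must have equal length")
  if (anyNA(xv) || anyNA(yv)) abort("paired samples must be complete (no missing pairs)")
  if (length(xv) < 2) abort("at least 2 pairs are required")
  xv - yv
}

# one-sample t machinery shared by paired_t / one_sample_t, with the
# degenerate zero-variance conventions: zero mean -> t = 0, p = 1;
# nonzero mean -> p -> 0 limit (flagged), so cohort loops never abort.
t_on_values <- function(v, mu0 = 0) {
  n <- length(v)
  m <- mean(v) - mu0
  s <- sd(v)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = n - 1))
    warn("zero variance with nonzero mean: reporting the p -> 0 limit")
    return(list(t = sign(m) * Inf, p = 0, df = n - 1))
  }
  tt <- m / (s / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), n - 1), df = n - 1)
}

#' Paired t-test
#'
#' Classical two-sided paired t-test on the differences between two methods
#' measured on the same subjects.
#'
#' @param data a data frame with one row per subject.
#' @param x,y columns holding the two paired measurements (tidy-eval).
#' @return One-row tibble: `n`, `mean_diff`, `t`, `df`, `p`.
#' @examples
#' paired_t(data.frame(a = c(2, 4, 6, 8), b = c(1, 2, 3, 4)), a, b)
#' @export
paired_t <- function(data, x, y) {
  d <- paired_diffs(data, {{ x }}, {{ y }})
  r <- t_on_values(d)
  tibble(n = length(d), mean_diff = mean(d), t = r$t, df = r$df, p = r$p)
}

#' One-sample t-test
#'
#' Two-sided one-sample t-test of a column against a reference value; the
#' default `mu0 = 0.9` tests cycle-averaged mixing against the uniform-mixing
#' threshold.
#'
#' @param data a data frame.
#' @param x column of values (tidy-eval).
#' @param mu0 null value (default 0.9).
#' @return One-row tibble: `n`, `mean`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(data, x, mu0 = 0.9) {
  v <- pull(data, {{ x }})
  if (length(v) < 2) abort("at least 2 values are required")
  r <- t_on_values(v, mu0)
  tibble(n = length(v), mean = mean(v), t = r$t, df = r$df, p = r$p)
}

#' Bland-Altman agreement
#'
#' Mean inter-method difference with the limits of agreement, defined as the
#' mean difference +/- 1.96 sample standard deviations of the differences.
#'
#' @inheritParams paired_t
#' @return One-row tibble: `n`, `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`.
#' @examples
#' bland_altman(data.frame(a = c(3, 0, 5), b = c(1, 4, 3)), a, b)
#' @export
bland_altman <- function(data, x, y) {
  d <- paired_diffs(data, {{ x }}, {{ y }})
  m <- mean(d); s <- sd(d)
  tibble(n = length(d), mean_diff = m, sd_diff = s,
         loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}

#' Intraclass correlation between two methods
#'
#' Single-measure ICC from the two-way mean-squares decomposition. The
#' default `"agreement"` form is ICC(A,1) (two-way mixed effects, absolute
#' agreement), the standard choice for method comparison with fixed methods;
#' `"consistency"` gives ICC(C,1).
#'
#' @inheritParams paired_t
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return One-row tibble: `n`, `k`, `icc`, `type`.
#' @export
icc_agreement <- function(data, x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  xv <- pull(data, {{ x }}); yv <- pull(data, {{ y }})
  if (length(xv) < 3) abort("ICC requires at least 3 subjects")
  mat <- cbind(xv, yv)
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((mat - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  denom <- if (type == "agreement") {
    msr + (k - 1) * mse + k / n * (msc - mse)
  } else {
    msr + (k - 1) * mse
  }
  icc <- if (denom <= 0) {
    warn("zero between-subject variance: ICC undefined")
    NA_real_
  } else {
    (msr - mse) / denom
  }
  tibble(n = n, k = k, icc = icc, type = type)
}

#' Mean absolute inter-method difference
#'
#' Mean of the absolute differences between two methods, with a
#' +/- 1.96 standard-error-of-the-mean interval (SEM of the absolute
#' differences). Quantifies by how much one method over- or underestimates
#' the other regardless of direction; always at least `|mean difference|`.
#'
#' @inheritParams paired_t
#' @return One-row tibble: `n`, `mad`, `sem`, `ci_lower`, `ci_upper`.
#' @export
mean_absolute_difference <- function(data, x, y) {
  d <- abs(paired_diffs(data, {{ x }}, {{ y }}))
  sem <- sd(d) / sqrt(length(d))
  tibble(n = length(d), mad = mean(d), sem = sem,
         ci_lower = mean(d) - 1.96 * sem, ci_upper = mean(d) + 1.96 * sem)
}

#' Repeated-measures one-way ANOVA with Tukey post hoc
#'
#' One-way repeated-measures ANOVA (subject as blocking factor) of a value
#' measured under several conditions per subject — e.g. `M_average` across
#' the four quadrants — followed by Tukey HSD pairwise comparisons of the
#' condition means.
#'
#' @param data a long data frame, one row per subject x condition.
#' @param subject,condition,value columns (tidy-eval); the table must be
#'   complete (every subject under every condition exactly once).
#' @return A list of class `fontan_rm_anova` with `anova` (one-row tibble:
#'   `df1`, `df2`, `F`, `p`) and `tukey` (tibble of pairwise contrasts with
#'   adjusted p-values). `tidy()` returns the Tukey table, `glance()` the
#'   ANOVA row.
#' @export
rm_anova_tukey <- function(data, subject, condition, value) {
  df <- tibble(
    subject = factor(pull(data, {{ subject }})),
    condition = factor(pull(data, {{ condition }})),
    value = pull(data, {{ value }})
  )
  if (anyNA(df$value)) abort("repeated-measures table must be complete")
  cells <- count(df, .data$subject, .data$condition)
  if (any(cells$n != 1) ||
      nrow(cells) != nlevels(df$subject) * nlevels(df$condition)) {
    abort("repeated-measures table must be complete: one value per subject and condition")
  }
  if (nlevels(df$subject) < 3) abort("at least 3 subjects are required")

  fit <- aov(value ~ subject + condition, data = df)
  s <- summary(fit)[[1]]
  ssc <- s["condition", "Sum Sq"]
  sse <- s["Residuals", "Sum Sq"]
  df1 <- s["condition", "Df"]; df2 <- s["Residuals", "Df"]
  if (ssc < 1e-12 * max(1, sum(df$value^2))) {
    # all condition means identical: define F = 0, p = 1 so cohort loops
    # never abort on degenerate (e.g. perfectly mixed) data
    warn("no between-condition variation: F set to 0")
    anova_row <- tibble(df1 = df1, df2 = df2, F = 0, p = 1)
    prs <- utils::combn(levels(df$condition), 2)
    tukey <- tibble(contrast = paste(prs[2, ], prs[1, ], sep = "-"),
                    diff = 0, lwr = 0, upr = 0, p_adj = 1)
  } else {
    anova_row <- tibble(df1 = df1, df2 = df2,
                        F = s["condition", "F value"],
                        p = s["condition", "Pr(>F)"])
    tk <- TukeyHSD(fit, which = "condition")$condition
    tukey <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"])
  }
  structure(list(anova = anova_row, tukey = tukey), class = "fontan_rm_anova")
}

#' @export
print.fontan_rm_anova <- function(x, ...) {
  cat(sprintf("<fontan_rm_anova> F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  print(as.data.frame(x$tukey), row.names = FALSE)
  invisible(x)
}

#' @rdname rm_anova_tukey
#' @param x a `fontan_rm_anova` object.
#' @param ... unused.
#' @export
tidy.fontan_rm_anova <- function(x, ...) x$tukey

#' @rdname rm_anova_tukey
#' @export
glance.fontan_rm_anova <- function(x, ...) x$anova

#' Pearson correlation
#'
#' Pearson correlation between two columns with the two-sided t-based
#' p-value.
#'
#' @inheritParams paired_t
#' @return One-row tibble: `n`, `r`, `p`.
#' @export
pearson_r <- function(data, x, y) {
  xv <- pull(data, {{ x }}); yv <- pull(data, {{ y }})
  if (length(xv) < 3) abort("at least 3 pairs are required")
  if (sd(xv) == 0 || sd(yv) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(n = length(xv), r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(n = length(xv), r = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise agreement report across HFD methods
#'
#' Builds the full method-comparison report for a cohort: for every pair of
#' methods, the paired-t p-value, the Bland-Altman mean difference and limits
#' of agreement, the ICC and the mean absolute difference with its
#' +/- 1.96 SEM interval (all differences in percentage points).
#'
#' @param data a long data frame, one row per subject x method.
#' @param subject,method,value columns (tidy-eval).
#' @return A tibble of class `hfd_agreement`, one row per method pair, with
#'   columns `comparison`, `n`, `p_value`, `mean_diff`, `loa_lower`,
#'   `loa_upper`, `icc`, `mad`, `mad_ci_lower`, `mad_ci_upper`. The wide
#'   subject x method table is attached as attribute `wide` (used by
#'   `autoplot()`).
#' @examples
#' hfd <- tidyr::expand_grid(subject = 1:5, method = c("hv", "caudal"))
#' hfd$value <- 50 + stats::rnorm(nrow(hfd))
#' hfd_agreement(hfd, subject, method, value)
#' @export
hfd_agreement <- function(data, subject, method, value) {
  wide <- tibble(
    subject = pull(data, {{ subject }}),
    method = as.character(pull(data, {{ method }})),
    value = pull(data, {{ value }})
  ) %>%
    tidyr::pivot_wider(names_from = "method", values_from = "value")
  methods <- setdiff(names(wide), "subject")
  if (length(methods) < 2) abort("at least 2 methods are required")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    d <- tibble(x = x, y = y)
    tt <- paired_t(d, x, y)
    ba <- bland_altman(d, x, y)
    ic <- icc_agreement(d, x, y)
    md <- mean_absolute_difference(d, x, y)
    tibble(comparison = paste(pr[1], "vs", pr[2]), n = tt$n,
           p_value = tt$p, mean_diff = ba$mean_diff,
           loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
           icc = ic$icc, mad = md$mad,
           mad_ci_lower = md$ci_lower, mad_ci_upper = md$ci_upper)
  })
  structure(rows, class = c("hfd_agreement", class(rows)), wide = wide)
}

#' @rdname hfd_agreement
#' @param x an `hfd_agreement` object.
#' @param ... unused.
#' @export
tidy.hfd_agreement <- function(x, ...) as_tibble(as.data.frame(x))

#' @rdname hfd_agreement
#' @export
glance.hfd_agreement <- function(x, ...) {
  tibble(n_subjects = x$n[1], n_comparisons = nrow(x),
         min_icc = min(x$icc), max_abs_mean_diff = max(abs(x$mean_diff)))
}
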