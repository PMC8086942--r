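test_that("paired t-test matches hand-computed examples", {
  d0 <- tibble::tibble(a = c(1, 2, 3), b = c(1, 2, 3))
  r0 <- paired_t(d0, a, b)
  expect_equal(r0$mean_diff, 0); expect_equal(r0$p, 1)
  # differences (2, -4, 2): zero mean
  r1 <- paired_t(tibble::tibble(a = c(3, 0, 5), b = c(1, 4, 3)), a, b)
  expect_equal(r1$t, 0); expect_equal(r1$p, 1)
  # differences (1, 2, 3, 4): textbook-formula oracle
  r2 <- paired_t(tibble::tibble(a = c(2, 4, 6, 8), b = c(1, 2, 3, 4)), a, b)
  expect_equal(r2$t, 3.873, tolerance = 1e-3)
  expect_equal(r2$p, 0.03047, tolerance = 1e-3)
})

test_that("one-sample t-test against the uniform-mixing threshold", {
  expect_equal(one_sample_t(tibble::tibble(m = rep(0.9, 4)), m)$p, 1)
  expect_warning(
    r <- one_sample_t(tibble::tibble(m = rep(0.8, 4)), m),
    "zero variance")
  expect_equal(r$p, 0)
  r2 <- one_sample_t(tibble::tibble(m = c(0.6, 0.7, 0.8)), m, mu0 = 0.9)
  expect_equal(r2$t, -3.4641, tolerance = 1e-4)
  expect_equal(r2$p, 0.07418, tolerance = 1e-4)
})

test_that("paired t equals the one-sample t on the differences", {
  set.seed(40)
  d <- tibble::tibble(a = rnorm(10, 50, 5), b = rnorm(10, 48, 5))
  r1 <- paired_t(d, a, b)
  r2 <- one_sample_t(tibble::tibble(x = d$a - d$b), x, mu0 = 0)
  expect_equal(r1$t, r2$t); expect_equal(r1$p, r2$p)
})

test_that("Bland-Altman limits bracket the mean difference symmetrically", {
  r0 <- bland_altman(tibble::tibble(a = 1:4, b = 1:4), a, b)
  expect_equal(c(r0$mean_diff, r0$loa_lower, r0$loa_upper), c(0, 0, 0))
  r1 <- bland_altman(tibble::tibble(a = c(3, 0, 5), b = c(1, 4, 3)), a, b)
  expect_equal(r1$mean_diff, 0)
  expect_equal(r1$sd_diff, 3.4641, tolerance = 1e-4)
  expect_equal(r1$loa_lower, -6.7897, tolerance = 1e-3)
  expect_equal(r1$loa_upper, 6.7897, tolerance = 1e-3)
  # translation: shifting one method moves the mean, not the width
  set.seed(41)
  d <- tibble::tibble(a = rnorm(8), b = rnorm(8))
  base <- bland_altman(d, a, b)
  shift <- bland_altman(dplyr::mutate(d, a = a + 5), a, b)
  expect_equal(shift$mean_diff, base$mean_diff + 5)
  expect_equal(shift$loa_upper - shift$loa_lower,
               base$loa_upper - base$loa_lower)
  expect_lte(base$loa_lower, base$mean_diff)
  expect_gte(base$loa_upper, base$mean_diff)
})

test_that("ICC matches the mean-squares oracle and its limits", {
  # perfect agreement with between-subject spread
  perf <- tibble::tibble(a = c(10, 20, 30, 40), b = c(10, 20, 30, 40))
  expect_equal(icc_agreement(perf, a, b)$icc, 1)
  # large constant offset with small spread: absolute agreement collapses
  off <- tibble::tibble(a = c(10, 11, 12), b = c(50, 51, 52))
  expect_lt(icc_agreement(off, a, b)$icc, 0.05)
  # 5-subject table against an independently computed ICC(A,1) / ICC(C,1)
  tab <- tibble::tibble(m1 = c(10, 12, 14, 16, 18), m2 = c(11, 13, 13, 17, 20))
  expect_equal(icc_agreement(tab, m1, m2)$icc, 0.932203, tolerance = 1e-5)
  expect_equal(icc_agreement(tab, m1, m2, type = "consistency")$icc,
               0.948276, tolerance = 1e-5)
  expect_warning(
    flat <- icc_agreement(tibble::tibble(a = rep(1, 4), b = rep(1, 4)), a, b),
    "undefined")
  expect_true(is.na(flat$icc))
})

test_that("mean absolute difference and its SEM interval", {
  r1 <- mean_absolute_difference(tibble::tibble(a = c(3, 0, 5), b = c(1, 4, 3)),
                                 a, b)
  expect_equal(r1$mad, 8 / 3, tolerance = 1e-9)
  r0 <- mean_absolute_difference(tibble::tibble(a = 1:3, b = 1:3), a, b)
  expect_equal(c(r0$mad, r0$ci_lower, r0$ci_upper), c(0, 0, 0))
  set.seed(42)
  for (i in 1:20) {
    d <- tibble::tibble(a = rnorm(6), b = rnorm(6))
    expect_gte(mean_absolute_difference(d, a, b)$mad,
               abs(paired_t(d, a, b)$mean_diff))
  }
})

test_that("repeated-measures ANOVA with Tukey post hoc", {
  # frozen 4 subjects x 4 conditions table; F and p from an independent
  # repeated-measures ANOVA implementation
  vals <- matrix(c(0.500025, 0.555975, 0.594517, 0.782188,
                   0.590907, 0.630167, 0.701203, 0.926804,
                   0.690156, 0.737591, 0.809797, 1.007138,
                   0.802108, 0.831391, 0.899415, 1.113906),
                 nrow = 4, byrow = TRUE)
  long <- tidyr::expand_grid(subject = 1:4, quadrant = paste0("q", 1:4)) %>%
    dplyr::mutate(m = as.vector(t(vals)))
  fit <- rm_anova_tukey(long, subject, quadrant, m)
  expect_equal(fit$anova$df1, 3); expect_equal(fit$anova$df2, 9)
  expect_equal(fit$anova$F, 409.6369, tolerance = 1e-4)
  expect_equal(fit$anova$p, 6.144e-10, tolerance = 1e-3)
  expect_equal(nrow(fit$tukey), 6)
  # q4 is shifted by many residual SDs: its pairwise contrasts are extreme
  q4 <- fit$tukey[grepl("q4", fit$tukey$contrast), ]
  expect_true(all(q4$p_adj < 0.001))
  # degenerate: no condition effect at all
  flat <- dplyr::mutate(long, m = as.numeric(subject))
  expect_warning(f2 <- rm_anova_tukey(flat, subject, quadrant, m),
                 "no between-condition")
  expect_equal(f2$anova$F, 0); expect_equal(f2$anova$p, 1)
  expect_true(all(f2$tukey$p_adj == 1))
  # incomplete table refuses to run
  expect_error(rm_anova_tukey(long[-1, ], subject, quadrant, m), "complete")
  # tidy/glance accessors
  expect_equal(nrow(tidy(fit)), 6)
  expect_equal(nrow(glance(fit)), 1)
})

test_that("Pearson correlation with its t-based p-value", {
  d <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 1)
  expect_equal(pearson_r(d, x, y)$r, 1)
  d2 <- tibble::tibble(x = c(-1, 0, 1), y = c(1, -2, 1))  # orthogonal
  expect_equal(pearson_r(d2, x, y)$r, 0)
  d3 <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5))
  r <- pearson_r(d3, x, y)
  expect_equal(r$r, 0.8)
  expect_equal(r$p, 0.10409, tolerance = 1e-4)
  expect_warning(rz <- pearson_r(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
                 "zero variance")
  expect_true(is.na(rz$r))
})

test_that("the agreement report covers every method pair with sane bounds", {
  set.seed(43)
  hfd <- tidyr::expand_grid(patient = 1:8,
                            method = c("hv", "caudal", "cranial")) %>%
    dplyr::mutate(hfd = 50 + rnorm(dplyr::n(), 0, 8) +
                    ifelse(method == "hv", 3, 0))
  rep <- hfd_agreement(hfd, patient, method, hfd)
  expect_s3_class(rep, "hfd_agreement")
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$loa_lower <= rep$mean_diff))
  expect_true(all(rep$loa_upper >= rep$mean_diff))
  expect_true(all(rep$mad >= abs(rep$mean_diff) - 1e-12))
  expect_equal(nrow(tidy(rep)), 3)
  expect_equal(nrow(glance(rep)), 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
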