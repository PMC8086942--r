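test_that("quadrant assignment follows the axes convention", {
  expect_equal(quadrant_of(0.4, 0.4), "left-anterior")
  expect_equal(quadrant_of(-0.4, -0.4), "right-posterior")
  expect_equal(quadrant_of(0.4, -0.4), "left-posterior")
  expect_equal(quadrant_of(-0.4, 0.4), "right-anterior")
  # axis points go to the positive (left/anterior) side
  expect_equal(quadrant_of(0, -0.4), "left-posterior")
  expect_equal(quadrant_of(-0.4, 0), "right-anterior")
})

test_that("mixing index hits its defining endpoints", {
  # pure subsection in a mixed cross-section: no mixing
  expect_equal(mixing_index(12, 0, 40, 60), 0)
  expect_equal(mixing_index(0, 9, 40, 60), 0)
  # subsection ratio equal to the cross-section ratio: perfect mixing
  expect_equal(mixing_index(5, 15, 25, 75), 1)
  expect_equal(mixing_index(10, 30, 40, 120), 1)
  # intermediate value of the tent ratio
  expect_equal(mixing_index(10, 10, 25, 75), min(2, 0.5 / 0.75))
})

test_that("mixing index is undefined without ratio information", {
  expect_true(is.na(mixing_index(0, 0, 40, 60)))   # empty subsection
  expect_true(is.na(mixing_index(5, 5, 100, 0)))   # pure cross-section
  expect_true(is.na(mixing_index(5, 5, 0, 100)))
  expect_error(mixing_index(-1, 2, 3, 4), "non-negative")
})

test_that("mixing index is bounded and label-exchange invariant", {
  set.seed(20)
  for (i in 1:200) {
    ns <- sample(0:30, 2); ng <- ns + sample(0:50, 2)
    m1 <- mixing_index(ns[1], ns[2], ng[1], ng[2])
    m2 <- mixing_index(ns[2], ns[1], ng[2], ng[1])  # swap HV and IVC labels
    expect_identical(is.na(m1), is.na(m2))
    if (!is.na(m1)) {
      expect_gte(m1, 0); expect_lte(m1, 1)
      expect_equal(m1, m2)
    }
  }
})

test_that("cross-section mixing is the count-weighted mean of defined quadrants", {
  expect_equal(cross_section_mixing(rep(1, 4), c(5, 9, 2, 7)), 1)
  expect_equal(cross_section_mixing(c(0, 1), c(10, 10)), 0.5)
  expect_equal(cross_section_mixing(c(0.4, 0.8), c(30, 10)), 0.5)
  expect_equal(cross_section_mixing(c(0.4, NA, 0.8), c(30, 99, 10)), 0.5)
  expect_true(is.na(cross_section_mixing(c(NA, NA), c(3, 4))))
  expect_equal(cross_section_mixing(c(0.2, 0.8), c(30, 10), weighted = FALSE), 0.5)
})

test_that("cycle averaging runs over defined phases and reports the rest", {
  # constant M = 0.7: one quadrant always 7 HV / 13 IVC vs matched global
  tbl <- tidyr::expand_grid(plane = "caudal", phase = 1:100,
                            quadrant = fontanmix:::QUADRANTS) %>%
    dplyr::mutate(n_hv = 20, n_ivc = 20)
  res <- average_mixing(tbl)
  expect_equal(res$summary$M_average, rep(1, 5))  # all quadrants match global
  # alternating 0.2 / 0.8 pattern for one quadrant
  mk <- function(ph) {
    # quadrant A: hv count chosen so M alternates between 0.2 and 0.8
    # global f_g = 0.5; f_s = 0.1 gives M = 0.2, f_s = 0.4 gives M = 0.8
    fs <- if (ph %% 2 == 0) 0.1 else 0.4
    tibble::tibble(plane = "p", phase = ph,
                   quadrant = fontanmix:::QUADRANTS,
                   n_hv = c(fs * 100, 100 - fs * 100, 25, 25),
                   n_ivc = c(100 - fs * 100, fs * 100, 25, 25))
  }
  tbl2 <- purrr::map_dfr(1:100, mk)
  # verify construction: global ratio is 0.5 at every phase
  glob <- tbl2 %>% dplyr::group_by(phase) %>%
    dplyr::summarise(f = sum(n_hv) / sum(n_hv + n_ivc))
  expect_true(all(abs(glob$f - 0.5) < 1e-12))
  res2 <- average_mixing(tbl2)
  first <- dplyr::filter(res2$summary, quadrant == fontanmix:::QUADRANTS[1])
  expect_equal(first$M_average, 0.5, tolerance = 1e-12)
})

test_that("undefined phases are excluded from the average and counted", {
  tbl <- tidyr::expand_grid(plane = "caudal", phase = 1:100,
                            quadrant = fontanmix:::QUADRANTS) %>%
    dplyr::mutate(n_hv = ifelse(.data$phase <= 50 & .data$quadrant == "left-anterior",
                                3, ifelse(.data$quadrant == "left-anterior", 0, 10)),
                  n_ivc = ifelse(.data$quadrant == "left-anterior", 7, 10))
  res <- average_mixing(tbl)
  la <- dplyr::filter(res$summary, quadrant == "left-anterior")
  expect_equal(la$n_defined, 100)  # 3/7 quadrant defined, 0/7 still non-empty
  tbl2 <- dplyr::mutate(tbl, n_ivc = ifelse(.data$quadrant == "left-anterior" &
                                              .data$phase > 50, 0, .data$n_ivc))
  res2 <- average_mixing(tbl2)
  la2 <- dplyr::filter(res2$summary, quadrant == "left-anterior")
  expect_equal(la2$n_undefined, 50)  # empty quadrant phases are undefined
})

test_that("clinical categories use half-open bins", {
  expect_equal(as.character(categorize_mixing(c(0.05, 0.66, 0.79, 0.95))),
               c("no mixing", "moderate mixing", "good mixing", "uniform mixing"))
  expect_equal(as.character(categorize_mixing(c(0.1, 0.3, 0.5, 0.7, 0.9, 1))),
               c("poor mixing", "mild mixing", "moderate mixing",
                 "good mixing", "uniform mixing", "uniform mixing"))
  expect_error(categorize_mixing(1.2), "\\[0, 1\\]")
  expect_error(categorize_mixing(-0.1), "\\[0, 1\\]")
})

test_that("transection tables conserve counts by plane, phase and label", {
  cfg <- flow_config(eps = 0.6, seed = 21)
  fld <- make_duct_field(cfg)
  seeds <- seed_plan(cfg, n_hv = 15, seed = 22)
  tr <- trace_particles(fld, seeds, n_steps = 100, substeps = 10,
                        max_cycles = 2,
                        planes = c(caudal = cfg$z_c, cranial = cfg$z_cr))
  cyc <- dplyr::filter(tr$crossings, cycle == 1)
  expect_gt(nrow(cyc), 0)
  tbl <- transection_table(cyc, n_steps = 100)
  expect_equal(sum(tbl$n_hv) + sum(tbl$n_ivc), nrow(cyc))
  byplane <- tbl %>% dplyr::group_by(plane) %>%
    dplyr::summarise(n = sum(n_hv + n_ivc))
  expect_equal(byplane$n, as.integer(table(cyc$plane)[byplane$plane]),
               ignore_attr = TRUE)
  expect_equal(nrow(tbl), length(unique(cyc$plane)) * 100 * 4)
})

test_that("quadrant-pure streams give zero mixing at every defined phase", {
  crossings <- tidyr::expand_grid(phase = 1:20, i = 1:30) %>%
    dplyr::mutate(plane = "caudal",
                  x = ifelse(i <= 10, 0.4, -0.4),       # HV left, IVC right
                  y = ifelse(i %% 2 == 0, 0.3, -0.3),
                  label = ifelse(i <= 10, "HV", "IVC"))
  res <- average_mixing(transection_table(crossings, n_steps = 20))
  expect_equal(dplyr::filter(res$summary, quadrant == "all")$M_average, 0)
})
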