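steady_seeds <- function(x, y, z = 0) {
  tibble::tibble(particle_id = seq_along(x), label = "HV", region = "HV",
                 release_step = 1L, x = x, y = y, z = z)
}

test_that("steady axial transport matches the closed form", {
  cfg <- flow_config(eps = 0, P = 0, w0 = 5, seed = 1)
  fld <- make_duct_field(cfg)
  tr <- advect(fld, steady_seeds(0, 0), n_steps = 100, substeps = 10,
               max_cycles = 1)
  # on the axis w = w0 exactly: after time t, z = w0 * t
  last <- dplyr::slice_tail(tr$samples, n = 1)
  expect_equal(last$z, 5 * last$t, tolerance = 1e-10)
  expect_equal(last$x, 0); expect_equal(last$y, 0)
})

test_that("pathlines keep constant transverse position when eps = 0", {
  cfg <- flow_config(eps = 0, w0 = 6, seed = 2)
  fld <- make_duct_field(cfg)
  seeds <- seed_plan(cfg, n_hv = 20, seed = 3)
  tr <- advect(fld, seeds, n_steps = 100, substeps = 10, max_cycles = 2)
  drift <- tr$samples %>%
    dplyr::group_by(particle_id) %>%
    dplyr::summarise(dx = max(x) - min(x), dy = max(y) - min(y))
  expect_true(all(drift$dx < 1e-9 * cfg$a))
  expect_true(all(drift$dy < 1e-9 * cfg$a))
})

test_that("the RK4 tracer agrees with a tiny-step Euler oracle", {
  cfg <- flow_config(eps = 0.3, w0 = 5, seed = 4)  # slow flow: no outlet exit
  fld <- make_duct_field(cfg)
  tr <- advect(fld, steady_seeds(0.2, -0.3), n_steps = 100, substeps = 10,
               max_cycles = 1)
  last <- dplyr::slice_tail(tr$samples, n = 1)
  expect_equal(last$t, 1)  # still in the duct after one cycle
  oracle <- euler_path(fld, 0.2, -0.3, 0, t_end = 1, h = 1e-5)
  expect_lt(abs(last$x - oracle["x"]), 1e-3 * cfg$a)
  expect_lt(abs(last$y - oracle["y"]), 1e-3 * cfg$a)
  expect_lt(abs(last$z - oracle["z"]), 1e-3 * cfg$a)
})

test_that("halving the integrator substep barely moves the crossings", {
  # smooth test field: a steady recirculation cell (blink period far beyond
  # the horizon), so the comparison probes integration and crossing
  # interpolation error, not chaotic trajectory divergence
  cfg <- flow_config(eps = 0.2, tau = 1e3, seed = 5)
  fld <- make_duct_field(cfg)
  seeds <- seed_plan(cfg, n_hv = 15, seed = 6)
  planes <- c(caudal = cfg$z_c, cranial = cfg$z_cr)
  tr10 <- trace_particles(fld, seeds, n_steps = 100, substeps = 10,
                          max_cycles = 3, planes = planes)
  tr20 <- trace_particles(fld, seeds, n_steps = 100, substeps = 20,
                          max_cycles = 3, planes = planes)
  a <- dplyr::arrange(tr10$crossings, plane, particle_id)
  b <- dplyr::arrange(tr20$crossings, plane, particle_id)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$particle_id, b$particle_id)
  expect_true(all(abs(a$x - b$x) < 1e-4 * cfg$a))
  expect_true(all(abs(a$y - b$y) < 1e-4 * cfg$a))
})

test_that("plane-crossing detection interpolates and keeps only +z events", {
  path <- tibble::tibble(x = c(1, 2), y = c(5, 7), z = c(0.4, 0.6))
  cr <- detect_crossings(path, plane_z = 0.5)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$x, 1.5); expect_equal(cr$y, 6)
  # monotone pathline entirely below the plane
  below <- tibble::tibble(x = 0, y = 0, z = c(0.1, 0.2, 0.3))
  expect_equal(nrow(detect_crossings(below, plane_z = 0.5)), 0)
  # oscillating pathline: two +z crossings, the -z one is ignored
  osc <- tibble::tibble(x = c(0, 1, 2, 3), y = 0, z = c(0.4, 0.6, 0.4, 0.6))
  cr2 <- detect_crossings(osc, plane_z = 0.5)
  expect_equal(nrow(cr2), 2)
  expect_equal(cr2$x, c(0.5, 2.5))
  # a sample exactly on the plane is counted once, with the ending segment
  onplane <- tibble::tibble(x = c(0, 1, 2), y = 0, z = c(0.4, 0.5, 0.7))
  expect_equal(nrow(detect_crossings(onplane, plane_z = 0.5)), 1)
})

test_that("the streaming tracer and pathline post-processing agree", {
  cfg <- flow_config(eps = 0.4, seed = 7)
  fld <- make_duct_field(cfg)
  seeds <- seed_plan(cfg, n_hv = 10, seed = 8)
  planes <- c(caudal = cfg$z_c, cranial = cfg$z_cr)
  tr <- trace_particles(fld, seeds, n_steps = 100, substeps = 10,
                        max_cycles = 3, planes = planes, record_path = TRUE)
  redet <- dplyr::bind_rows(
    detect_crossings(tr$samples %>%
                       dplyr::left_join(dplyr::select(seeds, particle_id, label),
                                        by = "particle_id"),
                     plane_z = cfg$z_c, plane_id = "caudal", n_steps = 100),
    detect_crossings(tr$samples %>%
                       dplyr::left_join(dplyr::select(seeds, particle_id, label),
                                        by = "particle_id"),
                     plane_z = cfg$z_cr, plane_id = "cranial", n_steps = 100))
  a <- dplyr::arrange(tr$crossings, plane, step, particle_id)
  b <- dplyr::arrange(redet, plane, step, particle_id)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$particle_id, b$particle_id)
  expect_equal(a$step, b$step)
  expect_equal(a$x, b$x, tolerance = 1e-12)
  expect_equal(a$phase, b$phase)
})

test_that("every particle ends in exactly one terminal state", {
  cfg <- flow_config(eps = 1, stirring = "shear", seed = 9)  # shear expels some
  fld <- make_duct_field(cfg)
  seeds <- seed_plan(cfg, n_hv = 60, seed = 10)
  tr <- trace_particles(fld, seeds, n_steps = 100, substeps = 10,
                        max_cycles = 6)
  expect_equal(nrow(tr$status), nrow(seeds))
  expect_true(all(tr$status$status %in% c("active", "exited", "out_of_domain")))
  expect_gt(sum(tr$status$status == "out_of_domain"), 0)
  # wall-clamped particles sit on the wall; exited ones on the outlet plane
  oob <- dplyr::filter(tr$status, status == "out_of_domain")
  expect_true(all(pmax(abs(oob$x), abs(oob$y)) == cfg$a))
  ex <- dplyr::filter(tr$status, status == "exited")
  expect_true(all(ex$z == cfg$L))
})

test_that("unidirectional flow crosses each plane exactly once per particle", {
  cfg <- flow_config(eps = 0.2, seed = 11)  # q(t) > 0, w > 0: z monotone
  fld <- make_duct_field(cfg)
  seeds <- seed_plan(cfg, n_hv = 25, seed = 12)
  tr <- trace_particles(fld, seeds, n_steps = 100, substeps = 10,
                        max_cycles = 12, min_cycles = 5, early_stop = 0.999,
                        planes = c(caudal = cfg$z_c, cranial = cfg$z_cr))
  exited <- tr$status$particle_id[tr$status$status == "exited"]
  per <- dplyr::count(dplyr::filter(tr$crossings, particle_id %in% exited),
                      particle_id, plane)
  expect_true(all(per$n == 1))
  expect_equal(nrow(per), 2 * length(exited))
})

test_that("outlet classification splits on x_split with deterministic ties", {
  status <- tibble::tibble(
    particle_id = 1:5,
    label = "HV", region = "HV", release_step = 1L,
    status = c("exited", "exited", "active", "exited", "exited"),
    x = c(0.5, -0.5, 0.1, 1e-15, 1e-15), y = 0, z = 10, t_end = 1)
  out <- classify_outlet(status, x_split = 0, a = 1)
  expect_equal(out$outlet, c("LPA", "RPA", "unresolved", "LPA", "RPA"))
})

test_that("straight streamlines make the LPA fraction equal the seed split", {
  cfg <- flow_config(eps = 0, s = 0.5, seed = 13)
  fld <- make_duct_field(cfg)
  seeds <- seed_conduit_uniform(cfg, "caudal", n = 400, seed = 14)
  tr <- trace_particles(fld, seeds, n_steps = 100, substeps = 10,
                        max_cycles = 12, min_cycles = 5, early_stop = 0.995)
  st <- classify_outlet(tr, 0, a = cfg$a)
  resolved <- dplyr::filter(st, outlet != "unresolved")
  expect_equal(mean(resolved$outlet == "LPA"),
               mean(seeds$x[seeds$particle_id %in% resolved$particle_id] > 0))
})
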