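# Independent oracles used across the suite; these deliberately avoid the
# package's own code paths.

# Fraction of the time-mean axial flux through {x > xs}, by dense 2-D
# midpoint quadrature of w(x, y) = w0 cos(pi x/2a) cos(pi y/2a).
flux_fraction_quadrature <- function(a, xs, n = 2000) {
  mid_int <- function(lo, hi) {
    g <- seq(lo, hi, length.out = n + 1)
    m <- (g[-1] + g[-(n + 1)]) / 2
    sum(cospi(m / (2 * a))) * (hi - lo) / n
  }
  gy <- mid_int(-a, a)
  mid_int(xs, a) * gy / (mid_int(-a, a) * gy)
}

# Fraction of uniformly seeded hepatic-vein particles lying above xs:
# seeding density is uniform over the union of the sub-regions (counts are
# apportioned by area), so this is an area fraction, computed by midpoint
# quadrature per rectangle.
hv_seed_fraction_above <- function(hv_regions, xs, n = 4000) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(hv_regions))) {
    r <- hv_regions[i, ]
    gx <- seq(r$xmin, r$xmax, length.out = n + 1)
    mx <- (gx[-1] + gx[-(n + 1)]) / 2
    wdt <- (r$xmax - r$xmin) / n
    hgt <- r$ymax - r$ymin
    num <- num + sum(mx > xs) * wdt * hgt
    den <- den + (r$xmax - r$xmin) * hgt
  }
  num / den
}

# Forward-Euler pathline integration at a very small step, as an
# independent check on the RK4 tracer.
euler_path <- function(field, x, y, z, t_end, h) {
  t <- 0
  while (t < t_end - h / 2) {
    v <- field$velocity(x, y, z, t)
    x <- x + h * v$u; y <- y + h * v$v; z <- z + h * v$w
    t <- t + h
  }
  c(x = x, y = y, z = z)
}
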