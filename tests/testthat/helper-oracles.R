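# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths.

# Naive direct evaluation of the generalized mean over DVH bins:
# (sum v_i d_i^a)^(1/a), no factoring, no flooring.
geud_naive <- function(v, d, a) {
  sum(v * d^a)^(1 / a)
}

# Rasterization oracle for rectilinear apertures built from horizontal
# strips. `strips` is a data frame with columns y_lo, y_hi, x_lo, x_hi
# (open interval per strip; omit closed strips). Pixel centers are offset
# half a cell so edges on the raster lattice are unambiguous.
raster_aperture <- function(strips, px = 0.1) {
  x0 <- min(strips$x_lo) - 5 * px
  x1 <- max(strips$x_hi) + 5 * px
  y0 <- min(strips$y_lo) - 5 * px
  y1 <- max(strips$y_hi) + 5 * px
  xc <- seq(x0 + px / 2, x1, by = px)
  yc <- seq(y0 + px / 2, y1, by = px)
  open <- matrix(FALSE, nrow = length(yc), ncol = length(xc))
  for (i in seq_len(nrow(strips))) {
    ry <- yc > strips$y_lo[i] & yc < strips$y_hi[i]
    rx <- xc > strips$x_lo[i] & xc < strips$x_hi[i]
    open[ry, rx] <- open[ry, rx] | TRUE
  }
  area <- sum(open) * px^2
  # Perimeter: count open/closed transitions along rows and columns,
  # including the padded border.
  horiz <- sum(abs(diff(rbind(FALSE, open, FALSE)))) # vertical neighbors
  vert <- sum(abs(diff(t(cbind(FALSE, open, FALSE))))) # horizontal neighbors
  list(area = area, perimeter = (horiz + vert) * px)
}

# Random rectilinear aperture on a 0.1-mm lattice: returns both the strip
# table for the raster oracle and a control point + geometry for the
# analytic path.
random_aperture <- function(n_strips = 20, leaf_width = 5) {
  n <- n_strips
  geom <- mlc_geometry(n_pairs = n, leaf_width_mm = leaf_width, min_gap_mm = 0)
  x1 <- rep(0, n)
  x2 <- rep(0, n)
  open <- runif(n) < 0.8
  # round to the raster lattice so pixel counting is exact
  x1[open] <- round(runif(sum(open), -60, 10), 1)
  x2[open] <- x1[open] + round(runif(sum(open), 2, 60), 1)
  cp <- control_point(0, 0, 0, x1, x2, c(-100, 100), c(-100, 100))
  bounds <- geom$leaf_boundaries_mm
  strips <- data.frame(
    y_lo = bounds[-length(bounds)][open], y_hi = bounds[-1][open],
    x_lo = x1[open], x_hi = x2[open]
  )
  list(cp = cp, geom = geom, strips = strips, any_open = any(open))
}

# Uniform-dose DVH fixture on the package's bin-center convention.
uniform_dvh <- function(dose_gy, structure = "target", bw = 0.05,
                        volume_cc = 10) {
  k <- round(dose_gy / bw)
  centers <- (0:k) * bw
  v <- numeric(k + 1)
  v[k + 1] <- 1
  structure(
    list(structure = structure,
         bin_edges_gy = c(centers - bw / 2, centers[k + 1] + bw / 2),
         bin_centers_gy = centers, diff_volume = v,
         total_volume_cc = volume_cc),
    class = "dvh_curve"
  )
}

# Two-level DVH: fraction `f1` at dose d1, rest at d2.
two_level_dvh <- function(d1, d2, f1 = 0.5, structure = "target", bw = 0.05,
                          volume_cc = 10) {
  k1 <- round(d1 / bw); k2 <- round(d2 / bw)
  kmax <- max(k1, k2)
  centers <- (0:kmax) * bw
  v <- numeric(kmax + 1)
  v[k1 + 1] <- v[k1 + 1] + f1
  v[k2 + 1] <- v[k2 + 1] + (1 - f1)
  structure(
    list(structure = structure,
         bin_edges_gy = c(centers - bw / 2, centers[kmax + 1] + bw / 2),
         bin_centers_gy = centers, diff_volume = v,
         total_volume_cc = volume_cc),
    class = "dvh_curve"
  )
}

# A tiny hand-built static plan: one beam, two control points, a block of
# open leaf pairs forming a rectangle around the isocenter.
static_plan <- function(open_halfwidth = 30, open_strips = 5:16,
                        n_pairs = 20, beam_mu = 200, gantry = 0,
                        dose_per_fraction = 2, n_fractions = 10,
                        site = "prostate") {
  geom <- mlc_geometry(n_pairs = n_pairs, leaf_width_mm = 5, min_gap_mm = 0.5)
  x1 <- rep(-0.25, n_pairs); x2 <- rep(0.25, n_pairs)
  x1[open_strips] <- -open_halfwidth
  x2[open_strips] <- open_halfwidth
  cps <- lapply(0:1, function(i) {
    control_point(i, gantry, i, x1, x2,
                  c(-open_halfwidth - 5, open_halfwidth + 5),
                  c(geom$leaf_boundaries_mm[min(open_strips)],
                    geom$leaf_boundaries_mm[max(open_strips) + 1]))
  })
  vmat_plan("static", site, prescription(dose_per_fraction, n_fractions),
            list(beam("b1", beam_mu, cps, geom)))
}
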