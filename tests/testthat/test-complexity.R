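square_cp <- function() {
  # two adjacent 5-mm strips open (-5, 5): a 10 x 10 mm square
  geom <- mlc_geometry(n_pairs = 4, leaf_width_mm = 5, min_gap_mm = 0)
  x1 <- c(0, -5, -5, 0); x2 <- c(0, 5, 5, 0)
  list(geom = geom,
       cp = control_point(0, 0, 0, x1, x2, c(-50, 50), c(-50, 50)))
}

test_that("mu_per_gy is total MU over fraction dose", {
  p <- static_plan(beam_mu = 500, dose_per_fraction = 2)
  expect_equal(mu_per_gy(p), 250)
  p2 <- static_plan(beam_mu = 1450, dose_per_fraction = 7.25, n_fractions = 5)
  expect_equal(mu_per_gy(p2), 200)
  p3 <- static_plan(beam_mu = 1000, dose_per_fraction = 2)
  expect_equal(mu_per_gy(p3), 2 * mu_per_gy(p))
})

test_that("aperture geometry of simple shapes is exact", {
  sq <- square_cp()
  ag <- aperture_geometry(sq$cp, sq$geom)
  expect_equal(ag$area_mm2, 100)
  expect_equal(ag$perimeter_mm, 40)
  expect_equal(ag$n_subapertures, 1)
  expect_equal(aperture_irregularity(ag), 4 / pi, tolerance = 1e-12)

  # one 5-mm strip open (-5, 5): 10 x 5 rectangle
  geom <- mlc_geometry(n_pairs = 3, leaf_width_mm = 5, min_gap_mm = 0)
  cp <- control_point(0, 0, 0, c(0, -5, 0), c(0, 5, 0), c(-50, 50), c(-50, 50))
  ag2 <- aperture_geometry(cp, geom)
  expect_equal(ag2$area_mm2, 50)
  expect_equal(ag2$perimeter_mm, 30)

  # 20 x 5 rectangle: AI = 50^2 / (4 pi 100)
  cp3 <- control_point(0, 0, 0, c(0, -10, 0), c(0, 10, 0), c(-50, 50), c(-50, 50))
  ag3 <- aperture_geometry(cp3, geom)
  expect_equal(aperture_irregularity(ag3), 2500 / (400 * pi), tolerance = 1e-12)

  # closed aperture: zeros, AI undefined
  cp4 <- control_point(0, 0, 0, c(0, 0, 0), c(0, 0, 0), c(-50, 50), c(-50, 50))
  ag4 <- aperture_geometry(cp4, geom)
  expect_equal(ag4$area_mm2, 0)
  expect_equal(ag4$perimeter_mm, 0)
  expect_error(aperture_irregularity(ag4), "zero area")
})

test_that("disconnected sub-apertures are counted and summed", {
  geom <- mlc_geometry(n_pairs = 5, leaf_width_mm = 5, min_gap_mm = 0)
  # strips 1-2 open on the left, strip 4 open on the right, 3 & 5 closed
  x1 <- c(-20, -20, 0, 10, 0); x2 <- c(-10, -10, 0, 20, 0)
  cp <- control_point(0, 0, 0, x1, x2, c(-50, 50), c(-50, 50))
  ag <- aperture_geometry(cp, geom)
  expect_equal(ag$n_subapertures, 2)
  expect_equal(ag$area_mm2, 10 * 10 + 10 * 5)
  expect_equal(ag$perimeter_mm, 40 + 30)
  # non-overlapping adjacent strips are also disconnected
  x1b <- c(-20, 5, 0, 0, 0); x2b <- c(-5, 20, 0, 0, 0)
  agb <- aperture_geometry(control_point(0, 0, 0, x1b, x2b,
                                         c(-50, 50), c(-50, 50)), geom)
  expect_equal(agb$n_subapertures, 2)
})

test_that("jaws truncate the aperture before area/perimeter", {
  sq <- square_cp()
  cp <- sq$cp
  cp$jaw_x_mm <- c(-2, 5)    # cuts the left 3 mm
  ag <- aperture_geometry(cp, sq$geom)
  expect_equal(ag$area_mm2, 70)
  expect_equal(ag$perimeter_mm, 2 * (7 + 10))
  cp$jaw_y_mm <- c(-5, 2.5)  # cuts strips in y
  ag2 <- aperture_geometry(cp, sq$geom)
  expect_equal(ag2$area_mm2, 7 * 7.5)
})

test_that("AI is invariant to translation and uniform scaling", {
  geom <- mlc_geometry(n_pairs = 6, leaf_width_mm = 5, min_gap_mm = 0)
  x1 <- c(0, -12, -15, -8, 0, 0); x2 <- c(0, -2, 6, 11, 0, 0)
  ai0 <- aperture_irregularity(aperture_geometry(
    control_point(0, 0, 0, x1, x2, c(-90, 90), c(-90, 90)), geom))
  shifted <- aperture_irregularity(aperture_geometry(
    control_point(0, 0, 0, x1 + 30, x2 + 30, c(-90, 90), c(-90, 90)), geom))
  expect_equal(shifted, ai0, tolerance = 1e-12)
  geom2 <- mlc_geometry(n_pairs = 6, leaf_width_mm = 10, min_gap_mm = 0)
  scaled <- aperture_irregularity(aperture_geometry(
    control_point(0, 0, 0, 2 * x1, 2 * x2, c(-90, 90), c(-90, 90)), geom2))
  expect_equal(scaled, ai0, tolerance = 1e-12)
})

test_that("area and perimeter match the 0.1-mm rasterization oracle", {
  set.seed(515)
  n_checked <- 0
  for (i in 1:100) {
    ap <- random_aperture()
    if (!ap$any_open) next
    n_checked <- n_checked + 1
    ag <- aperture_geometry(ap$cp, ap$geom)
    oracle <- raster_aperture(ap$strips)
    expect_lt(abs(ag$area_mm2 - oracle$area) / oracle$area, 0.01)
    expect_lt(abs(ag$perimeter_mm - oracle$perimeter) / oracle$perimeter, 0.01)
  }
  expect_gt(n_checked, 90)
})

test_that("PI is the MU-weighted mean of aperture irregularities", {
  geom <- mlc_geometry(n_pairs = 4, leaf_width_mm = 5, min_gap_mm = 0)
  sq <- c(0, -5, -5, 0)                       # 10x10 square, AI = 4/pi
  mk_plan <- function(weights) {
    n <- length(weights)
    cps <- lapply(seq_len(n), function(i) {
      control_point(i - 1, 0, weights[i], sq, -sq, c(-50, 50), c(-50, 50))
    })
    vmat_plan("pi", "prostate", prescription(2, 39),
              list(beam("b1", 100, cps, geom)))
  }
  cr <- plan_irregularity(mk_plan(c(0, 0.3, 0.7, 1)))
  expect_equal(cr$pi, 4 / pi, tolerance = 1e-12)
  expect_gte(cr$pi, 1)

  # two equal-MU segments with AI 1.3 and 1.7 -> BI = 1.5 (synthetic AI table)
  bi <- sum(c(50, 50) * c(1.3, 1.7)) / 100
  expect_equal(bi, 1.5)
})

test_that("shifting MU toward the higher-AI segment raises PI", {
  geom <- mlc_geometry(n_pairs = 4, leaf_width_mm = 5, min_gap_mm = 0)
  sq1 <- list(x1 = c(0, -5, -5, 0), x2 = c(0, 5, 5, 0))      # square
  rect <- list(x1 = c(0, -20, -20, 0), x2 = c(0, 20, 20, 0)) # elongated, higher AI
  mk <- function(w2) {
    cps <- list(
      control_point(0, 0, 0, sq1$x1, sq1$x2, c(-50, 50), c(-50, 50)),
      control_point(1, 10, 1 - w2, rect$x1, rect$x2, c(-50, 50), c(-50, 50)),
      control_point(2, 20, 1, rect$x1, rect$x2, c(-50, 50), c(-50, 50))
    )
    vmat_plan("w", "prostate", prescription(2, 39),
              list(beam("b1", 100, cps, geom)))
  }
  pis <- vapply(c(0.2, 0.5, 0.8), function(w) plan_irregularity(mk(w))$pi,
                numeric(1))
  expect_true(all(diff(pis) > 0))
})

test_that("PI is invariant to uniform MU rescaling", {
  tpl <- site_template("lung")
  ph <- make_phantom(tpl, case_seed = 2)
  p <- make_plan(tpl, ph, modulation = 0.5, case_seed = 2,
                 n_control_points = 20)
  p2 <- p
  p2$beams[[1]]$beam_mu <- p$beams[[1]]$beam_mu * 3
  expect_equal(plan_irregularity(p2)$pi, plan_irregularity(p)$pi,
               tolerance = 1e-12)
  expect_equal(mu_per_gy(p2), 3 * mu_per_gy(p))
})
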