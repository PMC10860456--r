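# A small open plan used throughout: all pairs open and inside the jaws, so
# every pair is eligible for displacement.
open_test_plan <- function(gap = 20, n_pairs = 6, min_gap = 0, n_cp = 3) {
  geom <- mlc_geometry(n_pairs = n_pairs, leaf_width_mm = 5, min_gap_mm = min_gap)
  w <- seq(0, 1, length.out = n_cp)
  cps <- lapply(seq_len(n_cp), function(i) {
    control_point(i - 1, (i - 1) * 10, w[i],
                  rep(-gap / 2, n_pairs), rep(gap / 2, n_pairs),
                  c(-40, 40), c(-20, 20))
  })
  vmat_plan("open", "prostate", prescription(2, 39),
            list(beam("b1", 100, cps, geom)))
}

leaf_positions <- function(plan, bank = 1) {
  do.call(rbind, lapply(plan$beams[[1]]$control_points,
                        function(cp) if (bank == 1) cp$x1_mm else cp$x2_mm))
}

test_that("systematic close/open shift both banks by the magnitude", {
  p <- open_test_plan(gap = 20)
  cl <- apply_systematic(p, error_spec("systematic_close", 2))
  expect_equal(leaf_positions(cl, 1), leaf_positions(p, 1) + 2)
  expect_equal(leaf_positions(cl, 2), leaf_positions(p, 2) - 2)
  op <- apply_systematic(p, error_spec("systematic_open", 2))
  expect_equal(leaf_positions(op, 1), leaf_positions(p, 1) - 2)
  expect_equal(leaf_positions(op, 2), leaf_positions(p, 2) + 2)
  # gap change is -/+ 2 delta
  expect_equal(leaf_positions(cl, 2) - leaf_positions(cl, 1),
               leaf_positions(p, 2) - leaf_positions(p, 1) - 4)
  # input untouched, jaws and weights untouched
  expect_equal(leaf_positions(p, 1)[1, 1], -10)
  expect_equal(cl$beams[[1]]$control_points[[1]]$jaw_x_mm, c(-40, 40))
  expect_equal(total_mu(cl), total_mu(p))
})

test_that("pairs crossing under a close error clamp to min_gap and are logged", {
  p <- open_test_plan(gap = 2, min_gap = 0)
  cl <- apply_systematic(p, error_spec("systematic_close", 2))
  expect_true(all(leaf_positions(cl, 1) == 0))
  expect_true(all(leaf_positions(cl, 2) == 0))
  log <- attr(cl, "clamp_log")
  expect_equal(nrow(log), 6 * 3)      # every pair at every control point
  expect_setequal(unique(log$leaf), 1:6)
})

test_that("open then close round-trips when nothing clamps", {
  p <- open_test_plan(gap = 20)
  q <- apply_systematic(apply_systematic(p, error_spec("systematic_open", 1.5)),
                        error_spec("systematic_close", 1.5))
  expect_equal(leaf_positions(q, 1), leaf_positions(p, 1), tolerance = 1e-12)
  expect_equal(leaf_positions(q, 2), leaf_positions(p, 2), tolerance = 1e-12)
})

test_that("close errors compose additively when nothing clamps", {
  p <- open_test_plan(gap = 30)
  q12 <- apply_systematic(apply_systematic(p, error_spec("systematic_close", 1)),
                          error_spec("systematic_close", 2))
  q3 <- apply_systematic(p, error_spec("systematic_close", 3))
  expect_equal(leaf_positions(q12, 1), leaf_positions(q3, 1), tolerance = 1e-12)
  expect_equal(leaf_positions(q12, 2), leaf_positions(q3, 2), tolerance = 1e-12)
})

test_that("random displacements have the requested SD and near-zero mean", {
  # >10^4 leaf positions: 50 pairs x 101 control points x 2 banks
  p <- open_test_plan(gap = 50, n_pairs = 50, n_cp = 101)
  spec <- error_spec("random", 1, seed = 424)
  q <- apply_random(p, spec)
  disp <- c(leaf_positions(q, 1) - leaf_positions(p, 1),
            leaf_positions(q, 2) - leaf_positions(p, 2))
  expect_gt(length(disp), 1e4)
  expect_lt(abs(stats::sd(disp) - 1), 0.05)
  expect_lt(abs(mean(disp)), 3 / sqrt(length(disp)))
  expect_equal(nrow(attr(q, "clamp_log")), 0)
})

test_that("random mode is deterministic in the seed and requires one", {
  p <- open_test_plan(gap = 20)
  a <- apply_random(p, error_spec("random", 0.5, seed = 9))
  b <- apply_random(p, error_spec("random", 0.5, seed = 9))
  expect_equal(leaf_positions(a, 1), leaf_positions(b, 1))
  c2 <- apply_random(p, error_spec("random", 0.5, seed = 10))
  expect_false(identical(leaf_positions(a, 1), leaf_positions(c2, 1)))
  expect_error(error_spec("random", 0.5), "seed")
})

test_that("no operation ever emits x1 > x2", {
  p <- open_test_plan(gap = 3, min_gap = 0.5)
  for (spec in list(error_spec("systematic_close", 2),
                    error_spec("systematic_open", 2),
                    error_spec("random", 2, seed = 1))) {
    q <- apply_error(p, spec)
    expect_true(all(leaf_positions(q, 2) >= leaf_positions(q, 1)))
    expect_no_error(validate_plan(q))
  }
})

test_that("parked pairs are skipped unless perturb_parked is set", {
  geom <- mlc_geometry(n_pairs = 4, leaf_width_mm = 5, min_gap_mm = 0.5)
  # pairs 1 and 4 parked: closed and outside jaw_y (jaws cover strips 2-3)
  x1 <- c(-0.25, -10, -10, -0.25); x2 <- c(0.25, 10, 10, 0.25)
  cps <- lapply(0:1, function(i) {
    control_point(i, 0, i, x1, x2, c(-20, 20), c(-5, 5))
  })
  p <- vmat_plan("park", "prostate", prescription(2, 39),
                 list(beam("b1", 100, cps, geom)))
  cl <- apply_systematic(p, error_spec("systematic_close", 1))
  expect_equal(leaf_positions(cl, 1)[, 1], c(-0.25, -0.25))   # untouched
  expect_equal(leaf_positions(cl, 1)[, 2], c(-9, -9))         # displaced
  cl2 <- apply_systematic(p, error_spec("systematic_close", 1,
                                        perturb_parked = TRUE))
  expect_equal(nrow(attr(cl2, "clamp_log")), 4)  # both parked pairs, both cps
})

test_that("build_error_set enumerates the full cross product", {
  plans <- vector("list", 640)
  syst <- build_error_set(plans, grid = c(0.25, 0.5, 1, 2),
                          modes = c("systematic_close", "systematic_open"))
  expect_equal(nrow(syst), 5120)
  one <- build_error_set(list(1), grid = 1, modes = "systematic_close")
  expect_equal(nrow(one), 1)
  rnd <- build_error_set(vector("list", 160), grid = c(0.25, 0.5, 1, 2),
                         modes = "random", n_replicates = 2)
  expect_equal(nrow(rnd), 1280)
  expect_true(all(!is.na(rnd$seed)))
  expect_s3_class(rnd$spec[[1]], "error_spec")
  expect_error(build_error_set(plans, grid = numeric(0)), "empty")
})
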