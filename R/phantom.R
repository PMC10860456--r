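# Voxel phantoms: isotropic grids with labeled boolean structure masks.
# Axes: x lateral, y longitudinal (the MLC leaf-stack direction), z
# anterior-posterior. The gantry rotates in the x-z plane.

#' Build a voxel phantom for a site template
#'
#' Places the template's target and OAR masks on an isotropic voxel grid,
#' with per-case jitter of sizes (±10%) and positions (±4 mm) drawn
#' deterministically from `case_seed`.
#'
#' @param template A [site_template()].
#' @param case_seed Integer seed; the same seed always yields the same
#'   phantom.
#' @param spacing_mm Isotropic voxel size (mm); default 2.
#' @param jitter Apply the per-case size/position jitter (default `TRUE`).
#'   `FALSE` places structures exactly at template sizes (useful for
#'   analytic geometry checks).
#' @param shape Grid dimensions `c(nx, ny, nz)`; default `c(50, 48, 50)`
#'   (100 x 96 x 100 mm centered on the isocenter).
#'
#' @return An object of class `phantom`: list with `spacing_mm`, `shape`,
#'   `origin_mm` (coordinate of the first voxel center), `masks` (named list
#'   of logical arrays) and the coordinate vectors `xs`, `ys`, `zs`.
#' @export
make_phantom <- function(template, case_seed, spacing_mm = 2,
                         shape = c(50, 48, 50), jitter = TRUE) {
  stopifnot(inherits(template, "site_template"), length(shape) == 3)
  local_seed(case_seed, {
    specs <- c(list(target = template$target), template$oars)
    jittered <- lapply(specs, function(s) {
      size_f <- if (jitter) stats::runif(1, 0.9, 1.1) else 1
      shift <- if (jitter) stats::runif(3, -4, 4) else c(0, 0, 0)
      s$center_mm <- s$center_mm + shift
      for (f in c("radius_mm", "outer_radius_mm", "inner_radius_mm",
                  "half_length_mm")) {
        if (!is.null(s[[f]])) s[[f]] <- s[[f]] * size_f
      }
      s
    })
    xs <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * spacing_mm
    ys <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * spacing_mm
    zs <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * spacing_mm
    masks <- lapply(jittered, shape_mask, xs = xs, ys = ys, zs = zs)
    if (!any(masks$target)) stop("phantom generation produced an empty target mask")
    structure(
      list(
        spacing_mm = spacing_mm,
        shape = as.integer(shape),
        origin_mm = c(xs[1], ys[1], zs[1]),
        xs = xs, ys = ys, zs = zs,
        masks = masks
      ),
      class = "phantom"
    )
  })
}

# Rasterize one shape spec onto the grid.
shape_mask <- function(spec, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  cx <- spec$center_mm[1]; cy <- spec$center_mm[2]; cz <- spec$center_mm[3]
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  dz2 <- (zs - cz)^2
  m <- switch(spec$shape,
    sphere = {
      r2 <- spec$radius_mm^2
      outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    },
    cylinder_y = {
      r2 <- spec$radius_mm^2
      radial <- outer(dx2, dz2, "+") <= r2            # nx x nz
      iny <- abs(ys - cy) <= spec$half_length_mm
      aperm(outer(radial, iny), c(1, 3, 2))           # nx x ny x nz
    },
    annulus_y = {
      rad2 <- outer(dx2, dz2, "+")                    # nx x nz
      ring <- rad2 <= spec$outer_radius_mm^2 & rad2 >= spec$inner_radius_mm^2
      iny <- abs(ys - cy) <= spec$half_length_mm
      aperm(outer(ring, iny), c(1, 3, 2))
    },
    stop("unknown shape: ", spec$shape)
  )
  m <- m > 0   # outer() products return numeric; masks are logical
  dim(m) <- c(nx, ny, nz)
  m
}

#' Structure volume in cubic centimeters
#'
#' @param phantom A [make_phantom()] result.
#' @param structure Structure name.
#' @return Volume (cc).
#' @export
structure_volume_cc <- function(phantom, structure) {
  m <- phantom$masks[[structure]]
  if (is.null(m)) stop("no such structure: ", structure)
  sum(m) * phantom$spacing_mm^3 / 1000
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d x %d voxels @ %g mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing_mm))
  for (nm in names(x$masks)) {
    cat(sprintf("  %-14s %8.1f cc\n", nm, structure_volume_cc(x, nm)))
  }
  invisible(x)
}
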