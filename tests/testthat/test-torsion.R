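test_that("circle fitting matches known circles and the grid oracle", {
  f1 <- fit_circle(rbind(c(5, 0), c(0, 5), c(-5, 0), c(0, -5)))
  expect_equal(unname(f1$center), c(0, 0), tolerance = 1e-12)
  expect_equal(f1$radius, 5, tolerance = 1e-12)
  expect_lt(f1$rms_residual, 1e-12)
  f2 <- fit_circle(rbind(c(0, 0), c(0, 2), c(2, 0)))  # circumcircle
  expect_equal(unname(f2$center), c(1, 1), tolerance = 1e-12)
  expect_equal(f2$radius, sqrt(2), tolerance = 1e-12)
  # noisy circle: close to truth and to the grid-refinement oracle
  set.seed(7)
  th <- stats::runif(100, 0, 2 * pi)
  pts <- cbind(-2 + 7 * sin(th), 3 + 7 * cos(th)) +
    matrix(stats::rnorm(200, 0, 0.1), ncol = 2)
  f3 <- fit_circle(pts)
  expect_lt(max(abs(f3$center - c(-2, 3))), 0.05)
  orc <- oracle_circle_fit(pts, init = f3$center)
  expect_lt(max(abs(f3$center - orc$center)), 1e-6)
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))), "3 points")
  expect_error(fit_circle(cbind(1:5, 1:5)), "collinear")
})

# rasterize discs on a fine grid, in mm
disc_slice <- function(centres_xy, radii, px = 0.2, half = 8) {
  n <- round(2 * half / px) + 1
  g <- torsionlab:::plane_grid(n, n, px, px)
  m <- matrix(FALSE, n, n)
  for (i in seq_along(radii)) {
    m <- m | ((g$y - centres_xy[i, 2])^2 + (g$x - centres_xy[i, 1])^2 <=
                radii[i]^2)
  }
  m
}

test_that("posterior tangent matches symmetry and the rotating-line oracle", {
  # two equal discs: horizontal tangent
  m <- disc_slice(rbind(c(-3, 0), c(3, 0)), c(1, 1))
  t0 <- posterior_tangent(m, c(0.2, 0.2))
  expect_lt(abs(t0$angle_deg), 0.5)
  # unequal radii (1 and 2, centres 6 apart): asin(1/6) = 9.594 degrees
  m2 <- disc_slice(rbind(c(-3, 0), c(3, 0)), c(1, 2))
  t2 <- posterior_tangent(m2, c(0.2, 0.2))
  expect_equal(t2$angle_deg, asin(1 / 6) * 180 / pi, tolerance = 0.5)
  # agrees with the explicit shift-and-rotate search
  comps <- torsionlab:::slice_components(m2)
  p1 <- torsionlab:::mask_boundary_points(comps[[1]], c(0.2, 0.2))
  p2 <- torsionlab:::mask_boundary_points(comps[[2]], c(0.2, 0.2))
  phi <- oracle_posterior_tangent(p1, p2)
  expect_equal(t2$angle_deg, phi, tolerance = 0.02)
  # single disc is an error unless splitting is allowed
  single <- disc_slice(rbind(c(0, 0)), 2)
  expect_error(posterior_tangent(single, c(0.2, 0.2)), "not separable")
  expect_silent(posterior_tangent(single, c(0.2, 0.2), split_if_merged = TRUE))
  expect_error(posterior_tangent(matrix(FALSE, 4, 4)), "empty mask")
})

test_that("posterior tangent tracks the oracle on random two-disc layouts", {
  set.seed(21)
  for (i in 1:25) {
    ang <- stats::runif(1, -30, 30)
    d <- stats::runif(1, 6, 10)
    r1 <- stats::runif(1, 1, 2.5); r2 <- stats::runif(1, 1, 2.5)
    u <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    m <- disc_slice(rbind(-d / 2 * u, d / 2 * u), c(r1, r2))
    tg <- posterior_tangent(m, c(0.2, 0.2))
    comps <- torsionlab:::slice_components(m)
    phi <- oracle_posterior_tangent(
      torsionlab:::mask_boundary_points(comps[[1]], c(0.2, 0.2)),
      torsionlab:::mask_boundary_points(comps[[2]], c(0.2, 0.2)))
    expect_lt(abs(tg$angle_deg - phi), 0.5)
  }
})

test_that("centroid lines and angle differences follow their definitions", {
  mk <- function(cy, cx) {
    m <- matrix(FALSE, 30, 30); m[cy + 1, cx + 1] <- TRUE
    m
  }
  expect_equal(centroid_line(mk(5, 2), mk(5, 20))$angle_deg, 0)
  expect_equal(centroid_line(mk(0, 0), mk(10, 10))$angle_deg, 45)
  expect_error(centroid_line(mk(1, 1), matrix(FALSE, 30, 30)), "fibula")
  expect_error(centroid_line(matrix(FALSE, 30, 30), mk(1, 1)), "tibia")
  expect_equal(line_angle_diff(20, 5), 15)
  expect_equal(line_angle_diff(-85, 85), 10)
  expect_equal(line_angle_diff(33, 33), 0)
  expect_equal(line_angle_diff(line2d(50), line2d(-50)), 100 - 180)
})

test_that("torsion angles are recovered within tolerance across the sweep", {
  for (ft in c(-30, 0, 30, 45)) {
    for (tt in c(0, 35, 50)) {
      limb <- generate_limb(hires_spec(femoral_torsion_deg = ft,
                                       tibial_torsion_deg = tt))
      r <- measure_limb(limb$hip$labels, limb$knee$labels, limb$ankle$labels)
      expect_true(r$success)
      expect_lt(abs(r$femoral_torsion_deg - wrap_angle(ft)), 2)
      expect_lt(abs(r$tibial_torsion_deg - wrap_angle(tt)), 2)
    }
  }
})

test_that("zero-torsion symmetric geometry measures zero", {
  limb <- generate_limb(hires_spec(femoral_torsion_deg = 0,
                                   tibial_torsion_deg = 0,
                                   condylar_angle_deg = 0,
                                   tibial_plateau_angle_deg = 0))
  r <- measure_limb(limb$hip$labels, limb$knee$labels, limb$ankle$labels,
                    slice_hints = limb$truth$designated_slices)
  expect_lt(abs(r$femoral_torsion_deg), 0.5)
  expect_lt(abs(r$tibial_torsion_deg), 0.5)
})

test_that("measurements are equivariant to in-plane rotation and translation", {
  limb <- generate_limb(hires_spec(femoral_torsion_deg = 18,
                                   tibial_torsion_deg = 28))
  base <- measure_limb(limb$hip$labels, limb$knee$labels, limb$ankle$labels)
  rot_stack <- function(ls, delta) {
    out <- ls
    for (iz in seq_len(dim(ls$labels)[1])) {
      out$labels[iz, , ] <- torsionlab:::warp_slice(ls$labels[iz, , ], delta,
                                                    1, c(0, 0),
                                                    interp = "nearest")
    }
    storage.mode(out$labels) <- "integer"
    out
  }
  for (delta in c(-10, -5, 5, 10)) {
    r <- measure_limb(rot_stack(limb$hip$labels, delta),
                      rot_stack(limb$knee$labels, delta),
                      rot_stack(limb$ankle$labels, delta))
    expect_true(r$success)
    expect_lt(abs(r$femoral_torsion_deg - base$femoral_torsion_deg), 0.5)
    expect_lt(abs(r$tibial_torsion_deg - base$tibial_torsion_deg), 0.5)
  }
  shift_stack <- function(ls, dy, dx) {
    out <- ls
    d <- dim(ls$labels)
    sl <- array(0L, d)
    sl[, (1 + dy):d[2], (1 + dx):d[3]] <- ls$labels[, 1:(d[2] - dy),
                                                    1:(d[3] - dx)]
    out$labels <- sl
    out
  }
  r <- measure_limb(shift_stack(limb$hip$labels, 3, 5),
                    shift_stack(limb$knee$labels, 3, 5),
                    shift_stack(limb$ankle$labels, 3, 5))
  expect_equal(r$femoral_torsion_deg, base$femoral_torsion_deg)
  expect_equal(r$tibial_torsion_deg, base$tibial_torsion_deg)
})

test_that("landmark failures are captured with their reasons, never raised", {
  limb <- generate_limb(desk_spec())
  empty <- label_stack(array(0L, dim(limb$hip$labels$labels)),
                       limb$hip$labels$spacing, "hip", "right")
  r <- measure_limb(empty, limb$knee$labels, limb$ankle$labels)
  expect_false(r$success)
  expect_match(r$failure_reason, "head fit: empty mask")
  expect_false(is.na(r$tibial_torsion_deg))  # tibial chain still reported
  # emptied ankle: femoral angle still reported in landmarks
  empty_ankle <- label_stack(array(0L, dim(limb$ankle$labels$labels)),
                             limb$ankle$labels$spacing, "ankle", "right")
  r2 <- measure_limb(limb$hip$labels, limb$knee$labels, empty_ankle)
  expect_false(r2$success)
  expect_false(is.na(r2$femoral_torsion_deg))
  expect_match(r2$failure_reason, "tibia")
  # everything empty: aggregated reasons from both chains
  empty_knee <- label_stack(array(0L, dim(limb$knee$labels$labels)),
                            limb$knee$labels$spacing, "knee", "right")
  r3 <- measure_limb(empty, empty_knee, empty_ankle)
  expect_false(r3$success)
  expect_match(r3$failure_reason, "femoral:")
  expect_match(r3$failure_reason, "tibial:")
})
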