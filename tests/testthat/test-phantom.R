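test_that("truth angles satisfy the additive reference-line relations", {
  limb <- generate_limb(desk_spec(femoral_torsion_deg = 15,
                                  condylar_angle_deg = 5,
                                  tibial_torsion_deg = 35,
                                  tibial_plateau_angle_deg = -3))
  tr <- limb$truth
  expect_equal(tr$neck_axis_angle_deg, 20)
  expect_equal(tr$ankle_axis_angle_deg, wrap_angle(-3 - 35))
  expect_equal(wrap_angle(tr$neck_axis_angle_deg - tr$condylar_angle_deg),
               tr$femoral_torsion_deg)
  expect_equal(wrap_angle(tr$tibial_plateau_angle_deg - tr$ankle_axis_angle_deg),
               tr$tibial_torsion_deg)
  # wrapping: angles live on the (-90, 90] line-angle circle
  limb2 <- torsionlab:::limb_truth(desk_spec(femoral_torsion_deg = 85,
                                             condylar_angle_deg = 10))
  expect_equal(limb2$neck_axis_angle_deg, wrap_angle(95))
  expect_lte(limb2$neck_axis_angle_deg, 90)
})

test_that("left-sided limbs carry identical truth and mirrored geometry", {
  r <- generate_limb(desk_spec(side = "right", femoral_torsion_deg = 12,
                               tibial_torsion_deg = 30))
  l <- generate_limb(desk_spec(side = "left", femoral_torsion_deg = 12,
                               tibial_torsion_deg = 30))
  expect_equal(l$truth$femoral_torsion_deg, r$truth$femoral_torsion_deg)
  expect_equal(l$truth$tibial_torsion_deg, r$truth$tibial_torsion_deg)
  # geometry is the x-mirror image
  nx <- dim(r$hip$labels$labels)[3]
  expect_identical(l$hip$labels$labels, r$hip$labels$labels[, , nx:1])
})

test_that("phantom generation is deterministic given spec and seed", {
  a <- generate_limb(desk_spec(seed = 9))
  b <- generate_limb(desk_spec(seed = 9))
  expect_identical(a$hip$image$values, b$hip$image$values)
  expect_identical(a$knee$labels$labels, b$knee$labels$labels)
  c <- generate_limb(desk_spec(seed = 10))
  expect_false(identical(a$hip$image$values, c$hip$image$values))
})

test_that("rasterized head slice boundary recovers the head centre within a voxel", {
  limb <- generate_limb(hires_spec())
  zs <- limb$truth$designated_slices
  m <- limb$hip$labels$labels[zs$head, , ] == 1L
  pts <- torsionlab:::mask_boundary_points(m, c(0.6, 0.6))
  fit <- fit_circle(pts)
  # truth head centre in array-mm coordinates = FOV centre
  ctr_mm <- (dim(m) - 1) / 2 * 0.6
  expect_lt(max(abs(fit$center - ctr_mm)), 0.6)
  # and matches the brute-force grid-refinement fit
  orc <- oracle_circle_fit(pts, init = fit$center)
  expect_lt(max(abs(fit$center - orc$center)), 0.05)
})

test_that("geometry that cannot fit the field of view names the primitive", {
  expect_error(generate_limb(desk_spec(head_radius_mm = 80)), "femoral head")
  expect_error(generate_limb(limb_spec(stack_shape = c(8L, 160L, 160L))),
               "femoral neck")
})

test_that("T2 intensity model renders configured tissue means and texture", {
  spec0 <- desk_spec(texture_sd = 0)
  limb <- generate_limb(spec0)
  v <- limb$hip$image$values
  lab <- limb$hip$labels$labels
  tm <- spec0$tissue_means
  expect_setequal(unique(as.vector(v)),
                  unname(tm[c("background", "marrow", "cortex")]))
  expect_true(all(v[lab == 0L] == tm[["background"]]))
  # same seed twice -> identical images
  s <- desk_spec(texture_sd = 10, seed = 4)
  expect_identical(t2_intensity_model(limb$hip$labels, s)$values,
                   t2_intensity_model(limb$hip$labels, s)$values)
  bad <- limb$hip$labels
  bad$labels[1] <- 5L
  expect_error(t2_intensity_model(bad, s), "unknown label")
  # marrow sample mean within 3 sd / sqrt(n) of the configured mean (CLT)
  img <- t2_intensity_model(limb$hip$labels, s)
  marrow <- img$values[lab > 0L & limb$hip$image$values == tm[["marrow"]]]
  expect_lt(abs(mean(marrow) - tm[["marrow"]]), 3 * 10 / sqrt(length(marrow)))
})

test_that("cohort generation counts, jitters, and seeds as configured", {
  co <- generate_cohort(3, severity_plan = c("none", "severe"),
                        base_spec = desk_spec(), seed = 5)
  expect_length(co, 3)
  expect_equal(co[[1]]$severity_plan, c("none", "severe"))
  expect_named(co[[1]], c("id", "severity_plan", "right"))
  # zero-width jitter -> identical truths across participants
  z <- list(femoral_torsion_deg = c(15, 15), tibial_torsion_deg = c(35, 35),
            condylar_angle_deg = c(0, 0), tibial_plateau_angle_deg = c(0, 0))
  cz <- generate_cohort(3, base_spec = desk_spec(), jitter = z,
                        rasterize = FALSE, seed = 1)
  fts <- vapply(cz, function(p) p$right$truth$femoral_torsion_deg, numeric(1))
  expect_equal(fts, rep(15, 3))
  expect_error(generate_cohort(2, severity_plan = character(0)), "empty")
  expect_error(generate_cohort(2, severity_plan = "extreme"), "unknown severity")
})

test_that("sampled torsions are uniform over the configured jitter range", {
  co <- generate_cohort(1000, base_spec = desk_spec(),
                        jitter = list(femoral_torsion_deg = c(0, 30)),
                        rasterize = FALSE, seed = 42)
  fts <- vapply(co, function(p) p$right$truth$femoral_torsion_deg, numeric(1))
  ks <- stats::ks.test(fts, "punif", 0, 30)
  expect_gt(ks$p.value, 0.01)
  expect_true(all(fts >= 0 & fts <= 30))
})
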