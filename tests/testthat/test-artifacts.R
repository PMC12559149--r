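set.seed(1)
rand_img <- matrix(stats::rnorm(32 * 32), 32, 32)

test_that("ghosting attenuates exactly the targeted k-space lines", {
  expect_lt(max(abs(apply_ghosting(rand_img, intensity = 0) - rand_img)), 1e-9)
  cst <- matrix(7, 32, 32)
  expect_lt(max(abs(apply_ghosting(cst, intensity = 1) - cst)), 1e-9)
  # impulse image, g = 4, s = 1: equals the direct-DFT oracle that zeroes
  # signed-frequency lines at non-zero multiples of 4
  imp <- matrix(0, 16, 16); imp[5, 9] <- 1
  K <- oracle_dft2(imp)
  fr <- torsionlab:::signed_freqs(16)
  K[fr != 0 & fr %% 4 == 0, ] <- 0
  expect_lt(max(abs(apply_ghosting(imp, ghost_order = 4, intensity = 1) -
                      Re(oracle_dft2(K, inverse = TRUE)))), 1e-9)
  expect_error(apply_ghosting(rand_img, ghost_order = 1), ">= 2")
  expect_error(apply_ghosting(rand_img, axis = "z"), "arg")
})

test_that("spikes insert Hermitian pairs producing real cosine stripes", {
  expect_lt(max(abs(apply_spike(rand_img, cbind(3, 5), 0) - rand_img)), 1e-9)
  out <- apply_spike(rand_img, cbind(3, 5), 0.5, phase_rad = 0.7)
  expect_true(all(is.finite(out)))
  # difference equals the 2D cosine predicted by a direct inverse DFT of
  # the two inserted conjugate samples
  K0 <- oracle_dft2(rand_img)
  m <- 0.5 * max(Mod(K0))
  Kd <- matrix(0 + 0i, 32, 32)
  Kd[3 + 1, 5 + 1] <- m * exp(0.7i)
  Kd[32 - 3 + 1, 32 - 5 + 1] <- m * exp(-0.7i)
  pred <- Re(oracle_dft2(Kd, inverse = TRUE))
  expect_lt(max(abs((out - rand_img) - pred)), 1e-9)
  expect_error(apply_spike(rand_img, cbind(0, 0), 0.5), "DC")
  expect_error(apply_spike(rand_img, cbind(40, 0), 0.5), "outside")
})

test_that("segment-wise motion assembles k-space from transformed states", {
  idt <- list(list(rotation_deg = 0, translation_mm = c(0, 0)))
  expect_lt(max(abs(apply_motion(rand_img, idt, list(1:16, 17:32)) -
                      rand_img)), 1e-6)
  # every line assigned to one rotated state -> the rotated image
  rot <- list(list(rotation_deg = 5, translation_mm = c(1, -2)))
  all_moved <- apply_motion(rand_img, rot, list(integer(0), 1:32))
  expect_lt(max(abs(all_moved -
                      torsionlab:::warp_slice(rand_img, 5, 1, c(1, -2)))), 1e-6)
  # two-state schedule on an impulse equals the line-wise DFT composition
  imp <- matrix(0, 16, 16); imp[7, 7] <- 1
  tr <- list(list(rotation_deg = 0, translation_mm = c(2, 0)))
  sched <- list(1:8, 9:16)
  K0 <- oracle_dft2(imp)
  K1 <- oracle_dft2(torsionlab:::warp_slice(imp, 0, 1, c(2, 0)))
  Kmix <- rbind(K0[1:8, ], K1[9:16, ])
  expect_lt(max(abs(apply_motion(imp, tr, sched) -
                      Re(oracle_dft2(Kmix, inverse = TRUE)))), 1e-9)
  expect_error(apply_motion(rand_img, tr, list(1:20, 10:32)), "exactly once")
  expect_error(apply_motion(rand_img, tr, list(1:10)), "per state")
})

test_that("k-space operators commute with global intensity scaling", {
  g1 <- apply_ghosting(3 * rand_img, ghost_order = 3, intensity = 0.4)
  g2 <- 3 * apply_ghosting(rand_img, ghost_order = 3, intensity = 0.4)
  expect_lt(max(abs(g1 - g2)), 1e-9)
  s1 <- apply_spike(3 * rand_img, cbind(2, 2), 0.3)
  s2 <- 3 * apply_spike(rand_img, cbind(2, 2), 0.3)
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("intensity artifacts: identity, blur mass conservation, noise sd", {
  vol <- array(stats::runif(12 * 24 * 24), c(12, 24, 24))
  expect_identical(apply_intensity_artifacts(vol), vol)
  bl <- apply_intensity_artifacts(vol, blur_sigma_mm = c(0.5, 1, 1),
                                  spacing_mm = c(1, 1, 1))
  expect_lt(abs(sum(bl) - sum(vol)) / sum(vol), 1e-6)
  # noise sd within 99% chi-square bounds at n = 1e6
  n <- 1e6
  flat <- array(10, c(100, 100, 100))
  ns <- apply_intensity_artifacts(flat, noise_sd = 5, seed = 2)
  s2 <- stats::var(as.vector(ns - flat))
  bounds <- (n - 1) * 25 / stats::qchisq(c(0.995, 0.005), n - 1)
  expect_gt(s2, bounds[1]); expect_lt(s2, bounds[2])
  # bias field is positive and multiplicative
  bf <- apply_intensity_artifacts(vol, bias_order = 2, bias_scale = 0.2,
                                  seed = 3)
  expect_true(all(bf > 0))
  expect_error(apply_intensity_artifacts(vol, noise_sd = -1), "non-negative")
})

test_that("the MRI-specific sampler respects probabilities, seeds, and labels", {
  set.seed(3)
  img <- tiny_image()
  off <- sampler_config(prob = c(motion = 0, ghosting = 0, spike = 0,
                                 blur = 0, bias_field = 0, noise = 0))
  r0 <- sample_mri_specific(img, config = off, seed = 1)
  expect_identical(r0$image$values, img$values)
  expect_length(r0$recipe$applied, 0)
  a <- sample_mri_specific(img, config = sampler_config(), seed = 9)
  b <- sample_mri_specific(img, config = sampler_config(), seed = 9)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$recipe$applied, b$recipe$applied)
  # labels untouched by volume-constant corruption
  limb <- generate_limb(desk_spec())
  s <- sample_mri_specific(limb$hip$image, limb$hip$labels,
                           severity_to_params("severe"), seed = 2)
  expect_identical(s$labels$labels, limb$hip$labels$labels)
})

test_that("severity presets are empty at none and widen monotonically", {
  expect_length(severity_to_params("none")$prob[severity_to_params("none")$prob > 0], 0)
  rg <- lapply(c("mild", "moderate", "severe"), torsionlab:::severity_ranges)
  mid <- function(r) mean(r$ghost_intensity)
  expect_true(mid(rg[[1]]) < mid(rg[[2]]) && mid(rg[[2]]) < mid(rg[[3]]))
  expect_true(all(diff(vapply(rg, `[[`, numeric(1), "rotation_max_deg")) > 0))
  expect_true(all(diff(vapply(rg, `[[`, numeric(1), "translation_max_mm")) > 0))
  expect_true(all(diff(vapply(rg, `[[`, numeric(1), "noise_frac_max")) > 0))
  expect_error(severity_to_params("catastrophic"), "arg")
  # seeded preset draw reproducible
  img <- withr::with_seed(1, tiny_image())
  x <- sample_mri_specific(img, config = severity_to_params("moderate"), seed = 4)
  y <- sample_mri_specific(img, config = severity_to_params("moderate"), seed = 4)
  expect_identical(x$recipe$applied, y$recipe$applied)
})
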