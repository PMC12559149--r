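# k-space and intensity-domain MRI artifact operators.
#
# FFT convention: stats::fft of a (y, x) matrix, DC at index (1, 1)
# (no shift); signed frequencies for an axis of length N are
# i - 1 for i <= N/2 + 1, i - 1 - N otherwise. The phase-encode axis
# defaults to y (anterior-posterior), matching axial acquisitions.

# map a function over the 2D slices of matrix / 3D array / image_stack
map_slices <- function(image, f) {
  if (inherits(image, "image_stack")) {
    out <- image
    out$values <- map_slices(image$values, f)
    return(out)
  }
  if (is.matrix(image)) return(f(image))
  stopifnot(is.array(image), length(dim(image)) == 3L)
  out <- image
  for (iz in seq_len(dim(image)[1])) out[iz, , ] <- f(image[iz, , ])
  out
}

signed_freqs <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n / 2, i, i - n)
}

#' Ghosting artifact: periodic attenuation of phase-encode lines
#'
#' Scales every `ghost_order`-th k-space line (in signed frequency,
#' excluding the DC line) by `1 - intensity`, producing the displaced,
#' superimposed anatomical duplicates characteristic of periodic-motion
#' ghosting along the phase-encode direction.
#'
#' @param image 2D matrix (y, x), 3D array (z, y, x), or `image_stack`.
#' @param axis phase-encode axis, `"y"` (default) or `"x"`.
#' @param ghost_order integer g >= 2; lines at signed frequencies that are
#'   non-zero multiples of g are attenuated.
#' @param intensity attenuation s in \[0, 1\]; 0 is the identity.
#' @return the corrupted image, same type as the input.
#' @export
apply_ghosting <- function(image, axis = "y", ghost_order = 2L, intensity = 0.5) {
  axis <- match.arg(axis, c("y", "x"))
  if (ghost_order < 2) abort("apply_ghosting: ghost_order must be >= 2")
  if (intensity < 0 || intensity > 1) abort("apply_ghosting: intensity must be in [0, 1]")
  map_slices(image, function(sl) {
    K <- stats::fft(sl)
    n <- if (axis == "y") nrow(sl) else ncol(sl)
    fr <- signed_freqs(n)
    hit <- fr != 0L & fr %% ghost_order == 0L
    if (axis == "y") K[hit, ] <- K[hit, ] * (1 - intensity)
    else K[, hit] <- K[, hit] * (1 - intensity)
    Re(stats::fft(K, inverse = TRUE)) / length(sl)
  })
}

#' Spike (Herringbone) artifact: point insertions in k-space
#'
#' Adds a complex value of magnitude `intensity * max(Mod(K))` at each
#' requested k-space position and its Hermitian mirror, so the output
#' stays real; in image space each spike is a two-dimensional cosine
#' stripe pattern.
#'
#' @inheritParams apply_ghosting
#' @param spike_positions matrix with columns (u, v): signed frequencies
#'   along y and x. The DC position (0, 0) is rejected.
#' @param intensity spike magnitude s >= 0 relative to the k-space
#'   maximum; 0 is the identity.
#' @param phase_rad phase of the inserted complex value (radians).
#' @return the corrupted image, same type as the input.
#' @export
apply_spike <- function(image, spike_positions, intensity = 0.2, phase_rad = 0) {
  if (intensity < 0) abort("apply_spike: intensity must be >= 0")
  sp <- matrix(as.numeric(spike_positions), ncol = 2)
  map_slices(image, function(sl) {
    ny <- nrow(sl); nx <- ncol(sl)
    if (any(abs(sp[, 1]) > ny / 2) || any(abs(sp[, 2]) > nx / 2)) {
      abort("apply_spike: spike position outside the k-space grid")
    }
    if (intensity == 0) return(sl)
    K <- stats::fft(sl)
    m <- intensity * max(Mod(K))
    val <- m * exp(1i * phase_rad)
    for (r in seq_len(nrow(sp))) {
      u <- sp[r, 1]; v <- sp[r, 2]
      if (u == 0 && v == 0) {
        abort("apply_spike: spike on the DC sample is rejected (would only shift global brightness)")
      }
      iu <- (u %% ny) + 1; iv <- (v %% nx) + 1
      mu <- ((-u) %% ny) + 1; mv <- ((-v) %% nx) + 1
      if (iu == mu && iv == mv) {
        # self-conjugate (Nyquist) position: keep it real
        K[iu, iv] <- K[iu, iv] + m * cos(phase_rad)
      } else {
        K[iu, iv] <- K[iu, iv] + val
        K[mu, mv] <- K[mu, mv] + Conj(val)
      }
    }
    Re(stats::fft(K, inverse = TRUE)) / length(sl)
  })
}

#' Segment-wise motion artifact
#'
#' Emulates patient motion during acquisition: k-space is assembled
#' line-wise from the k-spaces of differently posed copies of the image.
#' State 0 is the untransformed image; each further state is a rigid 2D
#' transform (rotation about the slice centre, translation in mm).
#'
#' @inheritParams apply_ghosting
#' @param transforms list of `list(rotation_deg =, translation_mm = c(ty, tx))`
#'   for motion states 1..K.
#' @param schedule list of length K + 1 of integer phase-encode line
#'   indices (1-based, unshifted FFT order); element 1 belongs to state 0.
#'   Must partition all lines exactly once.
#' @param spacing_mm (dy, dx) in mm for translation conversion; taken from
#'   the stack when `image` is an `image_stack`.
#' @return the corrupted image, same type as the input.
#' @export
apply_motion <- function(image, transforms, schedule, axis = "y",
                         spacing_mm = c(1, 1)) {
  axis <- match.arg(axis, c("y", "x"))
  if (inherits(image, "image_stack")) spacing_mm <- image$spacing[2:3]
  if (length(schedule) != length(transforms) + 1L) {
    abort("apply_motion: schedule must have one entry per state (including state 0)")
  }
  map_slices(image, function(sl) {
    n <- if (axis == "y") nrow(sl) else ncol(sl)
    lines <- sort(unlist(schedule))
    if (length(lines) != n || !identical(lines, seq_len(n))) {
      abort("apply_motion: schedule must cover every phase-encode line exactly once")
    }
    Kout <- stats::fft(sl)  # state 0
    sel <- function(K, idx) if (axis == "y") K[idx, , drop = FALSE] else K[, idx, drop = FALSE]
    put <- function(K, idx, val) {
      if (axis == "y") K[idx, ] <- val else K[, idx] <- val
      K
    }
    for (k in seq_along(transforms)) {
      idx <- schedule[[k + 1L]]
      if (length(idx) == 0) next
      tr <- transforms[[k]]
      tpx <- c(tr$translation_mm[1] / spacing_mm[1],
               tr$translation_mm[2] / spacing_mm[2])
      Kk <- stats::fft(warp_slice(sl, tr$rotation_deg, 1, tpx))
      Kout <- put(Kout, idx, sel(Kk, idx))
    }
    Re(stats::fft(Kout, inverse = TRUE)) / length(sl)
  })
}

#' Intensity-domain artifacts: blur, polynomial bias field, noise
#'
#' Applies, in order: separable Gaussian blur (sigma in mm, converted by
#' the voxel spacing; circular boundary, so total intensity is conserved),
#' a multiplicative positive bias field `exp(P)` with a random polynomial
#' `P` of the given order whose coefficients are scaled by `bias_scale`,
#' and additive Gaussian noise. All-zero parameters return the input
#' unchanged.
#'
#' @param image 3D array (z, y, x) or `image_stack`.
#' @param blur_sigma_mm per-axis (dz, dy, dx) Gaussian sigma in mm
#'   (scalars are recycled).
#' @param bias_order polynomial order of the log bias field (>= 0).
#' @param bias_scale scale of the log-bias coefficients (>= 0; 0 disables).
#' @param noise_sd additive Gaussian noise SD (image units).
#' @param seed seed for bias coefficients and noise.
#' @param spacing_mm (dz, dy, dx); taken from the stack when given one.
#' @return same type as the input.
#' @export
apply_intensity_artifacts <- function(image, blur_sigma_mm = 0, bias_order = 2L,
                                      bias_scale = 0, noise_sd = 0, seed = 1L,
                                      spacing_mm = c(1, 1, 1)) {
  if (inherits(image, "image_stack")) {
    out <- image
    out$values <- apply_intensity_artifacts(image$values, blur_sigma_mm,
                                            bias_order, bias_scale, noise_sd,
                                            seed, image$spacing)
    return(out)
  }
  stopifnot(is.array(image), length(dim(image)) == 3L)
  sig <- rep_len(blur_sigma_mm, 3L)
  if (any(sig < 0) || bias_scale < 0 || noise_sd < 0 || bias_order < 0) {
    abort("apply_intensity_artifacts: parameters must be non-negative")
  }
  vol <- image
  if (any(sig > 0)) {
    for (ax in 1:3) {
      spx <- sig[ax] / spacing_mm[ax]
      if (spx <= 0) next
      vol <- blur_axis(vol, ax, spx)
    }
  }
  if (bias_scale > 0 || noise_sd > 0) {
    vol <- withr::with_seed(derive_seed(seed, "intensity-artifacts"), {
      v <- vol
      if (bias_scale > 0) {
        d <- dim(v)
        cz <- seq(-1, 1, length.out = d[1])
        cy <- seq(-1, 1, length.out = d[2])
        cx <- seq(-1, 1, length.out = d[3])
        P <- array(0, d)
        for (i in 0:bias_order) for (j in 0:(bias_order - i)) {
          for (k in 0:(bias_order - i - j)) {
            coef <- stats::runif(1, -1, 1) * bias_scale
            P <- P + coef * outer(outer(cz^i, cy^j), cx^k)
          }
        }
        v <- v * exp(P)
      }
      if (noise_sd > 0) {
        v <- v + array(stats::rnorm(length(v), 0, noise_sd), dim(v))
      }
      v
    })
  }
  vol
}

# separable 1D Gaussian blur along axis `ax` with circular boundary
blur_axis <- function(vol, ax, sigma_px) {
  n <- dim(vol)[ax]
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  out <- array(0, dim(vol))
  for (o in seq(-half, half)) {
    idx <- ((seq_len(n) - 1 + o) %% n) + 1
    shifted <- switch(ax,
                      vol[idx, , , drop = FALSE],
                      vol[, idx, , drop = FALSE],
                      vol[, , idx, drop = FALSE])
    out <- out + k[o + half + 1] * shifted
  }
  out
}

#' Sampler configuration for MRI-specific augmentation
#'
#' Per-kind inclusion probabilities default to 0.5 for every artifact
#' except spikes (0.02). Parameter ranges default to the `moderate`
#' severity preset (see [severity_to_params()]); every range is
#' overridable.
#'
#' @param prob named inclusion probabilities for `motion`, `ghosting`,
#'   `spike`, `blur`, `bias_field`, `noise` (in \[0, 1\]).
#' @param ranges named list of parameter ranges; see
#'   [severity_to_params()] for the preset structure.
#' @param slice_wise if `TRUE`, motion is emulated as per-slice rigid
#'   misalignment applied to image and labels (through-plane emulation for
#'   ankle stacks) instead of a k-space segment artifact.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(prob = c(motion = 0.5, ghosting = 0.5, spike = 0.02,
                                    blur = 0.5, bias_field = 0.5, noise = 0.5),
                           ranges = severity_ranges("moderate"),
                           slice_wise = FALSE) {
  kinds <- c("motion", "ghosting", "spike", "blur", "bias_field", "noise")
  p <- rep(0.5, length(kinds)); names(p) <- kinds; p["spike"] <- 0.02
  p[names(prob)] <- prob
  if (any(p < 0 | p > 1)) abort("sampler_config: probabilities must be in [0, 1]")
  structure(list(prob = p, ranges = ranges, slice_wise = isTRUE(slice_wise)),
            class = "sampler_config")
}

# severity preset parameter-range table; ranges widen monotonically
severity_ranges <- function(severity) {
  tab <- list(
    mild = list(ghost_intensity = c(0.1, 0.3), ghost_order = 2:4,
                n_movements = 1L, rotation_max_deg = 2, translation_max_mm = 2,
                blur_sigma_max_mm = 0.5, bias_scale_max = 0.1,
                noise_frac_max = 0.02, spike_intensity = c(0.05, 0.15)),
    moderate = list(ghost_intensity = c(0.3, 0.6), ghost_order = 2:4,
                    n_movements = 2L, rotation_max_deg = 5, translation_max_mm = 5,
                    blur_sigma_max_mm = 1.0, bias_scale_max = 0.2,
                    noise_frac_max = 0.05, spike_intensity = c(0.1, 0.25)),
    severe = list(ghost_intensity = c(0.6, 0.9), ghost_order = 2:4,
                  n_movements = 3L, rotation_max_deg = 10, translation_max_mm = 10,
                  blur_sigma_max_mm = 1.5, bias_scale_max = 0.3,
                  noise_frac_max = 0.08, spike_intensity = c(0.15, 0.35))
  )
  tab[[match.arg(severity, names(tab))]]
}

#' Map a severity grade to a sampler configuration
#'
#' `none` yields an empty configuration (no artifacts). The graded
#' presets apply the motion-artifact triad — segment-wise motion,
#' ghosting, and noise — deterministically (probability 1), blur and bias
#' field at 0.5, and spikes at the training probability 0.02, with
#' parameter ranges that widen strictly with severity.
#'
#' @param severity one of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param slice_wise passed through to [sampler_config()].
#' @return a `sampler_config`.
#' @export
severity_to_params <- function(severity, slice_wise = FALSE) {
  severity <- match.arg(severity, c("none", "mild", "moderate", "severe"))
  if (severity == "none") {
    cfg <- sampler_config(prob = c(motion = 0, ghosting = 0, spike = 0,
                                   blur = 0, bias_field = 0, noise = 0),
                          slice_wise = slice_wise)
  } else {
    cfg <- sampler_config(prob = c(motion = 1, ghosting = 1, spike = 0.02,
                                   blur = 0.5, bias_field = 0.5, noise = 1),
                          ranges = severity_ranges(severity),
                          slice_wise = slice_wise)
  }
  cfg$severity <- severity
  cfg
}

#' Probabilistic MRI-specific artifact sampler
#'
#' Each artifact kind is included independently with its configured
#' probability; parameters are drawn uniformly from the configured
#' ranges. Artifacts are applied in a fixed order (motion, ghosting,
#' spike, blur, bias field, noise). Labels are returned unchanged —
#' all sampled artifacts live in k-space or the intensity domain — except
#' under `slice_wise` motion, where the per-slice rigid misalignment is
#' applied to the labels as well so that registration recovery is
#' testable.
#'
#' @param image an `image_stack` (or 3D array).
#' @param labels optional congruent `label_stack`.
#' @param config a [sampler_config()].
#' @param seed integer seed; identical seeds give identical draws.
#' @return `list(image, labels, recipe)`; `recipe` is an
#'   `artifact_recipe` logging every applied artifact and its parameters.
#' @export
sample_mri_specific <- function(image, labels = NULL,
                                config = sampler_config(), seed = 1L) {
  stopifnot(inherits(config, "sampler_config"))
  is_stack <- inherits(image, "image_stack")
  spacing <- if (is_stack) image$spacing else c(1, 1, 1)
  vol <- if (is_stack) image$values else image
  if (is.matrix(vol)) vol <- array(vol, c(1L, dim(vol)))
  rg <- config$ranges
  severity <- if (is.null(config$severity)) "custom" else config$severity

  drawn <- withr::with_seed(derive_seed(seed, "mri-specific-sampler"), {
    applied <- list()
    include <- stats::runif(length(config$prob)) < config$prob
    names(include) <- names(config$prob)
    if (include[["motion"]]) {
      if (config$slice_wise) {
        nz <- dim(vol)[1]
        tf <- lapply(seq_len(nz), function(i) {
          list(rotation_deg = stats::runif(1, -rg$rotation_max_deg, rg$rotation_max_deg),
               translation_mm = stats::runif(2, -rg$translation_max_mm, rg$translation_max_mm))
        })
        applied <- c(applied, list(list(kind = "motion", params = list(
          slice_transforms = tf))))
      } else {
        k <- rg$n_movements
        tf <- lapply(seq_len(k), function(i) {
          list(rotation_deg = stats::runif(1, -rg$rotation_max_deg, rg$rotation_max_deg),
               translation_mm = stats::runif(2, -rg$translation_max_mm, rg$translation_max_mm))
        })
        n_pe <- dim(vol)[2]
        applied <- c(applied, list(list(kind = "motion", params = list(
          transforms = tf, schedule = random_motion_schedule(n_pe, k)))))
      }
    }
    if (include[["ghosting"]]) {
      applied <- c(applied, list(list(kind = "ghosting", params = list(
        ghost_order = sample(rg$ghost_order, 1),
        intensity = stats::runif(1, rg$ghost_intensity[1], rg$ghost_intensity[2])))))
    }
    if (include[["spike"]]) {
      ny <- dim(vol)[2]; nx <- dim(vol)[3]
      pos <- cbind(sample(seq.int(2, floor(ny / 2) - 1), 1) * sample(c(-1, 1), 1),
                   sample(seq.int(2, floor(nx / 2) - 1), 1) * sample(c(-1, 1), 1))
      applied <- c(applied, list(list(kind = "spike", params = list(
        spike_positions = pos,
        intensity = stats::runif(1, rg$spike_intensity[1], rg$spike_intensity[2]),
        phase_rad = stats::runif(1, 0, 2 * pi)))))
    }
    if (include[["blur"]]) {
      applied <- c(applied, list(list(kind = "blur", params = list(
        blur_sigma_mm = stats::runif(1, 0, rg$blur_sigma_max_mm)))))
    }
    if (include[["bias_field"]]) {
      applied <- c(applied, list(list(kind = "bias_field", params = list(
        bias_order = 2L, bias_scale = stats::runif(1, 0, rg$bias_scale_max)))))
    }
    if (include[["noise"]]) {
      applied <- c(applied, list(list(kind = "noise", params = list(
        noise_sd = stats::runif(1, 0, rg$noise_frac_max) * max(vol)))))
    }
    applied
  })

  lab_vol <- if (!is.null(labels)) labels$labels else NULL
  for (a in drawn) {
    p <- a$params
    vol <- switch(a$kind,
      motion = {
        if (config$slice_wise) {
          for (iz in seq_len(dim(vol)[1])) {
            tr <- p$slice_transforms[[iz]]
            tpx <- tr$translation_mm / spacing[2:3]
            vol[iz, , ] <- warp_slice(vol[iz, , ], tr$rotation_deg, 1, tpx)
            if (!is.null(lab_vol)) {
              lab_vol[iz, , ] <- warp_slice(lab_vol[iz, , ], tr$rotation_deg, 1,
                                            tpx, interp = "nearest", pad = 0)
            }
          }
          vol
        } else {
          apply_motion(vol, p$transforms, p$schedule, spacing_mm = spacing[2:3])
        }
      },
      ghosting = apply_ghosting(vol, ghost_order = p$ghost_order,
                                intensity = p$intensity),
      spike = apply_spike(vol, p$spike_positions, p$intensity, p$phase_rad),
      blur = apply_intensity_artifacts(vol, blur_sigma_mm = c(0, p$blur_sigma_mm,
                                                              p$blur_sigma_mm),
                                       bias_scale = 0, noise_sd = 0,
                                       spacing_mm = spacing),
      bias_field = apply_intensity_artifacts(vol, bias_order = p$bias_order,
                                             bias_scale = p$bias_scale,
                                             noise_sd = 0,
                                             seed = derive_seed(seed, "bias"),
                                             spacing_mm = spacing),
      noise = apply_intensity_artifacts(vol, noise_sd = p$noise_sd,
                                        seed = derive_seed(seed, "noise"),
                                        spacing_mm = spacing))
  }

  recipe <- structure(list(applied = drawn, severity = severity,
                           seed = as.integer(seed),
                           slice_wise = config$slice_wise),
                      class = "artifact_recipe")
  out_img <- if (is_stack) { s <- image; s$values <- vol; s } else vol
  out_lab <- labels
  if (!is.null(labels) && !is.null(lab_vol)) {
    out_lab$labels <- lab_vol
    storage.mode(out_lab$labels) <- "integer"
  }
  list(image = out_img, labels = out_lab, recipe = recipe)
}

# contiguous random partition of phase-encode lines (centred frequency
# order); the block containing DC stays in state 0
random_motion_schedule <- function(n_pe, k) {
  fr <- signed_freqs(n_pe)
  ord <- order(fr)                      # centred order of 1-based line indices
  cuts <- sort(sample(seq_len(n_pe - 1), k))
  blocks <- split(ord, findInterval(seq_len(n_pe) - 1, cuts))
  dc_line <- which(fr == 0L)
  dc_block <- which(vapply(blocks, function(b) dc_line %in% b, logical(1)))
  sched <- c(blocks[dc_block], blocks[-dc_block])
  names(sched) <- NULL
  # pad with empty states if fewer blocks than states (cuts may coincide)
  while (length(sched) < k + 1L) sched <- c(sched, list(integer(0)))
  sched
}

#' @exportS3Method base::print
print.artifact_recipe <- function(x, ...) {
  kinds <- vapply(x$applied, `[[`, character(1), "kind")
  cat(sprintf("<artifact_recipe> severity=%s seed=%d slice_wise=%s applied={%s}\n",
              x$severity, x$seed, x$slice_wise,
              paste(kinds, collapse = ",")))
  invisible(x)
}
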