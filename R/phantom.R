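#' Specification of one synthetic limb
#'
#' A limb is parameterised by its two torsion angles and the orientation
#' of the reference structures they are defined against. The phantom
#' geometry is deliberately minimal — sphere, cylinders, discs, one
#' ellipse — so that every landmark the measurement chain extracts
#' (femoral head and neck centres, posterior condylar tangents, distal
#' tibio-fibular centroid axis) is known in closed form.
#'
#' Derived angles:
#' * neck axis angle = `condylar_angle_deg + femoral_torsion_deg`, wrapped
#'   into (-90, 90];
#' * distal tibio-fibular axis angle =
#'   `tibial_plateau_angle_deg - tibial_torsion_deg`, wrapped.
#'
#' @param side "right" or "left". Left limbs are generated by mirroring
#'   the canonical geometry in x; the measurement convention mirrors back,
#'   so positive torsion means anteversion on both sides.
#' @param femoral_torsion_deg,tibial_torsion_deg torsion angles (degrees,
#'   in (-90, 90]).
#' @param condylar_angle_deg orientation of the posterior femoral condylar
#'   tangent (degrees).
#' @param tibial_plateau_angle_deg orientation of the posterior tibial
#'   tangent (degrees).
#' @param head_radius_mm,neck_radius_mm,shaft_radius_mm femoral head
#'   sphere, neck cylinder, and distal shaft radii (mm).
#' @param condyle_radius_mm length-2 (medial, lateral) condylar lobe radii
#'   (mm); also used for the tibial plateau lobes.
#' @param tibia_radius_mm length-2 semi-axes of the distal tibial ellipse
#'   (mm); a single value gives a circle.
#' @param fibula_radius_mm fibular radius (mm).
#' @param stack_shape integer (n_slices, n_rows, n_cols) used for all
#'   three stacks, or a named list with entries `hip`, `knee`, `ankle`.
#' @param spacing_mm voxel spacing (dz, dy, dx) in mm; anisotropic by
#'   default, emulating 2D TSE stacks.
#' @param tissue_means named grey levels for `background`, `marrow`, and
#'   the dark cortical rim (`cortex`), emulating T2-weighted contrast.
#' @param texture_sd grey-level SD of the seeded Gaussian texture.
#' @param seed integer seed for the texture.
#' @return an object of class `limb_spec`.
#' @export
limb_spec <- function(side = "right",
                      femoral_torsion_deg = 15,
                      tibial_torsion_deg = 35,
                      condylar_angle_deg = 0,
                      tibial_plateau_angle_deg = 0,
                      head_radius_mm = 20,
                      neck_radius_mm = 11,
                      shaft_radius_mm = 9,
                      condyle_radius_mm = c(12, 12),
                      tibia_radius_mm = c(14, 10),
                      fibula_radius_mm = 6,
                      stack_shape = c(14L, 160L, 160L),
                      spacing_mm = c(3.0, 0.6, 0.6),
                      tissue_means = c(background = 40, marrow = 180, cortex = 12),
                      texture_sd = 10,
                      seed = 1L) {
  side <- match.arg(side, c("right", "left"))
  condyle_radius_mm <- rep_len(condyle_radius_mm, 2L)
  tibia_radius_mm <- rep_len(tibia_radius_mm, 2L)
  radii <- c(head_radius_mm, neck_radius_mm, shaft_radius_mm,
             condyle_radius_mm, tibia_radius_mm, fibula_radius_mm)
  if (any(radii <= 0)) abort("limb_spec: all radii must be > 0")
  if (any(spacing_mm <= 0)) abort("limb_spec: spacing must be > 0")
  shapes <- if (is.list(stack_shape)) stack_shape else
    list(hip = stack_shape, knee = stack_shape, ankle = stack_shape)
  if (!all(c("hip", "knee", "ankle") %in% names(shapes))) {
    abort("limb_spec: stack_shape list needs hip/knee/ankle entries")
  }
  for (jl in names(shapes)) {
    if (shapes[[jl]][1] < 5) abort("limb_spec: n_slices must be >= 5 (%s)", jl)
  }
  if (!all(c("background", "marrow", "cortex") %in% names(tissue_means))) {
    abort("limb_spec: tissue_means needs background/marrow/cortex")
  }
  structure(list(
    side = side,
    femoral_torsion_deg = femoral_torsion_deg,
    tibial_torsion_deg = tibial_torsion_deg,
    condylar_angle_deg = condylar_angle_deg,
    tibial_plateau_angle_deg = tibial_plateau_angle_deg,
    head_radius_mm = head_radius_mm,
    neck_radius_mm = neck_radius_mm,
    shaft_radius_mm = shaft_radius_mm,
    condyle_radius_mm = condyle_radius_mm,
    tibia_radius_mm = tibia_radius_mm,
    fibula_radius_mm = fibula_radius_mm,
    stack_shape = lapply(shapes, function(s) as.integer(s[1:3])),
    spacing_mm = as.numeric(spacing_mm),
    tissue_means = tissue_means,
    texture_sd = texture_sd,
    seed = as.integer(seed)
  ), class = "limb_spec")
}

# ---- raster primitives (in-plane, mm coordinates, vectorized) ----------

# grid of in-plane coordinates centred on the FOV centre
plane_grid <- function(ny, nx, dy, dx) {
  cy <- (ny - 1) / 2 * dy
  cx <- (nx - 1) / 2 * dx
  list(y = matrix((seq_len(ny) - 1) * dy - cy, ny, nx),
       x = matrix((seq_len(nx) - 1) * dx - cx, ny, nx, byrow = TRUE),
       cy = cy, cx = cx)
}

raster_disc <- function(g, cy, cx, r) {
  (g$y - cy)^2 + (g$x - cx)^2 <= r^2
}

# ellipse with semi-axis `a` along in-plane angle theta (deg), `b` across
raster_ellipse <- function(g, cy, cx, a, b, theta_deg) {
  th <- deg2rad(theta_deg)
  u <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
  v <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# in-plane unit vector (x, y) at angle theta (deg, CCW from +x)
unit_xy <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  c(x = cos(th), y = sin(th))
}

# place two lobe centres so that their common posterior (+y) tangent has
# exactly the requested angle: with centres cA -> cB along direction
# theta_c and radii rA, rB, the tangent angle phi satisfies
# D * sin(theta_c - phi) = rA - rB.
lobe_centres <- function(tangent_deg, D, rA, rB) {
  theta_c <- tangent_deg + rad2deg(asin((rA - rB) / D))
  u <- unit_xy(theta_c)
  list(A = -D / 2 * u, B = D / 2 * u)
}

check_fov <- function(extent_mm, half_fov_mm, what, margin = 2) {
  if (extent_mm > half_fov_mm - margin) {
    abort("phantom geometry exceeds the field of view: %s (needs %.1f mm, FOV half-width %.1f mm)",
          what, extent_mm + margin, half_fov_mm)
  }
}

# ---- analytic layout and truth -----------------------------------------

# closed-form geometry of one limb: primitive placement and the
# designated slice indices, independent of rasterization
limb_layout <- function(spec) {
  sp <- spec$spacing_mm
  dz <- sp[1]
  neck_axis <- wrap_angle(spec$condylar_angle_deg + spec$femoral_torsion_deg)
  ankle_axis <- wrap_angle(spec$tibial_plateau_angle_deg - spec$tibial_torsion_deg)
  rh <- spec$head_radius_mm
  z_head <- 4L
  sphere_last <- z_head + ceiling(rh / dz) - 1L
  z_neck <- sphere_last + 2L
  drift <- 0.8                       # in-plane neck drift, mm per mm of z
  u_n <- unit_xy(neck_axis)
  neck_off <- drift * (z_neck - z_head) * dz
  nzk <- spec$stack_shape$knee[1]
  n_prox <- max(3L, floor(nzk / 3))
  z_cond <- seq_len(n_prox)
  z_plat <- seq.int(nzk - n_prox + 1L, nzk)
  nza <- spec$stack_shape$ankle[1]
  list(neck_axis = neck_axis, ankle_axis = ankle_axis,
       z_head = z_head, sphere_last = sphere_last, z_neck = z_neck,
       drift = drift, u_n = u_n, neck_off = neck_off,
       z_cond = z_cond, z_plat = z_plat, nza = nza)
}

# ground truth record for one limb (canonical right-side frame)
limb_truth <- function(spec) {
  ly <- limb_layout(spec)
  list(
    head_center = c(y = 0, x = 0),
    neck_center = c(y = unname(ly$neck_off * ly$u_n["y"]),
                    x = unname(ly$neck_off * ly$u_n["x"])),
    neck_axis_angle_deg = ly$neck_axis,
    condylar_angle_deg = wrap_angle(spec$condylar_angle_deg),
    tibial_plateau_angle_deg = wrap_angle(spec$tibial_plateau_angle_deg),
    ankle_axis_angle_deg = ly$ankle_axis,
    femoral_torsion_deg = wrap_angle(spec$femoral_torsion_deg),
    tibial_torsion_deg = wrap_angle(spec$tibial_torsion_deg),
    designated_slices = list(
      head = ly$z_head, neck = ly$z_neck,
      femoral_condyle = ly$z_cond[ceiling(length(ly$z_cond) / 2)],
      tibial_plateau = ly$z_plat[ceiling(length(ly$z_plat) / 2)],
      distal_tibia = ceiling(ly$nza / 2))
  )
}

# ---- limb generation ---------------------------------------------------

#' Generate one synthetic limb: hip, knee, and ankle stacks plus truth
#'
#' Produces three axial stacks with integer label maps (femur = 1,
#' tibia = 2, fibula = 3) and a ground-truth record of every landmark and
#' angle. The femur appears in the hip and knee stacks; tibia and fibula
#' appear in the knee and ankle stacks. Geometry that does not fit the
#' field of view raises an error naming the offending primitive.
#'
#' @param spec a [limb_spec()].
#' @return a list with elements `hip`, `knee`, `ankle` (each a list of
#'   `image` and `labels`), and `truth` (see Details).
#' @details The `truth` element contains the head and neck centres (mm, in
#'   the canonical right-side frame), all reference-line angles, both
#'   torsion angles, and `designated_slices` (1-based z indices for the
#'   head, neck, femoral-condyle, tibial-plateau, and distal-tibia
#'   levels), which let geometry tests bypass automatic slice selection.
#' @export
generate_limb <- function(spec) {
  stopifnot(inherits(spec, "limb_spec"))
  sp <- spec$spacing_mm
  dz <- sp[1]; dy <- sp[2]; dx <- sp[3]
  ly <- limb_layout(spec)
  neck_axis <- ly$neck_axis
  ankle_axis <- ly$ankle_axis

  ## --- hip stack: head sphere + oblique neck cylinder + shaft ----------
  sh <- spec$stack_shape$hip
  nz <- sh[1]; ny <- sh[2]; nx <- sh[3]
  g <- plane_grid(ny, nx, dy, dx)
  half_fov <- min((ny - 1) / 2 * dy, (nx - 1) / 2 * dx)
  rh <- spec$head_radius_mm; rn <- spec$neck_radius_mm
  z_head <- ly$z_head
  z_neck <- ly$z_neck
  check_fov(rh, half_fov, "femoral head")
  if (z_neck + 1L > nz) {
    abort("phantom geometry exceeds the field of view: femoral neck needs %d slices, stack has %d",
          z_neck + 1L, nz)
  }
  drift <- ly$drift
  u_n <- ly$u_n
  neck_off <- ly$neck_off
  check_fov(neck_off + rn, half_fov, "femoral neck")

  hip_lab <- array(0L, c(nz, ny, nx))
  for (iz in seq_len(nz)) {
    m <- matrix(FALSE, ny, nx)
    zoff <- (iz - z_head) * dz
    if (abs(zoff) < rh) {                      # head sphere cross-section
      m <- m | raster_disc(g, 0, 0, sqrt(rh^2 - zoff^2))
    }
    if (iz >= z_head) {                        # neck / shaft along the axis
      d <- drift * zoff
      r <- if (iz > z_neck) spec$shaft_radius_mm else rn
      m <- m | raster_disc(g, d * u_n["y"], d * u_n["x"], r)
    }
    hip_lab[iz, , ][m] <- 1L
  }

  ## --- knee stack: condylar lobes (femur), plateau lobes + fibula ------
  sk <- spec$stack_shape$knee
  nzk <- sk[1]; nyk <- sk[2]; nxk <- sk[3]
  gk <- plane_grid(nyk, nxk, dy, dx)
  half_fov_k <- min((nyk - 1) / 2 * dy, (nxk - 1) / 2 * dx)
  D_cond <- 36
  rc <- spec$condyle_radius_mm
  cc <- lobe_centres(spec$condylar_angle_deg, D_cond, rc[1], rc[2])
  check_fov(D_cond / 2 + max(rc), half_fov_k, "femoral condyles")
  pc <- lobe_centres(spec$tibial_plateau_angle_deg, D_cond, rc[1], rc[2])
  fib_knee <- c(x = -36, y = 12)  # lateral (canonical right = -x) fibular head
  check_fov(sqrt(sum(fib_knee^2)) + spec$fibula_radius_mm, half_fov_k,
            "fibular head")
  z_cond <- ly$z_cond
  z_plat <- ly$z_plat
  knee_lab <- array(0L, c(nzk, nyk, nxk))
  cond_m <- raster_disc(gk, cc$A["y"], cc$A["x"], rc[1]) |
    raster_disc(gk, cc$B["y"], cc$B["x"], rc[2])
  plat_m <- raster_disc(gk, pc$A["y"], pc$A["x"], rc[1]) |
    raster_disc(gk, pc$B["y"], pc$B["x"], rc[2])
  fib_m <- raster_disc(gk, fib_knee["y"], fib_knee["x"], spec$fibula_radius_mm)
  if (any(plat_m & fib_m)) abort("phantom geometry exceeds the field of view: fibular head overlaps tibial plateau")
  for (iz in z_cond) knee_lab[iz, , ][cond_m] <- 1L
  for (iz in z_plat) {
    knee_lab[iz, , ][plat_m] <- 2L
    knee_lab[iz, , ][fib_m] <- 3L
  }

  ## --- ankle stack: distal tibial ellipse + fibula along the axis ------
  sa <- spec$stack_shape$ankle
  nza <- sa[1]; nya <- sa[2]; nxa <- sa[3]
  ga <- plane_grid(nya, nxa, dy, dx)
  half_fov_a <- min((nya - 1) / 2 * dy, (nxa - 1) / 2 * dx)
  D_tf <- 30
  u_a <- unit_xy(ankle_axis)
  # fibula on the lateral (-x) end of the axis
  sgn <- if (u_a["x"] >= 0) 1 else -1
  tib_c <- sgn * D_tf / 2 * u_a
  fib_c <- -sgn * D_tf / 2 * u_a
  check_fov(D_tf / 2 + max(spec$tibia_radius_mm), half_fov_a, "distal tibia")
  ankle_lab <- array(0L, c(nza, nya, nxa))
  tib_m <- raster_ellipse(ga, tib_c["y"], tib_c["x"],
                          spec$tibia_radius_mm[1], spec$tibia_radius_mm[2],
                          ankle_axis)
  fib_ma <- raster_disc(ga, fib_c["y"], fib_c["x"], spec$fibula_radius_mm)
  for (iz in seq_len(nza)) {
    ankle_lab[iz, , ][tib_m] <- 2L
    ankle_lab[iz, , ][fib_ma] <- 3L
  }

  ## --- truth (canonical right-side frame) ------------------------------
  truth <- limb_truth(spec)

  mirror_x <- function(a) a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  if (spec$side == "left") {
    hip_lab <- mirror_x(hip_lab); knee_lab <- mirror_x(knee_lab)
    ankle_lab <- mirror_x(ankle_lab)
  }

  mk <- function(lab, joint) {
    ls <- label_stack(lab, sp, joint, spec$side)
    list(image = t2_intensity_model(ls, spec), labels = ls)
  }
  list(hip = mk(hip_lab, "hip"),
       knee = mk(knee_lab, "knee"),
       ankle = mk(ankle_lab, "ankle"),
       truth = truth)
}

#' Render T2-like intensities from a label map
#'
#' Emulates T2-weighted non-fat-saturated contrast: bright bone marrow, a
#' dark one-voxel cortical rim around each bone, and an intermediate
#' background, plus seeded Gaussian texture. Values are clipped at zero.
#'
#' @param labels a `label_stack`.
#' @param spec a [limb_spec()] supplying `tissue_means`, `texture_sd`, and
#'   the texture `seed`.
#' @return an `image_stack` congruent with `labels`.
#' @export
t2_intensity_model <- function(labels, spec) {
  stopifnot(inherits(labels, "label_stack"), inherits(spec, "limb_spec"))
  lab <- labels$labels
  if (!all(lab %in% 0:3)) abort("t2_intensity_model: unknown label code")
  tm <- spec$tissue_means
  vals <- array(tm[["background"]], dim(lab))
  bone <- lab > 0L
  vals[bone] <- tm[["marrow"]]
  # cortical rim: in-plane boundary voxels of the bone mask
  nz <- dim(lab)[1]
  for (iz in seq_len(nz)) {
    m <- bone[iz, , ]
    if (!any(m)) next
    er <- EBImage::erode(m + 0, EBImage::makeBrush(3, "box")) > 0.5
    vals[iz, , ][m & !er] <- tm[["cortex"]]
  }
  if (spec$texture_sd > 0) {
    vals <- vals + withr::with_seed(
      derive_seed(spec$seed, paste0("texture-", labels$joint, "-", labels$side)),
      array(stats::rnorm(length(vals), 0, spec$texture_sd), dim(vals)))
  }
  vals[vals < 0] <- 0
  image_stack(vals, labels$spacing, labels$joint, labels$side)
}

#' Generate a synthetic cohort
#'
#' Draws `n_participants` limb specifications by jittering a base
#' specification within uniform ranges, and rasterises one clean
#' ("reference") set of stacks per limb. Artifact corruption of the
#' planned severity conditions is applied downstream (see
#' [severity_to_params()] and [sample_mri_specific()]); the plan is
#' recorded here so that a cohort fully determines the experiment.
#'
#' @param n_participants number of participants (>= 1).
#' @param severity_plan character vector of severity conditions per
#'   participant, e.g. `c("none", "mild", "moderate", "severe")`.
#' @param base_spec a [limb_spec()] used as template.
#' @param jitter named list of `c(lo, hi)` uniform ranges overriding the
#'   template fields `femoral_torsion_deg`, `tibial_torsion_deg`,
#'   `condylar_angle_deg`, `tibial_plateau_angle_deg`. Zero-width ranges
#'   give identical participants.
#' @param sides which sides to generate per participant.
#' @param rasterize if `FALSE`, only specifications and analytic truth
#'   are produced (no image/label volumes) — useful for statistical
#'   checks on the sampled parameters.
#' @param seed master seed; every draw is derived from it.
#' @return a list of participants; each has `id`, `severity_plan`, and one
#'   entry per side holding `spec`, the clean `hip`/`knee`/`ankle` stacks,
#'   and `truth`.
#' @export
generate_cohort <- function(n_participants,
                            severity_plan = c("none", "mild", "moderate", "severe"),
                            base_spec = limb_spec(),
                            jitter = list(femoral_torsion_deg = c(0, 30),
                                          tibial_torsion_deg = c(20, 50),
                                          condylar_angle_deg = c(-5, 5),
                                          tibial_plateau_angle_deg = c(-5, 5)),
                            sides = "right",
                            rasterize = TRUE,
                            seed = 1L) {
  if (n_participants < 1) abort("generate_cohort: n_participants must be >= 1")
  if (length(severity_plan) == 0) abort("generate_cohort: empty severity_plan")
  bad <- setdiff(severity_plan, c("none", "mild", "moderate", "severe"))
  if (length(bad)) abort("generate_cohort: unknown severity '%s'", bad[1])
  sides <- match.arg(sides, c("right", "left"), several.ok = TRUE)
  lapply(seq_len(n_participants), function(i) {
    p <- list(id = sprintf("P%03d", i), severity_plan = severity_plan)
    for (sd in sides) {
      spec_i <- base_spec
      ds <- derive_seed(seed, sprintf("participant-%d-%s", i, sd))
      draws <- withr::with_seed(ds, {
        vapply(names(jitter), function(f) {
          r <- jitter[[f]]
          stats::runif(1, r[1], r[2])
        }, numeric(1))
      })
      for (f in names(draws)) spec_i[[f]] <- unname(draws[[f]])
      spec_i$side <- sd
      spec_i$seed <- derive_seed(ds, "texture")
      p[[sd]] <- if (rasterize) {
        c(generate_limb(spec_i), list(spec = spec_i))
      } else {
        list(truth = limb_truth(spec_i), spec = spec_i)
      }
    }
    p
  })
}
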