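# Landmark extraction and torsion quantification.
#
# Femoral torsion follows the Lee construction: the proximal reference
# line runs through the least-squares circle centres of the femoral head
# and neck; the distal reference is the posterior condylar tangent.
# Tibial torsion follows the Ulm construction: proximal posterior tibial
# tangent vs. the line through the centroids of distal tibia and fibula.
# All angles are undirected line angles in (-90, 90] degrees, CCW from
# +x; positive torsion means anteversion. Left limbs are mirrored in x
# before any angle is computed, so the sign convention holds bilaterally.

#' Least-squares circle fit
#'
#' Fits a circle to planar points by least squares on the radial
#' residual: the algebraic (Kasa) fit — linear least squares on
#' `x^2 + y^2 - 2 a x - 2 b y - c` — provides the starting point, which
#' is then refined to the minimiser of the geometric residual
#' `sum((d_i - r)^2)` (for a fixed centre the optimal radius is the mean
#' point distance). `rms_residual` is the root-mean-square distance of
#' the points from the fitted circle.
#'
#' @param points n x 2 matrix of (y, x) coordinates in mm, n >= 3,
#'   not collinear.
#' @return an object of class `circle_fit` with fields `center` (y, x),
#'   `radius`, `rms_residual`, `n_points`.
#' @export
fit_circle <- function(points) {
  pts <- matrix(as.numeric(points), ncol = 2)
  if (nrow(pts) < 3) abort("fit_circle: need at least 3 points")
  y <- pts[, 1]; x <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) abort("fit_circle: points are collinear")
  sol <- qr.coef(qrA, b)
  cx <- sol[1]; cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  if (r2 <= 0) abort("fit_circle: degenerate fit")
  # geometric refinement from the algebraic start
  obj <- function(ctr) {
    d <- sqrt((y - ctr[1])^2 + (x - ctr[2])^2)
    sum((d - mean(d))^2)
  }
  opt <- stats::optim(c(cy, cx), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  cy <- opt$par[1]; cx <- opt$par[2]
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  r <- mean(d)
  structure(list(center = c(y = unname(cy), x = unname(cx)),
                 radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2)),
                 n_points = nrow(pts)),
            class = "circle_fit")
}

#' An undirected 2D reference line
#'
#' @param angle_deg line orientation in degrees (wrapped into (-90, 90]).
#' @param anchor a point (y, x) in mm on the line.
#' @return an object of class `line2d`.
#' @export
line2d <- function(angle_deg, anchor = c(y = 0, x = 0)) {
  structure(list(angle_deg = unname(wrap_angle(angle_deg)),
                 anchor = c(y = unname(anchor[1]), x = unname(anchor[2]))),
            class = "line2d")
}

#' Signed difference between two reference-line angles
#'
#' @param proximal,distal `line2d` objects (or plain angles in degrees).
#' @return `proximal - distal` wrapped into (-90, 90] degrees.
#' @export
line_angle_diff <- function(proximal, distal) {
  a <- if (inherits(proximal, "line2d")) proximal$angle_deg else proximal
  b <- if (inherits(distal, "line2d")) distal$angle_deg else distal
  wrap_angle(a - b)
}

# outer-contour pixel centres of a binary slice, in mm (8-connectivity:
# a boundary pixel is a mask pixel removed by 3x3 box erosion)
mask_boundary_points <- function(mask, spacing_yx) {
  m <- mask > 0
  if (!any(m)) return(matrix(numeric(0), ncol = 2))
  er <- EBImage::erode(m + 0, EBImage::makeBrush(3, "box")) > 0.5
  idx <- which(m & !er, arr.ind = TRUE)
  cbind(y = (idx[, 1] - 1) * spacing_yx[1],
        x = (idx[, 2] - 1) * spacing_yx[2])
}

# connected components of a binary slice (8-connectivity), largest first
slice_components <- function(mask) {
  lab <- EBImage::bwlabel(mask > 0)
  n <- max(lab)
  if (n == 0) return(list())
  comps <- lapply(seq_len(n), function(i) lab == i)
  comps[order(vapply(comps, sum, numeric(1)), decreasing = TRUE)]
}

#' Posterior tangent of the two condylar lobes
#'
#' Finds the unique line touching both condyles from posterior (+y) with
#' every mask pixel on its anterior side. Implemented as the posterior
#' convex-hull edge spanning both components, which is equivalent to
#' advancing a line anteriorly until first contact with both lobes; the
#' equivalence with an explicit rotating-line search is exercised in the
#' tests rather than at run time.
#'
#' @param mask_slice binary (y, x) matrix of the condylar mask.
#' @param spacing_yx (dy, dx) in mm.
#' @param split_if_merged if `TRUE` and the mask is a single connected
#'   component, it is split by the vertical line through its centroid
#'   (condylar lobes can merge at coarse spacing); otherwise a single
#'   component is an error.
#' @return a `line2d` with attributes `contacts` (the two tangent points,
#'   mm).
#' @export
posterior_tangent <- function(mask_slice, spacing_yx = c(1, 1),
                              split_if_merged = FALSE) {
  comps <- slice_components(mask_slice)
  if (length(comps) == 0) abort("posterior tangent: empty mask")
  if (length(comps) < 2) {
    if (!split_if_merged) abort("posterior tangent: condyles not separable (single component)")
    m <- comps[[1]]
    idx <- which(m, arr.ind = TRUE)
    cx <- mean(idx[, 2])
    left <- m; left[, seq_len(ncol(m)) > cx] <- FALSE
    right <- m; right[, seq_len(ncol(m)) <= cx] <- FALSE
    if (!any(left) || !any(right)) {
      abort("posterior tangent: condyles not separable (single component)")
    }
    comps <- list(left, right)
  }
  p1 <- mask_boundary_points(comps[[1]], spacing_yx)
  p2 <- mask_boundary_points(comps[[2]], spacing_yx)
  pts <- rbind(p1, p2)
  grp <- rep(1:2, c(nrow(p1), nrow(p2)))
  hull <- grDevices::chull(pts[, 2], pts[, 1])   # (x, y) order
  nh <- length(hull)
  ctr <- colMeans(pts)
  best <- NULL; best_ny <- -Inf
  for (i in seq_len(nh)) {
    a <- hull[i]; b <- hull[if (i == nh) 1L else i + 1L]
    if (grp[a] == grp[b]) next
    dvec <- pts[b, ] - pts[a, ]                   # (dy, dx)
    len <- sqrt(sum(dvec^2))
    if (len == 0) next
    nrm <- c(dvec[2], -dvec[1]) / len             # normal (ny, nx)
    mid <- (pts[a, ] + pts[b, ]) / 2
    if (sum(nrm * (mid - ctr)) < 0) nrm <- -nrm   # outward
    if (nrm[1] > best_ny) {                       # most posterior-facing
      best_ny <- nrm[1]
      best <- list(a = pts[a, ], b = pts[b, ], d = dvec)
    }
  }
  if (is.null(best) || best_ny <= 0) {
    abort("posterior tangent: tangent contact within one component only")
  }
  ln <- line2d(rad2deg(atan2(best$d[1], best$d[2])),
               anchor = (best$a + best$b) / 2)
  attr(ln, "contacts") <- rbind(best$a, best$b)
  ln
}

#' Line through the centroids of two masks
#'
#' Used for the distal tibio-fibular axis: the centres of the distal
#' tibia and fibula are the pixel centroids of their segmentation masks.
#'
#' @param mask_a_slice,mask_b_slice binary (y, x) matrices.
#' @param spacing_yx (dy, dx) in mm.
#' @param names bone names used in error messages, in order (a, b).
#' @return a `line2d` anchored at the first centroid, with attribute
#'   `centroids`.
#' @export
centroid_line <- function(mask_a_slice, mask_b_slice, spacing_yx = c(1, 1),
                          names = c("tibia", "fibula")) {
  cent <- function(m, nm) {
    if (!any(m > 0)) abort("centroid line: empty mask: %s", nm)
    idx <- which(m > 0, arr.ind = TRUE)
    c(y = (mean(idx[, 1]) - 1) * spacing_yx[1],
      x = (mean(idx[, 2]) - 1) * spacing_yx[2])
  }
  ca <- cent(mask_a_slice, names[1])
  cb <- cent(mask_b_slice, names[2])
  ln <- line2d(rad2deg(atan2(cb[1] - ca[1], cb[2] - ca[2])), anchor = ca)
  attr(ln, "centroids") <- rbind(ca, cb)
  ln
}

# ---- slice selection and side handling ---------------------------------

# mirror a (z, y, x) volume in x; applied to left limbs so that positive
# torsion means anteversion on both sides
mirror_left <- function(vol, side) {
  if (side == "left") vol[, , rev(seq_len(dim(vol)[3])), drop = FALSE] else vol
}

slice_areas <- function(vol, code) {
  apply(vol == code, 1, sum)
}

# head slice: maximal femur area; neck slice: minimal femur area distal
# to the head among slices with > 25% of the head-slice area
select_hip_slices <- function(femur_areas) {
  if (all(femur_areas == 0)) abort("head fit: empty mask")
  z_head <- which.max(femur_areas)
  distal <- femur_areas
  distal[seq_len(z_head)] <- NA
  distal[distal <= 0.25 * femur_areas[z_head]] <- NA
  if (all(is.na(distal))) abort("neck fit: no eligible neck slice")
  z_neck <- which.min(distal)
  list(head = z_head, neck = z_neck)
}

circle_center_at <- function(vol, code, iz, spacing_yx, what) {
  m <- vol[iz, , ] == code
  if (!any(m)) abort("%s: empty mask", what)
  pts <- mask_boundary_points(m, spacing_yx)
  tryCatch(fit_circle(pts),
           error = function(e) abort("%s: %s", what, conditionMessage(e)))
}

#' Femoral torsion by the Lee method
#'
#' Proximal reference: the line through the least-squares circle centres
#' of the femoral head (hip slice of maximal femur area, or the provided
#' hint) and neck (most distal-tapering slice, see
#' [posterior_tangent()] for the distal construction). Distal reference:
#' the posterior condylar tangent on the knee slice of maximal femur
#' area. Torsion is the wrapped angle difference, positive = anteversion.
#'
#' @param hip,knee `label_stack`s containing the femur (code 1).
#' @param side "right" or "left"; defaults to the stacks' side. Left
#'   limbs are mirrored in x before measurement.
#' @param slice_hints optional list with `head`, `neck`,
#'   `femoral_condyle` (1-based z indices), e.g. the phantom's
#'   `designated_slices`, bypassing automatic slice selection.
#' @return list with `angle` (degrees) and `landmarks` (head/neck circle
#'   fits, neck axis and condylar tangent `line2d`s, slice indices).
#' @export
femoral_torsion <- function(hip, knee, side = hip$side, slice_hints = NULL) {
  stopifnot(inherits(hip, "label_stack"), inherits(knee, "label_stack"))
  sp <- hip$spacing[2:3]
  hv <- mirror_left(hip$labels, side)
  kv <- mirror_left(knee$labels, side)
  areas <- slice_areas(hv, 1L)
  if (!is.null(slice_hints$head) && !is.null(slice_hints$neck)) {
    zs <- list(head = slice_hints$head, neck = slice_hints$neck)
  } else {
    zs <- select_hip_slices(areas)
  }
  head_fit <- circle_center_at(hv, 1L, zs$head, sp, "head fit")
  neck_fit <- circle_center_at(hv, 1L, zs$neck, sp, "neck fit")
  d <- neck_fit$center - head_fit$center
  if (sqrt(sum(d^2)) < 1e-6) abort("neck axis: head and neck centers coincide")
  neck_axis <- line2d(rad2deg(atan2(d[1], d[2])), anchor = head_fit$center)
  k_areas <- slice_areas(kv, 1L)
  z_cond <- if (!is.null(slice_hints$femoral_condyle)) slice_hints$femoral_condyle
            else which.max(k_areas)
  if (k_areas[z_cond] == 0) abort("condylar tangent: empty mask")
  cond <- posterior_tangent(kv[z_cond, , ] == 1L, knee$spacing[2:3],
                            split_if_merged = TRUE)
  list(angle = line_angle_diff(neck_axis, cond),
       landmarks = list(head_fit = head_fit, neck_fit = neck_fit,
                        neck_axis = neck_axis, condylar_tangent = cond,
                        slices = c(head = zs$head, neck = zs$neck,
                                   femoral_condyle = z_cond)))
}

#' Tibial torsion by the Ulm method
#'
#' Proximal reference: posterior tangent of the tibial plateau on the
#' knee slice of maximal tibia area. Distal reference: the line through
#' the centroids of the distal tibia and fibula on the ankle slice of
#' maximal tibia area. Torsion is the wrapped angle difference.
#'
#' @param knee,ankle `label_stack`s; tibia (2) in both, fibula (3) in the
#'   ankle stack.
#' @inheritParams femoral_torsion
#' @param slice_hints optional list with `tibial_plateau`,
#'   `distal_tibia` z indices.
#' @return list with `angle` and `landmarks`.
#' @export
tibial_torsion <- function(knee, ankle, side = knee$side, slice_hints = NULL) {
  stopifnot(inherits(knee, "label_stack"), inherits(ankle, "label_stack"))
  kv <- mirror_left(knee$labels, side)
  av <- mirror_left(ankle$labels, side)
  k_areas <- slice_areas(kv, 2L)
  z_plat <- if (!is.null(slice_hints$tibial_plateau)) slice_hints$tibial_plateau
            else which.max(k_areas)
  if (k_areas[z_plat] == 0) abort("plateau tangent: empty mask: tibia")
  plat <- posterior_tangent(kv[z_plat, , ] == 2L, knee$spacing[2:3],
                            split_if_merged = TRUE)
  a_areas <- slice_areas(av, 2L)
  z_dist <- if (!is.null(slice_hints$distal_tibia)) slice_hints$distal_tibia
            else which.max(a_areas)
  axis <- centroid_line(av[z_dist, , ] == 2L, av[z_dist, , ] == 3L,
                        ankle$spacing[2:3], names = c("tibia", "fibula"))
  list(angle = line_angle_diff(plat, axis),
       landmarks = list(plateau_tangent = plat, tibiofibular_axis = axis,
                        slices = c(tibial_plateau = z_plat,
                                   distal_tibia = z_dist)))
}

#' Measure both torsion angles of one limb
#'
#' Attempts femoral and tibial torsion; never raises. `success` is `TRUE`
#' iff both angles were computed — the same success semantics used for
#' the completed-measurement rate tables — and every failure is captured
#' in `failure_reason`.
#'
#' @param hip,knee,ankle `label_stack`s of the limb.
#' @inheritParams femoral_torsion
#' @param slice_hints optional, passed to both measurements.
#' @return an object of class `torsion_result`: `success`,
#'   `femoral_torsion_deg`, `tibial_torsion_deg` (NA on failure),
#'   `landmarks`, `failure_reason`.
#' @export
measure_limb <- function(hip, knee, ankle, side = hip$side,
                         slice_hints = NULL) {
  reasons <- character(0)
  fem <- tryCatch(femoral_torsion(hip, knee, side, slice_hints),
                  error = function(e) {
                    reasons <<- c(reasons, paste0("femoral: ", conditionMessage(e)))
                    NULL
                  })
  tib <- tryCatch(tibial_torsion(knee, ankle, side, slice_hints),
                  error = function(e) {
                    reasons <<- c(reasons, paste0("tibial: ", conditionMessage(e)))
                    NULL
                  })
  structure(list(
    success = !is.null(fem) && !is.null(tib),
    femoral_torsion_deg = if (!is.null(fem)) fem$angle else NA_real_,
    tibial_torsion_deg = if (!is.null(tib)) tib$angle else NA_real_,
    landmarks = list(femoral = if (!is.null(fem)) fem$landmarks,
                     tibial = if (!is.null(tib)) tib$landmarks),
    failure_reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_
  ), class = "torsion_result")
}

#' @exportS3Method base::print
print.torsion_result <- function(x, ...) {
  cat(sprintf("<torsion_result> success=%s femoral=%.2f tibial=%.2f%s\n",
              x$success, x$femoral_torsion_deg, x$tibial_torsion_deg,
              if (!is.na(x$failure_reason)) paste0("  [", x$failure_reason, "]") else ""))
  invisible(x)
}
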