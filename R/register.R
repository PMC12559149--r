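# Slice-wise 2D similarity registration by mutual-information ascent.
#
# Used for ankle stacks whose slices were displaced by through-plane
# motion: each corrupted slice is registered back to the corresponding
# reference slice with a similarity transform (rotation, isotropic
# scale, translation) found by regular-step gradient ascent on the
# joint-histogram mutual information.

#' A 2D similarity transform
#'
#' Rotation (degrees, CCW about the slice centre), isotropic scale, and
#' translation in mm `(ty, tx)`.
#'
#' @param rotation_deg rotation angle in degrees.
#' @param scale isotropic scale factor, > 0.
#' @param translation_mm length-2 translation (ty, tx) in mm.
#' @return an object of class `similarity2d`.
#' @export
similarity2d <- function(rotation_deg = 0, scale = 1, translation_mm = c(0, 0)) {
  if (scale <= 0) abort("similarity2d: scale must be > 0")
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 translation_mm = as.numeric(translation_mm)),
            class = "similarity2d")
}

#' @rdname similarity2d
#' @param t,a,b `similarity2d` objects.
#' @return `invert_similarity` and `compose_similarity` return
#'   `similarity2d` objects; composing a transform with its inverse gives
#'   the identity to within numerical precision on the parameters.
#' @export
invert_similarity <- function(t) {
  th <- deg2rad(-t$rotation_deg)
  tx <- t$translation_mm[2]; ty <- t$translation_mm[1]
  rx <- cos(th) * tx - sin(th) * ty
  ry <- sin(th) * tx + cos(th) * ty
  similarity2d(-t$rotation_deg, 1 / t$scale, c(-ry, -rx) / t$scale)
}

#' @rdname similarity2d
#' @export
compose_similarity <- function(b, a) {
  # (b o a): apply a first, then b
  th <- deg2rad(b$rotation_deg)
  ax <- a$translation_mm[2]; ay <- a$translation_mm[1]
  rx <- cos(th) * ax - sin(th) * ay
  ry <- sin(th) * ax + cos(th) * ay
  similarity2d(a$rotation_deg + b$rotation_deg, a$scale * b$scale,
               c(b$scale * ry + b$translation_mm[1],
                 b$scale * rx + b$translation_mm[2]))
}

#' Apply a similarity transform to a slice
#'
#' Resamples with bilinear interpolation (nearest-neighbour on request,
#' e.g. for label slices) about the slice centre; the identity transform
#' returns the input exactly.
#'
#' @param slice 2D (y, x) matrix.
#' @param t a [similarity2d()].
#' @param spacing_yx (dy, dx) in mm, converting the translation.
#' @param interp "linear" or "nearest".
#' @return the resampled slice.
#' @export
apply_similarity <- function(slice, t, spacing_yx = c(1, 1),
                             interp = "linear") {
  warp_slice(slice, t$rotation_deg, t$scale,
             t$translation_mm / spacing_yx, interp = interp)
}

#' Mutual information of two images
#'
#' Joint-histogram mutual information in nats. Intensities are clipped
#' to their 1st-99th percentiles before binning (robustness to artifact
#' outliers). A constant image yields MI = 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b congruent 2D arrays.
#' @param bins number of histogram bins per image (>= 2), default 32.
#' @return a non-negative scalar (nats), attribute `degenerate` flags a
#'   constant input.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  if (!identical(dim(a), dim(b))) abort("mutual_information: shape mismatch")
  if (bins < 2) abort("mutual_information: bins must be >= 2")
  bin_idx <- function(x) {
    q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
    if (q[2] <= q[1]) return(NULL)
    x <- pmin(pmax(x, q[1]), q[2])
    i <- floor((x - q[1]) / (q[2] - q[1]) * bins) + 1
    pmin(i, bins)
  }
  ia <- bin_idx(as.vector(a)); ib <- bin_idx(as.vector(b))
  if (is.null(ia) || is.null(ib)) {
    return(structure(0, degenerate = TRUE))
  }
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(ia)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  structure(max(mi, 0), degenerate = FALSE)
}

# marginal histogram entropy with the same binning (nats)
marginal_entropy <- function(a, bins = 32L) {
  mutual_information(a, a, bins)
}

#' Register each slice of a moving stack to a fixed stack
#'
#' Per slice, finds the [similarity2d()] maximizing mutual information
#' via regular-step gradient ascent: a finite-difference gradient in
#' scaled parameter space, step length halved whenever the gradient
#' direction reverses, stopping when the step falls below
#' `step_tolerance` or after `max_iterations`. A coarse integer-shift
#' search initializes the translation. If the optimized transform does
#' not improve MI the identity is returned for that slice and the slice
#' is marked not converged; a non-finite MI aborts that slice with a
#' status, never the stack.
#'
#' @param moving,fixed congruent `image_stack`s.
#' @param options list: `step_init` (initial step, px/deg units, 2),
#'   `step_tolerance` (0.05), `max_iterations` (200), `bins` (32),
#'   `coarse_range_px` (10), `coarse_step_px` (2), `with_scale`
#'   (optimize the scale parameter, default TRUE).
#' @return list with `transforms` (per-slice `similarity2d`),
#'   `registered` (`image_stack`), and `status` (character per slice:
#'   "converged", "not_converged", "degenerate", or "aborted").
#' @export
register_slices <- function(moving, fixed, options = list()) {
  check_congruent(moving, fixed)
  opt <- utils::modifyList(list(step_init = 2, step_tolerance = 0.05,
                                max_iterations = 200L, bins = 32L,
                                coarse_range_px = 10L, coarse_step_px = 2L,
                                coarse_rot_deg = 12, coarse_rot_step = 2,
                                with_scale = TRUE), options)
  sp <- moving$spacing[2:3]
  nz <- dim(moving$values)[1]
  transforms <- vector("list", nz)
  status <- character(nz)
  reg <- moving$values
  for (iz in seq_len(nz)) {
    res <- register_one_slice(moving$values[iz, , ], fixed$values[iz, , ],
                              opt)
    transforms[[iz]] <- similarity2d(res$par[1], res$par[4],
                                     res$par[2:3] * sp)
    status[iz] <- res$status
    reg[iz, , ] <- apply_similarity(moving$values[iz, , ], transforms[[iz]], sp)
  }
  out <- moving
  out$values <- reg
  list(transforms = transforms, registered = out, status = status)
}

# par = (rotation_deg, ty_px, tx_px, scale)
register_one_slice <- function(mov, fix, opt) {
  identity_par <- c(0, 0, 0, 1)
  mi_at <- function(par) {
    w <- warp_slice(mov, par[1], par[4], par[2:3])
    as.numeric(mutual_information(w, fix, opt$bins))
  }
  mi0 <- mutual_information(mov, fix, opt$bins)
  if (isTRUE(attr(mi0, "degenerate"))) {
    return(list(par = identity_par, status = "degenerate"))
  }
  if (opt$max_iterations < 1) {
    return(list(par = identity_par, status = "not_converged"))
  }
  # coarse initialization: alternate shift and rotation grids
  best <- identity_par; best_mi <- as.numeric(mi0)
  try_par <- function(p) {
    m <- mi_at(p)
    if (is.finite(m) && m > best_mi) { best_mi <<- m; best <<- p }
  }
  shifts <- seq(-opt$coarse_range_px, opt$coarse_range_px, opt$coarse_step_px)
  rots <- seq(-opt$coarse_rot_deg, opt$coarse_rot_deg, opt$coarse_rot_step)
  for (r in rots) for (ty in shifts) for (tx in shifts) try_par(c(r, ty, tx, 1))
  for (ty in best[2] + seq(-2, 2)) for (tx in best[3] + seq(-2, 2)) {
    try_par(c(best[1], ty, tx, 1))
  }
  for (r in best[1] + seq(-2, 2, 0.5)) try_par(c(r, best[2], best[3], 1))
  par <- best
  # parameter scaling: one step unit = 1 deg, 1 px, 1 px, 0.005 scale
  unit <- c(1, 1, 1, if (isTRUE(opt$with_scale)) 0.005 else 0)
  step <- opt$step_init
  g_prev <- NULL
  converged <- FALSE
  for (it in seq_len(opt$max_iterations)) {
    eps <- pmax(step, 0.25) * unit / 2
    g <- numeric(4)
    for (j in 1:4) {
      if (unit[j] == 0) next
      dp <- numeric(4); dp[j] <- eps[j]
      hi <- mi_at(par + dp); lo <- mi_at(par - dp)
      if (!is.finite(hi) || !is.finite(lo)) {
        return(list(par = identity_par, status = "aborted"))
      }
      g[j] <- (hi - lo) / (2 * eps[j])
    }
    gn <- sqrt(sum((g * unit)^2))
    if (gn == 0) { converged <- TRUE; break }
    dirn <- g * unit^2 / gn
    if (!is.null(g_prev) && sum(g * g_prev) < 0) step <- step / 2
    if (step < opt$step_tolerance) { converged <- TRUE; break }
    cand <- par + step * dirn
    mi_c <- mi_at(cand)
    if (!is.finite(mi_c)) return(list(par = identity_par, status = "aborted"))
    if (mi_c > best_mi) { best_mi <- mi_c; best <- cand; par <- cand }
    else { par <- cand }
    g_prev <- g
  }
  # never accept a transform that does not improve MI over the identity
  if (best_mi < as.numeric(mi0)) {
    return(list(par = identity_par, status = "not_converged"))
  }
  list(par = best, status = if (converged) "converged" else "not_converged")
}
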