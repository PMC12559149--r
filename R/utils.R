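#' Wrap an undirected line angle into (-90, 90]
#'
#' Axial reference lines are undirected, so their orientation is defined
#' modulo 180 degrees. All angles in the package are reported in the
#' half-open interval (-90, 90] degrees, measured counterclockwise from +x.
#'
#' @param angle_deg numeric vector of angles in degrees.
#' @return numeric vector wrapped into (-90, 90].
#' @export
#' @examples
#' wrap_angle(c(95, -170, 90, 180))
wrap_angle <- function(angle_deg) {
  r <- angle_deg %% 180
  r[r > 90] <- r[r > 90] - 180
  r
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministically maps (master seed, label) to a 31-bit integer so that
#' every stochastic stage of the pipeline gets its own reproducible stream.
#'
#' @param seed master seed (integer).
#' @param tag character label of the stage.
#' @return a single integer in [0, 2^31 - 1].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(paste(tag, collapse = ""))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# internal: stop with a formatted message
abort <- function(...) stop(sprintf(...), call. = FALSE)

# internal: check a scalar flag
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# internal: degrees <-> radians
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
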