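# shared fixtures, built in code

# geometry-validation phantom: 0.6 mm in-plane (the resolution the 2-degree
# torsion recovery tolerance is stated at)
hires_spec <- function(...) limb_spec(...)

# coarser desk-scale phantom used where many stacks are needed
desk_spec <- function(...) {
  limb_spec(spacing_mm = c(3.0, 1.2, 1.2),
            stack_shape = list(hip = c(14L, 96L, 96L),
                               knee = c(12L, 96L, 96L),
                               ankle = c(10L, 64L, 64L)),
            ...)
}

desk_config <- function(...) {
  experiment_config(base_spec = desk_spec(), ...)
}

# tiny image for high-iteration sampler draws (seed set by the caller)
tiny_image <- function() {
  image_stack(array(stats::runif(64), c(1, 8, 8)), c(1, 1, 1), "hip", "right")
}
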