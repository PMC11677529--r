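# Small-grid phantom parameters for fast unit tests; the full-size default
# grid is exercised by the acceptance suite.
small_phantom_params <- function(seed = 1L, ...) {
  phantom_params(grid_shape = c(48L, 48L, 10L),
                 voxel_spacing = c(0.4, 0.4, 1),
                 seed = seed, ...)
}

# A simple box "brain" for geometry tests: 10x10x10 voxels centered in a
# 20x20x20 grid (1000 voxels, split 500/500 by the mid-sagittal plane).
box_brain <- function() {
  m <- array(FALSE, c(20L, 20L, 20L))
  m[6:15, 6:15, 6:15] <- TRUE
  m
}
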