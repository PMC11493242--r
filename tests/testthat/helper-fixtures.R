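# Shared fixtures, all generated in code.

# random classified volume: intensities uniform on [0, 100]
random_volume <- function(dims, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume(array(runif(prod(dims), 0, 100), dims), spacing = spacing)
}

# smooth tf: alpha ramps 0 -> amax over the intensity range, grey colour
ramp_tf <- function(amax = 0.8) {
  transfer_function(c(0, 100),
                    rbind(c(0, 0, 0, 0), c(1, 1, 1, amax)))
}

# 1x1x4 column with alpha 0, a, a, 0 under ramp_tf(2*a) sampling:
# use explicit levels so classification is exact at voxel centres
column_volume <- function() {
  volume(array(c(0, 100, 100, 0), c(1, 1, 4)))
}

column_tf <- function(alpha = 0.5) {
  transfer_function(c(0, 100), rbind(c(0, 0, 0, 0), c(1, 1, 1, alpha)))
}

empty_field <- function(vol) {
  light_field(array(0, dim(vol$data)), spacing = vol$spacing,
              origin = vol$origin)
}

constant_field <- function(vol, value) {
  light_field(array(value, dim(vol$data)), spacing = vol$spacing,
              origin = vol$origin)
}
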