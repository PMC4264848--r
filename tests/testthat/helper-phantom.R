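## Small phantom used by most tests: 64 x 64 x 32 voxels, coarse slices,
## same scaffold geometry as the full-size default. Cheap enough to
## rebuild per test file.

small_acquisition <- function(seed = 1L, bias_amplitude = 0.2,
                              noise_sigma = 5, ...) {
  acquisition_model(matrix_size = 64, n_slices = 32, slice_thickness = 0.1,
                    bias_amplitude = bias_amplitude,
                    noise_sigma = noise_sigma, seed = seed, ...)
}

small_phantom <- function(seed = 1L, occ = c(top = 0, middle = 0,
                                             bottom = 0.02),
                          bias_amplitude = 0.2, noise_sigma = 5, ...) {
  build_phantom(tissue = tissue_model(occ),
                acquisition = small_acquisition(
                  seed = seed, bias_amplitude = bias_amplitude,
                  noise_sigma = noise_sigma, ...),
                seed = seed)
}

## liquid voxels of a phantom (inside the ROI, neither scaffold nor tissue)
liquid_voxels <- function(ph) {
  rm2 <- roi_mask(ph$roi, dim(ph$scaffold_mask)[1], dim(ph$scaffold_mask)[2])
  array(rm2, dim(ph$scaffold_mask)) & !ph$scaffold_mask & !ph$tissue_mask
}
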