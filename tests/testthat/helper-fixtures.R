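# Shared fixtures: small phantoms and noiseless protocols keep unit tests fast.

small_shape <- c(64, 64)

noiseless_protocol <- function(...) {
  default_protocol(snr = Inf, ...)
}

control_phantom <- function(shape = small_shape, seed = 1) {
  make_phantom(tissue_parameters("control"), shape, seed = seed)
}

allograft_phantom <- function(shape = small_shape, seed = 1,
                              timepoint = "w3") {
  make_phantom(tissue_parameters("allogenic", timepoint), shape, seed = seed)
}

# Relative error helper on tissue voxels.
rel_err <- function(fitted, truth, tissue) {
  max(abs(fitted[tissue] - truth[tissue]) / truth[tissue])
}
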