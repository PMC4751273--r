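# Small shared fixtures. Full-resolution (25 um) slice runs live only in
# the acceptance tests; unit tests use coarser grids for speed.

coarse_coronal <- function(dx = 50e-6) {
  make_slice(slice_spec("coronal_like", dx = dx))
}

# parameters scaled to short unit-test runs
short_params <- function(...) {
  default_parameters(t_total = 240, ...)
}
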