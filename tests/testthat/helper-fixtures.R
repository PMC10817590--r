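# Shared fixtures: desk-scale configurations used across test files.

# Small square volume for fast unit tests of the generator/projection chain.
tiny_vconfig <- function(...) {
  volume_config(n_bscan = 16L, n_ascan = 16L, n_depth = 24L,
                layers = c("GCL", "IPL"),
                layer_mean_thickness = c(GCL = 5, IPL = 4),
                foveal_dip_radius = 3, ...)
}

# The reduced desk-scale study configuration: 3 mid-retinal layers,
# shallow depth, full 128 x 512 en-face grid (the texture chain requires it).
reduced_vconfig <- function(...) {
  volume_config(layers = c("GCL", "IPL", "INL"), n_depth = 32L, ...)
}

# A deterministic MVF image wrapper for texture tests.
as_mvf <- function(values, mask = NULL, layer = "IPL", eye = "OD") {
  structure(list(values = values,
                 mask = if (is.null(mask)) !is.na(values) else mask,
                 layer = layer, eye = eye, participant_id = "T001",
                 flipped = FALSE),
            class = "mvf_image")
}
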