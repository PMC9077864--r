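# Shared fixtures: artifact-free materials and small render configurations
# so individual tests stay fast.

# gap medium index-matched to glass and lens: fringe visibility is exactly 0
matched_material <- function(noise_sd = 0) {
  material_spec("matched", 1.5, noise_sd)
}

# render with every stochastic element switched off
render_clean <- function(doses_gy, mode = "reflective", seed = 1, ...) {
  render_scan(doses_gy, material = matched_material(),
              config = scan_config(mode, seed = seed),
              n_glass = 1.5, n_lens = 1.5, jitter_gap = FALSE, ...)
}

# exact power-law points
power_points <- function(doses, a, b, n) a * doses + b * doses^n
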