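# shared fixtures for the solver tests

# six-face BC list: fixed-temperature x ends, insulated elsewhere
slab_bcs <- function(T_end = 310.15) {
  c(rep(list(bc_spec("fixed", T_fix = T_end)), 2),
    rep(list(bc_spec("insulated")), 4))
}

# independent scalar oracle for the diffusion-kernel fluence: plain
# arithmetic on mu_a, mu_s', depth and distance -- no package internals
phi_oracle <- function(P0, mu_a, mu_s_prime, depth, r) {
  mu_tr <- mu_a + mu_s_prime
  D <- 1 / (3 * mu_tr)
  mu_eff <- sqrt(3 * mu_a * mu_tr)
  P0 * exp(-mu_eff * max(depth, 0)) / (4 * pi * D * r)
}

# small single-seed phantom that resolves the seed on a 1 mm grid
small_seed_config <- function(spacing = 1e-3) {
  breast_phantom_config(block = c(0.031, 0.031, 0.031), spacing = spacing,
                        fat_thickness = 0.005, seed_rows = 1, seed_cols = 1)
}
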