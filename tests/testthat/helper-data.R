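# Small in-code fixtures shared across test files.

tiny_bound <- function() {
  data.frame(
    ligand_id    = c("L1", "L1", "L2", "L2"),
    protein_conf = c("P70", "P70", "P70", "P70"),
    pose         = c("M1", "M2", "M1", "M2"),
    replicate    = c("S1", "S1", "S1", "S1"),
    v_el_bound   = c(-120, -115, -140, -130),
    v_vdw_bound  = c(-80, -85, -90, -95),
    stringsAsFactors = FALSE)
}

tiny_free <- function() {
  data.frame(ligand_id = c("L1", "L2"),
             v_el_free = c(-100, -120),
             v_vdw_free = c(-60, -70),
             stringsAsFactors = FALSE)
}

tiny_experimental <- function() {
  data.frame(ligand_id = c("L1", "L2"),
             dg_exp = c(-25, -30),
             dg_err = NA_real_, ic50_uM = NA_real_,
             ic50_sigma_uM = NA_real_,
             stringsAsFactors = FALSE)
}

# Noise-free synthetic data set under known coefficients.
noise_free_data <- function(n_ligands = 10, seed = 42, alpha = 0.42,
                            beta = 0.22) {
  generate_lie_data(generator_spec(
    n_ligands = n_ligands, true_alpha = alpha, true_beta = beta,
    replicate_noise_sd = 0, obs_noise_sd = 0, seed = seed))
}

as_dataset <- function(data) {
  lie_dataset(data$bound, data$free, data$experimental)
}

# One simulation per ligand: calibration must reduce to plain least
# squares.
single_sim_data <- function(n_ligands = 8, seed = 1, obs_noise_sd = 1) {
  generate_lie_data(generator_spec(
    n_ligands = n_ligands, protein_confs = "P70", poses = "M1",
    replicates = "S1", pose_offset_scale = 0, replicate_noise_sd = 0,
    obs_noise_sd = obs_noise_sd, seed = seed))
}

# Independent closed-form least-squares oracle (normal equations).
normal_equations_fit <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}
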