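## Synthetic benchmark data with known ground-truth LIE parameters.
##
## The generator emulates the statistical structure of a multi-pose,
## multi-conformation MD study: each ligand has a characteristic pair of
## interaction-energy differences, each starting configuration (protein
## conformation x pose) perturbs them by a configuration-specific offset,
## and replicate runs scatter around the configuration mean.  The
## "experimental" affinities are the Boltzmann-weighted model values at
## the ground-truth coefficients, plus optional observation noise.

#' Specification for the synthetic LIE data generator
#'
#' @param n_ligands Number of ligands (>= 2).
#' @param protein_confs,poses,replicates Label vectors for the simulated
#'   starting configurations and replicate runs.
#' @param true_alpha,true_beta Ground-truth LIE coefficients used to
#'   construct the affinities.
#' @param kT Thermal energy for the ground-truth weighting, kJ/mol.
#' @param d_el_range,d_vdw_range Uniform sampling intervals for each
#'   ligand's central electrostatic and van der Waals energy differences,
#'   kJ/mol.
#' @param pose_offset_scale Standard deviation of the Gaussian
#'   per-configuration offsets added to both energy differences, kJ/mol.
#'   The default of 8 gives per-configuration free-energy spreads of a
#'   few kT, i.e. order-of-magnitude contrasts between configuration
#'   weights.
#' @param replicate_noise_sd Standard deviation of the between-replicate
#'   scatter of the averages, kJ/mol.
#' @param obs_noise_sd Standard deviation of Gaussian noise added to the
#'   experimental free energies, kJ/mol.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `lie_generator_spec`.
#' @export
generator_spec <- function(n_ligands = 10,
                           protein_confs = c("P70", "P170"),
                           poses = c("M1", "M2"),
                           replicates = c("S1", "S2"),
                           true_alpha = 0.411, true_beta = 0.217,
                           kT = lie_kT(),
                           d_el_range = c(-60, 0),
                           d_vdw_range = c(-120, -20),
                           pose_offset_scale = 8,
                           replicate_noise_sd = 1,
                           obs_noise_sd = 1,
                           seed = 1L) {
  stopifnot(n_ligands >= 2,
            length(protein_confs) >= 1, length(poses) >= 1,
            length(replicates) >= 1,
            is.finite(true_alpha), is.finite(true_beta), kT > 0,
            length(d_el_range) == 2, diff(d_el_range) > 0,
            length(d_vdw_range) == 2, diff(d_vdw_range) > 0,
            pose_offset_scale >= 0, replicate_noise_sd >= 0,
            obs_noise_sd >= 0)
  structure(list(n_ligands = as.integer(n_ligands),
                 protein_confs = protein_confs, poses = poses,
                 replicates = replicates,
                 true_alpha = true_alpha, true_beta = true_beta,
                 kT = kT, d_el_range = d_el_range,
                 d_vdw_range = d_vdw_range,
                 pose_offset_scale = pose_offset_scale,
                 replicate_noise_sd = replicate_noise_sd,
                 obs_noise_sd = obs_noise_sd,
                 seed = as.integer(seed)),
            class = "lie_generator_spec")
}

## Run code with a local RNG stream so generation never disturbs the
## caller's random state.
.with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic LIE data set
#'
#' Draws bound-state, free-state and experimental tables under a known
#' ground truth.  Per ligand, central energy differences are drawn
#' uniformly from the spec ranges; each starting configuration adds
#' Gaussian offsets (`pose_offset_scale`) and each replicate adds
#' Gaussian scatter (`replicate_noise_sd`).  Free-state averages are
#' drawn independently and the bound-state values are constructed so the
#' intended differences hold exactly.  The experimental free energy of a
#' ligand is the Boltzmann-weighted combined model value over all its
#' simulations (treated separately) at the ground-truth coefficients,
#' plus `obs_noise_sd` noise.
#'
#' @param spec A [generator_spec()].
#' @return A list with `bound`, `free`, `experimental` data frames (the
#'   exact column layouts of the readers), and `ground_truth` (list:
#'   `alpha`, `beta`, `kT`, `seed`, and the noise-free `dg_true` per
#'   ligand).
#' @export
generate_lie_data <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "lie_generator_spec"))
  .with_local_seed(spec$seed, {
    ligs <- sprintf("L%d", seq_len(spec$n_ligands))
    cfg <- expand.grid(pose = spec$poses,
                       protein_conf = spec$protein_confs,
                       stringsAsFactors = FALSE)[, c("protein_conf", "pose")]
    rows <- list()
    free <- data.frame(ligand_id = ligs,
                       v_el_free = stats::runif(spec$n_ligands, -250, -100),
                       v_vdw_free = stats::runif(spec$n_ligands, -80, -30),
                       stringsAsFactors = FALSE)
    for (li in seq_along(ligs)) {
      base_el <- stats::runif(1, spec$d_el_range[1], spec$d_el_range[2])
      base_vdw <- stats::runif(1, spec$d_vdw_range[1], spec$d_vdw_range[2])
      for (ci in seq_len(nrow(cfg))) {
        cfg_el <- base_el + stats::rnorm(1, 0, spec$pose_offset_scale)
        cfg_vdw <- base_vdw + stats::rnorm(1, 0, spec$pose_offset_scale)
        for (r in spec$replicates) {
          d_el <- cfg_el + stats::rnorm(1, 0, spec$replicate_noise_sd)
          d_vdw <- cfg_vdw + stats::rnorm(1, 0, spec$replicate_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            ligand_id = ligs[li],
            protein_conf = cfg$protein_conf[ci],
            pose = cfg$pose[ci],
            replicate = r,
            v_el_bound = free$v_el_free[li] + d_el,
            v_vdw_bound = free$v_vdw_free[li] + d_vdw,
            stringsAsFactors = FALSE)
        }
      }
    }
    bound <- do.call(rbind, rows)
    truth <- lie_params(alpha = spec$true_alpha, beta = spec$true_beta,
                        kT = spec$kT)
    deltas <- delta_energies(bound, free)
    dg_true <- vapply(ligs, function(l) {
      combined_free_energy(truth,
                           deltas[deltas$ligand_id == l, ,
                                  drop = FALSE])$dg_calc
    }, numeric(1))
    dg_exp <- dg_true + stats::rnorm(spec$n_ligands, 0, spec$obs_noise_sd)
    experimental <- data.frame(ligand_id = ligs, dg_exp = dg_exp,
                               dg_err = rep(spec$obs_noise_sd,
                                            spec$n_ligands),
                               ic50_uM = NA_real_,
                               ic50_sigma_uM = NA_real_,
                               stringsAsFactors = FALSE)
    list(bound = bound, free = free, experimental = experimental,
         ground_truth = list(alpha = spec$true_alpha,
                             beta = spec$true_beta, kT = spec$kT,
                             seed = spec$seed, dg_true = dg_true),
         spec = spec)
  })
}

#' Write a generated data set to a directory
#'
#' Writes `bound.tsv`, `free.tsv`, `experimental.tsv` in the reader
#' formats plus a `generator.json` sidecar recording the spec, seed and
#' ground truth.
#'
#' @param data Result of [generate_lie_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lie_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_energy_table(data$bound, file.path(dir, "bound.tsv"))
  write_energy_table(data$free, file.path(dir, "free.tsv"))
  write_energy_table(data$experimental, file.path(dir, "experimental.tsv"))
  sidecar <- c(unclass(data$spec),
               list(ground_truth_dg = as.list(data$ground_truth$dg_true)))
  jsonlite::write_json(sidecar, file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Packaged thiourea CYP 2D6 affinity table
#'
#' Returns the packaged experimental affinity fixture: ten thiourea CYP
#' 2D6 inhibitors (L1-L10) with published IC50 +/- sigma (micromolar)
#' and the corresponding relative binding free energies.
#'
#' @return Data frame with columns `ligand_id`, `substituent`,
#'   `ic50_uM`, `ic50_sigma_uM`, `dg_exp`, `dg_err`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_experimental.tsv",
                      package = "iterlie", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate a correlated interaction-energy time series
#'
#' A minimal AR(1) fluctuation model around stationary means, for
#' exercising [average_timeseries()]; it makes no claim to reproduce real
#' MD autocorrelation structure.
#'
#' @param n_frames Number of frames.
#' @param mean_el,mean_vdw Stationary means, kJ/mol.
#' @param sd_el,sd_vdw Stationary standard deviations, kJ/mol.
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param dt Frame spacing in ps.
#' @return Data frame with `time_ps`, `v_el`, `v_vdw`.
#' @export
simulate_energy_timeseries <- function(n_frames, mean_el, mean_vdw,
                                       sd_el = 5, sd_vdw = 3, phi = 0.8,
                                       dt = 0.02) {
  stopifnot(n_frames >= 2, phi >= 0, phi < 1, sd_el >= 0, sd_vdw >= 0)
  ar1 <- function(mu, sd) {
    x <- numeric(n_frames)
    innov_sd <- sd * sqrt(1 - phi^2)
    x[1] <- stats::rnorm(1, 0, sd)
    for (t in seq_len(n_frames - 1L)) {
      x[t + 1L] <- phi * x[t] + stats::rnorm(1, 0, innov_sd)
    }
    mu + x
  }
  data.frame(time_ps = dt * seq_len(n_frames),
             v_el = ar1(mean_el, sd_el),
             v_vdw = ar1(mean_vdw, sd_vdw))
}
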