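## Core LIE arithmetic: per-simulation binding free energies, Boltzmann
## weights over the simulations of a ligand, and the weighted combined
## binding free energy.

#' LIE model parameters
#'
#' Creates a parameter set for the linear interaction energy model.  In
#' the standard variant the binding free energy of a simulation is
#' `beta * dV_el + alpha * dV_vdw`; in the offset variant the
#' electrostatic coefficient is fixed at zero and a constant `gamma`
#' (kJ/mol) is added: `alpha * dV_vdw + gamma`.
#'
#' @param alpha Dimensionless van der Waals coefficient.
#' @param beta Dimensionless electrostatic coefficient (standard
#'   variant); exactly one of `beta`, `gamma` must be given.
#' @param gamma Constant offset in kJ/mol (offset variant).
#' @param kT Thermal energy for Boltzmann weighting, kJ/mol.
#' @return An object of class `lie_params`.
#' @examples
#' lie_params(alpha = 0.5, beta = 0.5)
#' lie_params(alpha = 0.4, gamma = -3)
#' @export
lie_params <- function(alpha, beta = NULL, gamma = NULL, kT = lie_kT()) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(kT), kT > 0)
  if (is.null(beta) == is.null(gamma)) {
    stop("exactly one of beta (standard variant) or gamma (offset ",
         "variant) must be supplied", call. = FALSE)
  }
  variant <- if (is.null(gamma)) "alpha_beta" else "alpha_gamma"
  if (variant == "alpha_beta") {
    stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  } else {
    stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 kT = kT, variant = variant),
            class = "lie_params")
}

#' @export
print.lie_params <- function(x, digits = 4, ...) {
  if (x$variant == "alpha_beta") {
    cat(sprintf("<lie_params> beta = %.*g, alpha = %.*g, kT = %.*g kJ/mol\n",
                digits, x$beta, digits, x$alpha, digits, x$kT))
  } else {
    cat(sprintf(
      "<lie_params> alpha = %.*g, gamma = %.*g kJ/mol (beta = 0), kT = %.*g kJ/mol\n",
      digits, x$alpha, digits, x$gamma, digits, x$kT))
  }
  invisible(x)
}

.sim_id <- function(protein_conf, pose, replicate = NULL) {
  if (is.null(replicate) || all(is.na(replicate))) {
    paste(protein_conf, pose, sep = "-")
  } else {
    paste(protein_conf, pose, replicate, sep = "-")
  }
}

#' Bound-minus-free interaction-energy differences
#'
#' Subtracts each ligand's free-state averages from its bound-state
#' averages, yielding the electrostatic (`d_el`) and van der Waals
#' (`d_vdw`) interaction-energy differences that enter the LIE model.
#'
#' @param bound Bound-state averages (possibly already combined over
#'   replicates by [combine_replicates()]).
#' @param free Free-state averages, one row per ligand.
#' @return A data frame with the simulation key columns, a `sim_id`
#'   label, and `d_el`, `d_vdw` in kJ/mol.
#' @export
delta_energies <- function(bound, free) {
  i <- match(bound$ligand_id, free$ligand_id)
  if (anyNA(i)) {
    stop("ligand mismatch: no free-state record for ligand '",
         bound$ligand_id[which(is.na(i))[1]], "'", call. = FALSE)
  }
  rep_col <- if ("replicate" %in% names(bound)) bound$replicate else NULL
  data.frame(
    ligand_id    = bound$ligand_id,
    protein_conf = bound$protein_conf,
    pose         = bound$pose,
    replicate    = if (is.null(rep_col)) NA_character_ else rep_col,
    sim_id       = .sim_id(bound$protein_conf, bound$pose, rep_col),
    d_el         = bound$v_el_bound - free$v_el_free[i],
    d_vdw        = bound$v_vdw_bound - free$v_vdw_free[i],
    stringsAsFactors = FALSE)
}

#' Per-simulation LIE binding free energy
#'
#' Evaluates the LIE estimate for one or more simulations:
#' `beta * d_el + alpha * d_vdw` (standard variant) or
#' `alpha * d_vdw + gamma` (offset variant).
#'
#' @param params [lie_params()] object.
#' @param d_el,d_vdw Interaction-energy differences, kJ/mol (vectorized).
#' @return Binding free energies in kJ/mol.
#' @export
pose_free_energy <- function(params, d_el, d_vdw) {
  stopifnot(inherits(params, "lie_params"))
  if (params$variant == "alpha_beta") {
    params$beta * d_el + params$alpha * d_vdw
  } else {
    params$alpha * d_vdw + params$gamma
  }
}

#' Boltzmann weights over a ligand's simulations
#'
#' Normalized weights `W_i = exp(-dG_i/kT) / sum_j exp(-dG_j/kT)` giving
#' the relative contribution of each independent simulation to the
#' combined binding free energy.  Computed shift-stably: the minimum
#' `dG_i` is subtracted before exponentiating, so arbitrarily large
#' magnitudes cannot overflow.  In the `kT -> 0` limit weight
#' concentrates on the minimum (shared equally among exact ties).
#'
#' @param dg Per-simulation binding free energies, kJ/mol (non-empty).
#' @param kT Thermal energy, kJ/mol (> 0).
#' @return Numeric vector of weights summing to 1, named like `dg`.
#' @export
boltzmann_weights <- function(dg, kT = lie_kT()) {
  if (length(dg) == 0L) stop("empty free-energy list", call. = FALSE)
  stopifnot(is.numeric(dg), all(is.finite(dg)), kT > 0)
  e <- exp(-(dg - min(dg)) / kT)
  e / sum(e)
}

#' Combine replicate simulations of one starting configuration
#'
#' Applies one of the two replicate-combination schemes to a bound-state
#' table.  `"separate"` keeps every replicate as an independent entry in
#' the weighting; `"replicate_averaged"` replaces the replicates of each
#' (ligand, protein conformation, pose) configuration by a single record
#' with arithmetic-mean energies (the replicate label is dropped).  A
#' configuration with a single replicate contributes that run unchanged
#' under both schemes (a message notes such singletons when averaging).
#'
#' @param bound Bound-state averages table.
#' @param scheme `"separate"` or `"replicate_averaged"`.
#' @return A bound-state table; under `"replicate_averaged"` the
#'   `replicate` column is `NA` and rows are one per configuration.
#' @export
combine_replicates <- function(bound,
                               scheme = c("separate", "replicate_averaged")) {
  scheme <- match.arg(scheme)
  if (scheme == "separate" || nrow(bound) == 0L) return(bound)
  g <- interaction(bound$ligand_id, bound$protein_conf, bound$pose,
                   drop = TRUE, lex.order = TRUE)
  sizes <- table(g)
  if (length(unique(sizes)) > 1L && any(sizes == 1L)) {
    single <- names(sizes)[sizes == 1L]
    message("combine_replicates: configuration(s) with a single ",
            "replicate contribute one run unchanged: ",
            paste(single, collapse = ", "))
  }
  first <- !duplicated(g)
  out <- data.frame(
    ligand_id    = bound$ligand_id[first],
    protein_conf = bound$protein_conf[first],
    pose         = bound$pose[first],
    replicate    = NA_character_,
    v_el_bound   = as.numeric(tapply(bound$v_el_bound, g, mean)[g[first]]),
    v_vdw_bound  = as.numeric(tapply(bound$v_vdw_bound, g, mean)[g[first]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Boltzmann-weighted combined binding free energy for one ligand
#'
#' Combines the per-simulation LIE estimates of one ligand into a single
#' predicted binding free energy: weights are the Boltzmann weights of
#' the per-simulation free energies, and the prediction applies the LIE
#' coefficients to the weight-averaged energy differences.  This equals
#' the weighted mean of the per-simulation free energies.
#'
#' @param params [lie_params()] object.
#' @param deltas Data frame of energy differences for one ligand (as one
#'   ligand's rows from [delta_energies()]).
#' @return A list with `dg_calc` (kJ/mol), `weights` (named by
#'   `sim_id`), `dg_i` (per-simulation free energies), and the weighted
#'   sums `wd_el`, `wd_vdw`.
#' @export
combined_free_energy <- function(params, deltas) {
  stopifnot(inherits(params, "lie_params"))
  if (nrow(deltas) == 0L) stop("empty simulation list", call. = FALSE)
  if (length(unique(deltas$ligand_id)) != 1L) {
    stop("deltas must belong to a single ligand", call. = FALSE)
  }
  dg_i <- pose_free_energy(params, deltas$d_el, deltas$d_vdw)
  w <- boltzmann_weights(dg_i, params$kT)
  names(w) <- deltas$sim_id
  wd_el <- sum(w * deltas$d_el)
  wd_vdw <- sum(w * deltas$d_vdw)
  dg_calc <- if (params$variant == "alpha_beta") {
    params$beta * wd_el + params$alpha * wd_vdw
  } else {
    params$alpha * wd_vdw + params$gamma
  }
  list(dg_calc = dg_calc, weights = w, dg_i = dg_i,
       wd_el = wd_el, wd_vdw = wd_vdw)
}
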