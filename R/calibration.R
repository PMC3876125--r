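## Self-consistent calibration of LIE coefficients against experimental
## binding free energies.
##
## The objective is the RMSE between the Boltzmann-weighted predictions
## and experiment.  Because the weights themselves depend on the
## coefficients, the fit alternates between (i) evaluating weights at the
## current coefficients and (ii) refitting the coefficients by linear
## least squares on the weight-averaged energy differences, until both
## the coefficients and the RMSE stop moving.

#' Model specification for a LIE calibration
#'
#' Selects which simulations enter a model (by protein conformation and
#' pose), how replicate runs are combined, and which parameter variant is
#' fitted.
#'
#' @param name Model label, e.g. `"P70-M1"` (single starting
#'   configuration), `"P70"`, `"M2"`, or `"all"`.
#' @param protein_confs Allowed protein-conformation labels (`NULL` = all).
#' @param poses Allowed pose labels (`NULL` = all).
#' @param scheme Replicate scheme: `"separate"` weights every replicate
#'   individually; `"replicate_averaged"` averages the replicates of each
#'   starting configuration first.
#' @param variant `"alpha_beta"` (fit both coefficients) or
#'   `"alpha_gamma"` (electrostatic coefficient fixed at zero, constant
#'   offset fitted).
#' @return An object of class `lie_model_spec`.
#' @export
model_spec <- function(name = "all", protein_confs = NULL, poses = NULL,
                       scheme = c("separate", "replicate_averaged"),
                       variant = c("alpha_beta", "alpha_gamma")) {
  structure(list(name = name, protein_confs = protein_confs,
                 poses = poses, scheme = match.arg(scheme),
                 variant = match.arg(variant)),
            class = "lie_model_spec")
}

#' @export
print.lie_model_spec <- function(x, ...) {
  cat("<lie_model_spec>", x$name, "| scheme:", x$scheme,
      "| variant:", x$variant, "\n")
  if (!is.null(x$protein_confs))
    cat("  protein conformations:", paste(x$protein_confs, collapse = ", "), "\n")
  if (!is.null(x$poses))
    cat("  poses:", paste(x$poses, collapse = ", "), "\n")
  invisible(x)
}

## Filter + replicate-combine + subtract free state for a model.
.model_deltas <- function(dataset, spec) {
  stopifnot(inherits(dataset, "lie_dataset"),
            inherits(spec, "lie_model_spec"))
  bound <- dataset$bound
  if (!is.null(spec$protein_confs)) {
    bound <- bound[bound$protein_conf %in% spec$protein_confs, , drop = FALSE]
  }
  if (!is.null(spec$poses)) {
    bound <- bound[bound$pose %in% spec$poses, , drop = FALSE]
  }
  ligs <- unique(dataset$bound$ligand_id)
  gone <- setdiff(ligs, unique(bound$ligand_id))
  if (length(gone)) {
    stop("model '", spec$name, "' leaves no simulations for ligand(s): ",
         paste(gone, collapse = ", "), call. = FALSE)
  }
  bound <- combine_replicates(bound, spec$scheme)
  delta_energies(bound, dataset$free)
}

#' Root-mean-square error between predicted and experimental free energies
#'
#' @param calc Named vector of predicted binding free energies, kJ/mol.
#' @param exp Named vector of experimental values over the same ligands.
#' @return RMSE in kJ/mol, using 1/n inside the root.
#' @export
lie_rmse <- function(calc, exp) {
  if (length(calc) == 0L) stop("empty prediction vector", call. = FALSE)
  if (!is.null(names(calc)) && !is.null(names(exp))) {
    if (!setequal(names(calc), names(exp))) {
      stop("mismatched ligand sets between calculated and experimental ",
           "values", call. = FALSE)
    }
    exp <- exp[names(calc)]
  } else if (length(calc) != length(exp)) {
    stop("mismatched lengths between calculated and experimental values",
         call. = FALSE)
  }
  sqrt(mean((calc - exp)^2))
}

#' Ligands predicted outside the 1 kcal/mol band
#'
#' Lists the ligands whose absolute prediction error strictly exceeds the
#' threshold (default 4.184 kJ/mol = 1 kcal/mol), with the absolute error
#' reported to 2 decimals, sorted by ligand id.
#'
#' @param residuals Named vector of residuals (`dg_calc - dg_exp`),
#'   kJ/mol, or a `lie_calibration` object.
#' @param threshold Outlier threshold in kJ/mol; the comparison is
#'   strict (an error exactly at the threshold is not an outlier).
#' @return Data frame with columns `ligand_id`, `abs_error`.
#' @export
find_outliers <- function(residuals, threshold = 4.184) {
  if (inherits(residuals, "lie_calibration")) {
    residuals <- stats::setNames(residuals$per_ligand$residual,
                                 residuals$per_ligand$ligand_id)
  }
  stopifnot(is.numeric(residuals), !is.null(names(residuals)))
  out <- abs(residuals) > threshold
  res <- data.frame(ligand_id = names(residuals)[out],
                    abs_error = round(abs(residuals[out]), 2),
                    stringsAsFactors = FALSE)
  res <- res[order(res$ligand_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Linear refit of the LIE coefficients at frozen weights
#'
#' The inner step of the self-consistent calibration: with the Boltzmann
#' weights held fixed, the combined prediction is linear in the
#' coefficients, so the least-squares minimizer is found by an ordinary
#' linear model on the weight-averaged energy differences — without an
#' intercept for the standard variant, and regressing on the van der
#' Waals term plus an intercept for the offset variant.
#'
#' @param weighted Data frame with one row per ligand and columns
#'   `ligand_id`, `wd_el`, `wd_vdw` (Boltzmann-weighted mean energy
#'   differences, kJ/mol).
#' @param dg_exp Named vector of experimental free energies over the same
#'   ligands, kJ/mol.
#' @param variant `"alpha_beta"` or `"alpha_gamma"`.
#' @param kT Thermal energy carried into the returned parameter set.
#' @return A [lie_params()] object with a `"se"` attribute holding the
#'   coefficient standard errors from the linear fit.
#' @export
fit_given_weights <- function(weighted, dg_exp,
                              variant = c("alpha_beta", "alpha_gamma"),
                              kT = lie_kT()) {
  variant <- match.arg(variant)
  n_par <- 2L
  if (nrow(weighted) < n_par) {
    stop("degenerate design: need at least ", n_par, " ligands to fit ",
         n_par, " parameters", call. = FALSE)
  }
  y <- dg_exp[weighted$ligand_id]
  if (anyNA(y)) {
    stop("missing experimental value for ligand '",
         weighted$ligand_id[which(is.na(y))[1]], "'", call. = FALSE)
  }
  if (variant == "alpha_beta") {
    const <- c(el = stats::sd(weighted$wd_el) == 0,
               vdw = stats::sd(weighted$wd_vdw) == 0)
    if (any(const)) {
      stop("degenerate design: constant predictor column(s) ",
           paste(c("wd_el", "wd_vdw")[const], collapse = ", "),
           " carry no fittable signal", call. = FALSE)
    }
    X <- cbind(wd_el = weighted$wd_el, wd_vdw = weighted$wd_vdw)
    if (qr(X)$rank < 2L) {
      stop("degenerate design: wd_el and wd_vdw are collinear",
           call. = FALSE)
    }
    fit <- stats::lm(y ~ 0 + wd_el + wd_vdw,
                     data = data.frame(y = y, weighted))
    cf <- stats::coef(fit)
    ## on an exactly-fitting design the residual variance is 0 and
    ## lm's summary warns; the zero SEs are still the right answer
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    params <- lie_params(alpha = unname(cf["wd_vdw"]),
                         beta = unname(cf["wd_el"]), kT = kT)
    attr(params, "se") <- c(beta = unname(se["wd_el"]),
                            alpha = unname(se["wd_vdw"]))
  } else {
    if (stats::sd(weighted$wd_vdw) == 0) {
      stop("degenerate design: constant predictor column wd_vdw is ",
           "collinear with the offset", call. = FALSE)
    }
    fit <- stats::lm(y ~ wd_vdw, data = data.frame(y = y, weighted))
    cf <- stats::coef(fit)
    ## on an exactly-fitting design the residual variance is 0 and
    ## lm's summary warns; the zero SEs are still the right answer
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    params <- lie_params(alpha = unname(cf["wd_vdw"]),
                         gamma = unname(cf["(Intercept)"]), kT = kT)
    attr(params, "se") <- c(alpha = unname(se["wd_vdw"]),
                            gamma = unname(se["(Intercept)"]))
  }
  params
}

## Evaluate predictions, weights and RMSE at fixed parameters.
## `deltas` is the full delta table; ligand grouping is vectorized.
.evaluate_params <- function(params, deltas, dg_exp) {
  g <- factor(deltas$ligand_id, levels = unique(deltas$ligand_id))
  dg_i <- pose_free_energy(params, deltas$d_el, deltas$d_vdw)
  m <- stats::ave(dg_i, g, FUN = min)
  e <- exp(-(dg_i - m) / params$kT)
  w <- e / stats::ave(e, g, FUN = sum)
  lig <- levels(g)
  wd_el <- rowsum(w * deltas$d_el, g)[, 1]
  wd_vdw <- rowsum(w * deltas$d_vdw, g)[, 1]
  dg_calc <- if (params$variant == "alpha_beta") {
    params$beta * wd_el + params$alpha * wd_vdw
  } else {
    params$alpha * wd_vdw + params$gamma
  }
  names(dg_calc) <- lig
  resid <- dg_calc - dg_exp[lig]
  list(weighted = data.frame(ligand_id = lig, wd_el = unname(wd_el),
                             wd_vdw = unname(wd_vdw),
                             stringsAsFactors = FALSE),
       weights = stats::setNames(w, deltas$sim_id),
       group = g,
       dg_calc = dg_calc,
       residual = resid,
       rmse = sqrt(mean(resid^2)))
}

.param_vec <- function(p) {
  if (p$variant == "alpha_beta") c(alpha = p$alpha, beta = p$beta)
  else c(alpha = p$alpha, gamma = p$gamma)
}

.vec_param <- function(v, variant, kT) {
  if (variant == "alpha_beta") {
    lie_params(alpha = v[["alpha"]], beta = v[["beta"]], kT = kT)
  } else {
    lie_params(alpha = v[["alpha"]], gamma = v[["gamma"]], kT = kT)
  }
}

## One self-consistent run from a single initial guess.
##
## The iteration is not RMSE-monotone: the self-consistent fixed point
## can sit marginally above the locally minimal RMSE (the weights move
## with the parameters), so the final approach is a damped oscillation.
## When a step increases the RMSE, step-halving damping is attempted;
## if no damped step improves either, the full step is kept — the
## increase is then the legitimate approach to the fixed point.
## Genuine oscillation never becomes stationary and is reported as
## non-convergence when max_iter is exhausted.
.calibrate_once <- function(deltas, dg_exp, variant, kT, init, tol,
                            rmse_tol, max_iter) {
  params <- init
  ev <- .evaluate_params(params, deltas, dg_exp)
  converged <- FALSE
  n_iter <- 0L
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    new <- fit_given_weights(ev$weighted, dg_exp, variant, kT)
    ev_new <- .evaluate_params(new, deltas, dg_exp)
    if (ev_new$rmse > ev$rmse + 1e-12) {
      v0 <- .param_vec(params); v1 <- .param_vec(new)
      for (k in seq_len(10)) {
        cand <- .vec_param(v0 + (v1 - v0) / 2^k, variant, kT)
        ev_c <- .evaluate_params(cand, deltas, dg_exp)
        if (ev_c$rmse <= ev$rmse + 1e-12) {
          new <- cand; ev_new <- ev_c
          break
        }
      }
    }
    dpar <- max(abs(.param_vec(new) - .param_vec(params)))
    drmse <- abs(ev_new$rmse - ev$rmse)
    params <- new
    ev <- ev_new
    if (dpar < tol && drmse < rmse_tol) {
      converged <- TRUE
      break
    }
  }
  se <- tryCatch(
    attr(fit_given_weights(ev$weighted, dg_exp, variant, kT), "se"),
    error = function(e) NULL)
  list(params = params, eval = ev, converged = converged,
       n_iter = n_iter, se = se)
}

.default_inits <- function(variant, kT) {
  if (variant == "alpha_beta") {
    grid <- expand.grid(alpha = c(0.1, 0.4, 0.7),
                        beta = c(0.1, 0.4, 0.7))
    ## plus the linear-response starting point beta = 0.5
    grid <- rbind(grid, data.frame(alpha = 0.5, beta = 0.5))
    lapply(seq_len(nrow(grid)), function(i) {
      lie_params(alpha = grid$alpha[i], beta = grid$beta[i], kT = kT)
    })
  } else {
    c(lapply(c(0.1, 0.4, 0.7), function(a) {
      lie_params(alpha = a, gamma = 0, kT = kT)
    }), list(lie_params(alpha = 0.5, gamma = 0, kT = kT)))
  }
}

#' Self-consistent calibration of a LIE model
#'
#' Fits the LIE coefficients by alternating Boltzmann-weight evaluation
#' and linear least-squares refitting until both the coefficients and the
#' RMSE against experiment are stationary.  Because the weights depend on
#' the coefficients, several fixed points may exist; the fit is restarted
#' from a small grid of initial guesses and the lowest-RMSE converged
#' fixed point is returned, with every restart recorded.  Negative
#' electrostatic coefficients are permitted.
#'
#' @param dataset A [lie_dataset()].
#' @param spec A [model_spec()] selecting simulations, replicate scheme
#'   and parameter variant.
#' @param init Optional single [lie_params()] initial guess; when `NULL`
#'   the default restart grid is used (alpha, beta in \{0.1, 0.4, 0.7\}
#'   crossed, plus alpha = beta = 0.5).
#' @param kT Thermal energy for the weighting, kJ/mol.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param rmse_tol Convergence tolerance on the RMSE change, kJ/mol.
#' @param max_iter Maximum iterations per restart; `max_iter = 0` returns
#'   the initial parameters (with their RMSE) unconverged.
#' @param outlier_threshold Threshold for [find_outliers()], kJ/mol.
#' @return An object of class `lie_calibration` with elements `params`,
#'   `per_ligand` (data frame: `ligand_id`, `dg_calc`, `dg_exp`,
#'   `residual`), `weights` (long data frame), `rmse`, `outliers`,
#'   `converged`, `n_iter`, `se`, `restart_log`, `spec`, `kT`.
#' @export
lie_calibrate <- function(dataset, spec = model_spec(), init = NULL,
                          kT = lie_kT(), tol = 1e-6, rmse_tol = 1e-8,
                          max_iter = 500L, outlier_threshold = 4.184) {
  deltas <- .model_deltas(dataset, spec)
  dg_exp <- stats::setNames(dataset$experimental$dg_exp,
                            dataset$experimental$ligand_id)
  inits <- if (is.null(init)) {
    .default_inits(spec$variant, kT)
  } else {
    stopifnot(inherits(init, "lie_params"), init$variant == spec$variant)
    list(init)
  }
  runs <- lapply(inits, function(p0) {
    r <- .calibrate_once(deltas, dg_exp, spec$variant, kT, p0, tol,
                         rmse_tol, max_iter)
    r$init <- p0
    r
  })
  restart_log <- lapply(runs, function(r) {
    list(init = .param_vec(r$init), final = .param_vec(r$params),
         rmse = r$eval$rmse, converged = r$converged, n_iter = r$n_iter)
  })
  conv <- vapply(runs, `[[`, logical(1), "converged")
  pool <- if (any(conv)) runs[conv] else runs
  if (!any(conv) && max_iter > 0L) {
    cond <- simpleError(paste0(
      "calibration did not converge from any of ", length(runs),
      " initial guesses (model '", spec$name, "')"))
    cond$restart_log <- restart_log
    class(cond) <- c("iterlie_no_convergence", class(cond))
    stop(cond)
  }
  best <- pool[[which.min(vapply(pool, function(r) r$eval$rmse,
                                 numeric(1)))]]
  ev <- best$eval
  per_ligand <- data.frame(ligand_id = names(ev$dg_calc),
                           dg_calc = unname(ev$dg_calc),
                           dg_exp = unname(dg_exp[names(ev$dg_calc)]),
                           residual = unname(ev$residual),
                           stringsAsFactors = FALSE)
  weights <- data.frame(ligand_id = as.character(ev$group),
                        sim_id = names(ev$weights),
                        weight = unname(ev$weights),
                        stringsAsFactors = FALSE)
  res <- structure(list(
    params = best$params,
    per_ligand = per_ligand,
    weights = weights,
    rmse = ev$rmse,
    outliers = find_outliers(stats::setNames(per_ligand$residual,
                                             per_ligand$ligand_id),
                             outlier_threshold),
    outlier_threshold = outlier_threshold,
    converged = best$converged,
    n_iter = best$n_iter,
    se = best$se,
    restart_log = restart_log,
    spec = spec,
    kT = kT), class = "lie_calibration")
  res
}

#' @export
print.lie_calibration <- function(x, ...) {
  cat("<lie_calibration> model:", x$spec$name,
      "| scheme:", x$spec$scheme, "| variant:", x$spec$variant, "\n")
  ## beta printed before alpha, the conventional reporting order
  if (x$params$variant == "alpha_beta") {
    cat(sprintf("  beta  = %8.3f\n  alpha = %8.3f\n",
                x$params$beta, x$params$alpha))
  } else {
    cat(sprintf("  alpha = %8.3f\n  gamma = %8.3f kJ/mol (beta fixed at 0)\n",
                x$params$alpha, x$params$gamma))
  }
  cat(sprintf("  RMSE  = %8.3f kJ/mol over %d ligands\n", x$rmse,
              nrow(x$per_ligand)))
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              x$converged, x$n_iter))
  if (nrow(x$outliers)) {
    cat("  outliers (> ", x$outlier_threshold, " kJ/mol): ",
        paste(sprintf("%s %.2f", x$outliers$ligand_id,
                      x$outliers$abs_error), collapse = ", "), "\n",
        sep = "")
  } else {
    cat("  outliers: none\n")
  }
  invisible(x)
}

#' Predict binding free energies at fixed parameters
#'
#' Deterministic evaluation of the Boltzmann-weighted LIE prediction for
#' every ligand of a data set under a model specification, at supplied
#' (e.g. previously calibrated) parameters.
#'
#' @inheritParams lie_calibrate
#' @param params A [lie_params()] object matching the spec's variant.
#' @return A list with `per_ligand` (data frame: `ligand_id`, `dg_calc`)
#'   and `weights` (long data frame: `ligand_id`, `sim_id`, `weight`).
#' @export
lie_predict <- function(dataset, spec = model_spec(), params) {
  stopifnot(inherits(params, "lie_params"))
  if (params$variant != spec$variant) {
    stop("params variant '", params$variant,
         "' does not match model variant '", spec$variant, "'",
         call. = FALSE)
  }
  deltas <- .model_deltas(dataset, spec)
  dg_exp <- stats::setNames(rep(NA_real_, 0), character())
  ev <- .evaluate_params(params, deltas,
                         stats::setNames(rep(0, length(unique(deltas$ligand_id))),
                                         unique(deltas$ligand_id)))
  list(per_ligand = data.frame(ligand_id = names(ev$dg_calc),
                               dg_calc = unname(ev$dg_calc),
                               stringsAsFactors = FALSE),
       weights = data.frame(ligand_id = as.character(ev$group),
                            sim_id = names(ev$weights),
                            weight = unname(ev$weights),
                            stringsAsFactors = FALSE))
}

#' Weight table in wide layout
#'
#' Reshapes a long weight table (from [lie_calibrate()] or
#' [lie_predict()]) to one row per ligand and one column per simulation
#' (or averaged configuration), plus a `max_sim` column naming the
#' per-ligand maximum-weight simulation.
#'
#' @param weights Long data frame with `ligand_id`, `sim_id`, `weight`,
#'   or a `lie_calibration` object.
#' @return A wide data frame.
#' @export
weight_table <- function(weights) {
  if (inherits(weights, "lie_calibration")) weights <- weights$weights
  sims <- unique(weights$sim_id)
  ligs <- unique(weights$ligand_id)
  wide <- data.frame(ligand_id = ligs, stringsAsFactors = FALSE)
  for (s in sims) {
    v <- rep(NA_real_, length(ligs))
    sel <- weights$sim_id == s
    v[match(weights$ligand_id[sel], ligs)] <- weights$weight[sel]
    wide[[s]] <- v
  }
  m <- as.matrix(wide[, sims, drop = FALSE])
  wide$max_sim <- sims[apply(m, 1L, which.max)]
  wide
}

#' RMSE surface over the LIE coefficients
#'
#' Evaluates the calibration objective on a grid of (alpha, beta) values
#' for the standard variant: at each grid point the Boltzmann weights are
#' recomputed at that parameter pair (no refitting inside a cell) and the
#' RMSE of the combined predictions against experiment is recorded.
#' Optionally the weights can instead be frozen at a reference parameter
#' set, which isolates the linear part of the objective.
#'
#' @inheritParams lie_calibrate
#' @param alpha_grid,beta_grid Strictly increasing, non-empty grids.
#' @param weights `"per_point"` (default) recomputes weights at each grid
#'   point; `"frozen"` evaluates all cells at the weights implied by
#'   `params_for_weights`.
#' @param params_for_weights Reference [lie_params()] for
#'   `weights = "frozen"`.
#' @param display_ceiling RMSE ceiling used only to flag cells for
#'   contour display (values are reported unclamped); the conventional
#'   plotting window tops out at 5 kJ/mol.
#' @return An object of class `lie_surface`: a matrix of RMSE values
#'   (rows = alpha, cols = beta) with the grids, the flag matrix and the
#'   ceiling as attributes.
#' @export
rmse_surface <- function(dataset, spec = model_spec(), alpha_grid,
                         beta_grid, kT = lie_kT(),
                         weights = c("per_point", "frozen"),
                         params_for_weights = NULL,
                         display_ceiling = 5) {
  weights <- match.arg(weights)
  if (length(alpha_grid) == 0L || length(beta_grid) == 0L) {
    stop("empty parameter grid", call. = FALSE)
  }
  if (is.unsorted(alpha_grid, strictly = TRUE) ||
      is.unsorted(beta_grid, strictly = TRUE)) {
    stop("parameter grids must be strictly increasing", call. = FALSE)
  }
  if (spec$variant != "alpha_beta") {
    stop("RMSE surfaces are defined for the alpha/beta variant",
         call. = FALSE)
  }
  deltas <- .model_deltas(dataset, spec)
  dg_exp <- stats::setNames(dataset$experimental$dg_exp,
                            dataset$experimental$ligand_id)
  frozen <- NULL
  if (weights == "frozen") {
    if (is.null(params_for_weights)) {
      stop("params_for_weights is required when weights = 'frozen'",
           call. = FALSE)
    }
    frozen <- .evaluate_params(params_for_weights, deltas, dg_exp)$weighted
  }
  z <- matrix(NA_real_, length(alpha_grid), length(beta_grid),
              dimnames = list(alpha = format(alpha_grid),
                              beta = format(beta_grid)))
  for (i in seq_along(alpha_grid)) {
    for (j in seq_along(beta_grid)) {
      p <- lie_params(alpha = alpha_grid[i], beta = beta_grid[j], kT = kT)
      if (is.null(frozen)) {
        z[i, j] <- .evaluate_params(p, deltas, dg_exp)$rmse
      } else {
        pred <- p$beta * frozen$wd_el + p$alpha * frozen$wd_vdw
        z[i, j] <- sqrt(mean((pred - dg_exp[frozen$ligand_id])^2))
      }
    }
  }
  structure(z, class = c("lie_surface", "matrix"),
            alpha = alpha_grid, beta = beta_grid,
            display_ceiling = display_ceiling,
            above_ceiling = z > display_ceiling)
}

#' Long-format view of an RMSE surface
#'
#' @param surface A `lie_surface` object.
#' @return Data frame with columns `alpha`, `beta`, `rmse`,
#'   `above_display_ceiling`, suitable for contour plotting or TSV export.
#' @export
surface_table <- function(surface) {
  stopifnot(inherits(surface, "lie_surface"))
  a <- attr(surface, "alpha"); b <- attr(surface, "beta")
  data.frame(alpha = rep(a, times = length(b)),
             beta = rep(b, each = length(a)),
             rmse = as.vector(unclass(surface)),
             above_display_ceiling = as.vector(attr(surface, "above_ceiling")))
}
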