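## Configuration-driven entry points and report writers.  Each run_*()
## function backs one CLI subcommand (inst/cli/lietool.R) and writes
## machine-readable (JSON) and flat (TSV) reports plus a run manifest.

#' Read a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration file describing a
#' model, its input tables and fitting options.  Recognized top-level
#' blocks: `model` (`name`, `protein_confs`, `poses`, `scheme`,
#' `variant`), `inputs` (`bound`, `free`, `experimental`, optional
#' `unit`), `options` (`kT`, `temperature`, `tol`, `rmse_tol`,
#' `max_iter`, `outlier_threshold`), `surface` (`alpha`/`beta` each with
#' `from`, `to`, `n`), `params` (`alpha`, `beta` or `gamma`, for
#' prediction), `generator` (passed to [generator_spec()]).
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_lie_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.config_spec <- function(config) {
  m <- config$model
  if (is.null(m)) m <- list()
  model_spec(name = if (is.null(m$name)) "all" else m$name,
             protein_confs = m$protein_confs,
             poses = m$poses,
             scheme = if (is.null(m$scheme)) "separate" else m$scheme,
             variant = if (is.null(m$variant)) "alpha_beta" else m$variant)
}

.config_opt <- function(config, name, default) {
  v <- config$options[[name]]
  if (is.null(v)) default else v
}

.config_kT <- function(config) {
  if (!is.null(config$options$kT)) return(config$options$kT)
  lie_kT(.config_opt(config, "temperature", 300))
}

.config_dataset <- function(config, base_dir = ".") {
  inp <- config$inputs
  if (is.null(inp$bound) || is.null(inp$free) || is.null(inp$experimental)) {
    stop("config error: inputs must name bound, free and experimental ",
         "tables", call. = FALSE)
  }
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  unit <- if (is.null(inp$unit)) "kJ/mol" else inp$unit
  lie_dataset(
    bound = read_bound_energies(resolve(inp$bound), unit = unit),
    free = read_free_energies(resolve(inp$free), unit = unit),
    experimental = read_experimental(resolve(inp$experimental),
                                     temperature = .config_opt(config,
                                                               "temperature",
                                                               300)))
}

.input_paths <- function(config, base_dir = ".") {
  inp <- config$inputs
  paths <- unlist(inp[intersect(names(inp),
                                c("bound", "free", "experimental"))])
  paths[!file.exists(paths)] <- file.path(base_dir,
                                          paths[!file.exists(paths)])
  paths
}

.write_manifest <- function(out_dir, config, input_paths = character(),
                            seed = NULL) {
  digests <- if (length(input_paths)) {
    as.list(tools::md5sum(input_paths))
  } else {
    list()
  }
  manifest <- list(
    toolkit = "iterlie",
    version = as.character(utils::packageVersion("iterlie")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

.fmt3 <- function(x) formatC(x, format = "f", digits = 3)

## Model-summary row in the conventional reporting order: beta before
## alpha, then RMSE, then the outliers with their absolute errors.
.summary_row <- function(result) {
  p <- result$params
  out <- if (nrow(result$outliers)) {
    paste(sprintf("%s:%.2f", result$outliers$ligand_id,
                  result$outliers$abs_error), collapse = ";")
  } else {
    ""
  }
  if (p$variant == "alpha_beta") {
    data.frame(model = result$spec$name, scheme = result$spec$scheme,
               beta = .fmt3(p$beta), alpha = .fmt3(p$alpha),
               rmse = .fmt3(result$rmse), outliers = out,
               stringsAsFactors = FALSE)
  } else {
    data.frame(model = result$spec$name, scheme = result$spec$scheme,
               alpha = .fmt3(p$alpha), gamma = .fmt3(p$gamma),
               rmse = .fmt3(result$rmse), outliers = out,
               stringsAsFactors = FALSE)
  }
}

## Weight table with 3-decimal weights and the per-ligand maximum
## flagged with an asterisk (the printed-table convention of bolding).
.format_weight_table <- function(weights) {
  wide <- weight_table(weights)
  sims <- setdiff(names(wide), c("ligand_id", "max_sim"))
  for (s in sims) {
    flag <- ifelse(wide$max_sim == s, "*", "")
    wide[[s]] <- paste0(.fmt3(wide[[s]]), flag)
  }
  wide[, c("ligand_id", sims), drop = FALSE]
}

.calibration_report <- function(result) {
  p <- result$params
  list(model = result$spec$name,
       scheme = result$spec$scheme,
       variant = result$spec$variant,
       params = list(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
                     kT = p$kT),
       se = as.list(result$se),
       rmse = result$rmse,
       converged = result$converged,
       n_iter = result$n_iter,
       outlier_threshold = result$outlier_threshold,
       outliers = result$outliers,
       per_ligand = result$per_ligand,
       weights = result$weights,
       restart_log = result$restart_log)
}

#' Run a calibration from a configuration file
#'
#' Reads the configured tables, calibrates the specified model and
#' writes `calibration.json` (full result), `model_summary.tsv` (one row:
#' model, beta, alpha or alpha, gamma, RMSE, outliers),
#' `weights.tsv` (per-ligand simulation weights, 3 decimals, per-ligand
#' maximum flagged with `*`) and `manifest.json` into `out_dir`.
#'
#' @param config Path to a YAML/JSON configuration, or an equivalent
#'   list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer seed recorded in the manifest (the
#'   calibration itself is deterministic).
#' @return The `lie_calibration` result, invisibly.
#' @export
run_calibrate <- function(config, out_dir, seed = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- read_lie_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- .config_dataset(config, base_dir)
  spec <- .config_spec(config)
  kT <- .config_kT(config)
  message("calibrating model '", spec$name, "' (scheme ", spec$scheme,
          ", variant ", spec$variant, ", kT = ", format(kT),
          " kJ/mol, tol = ", format(.config_opt(config, "tol", 1e-6)),
          ", max_iter = ", .config_opt(config, "max_iter", 500L),
          ", outlier threshold = ",
          .config_opt(config, "outlier_threshold", 4.184), " kJ/mol)")
  result <- lie_calibrate(
    dataset, spec, kT = kT,
    tol = .config_opt(config, "tol", 1e-6),
    rmse_tol = .config_opt(config, "rmse_tol", 1e-8),
    max_iter = .config_opt(config, "max_iter", 500L),
    outlier_threshold = .config_opt(config, "outlier_threshold", 4.184))
  jsonlite::write_json(.calibration_report(result),
                       file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  write_energy_table(.summary_row(result),
                     file.path(out_dir, "model_summary.tsv"))
  write_energy_table(.format_weight_table(result$weights),
                     file.path(out_dir, "weights.tsv"))
  .write_manifest(out_dir, config, .input_paths(config, base_dir), seed)
  invisible(result)
}

#' Scan an RMSE surface from a configuration file
#'
#' Evaluates [rmse_surface()] on the grid given in the config's
#' `surface` block and writes `surface.tsv` (long format: alpha, beta,
#' rmse, above_display_ceiling), `surface_matrix.tsv` (rows = alpha,
#' columns = beta) and `manifest.json`.  The display-ceiling annotation
#' records the conventional 2-5 kJ/mol contour window.
#'
#' @inheritParams run_calibrate
#' @return The `lie_surface`, invisibly.
#' @export
run_surface <- function(config, out_dir, seed = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- read_lie_config(config)
  }
  s <- config$surface
  grid_from <- function(block, what) {
    ## YAML 1.1 parses a bare key `n` as boolean FALSE; accept that
    ## spelling as well as the `points` alias
    npts <- block[["n"]]
    if (is.null(npts)) npts <- block[["points"]]
    if (is.null(npts)) npts <- block[["FALSE"]]
    if (is.null(block) || is.null(block$from) || is.null(block$to) ||
        is.null(npts) || npts < 1) {
      stop("config error: surface block needs ", what,
           ": {from, to, n}", call. = FALSE)
    }
    seq(block$from, block$to, length.out = npts)
  }
  alpha_grid <- grid_from(s$alpha, "alpha")
  beta_grid <- grid_from(s$beta, "beta")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- .config_dataset(config, base_dir)
  spec <- .config_spec(config)
  surf <- rmse_surface(dataset, spec, alpha_grid, beta_grid,
                       kT = .config_kT(config))
  tab <- surface_table(surf)
  write_energy_table(tab, file.path(out_dir, "surface.tsv"))
  mat <- as.data.frame(unclass(surf))
  names(mat) <- format(attr(surf, "beta"))
  mat <- cbind(alpha = attr(surf, "alpha"), mat)
  write_energy_table(mat, file.path(out_dir, "surface_matrix.tsv"))
  .write_manifest(out_dir, config, .input_paths(config, base_dir), seed)
  invisible(surf)
}

#' Predict affinities at fixed parameters from a configuration file
#'
#' Evaluates [lie_predict()] at the parameters in the config's `params`
#' block and writes `predictions.tsv`, `weights.tsv` and
#' `manifest.json`.
#'
#' @inheritParams run_calibrate
#' @return The prediction list, invisibly.
#' @export
run_predict <- function(config, out_dir, seed = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- read_lie_config(config)
  }
  pb <- config$params
  if (is.null(pb) || is.null(pb$alpha)) {
    stop("config error: predict needs a params block with alpha and ",
         "beta (or gamma)", call. = FALSE)
  }
  params <- lie_params(alpha = pb$alpha, beta = pb$beta,
                       gamma = pb$gamma, kT = .config_kT(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- .config_dataset(config, base_dir)
  spec <- .config_spec(config)
  pred <- lie_predict(dataset, spec, params)
  write_energy_table(pred$per_ligand, file.path(out_dir, "predictions.tsv"))
  write_energy_table(.format_weight_table(pred$weights),
                     file.path(out_dir, "weights.tsv"))
  .write_manifest(out_dir, config, .input_paths(config, base_dir), seed)
  invisible(pred)
}

#' Convert an IC50 table to a free-energy table
#'
#' Reads an IC50 table (`ligand_id`, `ic50_uM`, optional
#' `ic50_sigma_uM`), converts it with [convert_ic50_table()] and writes
#' the experimental-table format.  Invalid rows are reported with their
#' 1-based data row numbers; any invalid row aborts the conversion.
#'
#' @param input Path to the IC50 table.
#' @param output Path for the converted table.
#' @param temperature Temperature in K.
#' @return The converted data frame, invisibly.
#' @export
run_convert_ic50 <- function(input, output, temperature = 300) {
  df <- .read_raw_table(input)
  .require_columns(df, c("ligand_id", "ic50_uM"), "IC50")
  if (nrow(df) == 0L) {
    warning("IC50 table at '", input, "' has a header but no rows",
            call. = FALSE)
    out <- data.frame(ligand_id = character(), ic50_uM = numeric(),
                      ic50_sigma_uM = numeric(), dg_exp = numeric(),
                      dg_err = numeric(), stringsAsFactors = FALSE)
    write_energy_table(out, output)
    return(invisible(out))
  }
  df$ic50_uM <- .parse_numeric(df$ic50_uM, "ic50_uM")
  if ("ic50_sigma_uM" %in% names(df)) {
    df$ic50_sigma_uM <- .parse_numeric(df$ic50_sigma_uM, "ic50_sigma_uM",
                                       required = FALSE)
  } else {
    df$ic50_sigma_uM <- NA_real_
  }
  bad <- character()
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$ic50_uM[i]) || df$ic50_uM[i] <= 0) {
      bad <- c(bad, sprintf("row %d (%s): non-positive IC50", i,
                            df$ligand_id[i]))
    } else if (!is.na(df$ic50_sigma_uM[i]) &&
               df$ic50_sigma_uM[i] >= df$ic50_uM[i]) {
      bad <- c(bad, sprintf("row %d (%s): sigma >= IC50", i,
                            df$ligand_id[i]))
    }
  }
  if (length(bad)) {
    stop("invalid IC50 rows:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  out <- convert_ic50_table(df[, c("ligand_id", "ic50_uM",
                                   "ic50_sigma_uM")],
                            temperature = temperature)
  write_energy_table(out, output)
  invisible(out)
}

#' Generate a synthetic data set from a configuration file
#'
#' Builds a [generator_spec()] from the config's `generator` block
#' (fields as the constructor arguments) and writes the tables with
#' [write_lie_data()].
#'
#' @inheritParams run_calibrate
#' @param seed Optional seed overriding the one in the config.
#' @return The generated data, invisibly.
#' @export
run_generate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_lie_config(config)
  args <- config$generator
  if (is.null(args)) args <- list()
  if (!is.null(seed)) args$seed <- seed
  spec <- do.call(generator_spec, args)
  data <- generate_lie_data(spec)
  write_lie_data(data, out_dir)
  .write_manifest(out_dir, config, character(), spec$seed)
  invisible(data)
}
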