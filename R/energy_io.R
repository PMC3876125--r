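## Readers/writers for the columnar energy and affinity tables.
##
## All energies are kept internally in kJ/mol.  Tables are plain text with
## a header row; the delimiter (tab, comma or semicolon) is auto-detected
## unless given.  Decimal commas are not supported.

KCAL_TO_KJ <- 4.184

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  counts <- vapply(c("\t", ",", ";"), function(d) {
    lengths(regmatches(first, gregexpr(d, first, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0L)) "\t" else c("\t", ",", ";")[which.max(counts)]
}

.read_raw_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(delim)) delim <- .detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("format error in ", what, " table: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

## Parse a character column to numeric, reporting the 1-based data row of
## the first failure.
.parse_numeric <- function(x, column, required = TRUE) {
  blank <- is.na(x) | !nzchar(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !blank)
  if (length(bad)) {
    stop("parse error: non-numeric value '", x[bad[1]], "' in column '",
         column, "', row ", bad[1], call. = FALSE)
  }
  if (required && any(blank)) {
    stop("parse error: missing value in column '", column, "', row ",
         which(blank)[1], call. = FALSE)
  }
  out
}

.check_unit_column <- function(df, what) {
  if ("unit" %in% names(df) && nrow(df) > 0L &&
      !all(df$unit == "kJ/mol")) {
    stop("validation error in ", what,
         " table: unit column must read 'kJ/mol' (convert kcal/mol ",
         "inputs with unit = 'kcal/mol')", call. = FALSE)
  }
}

#' Read per-simulation bound-state interaction-energy averages
#'
#' Reads a table with one row per MD simulation of the protein-bound
#' state, identified by (`ligand_id`, `protein_conf`, `pose`,
#' `replicate`), carrying the ensemble-averaged electrostatic and van der
#' Waals ligand--surrounding interaction energies in kJ/mol.
#'
#' Required columns: `ligand_id`, `protein_conf`, `pose`, `replicate`,
#' `v_el_bound`, `v_vdw_bound`.  Optional: `n_frames`, `se_el`, `se_vdw`,
#' `unit` (must read `"kJ/mol"` when present).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; auto-detected among tab/comma/semicolon
#'   when `NULL`.
#' @param unit Unit of the energy columns in the file; `"kcal/mol"`
#'   inputs are converted to kJ/mol (x 4.184).
#' @return A data frame of bound-state averages, one row per simulation.
#' @seealso [read_free_energies()], [lie_dataset()]
#' @export
read_bound_energies <- function(path, delim = NULL,
                                unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  df <- .read_raw_table(path, delim)
  .require_columns(df, c("ligand_id", "protein_conf", "pose", "replicate",
                         "v_el_bound", "v_vdw_bound"), "bound-state")
  .check_unit_column(df, "bound-state")
  if (nrow(df) == 0L) {
    warning("bound-state table at '", path, "' has a header but no rows",
            call. = FALSE)
    return(data.frame(ligand_id = character(), protein_conf = character(),
                      pose = character(), replicate = character(),
                      v_el_bound = numeric(), v_vdw_bound = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    ligand_id    = df$ligand_id,
    protein_conf = df$protein_conf,
    pose         = df$pose,
    replicate    = df$replicate,
    v_el_bound   = .parse_numeric(df$v_el_bound, "v_el_bound"),
    v_vdw_bound  = .parse_numeric(df$v_vdw_bound, "v_vdw_bound"),
    stringsAsFactors = FALSE)
  for (opt in c("n_frames", "se_el", "se_vdw")) {
    if (opt %in% names(df)) {
      out[[opt]] <- .parse_numeric(df[[opt]], opt, required = FALSE)
    }
  }
  validate_bound_energies(out)
  if (unit == "kcal/mol") {
    for (cc in intersect(c("v_el_bound", "v_vdw_bound", "se_el", "se_vdw"),
                         names(out))) {
      out[[cc]] <- out[[cc]] * KCAL_TO_KJ
    }
  }
  out
}

#' Validate a bound-state averages table
#'
#' Checks the structural invariants of a bound-state table: non-empty key
#' fields, finite energies, unique simulation keys, positive frame counts.
#' Called by [read_bound_energies()]; useful directly for tables built in
#' code.
#'
#' @param bound Data frame of bound-state averages.
#' @return The table, invisibly, if valid.
#' @export
validate_bound_energies <- function(bound) {
  key_cols <- c("ligand_id", "protein_conf", "pose", "replicate")
  .require_columns(bound, c(key_cols, "v_el_bound", "v_vdw_bound"),
                   "bound-state")
  for (k in key_cols) {
    if (any(is.na(bound[[k]]) | !nzchar(bound[[k]]))) {
      stop("validation error: empty ", k, " in bound-state table",
           call. = FALSE)
    }
  }
  if (!all(is.finite(bound$v_el_bound)) ||
      !all(is.finite(bound$v_vdw_bound))) {
    stop("validation error: non-finite energy in bound-state table",
         call. = FALSE)
  }
  key <- do.call(paste, c(bound[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- bound[duplicated(key), key_cols, drop = FALSE][1, ]
    stop("validation error: duplicate simulation key (",
         paste(unlist(dup), collapse = ", "), ")", call. = FALSE)
  }
  if ("n_frames" %in% names(bound) &&
      any(!is.na(bound$n_frames) & bound$n_frames <= 0)) {
    stop("validation error: n_frames must be positive", call. = FALSE)
  }
  invisible(bound)
}

#' Read free-state interaction-energy averages
#'
#' Reads the table of ensemble-averaged electrostatic and van der Waals
#' interaction energies of each ligand free in water (one row per
#' ligand).  Required columns: `ligand_id`, `v_el_free`, `v_vdw_free`.
#'
#' @inheritParams read_bound_energies
#' @return A data frame with one row per ligand.
#' @export
read_free_energies <- function(path, delim = NULL,
                               unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  df <- .read_raw_table(path, delim)
  .require_columns(df, c("ligand_id", "v_el_free", "v_vdw_free"),
                   "free-state")
  .check_unit_column(df, "free-state")
  if (nrow(df) == 0L) {
    warning("free-state table at '", path, "' has a header but no rows",
            call. = FALSE)
    return(data.frame(ligand_id = character(), v_el_free = numeric(),
                      v_vdw_free = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    ligand_id  = df$ligand_id,
    v_el_free  = .parse_numeric(df$v_el_free, "v_el_free"),
    v_vdw_free = .parse_numeric(df$v_vdw_free, "v_vdw_free"),
    stringsAsFactors = FALSE)
  if (any(is.na(out$ligand_id) | !nzchar(out$ligand_id))) {
    stop("validation error: empty ligand_id in free-state table",
         call. = FALSE)
  }
  if (anyDuplicated(out$ligand_id)) {
    stop("validation error: ligand '",
         out$ligand_id[duplicated(out$ligand_id)][1],
         "' listed more than once in free-state table", call. = FALSE)
  }
  if (!all(is.finite(out$v_el_free)) || !all(is.finite(out$v_vdw_free))) {
    stop("validation error: non-finite energy in free-state table",
         call. = FALSE)
  }
  if (unit == "kcal/mol") {
    out$v_el_free <- out$v_el_free * KCAL_TO_KJ
    out$v_vdw_free <- out$v_vdw_free * KCAL_TO_KJ
  }
  out
}

#' Read an experimental-affinity table
#'
#' Reads ligand affinities given either directly as binding free energies
#' `dg_exp` (kJ/mol) or as inhibition constants `ic50_uM` (micromolar,
#' with optional `ic50_sigma_uM`).  When only IC50 is present, `dg_exp`
#' and its uncertainty are derived via [ic50_to_dg()] and
#' [ic50_error_to_dg_error()].  When both are present they are
#' cross-checked for agreement within 0.02 kJ/mol.
#'
#' @inheritParams read_bound_energies
#' @param temperature Temperature in K for the IC50 conversion.
#' @return A data frame with columns `ligand_id`, `dg_exp`, `dg_err`,
#'   `ic50_uM`, `ic50_sigma_uM` (the latter two `NA` when not supplied).
#' @export
read_experimental <- function(path, delim = NULL, temperature = 300) {
  df <- .read_raw_table(path, delim)
  .require_columns(df, "ligand_id", "experimental")
  if (!any(c("dg_exp", "ic50_uM") %in% names(df))) {
    stop("format error in experimental table: need a dg_exp or ic50_uM ",
         "column", call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("experimental table at '", path, "' has a header but no rows",
            call. = FALSE)
    return(data.frame(ligand_id = character(), dg_exp = numeric(),
                      dg_err = numeric(), ic50_uM = numeric(),
                      ic50_sigma_uM = numeric(), stringsAsFactors = FALSE))
  }
  n <- nrow(df)
  num_or_na <- function(col) {
    if (col %in% names(df)) .parse_numeric(df[[col]], col, required = FALSE)
    else rep(NA_real_, n)
  }
  out <- data.frame(
    ligand_id     = df$ligand_id,
    dg_exp        = num_or_na("dg_exp"),
    dg_err        = num_or_na("dg_err"),
    ic50_uM       = num_or_na("ic50_uM"),
    ic50_sigma_uM = num_or_na("ic50_sigma_uM"),
    stringsAsFactors = FALSE)
  validate_experimental(out, temperature = temperature)
}

#' Validate (and complete) an experimental-affinity table
#'
#' Enforces the affinity-record invariants and fills `dg_exp`/`dg_err`
#' from IC50 columns where absent.
#'
#' @param exp_df Data frame with at least `ligand_id` and one of
#'   `dg_exp`, `ic50_uM`.
#' @param temperature Temperature in K for the IC50 conversion.
#' @return The completed data frame.
#' @export
validate_experimental <- function(exp_df, temperature = 300) {
  if (any(is.na(exp_df$ligand_id) | !nzchar(exp_df$ligand_id))) {
    stop("validation error: empty ligand_id in experimental table",
         call. = FALSE)
  }
  if (anyDuplicated(exp_df$ligand_id)) {
    stop("validation error: ligand '",
         exp_df$ligand_id[duplicated(exp_df$ligand_id)][1],
         "' listed more than once in experimental table", call. = FALSE)
  }
  for (col in c("dg_exp", "dg_err", "ic50_uM", "ic50_sigma_uM")) {
    if (!col %in% names(exp_df)) exp_df[[col]] <- NA_real_
  }
  has_ic50 <- !is.na(exp_df$ic50_uM)
  has_dg   <- !is.na(exp_df$dg_exp)
  if (any(!has_ic50 & !has_dg)) {
    stop("validation error: ligand '",
         exp_df$ligand_id[!has_ic50 & !has_dg][1],
         "' has neither dg_exp nor ic50_uM", call. = FALSE)
  }
  if (any(has_ic50 & exp_df$ic50_uM <= 0)) {
    stop("validation error: non-positive ic50_uM for ligand '",
         exp_df$ligand_id[has_ic50 & exp_df$ic50_uM <= 0][1], "'",
         call. = FALSE)
  }
  sig <- exp_df$ic50_sigma_uM
  if (any(!is.na(sig) & sig < 0)) {
    stop("validation error: negative ic50_sigma_uM", call. = FALSE)
  }
  conv <- rep(NA_real_, nrow(exp_df))
  conv[has_ic50] <- ic50_to_dg(exp_df$ic50_uM[has_ic50] * 1e-6,
                               temperature = temperature)
  both <- has_ic50 & has_dg
  if (any(both)) {
    dev <- abs(conv[both] - exp_df$dg_exp[both])
    if (any(dev > 0.02)) {
      off <- exp_df$ligand_id[both][dev > 0.02][1]
      stop("validation error: dg_exp and IC50 disagree by more than ",
           "0.02 kJ/mol for ligand '", off, "'", call. = FALSE)
    }
  }
  fill <- has_ic50 & !has_dg
  exp_df$dg_exp[fill] <- conv[fill]
  fill_err <- has_ic50 & !is.na(sig) & is.na(exp_df$dg_err)
  if (any(fill_err)) {
    exp_df$dg_err[fill_err] <- ic50_error_to_dg_error(
      exp_df$ic50_uM[fill_err] * 1e-6, sig[fill_err] * 1e-6,
      temperature = temperature)
  }
  exp_df
}

#' Write an energy or affinity table
#'
#' Writes any of the package's tables back to delimited text.  A write
#' followed by the matching read reproduces all records.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(df, path, delim = "\t") {
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an interaction-energy time series
#'
#' Reads a whitespace-delimited file with columns `time_ps`, `v_el`,
#' `v_vdw`; lines starting with `#` are comments.  A non-numeric first
#' line is treated as a header.
#'
#' @param path Path to the time-series file.
#' @return A data frame with columns `time_ps`, `v_el`, `v_vdw`.
#' @export
read_energy_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    stop("insufficient data: no frames in '", path, "'", call. = FALSE)
  }
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = lines, header = header)
  if (ncol(df) < 3L) {
    stop("format error: time-series file needs columns time_ps, v_el, ",
         "v_vdw", call. = FALSE)
  }
  df <- df[, 1:3]
  names(df) <- c("time_ps", "v_el", "v_vdw")
  df
}

#' Average an interaction-energy time series
#'
#' Reduces a stored per-frame energy trace to the ensemble averages used
#' in the LIE model.  Means are plain arithmetic means over the retained
#' frames; standard errors come from block averaging (standard deviation
#' of block means divided by the square root of the number of blocks).
#'
#' @param ts Data frame with columns `time_ps`, `v_el`, `v_vdw` (as from
#'   [read_energy_timeseries()]).
#' @param discard Initial fraction of frames to drop as equilibration
#'   (default 0: stored production data are assumed post-equilibration).
#' @param blocks Number of equal blocks for the standard-error estimate
#'   (default 10; reduced to the number of frames when fewer).
#' @return A list with `mean_el`, `mean_vdw`, `se_el`, `se_vdw`,
#'   `n_frames`.
#' @export
average_timeseries <- function(ts, discard = 0, blocks = 10) {
  stopifnot(is.data.frame(ts), discard >= 0, discard < 1, blocks >= 1)
  if (is.unsorted(ts$time_ps, strictly = TRUE)) {
    stop("validation error: times must be strictly increasing",
         call. = FALSE)
  }
  n0 <- nrow(ts)
  keep <- ts[seq_len(n0) > floor(discard * n0), , drop = FALSE]
  n <- nrow(keep)
  if (n < 2L) {
    stop("insufficient data: fewer than 2 frames retained after discard",
         call. = FALSE)
  }
  block_se <- function(x) {
    b <- min(blocks, n)
    idx <- cut(seq_len(n), breaks = b, labels = FALSE)
    bm <- tapply(x, idx, mean)
    stats::sd(bm) / sqrt(b)
  }
  list(mean_el  = mean(keep$v_el),
       mean_vdw = mean(keep$v_vdw),
       se_el    = block_se(keep$v_el),
       se_vdw   = block_se(keep$v_vdw),
       n_frames = n)
}

#' Assemble a LIE data set
#'
#' Bundles the bound-state, free-state and experimental tables into a
#' single validated object.  Every ligand appearing in the bound table
#' must have exactly one free-state record and one experimental record.
#'
#' @param bound Bound-state averages (as from [read_bound_energies()]).
#' @param free Free-state averages (as from [read_free_energies()]).
#' @param experimental Experimental affinities (as from
#'   [read_experimental()]); `dg_exp` must be present or derivable.
#' @return An object of class `lie_dataset`.
#' @export
lie_dataset <- function(bound, free, experimental) {
  validate_bound_energies(bound)
  experimental <- validate_experimental(experimental)
  ligs <- unique(bound$ligand_id)
  no_free <- setdiff(ligs, free$ligand_id)
  if (length(no_free)) {
    stop("dataset assembly error: ligand(s) without a free-state record: ",
         paste(no_free, collapse = ", "), call. = FALSE)
  }
  no_exp <- setdiff(ligs, experimental$ligand_id)
  if (length(no_exp)) {
    stop("dataset assembly error: ligand(s) without an experimental ",
         "record: ", paste(no_exp, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(free$ligand_id)) {
    stop("dataset assembly error: duplicated free-state ligand",
         call. = FALSE)
  }
  structure(list(bound = bound, free = free, experimental = experimental),
            class = "lie_dataset")
}

#' @export
print.lie_dataset <- function(x, ...) {
  cat("<lie_dataset>\n")
  cat("  ligands:     ", length(unique(x$bound$ligand_id)), "\n")
  cat("  simulations: ", nrow(x$bound), "\n")
  cat("  protein conformations:",
      paste(sort(unique(x$bound$protein_conf)), collapse = ", "), "\n")
  cat("  poses:       ",
      paste(sort(unique(x$bound$pose)), collapse = ", "), "\n")
  cat("  replicates:  ",
      paste(sort(unique(x$bound$replicate)), collapse = ", "), "\n")
  invisible(x)
}
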