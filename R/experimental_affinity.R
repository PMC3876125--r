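## Conversion of inhibition data (IC50 +/- sigma) to relative binding
## free energies and their uncertainties.

#' Convert an IC50 to a relative binding free energy
#'
#' `dG_exp = R * T * ln(IC50 / c_ref)` with the gas constant
#' R = 0.0083145 kJ/(mol K) and a standard-state reference concentration
#' of 1 mol/L.  The result is a *relative* binding free energy: no
#' substrate-competition (Cheng-Prusoff) correction is applied.
#'
#' @param ic50 IC50 in mol/L (> 0, vectorized).
#' @param temperature Temperature in K (default 300).
#' @param reference Reference concentration in mol/L (default 1).
#' @return Binding free energy in kJ/mol (negative for sub-molar IC50).
#' @examples
#' ic50_to_dg(87e-6)   # -23.32 kJ/mol
#' ic50_to_dg(1)       # 0
#' @export
ic50_to_dg <- function(ic50, temperature = 300, reference = 1) {
  stopifnot(is.numeric(ic50), temperature > 0, reference > 0)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("validation error: IC50 must be positive and finite",
         call. = FALSE)
  }
  .GAS_KJ * temperature * log(ic50 / reference)
}

#' Propagate an IC50 uncertainty to the free-energy scale
#'
#' Maps the reported IC50 standard deviation to a free-energy
#' uncertainty as `R * T * ln(IC50 / (IC50 - sigma))`, i.e. the
#' free-energy shift produced by lowering the IC50 by one sigma.  The
#' expression diverges as sigma approaches IC50, so sigma must be
#' strictly smaller.  This propagation rule is inferred from exact
#' numerical agreement with published error bars rather than from a
#' stated derivation; see the methods vignette.
#'
#' @param ic50 IC50 in mol/L (vectorized).
#' @param sigma IC50 standard deviation in the same unit,
#'   `0 <= sigma < ic50`.
#' @inheritParams ic50_to_dg
#' @return Free-energy uncertainty in kJ/mol (>= 0).
#' @examples
#' ic50_error_to_dg_error(42e-6, 14e-6)  # 1.01 kJ/mol
#' @export
ic50_error_to_dg_error <- function(ic50, sigma, temperature = 300) {
  stopifnot(is.numeric(ic50), is.numeric(sigma), temperature > 0)
  if (any(ic50 <= 0)) {
    stop("validation error: IC50 must be positive", call. = FALSE)
  }
  if (any(sigma < 0)) {
    stop("validation error: sigma must be non-negative", call. = FALSE)
  }
  if (any(sigma >= ic50)) {
    stop("validation error: sigma >= IC50 gives a divergent ",
         "free-energy uncertainty", call. = FALSE)
  }
  .GAS_KJ * temperature * log(ic50 / (ic50 - sigma))
}

#' Convert an IC50 table to binding free energies
#'
#' Applies [ic50_to_dg()] and [ic50_error_to_dg_error()] to a table with
#' `ligand_id`, `ic50_uM` and optional `ic50_sigma_uM` columns
#' (micromolar units), filling/overwriting `dg_exp` and `dg_err`.
#'
#' @param df Input data frame.
#' @inheritParams ic50_to_dg
#' @return The data frame with `dg_exp` and `dg_err` columns in kJ/mol.
#' @export
convert_ic50_table <- function(df, temperature = 300) {
  .require_columns(df, c("ligand_id", "ic50_uM"), "IC50")
  df$dg_exp <- ic50_to_dg(df$ic50_uM * 1e-6, temperature = temperature)
  if ("ic50_sigma_uM" %in% names(df)) {
    has <- !is.na(df$ic50_sigma_uM)
    df$dg_err <- NA_real_
    df$dg_err[has] <- ic50_error_to_dg_error(
      df$ic50_uM[has] * 1e-6, df$ic50_sigma_uM[has] * 1e-6,
      temperature = temperature)
  }
  df
}
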