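# Unit conversion constants used throughout. Declared once; every module
# converts through these, never through locally repeated literals.

#' Physical constants and unit conversions
#'
#' Conversion factors between the atomic unit of energy (Hartree) and the
#' units conventional in antioxidant thermochemistry (kcal/mol for reaction
#' enthalpies, eV for orbital energies), plus the default gas-phase proton
#' enthalpy.
#'
#' `hartree_kcal` and `hartree_ev` imply 1 eV = 23.0605 kcal/mol, consistent
#' with the common rounding "1 eV is approximately 23 kcal/mol" to within
#' 0.3%.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_kcal}{kcal/mol per Hartree (627.5095).}
#'   \item{hartree_ev}{eV per Hartree (27.2114).}
#'   \item{gas_constant_kcal}{Ideal-gas constant in kcal/(mol K).}
#'   \item{proton_enthalpy_kcal}{Default gas-phase proton enthalpy,
#'     5/2 RT at 298.15 K, in kcal/mol (~1.48).}
#' }
#' @export
#' @examples
#' dft_constants$hartree_kcal
#' dft_constants$hartree_ev / dft_constants$hartree_kcal # Hartree per (eV*kcal...) ratio
dft_constants <- list(
  hartree_kcal = 627.5095,
  hartree_ev = 27.2114,
  gas_constant_kcal = 0.0019872,
  proton_enthalpy_kcal = 2.5 * 0.0019872 * 298.15
)

# round() in R rounds half to even; tables in this field round half up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if_not_finite <- function(..., what = "input") {
  vals <- c(...)
  if (!all(is.finite(vals))) {
    stop("non-finite ", what, " supplied", call. = FALSE)
  }
  invisible(TRUE)
}
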