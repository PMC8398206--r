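# Reactivity indices of a phenolic antioxidant from species enthalpies and
# frontier-orbital energies. All reaction enthalpies follow the vacuum,
# gas-phase conventions of antioxidant thermochemistry:
#   BDE :  ArOH -> ArO. + H.         (hydrogen atom transfer)
#   aIP :  ArOH -> ArOH.+ + e-       (single electron transfer)
#   aEA :  ArOH + e- -> ArOH.-
#   PA  :  ArOH -> ArO-  + H+        (deprotonation enthalpy, SPLET sense)
# The free electron contributes zero enthalpy; the gas-phase proton enthalpy
# defaults to 5/2 RT (~1.48 kcal/mol) and is configurable.

#' Bond dissociation enthalpy of an O-H bond
#'
#' Enthalpy of homolytic cleavage, `ArOH -> ArO. + H.`, in kcal/mol. The
#' hydrogen-atom enthalpy is an input computed at the same level of theory
#' as the parent, never a hard-coded constant. A negative BDE (exothermic
#' cleavage) is physically unusual but not an error.
#'
#' @param h_parent,h_radical,h_h_atom enthalpies of the parent molecule, the
#'   O-radical and the free hydrogen atom, in Hartree.
#' @return BDE in kcal/mol.
#' @export
#' @examples
#' bde(-500.0, -499.4, -0.497912) # 64.06
bde <- function(h_parent, h_radical, h_h_atom) {
  stop_if_not_finite(h_parent, h_radical, h_h_atom, what = "enthalpy")
  (h_radical + h_h_atom - h_parent) * dft_constants$hartree_kcal
}

#' Adiabatic ionization potential
#'
#' Enthalpy of `ArOH -> ArOH.+ + e-` with geometry relaxation permitted in
#' the cation, in kcal/mol; the free electron carries zero enthalpy. A
#' cation below the neutral gives a negative value, which is returned (with
#' a warning) rather than rejected.
#'
#' @param h_parent,h_cation_radical enthalpies in Hartree.
#' @return adiabatic IP in kcal/mol.
#' @export
#' @examples
#' adiabatic_ip(-500.0, -499.70665) # 184.08
adiabatic_ip <- function(h_parent, h_cation_radical) {
  stop_if_not_finite(h_parent, h_cation_radical, what = "enthalpy")
  out <- (h_cation_radical - h_parent) * dft_constants$hartree_kcal
  if (any(out < 0)) warning("negative adiabatic IP: cation radical below the neutral parent")
  out
}

#' Adiabatic electron affinity
#'
#' Enthalpy of `ArOH + e- -> ArOH.-`, in kcal/mol, reported as
#' `H(anion) - H(neutral)`: a *negative* value means the anion is bound.
#' The opposite sign convention (EA as energy released) also circulates in
#' the field; this package fixes the delta-H convention so that a bound
#' radical anion of a typical phenolic acid sits near -13 kcal/mol.
#'
#' @param h_parent,h_anion_radical enthalpies in Hartree.
#' @return adiabatic EA in kcal/mol (negative = bound anion).
#' @export
#' @examples
#' adiabatic_ea(-500.0, -500.0204) # -12.80
adiabatic_ea <- function(h_parent, h_anion_radical) {
  stop_if_not_finite(h_parent, h_anion_radical, what = "enthalpy")
  (h_anion_radical - h_parent) * dft_constants$hartree_kcal
}

#' Proton affinity (deprotonation enthalpy)
#'
#' Enthalpy of heterolytic deprotonation `ArOH -> ArO- + H+`, in kcal/mol.
#' The proton enthalpy is supplied in kcal/mol and defaults to the
#' ideal-gas value 5/2 RT at 298.15 K (~1.48 kcal/mol).
#'
#' @param h_parent,h_anion enthalpies of the parent and the deprotonated
#'   anion, in Hartree.
#' @param h_proton gas-phase proton enthalpy in kcal/mol.
#' @return PA in kcal/mol.
#' @export
#' @examples
#' proton_affinity(-500.0, -499.487, h_proton = 1.48) # 323.39
proton_affinity <- function(h_parent, h_anion,
                            h_proton = dft_constants$proton_enthalpy_kcal) {
  stop_if_not_finite(h_parent, h_anion, h_proton, what = "enthalpy")
  (h_anion - h_parent) * dft_constants$hartree_kcal + h_proton
}

#' Vertical ionization potential via Janak's theorem
#'
#' Janak's theorem (the DFT analogue of Koopmans' theorem) approximates the
#' vertical ionization potential by the negative HOMO eigenvalue.
#'
#' @param eps_homo HOMO orbital energy in Hartree.
#' @return vertical IP in eV.
#' @export
#' @examples
#' janak_vip(-0.263125) # 7.16
janak_vip <- function(eps_homo) {
  stop_if_not_finite(eps_homo, what = "orbital energy")
  -eps_homo * dft_constants$hartree_ev
}

#' Vertical electron affinity via Janak's theorem
#'
#' Approximated by the negative LUMO eigenvalue; a positive LUMO gives a
#' negative vertical EA, which is permitted.
#'
#' @param eps_lumo LUMO orbital energy in Hartree.
#' @return vertical EA in eV.
#' @export
#' @examples
#' janak_vea(-0.024622) # 0.67
janak_vea <- function(eps_lumo) {
  stop_if_not_finite(eps_lumo, what = "orbital energy")
  -eps_lumo * dft_constants$hartree_ev
}

#' Bundle the species energetics of one functional/basis combination
#'
#' Collects the per-species enthalpies and frontier-orbital energies needed
#' to compute the reactivity indices for one level of theory. Any species
#' may be omitted (`NULL`); [compute_indices()] then simply leaves the
#' dependent indices absent.
#'
#' @param functional,basis names identifying the combination.
#' @param h_parent parent enthalpy.
#' @param h_radical_by_site named numeric: O-radical enthalpy per
#'   deprotonation/abstraction site (e.g. `c(C3 = ..., C4 = ...)`).
#' @param h_cation_radical,h_anion_radical enthalpies of the ionized
#'   species.
#' @param h_anion_by_site named numeric: deprotonated-anion enthalpy per
#'   site.
#' @param h_h_atom hydrogen-atom enthalpy at the same level of theory.
#' @param eps_homo,eps_lumo frontier-orbital energies in Hartree
#'   (`eps_homo < eps_lumo` enforced when both are present).
#' @param units `"hartree"` (default) or `"kcal/mol"` for the enthalpy
#'   fields; orbital energies are always Hartree.
#' @return list of class `species_energetics`.
#' @export
species_energetics <- function(functional, basis,
                               h_parent = NULL,
                               h_radical_by_site = NULL,
                               h_cation_radical = NULL,
                               h_anion_radical = NULL,
                               h_anion_by_site = NULL,
                               h_h_atom = NULL,
                               eps_homo = NULL,
                               eps_lumo = NULL,
                               units = c("hartree", "kcal/mol")) {
  units <- match.arg(units)
  enths <- c(h_parent, h_radical_by_site, h_cation_radical,
             h_anion_radical, h_anion_by_site, h_h_atom)
  if (length(enths) && !all(is.finite(enths))) {
    stop("non-finite enthalpy in species record ", functional, "/", basis, call. = FALSE)
  }
  for (m in c("h_radical_by_site", "h_anion_by_site")) {
    v <- get(m)
    if (!is.null(v) && is.null(names(v))) {
      stop(m, " must be a named vector of per-site enthalpies", call. = FALSE)
    }
  }
  if (!is.null(eps_homo) && !is.null(eps_lumo) && !(eps_homo < eps_lumo)) {
    stop("eps_homo must lie below eps_lumo (", functional, "/", basis, ")", call. = FALSE)
  }
  structure(list(functional = functional, basis = basis,
                 h_parent = h_parent,
                 h_radical_by_site = h_radical_by_site,
                 h_cation_radical = h_cation_radical,
                 h_anion_radical = h_anion_radical,
                 h_anion_by_site = h_anion_by_site,
                 h_h_atom = h_h_atom,
                 eps_homo = eps_homo, eps_lumo = eps_lumo,
                 units = units),
            class = "species_energetics")
}

to_hartree <- function(x, units) {
  if (is.null(x)) return(NULL)
  if (units == "kcal/mol") x / dft_constants$hartree_kcal else x
}

#' Compute all reactivity indices from one species record
#'
#' Applies [bde()], [adiabatic_ip()], [adiabatic_ea()], [proton_affinity()],
#' [janak_vip()] and [janak_vea()] to whichever species the record carries.
#' Missing optional species yield absent index fields rather than errors;
#' use `require` to insist on a subset.
#'
#' @param s a [species_energetics()] record.
#' @param h_proton gas-phase proton enthalpy in kcal/mol.
#' @param require character vector of index names (among `"bde"`, `"aip"`,
#'   `"aea"`, `"pa"`, `"vip"`, `"vea"`) that must be computable; a missing
#'   ingredient raises an error naming the absent species.
#' @return list of class `reactivity_indices`: `bde_by_site`, `aip`, `aea`,
#'   `pa_by_site` (kcal/mol) and `vip`, `vea` (eV); absent entries are
#'   `NULL`.
#' @export
compute_indices <- function(s, h_proton = dft_constants$proton_enthalpy_kcal,
                            require = character()) {
  stopifnot(inherits(s, "species_energetics"))
  needs <- list(
    bde = c("h_parent", "h_radical_by_site", "h_h_atom"),
    aip = c("h_parent", "h_cation_radical"),
    aea = c("h_parent", "h_anion_radical"),
    pa  = c("h_parent", "h_anion_by_site"),
    vip = "eps_homo",
    vea = "eps_lumo")
  for (idx in require) {
    if (!idx %in% names(needs)) stop("unknown index '", idx, "'", call. = FALSE)
    missing <- needs[[idx]][vapply(needs[[idx]], function(f) is.null(s[[f]]), FALSE)]
    if (length(missing)) {
      stop("index '", idx, "' requested but species missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  u <- s$units
  hp <- to_hartree(s$h_parent, u)
  out <- list(bde_by_site = NULL, aip = NULL, aea = NULL,
              pa_by_site = NULL, vip = NULL, vea = NULL)
  if (!is.null(hp) && !is.null(s$h_radical_by_site) && !is.null(s$h_h_atom)) {
    out$bde_by_site <- vapply(to_hartree(s$h_radical_by_site, u),
                              bde, numeric(1),
                              h_parent = hp, h_h_atom = to_hartree(s$h_h_atom, u))
  }
  if (!is.null(hp) && !is.null(s$h_cation_radical)) {
    out$aip <- adiabatic_ip(hp, to_hartree(s$h_cation_radical, u))
  }
  if (!is.null(hp) && !is.null(s$h_anion_radical)) {
    out$aea <- adiabatic_ea(hp, to_hartree(s$h_anion_radical, u))
  }
  if (!is.null(hp) && !is.null(s$h_anion_by_site)) {
    out$pa_by_site <- vapply(to_hartree(s$h_anion_by_site, u),
                             proton_affinity, numeric(1),
                             h_parent = hp, h_proton = h_proton)
  }
  if (!is.null(s$eps_homo)) out$vip <- janak_vip(s$eps_homo)
  if (!is.null(s$eps_lumo)) out$vea <- janak_vea(s$eps_lumo)
  out$functional <- s$functional
  out$basis <- s$basis
  structure(out, class = "reactivity_indices")
}

#' @export
print.reactivity_indices <- function(x, digits = 2, ...) {
  cat(sprintf("Reactivity indices for %s/%s\n", x$functional, x$basis))
  fmt <- function(v) paste(sprintf("%s=%.*f", names(v), digits, v), collapse = "  ")
  if (!is.null(x$bde_by_site)) cat("  BDE [kcal/mol]: ", fmt(x$bde_by_site), "\n", sep = "")
  if (!is.null(x$aip)) cat(sprintf("  aIP [kcal/mol]: %.*f\n", digits, x$aip))
  if (!is.null(x$aea)) cat(sprintf("  aEA [kcal/mol]: %.*f\n", digits, x$aea))
  if (!is.null(x$pa_by_site)) cat("  PA  [kcal/mol]: ", fmt(x$pa_by_site), "\n", sep = "")
  if (!is.null(x$vip)) cat(sprintf("  vIP [eV]: %.*f\n", digits, x$vip))
  if (!is.null(x$vea)) cat(sprintf("  vEA [eV]: %.*f\n", digits, x$vea))
  invisible(x)
}
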