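# Expected values below were frozen from hand arithmetic on the unit
# constants (Hartree differences times 627.5095 or 27.2114).

test_that("bond dissociation enthalpy follows the homolytic cycle", {
  expect_equal(bde(-500.000000, -499.400000, -0.497912), 64.0612, tolerance = 1e-4)
  expect_equal(bde(-500.0, -499.5, -0.5), 0)
  # exothermic cleavage is permitted, not an error
  expect_lt(bde(-500.0, -499.9, -0.5), 0)
  expect_error(bde(NaN, -499.4, -0.5), "non-finite")
})

test_that("adiabatic ionization potential uses a zero-enthalpy electron", {
  expect_equal(adiabatic_ip(-500.000000, -499.706650), 184.0799, tolerance = 1e-4)
  expect_equal(adiabatic_ip(-500.0, -500.0), 0)
  expect_warning(v <- adiabatic_ip(-500.0, -500.1), "negative")
  expect_lt(v, 0)
})

test_that("adiabatic electron affinity keeps the bound-anion sign convention", {
  expect_equal(adiabatic_ea(-500.000000, -500.020400), -12.8012, tolerance = 1e-4)
  expect_equal(adiabatic_ea(-500.0, -500.0), 0)
  expect_equal(adiabatic_ea(-500.0, -499.99), 6.275095, tolerance = 1e-6)
})

test_that("proton affinity adds the gas-phase proton enthalpy", {
  expect_equal(proton_affinity(-500.000000, -499.487000, h_proton = 1.48),
               323.3924, tolerance = 1e-4)
  expect_equal(proton_affinity(-500.0, -500.0, h_proton = 0), 0)
  # default proton enthalpy is the ideal-gas 5/2 RT at 298.15 K
  expect_equal(dft_constants$proton_enthalpy_kcal, 1.48121, tolerance = 1e-5)
})

test_that("Janak vertical indices are the negated frontier eigenvalues", {
  expect_equal(janak_vip(-0.263125), 7.1600, tolerance = 1e-4)
  expect_equal(janak_vip(0), 0)
  expect_equal(janak_vip(-1), 27.2114)
  expect_equal(janak_vea(-0.024622), 0.6700, tolerance = 1e-4)
  expect_equal(janak_vea(0.036752), -1.0001, tolerance = 1e-4)
})

test_that("the eV/kcal conversion agrees with the 23.0 rounding within 0.3%", {
  ev_in_kcal <- dft_constants$hartree_kcal / dft_constants$hartree_ev
  expect_lt(abs(ev_in_kcal - 23.0) / 23.0, 0.003)
})

test_that("compute_indices composes the individual operations per site", {
  s <- species_energetics(
    "M06-2X", "6-311G(d,p)",
    h_parent = -500.0,
    h_radical_by_site = c(C3 = -499.355, C4 = -499.375),
    h_cation_radical = -499.70665,
    h_anion_radical = -500.0204,
    h_anion_by_site = c(C3 = -499.46, C4 = -499.49),
    h_h_atom = -0.497912,
    eps_homo = -0.263125, eps_lumo = -0.024622)
  idx <- compute_indices(s, h_proton = 1.48)
  expect_named(idx$bde_by_site, c("C3", "C4"))
  expect_equal(unname(idx$bde_by_site["C3"]),
               bde(-500.0, -499.355, -0.497912))
  expect_equal(idx$aip, adiabatic_ip(-500.0, -499.70665))
  expect_equal(idx$aea, adiabatic_ea(-500.0, -500.0204))
  expect_equal(unname(idx$pa_by_site["C4"]),
               proton_affinity(-500.0, -499.49, h_proton = 1.48))
  expect_equal(idx$vip, janak_vip(-0.263125))
  expect_equal(idx$vea, janak_vea(-0.024622))
})

test_that("missing optional species yield absent indices, not errors", {
  s <- species_energetics("BLYP", "cc-pVDZ",
                          h_parent = -500.0,
                          h_cation_radical = -499.7,
                          eps_homo = -0.25, eps_lumo = -0.01)
  idx <- compute_indices(s)
  expect_null(idx$bde_by_site)
  expect_null(idx$pa_by_site)
  expect_false(is.null(idx$aip))
  expect_error(compute_indices(s, require = "pa"), "h_anion_by_site")
  expect_error(compute_indices(s, require = "nonsense"), "unknown index")
})

test_that("indices are invariant to pre-converting enthalpies to kcal/mol", {
  s_hartree <- species_energetics(
    "M11", "def2-TZVP",
    h_parent = -500.0,
    h_radical_by_site = c(C3 = -499.355, C4 = -499.375),
    h_cation_radical = -499.70665,
    h_anion_radical = -500.0204,
    h_anion_by_site = c(C3 = -499.46, C4 = -499.49),
    h_h_atom = -0.497912,
    eps_homo = -0.263125, eps_lumo = -0.024622)
  K <- dft_constants$hartree_kcal
  s_kcal <- species_energetics(
    "M11", "def2-TZVP",
    h_parent = -500.0 * K,
    h_radical_by_site = c(C3 = -499.355, C4 = -499.375) * K,
    h_cation_radical = -499.70665 * K,
    h_anion_radical = -500.0204 * K,
    h_anion_by_site = c(C3 = -499.46, C4 = -499.49) * K,
    h_h_atom = -0.497912 * K,
    eps_homo = -0.263125, eps_lumo = -0.024622,
    units = "kcal/mol")
  a <- compute_indices(s_hartree)
  b <- compute_indices(s_kcal)
  for (field in c("bde_by_site", "aip", "aea", "pa_by_site", "vip", "vea")) {
    expect_lt(max(abs(unlist(a[[field]]) - unlist(b[[field]]))), 1e-9)
  }
})

test_that("species records validate their invariants", {
  expect_error(species_energetics("A", "B", h_parent = Inf), "non-finite")
  expect_error(species_energetics("A", "B", h_radical_by_site = c(-499.4)), "named")
  expect_error(species_energetics("A", "B", eps_homo = -0.1, eps_lumo = -0.2),
               "eps_homo")
})
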