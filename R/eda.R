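# Extended-transition-state energy decomposition. The interaction energy is
# resolved by telescoping through two intermediate states:
#
#   E_A + E_B                         (isolated, frozen geometries)
#     -> E[rho_A + rho_B]            electrostatics + XC nonadditivity
#     -> E[rho0]                     Pauli (antisymmetrization)
#     -> E_AB                        orbital relaxation
#
# so dE_elstat + dE_Pauli + dE_orb = E_AB - E_A - E_B identically, with
# dispersion / MP2-correlation / composite-correction deltas added on top.

#' Geometric preparation energy
#'
#' Energy of distorting each fragment from its relaxed geometry to the frozen
#' geometry it adopts inside the adduct: the difference of fragment SCF
#' energies at the two geometries. Reported as 0 (with a flag) when no relaxed
#' geometries were supplied.
#'
#' @param system a [nocv_system()] (uses `system$relaxed`).
#' @param method a [nocv_method()].
#' @return list with `E` (Hartree) and logical `available`.
#' @export
preparation_energy <- function(system, method) {
  if (is.null(system$relaxed) ||
      all(vapply(system$relaxed, is.null, logical(1))))
    return(list(E = 0, available = FALSE))
  frozen <- list(system$fragA, system$fragB)
  E <- 0
  for (k in 1:2) {
    rg <- if (length(system$relaxed) >= k) system$relaxed[[k]] else NULL
    if (is.null(rg)) next
    if (isTRUE(all.equal(rg$xyz, frozen[[k]]$xyz, tolerance = 1e-12))) next
    if (length(rg$Z) == 1) next      # single atoms have no internal coordinates
    E <- E + run_scf(frozen[[k]], method)$E - run_scf(rg, method)$E
  }
  list(E = E, available = TRUE)
}

#' Quasi-classical electrostatic interaction of the frozen fragments
#'
#' Sum of the four cross terms between the frozen fragment charge
#' distributions: attraction of each density to the other fragment's nuclei,
#' cross nuclear repulsion, and the Coulomb repulsion between the densities,
#' all evaluated with supermolecule integrals.
#'
#' @param PA,PB embedded fragment total density matrices (supermolecule AO
#'   basis, occupancy summed over spin).
#' @param system the [nocv_system()].
#' @param ints supermolecule [system_integrals()].
#' @return energy in Hartree.
#' @export
electrostatic_energy <- function(PA, PB, system, ints) {
  VA <- fragment_attraction(ints, system$idxA)
  VB <- fragment_attraction(ints, system$idxB)
  enuc_cross <- nuclear_repulsion_cross(system$fragA$Z, system$fragA$xyz,
                                        system$fragB$Z, system$fragB$xyz)
  sum(PB * VA) + sum(PA * VB) + enuc_cross +
    sum(PA * coulomb_matrix(ints, PB))
}

#' Exchange(-correlation) nonadditivity of the frozen densities
#'
#' The difference `E_XC[rho_A + rho_B] - E_XC[rho_A] - E_XC[rho_B]`. For the
#' single-determinant backend the XC term is the full HF exchange
#' (`hf_exchange`-scaled), evaluated per spin channel on the same embedded
#' density matrices used by [electrostatic_energy()].
#'
#' @param PAs,PBs per-spin embedded fragment densities: lists with `a`, `b`.
#' @param ints supermolecule [system_integrals()].
#' @param method a [nocv_method()].
#' @return energy in Hartree.
#' @export
xc_cross_energy <- function(PAs, PBs, ints, method) {
  ex <- function(Pa, Pb) {
    -0.5 * (sum(exchange_matrix(ints, Pa) * Pa) +
              sum(exchange_matrix(ints, Pb) * Pb))
  }
  a <- method$hf_exchange
  a * (ex(PAs$a + PBs$a, PAs$b + PBs$b) - ex(PAs$a, PAs$b) - ex(PBs$a, PBs$b))
}

#' Pauli repulsion energies
#'
#' Returns both variants: the raw antisymmetrization cost
#' `dE_Pauli_raw = E[rho0] - E[rho_A + rho_B]` (always destabilizing for
#' overlapping closed shells) and the conventionally reported
#' `dE_Pauli = dE_Pauli_raw + dE_XC0`.
#'
#' @param promol a [nocv_promolecule()].
#' @param dE_xc0 the XC nonadditivity from [xc_cross_energy()].
#' @return list with `raw` and `reported` (Hartree).
#' @export
pauli_energies <- function(promol, dE_xc0) {
  raw <- promol$E0 - promol$E_sum
  list(raw = raw, reported = raw + dE_xc0)
}

# Transition-state Fock matrices: F at rho_TS = (rho + rho0)/2, at rho, at
# rho0, and the 2/3-1/6-1/6 combination used for channel energies.
transition_state_focks <- function(scf_AB, promol, ints) {
  half <- list(a = (scf_AB$Pa + promol$P0a) / 2,
               b = (scf_AB$Pb + promol$P0b) / 2)
  evTS <- evaluate_at_density(ints, half$a, half$b)
  ev1 <- evaluate_at_density(ints, scf_AB$Pa, scf_AB$Pb)
  ev0 <- promol$eval0
  comb <- function(sel) {
    2 / 3 * evTS[[sel]] + 1 / 6 * ev1[[sel]] + 1 / 6 * ev0[[sel]]
  }
  list(F_TS = list(a = evTS$Fa, b = evTS$Fb),
       F_ad = list(a = ev1$Fa, b = ev1$Fb),
       F_0 = list(a = ev0$Fa, b = ev0$Fb),
       F_tilde = list(a = comb("Fa"), b = comb("Fb")))
}

#' Orbital-relaxation energy, exact and transition-state estimates
#'
#' The exact difference `E[rho] - E[rho0]` plus the two linearized trace
#' expressions: first order in the transition-state Fock, `Tr{F^TS dP}`, and
#' the weighted 2/3-1/6-1/6 combination `Tr{F~ dP}` that anchors the
#' per-channel energies. For a quadratic (Hartree-Fock) energy functional the
#' Fock matrix is linear in the density, so both estimates coincide with the
#' exact difference to numerical precision; with a nonlinear XC term they are
#' approximations.
#'
#' @param scf_AB converged adduct SCF.
#' @param promol the [nocv_promolecule()].
#' @param tsf transition-state Fock bundle.
#' @return list with `exact`, `ets1`, `ets2` (Hartree).
#' @export
orbital_energy <- function(scf_AB, promol, tsf) {
  dPa <- scf_AB$Pa - promol$P0a
  dPb <- scf_AB$Pb - promol$P0b
  tr2 <- function(Fs) sum(Fs$a * dPa) + sum(Fs$b * dPb)
  list(exact = scf_AB$E - promol$E0,
       ets1 = tr2(tsf$F_TS),
       ets2 = tr2(tsf$F_tilde))
}

#' Dispersion-energy change upon complex formation
#'
#' `E_disp(AB) - E_disp(A) - E_disp(B)` at the frozen geometries, through the
#' configured provider ([register_dispersion_provider()]).
#'
#' @param system a [nocv_system()].
#' @param method a [nocv_method()].
#' @return energy in Hartree.
#' @export
dispersion_delta <- function(system, method) {
  if (identical(method$dispersion, "none")) return(0)
  dispersion_energy(system$adduct, method) -
    dispersion_energy(system$fragA, method) -
    dispersion_energy(system$fragB, method)
}

# ---- correction providers (composite-method style grouped deltas) --------

.correction_registry <- new.env(parent = emptyenv())

#' Register a composite-correction provider
#'
#' Providers supply additive semi-empirical corrections (geometric
#' counterpoise, short-range basis penalties, ...) computed for adduct and
#' fragments alike; their deltas are grouped into a single corrections line
#' of the decomposition. The default is no providers.
#'
#' @param name identifier.
#' @param fun `function(species, method)` returning Hartree.
#' @export
register_correction_provider <- function(name, fun) {
  assign(name, fun, envir = .correction_registry)
  invisible(name)
}

#' @rdname register_correction_provider
#' @export
clear_correction_providers <- function() {
  rm(list = ls(.correction_registry), envir = .correction_registry)
  invisible(NULL)
}

corrections_delta <- function(system, method) {
  provs <- ls(.correction_registry)
  if (length(provs) == 0) return(0)
  sum(vapply(provs, function(nm) {
    f <- get(nm, envir = .correction_registry)
    f(system$adduct, method) - f(system$fragA, method) - f(system$fragB, method)
  }, numeric(1)))
}

#' Full extended-transition-state decomposition
#'
#' Orchestrates the three SCF calculations (adduct and both frozen
#' fragments), builds the promolecule, and assembles every term of the
#' decomposition with its telescoping-closure residual. For MP2-augmented
#' methods the scaled correlation-energy difference is reported as a separate
#' MP2-correlation line computed from the SCF orbitals of each species.
#'
#' @param system a [nocv_system()] from [build_system()] or [make_fixture()].
#' @param method a [nocv_method()].
#' @param order promolecule orthogonalization order (`"AB"` or `"BA"`).
#' @return an object of class `nocv_eda`; energies in Hartree in `$terms`,
#'   kcal/mol view via [eda_kcal()] or `print()`.
#' @export
decompose <- function(system, method = nocv_method(), order = "AB") {
  stopifnot(inherits(system, "nocv_system"), inherits(method, "nocv_method"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ints <- stage("supermolecule integrals",
                system_integrals(system$adduct, method$basis))
  force_u <- method$force_unrestricted ||
    system$adduct$multiplicity > 1L ||
    system$fragA$multiplicity > 1L || system$fragB$multiplicity > 1L
  m_run <- method
  m_run$force_unrestricted <- force_u
  scf_AB <- stage("adduct SCF", run_scf(system$adduct, m_run, ints = ints))
  scf_A <- stage("fragment A SCF", run_scf(system$fragA, m_run))
  scf_B <- stage("fragment B SCF", run_scf(system$fragB, m_run))
  # (open-shell orientation: build_system already assigned fragment B its
  # excess-beta electron counts, which run_scf honors per spin channel)
  promol <- stage("promolecule",
                  build_promolecule(scf_A, scf_B, system, ints, order = order))

  PAs <- promol$PA; PBs <- promol$PB
  PA <- PAs$a + PAs$b; PB <- PBs$a + PBs$b

  dE_elstat <- stage("electrostatics",
                     electrostatic_energy(PA, PB, system, ints))
  dE_xc0 <- stage("XC nonadditivity", xc_cross_energy(PAs, PBs, ints, method))
  pauli <- pauli_energies(promol, dE_xc0)
  tsf <- stage("transition-state Focks",
               transition_state_focks(scf_AB, promol, ints))
  orb <- orbital_energy(scf_AB, promol, tsf)
  prep <- preparation_energy(system, method)
  dE_disp <- stage("dispersion", dispersion_delta(system, method))
  dE_corr <- stage("corrections", corrections_delta(system, method))

  # MP2 correlation line for double-hybrid-style methods
  dE_mp2 <- 0; mp2 <- NULL
  if (method$mp2_coefficient > 0) {
    mp2 <- stage("MP2 correlation", list(
      AB = mp2_correlation(scf_AB, method),
      A = mp2_correlation(scf_A, method),
      B = mp2_correlation(scf_B, method)))
    dE_mp2 <- method$mp2_coefficient *
      (mp2$AB$E_mp2 - mp2$A$E_mp2 - mp2$B$E_mp2)
  }

  # fragment energies in their own (monomer) basis; the supramolecular
  # interaction energy
  dE_scf <- scf_AB$E - scf_A$E - scf_B$E
  dE_int <- dE_scf + dE_disp + dE_mp2 + dE_corr
  closure <- dE_scf - (dE_elstat + pauli$reported + orb$exact)

  terms <- list(
    dE_prep = prep$E, prep_available = prep$available,
    dE_elstat = dE_elstat, dE_xc0 = dE_xc0,
    dE_pauli_raw = pauli$raw, dE_pauli = pauli$reported,
    dE_orb = orb$exact, dE_orb_ets1 = orb$ets1, dE_orb_ets2 = orb$ets2,
    dE_disp = dE_disp, dE_mp2 = dE_mp2, dE_corrections = dE_corr,
    dE_int = dE_int, dE_binding = prep$E + dE_int,
    closure_residual = closure)

  structure(list(system = system, method = method, ints = ints,
                 scf = list(AB = scf_AB, A = scf_A, B = scf_B),
                 promolecule = promol, ts_focks = tsf, mp2 = mp2,
                 terms = terms),
            class = "nocv_eda")
}

#' Decomposition terms in kcal/mol
#' @param eda an `nocv_eda` object.
#' @return named numeric vector (kcal/mol).
#' @export
eda_kcal <- function(eda) {
  t <- eda$terms
  keys <- c("dE_int", "dE_orb", "dE_pauli", "dE_elstat", "dE_disp",
            "dE_mp2", "dE_corrections", "dE_prep", "dE_binding",
            "dE_pauli_raw", "dE_xc0", "dE_orb_ets2")
  vapply(keys, function(k) t[[k]] * HARTREE_TO_KCAL, numeric(1))
}

#' @export
print.nocv_eda <- function(x, ...) {
  k <- eda_kcal(x)
  fmt <- function(v) sprintf("%10.2f", v + 0)
  cat("ETS decomposition (kcal/mol)\n")
  cat("  dE_int      ", fmt(k[["dE_int"]]), "\n")
  cat("  dE_orb      ", fmt(k[["dE_orb"]]), "\n")
  cat("  dE_Pauli    ", fmt(k[["dE_pauli"]]), "\n")
  cat("  dE_elstat   ", fmt(k[["dE_elstat"]]), "\n")
  cat("  dE_disp     ", fmt(k[["dE_disp"]]), "\n")
  if (x$method$mp2_coefficient > 0)
    cat("  dE_C(MP2)   ", fmt(k[["dE_mp2"]]), "\n")
  if (x$terms$dE_corrections != 0)
    cat("  corrections ", fmt(k[["dE_corrections"]]), "\n")
  cat(sprintf("  closure residual %.3e Ha\n", x$terms$closure_residual))
  invisible(x)
}
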