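# Parameterized toy systems and independent brute-force oracles. Fixtures
# make the full pipeline testable without any external geometry files; the
# default separations are for property tests, not for reproducing published
# benchmark tables (which additionally require basis sets and functionals
# beyond the built-in backend).

#' Construct a named fixture system
#'
#' @param name one of `"he2"`, `"heh+"`, `"h2_from_atoms"`, `"ar2"`,
#'   `"arli+"`, `"be2"`, `"hf2"`, `"water2"`.
#' @param R separation parameter in Angstrom (meaning depends on the
#'   fixture: interatomic distance for the diatomics, heavy-atom distance for
#'   the hydrogen-bonded dimers). Defaults per fixture.
#' @return a [nocv_system()].
#' @export
make_fixture <- function(name, R = NULL) {
  name <- tolower(name)
  lin <- function(syms, zs) list(symbols = syms,
                                 coords = cbind(0, 0, zs))
  sys <- switch(
    name,
    he2 = {
      R <- R %||% 2.0
      build_system(lin(c("He", "He"), c(0, R)), list(1L, 2L))
    },
    "heh+" = {
      R <- R %||% 0.772
      build_system(lin(c("He", "H"), c(0, R)), list(1L, 2L),
                   charges = c(0L, 1L), mults = c(1L, 1L))
    },
    h2_from_atoms = {
      R <- R %||% 0.74
      build_system(lin(c("H", "H"), c(0, R)), list(1L, 2L),
                   charges = c(0L, 0L), mults = c(2L, 2L),
                   spin_orientation = "ab")
    },
    ar2 = {
      R <- R %||% 3.76
      build_system(lin(c("Ar", "Ar"), c(0, R)), list(1L, 2L))
    },
    "arli+" = {
      R <- R %||% 2.4
      build_system(lin(c("Ar", "Li"), c(0, R)), list(1L, 2L),
                   charges = c(0L, 1L), mults = c(1L, 1L))
    },
    be2 = {
      R <- R %||% 2.45
      build_system(lin(c("Be", "Be"), c(0, R)), list(1L, 2L))
    },
    hf2 = {
      # hydrogen-bonded HF dimer, donor F-H...F, R = F...F distance
      R <- R %||% 2.74
      rFH <- 0.92
      coords <- rbind(c(0, 0, 0),            # F donor
                      c(0, 0, rFH),          # H donor (points at acceptor F)
                      c(0, 0, R),            # F acceptor
                      c(0.89, 0, R + 0.23))  # H acceptor, bent away
      build_system(list(symbols = c("F", "H", "F", "H"), coords = coords),
                   list(1:2, 3:4))
    },
    water2 = {
      # near-linear hydrogen-bonded water dimer, R = O...O distance
      R <- R %||% 2.98
      rOH <- 0.9572; ang <- 104.52 * pi / 180
      donor <- rbind(c(0, 0, 0),
                     c(0, 0, rOH),                       # donating H on the O-O axis
                     c(sin(ang) * rOH, 0, cos(ang) * rOH))
      acc_O <- c(0, 0, R)
      h1 <- acc_O + c(sin(ang / 2) * rOH, cos(ang / 2) * rOH * 0.4,
                      cos(ang / 2) * rOH * 0.8)
      h2 <- acc_O + c(-sin(ang / 2) * rOH, cos(ang / 2) * rOH * 0.4,
                      cos(ang / 2) * rOH * 0.8)
      build_system(list(symbols = c("O", "H", "H", "O", "H", "H"),
                        coords = rbind(donor, acc_O, h1, h2)),
                   list(1:3, 4:6))
    },
    stop("unknown fixture '", name, "'")
  )
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Slater-determinant energy oracle
#'
#' Brute-force determinant energy assembled term by term from one-electron
#' integrals and explicit Coulomb/exchange double sums over occupied
#' orbitals, independent of the production density-matrix energy assembly.
#' Intended to cross-check promolecule and SCF energies on minimal-basis
#' fixtures; guarded to small basis dimensions.
#'
#' @param C_occ occupied orbital coefficients: either one matrix (closed
#'   shell, each orbital doubly occupied) or a list with per-spin matrices
#'   `a` and `b`.
#' @param ints [system_integrals()] of the system whose nuclear frame and
#'   AO basis define the energy.
#' @return energy in Hartree.
#' @export
determinant_energy_oracle <- function(C_occ, ints) {
  if (ints$n > 8) stop("determinant oracle guarded to <= 8 basis functions")
  eri <- array(ints$eri, dim = rep(ints$n, 4))
  mo_h <- function(ci, cj) drop(crossprod(ci, ints$hcore %*% cj))
  mo_eri <- function(ci, cj, ck, cl) {
    # (ij|kl) by explicit summation
    v <- 0
    for (mu in seq_len(ints$n)) for (nu in seq_len(ints$n))
      for (la in seq_len(ints$n)) for (si in seq_len(ints$n))
        v <- v + ci[mu] * cj[nu] * ck[la] * cl[si] * eri[mu, nu, la, si]
    v
  }
  if (is.list(C_occ)) {
    Ca <- C_occ$a; Cb <- C_occ$b
    na <- ncol(Ca); nb <- ncol(Cb)
    E <- 0
    for (i in seq_len(na)) E <- E + mo_h(Ca[, i], Ca[, i])
    for (i in seq_len(nb)) E <- E + mo_h(Cb[, i], Cb[, i])
    allC <- cbind(Ca, Cb)
    spin <- c(rep("a", na), rep("b", nb))
    ntot <- na + nb
    for (i in seq_len(ntot)) for (j in seq_len(ntot)) {
      if (i == j) next
      J <- mo_eri(allC[, i], allC[, i], allC[, j], allC[, j])
      E <- E + 0.5 * J
      if (spin[i] == spin[j])
        E <- E - 0.5 * mo_eri(allC[, i], allC[, j], allC[, j], allC[, i])
    }
    return(E + ints$enuc)
  }
  no <- ncol(C_occ)
  E <- 0
  for (i in seq_len(no)) E <- E + 2 * mo_h(C_occ[, i], C_occ[, i])
  for (i in seq_len(no)) for (j in seq_len(no)) {
    E <- E + 2 * mo_eri(C_occ[, i], C_occ[, i], C_occ[, j], C_occ[, j]) -
      mo_eri(C_occ[, i], C_occ[, j], C_occ[, j], C_occ[, i])
  }
  E + ints$enuc
}
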