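# Integral bundle for one species / AO basis. All matrices are in the AO
# basis of `species`; `eri` is the full (mu nu | la si) array (chemists'
# notation). The reshaped `eri_J` / `eri_K` matrices turn Coulomb and
# exchange builds into single matrix-vector products.

MAX_AO <- 48L  # full in-core ERI tensor guard

#' Compute the integral bundle for a species
#'
#' @param species a [nocv_species()].
#' @param basis basis-set name.
#' @return a list with overlap `S`, kinetic `T`, total nuclear attraction
#'   `Vne`, core Hamiltonian `hcore`, ERI tensor `eri`, nuclear repulsion
#'   `enuc`, Loewdin transforms `S_half`/`S_invhalf`, and the basis object.
#' @export
system_integrals <- function(species, basis = "sto-3g") {
  b <- build_basis(species, basis)
  if (b$nao > MAX_AO)
    stop("basis dimension ", b$nao, " exceeds the in-core ERI guard (", MAX_AO, ")")
  S <- .overlap_matrix(b)
  T_ <- .kinetic_matrix(b)
  Vne <- .nuclear_attraction(b, as.numeric(species$Z), species$xyz)
  eri <- .eri_array(b)
  n <- b$nao
  eJ <- matrix(eri, n * n, n * n)                       # (mu nu | la si)
  eK <- matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n) # (mu la | nu si)
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-10) stop("overlap matrix not positive definite")
  S_half <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  S_invhalf <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  list(species = species, basis = b, n = n,
       S = S, T = T_, Vne = Vne, hcore = T_ + Vne,
       eri = eri, eri_J = eJ, eri_K = eK,
       enuc = nuclear_repulsion(species$Z, species$xyz),
       S_half = S_half, S_invhalf = S_invhalf)
}

# Nuclear attraction operator for a subset of this system's nuclei,
# in the full AO basis (the per-fragment external potential of the
# electrostatic term).
fragment_attraction <- function(ints, atom_idx) {
  sp <- ints$species
  .nuclear_attraction(ints$basis, as.numeric(sp$Z[atom_idx]),
                      sp$xyz[atom_idx, , drop = FALSE])
}

coulomb_matrix <- function(ints, P) {
  n <- ints$n
  matrix(ints$eri_J %*% as.numeric(P), n, n)
}

exchange_matrix <- function(ints, P) {
  n <- ints$n
  matrix(ints$eri_K %*% as.numeric(P), n, n)
}
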