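# The promolecule: the antisymmetrized, renormalized juxtaposition of the
# frozen fragment determinants at the adduct geometry. Operationally, the
# occupied fragment orbitals are embedded in the supermolecule AO basis and
# sequentially orthonormalized in the S metric (Schmidt orthogonalization);
# the resulting determinant's density matrix P0 and energy E[rho0] define
# the reference state from which orbital relaxation is measured.

#' Sequential Gram-Schmidt orthonormalization in the S metric
#'
#' Orthonormalizes the concatenated columns of `blocks` against the metric
#' `S`, in order. Each vector is projected against all previously accepted
#' vectors and renormalized; a residual S-norm below `threshold` signals
#' linear dependence and is a hard error naming the offending orbital.
#'
#' @param blocks list of coefficient matrices (columns = orbitals), each
#'   internally S-orthonormal.
#' @param S overlap (metric) matrix.
#' @param threshold linear-dependence threshold on the residual S-norm.
#' @return matrix of orthonormalized coefficient columns, in input order.
#' @export
schmidt_orthonormalize <- function(blocks, S, threshold = 1e-8) {
  C <- do.call(cbind, blocks)
  if (ncol(C) > nrow(C))
    stop("more orbitals (", ncol(C), ") than basis functions (", nrow(C), ")")
  n <- ncol(C)
  if (n == 0) return(C)
  out <- matrix(0, nrow(C), n)
  for (k in seq_len(n)) {
    v <- C[, k]
    if (k > 1) {
      prev <- out[, seq_len(k - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, S %*% v)
    }
    nrm <- sqrt(drop(crossprod(v, S %*% v)))
    if (!is.finite(nrm) || nrm < threshold)
      stop("linear dependence in Schmidt orthogonalization at orbital ", k,
           " (residual S-norm ", format(nrm, digits = 3), ")")
    out[, k] <- v / nrm
  }
  out
}

#' Build the promolecule state
#'
#' Embeds the occupied fragment orbitals (A first, then B) into the
#' supermolecule AO basis, Schmidt-orthonormalizes them per spin channel, and
#' assembles the promolecule density matrix `P0` together with the two
#' reference energies: `E0 = E[rho0]` (antisymmetrized product) and
#' `E_sum = E[rho_A + rho_B]` (plain summed densities), both evaluated with
#' the supermolecule integrals. Their difference is the raw Pauli repulsion.
#'
#' @param scf_A,scf_B converged fragment SCF solutions (monomer basis).
#' @param system the [nocv_system()].
#' @param ints supermolecule [system_integrals()].
#' @param order orthogonalization order, `"AB"` (default, A's occupieds kept)
#'   or `"BA"`. The occupied-span projector -- hence every downstream energy
#'   -- is order-invariant; the order only affects per-orbital provenance.
#' @return an object of class `nocv_promolecule`.
#' @export
build_promolecule <- function(scf_A, scf_B, system, ints, order = c("AB", "BA")) {
  order <- match.arg(order)
  emb <- ao_embedding(system, ints)
  n <- ints$n
  restricted <- scf_A$restricted && scf_B$restricted &&
    system$adduct$multiplicity == 1L &&
    scf_A$species$multiplicity == 1L && scf_B$species$multiplicity == 1L

  occ_cols <- function(scf, spin) {
    no <- scf$nocc[[spin]]
    scf$C[[spin]][, seq_len(no), drop = FALSE]
  }
  one_spin <- function(spin) {
    CA <- embed_columns(occ_cols(scf_A, spin), emb$A, n)
    CB <- embed_columns(occ_cols(scf_B, spin), emb$B, n)
    blocks <- if (order == "AB") list(CA, CB) else list(CB, CA)
    prov <- if (order == "AB") {
      c(rep("A", ncol(CA)), rep("B", ncol(CB)))
    } else c(rep("B", ncol(CB)), rep("A", ncol(CA)))
    C0 <- schmidt_orthonormalize(blocks, ints$S)
    list(C = C0, P = tcrossprod(C0), prov = prov)
  }
  a <- one_spin("a"); b <- one_spin("b")
  P0a <- a$P; P0b <- b$P

  PAa <- embed_matrix(scf_A$Pa, emb$A, n); PAb <- embed_matrix(scf_A$Pb, emb$A, n)
  PBa <- embed_matrix(scf_B$Pa, emb$B, n); PBb <- embed_matrix(scf_B$Pb, emb$B, n)

  ev0 <- evaluate_at_density(ints, P0a, P0b)
  evsum <- evaluate_at_density(ints, PAa + PBa, PAb + PBb)

  structure(list(
    C0 = list(a = a$C, b = b$C), provenance = list(a = a$prov, b = b$prov),
    P0a = P0a, P0b = P0b, P0 = P0a + P0b,
    PA = list(a = PAa, b = PAb), PB = list(a = PBa, b = PBb),
    E0 = ev0$E, E_sum = evsum$E, eval0 = ev0, evalsum = evsum,
    restricted = restricted, order = order, emb = emb
  ), class = "nocv_promolecule")
}

#' @export
print.nocv_promolecule <- function(x, ...) {
  cat(sprintf(
    "<nocv_promolecule> %d occupied orbitals; E[rho0] = %.8f Ha, E[rhoA+rhoB] = %.8f Ha\n",
    ncol(x$C0$a) + ncol(x$C0$b), x$E0, x$E_sum))
  invisible(x)
}
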