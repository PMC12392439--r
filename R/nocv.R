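# Natural orbitals for chemical valence: eigenpairs of the deformation
# density matrix dP = P - P0, paired as (+v, -v) charge-flow channels, with
# per-channel energies from the transition-state Fock combination and
# per-channel deformation-density fields.

#' Eigenpairs of the deformation-density matrix
#'
#' Diagonalizes `dP` in the Loewdin-orthogonalized basis (the symmetric
#' eigenproblem of `S^1/2 dP S^1/2`), back-transforms, and S-normalizes the
#' eigenvectors. Ordering is by descending eigenvalue; each vector's phase is
#' fixed so its largest-magnitude coefficient is positive, making the output
#' reproducible across linear-algebra backends.
#'
#' @param dP symmetric deformation-density matrix (AO basis).
#' @param ints [system_integrals()] bundle (provides `S_half`/`S_invhalf`),
#'   or a plain overlap matrix `S`.
#' @return list with `values` (descending) and `vectors` (S-normalized
#'   columns).
#' @export
nocv_eigenpairs <- function(dP, ints) {
  if (is.matrix(ints)) {
    S <- ints
    es <- eigen(S, symmetric = TRUE)
    if (min(es$values) <= 0) stop("overlap matrix not positive definite")
    Sh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
    Sih <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  } else {
    Sh <- ints$S_half; Sih <- ints$S_invhalf
  }
  if (max(abs(dP - t(dP))) > 1e-8) stop("dP must be symmetric")
  M <- Sh %*% dP %*% Sh
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- Sih %*% e$vectors[, ord, drop = FALSE]
  # phase fix: largest-|coefficient| positive; ties broken by ascending AO index
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(values = vals, vectors = vecs)
}

#' Pair NOCV eigenvalues into charge-flow channels
#'
#' Greedily matches positive eigenvalues with negative partners of equal
#' magnitude. Channels with `v` below `cutoff` are dropped from the printed
#' list (their energy stays in the residual diagnostics); magnitude mismatch
#' beyond `pair_tol` on an idempotent-difference input is an internal
#' consistency error.
#'
#' @param eig output of [nocv_eigenpairs()].
#' @param cutoff significance cutoff on `v` (default 1e-3).
#' @param pair_tol allowed `|v_k - |v_-k||` mismatch.
#' @param spin spin label attached to the channels.
#' @return list of channel skeletons plus `diagnostics` (unpaired weight).
#' @export
pair_channels <- function(eig, cutoff = 1e-3, pair_tol = 1e-7,
                          spin = "restricted") {
  vals <- eig$values
  pos <- which(vals > cutoff)
  neg <- which(vals < -cutoff)
  neg <- neg[order(vals[neg])]             # most negative first
  channels <- list()
  used_neg <- integer(0)
  for (kk in seq_along(pos)) {
    k <- pos[kk]
    if (kk > length(neg)) break
    m <- neg[kk]
    if (abs(vals[k] + vals[m]) > pair_tol)
      stop(sprintf(
        "NOCV pairing failure: +%.8f has no partner (best mismatch %.2e)",
        vals[k], abs(vals[k] + vals[m])))
    used_neg <- c(used_neg, m)
    channels[[length(channels) + 1]] <- list(
      k = kk, v = vals[k],
      c_plus = eig$vectors[, k], c_minus = eig$vectors[, m],
      spin = spin)
  }
  unmatched <- setdiff(c(pos[seq_along(pos) > length(neg)],
                         neg[!(neg %in% used_neg)]), integer(0))
  below <- sum(abs(vals[abs(vals) <= cutoff]))
  list(channels = channels,
       diagnostics = list(unmatched_idx = unmatched,
                          unmatched_weight = sum(abs(vals[unmatched])),
                          subcutoff_weight = below))
}

#' Per-channel orbital-interaction energies
#'
#' `dE_orb,k = v_k (c_k' F~ c_k - c_-k' F~ c_-k)` with the 2/3-1/6-1/6
#' transition-state Fock. With all channels kept the sum equals
#' `Tr{F~ dP}` exactly (trace invariance under the orthonormal NOCV basis).
#'
#' @param channels channel list from [pair_channels()].
#' @param Ftilde the combined Fock matrix for the matching spin channel.
#' @return the channel list with `dE` (Hartree) added to each element.
#' @export
channel_energies <- function(channels, Ftilde) {
  lapply(channels, function(ch) {
    fp <- drop(crossprod(ch$c_plus, Ftilde %*% ch$c_plus))
    fm <- drop(crossprod(ch$c_minus, Ftilde %*% ch$c_minus))
    ch$dE <- ch$v * (fp - fm)
    ch
  })
}

#' Total valence diagnostic
#'
#' `V = Tr(P dP)` evaluated in an orthonormal (Loewdin) representation,
#' i.e. `Tr(P S dP S)` in the AO basis; invariant under the choice of
#' orthogonalization.
#'
#' @param P adduct density matrix (AO basis).
#' @param dP deformation-density matrix.
#' @param S overlap matrix.
#' @return the total valence (dimensionless).
#' @export
total_valence <- function(P, dP, S) {
  sum((P %*% S) * t(dP %*% S))
}

#' NOCV analysis of a completed decomposition
#'
#' Extracts the charge-flow channels of the orbital term. Restricted
#' decompositions yield one channel set (occupancy-2 eigenvalue convention:
#' the spatial density matrices carry occupancy 2, so eigenvalues can reach
#' 2); any open-shell participant switches to the spin-resolved path where
#' each spin channel is diagonalized and paired independently and
#' `dE_orb = sum_sigma sum_k dE_orb,k^sigma`.
#'
#' @param eda an `nocv_eda` from [decompose()].
#' @param cutoff printed-channel significance cutoff on `v`.
#' @return an object of class `nocv_result` with `channels` (all spins
#'   merged, ordered by descending `v`), per-spin detail, the channel-energy
#'   sum, its reference `Tr{F~ dP}` value, and the total-valence diagnostic.
#' @export
nocv_channels <- function(eda, cutoff = 1e-3) {
  stopifnot(inherits(eda, "nocv_eda"))
  scf <- eda$scf$AB; promol <- eda$promolecule; ints <- eda$ints
  restricted <- scf$restricted
  spins <- if (restricted) "restricted" else c("alpha", "beta")
  per_spin <- list()
  total_sum <- 0; trace_ref <- 0; valence <- 0
  for (sp in spins) {
    if (restricted) {
      dP <- scf$P - promol$P0           # occupancy-2 spatial matrices
      P <- scf$P
      Ft <- eda$ts_focks$F_tilde$a
    } else if (sp == "alpha") {
      dP <- scf$Pa - promol$P0a; P <- scf$Pa; Ft <- eda$ts_focks$F_tilde$a
    } else {
      dP <- scf$Pb - promol$P0b; P <- scf$Pb; Ft <- eda$ts_focks$F_tilde$b
    }
    eig <- nocv_eigenpairs(dP, ints)
    pr <- pair_channels(eig, cutoff = cutoff, spin = sp)
    chans <- channel_energies(pr$channels, Ft)
    kept <- sum(vapply(chans, `[[`, numeric(1), "dE"))
    per_spin[[sp]] <- list(eig = eig, channels = chans,
                           diagnostics = pr$diagnostics,
                           trace = sum(Ft * dP), kept_sum = kept)
    total_sum <- total_sum + kept
    trace_ref <- trace_ref + sum(Ft * dP)
    valence <- valence + total_valence(P, dP, ints$S)
  }
  merged <- do.call(c, lapply(per_spin, `[[`, "channels"))
  merged <- merged[order(vapply(merged, `[[`, numeric(1), "v"),
                         decreasing = TRUE)]
  for (k in seq_along(merged)) merged[[k]]$k <- k
  structure(list(channels = merged, per_spin = per_spin,
                 restricted = restricted,
                 channel_sum = total_sum, trace_ref = trace_ref,
                 residual = trace_ref - total_sum,
                 dE_orb_ets2 = eda$terms$dE_orb_ets2,
                 valence = valence, cutoff = cutoff),
            class = "nocv_result")
}

#' @export
print.nocv_result <- function(x, ...) {
  cat(sprintf("NOCV channels (%s, cutoff v >= %g)\n",
              if (x$restricted) "restricted" else "spin-resolved", x$cutoff))
  cat(sprintf("  %3s %-10s %10s %14s\n", "k", "spin", "v_k",
              "dE_orb,k (kcal)"))
  for (ch in x$channels)
    cat(sprintf("  %3d %-10s %10.5f %14.2f\n", ch$k, ch$spin, ch$v,
                ch$dE * HARTREE_TO_KCAL))
  cat(sprintf("  channel sum %.4f kcal/mol; Tr{F~ dP} %.4f kcal/mol; V = %.4f\n",
              x$channel_sum * HARTREE_TO_KCAL,
              x$trace_ref * HARTREE_TO_KCAL, x$valence))
  invisible(x)
}

#' Spin-resolved decomposition summary
#'
#' Convenience wrapper returning the per-spin channel analysis of an
#' unrestricted decomposition together with combined totals.
#'
#' @inheritParams nocv_channels
#' @return list with per-spin `nocv_result`-style entries and combined
#'   `dE_orb` (sum over spins and channels plus residuals).
#' @export
spin_resolved_decomposition <- function(eda, cutoff = 1e-3) {
  res <- nocv_channels(eda, cutoff = cutoff)
  list(per_spin = res$per_spin,
       dE_orb = res$trace_ref,
       channel_sum = res$channel_sum,
       result = res)
}

#' Double-hybrid-style density split
#'
#' For MP2-augmented methods the correlated density is not idempotent, so the
#' channel analysis runs on the SCF part of the deformation density only
#' (pairing preserved), while the MP2 difference-density correction
#' `ddrho_C^MP2 = D^MP2(AB) - D^MP2(A) - D^MP2(B)` (unrelaxed, embedded in
#' the supermolecule basis) is returned as a separate trace-free field
#' source, with its `a_C`-scaled energy line.
#'
#' @param eda an `nocv_eda` computed with an `"hf+mp2"` method.
#' @return list with `dP_scf` (per NOCV), `D_mp2_delta` (AO matrix of the
#'   correlation difference density), and `dE_mp2` (Hartree).
#' @export
dh_density_split <- function(eda) {
  method <- eda$method
  if (method$mp2_coefficient == 0) {
    n <- eda$ints$n
    return(list(dP_scf = eda$scf$AB$P - eda$promolecule$P0,
                D_mp2_delta = matrix(0, n, n), dE_mp2 = 0))
  }
  if (is.null(eda$mp2)) stop("missing MP2 densities in the decomposition")
  emb <- eda$promolecule$emb
  dens <- function(scf) mp2_correlation(scf, eda$method, want_density = TRUE)$D_ao
  D_AB <- dens(eda$scf$AB)
  D_A <- embed_matrix(dens(eda$scf$A), emb$A, emb$n)
  D_B <- embed_matrix(dens(eda$scf$B), emb$B, emb$n)
  list(dP_scf = eda$scf$AB$P - eda$promolecule$P0,
       D_mp2_delta = D_AB - D_A - D_B,
       dE_mp2 = eda$terms$dE_mp2)
}
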