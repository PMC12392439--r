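# Self-consistent field solver (restricted and unrestricted Hartree-Fock)
# with DIIS acceleration, plus energy/Fock evaluation at arbitrary (not
# necessarily idempotent) densities -- the workhorse for the promolecule and
# transition-state intermediates of the decomposition.

#' Run a self-consistent-field calculation
#'
#' Solves the Hartree-Fock equations for `species`. Closed-shell singlets use
#' the restricted path (one spatial density matrix with occupancy 2) unless
#' `method$force_unrestricted` is set; any open-shell species uses the
#' spin-unrestricted path.
#'
#' @param species a [nocv_species()].
#' @param method a [nocv_method()].
#' @param ints optional precomputed [system_integrals()] bundle (reused so the
#'   whole decomposition shares one set of integrals).
#' @param max_iter,conv_energy,conv_dens convergence controls. The defaults
#'   (1e-8 Ha on the energy, 1e-7 on the density RMS) are tighter than usual
#'   single-point practice because decomposition terms are differences of
#'   large totals printed to 0.01 kcal/mol.
#' @return an object of class `nocv_scf` with per-spin orbital coefficients
#'   `C`, orbital energies `eps`, occupations, per-spin density matrices
#'   `Pa`/`Pb` (occupancy-1 convention), total `P`, and the converged energy
#'   `E` in Hartree.
#' @export
run_scf <- function(species, method = nocv_method(), ints = NULL,
                    max_iter = 200, conv_energy = 1e-8, conv_dens = 1e-7) {
  if (is.null(ints)) ints <- system_integrals(species, method$basis)
  na <- species$nalpha; nb <- species$nbeta
  n <- ints$n

  if (species$nelec == 0) {
    # bare-nucleus limit: no electrons, energy is the nuclear repulsion
    z <- matrix(0, n, n)
    return(structure(list(
      species = species, method = method, ints = ints, restricted = TRUE,
      C = list(a = matrix(0, n, 0), b = matrix(0, n, 0)),
      eps = list(a = numeric(0), b = numeric(0)),
      nocc = c(a = 0L, b = 0L), Pa = z, Pb = z, P = z,
      E = ints$enuc, converged = TRUE, niter = 0L,
      energies = list(one_electron = 0, coulomb = 0, exchange = 0,
                      enuc = ints$enuc),
      history = numeric(0)), class = "nocv_scf"))
  }

  restricted <- (species$multiplicity == 1L) && !method$force_unrestricted
  X <- ints$S_invhalf
  h <- ints$hcore

  dens <- function(C, nocc) {
    if (nocc == 0) return(matrix(0, n, n))
    Co <- C[, seq_len(nocc), drop = FALSE]
    tcrossprod(Co)
  }
  solve_fock <- function(F) {
    Ft <- t(X) %*% F %*% X
    e <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    list(C = X %*% e$vectors[, ord, drop = FALSE], eps = e$values[ord])
  }

  # core guess
  g <- solve_fock(h)
  Ca <- Cb <- g$C
  if (!restricted && na == nb && length(species$Z) > 1) {
    # break spin symmetry slightly so UHF can find broken-symmetry solutions
    # when they exist; for genuinely closed-shell systems SCF restores symmetry
  }
  Pa <- dens(Ca, na); Pb <- dens(Cb, nb)

  Eold <- Inf; history <- numeric(0)
  diis_F <- list(); diis_e <- list(); maxdiis <- 8
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    J <- coulomb_matrix(ints, Pa + Pb)
    Ka <- exchange_matrix(ints, Pa)
    Kb <- if (restricted) Ka else exchange_matrix(ints, Pb)
    Fa <- h + J - Ka
    Fb <- h + J - Kb
    E1 <- sum(h * (Pa + Pb))
    EJ <- 0.5 * sum(J * (Pa + Pb))
    EK <- -0.5 * (sum(Ka * Pa) + sum(Kb * Pb))
    E <- E1 + EJ + EK + ints$enuc

    # DIIS on the orthogonalized gradient FPS - SPF
    errA <- t(X) %*% (Fa %*% Pa %*% ints$S - ints$S %*% Pa %*% Fa) %*% X
    errB <- t(X) %*% (Fb %*% Pb %*% ints$S - ints$S %*% Pb %*% Fb) %*% X
    err <- rbind(errA, errB)
    diis_F[[length(diis_F) + 1]] <- rbind(Fa, Fb)
    diis_e[[length(diis_e) + 1]] <- err
    if (length(diis_F) > maxdiis) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m))
        B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cw <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cw) && all(is.finite(cw))) {
        Fmix <- Reduce(`+`, Map(`*`, diis_F, cw))
        Fa <- Fmix[seq_len(n), , drop = FALSE]
        Fb <- Fmix[n + seq_len(n), , drop = FALSE]
      }
    }

    sa <- solve_fock(Fa)
    sb <- if (restricted) sa else solve_fock(Fb)
    Ca <- sa$C; Cb <- sb$C
    Pa_new <- dens(Ca, na); Pb_new <- dens(Cb, nb)
    dP <- sqrt(mean((Pa_new - Pa)^2 + (Pb_new - Pb)^2))
    history <- c(history, E)
    if (abs(E - Eold) < conv_energy && dP < conv_dens) { conv <- TRUE }
    Pa <- Pa_new; Pb <- Pb_new; Eold <- E
    if (conv) break
  }
  if (!conv) {
    cnd <- structure(class = c("nocv_scf_error", "error", "condition"),
                     list(message = sprintf(
                       "SCF failed to converge in %d iterations (last dE = %.3e)",
                       max_iter, abs(E - history[max(1, length(history) - 1)])),
                       call = sys.call(-1), history = history))
    stop(cnd)
  }
  # final energy at the converged density
  J <- coulomb_matrix(ints, Pa + Pb)
  Ka <- exchange_matrix(ints, Pa)
  Kb <- if (restricted) Ka else exchange_matrix(ints, Pb)
  E1 <- sum(h * (Pa + Pb)); EJ <- 0.5 * sum(J * (Pa + Pb))
  EK <- -0.5 * (sum(Ka * Pa) + sum(Kb * Pb))
  structure(list(
    species = species, method = method, ints = ints, restricted = restricted,
    C = list(a = Ca, b = if (restricted) Ca else Cb),
    eps = list(a = sa$eps, b = if (restricted) sa$eps else sb$eps),
    nocc = c(a = na, b = nb),
    Pa = Pa, Pb = Pb, P = Pa + Pb,
    E = E1 + EJ + EK + ints$enuc, converged = TRUE, niter = it,
    energies = list(one_electron = E1, coulomb = EJ, exchange = EK,
                    enuc = ints$enuc),
    history = history), class = "nocv_scf")
}

#' @export
print.nocv_scf <- function(x, ...) {
  cat(sprintf("<nocv_scf> E = %.10f Ha (%s, %d iterations)\n", x$E,
              if (x$restricted) "restricted" else "unrestricted", x$niter))
  invisible(x)
}

#' Evaluate energy and Fock matrices at an arbitrary density
#'
#' Computes the single-determinant energy functional and the corresponding
#' per-spin Fock matrices at supplied per-spin density matrices, which need
#' not be idempotent (the promolecule and transition-state densities are not
#' self-consistent). The electron-nuclear attraction operator and the nuclear
#' repulsion default to those of the full system but can be restricted to a
#' fragment's nuclear frame, which is how fragment energies are evaluated in
#' the supermolecule basis.
#'
#' @param ints [system_integrals()] bundle defining the AO basis.
#' @param Pa,Pb per-spin density matrices (occupancy-1 convention). For a
#'   restricted density pass `Pa = Pb = P/2`.
#' @param Vne,enuc external potential matrix and nuclear repulsion to use.
#' @return list with total energy `E`, per-spin Fock matrices `Fa`, `Fb`, the
#'   spin-summed (restricted) Fock `F = dE/dP_total` and the energy components
#'   including the retrievable HF-exchange value.
#' @export
evaluate_at_density <- function(ints, Pa, Pb = Pa,
                                Vne = ints$Vne, enuc = ints$enuc) {
  n <- ints$n
  stopifnot(all(dim(Pa) == c(n, n)), all(dim(Pb) == c(n, n)))
  if (max(abs(Pa - t(Pa))) > 1e-8 || max(abs(Pb - t(Pb))) > 1e-8)
    stop("density matrices must be symmetric")
  h <- ints$T + Vne
  P <- Pa + Pb
  J <- coulomb_matrix(ints, P)
  Ka <- exchange_matrix(ints, Pa)
  Kb <- exchange_matrix(ints, Pb)
  E1 <- sum(h * P)
  EJ <- 0.5 * sum(J * P)
  EX <- -0.5 * (sum(Ka * Pa) + sum(Kb * Pb))
  list(E = E1 + EJ + EX + enuc,
       Fa = h + J - Ka, Fb = h + J - Kb,
       F = h + J - 0.5 * (Ka + Kb),   # dE/dP_total when Pa = Pb = P/2
       one_electron = E1, coulomb = EJ, exchange = EX, enuc = enuc)
}

#' MP2 correlation energy and difference density
#'
#' Closed-shell MP2 from converged restricted orbitals. Optionally returns
#' the unrelaxed MP2 one-particle difference-density matrix in the AO basis
#' (occupancy-2 convention, trace-free), the correction that turns the SCF
#' density into the correlated one in the double-hybrid-style density split.
#'
#' @param scf converged restricted [run_scf()] result.
#' @param method a [nocv_method()]; must allow a correlation term
#'   (`method = "hf+mp2"`).
#' @param want_density also compute the difference-density matrix.
#' @return list with `E_mp2` (unscaled correlation energy, Hartree) and
#'   optionally `D_ao`.
#' @export
mp2_correlation <- function(scf, method = scf$method, want_density = FALSE) {
  if (method$method != "hf+mp2")
    stop("MP2 correlation requested for method '", method$method,
         "': contract violation (use method 'hf+mp2')")
  if (!scf$restricted)
    stop("the built-in MP2 path requires a restricted reference")
  ints <- scf$ints
  n <- ints$n
  no <- scf$nocc[["a"]]
  nv <- n - no
  if (no == 0 || nv == 0) return(list(E_mp2 = 0, D_ao = matrix(0, n, n)))
  C <- scf$C$a; eps <- scf$eps$a
  occ <- seq_len(no); vir <- no + seq_len(nv)
  Co <- C[, occ, drop = FALSE]; Cv <- C[, vir, drop = FALSE]
  # (ia|jb) via successive quarter transforms (reshape + crossprod)
  T1 <- array(crossprod(Co, matrix(ints$eri, n, n^3)), c(no, n, n, n))  # i,nu,la,si
  T2 <- array(crossprod(Cv, matrix(aperm(T1, c(2, 1, 3, 4)), n, no * n^2)),
              c(nv, no, n, n))                                          # a,i,la,si
  T3 <- array(crossprod(Co, matrix(aperm(T2, c(3, 1, 2, 4)), n, nv * no * n)),
              c(no, nv, no, n))                                         # j,a,i,si
  T4 <- array(crossprod(Cv, matrix(aperm(T3, c(4, 1, 2, 3)), n, no * nv * no)),
              c(nv, no, nv, no))                                        # b,j,a,i
  iajb <- aperm(T4, c(4, 3, 2, 1))                                      # i,a,j,b
  eo <- eps[occ]; ev <- eps[vir]
  dn <- outer(eo, -ev, "+")                                     # e_i - e_a
  denom <- array(0, dim = c(no, nv, no, nv))
  for (j in seq_len(no)) for (b in seq_len(nv))
    denom[, , j, b] <- dn + (eo[j] - ev[b])
  tamp <- iajb / denom
  tbar <- 2 * tamp - aperm(tamp, c(1, 4, 3, 2))                 # 2t - t(ib|ja)
  E_mp2 <- sum(iajb * tbar)
  out <- list(E_mp2 = E_mp2)
  if (want_density) {
    Dij <- matrix(0, no, no); Dab <- matrix(0, nv, nv)
    for (i in seq_len(no)) for (j in seq_len(no))
      Dij[i, j] <- -2 * sum(tamp[i, , , ] * tbar[j, , , ])
    for (a in seq_len(nv)) for (b in seq_len(nv))
      Dab[a, b] <- 2 * sum(tamp[, a, , ] * tbar[, b, , ])
    Dmo <- matrix(0, n, n)
    Dmo[occ, occ] <- (Dij + t(Dij)) / 2
    Dmo[vir, vir] <- (Dab + t(Dab)) / 2
    out$D_ao <- C %*% Dmo %*% t(C)
  }
  out
}

# ---- dispersion providers ------------------------------------------------

.dispersion_registry <- new.env(parent = emptyenv())

#' Register a dispersion-energy provider
#'
#' A provider is a function `function(species, method)` returning an additive
#' dispersion energy in Hartree for the given geometry. The built-in `"none"`
#' provider returns 0. Pairwise empirical models (D3-style corrections with
#' functional-specific parameters) plug in through this interface.
#'
#' @param name provider identifier used in [nocv_method()].
#' @param fun the provider function.
#' @export
register_dispersion_provider <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .dispersion_registry)
  invisible(name)
}

#' Dispersion energy of a species
#'
#' @param species a [nocv_species()].
#' @param method a [nocv_method()]; `method$dispersion` selects the provider.
#' @return energy in Hartree.
#' @export
dispersion_energy <- function(species, method) {
  name <- method$dispersion
  if (identical(name, "none") || is.null(name)) return(0)
  if (!exists(name, envir = .dispersion_registry))
    stop("unknown dispersion model '", name, "'")
  fun <- get(name, envir = .dispersion_registry)
  if (length(species$Z) < 2) return(0)  # pairwise models have no single-atom term
  fun(species, method)
}
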