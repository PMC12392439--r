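# Minimal Gaussian basis ("sto-3g" class): each occupied Slater-type shell of
# the atom is expanded in 3 Gaussians. The zeta = 1 expansions are generated
# once per (n, l) by a deterministic least-squares fit on a radial grid and
# rescaled analytically to the element's Slater exponent, so no external basis
# files are needed. Slater exponents are the Clementi-Raimondi effective
# values (H uses the standard molecular 1.24).

# shells: list of c(n, l, zeta) per element symbol
MINIMAL_SHELLS <- list(
  H  = list(c(1, 0, 1.24)),
  He = list(c(1, 0, 1.6875)),
  Li = list(c(1, 0, 2.6906), c(2, 0, 0.6396), c(2, 1, 0.6396)),
  Be = list(c(1, 0, 3.6848), c(2, 0, 0.9560), c(2, 1, 0.9560)),
  B  = list(c(1, 0, 4.6795), c(2, 0, 1.2881), c(2, 1, 1.2107)),
  C  = list(c(1, 0, 5.6727), c(2, 0, 1.6083), c(2, 1, 1.5679)),
  N  = list(c(1, 0, 6.6651), c(2, 0, 1.9237), c(2, 1, 1.9170)),
  O  = list(c(1, 0, 7.6579), c(2, 0, 2.2458), c(2, 1, 2.2266)),
  F  = list(c(1, 0, 8.6501), c(2, 0, 2.5638), c(2, 1, 2.5500)),
  Ne = list(c(1, 0, 9.6421), c(2, 0, 2.8792), c(2, 1, 2.8792)),
  Ar = list(c(1, 0, 17.5075), c(2, 0, 6.1152), c(2, 1, 7.0041),
            c(3, 0, 2.5856), c(3, 1, 2.2547))
)

.fit_cache <- new.env(parent = emptyenv())

# Least-squares expansion of the normalized radial Slater function
# r^(n-1) exp(-r) (zeta = 1) in ng Gaussians r^l exp(-a r^2).
# Linear coefficients are solved exactly for each trial exponent set; the
# exponents are optimized by Nelder-Mead from a fixed geometric start, so the
# result is deterministic.
fit_sto_gaussians <- function(n, l, ng = 3) {
  key <- sprintf("n%d_l%d_g%d", n, l, ng)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  r <- seq(1e-4, 30, length.out = 4000)
  w <- r^2 * c(diff(r)[1], diff(r))       # trapezoid-ish weights, r^2 measure
  sto <- r^(n - 1) * exp(-r)
  sto <- sto / sqrt(sum(w * sto^2))
  gmat <- function(la) {
    G <- sapply(exp(la), function(a) r^l * exp(-a * r^2))
    sweep(G, 2, sqrt(colSums(w * G^2)), "/")
  }
  obj <- function(la) {
    G <- gmat(la)
    A <- crossprod(G, w * G); b <- crossprod(G, w * sto)
    c0 <- solve(A + diag(1e-12, ng), b)
    sum(w * (sto - G %*% c0)^2)
  }
  start <- log(c(0.06, 0.25, 1.1) *
                 switch(n, c(1.8, 1.7, 2.0), c(1.2, 0.9, 0.9),
                        c(0.6, 0.45, 0.4)))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-13))
  la <- opt$par
  G <- gmat(la)
  A <- crossprod(G, w * G); b <- crossprod(G, w * sto)
  cfit <- drop(solve(A + diag(1e-12, ng), b))
  # coefficients refer to radially normalized primitives
  res <- list(alpha = exp(la), coef = cfit, rms = sqrt(opt$value))
  .fit_cache[[key]] <- res
  res
}

# Primitive normalization for a Cartesian Gaussian x^lx y^ly z^lz exp(-a r^2)
# with a single nonzero angular component (s or p here).
prim_norm <- function(a, ltot) {
  (2 * a / pi)^0.75 * (4 * a)^(ltot / 2)
}

#' Build the AO basis for a species
#'
#' Returns the contracted Cartesian Gaussian basis in the internal layout used
#' by the integral routines, with contraction coefficients normalized so the
#' overlap matrix has unit diagonal.
#'
#' @param species a [nocv_species()].
#' @param basis basis-set name (currently `"sto-3g"`).
#' @return a list with per-AO angular momenta, centers, primitive exponents
#'   and coefficients, plus `atom_of_ao` mapping each AO to its atom index.
#' @export
build_basis <- function(species, basis = "sto-3g") {
  stopifnot(inherits(species, "nocv_species"))
  lmat <- NULL; cen <- NULL; pstart <- integer(); pcount <- integer()
  alpha <- numeric(); coef <- numeric(); atom_of_ao <- integer()
  shell_of_ao <- character()
  for (ia in seq_along(species$Z)) {
    sym <- species$symbols[ia]
    shells <- MINIMAL_SHELLS[[sym]]
    if (is.null(shells)) stop("no minimal basis for element ", sym)
    for (sh in shells) {
      n <- sh[1]; l <- sh[2]; zeta <- sh[3]
      fit <- fit_sto_gaussians(n, l)
      a <- fit$alpha * zeta^2
      comps <- if (l == 0) list(c(0L, 0L, 0L)) else
        list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
      for (lv in comps) {
        lmat <- rbind(lmat, lv)
        cen <- rbind(cen, species$xyz[ia, ])
        pstart <- c(pstart, length(alpha))
        pcount <- c(pcount, length(a))
        alpha <- c(alpha, a)
        coef <- c(coef, fit$coef * prim_norm(a, l))
        atom_of_ao <- c(atom_of_ao, ia)
        shell_of_ao <- c(shell_of_ao, sprintf("%d%s", n, c("s", "p")[l + 1]))
      }
    }
  }
  b <- list(l = unname(lmat), center = unname(cen), pstart = pstart,
            pcount = pcount, alpha = alpha, coef = coef,
            atom_of_ao = atom_of_ao, shell = shell_of_ao,
            nao = nrow(lmat), name = basis)
  # contracted normalization: scale so diag(S) = 1
  S <- .overlap_matrix(b)
  scl <- 1 / sqrt(diag(S))
  for (i in seq_len(b$nao)) {
    idx <- b$pstart[i] + seq_len(b$pcount[i])
    b$coef[idx] <- b$coef[idx] * scl[i]
  }
  b
}
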