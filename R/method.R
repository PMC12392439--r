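#' Specify the electronic-structure method
#'
#' The built-in backend implements Hartree-Fock (restricted and unrestricted)
#' and MP2-augmented Hartree-Fock. The latter plays the role of a
#' double-hybrid-style method: the self-consistent part is a pure
#' single-determinant calculation whose density matrix is idempotent (so the
#' charge-flow channel pairing holds exactly), while an `mp2_coefficient`-scaled
#' MP2 correlation energy computed from the converged orbitals is added to the
#' total energy and reported as a separate correlation line in the
#' decomposition, with its own non-idempotent difference-density correction.
#'
#' @param method `"hf"` or `"hf+mp2"`.
#' @param basis basis set name; the built-in library provides `"sto-3g"`
#'   (a minimal Slater-fit Gaussian basis for H-Ar).
#' @param mp2_coefficient scaling a_C of the MP2 correlation term, in `[0, 1]`.
#'   Must be > 0 only for `method = "hf+mp2"`.
#' @param dispersion dispersion-model identifier: `"none"` or the name of a
#'   provider registered with [register_dispersion_provider()].
#' @param force_unrestricted run even closed-shell species through the
#'   spin-unrestricted path.
#' @return an object of class `nocv_method`.
#' @export
nocv_method <- function(method = "hf", basis = "sto-3g",
                        mp2_coefficient = if (method == "hf+mp2") 1 else 0,
                        dispersion = "none",
                        force_unrestricted = FALSE) {
  method <- tolower(method)
  if (!method %in% c("hf", "hf+mp2")) {
    stop("method '", method, "' is not supported by the built-in HF/MP2 ",
         "backend (supported: 'hf', 'hf+mp2')")
  }
  family <- if (method == "hf+mp2" && mp2_coefficient > 0) "double-hybrid" else "hf"
  if (mp2_coefficient < 0 || mp2_coefficient > 1)
    stop("mp2_coefficient must lie in [0, 1]")
  if (mp2_coefficient > 0 && method == "hf")
    stop("mp2_coefficient > 0 requires method 'hf+mp2'")
  basis <- tolower(basis)
  if (!basis %in% c("sto-3g"))
    stop("basis '", basis, "' is not available (built-in: 'sto-3g')")
  structure(list(
    method = method, family = family, functional = toupper(method),
    hf_exchange = 1,              # single-determinant backend: full HF exchange
    mp2_coefficient = mp2_coefficient,
    dft_correlation_scale = 1 - mp2_coefficient,
    dispersion = dispersion, basis = basis,
    force_unrestricted = isTRUE(force_unrestricted)
  ), class = "nocv_method")
}

#' @export
print.nocv_method <- function(x, ...) {
  cat(sprintf("<nocv_method> %s/%s, a_X = %g, a_C = %g, dispersion = %s\n",
              x$functional, x$basis, x$hf_exchange, x$mp2_coefficient,
              x$dispersion))
  invisible(x)
}
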