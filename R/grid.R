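# Rectilinear grids and scalar fields for deformation-density export.

#' Define a rectilinear grid
#'
#' @param origin grid origin (Bohr, length 3).
#' @param axes 3x3 matrix whose rows are the step vectors (Bohr).
#' @param counts integer point counts per axis (each >= 2).
#' @return an object of class `nocv_grid`.
#' @export
grid_spec <- function(origin, axes, counts) {
  axes <- matrix(as.numeric(axes), 3, 3)
  counts <- as.integer(counts)
  if (any(counts < 2)) stop("grid counts must be >= 2")
  if (abs(det(axes)) < 1e-14) stop("grid axes are linearly dependent")
  structure(list(origin = as.numeric(origin), axes = axes, counts = counts),
            class = "nocv_grid")
}

#' Default grid around a species
#'
#' Axis-aligned bounding box of the nuclei plus `padding` Bohr on each side,
#' with approximately `spacing` Bohr between points.
#'
#' @param species a [nocv_species()].
#' @param padding box padding in Bohr.
#' @param spacing target spacing in Bohr. The 0.2 default resolves isosurface
#'   levels down to the 1e-5 e/Bohr^3 range typically plotted; tests use
#'   coarser grids.
#' @return an `nocv_grid`.
#' @export
default_grid <- function(species, padding = 4, spacing = 0.2) {
  lo <- apply(species$xyz, 2, min) - padding
  hi <- apply(species$xyz, 2, max) + padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  step <- (hi - lo) / (counts - 1L)
  grid_spec(lo, diag(step), counts)
}

# All grid points as an m x 3 matrix, z fastest (cube-file ordering).
grid_points <- function(gs) {
  ix <- seq_len(gs$counts[1]) - 1L
  iy <- seq_len(gs$counts[2]) - 1L
  iz <- seq_len(gs$counts[3]) - 1L
  g <- expand.grid(z = iz, y = iy, x = ix)  # z fastest
  idx <- as.matrix(g[, c("x", "y", "z")])
  sweep(idx %*% gs$axes, 2, gs$origin, "+")
}

grid_volume_element <- function(gs) abs(det(gs$axes))

#' Evaluate an electron density on a grid
#'
#' `rho(r) = sum_{mu nu} P_{mu nu} chi_mu(r) chi_nu(r)` for any symmetric
#' AO-basis matrix `P` (density, deformation density, channel density, MP2
#' correction...).
#'
#' @param P AO-basis matrix.
#' @param ints [system_integrals()] bundle.
#' @param gs an `nocv_grid`.
#' @return numeric vector of values in cube (z-fastest) order, with
#'   attributes `grid` and `dV`.
#' @export
density_on_grid <- function(P, ints, gs) {
  pts <- grid_points(gs)
  X <- .ao_values(ints$basis, pts)
  vals <- rowSums((X %*% P) * X)
  structure(vals, grid = gs, dV = grid_volume_element(gs))
}

#' Numerically integrate a grid field
#' @param field output of [density_on_grid()] (or any vector with a `dV`
#'   attribute).
#' @return the Riemann-sum integral.
#' @export
field_integral <- function(field) {
  sum(field) * attr(field, "dV")
}

#' Deformation-density fields of NOCV channels
#'
#' Per-channel fields `drho_k = v_k (psi_k^2 - psi_-k^2)` plus the total; with
#' all channels kept the total equals the direct `dP`-contracted density
#' pointwise.
#'
#' @param result an `nocv_result` from [nocv_channels()].
#' @param eda the `nocv_eda` it came from.
#' @param gs an `nocv_grid`.
#' @param channels integer indices of the (merged) channels to evaluate.
#' @return list with `channels` (list of fields) and `total`.
#' @export
channel_density <- function(result, eda, gs,
                            channels = seq_along(result$channels)) {
  pts <- grid_points(gs)
  X <- .ao_values(eda$ints$basis, pts)
  dV <- grid_volume_element(gs)
  fields <- lapply(result$channels[channels], function(ch) {
    psi_p <- drop(X %*% ch$c_plus)
    psi_m <- drop(X %*% ch$c_minus)
    structure(ch$v * (psi_p^2 - psi_m^2), grid = gs, dV = dV)
  })
  tot <- if (length(fields) > 0) {
    structure(Reduce(`+`, fields), grid = gs, dV = dV)
  } else structure(numeric(nrow(pts)), grid = gs, dV = dV)
  list(channels = fields, total = tot)
}
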