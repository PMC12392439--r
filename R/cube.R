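# Gaussian cube files (Bohr units, z-fastest value order).

#' Write a scalar field as a Gaussian cube file
#'
#' @param field numeric vector in z-fastest order (as produced by
#'   [density_on_grid()]); its length must equal `prod(gs$counts)`.
#' @param gs the `nocv_grid`.
#' @param species the [nocv_species()] whose atoms go in the header.
#' @param path output path.
#' @param comment first comment line.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, gs, species, path, comment = "deformation density") {
  if (length(field) != prod(gs$counts))
    stop("field length ", length(field), " does not match grid (",
         prod(gs$counts), " points)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "generated by etsnocv"), con)
  nat <- length(species$Z)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat,
                     gs$origin[1], gs$origin[2], gs$origin[3]), con)
  for (d in 1:3)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", gs$counts[d],
                       gs$axes[d, 1], gs$axes[d, 2], gs$axes[d, 3]), con)
  for (ia in seq_len(nat))
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", species$Z[ia],
                       as.numeric(species$Z[ia]), species$xyz[ia, 1],
                       species$xyz[ia, 2], species$xyz[ia, 3]), con)
  # values: x outer, y middle, z fastest; 6 per line
  vals <- sprintf("%14.6e", field)
  nz <- gs$counts[3]
  pos <- 1L
  for (blk in seq_len(prod(gs$counts[1:2]))) {
    row <- vals[pos:(pos + nz - 1L)]
    writeLines(vapply(split(row, ceiling(seq_along(row) / 6)),
                      paste, "", collapse = " "), con)
    pos <- pos + nz
  }
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @return list with `comment`, `species`, `grid` (an `nocv_grid`) and
#'   `field` (z-fastest vector).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  comment <- lines[1]
  hdr <- scan(text = lines[3], quiet = TRUE)
  nat <- as.integer(hdr[1]); origin <- hdr[2:4]
  axes <- matrix(0, 3, 3); counts <- integer(3)
  for (d in 1:3) {
    h <- scan(text = lines[3 + d], quiet = TRUE)
    counts[d] <- as.integer(h[1]); axes[d, ] <- h[2:4]
  }
  Z <- integer(nat); xyz <- matrix(0, nat, 3)
  for (ia in seq_len(nat)) {
    h <- scan(text = lines[6 + ia], quiet = TRUE)
    Z[ia] <- as.integer(h[1]); xyz[ia, ] <- h[3:5]
  }
  field <- scan(text = lines[(7 + nat):length(lines)], quiet = TRUE)
  gs <- grid_spec(origin, axes, counts)
  sp <- nocv_species(Z, xyz / ANGSTROM_TO_BOHR,
                     multiplicity = 1L + sum(Z) %% 2L)
  list(comment = comment, species = sp, grid = gs,
       field = structure(field, grid = gs, dV = grid_volume_element(gs)))
}
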