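# Adduct + fragment-partition handling: XYZ input, fragment validation, and
# embedding of fragment-dimension matrices into supermolecule dimensions.

#' Read an XYZ file
#'
#' @param path path to a standard XYZ file (element symbol + Angstrom
#'   coordinates).
#' @return list with `symbols`, `coords` (Angstrom) and the comment line.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2) stop("malformed XYZ file: ", path)
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  symbols <- vapply(rows, `[[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  list(symbols = symbols, coords = coords, comment = trimws(lines[2]))
}

#' Write an XYZ file
#' @param species a [nocv_species()].
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(species, path, comment = "") {
  ang <- species$xyz / ANGSTROM_TO_BOHR
  lines <- c(length(species$Z), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f", species$symbols,
                     ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a fragment specification string
#'
#' Fragments are semicolon-separated lists of 1-based inclusive atom ranges,
#' e.g. `"1-3;4-6"` or `"1,3;2"`. Exactly two fragments are supported.
#'
#' @param spec the specification string.
#' @param natoms total atom count, for validation.
#' @return list of two integer vectors.
#' @export
parse_fragment_spec <- function(spec, natoms) {
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("fragment spec must define exactly two fragments (got ",
         length(parts), ")")
  idx <- lapply(parts, function(p) {
    unlist(lapply(strsplit(trimws(p), ",")[[1]], function(tok) {
      tok <- trimws(tok)
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        seq(ab[1], ab[2])
      } else as.integer(tok)
    }))
  })
  all_idx <- unlist(idx)
  if (anyNA(all_idx) || any(all_idx < 1) || any(all_idx > natoms))
    stop("fragment spec references atoms outside 1..", natoms)
  if (anyDuplicated(all_idx))
    stop("fragment spec assigns atom(s) ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ","),
         " to more than one fragment")
  if (length(all_idx) != natoms)
    stop("fragment spec misses atom(s) ",
         paste(setdiff(seq_len(natoms), all_idx), collapse = ","))
  idx
}

#' Build an adduct/fragment system
#'
#' Assembles the adduct species and the two fragments, frozen at the
#' geometries they exhibit within the complex (fragment coordinates are
#' verbatim slices of the adduct coordinates). Optional relaxed fragment
#' geometries feed the preparation-energy term.
#'
#' @param xyz either a path to an XYZ file or a list as returned by
#'   [read_xyz()].
#' @param fragments fragment specification string (see
#'   [parse_fragment_spec()]) or a list of two integer index vectors.
#' @param charges integer vector of two fragment charges.
#' @param mults integer vector of two fragment multiplicities.
#' @param charge,multiplicity adduct charge (default: sum of fragment
#'   charges) and multiplicity.
#' @param relaxed optional list of up to two [nocv_species()] (or `NULL`
#'   entries) with the relaxed fragment geometries.
#' @param spin_orientation for two open-shell fragments coupled to a
#'   lower-multiplicity adduct: `"ab"` (default) gives fragment A the excess
#'   alpha and fragment B the excess beta electrons; `"aa"` aligns both.
#' @return an object of class `nocv_system`.
#' @export
build_system <- function(xyz, fragments, charges = c(0L, 0L),
                         mults = c(1L, 1L), charge = sum(charges),
                         multiplicity = NULL, relaxed = NULL,
                         spin_orientation = c("ab", "aa")) {
  spin_orientation <- match.arg(spin_orientation)
  if (is.character(xyz)) xyz <- read_xyz(xyz)
  nat <- length(xyz$symbols)
  if (is.character(fragments)) fragments <- parse_fragment_spec(fragments, nat)
  stopifnot(length(fragments) == 2)
  idxA <- as.integer(fragments[[1]]); idxB <- as.integer(fragments[[2]])
  if (anyDuplicated(c(idxA, idxB)) || length(c(idxA, idxB)) != nat ||
      !setequal(c(idxA, idxB), seq_len(nat)))
    stop("fragment partition must cover all adduct atoms exactly once")
  # spin bookkeeping: excess alpha of A and excess beta of B (default) must
  # combine to the adduct's unpaired count
  upA <- mults[1] - 1L; upB <- mults[2] - 1L
  unpaired <- if (spin_orientation == "ab") abs(upA - upB) else upA + upB
  if (is.null(multiplicity)) multiplicity <- unpaired + 1L
  if (multiplicity - 1L != unpaired)
    stop("adduct multiplicity ", multiplicity,
         " inconsistent with fragment multiplicities ", mults[1], "/",
         mults[2], " under spin orientation '", spin_orientation, "'")
  adduct <- nocv_species(xyz$symbols, xyz$coords, charge, multiplicity)
  fragA <- nocv_species(xyz$symbols[idxA], xyz$coords[idxA, , drop = FALSE],
                        charges[1], mults[1])
  fragB <- nocv_species(xyz$symbols[idxB], xyz$coords[idxB, , drop = FALSE],
                        charges[2], mults[2])
  if (charge != charges[1] + charges[2])
    stop("fragment charges do not sum to the adduct charge")
  # B carries excess beta by convention: swap its alpha/beta counts
  if (spin_orientation == "ab" && upB > 0) {
    tmp <- fragB$nalpha; fragB$nalpha <- fragB$nbeta; fragB$nbeta <- tmp
  }
  if (adduct$nalpha != fragA$nalpha + fragB$nalpha ||
      adduct$nbeta != fragA$nbeta + fragB$nbeta)
    stop("per-spin electron counts of the fragments do not match the adduct")
  if (!is.null(relaxed)) {
    stopifnot(is.list(relaxed), length(relaxed) <= 2)
    for (k in seq_along(relaxed)) {
      rg <- relaxed[[k]]
      if (is.null(rg)) next
      stopifnot(inherits(rg, "nocv_species"))
      ref <- if (k == 1) fragA else fragB
      if (!identical(rg$Z, ref$Z))
        stop("relaxed geometry ", k, " has different atoms than fragment ",
             c("A", "B")[k])
    }
  }
  structure(list(adduct = adduct, fragA = fragA, fragB = fragB,
                 idxA = idxA, idxB = idxB, relaxed = relaxed),
            class = "nocv_system")
}

#' @export
print.nocv_system <- function(x, ...) {
  cat(sprintf(
    "<nocv_system> %d atoms; A: %d atoms (charge %+d, mult %d); B: %d atoms (charge %+d, mult %d)\n",
    length(x$adduct$Z), length(x$fragA$Z), x$fragA$charge,
    x$fragA$multiplicity, length(x$fragB$Z), x$fragB$charge,
    x$fragB$multiplicity))
  invisible(x)
}

#' AO index embedding of the fragments into the supermolecule
#'
#' Maps each fragment AO index to its supermolecule AO index. The maps are
#' injective with disjoint images covering all supermolecule AOs.
#'
#' @param system a [nocv_system()].
#' @param ints supermolecule [system_integrals()] (provides the AO-to-atom
#'   map).
#' @return list with integer vectors `A` and `B` and the three AO dimensions.
#' @export
ao_embedding <- function(system, ints) {
  atom_of_ao <- ints$basis$atom_of_ao
  embA <- unlist(lapply(system$idxA, function(ia) which(atom_of_ao == ia)))
  embB <- unlist(lapply(system$idxB, function(ia) which(atom_of_ao == ia)))
  stopifnot(length(intersect(embA, embB)) == 0,
            length(c(embA, embB)) == ints$n)
  list(A = as.integer(embA), B = as.integer(embB),
       nA = length(embA), nB = length(embB), n = ints$n)
}

#' Zero-pad a fragment matrix into supermolecule dimensions
#'
#' @param M square matrix of the fragment's AO dimension.
#' @param emb integer vector mapping fragment AO index to supermolecule AO
#'   index (one component of [ao_embedding()]).
#' @param n supermolecule AO dimension.
#' @return `n x n` matrix with `M` in the embedded block, zero elsewhere.
#' @export
embed_matrix <- function(M, emb, n) {
  M <- as.matrix(M)
  if (nrow(M) != length(emb) || ncol(M) != length(emb))
    stop("matrix dimension ", nrow(M), " does not match embedding length ",
         length(emb))
  out <- matrix(0, n, n)
  out[emb, emb] <- M
  out
}

# Zero-pad fragment orbital coefficient columns.
embed_columns <- function(C, emb, n) {
  out <- matrix(0, n, ncol(C))
  out[emb, ] <- C
  out
}
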