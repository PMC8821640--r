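#' Build a straight filament model from monomers
#'
#' Places `n` subunits (indices 0..n-1) by applying the lattice screw
#' operator for each index to the reference monomer of that subunit's
#' species. Subunit i's coordinates are exactly
#' `apply_screw(screw_operator(sym, i), monomer)`, so the model is straight
#' and perfectly symmetric by construction.
#'
#' @param monomers list of [monomer_model()] objects, one per species, in
#'   species order (species 0 first); or a single monomer for one-species
#'   filaments.
#' @param sym a [helical_symmetry()].
#' @param lab a [subunit_labeling()].
#' @param n number of subunits (>= 1).
#' @return object of class `filament_model`: fields `sym`, `labeling`,
#'   `monomers` and `subunits` (list of per-subunit records with `index`,
#'   `species`, `op` and transformed `atoms`).
#' @examples
#' cfg <- fixture_config()
#' m <- lapply(0:1, function(s) make_toy_monomer(cfg, s))
#' lab <- labeling_from_register(register_pattern(3, 2, c(0, 0, 1)))
#' fil <- build_filament(m, helical_symmetry(5.57, 108), lab, 12)
#' @export
build_filament <- function(monomers, sym, lab, n) {
  if (inherits(monomers, "monomer_model")) monomers <- list(monomers)
  stopifnot(is_helical_symmetry(sym), inherits(lab, "subunit_labeling"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("build_filament: n must be an integer >= 1", call. = FALSE)
  n <- as.integer(n)
  sp <- species_at(lab, 0:(n - 1L))
  used <- sort(unique(sp))
  if (max(used) + 1L > length(monomers))
    stop("build_filament: no monomer supplied for species ",
         paste(setdiff(used, seq_along(monomers) - 1L), collapse = ", "),
         call. = FALSE)
  subunits <- vector("list", n)
  for (i in seq_len(n)) {
    mono <- monomers[[sp[i] + 1L]]
    op <- screw_operator(sym, i - 1L)
    atoms <- mono$atoms
    atoms[c("x", "y", "z")] <- apply_screw(op, coords_of(mono))
    subunits[[i]] <- list(index = i - 1L, species = sp[i], op = op,
                          atoms = atoms)
  }
  structure(list(sym = sym, labeling = lab, monomers = monomers,
                 subunits = subunits),
            class = "filament_model")
}

#' @export
print.filament_model <- function(x, ...) {
  n <- length(x$subunits)
  cat(sprintf("Filament model: %d subunits, %d species, rise %s A, twist %s deg%s\n",
              n, length(x$monomers), format(signif(x$sym$rise, 6)),
              format(signif(x$sym$twist, 4)),
              if (isTRUE(attr(x, "bent"))) " [bent]" else ""))
  invisible(x)
}

n_subunits <- function(model) length(model$subunits)

subunit_atoms <- function(model, index) {
  # index is the 0-based subunit index
  if (index < 0 || index >= n_subunits(model))
    stop("subunit index ", index, " out of range", call. = FALSE)
  model$subunits[[index + 1L]]$atoms
}

subunit_xyz <- function(model, index)
  as.matrix(subunit_atoms(model, index)[c("x", "y", "z")])

all_atoms <- function(model) {
  do.call(rbind, lapply(model$subunits, function(s) {
    cbind(s$atoms, subunit = s$index, species = s$species)
  }))
}

#' Filament diameter
#'
#' Twice the maximum radial distance of any atom from the filament axis
#' (+z through the origin).
#'
#' @param model a [filament_model()].
#' @return diameter in Angstrom.
#' @export
filament_diameter <- function(model) {
  stopifnot(inherits(model, "filament_model"))
  2 * sqrt(max(vapply(model$subunits, function(s)
    max(s$atoms$x^2 + s$atoms$y^2), 0)))
}

# chain id pool for PDB output (62 single characters)
.pdb_chain_pool <- c(LETTERS, letters, as.character(0:9))

#' Write a filament model to mmCIF or PDB
#'
#' Every subunit receives a distinct chain identifier: `S0001`, `S0002`, ...
#' in mmCIF, or single characters (A-Z, a-z, 0-9) in PDB. PDB output is
#' limited to 62 subunits by the single-character chain field; larger models
#' must use mmCIF. Coordinates are written at 0.001 Angstrom precision.
#'
#' @param model a [filament_model()].
#' @param path output path.
#' @param format `"mmcif"` (default) or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("mmcif", "pdb")) {
  stopifnot(inherits(model, "filament_model"))
  format <- match.arg(format)
  n <- n_subunits(model)
  if (format == "pdb") {
    if (n > 62L)
      stop("write_structure: PDB chain identifiers are single characters; ",
           n, " subunits exceed the 62 available ids -- write mmCIF instead",
           call. = FALSE)
    at <- all_atoms(model)
    chain <- .pdb_chain_pool[at$subunit + 1L]
    bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
                       at[c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(at)), resno = at$resno,
                     resid = at$resid, chain = chain, elety = at$atom,
                     elesy = at$element)
  } else {
    at <- all_atoms(model)
    at$chain <- sprintf("S%04d", at$subunit + 1L)
    write_mmcif_atoms(at, path)
  }
  invisible(path)
}

#' Read a structure file into a plain atom table
#'
#' @param path `.pdb`, `.cif` or `.mmcif` file.
#' @return data.frame with columns `atom`, `element`, `resid`, `resno`,
#'   `chain`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) read_structure_atoms(path)
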