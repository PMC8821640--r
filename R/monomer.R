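#' Domain annotation of an archaellin-like chain
#'
#' Archaellins (and type-IV pilins generally) split into an N-terminal
#' alpha-helical tail, a short hinge and a globular head. Ranges are given in
#' mature-protein residue numbering, must be disjoint, ordered tail < hinge <
#' head and must jointly cover the chain.
#'
#' @param tail integer range `c(first, last)` of tail residues
#'   (archaellum default: 14-59).
#' @param hinge integer range of hinge residues (default 60-61, the
#'   conserved Ser-Gly linker).
#' @param head integer range of head residues (62 to the chain end).
#' @return object of class `domain_annotation`.
#' @examples
#' domain_annotation(c(14, 59), c(60, 61), c(62, 120))
#' @export
domain_annotation <- function(tail, hinge, head) {
  chk <- function(r, nm) {
    if (length(r) != 2L || any(r != round(r)) || r[1] > r[2])
      stop("domain_annotation: ", nm, " must be an ordered integer range",
           call. = FALSE)
    as.integer(r)
  }
  tail <- chk(tail, "tail"); hinge <- chk(hinge, "hinge"); head <- chk(head, "head")
  if (!(tail[2] < hinge[1] && hinge[2] < head[1]))
    stop("domain_annotation: ranges must be disjoint and ordered tail < hinge < head",
         call. = FALSE)
  if (hinge[1] != tail[2] + 1L || head[1] != hinge[2] + 1L)
    stop("domain_annotation: ranges must cover the chain without gaps",
         call. = FALSE)
  structure(list(tail = tail, hinge = hinge, head = head),
            class = "domain_annotation")
}

# which domain does each residue number fall in
domain_of <- function(annotation, resno) {
  out <- rep(NA_character_, length(resno))
  out[resno >= annotation$tail[1] & resno <= annotation$tail[2]] <- "tail"
  out[resno >= annotation$hinge[1] & resno <= annotation$hinge[2]] <- "hinge"
  out[resno >= annotation$head[1]] <- "head"
  out
}

#' Construct a monomer model
#'
#' A light-weight atomic (or pseudo-atomic) model of one subunit: a table of
#' atom records plus a species id and an optional domain annotation.
#'
#' @param atoms data.frame with columns `atom` (atom name), `element`,
#'   `resid` (residue name), `resno` (residue number), `x`, `y`, `z`
#'   (Angstrom). Residue numbers must be non-decreasing and coordinates
#'   finite.
#' @param species integer species id (0-based).
#' @param annotation optional [domain_annotation()].
#' @return object of class `monomer_model`.
#' @export
monomer_model <- function(atoms, species = 0L, annotation = NULL) {
  need <- c("atom", "element", "resid", "resno", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("monomer_model: atoms needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  atoms <- atoms[need]
  if (is.unsorted(atoms$resno))
    stop("monomer_model: residue numbers must be non-decreasing", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("monomer_model: coordinates must be finite", call. = FALSE)
  if (!is.null(annotation)) stopifnot(inherits(annotation, "domain_annotation"))
  structure(list(atoms = atoms, species = as.integer(species),
                 annotation = annotation),
            class = "monomer_model")
}

#' @export
print.monomer_model <- function(x, ...) {
  cat(sprintf("Monomer model: species %d, %d atoms, residues %d-%d\n",
              x$species, nrow(x$atoms), min(x$atoms$resno), max(x$atoms$resno)))
  if (!is.null(x$annotation))
    cat(sprintf("  domains: tail %d-%d, hinge %d-%d, head %d-%d\n",
                x$annotation$tail[1], x$annotation$tail[2],
                x$annotation$hinge[1], x$annotation$hinge[2],
                x$annotation$head[1], x$annotation$head[2]))
  invisible(x)
}

coords_of <- function(m) as.matrix(m$atoms[c("x", "y", "z")])

#' Read a monomer from a structure file
#'
#' Reads PDB (via bio3d) or mmCIF (minimal `_atom_site` parser) into a
#' [monomer_model()]. When `tail` and `hinge` ranges are given, the head is
#' taken as everything after the hinge through the last residue.
#'
#' @param path file path, ending in `.pdb`, `.cif` or `.mmcif`.
#' @param species integer species id.
#' @param tail,hinge optional integer ranges; see [domain_annotation()].
#' @return a [monomer_model()].
#' @export
read_monomer <- function(path, species = 0L, tail = NULL, hinge = NULL) {
  atoms <- read_structure_atoms(path)
  ann <- NULL
  if (!is.null(tail) && !is.null(hinge))
    ann <- domain_annotation(tail, hinge, c(hinge[2] + 1L, max(atoms$resno)))
  monomer_model(atoms[setdiff(names(atoms), "chain")], species, ann)
}

#' Find N-glycosylation sequons (N-X-S/T)
#'
#' Scans an amino-acid sequence for the canonical N-glycosylation consensus
#' motif: an asparagine followed by any residue followed by serine or
#' threonine. Overlapping motifs are all reported (e.g. the NNTT motif
#' carries sequons at both asparagines). Optionally X = proline is excluded,
#' as proline at the middle position is generally not glycosylated.
#'
#' @param sequence single amino-acid string over the 20-letter alphabet
#'   (case-insensitive).
#' @param exclude_proline if TRUE, motifs with proline at the X position are
#'   skipped.
#' @return integer vector of 1-based positions of qualifying asparagines.
#' @examples
#' find_sequons("ANNTTA")  # 2 3
#' find_sequons("ANPTA", exclude_proline = TRUE)  # none
#' @export
find_sequons <- function(sequence, exclude_proline = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("find_sequons: sequence must be a single string", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad) > 0L)
    stop("find_sequons: invalid amino-acid code(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  n <- length(aa)
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  hit <- aa[i] == "N" & aa[i + 2L] %in% c("S", "T")
  if (exclude_proline) hit <- hit & aa[i + 1L] != "P"
  i[hit]
}

#' Scan FASTA sequences for sequons
#'
#' @param path FASTA file of protein sequences.
#' @param exclude_proline see [find_sequons()].
#' @return named list of integer position vectors, one per record.
#' @export
find_sequons_fasta <- function(path, exclude_proline = FALSE) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  out <- lapply(seqs, function(s) find_sequons(as.character(s), exclude_proline))
  stats::setNames(out, names(seqs))
}
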