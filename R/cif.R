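# Minimal mmCIF _atom_site I/O.
#
# Only the atom_site loop is read/written; columns are located by their
# header names, so field order is irrelevant on input. Values written here
# never contain whitespace or quotes, which keeps the tokenizer a plain
# whitespace split. Multi-character asym ids (S0001, ...) are fully
# supported -- the reason this package does not route mmCIF through a PDB
# reader with single-character chain fields.

write_mmcif_atoms <- function(atoms, path, block = "model") {
  # atoms: data.frame with atom, element, resid, resno, chain, x, y, z
  n <- nrow(atoms)
  hdr <- c("data_" %+% block, "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d %.3f %.3f %.3f 1.00 0.00 %d %s 1",
                  seq_len(n), atoms$element, atoms$atom, atoms$resid,
                  atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
                  atoms$resno, atoms$chain)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)

read_mmcif_atoms <- function(path) {
  ln <- readLines(path, warn = FALSE)
  # locate the atom_site loop: contiguous _atom_site.* headers after a loop_
  hdr_idx <- grep("^_atom_site\\.", ln)
  if (length(hdr_idx) == 0L)
    stop("read_mmcif_atoms: no _atom_site loop in ", path, call. = FALSE)
  cols <- sub("^_atom_site\\.", "", trimws(ln[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in body_start:length(ln)) {
    l <- trimws(ln[i])
    if (!nzchar(l)) next
    if (grepl("^(#|loop_|data_|_)", l)) break
    body <- c(body, l)
  }
  if (length(body) == 0L)
    stop("read_mmcif_atoms: empty _atom_site loop in ", path, call. = FALSE)
  tok <- strsplit(body, "[ \t]+")
  nf <- lengths(tok)
  if (any(nf != length(cols)))
    stop("read_mmcif_atoms: malformed atom_site row at data line ",
         which(nf != length(cols))[1], " of ", path, call. = FALSE)
  m <- do.call(rbind, tok)
  colnames(m) <- cols
  getcol <- function(nm, alt = NULL) {
    if (nm %in% cols) return(m[, nm])
    if (!is.null(alt) && alt %in% cols) return(m[, alt])
    stop("read_mmcif_atoms: missing _atom_site.", nm, " in ", path,
         call. = FALSE)
  }
  data.frame(atom = getcol("label_atom_id"),
             element = getcol("type_symbol"),
             resid = getcol("label_comp_id"),
             resno = as.integer(getcol("auth_seq_id", "label_seq_id")),
             chain = getcol("auth_asym_id", "label_asym_id"),
             x = as.numeric(getcol("Cartn_x")),
             y = as.numeric(getcol("Cartn_y")),
             z = as.numeric(getcol("Cartn_z")))
}

# read any supported structure file into a plain atom table
read_structure_atoms <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return(read_mmcif_atoms(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    return(data.frame(atom = a$elety, element = a$elesy, resid = a$resid,
                      resno = a$resno, chain = a$chain,
                      x = a$x, y = a$y, z = a$z))
  }
  stop("read_structure_atoms: unsupported format '", ext,
       "' (use .pdb, .cif or .mmcif)", call. = FALSE)
}
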