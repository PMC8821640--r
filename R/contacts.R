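#' Contact criteria
#'
#' Distance cutoffs for geometric contact detection. Hydrogen bonds are
#' counted as donor/acceptor N/O heavy-atom pairs within `hbond_max`; salt
#' bridges as basic nitrogen to carboxyl oxygen pairs within
#' `saltbridge_max`; tail-core contacts as tail centre-line segments passing
#' within `tail_segment_cutoff` of each other. All criteria are
#' distance-only (no angle terms): the counts are geometric tallies, not
#' interface energetics.
#'
#' @param hbond_max donor-acceptor heavy-atom cutoff, Angstrom (default 3.5).
#' @param saltbridge_max charged-group N to carboxyl-O cutoff (default 4.0).
#' @param tail_segment_cutoff tail centre-line distance cutoff (default 8.0).
#' @return object of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_max = 3.5, saltbridge_max = 4.0,
                             tail_segment_cutoff = 8.0) {
  v <- c(hbond_max, saltbridge_max, tail_segment_cutoff)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("contact_criteria: all cutoffs must be positive", call. = FALSE)
  structure(list(hbond_max = hbond_max, saltbridge_max = saltbridge_max,
                 tail_segment_cutoff = tail_segment_cutoff),
            class = "contact_criteria")
}

# residue chemistry tables: which heavy atoms can donate/accept H-bonds,
# and which carry formal charge for salt bridges
.hb_donors <- list(ANY = "N", SER = "OG", THR = "OG1", TYR = "OH",
                   LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"), ASN = "ND2", GLN = "NE2",
                   TRP = "NE1")
.hb_acceptors <- list(ANY = c("O", "OXT"), ASP = c("OD1", "OD2"),
                      GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
                      SER = "OG", THR = "OG1", TYR = "OH",
                      HIS = c("ND1", "NE2"))
.sb_basic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))
.sb_acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

in_chem_table <- function(tab, resid, atom) {
  hit <- atom %in% tab[["ANY"]]
  for (r in setdiff(names(tab), "ANY"))
    hit <- hit | (resid == r & atom %in% tab[[r]])
  hit
}

as_atom_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && !is.null(x$atoms)) return(x$atoms)
  stop("expected an atom table, monomer_model or placed subunit", call. = FALSE)
}

#' Polar contacts between two placed subunits
#'
#' Counts hydrogen bonds (N/O donor to N/O acceptor heavy-atom pairs within
#' the cutoff, roles assigned from a residue chemistry table) and salt
#' bridges (Lys NZ / Arg NE,NH1,NH2 / His ND1,NE2 to Asp/Glu carboxyl
#' oxygens within the cutoff). A charged pair inside both cutoffs appears in
#' both tallies.
#'
#' @param subA,subB atom tables (or objects carrying `$atoms`) with columns
#'   `atom`, `element`, `resid`, `resno`, `x`, `y`, `z`.
#' @param criteria a [contact_criteria()].
#' @return list with `n_hbond`, `n_saltbridge` and `contacts`, a data.frame
#'   (type, atom_a, resid_a, resno_a, atom_b, resid_b, resno_b, dist,
#'   direction) in deterministic row order. Directions record which subunit
#'   donates: "A->B", "B->A" or "both".
#' @export
polar_contacts <- function(subA, subB, criteria = contact_criteria()) {
  stopifnot(inherits(criteria, "contact_criteria"))
  A <- as_atom_table(subA); B <- as_atom_table(subB)
  for (tb in list(A, B))
    if (is.null(tb$element) || any(is.na(tb$element) | tb$element == ""))
      stop("polar_contacts: element annotation missing", call. = FALSE)
  cutoff <- max(criteria$hbond_max, criteria$saltbridge_max)
  # restrict to polar/charged heavy atoms before the distance scan
  keepA <- A$element %in% c("N", "O"); keepB <- B$element %in% c("N", "O")
  ia <- which(keepA); ib <- which(keepB)
  pr <- close_atom_pairs(as.matrix(A[ia, c("x", "y", "z")]),
                         as.matrix(B[ib, c("x", "y", "z")]), cutoff)
  rows <- list()
  if (nrow(pr) > 0L) {
    a <- ia[pr[, 1]]; b <- ib[pr[, 2]]; d <- pr[, 3]
    donA <- in_chem_table(.hb_donors, A$resid[a], A$atom[a])
    accA <- in_chem_table(.hb_acceptors, A$resid[a], A$atom[a])
    donB <- in_chem_table(.hb_donors, B$resid[b], B$atom[b])
    accB <- in_chem_table(.hb_acceptors, B$resid[b], B$atom[b])
    hb <- d <= criteria$hbond_max & ((donA & accB) | (donB & accA))
    dir <- ifelse(donA & accB & donB & accA, "both",
                  ifelse(donA & accB, "A->B", "B->A"))
    basA <- in_chem_table(.sb_basic, A$resid[a], A$atom[a])
    acdA <- in_chem_table(.sb_acidic, A$resid[a], A$atom[a])
    basB <- in_chem_table(.sb_basic, B$resid[b], B$atom[b])
    acdB <- in_chem_table(.sb_acidic, B$resid[b], B$atom[b])
    sb <- d <= criteria$saltbridge_max & ((basA & acdB) | (basB & acdA))
    mk <- function(sel, type) {
      if (!any(sel)) return(NULL)
      data.frame(type = type, atom_a = A$atom[a[sel]],
                 resid_a = A$resid[a[sel]], resno_a = A$resno[a[sel]],
                 atom_b = B$atom[b[sel]], resid_b = B$resid[b[sel]],
                 resno_b = B$resno[b[sel]], dist = d[sel],
                 direction = ifelse(rep(type == "hbond", sum(sel)),
                                    dir[sel], ""))
    }
    rows <- list(mk(hb, "hbond"), mk(sb, "saltbridge"))
  }
  contacts <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(contacts))
    contacts <- data.frame(type = character(0), atom_a = character(0),
                           resid_a = character(0), resno_a = integer(0),
                           atom_b = character(0), resid_b = character(0),
                           resno_b = integer(0), dist = numeric(0),
                           direction = character(0))
  contacts <- contacts[order(contacts$type, contacts$resno_a, contacts$atom_a,
                             contacts$resno_b, contacts$atom_b), ]
  rownames(contacts) <- NULL
  list(n_hbond = sum(contacts$type == "hbond"),
       n_saltbridge = sum(contacts$type == "saltbridge"),
       contacts = contacts)
}

# all cross pairs within cutoff, via a cell-list spatial hash.
# returns matrix with columns (i, j, dist); i indexes A rows, j B rows.
close_atom_pairs <- function(A, B, cutoff) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "dist"))))
  cell <- function(m) floor(m / cutoff)
  cb <- cell(B)
  keyB <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_len(nB), keyB)
  ca <- cell(A)
  out <- vector("list", nA)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nA)) {
    keys <- paste(ca[i, 1] + off[, 1], ca[i, 2] + off[, 2], ca[i, 3] + off[, 3])
    js <- unlist(bmap[keys], use.names = FALSE)
    if (length(js) == 0L) next
    d2 <- (B[js, 1] - A[i, 1])^2 + (B[js, 2] - A[i, 2])^2 +
      (B[js, 3] - A[i, 3])^2
    sel <- d2 <= cutoff^2
    if (any(sel))
      out[[i]] <- cbind(i = i, j = js[sel], dist = sqrt(d2[sel]))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "dist"))))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# O(nA * nB) reference implementation of close_atom_pairs (oracle)
close_atom_pairs_brute <- function(A, B, cutoff) {
  out <- list()
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
                (B[, 3] - A[i, 3])^2)
    sel <- which(d <= cutoff)
    if (length(sel))
      out[[length(out) + 1L]] <- cbind(i = i, j = sel, dist = d[sel])
  }
  if (length(out) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "dist"))))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

min_interatomic_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  mn <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    mn <- min(mn, min(d2))
  }
  sqrt(mn)
}

#' Neighbour-offset contact map
#'
#' Tabulates, for every neighbour offset k in [-max_k, max_k] except 0, the
#' ordered species pair, hydrogen-bond and salt-bridge counts, minimal
#' inter-atomic distance and whether the two tail centre-lines are in
#' contact. For a straight filament the map is identical for every interior
#' reference subunit (screw symmetry).
#'
#' @param model a [filament_model()].
#' @param reference 0-based index of the reference subunit; must have at
#'   least `max_k` neighbours on each side.
#' @param max_k largest offset magnitude.
#' @param criteria a [contact_criteria()].
#' @return data.frame of class `contact_report` with columns `k`,
#'   `species_ref`, `species_nbr`, `n_hbond`, `n_saltbridge`, `min_dist`,
#'   `tail_contact`. Attribute `note` states that counts are geometric, not
#'   PISA energetics.
#' @export
neighbor_contact_map <- function(model, reference, max_k = 10,
                                 criteria = contact_criteria()) {
  stopifnot(inherits(model, "filament_model"))
  n <- n_subunits(model)
  if (reference - max_k < 0 || reference + max_k > n - 1L)
    stop("neighbor_contact_map: reference subunit ", reference,
         " has fewer than ", max_k, " neighbours on one side", call. = FALSE)
  tails <- tail_core_contacts(model, reference, criteria, max_k = max_k)
  ks <- setdiff(-max_k:max_k, 0L)
  refA <- subunit_atoms(model, reference)
  sp <- vapply(model$subunits, function(s) s$species, 0L)
  rows <- lapply(ks, function(k) {
    nbr <- subunit_atoms(model, reference + k)
    pc <- polar_contacts(refA, nbr, criteria)
    data.frame(k = k, species_ref = sp[reference + 1L],
               species_nbr = sp[reference + k + 1L],
               n_hbond = pc$n_hbond, n_saltbridge = pc$n_saltbridge,
               min_dist = min_interatomic_distance(
                 refA[c("x", "y", "z")], nbr[c("x", "y", "z")]),
               tail_contact = k %in% tails)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contact_report", "data.frame")
  attr(out, "note") <- paste("Counts are geometric distance-cutoff tallies,",
                             "not PISA interface energetics.")
  out
}

#' Write a contact report as TSV
#'
#' @param report a [neighbor_contact_map()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_report <- function(report, path) {
  stopifnot(inherits(report, "contact_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", attr(report, "note")), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# least-squares line through points, clipped to the data extent.
# returns list(p1, p2): segment endpoints
fit_segment <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  axis <- sv$v[, 1]
  t <- as.numeric(sweep(xyz, 2, ctr) %*% axis)
  list(p1 = ctr + min(t) * axis, p2 = ctr + max(t) * axis)
}

# minimal distance between two finite segments
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-12 && e < 1e-12) return(sqrt(sum(r * r)))
  if (a < 1e-12) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e < 1e-12) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-12) min(max((b * f - c1 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (q1 + t * d2)
  sqrt(sum(v * v))
}

#' Tail-core contact shell
#'
#' Offsets k whose tail centre-line segment (least-squares axis of the tail
#' atoms, as a finite segment) passes within the tail cutoff of the
#' reference subunit's tail segment. In the filament core the hydrophobic
#' tails interdigitate; on the packaged archaellum-like fixture this shell
#' is exactly {-7, -4, -3, -1, 1, 3, 4, 7}.
#'
#' @param model a [filament_model()] whose monomers carry a
#'   [domain_annotation()].
#' @param reference 0-based reference subunit index.
#' @param criteria a [contact_criteria()].
#' @param max_k largest offset magnitude scanned.
#' @return sorted integer vector of offsets in contact.
#' @export
tail_core_contacts <- function(model, reference, criteria = contact_criteria(),
                               max_k = 10) {
  stopifnot(inherits(model, "filament_model"))
  n <- n_subunits(model)
  if (reference < 0 || reference > n - 1L)
    stop("tail_core_contacts: reference out of range", call. = FALSE)
  seg_of <- function(idx) {
    sub <- model$subunits[[idx + 1L]]
    ann <- model$monomers[[sub$species + 1L]]$annotation
    if (is.null(ann))
      stop("tail_core_contacts: monomer for species ", sub$species,
           " has no domain annotation", call. = FALSE)
    sel <- sub$atoms$resno >= ann$tail[1] & sub$atoms$resno <= ann$tail[2]
    if (!any(sel))
      stop("tail_core_contacts: no tail atoms on subunit ", idx, call. = FALSE)
    fit_segment(sub$atoms[sel, c("x", "y", "z")])
  }
  ref_seg <- seg_of(reference)
  ks <- setdiff(-max_k:max_k, 0L)
  ks <- ks[reference + ks >= 0L & reference + ks <= n - 1L]
  hit <- vapply(ks, function(k) {
    s <- seg_of(reference + k)
    segment_distance(ref_seg$p1, ref_seg$p2, s$p1, s$p2) <=
      criteria$tail_segment_cutoff
  }, TRUE)
  sort(ks[hit])
}
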